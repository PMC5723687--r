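#' Simulation configuration for a synthetic inflammatory-aging study
#'
#' Builds the configuration object consumed by [generate_cohort()] and the
#' other `generate_*()` functions. Defaults emulate the structure of a
#' community-based family cohort with nine inflammatory biomarkers: a latent
#' biologic age `BA_true = age + delta` with `delta ~ N(0, delta_sd^2)`
#' independent of chronologic age; biomarkers linear in `BA_true` with noise
#' calibrated so realized biomarker-age correlations approximate
#' `biomarker_age_r` (seven of nine clearly age-correlated); one designated
#' biomarker pair sharing an extra latent factor so its cross-correlation
#' reaches `high_cor_r` (the CRP/IL-6 analog); a minority of expression
#' features truly associated with `delta` with a roughly 2:1 positive:negative
#' sign split; CpGs partially mediating a subset of those genes; family
#' clustering; and mortality whose hazard increases with the latent score.
#'
#' @param n_subjects,n_families cohort size and number of families.
#' @param age_range numeric length-2, chronologic age drawn uniformly (years).
#' @param n_biomarkers number of biomarkers (panel names used when 9).
#' @param biomarker_age_r target biomarker-age Pearson correlations, recycled
#'   or truncated to `n_biomarkers`.
#' @param biomarker_cross_r documented target range for off-diagonal biomarker
#'   correlations (induced by the shared latent age factor; approximate).
#' @param high_cor_pair,high_cor_r indices of the strongly correlated
#'   biomarker pair and its target correlation.
#' @param delta_sd SD of the latent age offset `delta`, years.
#' @param biomarker_noise_scale multiplier on all biomarker noise terms; 0
#'   makes every biomarker an exact affine function of `BA_true`.
#' @param n_genes,n_true_genes expression features and truly associated ones.
#' @param frac_positive fraction of true effects that are positive.
#' @param effect_size_sd scale of true effects, expression units per year of
#'   delta age; magnitudes are `effect_size_sd * U(0.5, 1.5)`. The default is
#'   calibrated (once, by simulation) so that planted genes are detectable at
#'   a transcriptome-scale Bonferroni threshold through the *estimated* delta
#'   age, whose correlation with the latent delta is well below 1; see the
#'   methods vignette.
#' @param expr_noise_sd,family_sd residual and family-intercept SD of
#'   expression (log2-scale units).
#' @param n_cpg_per_gene CpGs owned by each gene.
#' @param mediation_fraction fraction of true genes whose effect is partially
#'   CpG-mediated.
#' @param mediation_strength in `[0, 1]`; loading of the mediator CpG latent
#'   on `delta` and the share of the gene's effect routed through it. 0 means
#'   no mediation; 1 with `meth_noise_sd = 0` makes the CpG an exact monotone
#'   transform of `delta`.
#' @param meth_logit_sd,meth_noise_sd signal and measurement SD of the CpG
#'   latent on the logit scale (beta-values are logistic-squashed).
#' @param avg_degree mean degree of the random interaction network.
#' @param planted_cluster_size size of the planted connected cluster of true
#'   genes in the network (0 disables planting).
#' @param planted_density extra edge probability inside the planted cluster.
#' @param n_gene_sets,set_size_range random gene-set collection shape; one
#'   additional set is enriched for true genes.
#' @param baseline_hazard mortality hazard per year at the reference.
#' @param age_log_hr log hazard ratio per year of age.
#' @param score_log_hr log hazard ratio per SD of the latent score.
#' @param follow_up_years administrative censoring horizon, years.
#' @param marginal `"gaussian"` (biomarkers linear in `BA_true`) or
#'   `"lognormal"` (the same latent exponentiated, so the log scale is linear).
#' @param seed integer; single root seed from which each data type derives a
#'   deterministic sub-stream.
#'
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 2000,
                       n_families = 800,
                       age_range = c(50, 85),
                       n_biomarkers = 9,
                       biomarker_age_r = c(0.35, 0.30, 0.30, 0.25, 0.25,
                                           0.20, 0.15, 0.05, 0.02),
                       biomarker_cross_r = c(0.06, 0.27),
                       high_cor_pair = c(1, 3),
                       high_cor_r = 0.52,
                       delta_sd = 7,
                       biomarker_noise_scale = 1,
                       n_genes = 1000,
                       n_true_genes = 50,
                       frac_positive = 2 / 3,
                       effect_size_sd = 0.08,
                       expr_noise_sd = 1,
                       family_sd = 0.3,
                       n_cpg_per_gene = 3,
                       mediation_fraction = 0.5,
                       mediation_strength = 0.5,
                       meth_logit_sd = 1,
                       meth_noise_sd = 0.5,
                       avg_degree = 4,
                       planted_cluster_size = 15,
                       planted_density = 0.4,
                       n_gene_sets = 50,
                       set_size_range = c(10, 60),
                       baseline_hazard = 0.015,
                       age_log_hr = 0.08,
                       score_log_hr = log(1.62),
                       follow_up_years = 10,
                       marginal = c("gaussian", "lognormal"),
                       seed = 1L) {
  marginal <- match.arg(marginal)
  biomarker_age_r <- rep_len(biomarker_age_r, n_biomarkers)
  stopifnot(
    n_subjects >= 2, n_families >= 1, n_true_genes <= n_genes,
    frac_positive >= 0, frac_positive <= 1,
    age_range[1] < age_range[2],
    all(abs(biomarker_age_r) < 1), abs(high_cor_r) < 1,
    mediation_strength >= 0, mediation_strength <= 1,
    n_cpg_per_gene >= 1, delta_sd >= 0
  )
  if (planted_cluster_size > n_genes) {
    abort("`planted_cluster_size` exceeds the number of genes in the graph.")
  }
  if (planted_cluster_size > n_true_genes) {
    abort("`planted_cluster_size` exceeds `n_true_genes`; the planted cluster is drawn from true genes.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# deterministic sub-stream per data type; restores the caller's RNG state
with_substream <- function(seed, offset, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed((as.integer(seed) %% 1000003L) * 2011L + as.integer(offset))
  force(code)
}

biomarker_panel_names <- function(m) {
  panel <- c("crp", "icam1", "il6", "lppla2_mass", "lppla2_act",
             "mcp1", "opg", "pselectin", "tnfr2")
  if (m == length(panel)) panel else sprintf("bm%02d", seq_len(m))
}

#' Generate a synthetic cohort with latent biologic age
#'
#' Draws chronologic age uniformly over `config$age_range`, a latent offset
#' `delta ~ N(0, delta_sd^2)` independent of age (so `BA_true = age + delta`),
#' assigns subjects to families, and generates biomarkers linear in `BA_true`
#' with noise variances calibrated against the shared latent factor so the
#' realized biomarker-age correlations approximate `biomarker_age_r`. The
#' designated pair additionally shares a latent factor sized to reach
#' `high_cor_r`. Binary mortality-related covariates (smoking, diabetes,
#' treatment and prevalent-disease flags) and cell-fraction/technical
#' covariates are included. Gene-level ground truth (true genes, signed
#' effects, mediated subset and their mediator latents) is drawn here so that
#' expression and methylation generated later share it.
#'
#' @param config a [sim_config()] object.
#' @return A list with `cohort` (tibble, one row per subject) and `truth`
#'   (list: `true_gene_ids`, `true_effects`, `mediated_gene_ids`, `true_ba`,
#'   `delta`, `score_log_hr`, per-biomarker generating parameters, and the
#'   mediator latent matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, 1L, {
    n <- config$n_subjects
    m <- config$n_biomarkers
    age <- runif(n, config$age_range[1], config$age_range[2])
    delta <- rnorm(n, 0, config$delta_sd)
    ba_true <- age + delta

    sigma_ca2 <- diff(config$age_range)^2 / 12
    v_ba <- sigma_ca2 + config$delta_sd^2
    r <- config$biomarker_age_r
    k <- r / sqrt(sigma_ca2)                    # slope of biomarker on BA_true
    cvec <- numeric(m)
    pr <- config$high_cor_pair
    if (m >= max(pr)) {
      base_cross <- k[pr[1]] * k[pr[2]] * v_ba
      extra <- config$high_cor_r - base_cross
      if (extra > 0) cvec[pr] <- sqrt(extra)
    }
    resid_var <- 1 - k^2 * v_ba - cvec^2
    if (any(resid_var <= 0)) {
      bad <- biomarker_panel_names(m)[which(resid_var <= 0)]
      abort(paste0(
        "Infeasible correlation targets: implied covariance not positive ",
        "definite for biomarker(s) ", paste(bad, collapse = ", "),
        " (check `biomarker_age_r` and the `high_cor_pair` target)."
      ))
    }
    nm <- biomarker_panel_names(m)
    mid <- mean(config$age_range)
    mu <- 2 * seq_len(m)
    f_pair <- rnorm(n)
    ns <- config$biomarker_noise_scale
    bm <- vapply(seq_len(m), function(j) {
      mu[j] + k[j] * (ba_true - mid) +
        ns * (cvec[j] * f_pair + rnorm(n, 0, sqrt(resid_var[j])))
    }, numeric(n))
    colnames(bm) <- nm
    if (config$marginal == "lognormal") bm <- exp(bm / 4)

    family_id <- sprintf("F%04d", sample(rep_len(seq_len(config$n_families), n)))
    cohort <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      family_id = family_id,
      sex = rbinom(n, 1, 0.55),
      age = age,
      smoking = rbinom(n, 1, 0.083),
      diabetes = rbinom(n, 1, 0.17),
      htn_treatment = rbinom(n, 1, 0.49),
      lipid_treatment = rbinom(n, 1, 0.44),
      prev_cvd = rbinom(n, 1, 0.089),
      prev_cancer = rbinom(n, 1, 0.10),
      cell1 = runif(n, 0.1, 0.5),
      cell2 = runif(n, 0.05, 0.3),
      tech1 = rnorm(n)
    )
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(bm))

    gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
    true_ids <- sort(sample(gene_ids, config$n_true_genes))
    n_pos <- round(config$frac_positive * config$n_true_genes)
    signs <- sample(c(rep(1, n_pos), rep(-1, config$n_true_genes - n_pos)))
    effects <- signs * config$effect_size_sd * runif(config$n_true_genes, 0.5, 1.5)
    names(effects) <- true_ids
    n_med <- round(config$mediation_fraction * config$n_true_genes)
    mediated <- sort(sample(true_ids, n_med))
    # unit-variance mediator latent, correlation `mediation_strength` with
    # standardized delta; shared by the gene's expression and its lead CpG
    z <- if (config$delta_sd > 0) delta / config$delta_sd else rep(0, n)
    ms <- config$mediation_strength
    latents <- matrix(rnorm(n_med * n), nrow = n_med, ncol = n)
    if (n_med > 0) {
      latents <- ms * matrix(z, n_med, n, byrow = TRUE) +
        sqrt(1 - ms^2) * latents
    }
    rownames(latents) <- mediated

    truth <- list(
      gene_ids = gene_ids,
      true_gene_ids = true_ids,
      true_effects = effects,
      mediated_gene_ids = mediated,
      mediator_latent = latents,
      true_ba = ba_true,
      delta = delta,
      score_log_hr = config$score_log_hr,
      biomarker_params = tibble::tibble(
        biomarker = nm,
        q = mu - k * mid,
        k = k,
        resid_sd = ns * sqrt(resid_var + cvec^2)
      )
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Generate a synthetic expression matrix
#'
#' Genes-by-subjects matrix of log2-scale expression. True genes carry
#' `effect * ((1 - w) * delta + w * delta_sd * L)` where `L` is the gene's
#' mediator latent and `w = mediation_strength` for mediated genes (0
#' otherwise), plus small sex/cell/technical covariate effects, a per-family
#' random intercept (`family_sd`) and i.i.d. noise (`expr_noise_sd`). Null
#' genes carry no `delta` term.
#'
#' @param cohort,truth from [generate_cohort()].
#' @param config the [sim_config()] used to generate them.
#' @return A numeric matrix `n_genes x n_subjects` with gene ids as row names
#'   and subject ids as column names.
#' @export
generate_expression <- function(cohort, truth, config) {
  stopifnot(nrow(cohort) == config$n_subjects,
            length(truth$delta) == nrow(cohort))
  with_substream(config$seed, 2L, {
    n <- nrow(cohort)
    g <- config$n_genes
    gene_ids <- truth$gene_ids
    delta <- truth$delta

    baseline <- runif(g, 4, 8)
    b_sex <- rnorm(g, 0, 0.1)
    b_cell1 <- rnorm(g, 0, 0.2)
    b_cell2 <- rnorm(g, 0, 0.2)
    b_tech <- rnorm(g, 0, 0.1)

    fam <- factor(cohort$family_id)
    fam_eff <- matrix(rnorm(g * nlevels(fam), 0, config$family_sd), nrow = g)
    signal <- matrix(0, g, n)
    w <- config$mediation_strength
    for (gene in truth$true_gene_ids) {
      i <- match(gene, gene_ids)
      b <- truth$true_effects[[gene]]
      if (gene %in% truth$mediated_gene_ids) {
        L <- truth$mediator_latent[gene, ]
        signal[i, ] <- b * ((1 - w) * delta + w * config$delta_sd * L)
      } else {
        signal[i, ] <- b * delta
      }
    }
    expr <- baseline +
      outer(b_sex, cohort$sex) + outer(b_cell1, cohort$cell1) +
      outer(b_cell2, cohort$cell2) + outer(b_tech, cohort$tech1) +
      fam_eff[, as.integer(fam), drop = FALSE] +
      signal +
      matrix(rnorm(g * n, 0, config$expr_noise_sd), g, n)
    dimnames(expr) <- list(gene_ids, cohort$subject_id)
    expr
  })
}

#' Generate synthetic CpG methylation beta-values and their gene map
#'
#' Each gene owns `n_cpg_per_gene` CpGs. Beta-values are logistic-squashed
#' latent Gaussians, hence always in `[0, 1]`. For mediated genes the first
#' CpG's latent is the same mediator latent that feeds the gene's expression
#' (correlation `mediation_strength` with standardized delta); all other CpGs
#' are pure noise.
#'
#' @inheritParams generate_expression
#' @return A list with `meth` (CpG-by-subject matrix of beta-values) and
#'   `cpg_map` (tibble: `cpg_id`, `gene`, `position`).
#' @export
generate_methylation <- function(cohort, truth, config) {
  stopifnot(nrow(cohort) == config$n_subjects)
  with_substream(config$seed, 3L, {
    n <- nrow(cohort)
    genes <- truth$gene_ids
    k <- config$n_cpg_per_gene
    cpg_map <- tibble::tibble(
      gene = rep(genes, each = k),
      within = rep(seq_len(k), length(genes))
    )
    cpg_map$cpg_id <- sprintf("cg%s_%d", sub("^GENE", "", cpg_map$gene), cpg_map$within)
    cpg_map$position <- seq_len(nrow(cpg_map)) * 1000L
    mu <- rnorm(nrow(cpg_map), 0, 1.5)
    latent <- matrix(rnorm(nrow(cpg_map) * n), nrow = nrow(cpg_map))
    lead <- cpg_map$within == 1 & cpg_map$gene %in% truth$mediated_gene_ids
    if (any(lead)) {
      latent[lead, ] <- truth$mediator_latent[cpg_map$gene[lead], , drop = FALSE]
    }
    meth <- plogis(mu + config$meth_logit_sd * latent +
                     matrix(rnorm(nrow(cpg_map) * n, 0, config$meth_noise_sd),
                            nrow = nrow(cpg_map)))
    dimnames(meth) <- list(cpg_map$cpg_id, cohort$subject_id)
    list(meth = meth, cpg_map = cpg_map[, c("cpg_id", "gene", "position")])
  })
}

#' Generate a random interaction network with a planted true-gene cluster
#'
#' Erdos-Renyi background at mean degree `avg_degree` over all genes, plus a
#' planted connected cluster (random spanning path + extra edges at
#' `planted_density`) over `planted_cluster_size` true genes, so the greedy
#' module search has a recoverable target.
#'
#' @inheritParams generate_expression
#' @return A tibble edge list (`from`, `to`), undirected, deduplicated, no
#'   self-loops, with the planted members in `attr(, "planted")`.
#' @export
generate_network <- function(truth, config) {
  with_substream(config$seed, 4L, {
    genes <- truth$gene_ids
    g <- length(genes)
    if (config$planted_cluster_size > g) {
      abort("Planted cluster larger than the graph.")
    }
    n_edges <- round(config$avg_degree * g / 2)
    from <- sample.int(g, 2 * n_edges, replace = TRUE)
    to <- sample.int(g, 2 * n_edges, replace = TRUE)
    keep <- from != to
    e <- unique(cbind(pmin(from[keep], to[keep]), pmax(from[keep], to[keep])))
    e <- e[seq_len(min(n_edges, nrow(e))), , drop = FALSE]

    planted <- character(0)
    if (config$planted_cluster_size >= 2) {
      planted <- sample(truth$true_gene_ids, config$planted_cluster_size)
      pid <- match(planted, genes)
      chain <- cbind(pid[-length(pid)], pid[-1])
      pairs <- utils::combn(pid, 2)
      extra <- pairs[, runif(ncol(pairs)) < config$planted_density, drop = FALSE]
      e <- rbind(e, cbind(pmin(chain[, 1], chain[, 2]), pmax(chain[, 1], chain[, 2])),
                 cbind(pmin(extra[1, ], extra[2, ]), pmax(extra[1, ], extra[2, ])))
    } else if (config$planted_cluster_size == 1) {
      planted <- sample(truth$true_gene_ids, 1)
    }
    e <- unique(e[e[, 1] != e[, 2], , drop = FALSE])
    edges <- tibble::tibble(from = genes[e[, 1]], to = genes[e[, 2]])
    edges <- dplyr::arrange(edges, .data$from, .data$to)
    attr(edges, "planted") <- sort(planted)
    edges
  })
}

#' Generate a random gene-set collection with one planted enriched set
#'
#' @inheritParams generate_expression
#' @return A named list of character vectors (class `"gene_set_collection"`);
#'   the set `"PLANTED_SET"` contains every true gene plus random fill.
#' @export
generate_genesets <- function(truth, config) {
  with_substream(config$seed, 5L, {
    genes <- truth$gene_ids
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_gene_sets, replace = TRUE)
    sets <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(sets) <- sprintf("PATHWAY_%03d", seq_along(sets))
    fill <- sample(setdiff(genes, truth$true_gene_ids),
                   min(length(truth$true_gene_ids),
                       length(genes) - length(truth$true_gene_ids)))
    sets$PLANTED_SET <- sort(c(truth$true_gene_ids, fill))
    structure(sets, class = "gene_set_collection")
  })
}

#' Generate survival follow-up for a synthetic cohort
#'
#' Exponential event times with hazard
#' `baseline_hazard * exp(age_log_hr * (age - mean age) + score_log_hr * z)`
#' where `z` is the standardized latent score (standardized delta), with
#' administrative censoring at `follow_up_years`.
#'
#' @inheritParams generate_expression
#' @return The cohort tibble with `time` (years, strictly positive) and
#'   `event` (0/1) columns added.
#' @export
generate_survival <- function(cohort, truth, config) {
  stopifnot(nrow(cohort) == config$n_subjects)
  with_substream(config$seed, 6L, {
    n <- nrow(cohort)
    z <- if (sd(truth$delta) > 0) as.numeric(scale(truth$delta)) else rep(0, n)
    rate <- config$baseline_hazard *
      exp(config$age_log_hr * (cohort$age - mean(cohort$age)) +
            config$score_log_hr * z)
    t_death <- rexp(n) / rate
    cohort$time <- pmin(t_death, config$follow_up_years)
    cohort$time[cohort$time <= 0] <- .Machine$double.eps
    cohort$event <- as.integer(t_death <= config$follow_up_years)
    cohort
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running every generator off one configuration.
#'
#' @param config a [sim_config()].
#' @return A list: `config`, `cohort` (with survival columns), `truth`,
#'   `expression`, `meth`, `cpg_map`, `network`, `gene_sets`.
#' @export
simulate_study <- function(config = sim_config()) {
  cg <- generate_cohort(config)
  expr <- generate_expression(cg$cohort, cg$truth, config)
  me <- generate_methylation(cg$cohort, cg$truth, config)
  net <- generate_network(cg$truth, config)
  gs <- generate_genesets(cg$truth, config)
  cohort <- generate_survival(cg$cohort, cg$truth, config)
  list(config = config, cohort = cohort, truth = cg$truth,
       expression = expr, meth = me$meth, cpg_map = me$cpg_map,
       network = net, gene_sets = gs)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Phenotype, expression, methylation and CpG-map TSVs, gene sets as GMT, the
#' network as an edge-list TSV, and a truth TSV for test oracles.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(sim$cohort, file.path(dir, "pheno.tsv"))
  write_matrix_tsv(sim$expression, file.path(dir, "expression.tsv"))
  write_matrix_tsv(sim$meth, file.path(dir, "methylation.tsv"))
  readr::write_tsv(sim$cpg_map, file.path(dir, "cpg_map.tsv"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_edge_list(sim$network, file.path(dir, "network.tsv"))
  truth_tbl <- tibble::tibble(
    gene = sim$truth$true_gene_ids,
    effect = unname(sim$truth$true_effects[sim$truth$true_gene_ids]),
    mediated = as.integer(sim$truth$true_gene_ids %in% sim$truth$mediated_gene_ids)
  )
  readr::write_tsv(truth_tbl, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(
    tibble::tibble(subject_id = sim$cohort$subject_id,
                   true_ba = sim$truth$true_ba, delta = sim$truth$delta),
    file.path(dir, "truth_subjects.tsv")
  )
  invisible(dir)
}
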