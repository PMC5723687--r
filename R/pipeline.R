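#' Pipeline configuration
#'
#' Collects every input and tuning knob of the end-to-end analysis. Inputs
#' are either file paths (phenotype TSV, expression/methylation matrix TSVs,
#' CpG-map TSV, GMT, edge-list TSV, prior gene list) or, when
#' `simulate = TRUE`, a [sim_config()] whose synthetic study is generated on
#' the fly.
#'
#' @param simulate generate a synthetic study instead of reading files.
#' @param sim a [sim_config()] (simulate mode); its seed is overridden by
#'   `seed`.
#' @param pheno,expression,methylation,cpg_map,gmt,network,prior_genes input
#'   file paths (file mode).
#' @param biomarkers biomarker column names for the KD fit.
#' @param covariates covariate columns for the association scans.
#' @param family_col family-id column.
#' @param alpha_policy `"bonferroni"` (0.05 / n features) or `"fixed"`.
#' @param alpha_fixed threshold used when `alpha_policy = "fixed"`.
#' @param n_seeds seeds for the module search.
#' @param n_perm permutations for the DMG enrichment null.
#' @param seed single integer driving all randomness.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return A list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            pheno = NULL, expression = NULL,
                            methylation = NULL, cpg_map = NULL, gmt = NULL,
                            network = NULL, prior_genes = NULL,
                            biomarkers = biomarker_panel_names(9),
                            covariates = c("sex", "age", "cell1", "cell2", "tech1"),
                            family_col = "family_id",
                            alpha_policy = c("bonferroni", "fixed"),
                            alpha_fixed = NULL,
                            n_seeds = 25, n_perm = 1e5,
                            seed = 1L, out_dir = NULL) {
  alpha_policy <- match.arg(alpha_policy)
  if (alpha_policy == "fixed" && is.null(alpha_fixed)) {
    abort("`alpha_fixed` is required under the fixed alpha policy.")
  }
  stopifnot(length(seed) == 1, seed == round(seed))
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; `sim.*` keys
#' set fields of the embedded [sim_config()].
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  check_nonempty(path)
  raw <- yaml::read_yaml(path)
  sim_keys <- raw[startsWith(names(raw), "sim.")]
  names(sim_keys) <- sub("^sim\\.", "", names(sim_keys))
  raw <- raw[!startsWith(names(raw), "sim.")]
  sim <- do.call(sim_config, sim_keys)
  known <- setdiff(names(formals(pipeline_config)), "sim")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("Pipeline stage `", stage, "` failed: ", conditionMessage(e)),
          parent = e)
  })
}

#' Run the end-to-end inflammatory-age analysis
#'
#' Executes, in order: biologic-age estimation (KD fit + delta age),
#' the expression association scan, the weighted expression score with its
#' survival analysis, pathway enrichment (plus the prior-gene-list overlap
#' when a prior list is available), the greedy dense-module subnetwork, and
#' the methylation integration (EWAS, DMG calls, permutation enrichment,
#' CpG-adjusted attenuation). A stage failure aborts with the stage name.
#' When `out_dir` is set, every stage writes a TSV, a machine-readable
#' `summary.json` and a `run_log.txt` recording versions, seed and every
#' threshold in effect.
#'
#' @param config a `"pipeline_config"`.
#' @return A `"pipeline_result"` list with the stage objects and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(
    paste0("inflammage ", as.character(utils::packageVersion("inflammage"))),
    R.version.string,
    paste0("seed: ", config$seed),
    paste0("alpha policy: ", config$alpha_policy),
    paste0("covariates: ", paste(config$covariates, collapse = ", ")),
    paste0("family column: ", config$family_col)
  )

  inputs <- run_stage("inputs", {
    if (config$simulate) {
      sim <- config$sim
      sim$seed <- config$seed
      study <- simulate_study(sim)
      prior <- NULL
      study$prior_genes <- prior
      study
    } else {
      list(
        cohort = read_phenotypes(config$pheno),
        expression = read_matrix_tsv(config$expression),
        meth = if (!is.null(config$methylation)) read_matrix_tsv(config$methylation),
        cpg_map = if (!is.null(config$cpg_map)) read_cpg_map(config$cpg_map),
        gene_sets = if (!is.null(config$gmt)) read_gmt(config$gmt),
        network = if (!is.null(config$network)) read_edge_list(config$network),
        prior_genes = if (!is.null(config$prior_genes)) read_gene_list(config$prior_genes),
        truth = NULL
      )
    }
  })

  kd <- run_stage("kdage", {
    model <- fit_kd(inputs$cohort, config$biomarkers)
    est <- suppressMessages(estimate_ba(model, inputs$cohort))
    indep <- check_delta_independence(est, warn = TRUE)
    list(model = model, est = est, independence = indep)
  })

  scan <- run_stage("assoc", {
    alpha <- if (config$alpha_policy == "fixed") {
      config$alpha_fixed * nrow(inputs$expression)
    } else 0.05
    run_scan(inputs$expression, kd$est, inputs$cohort,
             covariate_names = config$covariates,
             family_col = config$family_col, alpha = alpha)
  })
  log_lines <- c(log_lines, paste0(
    "expression scan: ", scan$n_features, " features, Bonferroni alpha ",
    format(scan$alpha_bonferroni, digits = 10), " (= ", scan$alpha, "/",
    scan$n_features, "), ", scan$n_significant, " significant (",
    scan$n_positive, " positive, ", scan$n_negative, " negative)"
  ))
  sig <- dplyr::filter(scan$results, .data$significant)

  score <- run_stage("score", {
    if (nrow(sig) == 0) {
      inform("No significant genes; skipping the expression score and survival stages.")
      NULL
    } else {
      sc <- expression_score(sig, inputs$expression)
      surv <- if (all(c("time", "event") %in% names(inputs$cohort))) {
        score_survival(sc, inputs$cohort, family_col = config$family_col)
      }
      list(scores = sc, survival = surv)
    }
  })

  enrich <- run_stage("enrich", {
    universe <- scan$results$gene
    pw <- if (!is.null(inputs$gene_sets) && nrow(sig) > 0) {
      pathway_enrichment(sig$gene, inputs$gene_sets, universe)
    }
    ov <- if (!is.null(inputs$prior_genes) && nrow(sig) > 0) {
      overlap_test(sig$gene, intersect(toupper(inputs$prior_genes),
                                       toupper(universe)), universe)
    }
    list(pathways = pw, overlap = ov)
  })

  netmod <- run_stage("netmod", {
    if (is.null(inputs$network)) NULL else {
      net <- score_network(inputs$network, scan)
      sub <- build_subnetwork(net, n_seeds = config$n_seeds)
      list(network = net, subnetwork = sub)
    }
  })

  methyl <- run_stage("methyl", {
    if (is.null(inputs$meth) || nrow(sig) == 0) NULL else {
      ewas <- ewas_scan(inputs$meth, kd$est, inputs$cohort,
                        covariate_names = config$covariates,
                        family_col = config$family_col)
      dmg <- call_dmgs(ewas, inputs$cpg_map, sort(unique(sig$gene)))
      cutoff <- attr(dmg, "cutoff")
      universe <- sort(unique(scan$results$gene))
      gene_min_p <- inputs$cpg_map |>
        dplyr::inner_join(dplyr::rename(ewas$results[, c("feature", "p")],
                                        cpg_id = "feature"), by = "cpg_id") |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(min_p = min(.data$p), .groups = "drop")
      status <- rep(FALSE, length(universe))
      hit <- match(gene_min_p$gene, universe)
      ok <- !is.na(hit)
      status[hit[ok]] <- gene_min_p$min_p[ok] < cutoff
      perm <- permutation_enrichment(
        universe, status, observed = sum(dmg$is_dmg),
        set_size = nrow(dmg), n_perm = config$n_perm,
        seed = config$seed + 7L
      )
      att <- attenuation_analysis(inputs$expression, inputs$meth, dmg,
                                  kd$est, inputs$cohort,
                                  covariate_names = config$covariates,
                                  family_col = config$family_col)
      list(ewas = ewas, dmg = dmg, permutation = perm, attenuation = att)
    }
  })
  if (!is.null(methyl)) {
    log_lines <- c(log_lines, paste0(
      "methylation: N = ", attr(methyl$dmg, "N"), " CpGs in tested genes, ",
      "DMG cutoff ", format(attr(methyl$dmg, "cutoff"), digits = 10),
      " (= 0.05/", attr(methyl$dmg, "N"), "), ",
      sum(methyl$dmg$is_dmg), " DMGs; permutation n = ", config$n_perm
    ))
  }

  summary <- list(
    seed = config$seed,
    n_subjects = nrow(kd$est),
    kd = list(r_char = kd$model$r_char, s2_ba = kd$model$s2_ba,
              mean_delta_age = mean(kd$est$delta_age),
              sd_delta_age = sd(kd$est$delta_age),
              delta_age_ca_r = kd$independence$r,
              delta_age_ca_p = kd$independence$p),
    scan = list(n_features = scan$n_features,
                alpha_bonferroni = scan$alpha_bonferroni,
                n_significant = scan$n_significant,
                n_positive = scan$n_positive,
                n_negative = scan$n_negative),
    score = if (!is.null(score) && !is.null(score$survival)) {
      g <- glance(score$survival)
      list(hr_per_sd = g$hr_per_sd, ci_low = g$ci_low, ci_high = g$ci_high,
           p = g$p, n_events = g$n_events)
    },
    enrichment = if (!is.null(enrich$pathways)) {
      list(top_set = enrich$pathways$set[1],
           top_p = enrich$pathways$p[1],
           top_fdr = enrich$pathways$fdr[1])
    },
    overlap = if (!is.null(enrich$overlap)) {
      list(n_overlap = enrich$overlap$n_overlap, p = enrich$overlap$p)
    },
    subnetwork = if (!is.null(netmod)) {
      list(n_nodes = netmod$subnetwork$n_nodes,
           n_edges = netmod$subnetwork$n_edges)
    },
    methylation = if (!is.null(methyl)) {
      list(n_cpg_tested = attr(methyl$dmg, "N"),
           dmg_cutoff = attr(methyl$dmg, "cutoff"),
           n_dmg = sum(methyl$dmg$is_dmg),
           perm_null_mean = methyl$permutation$null_mean,
           perm_p = methyl$permutation$p,
           fraction_attenuated = attr(methyl$attenuation, "fraction_attenuated"))
    }
  )

  result <- structure(list(
    config = config, inputs = inputs, kd = kd, scan = scan, score = score,
    enrich = enrich, netmod = netmod, methyl = methyl,
    summary = summary, log = log_lines
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$kd$est, file.path(dir, "ba.tsv"))
  write_kd_model(result$kd$model, file.path(dir, "kd_model.txt"))
  readr::write_tsv(result$scan$results, file.path(dir, "scan_results.tsv"))
  if (!is.null(result$score)) {
    readr::write_tsv(result$score$scores, file.path(dir, "score.tsv"))
    if (!is.null(result$score$survival)) {
      readr::write_tsv(result$score$survival$tiers, file.path(dir, "survival.tsv"))
    }
  }
  if (!is.null(result$enrich$pathways)) {
    pw <- dplyr::mutate(result$enrich$pathways,
                        hits = vapply(.data$hits, paste, "", collapse = ";"))
    readr::write_tsv(pw, file.path(dir, "enrichment.tsv"))
  }
  if (!is.null(result$netmod)) {
    mods <- purrr::map_dfr(result$netmod$subnetwork$modules, function(m) {
      tibble::tibble(seed = m$seed, k = m$k, z_m = m$z_m,
                     members = paste(m$members, collapse = ";"))
    })
    readr::write_tsv(mods, file.path(dir, "modules.tsv"))
    write_subnetwork(result$netmod$subnetwork,
                     file.path(dir, "subnetwork_edges.tsv"),
                     file.path(dir, "subnetwork_nodes.tsv"))
  }
  if (!is.null(result$methyl)) {
    readr::write_tsv(result$methyl$ewas$results, file.path(dir, "ewas_results.tsv"))
    readr::write_tsv(tibble::as_tibble(result$methyl$dmg), file.path(dir, "dmg.tsv"))
    readr::write_tsv(tibble::as_tibble(result$methyl$attenuation),
                     file.path(dir, "attenuation.tsv"))
  }
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("inflammage pipeline result\n")
  cat("  subjects:", x$summary$n_subjects,
      " scan features:", x$summary$scan$n_features, "\n")
  cat("  significant genes:", x$summary$scan$n_significant,
      "(", x$summary$scan$n_positive, "+ /", x$summary$scan$n_negative, "- )\n")
  if (!is.null(x$summary$score)) {
    cat("  score HR per SD:", signif(x$summary$score$hr_per_sd, 3), "\n")
  }
  if (!is.null(x$summary$subnetwork)) {
    cat("  subnetwork:", x$summary$subnetwork$n_nodes, "nodes,",
        x$summary$subnetwork$n_edges, "edges\n")
  }
  if (!is.null(x$summary$methylation)) {
    cat("  DMGs:", x$summary$methylation$n_dmg,
        " (perm p:", format(x$summary$methylation$perm_p), ")\n")
  }
  invisible(x)
}
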