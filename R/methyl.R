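#' Epigenome-wide association scan of CpG methylation on delta age
#'
#' Identical mixed-model contract as the expression scan ([run_scan()]),
#' applied to CpG beta-values.
#'
#' @inheritParams run_scan
#' @param meth CpG-by-subject matrix of beta-values.
#' @return A `"delta_scan"` object.
#' @export
ewas_scan <- function(meth, est, cohort, covariate_names = character(0),
                      family_col = "family_id", kinship = NULL,
                      alpha = 0.05, force_ols = FALSE) {
  run_scan(meth, est, cohort, covariate_names = covariate_names,
           family_col = family_col, kinship = kinship,
           alpha = alpha, force_ols = force_ols)
}

#' Call differentially methylated genes (DMGs)
#'
#' A gene from `gene_list` is a DMG iff it contains at least one CpG whose
#' EWAS p-value falls below `0.05 / N`, where `N` is the total number of
#' tested CpG sites mapped to genes in `gene_list` (shared across all genes
#' in one analysis). Each DMG's most significant CpG is recorded (ties:
#' smaller p, then lexicographic CpG id) along with the sign of its effect.
#'
#' @param ewas a `"delta_scan"` from [ewas_scan()] (or its results tibble).
#' @param cpg_map tibble mapping `cpg_id` to `gene`.
#' @param gene_list genes to assess (typically the significant expression
#'   genes).
#' @param alpha numerator of the cutoff (default 0.05).
#' @return A `"dmg_calls"` object: tibble (`gene`, `n_cpg`, `min_p`,
#'   `top_cpg`, `direction`, `is_dmg`) with `N` and `cutoff` attributes.
#' @export
call_dmgs <- function(ewas, cpg_map, gene_list, alpha = 0.05) {
  if (inherits(ewas, "delta_scan")) ewas <- ewas$results
  ewas <- tibble::as_tibble(ewas)
  cpg_map <- tibble::as_tibble(cpg_map)
  if (nrow(cpg_map) == 0) abort("Empty CpG map.")
  stopifnot(all(c("cpg_id", "gene") %in% names(cpg_map)))
  map <- dplyr::filter(cpg_map, .data$gene %in% gene_list,
                       .data$cpg_id %in% ewas$feature)
  N <- nrow(map)
  cutoff <- if (N > 0) alpha / N else NA_real_
  per_cpg <- dplyr::inner_join(
    map, dplyr::rename(ewas[, c("feature", "p", "beta")], cpg_id = "feature"),
    by = "cpg_id"
  )
  per_gene <- per_cpg |>
    dplyr::arrange(.data$p, .data$cpg_id) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_cpg = dplyr::n(),
      min_p = .data$p[1],
      top_cpg = .data$cpg_id[1],
      direction = sign(.data$beta[1]),
      .groups = "drop"
    )
  calls <- tibble::tibble(gene = gene_list) |>
    dplyr::left_join(per_gene, by = "gene") |>
    dplyr::mutate(
      n_cpg = dplyr::coalesce(.data$n_cpg, 0L),
      is_dmg = !is.na(.data$min_p) & .data$min_p < cutoff
    )
  structure(calls, N = N, cutoff = cutoff,
            class = c("dmg_calls", class(calls)))
}

#' @export
print.dmg_calls <- function(x, ...) {
  cat("DMG calls: ", sum(x$is_dmg), "/", nrow(x),
      " genes; N = ", attr(x, "N"),
      " CpGs, cutoff = ", signif(attr(x, "cutoff"), 3), "\n", sep = "")
  NextMethod()
}

#' Permutation enrichment of DMGs in a gene list
#'
#' Draws `n_perm` uniform random subsets of size `set_size` (without
#' replacement) from the universe, counts DMGs in each, and reports the
#' add-one empirical p `(1 + #(null >= observed)) / (n_perm + 1)`, which is
#' never exactly zero.
#'
#' @param universe character vector of genes (or its length with
#'   `dmg_status` aligned).
#' @param dmg_status logical per-universe-gene DMG flag (aligned to
#'   `universe`).
#' @param observed observed DMG count among the focal gene list.
#' @param set_size size of each random set (the focal list's size).
#' @param n_perm number of random sets (default 1e5).
#' @param seed optional integer seed for a reproducible draw (uses a local
#'   RNG stream; the caller's RNG state is untouched).
#' @return A `"permutation_result"` object: list with `observed`, `n_perm`,
#'   `null_counts`, `null_mean`, `null_min`, `null_max`, `p`, `seed`.
#' @export
permutation_enrichment <- function(universe, dmg_status, observed, set_size,
                                   n_perm = 1e5, seed = NULL) {
  n_u <- length(universe)
  stopifnot(length(dmg_status) == n_u, n_perm >= 1)
  if (set_size > n_u) abort("`set_size` exceeds the universe size.")
  draw <- function() {
    vapply(seq_len(n_perm),
           function(i) sum(dmg_status[sample.int(n_u, set_size)]),
           integer(1))
  }
  null_counts <- if (is.null(seed)) draw() else
    with_substream(seed, 0L, draw())
  p <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  structure(list(observed = observed, n_perm = as.integer(n_perm),
                 null_counts = null_counts,
                 null_mean = mean(null_counts),
                 null_min = min(null_counts), null_max = max(null_counts),
                 p = p, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  ptxt <- if (x$p < 1 / x$n_perm) paste0("<", format(1 / x$n_perm)) else format(signif(x$p, 3))
  cat("Permutation enrichment: observed", x$observed, "vs null mean",
      signif(x$null_mean, 4), "(min", x$null_min, ", max", x$null_max, ")\n")
  cat("  empirical p", ptxt, "over", x$n_perm, "permutations\n")
  invisible(x)
}

#' @rdname permutation_enrichment
#' @param x a `"permutation_result"`.
#' @param ... unused.
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = x$null_mean,
                 null_min = x$null_min, null_max = x$null_max,
                 p = x$p, n_perm = x$n_perm)
}

#' @describeIn permutation_enrichment Histogram of the null DMG counts with
#'   the observed count marked.
#' @param object a `"permutation_result"`.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(count = object$null_counts),
                  ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::annotate("point", x = object$observed, y = 0, shape = 17,
                      colour = "firebrick", size = 3) +
    ggplot2::labs(x = "DMGs per random gene set", y = "Gene sets") +
    ggplot2::theme_minimal()
}

#' CpG-adjusted attenuation analysis
#'
#' For each DMG, refits the gene's expression mixed model adding the gene's
#' most significant CpG as a covariate; the association is "attenuated" when
#' the adjusted effect is smaller in magnitude than the unadjusted one. Both
#' fits use the same model family on the same (complete-case) subjects. A
#' constant CpG column makes the gene indeterminate (refit without it).
#'
#' @param expr expression matrix (genes x subjects).
#' @param meth methylation matrix (CpGs x subjects).
#' @param dmg_calls a `"dmg_calls"` object from [call_dmgs()].
#' @param est,cohort,covariate_names,family_col as in [run_scan()].
#' @return An `"attenuation_result"` tibble: `gene`, `top_cpg`,
#'   `beta_before`, `beta_after`, `attenuated`, `indeterminate`; the
#'   attenuated fraction is in `attr(, "fraction_attenuated")` and via
#'   [glance()].
#' @export
attenuation_analysis <- function(expr, meth, dmg_calls, est, cohort,
                                 covariate_names = character(0),
                                 family_col = "family_id") {
  dmgs <- dplyr::filter(tibble::as_tibble(dmg_calls), .data$is_dmg)
  est <- as.data.frame(est)
  cohort <- as.data.frame(cohort)
  ids <- Reduce(intersect, list(colnames(expr), colnames(meth),
                                est$subject_id, cohort$subject_id))
  if (length(ids) == 0) abort("No overlapping subjects across matrices and cohort.")
  cohort <- cohort[match(ids, cohort$subject_id), , drop = FALSE]
  est <- est[match(ids, est$subject_id), , drop = FALSE]
  covars <- if (length(covariate_names)) cohort[, covariate_names, drop = FALSE] else NULL
  family <- if (!is.null(family_col)) cohort[[family_col]] else NULL

  rows <- purrr::pmap_dfr(dmgs[, c("gene", "top_cpg")], function(gene, top_cpg) {
    if (!gene %in% rownames(expr)) {
      return(tibble::tibble(gene = gene, top_cpg = top_cpg,
                            beta_before = NA_real_, beta_after = NA_real_,
                            attenuated = NA, indeterminate = TRUE))
    }
    y <- expr[gene, ids]
    before <- fit_feature_lmm(y, est$delta_age, covars, family = family)
    cpg <- meth[top_cpg, ids]
    indeterminate <- var(cpg) == 0
    if (indeterminate) {
      after <- before
    } else {
      cov2 <- if (is.null(covars)) data.frame(cpg = cpg) else cbind(covars, cpg = cpg)
      after <- fit_feature_lmm(y, est$delta_age, cov2, family = family)
    }
    tibble::tibble(gene = gene, top_cpg = top_cpg,
                   beta_before = before$beta, beta_after = after$beta,
                   attenuated = if (indeterminate) NA else abs(after$beta) < abs(before$beta),
                   indeterminate = indeterminate)
  })
  frac <- mean(rows$attenuated, na.rm = TRUE)
  structure(rows, fraction_attenuated = frac,
            class = c("attenuation_result", class(rows)))
}

#' @rdname attenuation_analysis
#' @param x an `"attenuation_result"`.
#' @param ... unused.
#' @method glance attenuation_result
#' @export
glance.attenuation_result <- function(x, ...) {
  tibble::tibble(n_dmg = nrow(x),
                 n_attenuated = sum(x$attenuated, na.rm = TRUE),
                 fraction_attenuated = attr(x, "fraction_attenuated"),
                 n_indeterminate = sum(x$indeterminate))
}
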