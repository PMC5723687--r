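#' Feature-wide association scan of expression (or methylation) on delta age
#'
#' Applies the family-aware mixed model of [fit_feature_lmm()] to every row of
#' a features-by-subjects matrix, with one shared eigendecomposition of the
#' grouping covariance. Significance is Bonferroni-controlled at
#' `alpha = 0.05 / n_features`, and significant features are partitioned by
#' the sign of their effect.
#'
#' @param matrix numeric features-by-subjects matrix; column names must be
#'   subject ids present in `cohort`.
#' @param est an `"age_estimates"` tibble from [estimate_ba()] (needs
#'   `subject_id` and `delta_age`), or any data frame with those columns.
#' @param cohort the phenotype table carrying the covariate and family
#'   columns, one row per subject.
#' @param covariate_names character vector of `cohort` columns to adjust for
#'   (e.g. sex, age, imputed cell counts, technical covariates).
#' @param family_col name of the family-id column in `cohort`, or `NULL` for
#'   unrelated subjects.
#' @param kinship optional symmetric PSD relatedness matrix with subject ids
#'   as dimnames (overrides `family_col`).
#' @param gene_map optional tibble (`feature`, `gene`) annotating features
#'   with gene symbols; defaults to `gene = feature`.
#' @param alpha total type-I error to split across features (default 0.05).
#' @param force_ols force the no-random-effect (OLS) limit.
#' @return A `"delta_scan"` object: list with `results` (tibble: feature,
#'   gene, beta, se, z, p, n, converged, significant), `alpha_bonferroni`,
#'   `n_features`, `n_significant`, `n_positive`, `n_negative`.
#' @export
run_scan <- function(matrix, est, cohort, covariate_names = character(0),
                     family_col = "family_id", kinship = NULL,
                     gene_map = NULL, alpha = 0.05, force_ols = FALSE) {
  stopifnot(is.matrix(matrix))
  if (anyDuplicated(rownames(matrix))) abort("Duplicate feature ids in matrix.")
  est <- as.data.frame(est)
  stopifnot(all(c("subject_id", "delta_age") %in% names(est)) ||
              is.null(est$subject_id))
  cohort <- as.data.frame(cohort)
  ids <- intersect(colnames(matrix), intersect(est$subject_id, cohort$subject_id))
  if (length(ids) == 0) abort("No overlapping subjects between matrix, estimates and cohort.")
  cohort <- cohort[match(ids, cohort$subject_id), , drop = FALSE]
  est <- est[match(ids, est$subject_id), , drop = FALSE]
  Y <- matrix[, ids, drop = FALSE]

  miss <- setdiff(covariate_names, names(cohort))
  if (length(miss)) abort(paste0("Covariate column(s) missing from cohort: ",
                                 paste(miss, collapse = ", ")))
  covars <- if (length(covariate_names)) cohort[, covariate_names, drop = FALSE] else NULL
  X <- build_design(est$delta_age, covars, n = length(ids))

  family <- NULL
  if (!is.null(kinship)) {
    kinship <- kinship[ids, ids, drop = FALSE]
  } else if (!is.null(family_col)) {
    if (!family_col %in% names(cohort)) {
      abort(paste0("Family column `", family_col, "` not found in cohort."))
    }
    family <- cohort[[family_col]]
  }

  n_features <- nrow(Y)
  alpha_bonf <- alpha / max(n_features, 1)
  if (n_features == 0) {
    res <- tibble::tibble(feature = character(), gene = character(),
                          beta = numeric(), se = numeric(), z = numeric(),
                          p = numeric(), n = integer(), converged = logical(),
                          significant = logical())
  } else {
    res <- lmm_scan(Y, X, family = family, kinship = kinship,
                    force_ols = force_ols)
    gm <- if (is.null(gene_map)) {
      tibble::tibble(feature = res$feature, gene = res$feature)
    } else tibble::as_tibble(gene_map)
    res <- dplyr::left_join(res, gm, by = "feature")
    res$gene[is.na(res$gene)] <- res$feature[is.na(res$gene)]
    res$significant <- res$p < alpha_bonf
    res <- dplyr::select(res, "feature", "gene", "beta", "se", "z", "p",
                         "n", "converged", "significant",
                         "sigma2_g", "sigma2_e")
  }
  structure(list(
    results = res,
    n_features = n_features,
    alpha = alpha,
    alpha_bonferroni = alpha_bonf,
    n_significant = sum(res$significant),
    n_positive = sum(res$significant & res$beta > 0),
    n_negative = sum(res$significant & res$beta < 0)
  ), class = "delta_scan")
}

#' Bonferroni threshold for a feature-wide scan
#'
#' @param n_features number of features tested.
#' @param alpha total type-I error (default 0.05).
#' @return `alpha / n_features`.
#' @export
bonferroni_alpha <- function(n_features, alpha = 0.05) {
  stopifnot(n_features >= 1)
  alpha / n_features
}

#' @export
print.delta_scan <- function(x, ...) {
  cat("Delta-age association scan\n")
  cat("  features:", x$n_features,
      " Bonferroni alpha:", signif(x$alpha_bonferroni, 3), "\n")
  cat("  significant:", x$n_significant,
      "(", x$n_positive, "positive,", x$n_negative, "negative )\n")
  invisible(x)
}

#' @rdname run_scan
#' @param x a `"delta_scan"`.
#' @param ... unused.
#' @method tidy delta_scan
#' @export
tidy.delta_scan <- function(x, ...) x$results

#' @rdname run_scan
#' @method glance delta_scan
#' @export
glance.delta_scan <- function(x, ...) {
  tibble::tibble(n_features = x$n_features,
                 alpha_bonferroni = x$alpha_bonferroni,
                 n_significant = x$n_significant,
                 n_positive = x$n_positive,
                 n_negative = x$n_negative)
}

#' Volcano-plot coordinates for a scan
#'
#' @param scan a `"delta_scan"` (or its results tibble plus `alpha`).
#' @param alpha significance threshold; defaults to the scan's Bonferroni
#'   threshold.
#' @return Tibble: `feature`, `gene`, `beta`, `neg_log10_p`, `significant`,
#'   with the threshold line height in `attr(, "threshold")`.
#' @export
volcano_table <- function(scan, alpha = NULL) {
  if (inherits(scan, "delta_scan")) {
    alpha <- alpha %||% scan$alpha_bonferroni
    res <- scan$results
  } else {
    res <- tibble::as_tibble(scan)
    if (is.null(alpha)) abort("`alpha` is required when passing a results table.")
  }
  out <- tibble::tibble(
    feature = res$feature, gene = res$gene, beta = res$beta,
    neg_log10_p = -log10(res$p),
    significant = res$p < alpha
  )
  attr(out, "threshold") <- -log10(alpha)
  out
}

#' @describeIn run_scan Volcano plot of the scan (effect vs `-log10(p)`,
#'   dashed line at the Bonferroni threshold).
#' @param object a `"delta_scan"`.
#' @method autoplot delta_scan
#' @export
autoplot.delta_scan <- function(object, ...) {
  vt <- volcano_table(object)
  ggplot2::ggplot(vt, ggplot2::aes(x = .data$beta, y = .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(vt, "threshold"),
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Effect per year of delta age",
                  y = expression(-log[10](italic(p))),
                  colour = "Bonferroni\nsignificant") +
    ggplot2::theme_minimal()
}
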