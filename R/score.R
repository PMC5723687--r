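#' Weighted expression score over significant genes
#'
#' For subject `j`, `Score_j = sum_i beta_i * G_ij` over the significant
#' features `i`, with weights equal to the scan effect sizes. The score is
#' linear in both the betas and the expression values and invariant to
#' feature order.
#'
#' @param results a data frame with `feature` and `beta` columns (typically
#'   the significant rows of a [run_scan()] result), or a `"delta_scan"`
#'   whose significant features are used.
#' @param matrix features-by-subjects expression matrix containing every
#'   scored feature.
#' @return Tibble: `subject_id`, `score`.
#' @export
expression_score <- function(results, matrix) {
  if (inherits(results, "delta_scan")) {
    results <- dplyr::filter(results$results, .data$significant)
  }
  results <- tibble::as_tibble(results)
  stopifnot(all(c("feature", "beta") %in% names(results)))
  absent <- setdiff(results$feature, rownames(matrix))
  if (length(absent)) {
    abort(paste0("Feature(s) absent from the matrix: ",
                 paste(absent, collapse = ", ")))
  }
  if (nrow(results) == 0) {
    return(tibble::tibble(subject_id = colnames(matrix),
                          score = rep(0, ncol(matrix))))
  }
  G <- matrix[results$feature, , drop = FALSE]
  tibble::tibble(subject_id = colnames(matrix),
                 score = as.numeric(crossprod(G, results$beta)))
}

#' Survival association of the expression score
#'
#' Cox proportional-hazards regression of time-to-death on the expression
#' score with a family-clustered robust (sandwich) variance and Efron tie
#' handling, in two adjustment tiers: age and sex only, then additionally the
#' supplied mortality-related covariates. The hazard ratio is reported both
#' per unit of score and per SD of score (the per-SD scale anchors
#' interpretation across analyses).
#'
#' @param scores tibble from [expression_score()] (`subject_id`, `score`).
#' @param cohort phenotype table with `time` (years, > 0), `event` (0/1),
#'   the adjustment columns, and the family column.
#' @param adjustments character vector of extra covariates for the second
#'   tier (default: the six mortality-related covariates of the synthetic
#'   cohort).
#' @param base_adjustments covariates of the first tier (default age + sex).
#' @param family_col family-id column used for the clustered variance.
#' @param horizon administrative censoring horizon in years (default 10);
#'   follow-up beyond it is truncated. `Inf` disables truncation.
#' @return A `"score_survival"` object: list with `tiers` (tibble: tier,
#'   term, hr, hr_per_sd, ci_low, ci_high, p, n, n_events), `score_sd`, and
#'   the fitted `survival::coxph` objects.
#' @export
score_survival <- function(scores, cohort,
                           adjustments = c("smoking", "diabetes",
                                           "htn_treatment", "lipid_treatment",
                                           "prev_cvd", "prev_cancer"),
                           base_adjustments = c("age", "sex"),
                           family_col = "family_id", horizon = 10) {
  cohort <- as.data.frame(cohort)
  stopifnot(all(c("time", "event", "subject_id") %in% names(cohort)))
  dat <- dplyr::inner_join(tibble::as_tibble(cohort), scores, by = "subject_id")
  if (any(dat$time <= 0)) abort("Follow-up times must be strictly positive.")
  if (is.finite(horizon)) {
    dat$event <- as.integer(dat$event == 1 & dat$time <= horizon)
    dat$time <- pmin(dat$time, horizon)
  }
  if (sum(dat$event) < 1) abort("No events observed; cannot fit a Cox model.")
  score_sd <- sd(dat$score)
  if (score_sd == 0) abort("Expression score is constant across subjects.")
  dat$score_per_sd <- dat$score / score_sd

  tiers <- list(base = base_adjustments,
                full = unique(c(base_adjustments, adjustments)))
  fits <- list()
  rows <- purrr::imap_dfr(tiers, function(adj, tier) {
    adj <- intersect(adj, names(dat))
    rhs <- paste(c("score_per_sd", adj,
                   paste0("cluster(", family_col, ")")), collapse = " + ")
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
    fit <- survival::coxph(fml, data = dat, ties = "efron")
    fits[[tier]] <<- fit
    s <- summary(fit)
    i <- which(rownames(s$coefficients) == "score_per_sd")
    b <- s$coefficients[i, "coef"]
    se <- s$coefficients[i, "robust se"]
    zph_warn <- tryCatch({
      zph <- survival::cox.zph(fit)
      zph$table["score_per_sd", "p"] < 0.05
    }, error = function(e) FALSE)
    if (isTRUE(zph_warn)) {
      warn(paste0("Proportional-hazards diagnostic fails for the score (tier ",
                  tier, "); interpret the hazard ratio with care."))
    }
    tibble::tibble(
      tier = tier,
      log_hr_per_sd = b, se = se,
      hr_per_sd = exp(b),
      hr_per_unit = exp(b / score_sd),
      ci_low = exp(b - qnorm(0.975) * se),
      ci_high = exp(b + qnorm(0.975) * se),
      p = 2 * pnorm(-abs(b / se)),
      n = s$n, n_events = s$nevent
    )
  })
  structure(list(tiers = rows, score_sd = score_sd, fits = fits),
            class = "score_survival")
}

#' @export
print.score_survival <- function(x, ...) {
  cat("Expression score vs mortality (Cox PH, family-clustered robust SE)\n")
  print(as.data.frame(x$tiers[, c("tier", "hr_per_sd", "ci_low", "ci_high",
                                  "p", "n", "n_events")]), row.names = FALSE)
  invisible(x)
}

#' @rdname score_survival
#' @param x a `"score_survival"`.
#' @param ... unused.
#' @method tidy score_survival
#' @export
tidy.score_survival <- function(x, ...) x$tiers

#' @rdname score_survival
#' @method glance score_survival
#' @export
glance.score_survival <- function(x, ...) {
  base <- x$tiers[x$tiers$tier == "base", ]
  tibble::tibble(hr_per_sd = base$hr_per_sd, ci_low = base$ci_low,
                 ci_high = base$ci_high, p = base$p,
                 n = base$n, n_events = base$n_events,
                 score_sd = x$score_sd)
}
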