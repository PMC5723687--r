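#' Fit a Klemera-Doubal biologic-age model
#'
#' Regresses each biomarker on chronologic age by ordinary least squares to
#' obtain intercept `q_j`, slope `k_j`, residual SD `s_j` and biomarker-age
#' correlation `r_j`; combines them into the characteristic correlation
#' `r_char = sqrt(sum(w_j r_j^2) / sum(w_j))` with inverse-variance weights
#' `w_j = k_j^2 / s_j^2`; and estimates the variance `s2_BA` of the offset
#' between biologic and chronologic age as
#' `Var(BA_E - CA) - ((1 - r_char^2) / r_char^2) * (ca_max - ca_min)^2 / (12 m)`.
#' The variant that blends chronologic age in as an additional biomarker
#' (`BA_EC`) is the reported biologic age; see [estimate_ba()].
#'
#' Training uses complete cases across the requested biomarkers and age (the
#' complete-case policy of family-cohort practice). Biomarkers whose `|r_j|`
#' falls below `r_floor` are flagged (`weak = TRUE`) but retained: their
#' weights are tiny so they contribute almost nothing.
#'
#' @param cohort data frame with an age column and the biomarker columns.
#' @param biomarkers character vector of biomarker column names.
#' @param age_col name of the chronologic-age column (years).
#' @param log_transform optional: `TRUE`, or a character subset of
#'   `biomarkers`, to log-transform skewed biomarkers before fitting
#'   (values must be positive). Default off.
#' @param r_floor flag threshold for near-zero biomarker-age correlation.
#' @return An object of class `"kd_model"`: a list with `biomarkers` (tibble
#'   of per-biomarker `q`, `k`, `s`, `r`, `weight`, `weak`), `m`, `r_char`,
#'   `s2_ba`, `ca_min`, `ca_max`, `n`, and `s2_ba_fallback` (logical).
#' @export
fit_kd <- function(cohort, biomarkers, age_col = "age",
                   log_transform = FALSE, r_floor = 0.01,
                   r_char_method = c("mean_odds", "weighted_rms")) {
  r_char_method <- match.arg(r_char_method)
  stopifnot(is.data.frame(cohort), length(biomarkers) >= 1)
  missing_cols <- setdiff(c(age_col, biomarkers), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s) in cohort: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dat <- cohort[, c(age_col, biomarkers)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3) abort("Need at least 3 subjects with complete biomarkers and age.")
  ca <- dat[[age_col]]
  if (var(ca) == 0) abort("Chronologic age has zero variance.")

  log_set <- if (isTRUE(log_transform)) biomarkers else
    if (is.character(log_transform)) intersect(log_transform, biomarkers) else character(0)

  fits <- purrr::map_dfr(biomarkers, function(b) {
    x <- dat[[b]]
    if (b %in% log_set) {
      if (any(x <= 0)) abort(paste0("log transform requested for `", b,
                                    "` but it has non-positive values."))
      x <- log(x)
    }
    f <- lm(x ~ ca)
    s <- sqrt(sum(f$residuals^2) / f$df.residual)
    tibble::tibble(
      biomarker = b,
      q = unname(coef(f)[1]),
      k = unname(coef(f)[2]),
      s = max(s, .Machine$double.eps),
      r = cor(x, ca)
    )
  })
  if (all(fits$k == 0)) abort("No biomarker tracks age: all fitted slopes are zero.")
  fits$weight <- fits$k^2 / fits$s^2
  fits$weak <- abs(fits$r) < r_floor
  if (any(fits$weak)) {
    inform(paste0("Biomarker(s) with |r| below ", r_floor, " retained with near-zero weight: ",
                  paste(fits$biomarker[fits$weak], collapse = ", ")))
  }

  m <- nrow(fits)
  r_char <- kd_r_char(fits$r, fits$weight, method = r_char_method)
  ca_min <- min(ca)
  ca_max <- max(ca)

  model <- structure(list(
    biomarkers = fits, m = m, r_char = r_char,
    s2_ba = NA_real_, s2_ba_fallback = FALSE,
    ca_min = ca_min, ca_max = ca_max, n = nrow(dat),
    age_col = age_col, log_set = log_set
  ), class = "kd_model")

  ba_e <- kd_ba_e(model, dat)
  var_diff <- var(ba_e - ca)
  s2 <- var_diff - ((1 - r_char^2) / r_char^2) * (ca_max - ca_min)^2 / (12 * m)
  if (!is.finite(s2) || s2 <= 0) {
    warn(paste0("s2_BA non-positive (", signif(s2, 3),
                "); falling back to Var(BA_E - CA) = ", signif(var_diff, 3), "."))
    s2 <- var_diff
    model$s2_ba_fallback <- TRUE
  }
  model$s2_ba <- s2
  model
}

#' Characteristic correlation of a biomarker panel
#'
#' Summarizes per-biomarker age correlations `r_j` into the single `r_char`
#' that enters the `s2_BA` correction term. `"mean_odds"` (default) solves
#' `r_char^2 / (1 - r_char^2) = mean_j(r_j^2 / (1 - r_j^2))`, which makes the
#' correction `((1 - r_char^2) / r_char^2) * range^2 / (12 m)` equal the
#' inverse total information `1 / sum_j(k_j^2 / s_j^2)` scaled by the
#' uniform-age variance -- i.e. the actual sampling noise of `BA_E`, so the
#' shrinkage variance stays consistent under heterogeneous panels.
#' `"weighted_rms"` is `sqrt(sum(w_j r_j^2) / sum(w_j))` with
#' `w_j = k_j^2 / s_j^2`, which up-weights strong biomarkers and
#' under-shrinks when correlations are heterogeneous.
#'
#' @param r per-biomarker age correlations.
#' @param weight per-biomarker weights `k^2 / s^2` (used by
#'   `"weighted_rms"`).
#' @param method `"mean_odds"` or `"weighted_rms"`.
#' @return Scalar in `[0, 1)`.
#' @export
kd_r_char <- function(r, weight = rep(1, length(r)),
                      method = c("mean_odds", "weighted_rms")) {
  method <- match.arg(method)
  if (method == "weighted_rms") {
    sqrt(sum(weight * r^2) / sum(weight))
  } else {
    odds <- mean(r^2 / pmax(1 - r^2, .Machine$double.eps))
    sqrt(odds / (1 + odds))
  }
}

# uncorrected biologic age: inverse-variance weighted biomarker estimate
kd_ba_e <- function(model, dat) {
  p <- model$biomarkers
  num <- rep(0, nrow(dat))
  den <- sum(p$k^2 / p$s^2)
  for (j in seq_len(nrow(p))) {
    x <- dat[[p$biomarker[j]]]
    if (p$biomarker[j] %in% model$log_set) x <- log(x)
    num <- num + (x - p$q[j]) * p$k[j] / p$s[j]^2
  }
  num / den
}

#' Estimate biologic age and delta age for a cohort
#'
#' Applies a fitted [fit_kd()] model:
#' `BA_E = sum_j (x_j - q_j) k_j / s_j^2 / sum_j k_j^2 / s_j^2` and the
#' age-anchored estimate
#' `BA_EC = (sum_j (x_j - q_j) k_j / s_j^2 + CA / s2_BA) / (sum_j k_j^2 / s_j^2 + 1 / s2_BA)`,
#' a shrinkage of `BA_E` toward chronologic age whose strength is governed by
#' `s2_BA`. Delta age is `BA_EC - CA`; the reported inflammatory biologic age
#' is `BA_EC`.
#'
#' @param model a `"kd_model"`.
#' @param cohort data frame with the model's age and biomarker columns.
#' @param na_action `"drop"` (default) excludes subjects missing any
#'   biomarker; `"renormalize"` computes each subject's estimate from their
#'   observed biomarkers with renormalized weights.
#' @return An `"age_estimates"` tibble: `subject_id` (if present), `ca`,
#'   `ba_e`, `ba_ec`, `delta_age`.
#' @export
estimate_ba <- function(model, cohort, na_action = c("drop", "renormalize")) {
  stopifnot(inherits(model, "kd_model"))
  na_action <- match.arg(na_action)
  p <- model$biomarkers
  cols <- c(model$age_col, p$biomarker)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s) in cohort: ", paste(missing_cols, collapse = ", ")))
  }
  dat <- cohort
  cc <- complete.cases(dat[, cols])
  if (na_action == "drop") {
    if (any(!cc)) inform(paste0("Dropping ", sum(!cc),
                                " subject(s) with incomplete biomarkers (policy: complete-case)."))
    dat <- dat[cc, , drop = FALSE]
  } else {
    dat <- dat[!is.na(dat[[model$age_col]]), , drop = FALSE]
    inform("Missing biomarkers handled by renormalized weights.")
  }
  ca <- dat[[model$age_col]]
  X <- vapply(seq_len(nrow(p)), function(j) {
    x <- dat[[p$biomarker[j]]]
    if (p$biomarker[j] %in% model$log_set) x <- log(x)
    x
  }, numeric(nrow(dat)))
  if (nrow(dat) == 1L) X <- matrix(X, nrow = 1)
  wn <- sweep(sweep(X, 2, p$q), 2, p$k / p$s^2, `*`)        # (x - q) k / s^2
  wd <- matrix(p$k^2 / p$s^2, nrow(dat), nrow(p), byrow = TRUE)
  obs <- !is.na(wn)
  wn[!obs] <- 0
  wd[!obs] <- 0
  num <- rowSums(wn)
  den <- rowSums(wd)
  ba_e <- num / den
  ba_ec <- (num + ca / model$s2_ba) / (den + 1 / model$s2_ba)
  out <- tibble::tibble(ca = ca, ba_e = ba_e, ba_ec = ba_ec,
                        delta_age = ba_ec - ca)
  if ("subject_id" %in% names(dat)) {
    out <- dplyr::bind_cols(tibble::tibble(subject_id = dat$subject_id), out)
  }
  class(out) <- c("age_estimates", class(out))
  out
}

#' Check that delta age is uncorrelated with chronologic age
#'
#' A fitted biologic-age model should produce an offset orthogonal to
#' chronologic age; a strong correlation signals model misspecification.
#'
#' @param est an `"age_estimates"` tibble from [estimate_ba()].
#' @param warn emit a warning when the correlation is significant at 0.05.
#' @return A one-row tibble: `r`, `p`, `n`, `degenerate` (TRUE when the
#'   correlation is undefined, e.g. constant delta age).
#' @export
check_delta_independence <- function(est, warn = TRUE) {
  stopifnot(all(c("ca", "delta_age") %in% names(est)))
  n <- sum(complete.cases(est[, c("ca", "delta_age")]))
  if (n < 3 || sd(est$delta_age) == 0 || sd(est$ca) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- cor.test(est$delta_age, est$ca)
  if (warn && ct$p.value < 0.05) {
    rlang::warn(paste0("Delta age is correlated with chronologic age (r = ",
                       signif(ct$estimate, 3), ", p = ", signif(ct$p.value, 3), ")."))
  }
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}

#' @export
print.kd_model <- function(x, ...) {
  cat("Klemera-Doubal biologic-age model\n")
  cat("  biomarkers:", x$m, " subjects:", x$n, "\n")
  cat("  characteristic correlation r_char:", signif(x$r_char, 4), "\n")
  cat("  s2_BA:", signif(x$s2_ba, 4),
      if (x$s2_ba_fallback) "(fallback: Var(BA_E - CA))" else "", "\n")
  cat("  age range: [", signif(x$ca_min, 4), ",", signif(x$ca_max, 4), "]\n")
  invisible(x)
}

#' @rdname fit_kd
#' @param x a `"kd_model"`.
#' @param ... unused.
#' @method tidy kd_model
#' @export
tidy.kd_model <- function(x, ...) x$biomarkers

#' @rdname fit_kd
#' @method glance kd_model
#' @export
glance.kd_model <- function(x, ...) {
  tibble::tibble(m = x$m, n = x$n, r_char = x$r_char, s2_ba = x$s2_ba,
                 s2_ba_fallback = x$s2_ba_fallback,
                 ca_min = x$ca_min, ca_max = x$ca_max)
}

#' Serialize / read a KD model as a human-readable key-value text file
#'
#' @param model a `"kd_model"`.
#' @param path output file.
#' @return `path` (write) or a `"kd_model"` (read).
#' @export
write_kd_model <- function(model, path) {
  hdr <- c(
    paste0("m\t", model$m), paste0("n\t", model$n),
    paste0("r_char\t", format(model$r_char, digits = 17)),
    paste0("s2_ba\t", format(model$s2_ba, digits = 17)),
    paste0("s2_ba_fallback\t", as.integer(model$s2_ba_fallback)),
    paste0("ca_min\t", format(model$ca_min, digits = 17)),
    paste0("ca_max\t", format(model$ca_max, digits = 17)),
    paste0("age_col\t", model$age_col),
    paste0("log_set\t", paste(model$log_set, collapse = ",")),
    "biomarker\tq\tk\ts\tr\tweight\tweak"
  )
  b <- model$biomarkers
  rows <- paste(b$biomarker,
                format(b$q, digits = 17), format(b$k, digits = 17),
                format(b$s, digits = 17), format(b$r, digits = 17),
                format(b$weight, digits = 17), as.integer(b$weak),
                sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_kd_model
#' @export
read_kd_model <- function(path) {
  lines <- readLines(path)
  kv_end <- which(startsWith(lines, "biomarker\t"))
  kv <- strsplit(lines[seq_len(kv_end - 1)], "\t")
  kvm <- setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "", ""),
                  vapply(kv, `[`, "", 1))
  tab <- utils::read.delim(text = lines[kv_end:length(lines)], sep = "\t",
                           stringsAsFactors = FALSE)
  tab$weak <- as.logical(tab$weak)
  structure(list(
    biomarkers = tibble::as_tibble(tab),
    m = as.integer(kvm[["m"]]), n = as.integer(kvm[["n"]]),
    r_char = as.numeric(kvm[["r_char"]]), s2_ba = as.numeric(kvm[["s2_ba"]]),
    s2_ba_fallback = as.logical(as.integer(kvm[["s2_ba_fallback"]])),
    ca_min = as.numeric(kvm[["ca_min"]]), ca_max = as.numeric(kvm[["ca_max"]]),
    age_col = kvm[["age_col"]],
    log_set = if (nzchar(kvm[["log_set"]])) strsplit(kvm[["log_set"]], ",")[[1]] else character(0)
  ), class = "kd_model")
}
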