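#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test on the table `rbind(c(a, b), c(c, d))`. The
#' two-sided p sums, over the conditional support, every table probability
#' not exceeding the observed table's probability (point-probability method,
#' with the customary 1e-7 relative tie tolerance). One-sided alternatives
#' are plain hypergeometric tails. A zero row or column margin makes the
#' table degenerate: p = 1 with `degenerate = TRUE`.
#'
#' @param a,b,c,d nonnegative integer cell counts; `a` is the overlap cell.
#' @param alternative `"two.sided"` (default), `"greater"` (enrichment of
#'   `a`) or `"less"` (depletion).
#' @return A one-row tibble: `p`, `odds_ratio` (sample OR), `degenerate`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  or <- (a * d) / (b * c)
  m1 <- a + b   # row 1 margin
  m2 <- c + d
  n1 <- a + c   # column 1 margin
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0) {
    return(tibble::tibble(p = 1, odds_ratio = or, degenerate = TRUE))
  }
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(support, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a])
  )
  tibble::tibble(p = min(p, 1), odds_ratio = or, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with an explicit test count `m`,
#' which may exceed `length(p)` when only a subset of the tested hypotheses
#' is supplied.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m number of tests (default `length(p)`).
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= length(p))
  p.adjust(p, method = "BH", n = m)
}

#' Gene-set (pathway) enrichment of a significant-gene list
#'
#' For each set, builds the 2x2 table (significant-in-set,
#' significant-not-in-set, set-not-significant, rest of universe) over
#' `universe`, tests it with [fisher_exact_2x2()], and reports the ratio of
#' enrichment `n_hit / (n_set * |sig| / |universe|)` (observed over expected
#' hits). BH-FDR is computed across the sets actually tested (those with at
#' least `min_set_size` universe genes). Gene symbols are matched exactly
#' after uppercasing.
#'
#' @param sig_genes character vector of significant gene symbols.
#' @param collection named list of gene-symbol vectors (e.g. from
#'   [read_gmt()] or [generate_genesets()]).
#' @param universe background gene list; sets are intersected with it.
#' @param min_set_size smallest universe-intersected set tested (default 10).
#' @param alternative sidedness passed to [fisher_exact_2x2()].
#' @return Tibble: `set`, `n_set`, `n_hit`, `expected`, `ratio`, `p`, `fdr`,
#'   `hits` (list column), ordered by p.
#' @export
pathway_enrichment <- function(sig_genes, collection, universe,
                               min_set_size = 10,
                               alternative = "two.sided") {
  if (length(universe) == 0) abort("Empty universe.")
  universe <- unique(toupper(universe))
  sig <- unique(toupper(sig_genes))
  out <- setdiff(sig, universe)
  if (length(out)) {
    abort(paste0("Significant gene(s) not in the universe: ",
                 paste(head(out, 5), collapse = ", "),
                 if (length(out) > 5) " ..." else ""))
  }
  n_u <- length(universe)
  n_s <- length(sig)
  rows <- purrr::imap_dfr(collection, function(members, set_name) {
    set_u <- intersect(unique(toupper(members)), universe)
    n_set <- length(set_u)
    hits <- intersect(sig, set_u)
    n_hit <- length(hits)
    expected <- n_set * n_s / n_u
    tibble::tibble(
      set = set_name, n_set = n_set, n_hit = n_hit, expected = expected,
      ratio = if (expected > 0) n_hit / expected else 0,
      p = NA_real_, hits = list(sort(hits))
    )
  })
  tested <- rows$n_set >= min_set_size
  rows$p[tested] <- purrr::map2_dbl(
    rows$n_hit[tested], rows$n_set[tested],
    function(h, ns) fisher_exact_2x2(h, n_s - h, ns - h, n_u - n_s - ns + h,
                                     alternative = alternative)$p
  )
  rows$fdr <- NA_real_
  rows$fdr[tested] <- bh_fdr(rows$p[tested])
  rows <- rows[tested, , drop = FALSE]
  dplyr::arrange(rows, .data$p)
}

#' Fisher overlap test of two gene lists
#'
#' Tests whether lists `a` and `b` share more genes than expected given the
#' universe, via the 2x2 table (`|a & b|`, `|a - b|`, `|b - a|`, rest).
#'
#' @param list_a,list_b character gene lists, subsets of `universe`.
#' @param universe background gene list.
#' @param alternative `"greater"` (default; enrichment of the overlap, the
#'   convention under which a reported overlap p reproduces) or
#'   `"two.sided"`/`"less"`.
#' @return A one-row tibble: `n_overlap`, `n_a`, `n_b`, `n_universe`, `p`.
#' @export
overlap_test <- function(list_a, list_b, universe, alternative = "greater") {
  universe <- unique(toupper(universe))
  a <- unique(toupper(list_a))
  b <- unique(toupper(list_b))
  out <- setdiff(c(a, b), universe)
  if (length(out)) {
    abort(paste0("Gene(s) not in the universe: ",
                 paste(head(out, 5), collapse = ", "),
                 if (length(out) > 5) " ..." else ""))
  }
  ab <- length(intersect(a, b))
  ft <- fisher_exact_2x2(ab, length(a) - ab, length(b) - ab,
                         length(universe) - length(a) - length(b) + ab,
                         alternative = alternative)
  tibble::tibble(n_overlap = ab, n_a = length(a), n_b = length(b),
                 n_universe = length(universe), p = ft$p,
                 degenerate = ft$degenerate)
}
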