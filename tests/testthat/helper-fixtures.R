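# Shared fixtures. Small configurations keep per-file runtime low; the
# acceptance suite uses the full default configuration where a check is
# defined at study scale.

panel9 <- inflammage:::biomarker_panel_names(9)
scan_covars <- c("sex", "age", "cell1", "cell2", "tech1")

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_subjects = 300, n_families = 120, n_genes = 150,
         n_true_genes = 15, planted_cluster_size = 8,
         n_gene_sets = 15, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

small_study <- function(seed = 1, ...) {
  simulate_study(small_config(seed = seed, ...))
}

kd_estimates <- function(cohort) {
  model <- suppressMessages(fit_kd(cohort, panel9))
  suppressMessages(estimate_ba(model, cohort))
}

# deterministic toy network: a path A-B-C-D plus hub E connected to B and C
toy_network <- function(g_scores) {
  edges <- tibble::tibble(
    from = c("A", "B", "C", "B", "C"),
    to   = c("B", "C", "D", "E", "E")
  )
  results <- tibble::tibble(
    gene = names(g_scores),
    p = 1 - pnorm(g_scores),
    beta = 1
  )
  score_network(edges, results)
}

# brute-force two-sided Fisher p by enumeration over the conditional support,
# with table probabilities from log-binomial coefficients (independent of
# dhyper); same 1e-7 relative tie tolerance as the implementation contract
fisher_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  ks <- max(0, n1 - m2):min(n1, m1)
  logp <- lchoose(m1, ks) + lchoose(m2, n1 - ks) - lchoose(m1 + m2, n1)
  pr <- exp(logp)
  p_obs <- pr[match(a, ks)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# quadratic-time BH from the step-up definition
bh_brute <- function(p, m = length(p)) {
  n <- length(p)
  q <- numeric(n)
  o <- order(p)
  r <- rank(p, ties.method = "first")
  for (i in seq_len(n)) {
    cand <- vapply(seq_len(n), function(j) {
      if (p[j] >= p[i]) p[j] * m / r[j] else Inf
    }, 0)
    q[i] <- min(1, min(cand))
  }
  q
}
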