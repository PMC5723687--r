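test_that("DMG calling applies the shared 0.05/N cutoff with tie-stable top CpGs", {
  ewas <- tibble::tibble(
    feature = c("c1a", "c1b", "c2a", "c3a", "c3b"),
    gene = NA, beta = c(1, -1, 2, -0.5, 0.5),
    p = c(1e-6, 0.2, 4e-5, 0.5, 0.5)
  )
  map <- tibble::tibble(
    cpg_id = c("c1a", "c1b", "c2a", "c3a", "c3b", "c9"),
    gene = c("G1", "G1", "G2", "G3", "G3", "G9")
  )
  calls <- call_dmgs(ewas, map, c("G1", "G2", "G3", "G4"))
  # N counts tested CpGs mapped to listed genes: c9/G9 and G4 contribute 0
  expect_equal(attr(calls, "N"), 5)
  expect_equal(attr(calls, "cutoff"), 0.01)
  expect_equal(calls$is_dmg, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(calls$top_cpg[1:2], c("c1a", "c2a"))
  # tie on p within G3 resolved lexicographically
  expect_equal(calls$top_cpg[3], "c3a")
  expect_equal(calls$n_cpg, c(2L, 1L, 2L, 0L))
  expect_equal(calls$direction[1], 1)

  # 448 genes with 1000 mapped CpGs: cutoff 5e-5
  big_map <- tibble::tibble(cpg_id = sprintf("c%04d", 1:1000),
                            gene = rep(sprintf("g%03d", 1:448), length.out = 1000))
  big_ewas <- tibble::tibble(feature = big_map$cpg_id, beta = 1, p = 0.5)
  big <- call_dmgs(big_ewas, big_map, sprintf("g%03d", 1:448))
  expect_equal(attr(big, "cutoff"), 5e-5)

  # invariance to CpG row order
  calls2 <- call_dmgs(ewas[sample(5), ], map[sample(6), ], c("G1", "G2", "G3", "G4"))
  expect_equal(attr(calls2, "N"), attr(calls, "N"))
  expect_equal(calls2$is_dmg, calls$is_dmg)

  expect_error(call_dmgs(ewas, map[0, ], "G1"), "Empty CpG map")
})

test_that("permutation null matches the hypergeometric oracle and its edge cases", {
  universe <- sprintf("g%03d", 1:100)
  dmg <- rep(c(TRUE, FALSE), c(30, 70))
  res <- permutation_enrichment(universe, dmg, observed = 9, set_size = 10,
                                n_perm = 1e5, seed = 99)
  # closed-form hypergeometric mean 10 * 30/100 = 3 within 3 Monte-Carlo SEs
  hyper_sd <- sqrt(10 * 0.3 * 0.7 * 90 / 99)
  expect_lt(abs(res$null_mean - 3), 3 * hyper_sd / sqrt(1e5))
  expect_true(res$p > 0)
  expect_true(all(res$null_counts <= 10))

  # reproducibility under seed, and the caller's RNG is untouched
  set.seed(1); before <- .Random.seed
  res2 <- permutation_enrichment(universe, dmg, 9, 10, n_perm = 1000, seed = 99)
  expect_identical(.Random.seed, before)
  res3 <- permutation_enrichment(universe, dmg, 9, 10, n_perm = 1000, seed = 99)
  expect_identical(res2$null_counts, res3$null_counts)

  # saturated universe: every null count equals the set size, p = 1
  sat <- permutation_enrichment(universe, rep(TRUE, 100), observed = 10,
                                set_size = 10, n_perm = 500, seed = 1)
  expect_true(all(sat$null_counts == 10))
  expect_equal(sat$p, 1)

  # observed above every null count: p hits the add-one floor
  top <- permutation_enrichment(universe, dmg, observed = 11, set_size = 10,
                                n_perm = 1000, seed = 2)
  expect_equal(top$p, 1 / 1001)
  expect_error(permutation_enrichment(universe, dmg, 5, set_size = 101),
               "exceeds the universe")
})

test_that("empirical p is monotone in the observed count on a fixed null sample", {
  universe <- sprintf("g%02d", 1:50)
  dmg <- rep(c(TRUE, FALSE), c(10, 40))
  ps <- vapply(0:10, function(obs) {
    permutation_enrichment(universe, dmg, obs, set_size = 10,
                           n_perm = 2000, seed = 7)$p
  }, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("mediated genes are called DMGs and their CpG adjustment attenuates them", {
  study <- simulate_study(sim_config(n_subjects = 800, n_families = 320,
                                     n_genes = 120, n_true_genes = 24,
                                     planted_cluster_size = 10, seed = 81))
  est <- kd_estimates(study$cohort)
  scan <- run_scan(study$expression, est, study$cohort,
                   covariate_names = scan_covars)
  sig <- dplyr::filter(scan$results, significant)
  ewas <- ewas_scan(study$meth, est, study$cohort,
                    covariate_names = scan_covars)
  calls <- call_dmgs(ewas, study$cpg_map, sort(sig$gene))
  med_in_sig <- intersect(study$truth$mediated_gene_ids, sig$gene)
  expect_gt(length(med_in_sig), 3)
  expect_gt(mean(calls$is_dmg[calls$gene %in% med_in_sig]), 0.8)
  # non-mediated genes are rarely DMGs
  non_med <- setdiff(sig$gene, study$truth$mediated_gene_ids)
  expect_lt(mean(calls$is_dmg[calls$gene %in% non_med]), 0.3)

  att <- attenuation_analysis(study$expression, study$meth, calls, est,
                              study$cohort, covariate_names = scan_covars)
  g <- glance(att)
  expect_equal(g$n_dmg, sum(calls$is_dmg))
  expect_true(all(att$attenuated == (abs(att$beta_after) < abs(att$beta_before)),
                  na.rm = TRUE))
  # mediated DMGs should be attenuated essentially always
  expect_gt(mean(att$attenuated[att$gene %in% med_in_sig], na.rm = TRUE), 0.8)
})

test_that("a CpG unrelated to expression and delta age attenuates at chance level", {
  set.seed(83)
  n <- 300
  fam <- sample(rep(1:100, 3))
  x <- rnorm(n)
  atten <- vapply(1:60, function(i) {
    y <- 0.3 * x + rnorm(n)
    cpg <- runif(n)
    before <- fit_feature_lmm(y, x, family = fam)
    after <- fit_feature_lmm(y, x, data.frame(cpg = cpg), family = fam)
    abs(after$beta) < abs(before$beta)
  }, logical(1))
  expect_gt(mean(atten), 0.25)
  expect_lt(mean(atten), 0.75)
})

test_that("full mediation with vanishing noise drives the adjusted effect to zero", {
  # meth_noise_sd must stay nonzero: at exactly zero the mediator is an
  # exact affine function of delta age and the design is rank deficient,
  # which the fitter correctly refuses (checked below)
  cfg <- sim_config(n_subjects = 500, n_families = 200, n_genes = 60,
                    n_true_genes = 12, planted_cluster_size = 6,
                    mediation_strength = 1, meth_noise_sd = 0.02,
                    expr_noise_sd = 0.05, seed = 84)
  cg <- generate_cohort(cfg)
  expr <- generate_expression(cg$cohort, cg$truth, cfg)
  me <- generate_methylation(cg$cohort, cg$truth, cfg)
  est <- tibble::tibble(subject_id = cg$cohort$subject_id,
                        delta_age = cg$truth$delta)
  # with the mediator nearly an affine function of delta age, the adjusted
  # effect is an estimate of zero: strongly significant before, consistent
  # with zero after (the point estimate itself is noise under
  # near-collinearity, so the check is in z-statistic terms)
  for (gene in cg$truth$mediated_gene_ids[1:3]) {
    cpg <- me$cpg_map$cpg_id[me$cpg_map$gene == gene][1]
    latent <- qlogis(me$meth[cpg, ])   # logit scale, where the pathway is linear
    before <- fit_feature_lmm(expr[gene, ], est$delta_age,
                              family = cg$cohort$family_id)
    after <- fit_feature_lmm(expr[gene, ], est$delta_age,
                             data.frame(m = latent),
                             family = cg$cohort$family_id)
    expect_gt(abs(before$beta / before$se), 20)
    expect_lt(abs(after$beta / after$se), 3.5)
  }

  # the exactly-noise-free limit is a rank-deficient design, refused loudly
  cfg0 <- cfg; cfg0$meth_noise_sd <- 0
  me0 <- generate_methylation(cg$cohort, cg$truth, cfg0)
  gene <- cg$truth$mediated_gene_ids[1]
  cpg0 <- me0$cpg_map$cpg_id[me0$cpg_map$gene == gene][1]
  expect_error(
    fit_feature_lmm(expr[gene, ], est$delta_age,
                    data.frame(m = qlogis(me0$meth[cpg0, ])),
                    family = cg$cohort$family_id),
    "collinear"
  )
})
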