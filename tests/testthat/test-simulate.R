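test_that("cohort generation is reproducible and honours the latent-age structure", {
  cfg <- small_config(seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # delta independent of chronologic age as n grows (|r| < 2/sqrt(n), 20 seeds)
  bad <- 0
  for (s in 1:20) {
    cg <- generate_cohort(sim_config(n_subjects = 1000, seed = s))
    r <- cor(cg$truth$delta, cg$cohort$age)
    if (abs(r) >= 2 / sqrt(1000)) bad <- bad + 1
  }
  expect_lte(bad, 1)

  # sign composition of true effects matches frac_positive within rounding
  eff <- a$truth$true_effects
  expect_equal(sum(eff > 0), round(cfg$frac_positive * cfg$n_true_genes))
  expect_true(all(a$truth$mediated_gene_ids %in% a$truth$true_gene_ids))
})

test_that("zero biomarker noise makes every biomarker affine in true biologic age", {
  cfg <- small_config(seed = 2, biomarker_noise_scale = 0)
  cg <- generate_cohort(cfg)
  for (b in panel9) {
    f <- lm(cg$cohort[[b]] ~ cg$truth$true_ba)
    expect_lt(suppressWarnings(summary(f))$sigma, 1e-10)
  }
})

test_that("realized correlations approximate their targets at n = 2000", {
  cg <- generate_cohort(sim_config(seed = 1))
  # corr(delta, age) near zero
  expect_lt(abs(cor(cg$truth$delta, cg$cohort$age)), 0.05)
  # the designated pair (CRP/IL-6 analog) sits within +-0.07 of 0.52
  expect_lt(abs(cor(cg$cohort$crp, cg$cohort$il6) - 0.52), 0.07)
  # age-correlated biomarkers come out near their targets
  r_real <- vapply(panel9, function(b) cor(cg$cohort[[b]], cg$cohort$age), 0)
  targets <- sim_config()$biomarker_age_r
  expect_lt(max(abs(r_real - targets)), 0.07)
})

test_that("infeasible correlation targets raise an error naming the pair", {
  expect_error(
    generate_cohort(sim_config(n_subjects = 100, seed = 1,
                               biomarker_age_r = rep(0.9, 9),
                               high_cor_r = 0.95)),
    "positive definite"
  )
})

test_that("expression has the contracted shape and a clean null limit", {
  cfg <- small_config(seed = 3)
  cg <- generate_cohort(cfg)
  expr <- generate_expression(cg$cohort, cg$truth, cfg)
  expect_identical(dim(expr), as.integer(c(cfg$n_genes, cfg$n_subjects)))
  expect_identical(rownames(expr), cg$truth$gene_ids)
  expect_identical(colnames(expr), cg$cohort$subject_id)

  # n_true_genes = 0: no gene carries a delta term
  cfg0 <- small_config(seed = 3, n_true_genes = 0, planted_cluster_size = 0,
                       mediation_fraction = 0)  # override of the helper defaults
  cg0 <- generate_cohort(cfg0)
  expr0 <- generate_expression(cg0$cohort, cg0$truth, cfg0)
  slopes <- apply(expr0[1:30, ], 1, function(y) coef(lm(y ~ cg0$truth$delta))[2])
  expect_lt(max(abs(slopes)), 0.05)
})

test_that("methylation beta-values live in [0, 1] and track mediation strength", {
  cfg <- small_config(seed = 4)
  cg <- generate_cohort(cfg)
  me <- generate_methylation(cg$cohort, cg$truth, cfg)
  expect_true(all(me$meth >= 0 & me$meth <= 1))
  expect_equal(nrow(me$meth), cfg$n_genes * cfg$n_cpg_per_gene)

  # mediation_strength = 0: lead CpGs are independent of delta
  cfg0 <- small_config(seed = 4, mediation_strength = 0)
  cg0 <- generate_cohort(cfg0)
  me0 <- generate_methylation(cg0$cohort, cg0$truth, cfg0)
  lead0 <- me0$cpg_map$cpg_id[me0$cpg_map$gene %in% cg0$truth$mediated_gene_ids]
  lead0 <- lead0[endsWith(lead0, "_1")]
  r0 <- vapply(lead0, function(c) cor(me0$meth[c, ], cg0$truth$delta), 0)
  expect_lt(max(abs(r0)), 0.2)

  # mediation_strength = 1, noise -> 0: CpG is an exact monotone transform
  cfg1 <- small_config(seed = 4, mediation_strength = 1, meth_noise_sd = 0)
  cg1 <- generate_cohort(cfg1)
  me1 <- generate_methylation(cg1$cohort, cg1$truth, cfg1)
  lead1 <- me1$cpg_map$cpg_id[me1$cpg_map$gene %in% cg1$truth$mediated_gene_ids]
  lead1 <- lead1[endsWith(lead1, "_1")][1]
  expect_equal(cor(me1$meth[lead1, ], cg1$truth$delta, method = "spearman"), 1)
})

test_that("network generation is clean and plants a connected true-gene cluster", {
  cfg <- small_config(seed = 6)
  cg <- generate_cohort(cfg)
  net <- generate_network(cg$truth, cfg)
  expect_true(all(net$from != net$to))
  expect_false(any(duplicated(paste(net$from, net$to))))
  expect_true(all(net$from <= net$to))
  planted <- attr(net, "planted")
  expect_length(planted, cfg$planted_cluster_size)
  expect_true(all(planted %in% cg$truth$true_gene_ids))
  g <- igraph::graph_from_data_frame(net, directed = FALSE)
  sub <- igraph::induced_subgraph(g, planted)
  expect_true(igraph::is_connected(sub))

  cfg_bad <- small_config(seed = 6)
  cfg_bad$planted_cluster_size <- 1e6
  expect_error(generate_network(cg$truth, cfg_bad), "larger than the graph")
})

test_that("survival times are positive with a null-hazard Cox sanity limit", {
  cfg <- small_config(seed = 7)
  cg <- generate_cohort(cfg)
  coh <- generate_survival(cg$cohort, cg$truth, cfg)
  expect_true(all(coh$time > 0))
  expect_true(all(coh$event %in% c(0, 1)))
  expect_true(all(coh$time <= cfg$follow_up_years))

  # score_log_hr = 0: hazard does not depend on delta
  cfg0 <- sim_config(n_subjects = 1500, n_families = 600, n_genes = 50,
                     n_true_genes = 5, planted_cluster_size = 0,
                     score_log_hr = 0, seed = 7)
  cg0 <- generate_cohort(cfg0)
  coh0 <- generate_survival(cg0$cohort, cg0$truth, cfg0)
  fit <- survival::coxph(survival::Surv(time, event) ~ scale(cg0$truth$delta),
                         data = coh0)
  expect_gt(summary(fit)$coefficients[1, "Pr(>|z|)"], 0.01)
})

test_that("gene sets include a true-gene-enriched set and GMT round-trips", {
  cfg <- small_config(seed = 8)
  cg <- generate_cohort(cfg)
  sets <- generate_genesets(cg$truth, cfg)
  expect_true(all(cg$truth$true_gene_ids %in% sets$PLANTED_SET))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(unclass(back)[names(sets)],
                   lapply(unclass(sets), as.character))
})
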