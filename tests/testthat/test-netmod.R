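test_that("p-to-score conversion follows the standard-normal quantile contract", {
  out <- p_to_z(c(0.5, 0.05, 2.8e-6, 0.9), beta_sign = c(1, -1, 1, 1))
  expect_equal(out$g[1], 0)
  expect_equal(out$g[2], 1.6449, tolerance = 1e-4)
  expect_equal(out$g[3], qnorm(1 - 2.8e-6), tolerance = 1e-10)
  expect_equal(round(out$g[3], 2), 4.54)
  expect_equal(out$g[4], 0)  # p > 0.5 truncated at zero
  expect_equal(out$z_signed[2], -qnorm(1 - 0.05 / 2))
  expect_warning(capped <- p_to_z(0), "capped")
  expect_equal(capped$g, qnorm(1e-30, lower.tail = FALSE))
})

test_that("greedy growth accepts only strict improvements of Z_m", {
  # isolated seed
  net1 <- toy_network(c(A = 3, B = 0, C = 0, D = 0, E = 0))
  net1$edges <- net1$edges[0, ]
  m1 <- grow_module(net1, "A")
  expect_equal(m1$members, "A")
  expect_equal(m1$z_m, 3)

  # seed g = 3 with a zero-score neighbor: 3/sqrt(2) < 3, rejected
  net2 <- toy_network(c(A = 3, B = 0, C = 0, D = 0, E = 0))
  m2 <- grow_module(net2, "A")
  expect_equal(m2$members, "A")
  expect_equal(m2$z_m, 3)

  # a strong neighbor is absorbed: (3 + 3)/sqrt(2) > 3
  net3 <- toy_network(c(A = 3, B = 3, C = 0, D = 0, E = 0))
  m3 <- grow_module(net3, "A")
  expect_setequal(m3$members, c("A", "B"))
  expect_equal(m3$z_m, 6 / sqrt(2))
  expect_true(all(diff(m3$trace$z_m) > 0))

  expect_error(grow_module(net3, "ZZ"), "absent")
})

test_that("every greedy step is maximal among candidates on random small graphs", {
  set.seed(61)
  for (rep in 1:100) {
    k <- sample(4:8, 1)
    genes <- LETTERS[1:k]
    full <- t(combn(genes, 2))
    keep <- runif(nrow(full)) < 0.45
    if (!any(keep)) next
    edges <- tibble::tibble(from = full[keep, 1], to = full[keep, 2])
    gsc <- round(runif(k, 0, 4), 2)
    names(gsc) <- genes
    results <- tibble::tibble(gene = genes, p = 1 - pnorm(gsc), beta = 1)
    net <- score_network(edges, results)
    seed_gene <- sample(net$nodes$gene, 1)
    mod <- grow_module(net, seed_gene)

    # oracle: replay the greedy expansion with an exhaustive candidate scan
    adj <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                         vertices = net$nodes$gene)
    members <- seed_gene
    z <- net$nodes$g[match(seed_gene, net$nodes$gene)]
    repeat {
      nb <- unique(unlist(lapply(members, function(m)
        names(igraph::neighbors(adj, m)))))
      nb <- setdiff(nb, members)
      if (length(nb) == 0) break
      gg <- net$nodes$g[match(nb, net$nodes$gene)]
      tot <- sum(net$nodes$g[match(members, net$nodes$gene)])
      znew <- (tot + gg) / sqrt(length(members) + 1)
      if (max(znew) <= z) break
      best <- nb[znew == max(znew)]
      best <- best[order(-gg[match(best, nb)], best)][1]
      members <- c(members, best)
      z <- max(znew)
    }
    expect_setequal(mod$members, members)
    expect_equal(mod$z_m, z, tolerance = 1e-12)
    # Z_m recomputes from members exactly
    expect_equal(mod$z_m,
                 sum(net$nodes$g[match(mod$members, net$nodes$gene)]) /
                   sqrt(mod$k), tolerance = 1e-12)
    expect_gte(mod$z_m, net$nodes$g[match(seed_gene, net$nodes$gene)])
  }
})

test_that("the merged subnetwork is the induced union of the seed modules", {
  net <- toy_network(c(A = 3, B = 2.5, C = 2.2, D = 0.1, E = 1.5))
  sub <- suppressWarnings(build_subnetwork(net, n_seeds = 2))
  expect_setequal(sub$nodes$gene,
                  unique(unlist(lapply(sub$modules, `[[`, "members"))))
  # every edge of the parent network between members is present
  among <- net$edges$from %in% sub$nodes$gene & net$edges$to %in% sub$nodes$gene
  expect_equal(sub$n_edges, sum(among))
  expect_equal(glance(sub)$n_nodes, sub$n_nodes)

  # all scores zero: no growth beyond seeds
  net0 <- toy_network(c(A = 0, B = 0, C = 0, D = 0, E = 0))
  sub0 <- suppressWarnings(build_subnetwork(net0, n_seeds = 3))
  expect_equal(sort(sub0$nodes$gene), sort(sub0$seeds))
  expect_warning(build_subnetwork(net0, n_seeds = 10), "seeds")

  # duplicate modules merge idempotently
  net2 <- toy_network(c(A = 3, B = 3, C = 0, D = 0, E = 0))
  sub2 <- suppressWarnings(build_subnetwork(net2, n_seeds = 2))
  expect_false(any(duplicated(sub2$nodes$gene)))

  p <- autoplot(sub)
  expect_s3_class(p, "ggplot")
})

test_that("determinism and unscored-connector handling hold on simulated studies", {
  study <- small_study(seed = 62)
  est <- kd_estimates(study$cohort)
  scan <- run_scan(study$expression, est, study$cohort,
                   covariate_names = scan_covars)
  # score only half the genes: the rest stay as unscored connectors with g = 0
  half <- scan$results[1:75, ]
  net <- score_network(study$network, half)
  expect_true(all(net$nodes$g[!net$nodes$scored] == 0))
  sub1 <- suppressWarnings(build_subnetwork(net, n_seeds = 10))
  sub2 <- suppressWarnings(build_subnetwork(net, n_seeds = 10))
  expect_identical(sub1$nodes, sub2$nodes)
  expect_identical(sub1$edges, sub2$edges)
})

test_that("the planted cluster is recovered from full-size studies", {
  recovered <- numeric(0)
  for (s in 1:3) {
    cfg <- sim_config(seed = 70 + s)
    cg <- generate_cohort(cfg)
    expr <- generate_expression(cg$cohort, cg$truth, cfg)
    netw <- generate_network(cg$truth, cfg)
    est <- kd_estimates(cg$cohort)
    scan <- run_scan(expr, est, cg$cohort, covariate_names = scan_covars)
    net <- suppressWarnings(score_network(netw, scan))  # p = 0 cap warning
    sub <- build_subnetwork(net, n_seeds = 25)
    planted <- attr(netw, "planted")
    recovered <- c(recovered, mean(planted %in% sub$nodes$gene))
  }
  expect_gte(mean(recovered), 0.8)
})
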