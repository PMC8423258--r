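test_that("parallel one-step changes in a compound locus are both counted", {
  panel <- tiny_panel()
  # GT[19]GTCT[4] vs GT[20]GTCT[5]-style case: two motifs step in parallel
  a <- list(COMPOUND = matrix(c(7L, 15L), nrow = 1))
  b <- list(COMPOUND = matrix(c(8L, 16L), nrow = 1))
  cmp <- compare_pair(a, b, panel, meioses = 13)
  expect_equal(cmp$loci$steps_min, 2)
  expect_equal(cmp$loci$steps_max, 2)
  expect_equal(cmp$events$size, c(1L, 1L))

  # equal total allele call but different split is still a difference
  b2 <- list(COMPOUND = matrix(c(8L, 14L), nrow = 1))
  cmp2 <- compare_pair(a, b2, panel)
  expect_gt(cmp2$loci$steps_mid, 0)
})

test_that("identical profiles compare to zero everywhere", {
  panel <- tiny_panel()
  g <- reference_genotype(panel)
  cmp <- compare_pair(g, g, panel)
  expect_true(all(cmp$loci$steps_min == 0))
  expect_true(all(cmp$loci$steps_max == 0))
  expect_equal(nrow(cmp$events), 0L)

  # equal multi-copy calls in crossed order are still identical
  a <- list(DICOPY = matrix(c(19L, 21L), ncol = 1))
  b <- list(DICOPY = matrix(c(21L, 19L), ncol = 1))
  cmp2 <- compare_pair(a, b, panel)
  expect_equal(cmp2$loci$steps_max, 0)

  # an unchanged copy adds no steps to the overestimate
  c2 <- list(DICOPY = matrix(c(19L, 23L), ncol = 1))
  cmp3 <- compare_pair(a, c2, panel)
  expect_equal(cmp3$loci$steps_min, 2)
  expect_equal(cmp3$loci$steps_max, 2)
})

test_that("loci missing from either profile are skipped", {
  panel <- tiny_panel()
  g <- reference_genotype(panel)
  g2 <- g
  g2$SIMPLE <- NULL
  cmp <- compare_pair(g, g2, panel)
  expect_false("SIMPLE" %in% cmp$loci$locus)
  g3 <- g
  g3$DICOPY <- g$DICOPY[1, , drop = FALSE]
  expect_error(compare_pair(g, g3, panel), "copy_count mismatch")
})

test_that("multi-copy parsimony bounds match recursive brute force", {
  panel <- list(MC = tiny_panel()$DICOPY)
  set.seed(41)
  for (i in 1:200) {
    cc <- sample(c(2L, 4L), 1)
    nb <- sample(1:2, 1)
    a <- matrix(sample(10:25, cc * nb, replace = TRUE), nrow = cc)
    b <- matrix(sample(10:25, cc * nb, replace = TRUE), nrow = cc)
    cmp <- compare_pair(list(MC = a), list(MC = b),
                        list(MC = list(copy_count = cc,
                                       distinguishable_copies = FALSE)))
    bf <- brute_force_steps(a, b)
    expect_equal(cmp$loci$steps_min, unname(bf["min"]))
    expect_equal(cmp$loci$steps_max, unname(bf["max"]))
    # parsimony bound: optimal <= identity matching of sorted vectors
    if (nb == 1L) {
      sorted_cost <- sum(abs(sort(a[, 1]) - sort(b[, 1])))
      expect_equal(cmp$loci$steps_min, sorted_cost)
    }
  }
})

test_that("rate estimates reproduce published per-locus arithmetic", {
  # 1 difference over 1,279 meioses
  e <- mutation_rate(1, 1279)
  expect_equal(round(e$rate * 1e3, 2), 0.78)
  expect_equal(round(e$ci_low * 1e3, 2), 0.02)
  expect_equal(round(e$ci_high * 1e3, 2), 4.35)
  expect_equal(e$class, "slow")

  # 2 differences over 4,822 meioses (four-copy marker)
  e2 <- mutation_rate(2, 4822)
  expect_equal(round(e2$rate * 1e3, 2), 0.41)
  expect_equal(round(e2$ci_low * 1e3, 2), 0.05)
  expect_equal(round(e2$ci_high * 1e3, 2), 1.50)

  e0 <- mutation_rate(0, 500)
  expect_equal(e0$rate, 0)
  expect_equal(e0$ci_low, 0)
  expect_equal(e0$class, "non_mutating")

  expect_error(mutation_rate(1, 0), "meioses")
})

test_that("rate classes split on unrounded thresholds", {
  expect_equal(mutation_rate(0.99, 1000)$class, "slow")
  expect_equal(mutation_rate(1, 1000)$class, "moderate")
  expect_equal(mutation_rate(4.99, 1000)$class, "moderate")
  expect_equal(mutation_rate(5, 1000)$class, "fast")
  expect_equal(mutation_rate(10, 1000)$class, "rapid")
})

test_that("panel aggregation reproduces published totals", {
  s <- panel_rate_summary(982, 214859, 982, 214859 - 66972,
                          step_counts = c(one = 759, two = 98, multi = 53))
  expect_equal(round(s$rate * 1e3, 2), 4.57)
  expect_equal(round(s$mutating_rate * 1e3, 2), 6.64)
  expect_equal(round(s$ci_normal * 1e3, 2), c(4.29, 4.86))
  expect_equal(unname(s$step_ratio_pct), c(83, 11, 6))
})

test_that("aggregating a single pair equals the direct rate", {
  panel <- tiny_panel()
  a <- reference_genotype(panel)
  b <- a
  b$SIMPLE[1, 1] <- b$SIMPLE[1, 1] + 1L
  agg <- aggregate_rates(list(compare_pair(a, b, panel, meioses = 50)))
  row <- agg$per_locus[agg$per_locus$locus == "SIMPLE", ]
  direct <- mutation_rate(1, 50)
  expect_equal(row$rate, direct$rate)
  expect_equal(row$ci_low, direct$ci_low)
  expect_equal(row$ci_high, direct$ci_high)
})

test_that("simulated pedigrees recover the planted rate within the CI", {
  panel <- tiny_panel()[c("SIMPLE", "COMPOUND")]
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(seed = 3000 + r, mutation_rate = 5e-3,
                      step_one_prob = 1)
    ped <- simulate_pedigree(panel, cfg, 150)
    cmp <- compare_pair(ped$profiles[[1]], ped$profiles[[151]], panel,
                        meioses = 150)
    agg <- aggregate_rates(list(cmp))
    # panel-wide interval over 2 loci x 150 meioses
    ci <- agg$panel$ci_exact
    if (ci[1] <= 5e-3 && 5e-3 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 0.90 * n_rep)
})

test_that("chi-square literature comparison behaves like a binomial test", {
  eq <- compare_rate_to_reference(5, 1000, 5e-3)
  expect_equal(eq$statistic, 0)
  expect_false(eq$significant)

  # a locus with 1 event over 296 meioses against a 0.40e-3 reference
  res <- compare_rate_to_reference(1, 296, 0.40e-3)
  expect_true(res$significant)

  set.seed(19)
  for (i in 1:20) {
    m <- sample(2000:6000, 1)
    ref <- runif(1, 5e-3, 2e-2)
    x <- rbinom(1, m, 1.3 * ref)
    p_chi <- compare_rate_to_reference(x, m, ref)$p_value
    # the 1-df goodness-of-fit equals the two-sided score test exactly
    z <- (x - m * ref) / sqrt(m * ref * (1 - ref))
    expect_equal(p_chi, 2 * stats::pnorm(-abs(z)), tolerance = 1e-10)
    # and tracks the exact binomial test when expected counts are large
    p_bin <- stats::binom.test(x, m, ref)$p.value
    expect_lt(abs(p_chi - p_bin), 0.05)
  }
})

test_that("distinguishability reproduces the panel-level expectation", {
  expect_equal(distinguish_probability(6.64e-3, 0, 136), 0)
  expect_equal(round(panel_mutations_per_generation(6.64e-3, 136), 1), 0.9)
  expect_equal(round(100 * distinguish_probability(6.64e-3, 2, 136)), 84)

  # monotone in generations, loci and rates
  p2 <- distinguish_probability(6.64e-3, 2, 136)
  expect_gt(distinguish_probability(6.64e-3, 3, 136), p2)
  expect_gt(distinguish_probability(6.64e-3, 2, 150), p2)
  expect_gt(distinguish_probability(7e-3, 2, 136), p2)

  # heterogeneous rates match a Monte-Carlo simulation within 3 s.e.
  set.seed(29)
  rates <- runif(40, 1e-4, 2e-2)
  p <- distinguish_probability(rates, 3)
  n_mc <- 20000
  diffs <- replicate(n_mc, any(rbinom(40, 3, rates) > 0))
  se <- sqrt(p * (1 - p) / n_mc)
  expect_lt(abs(mean(diffs) - p), 3 * se + 1e-12)
})

test_that("maximum allowed differences matches binomial and Monte Carlo", {
  expect_equal(max_allowed_differences(rep(0, 20), 4), 0)
  # uniform rates reduce to a plain binomial quantile
  expect_equal(max_allowed_differences(rep(0.01, 50), 2, 0.95),
               qbinom(0.95, 100, 0.01))
  expect_equal(max_allowed_differences(rep(0.03, 30), 5, 0.99),
               qbinom(0.99, 150, 0.03))
  # heterogeneous rates against a large Monte-Carlo quantile
  set.seed(37)
  rates <- runif(60, 1e-3, 3e-2)
  k <- max_allowed_differences(rates, 4, 0.95)
  draws <- replicate(50000, sum(rbinom(60, 4, rates)))
  expect_equal(k, unname(quantile(draws, 0.95, type = 1)))
})
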