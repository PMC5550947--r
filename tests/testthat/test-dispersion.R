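# Method-of-moments dispersion estimation and its diagnostics.

test_that("neutral and gene proportions are the count ratios", {
  p1 <- toy_pair(c(2, 0), c(1, 1))
  expect_equal(gene_proportion(p1), 0.5)
  expect_equal(gene_proportion(toy_pair(c(5, 5), c(10, 0))), 0.5)
  expect_equal(gene_proportion(toy_pair(c(0, 0), c(2, 1))), 0)
  expect_equal(gene_proportion(toy_pair(1, 3)), 0.25)
  expect_true(is.na(gene_proportion(toy_pair(0, 0))))
  pair <- list(g1 = toy_pair(c(100, 200), c(300, 400)),
               g2 = toy_pair(0, 0))
  expect_equal(neutral_proportion(pair), 300 / 1000)
  expect_equal(neutral_proportion(list(g1 = toy_pair(c(3, 1), c(3, 1)))), 0.5)
  expect_error(neutral_proportion(list(g1 = toy_pair(0, 0))), "zero grand total")
})

test_that("the moment estimator reproduces hand-computed values", {
  # zero deviation: sigma = 0, theta-hat = -1/t (flagged by flooring later)
  expect_equal(estimate_theta(5, 5, 0.5)$theta, -0.1)
  # n = 8, m = 2, p_nr = 0.5: sigma = 0.09, theta-hat = 0.26/0.64
  expect_equal(estimate_theta(8, 2, 0.5)$theta, 0.40625)
  # invalid when the denominator is non-positive: n = 10, m = 0 gives
  # sigma/(pq) = 1
  est <- estimate_theta(10, 0, 0.5)
  expect_false(est$valid)
  expect_true(is.na(est$theta))
  expect_error(estimate_theta(0, 0, 0.5), "zero-depth")
})

test_that("the estimator is invariant under sample swap with p -> 1 - p", {
  set.seed(5)
  N <- matrix(rpois(300, 20), 100, 3)
  M <- matrix(rpois(300, 30), 100, 3)
  keep <- rowSums((N + M) == 0) == 0
  N <- N[keep, ]; M <- M[keep, ]
  p_nr <- c(0.4, 0.45, 0.38)
  a <- estimate_theta(N, M, p_nr)
  b <- estimate_theta(M, N, 1 - p_nr)
  expect_equal(a$theta, b$theta)
})

test_that("the estimator is consistent under beta-binomial sampling and
           centred at zero under binomial sampling", {
  set.seed(17)
  # fixed depth 200, true theta 0.05, 10000 positions, single pair
  t <- rep(200L, 10000)
  n <- rbetabinom(t, 0.5, 0.05)
  est <- estimate_theta(matrix(n, ncol = 1), matrix(t - n, ncol = 1), 0.5)
  expect_equal(mean(est$theta), 0.05, tolerance = 0.1)
  # binomial null: mean theta-hat within 3 standard errors of 0
  n0 <- rbinom(10000, 200L, 0.5)
  est0 <- estimate_theta(matrix(n0, ncol = 1), matrix(200L - n0, ncol = 1), 0.5)
  se <- sd(est0$theta) / sqrt(length(est0$theta))
  expect_lt(abs(mean(est0$theta)), 3 * se)
})

test_that("observation building floors, flags and filters correctly", {
  # a pair set with one gene: positions at depth below min_depth in any
  # pair are absent; non-positive estimates are floored and flagged
  ps <- list(list(g1 = toy_pair(c(5, 2, 1), c(5, 6, 1))),
             list(g1 = toy_pair(c(4, 3, 8), c(6, 5, 9))))
  obs <- build_theta_observations(ps, filter_config(min_depth = 5),
                                  floor = 1e-6)
  expect_equal(obs$position, c(0L, 1L))  # depth-2 position dropped
  expect_true(all(obs$depth >= 5))
  # position 0 has zero deviation in pair 1 -> negative raw estimate
  expect_true(obs$floored[1])
  expect_equal(obs$theta_hat[1], 1e-6)
  expect_lt(obs$theta_raw[1], 0)

  # record count equals simulator bookkeeping of retained positions
  cfg <- sim_config(G = 10, gene_length = 200, seed = 19)
  sim <- simulate_replicates(cfg, n_samples = 3)
  ps2 <- replicate_pair_set(sim)
  cfg_f <- filter_config(min_depth = 5)
  obs2 <- build_theta_observations(ps2, cfg_f)
  expected <- 0L
  for (g in sim$genes$gene_id) {
    t_pairs <- vapply(ps2, function(p) p[[g]]$depth,
                      numeric(sim$genes$length[1]))
    expected <- expected + sum(rowSums(t_pairs < 5) == 0)
  }
  expect_equal(nrow(obs2), expected)
})

test_that("the depth profile recovers a gamma = -1 slope and degenerates
           sensibly", {
  cfg <- sim_config(G = 60, gene_length = 400,
                    theta_model = list(variant = "primer_free", D = 1,
                                       gamma = -1),
                    seed = 23)
  sim <- simulate_replicates(cfg, n_samples = 4)
  obs <- build_theta_observations(replicate_pair_set(sim))
  prof <- depth_dispersion_profile(obs[!obs$floored, ], n_bins = 15)
  fit <- lm(mean_log10_theta ~ log10_depth_mid, data = prof,
            weights = prof$n)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
  expect_error(depth_dispersion_profile(obs, n_bins = 1), "at least 2")

  # all theta-hat equal: flat profile, and an empty GGGG subset is fine
  obs_flat <- obs[1:500, ]
  obs_flat$theta_hat <- 0.02
  obs_flat$floored <- FALSE
  obs_flat$context <- gsub("GGGG", "GTGT", obs_flat$context)
  prof_flat <- depth_dispersion_profile(obs_flat, n_bins = 5)
  expect_true(all(abs(prof_flat$mean_log10_theta - log10(0.02)) < 1e-12))
  expect_true(all(prof_flat$n_gggg == 0))
})

test_that("the positional profile ranks by distance to the gene end", {
  # tail-inflated dispersion: part 1 (tail) exceeds part 10 (start)
  cfg <- sim_config(G = 40, gene_length = 500, tail_factor = 3,
                    tail_length = 200, seed = 29)
  sim <- simulate_replicates(cfg, n_samples = 4)
  obs <- build_theta_observations(replicate_pair_set(sim))
  prof <- positional_profile(obs, sim$genes, n_parts = 10)
  expect_equal(nrow(prof), 10L)
  expect_gt(prof$mean_theta[1], prof$mean_theta[10])
  # equal data points per part (up to rounding)
  expect_lte(diff(range(prof$n)), 1)

  # uniform dispersion: no monotone trend (slope CI covers 0)
  cfg0 <- sim_config(G = 40, gene_length = 500, seed = 30)
  sim0 <- simulate_replicates(cfg0, n_samples = 4)
  obs0 <- build_theta_observations(replicate_pair_set(sim0))
  # remove the depth trend by using the raw estimate against part rank
  prof0 <- positional_profile(obs0, sim0$genes, n_parts = 10)
  fit0 <- lm(mean_theta ~ part, data = prof0)
  ci <- confint(fit0)["part", ]
  expect_true(ci[1] < 0 && ci[2] > 0)

  # n_parts = 1 is the overall mean
  prof1 <- positional_profile(obs, sim$genes, n_parts = 1)
  expect_equal(prof1$mean_theta,
               mean(obs$theta_hat[!obs$invalid & is.finite(obs$theta_hat)]))
  expect_error(positional_profile(obs[1:3, ], sim$genes, n_parts = 10),
               "fewer positions")
})
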