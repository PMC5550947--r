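# Indicator design, least-squares model fits, cross-validation and
# coefficient profiles.

test_that("the design has the documented column structure", {
  obs <- toy_obs(500, logD = log(0.5), gamma = -0.5, K = 80L)
  d <- build_design(obs, design_spec(K = 80))
  expect_equal(ncol(d$X), 242L)  # intercept + depth + 240 indicators
  expect_equal(colnames(d$X)[1:2], c("(Intercept)", "log_depth"))
  d2 <- build_design(obs, design_spec(K = 80, include_sequence = FALSE))
  expect_equal(ncol(d2$X), 2L)
  # indicators are exactly 0/1 and rows sum to K minus reference-base hits
  seq_cols <- d$X[, -(1:2)]
  expect_true(all(seq_cols %in% c(0, 1)))
  n_ref <- vapply(strsplit(obs$context, ""), function(ch) sum(ch == "G"),
                  numeric(1))
  expect_equal(unname(rowSums(seq_cols)), 80 - n_ref)
  expect_error(build_design(obs[0, ], design_spec()), "empty")
})

test_that("indicator coding follows the window and reference base", {
  obs <- toy_obs(3, logD = 0, gamma = 0, K = 2L)
  obs$context <- c("AG", "GG", "TC")
  d <- build_design(obs, design_spec(K = 2))
  # context AG, K = 2: A at offset -1 set, everything else 0
  expect_equal(unname(d$X[1, -(1:2)]),
               c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(d$X[2, -(1:2)]), rep(0, 6))  # GG: reference only
  expect_equal(unname(d$X[3, -(1:2)]), c(0, 1, 0, 0, 0, 1))  # T@-1, C@+1
})

test_that("least squares recovers the generating model", {
  # noise-free data: exact recovery
  obs0 <- toy_obs(2000, logD = log(0.3), gamma = -0.7,
                  beta = c(seq_1_A = 0.5, `seq_-2_C` = -0.3),
                  sigma = 0, K = 8L, seed = 2)
  m0 <- fit_theta_model(build_design(obs0, design_spec(K = 8)), "full")
  expect_equal(m0$gamma, -0.7, tolerance = 1e-8)
  expect_equal(m0$logD, log(0.3), tolerance = 1e-8)
  expect_equal(unname(m0$beta["seq_1_A"]), 0.5, tolerance = 1e-8)
  expect_equal(max(abs(m0$beta[setdiff(names(m0$beta),
                                       c("seq_1_A", "seq_-2_C"))])), 0,
               tolerance = 1e-8)
  # gaussian noise sigma = 0.3, 50000 positions: gamma within 0.05
  obs1 <- toy_obs(50000, logD = log(0.3), gamma = -0.8, sigma = 0.3,
                  K = 8L, seed = 3)
  m1 <- fit_theta_model(build_design(obs1, design_spec(K = 8)), "full")
  expect_equal(m1$gamma, -0.8, tolerance = 0.05)
  # constant variant is the mean of log theta-hat
  mC <- fit_theta_model(build_design(obs1, design_spec(K = 8)), "constant")
  expect_equal(mC$logD, mean(log(obs1$theta_hat)), tolerance = 1e-10)
  expect_equal(mC$gamma, 0)
  expect_null(mC$beta)
  # variant constraints: primer_free has no beta, depth_free has gamma 0
  mP <- fit_theta_model(build_design(obs1, design_spec(K = 8)), "primer_free")
  expect_null(mP$beta)
  mD <- fit_theta_model(build_design(obs1, design_spec(K = 8)), "depth_free")
  expect_equal(mD$gamma, 0)
  expect_length(mD$beta, 24L)
})

test_that("nested models cannot beat the full model in sample", {
  obs <- toy_obs(5000, logD = log(0.5), gamma = -0.6,
                 beta = c(seq_2_T = 0.4), sigma = 0.5, K = 8L, seed = 4)
  d <- build_design(obs, design_spec(K = 8))
  r2 <- function(v) fit_theta_model(d, v)$r_squared
  expect_gte(r2("full") + 1e-12, r2("primer_free"))
  expect_gte(r2("full") + 1e-12, r2("depth_free"))
  expect_gte(r2("primer_free") + 1e-12, r2("constant"))
})

test_that("cross-validated R2 behaves at the calibration points", {
  # noise-free linear response: R2 = 1
  obs0 <- toy_obs(3000, logD = 0, gamma = -1, sigma = 0, K = 8L, seed = 5)
  cv0 <- cross_validated_r2(obs0, design_spec(K = 8, include_sequence = FALSE),
                            variant = "primer_free", seed = 1)
  expect_equal(cv0$r_squared, 1, tolerance = 1e-8)
  expect_equal(cv0$r_squared_sse, 1, tolerance = 1e-8)
  expect_equal(nrow(cv0$per_round), 50L)
  # pure-noise response: R2 around 0
  obs_n <- toy_obs(100000, logD = log(0.1), gamma = 0, sigma = 1, K = 8L,
                   seed = 6)
  cv_n <- cross_validated_r2(obs_n, design_spec(K = 8, include_sequence = FALSE),
                             variant = "primer_free", seed = 2)
  expect_lt(abs(cv_n$r_squared), 0.02)
  expect_lt(abs(cv_n$r_squared_sse), 0.02)
  # population R2 = 0.5: slope and noise chosen so signal and error
  # variances match
  set.seed(7)
  n <- 30000
  x <- rnorm(n)
  y <- x + rnorm(n)
  obs_h <- toy_obs(n, logD = 0, gamma = 0, sigma = 0, K = 8L, seed = 8)
  obs_h$depth <- exp(x)
  obs_h$theta_hat <- exp(y)
  cv_h <- cross_validated_r2(obs_h, design_spec(K = 8, include_sequence = FALSE),
                             variant = "primer_free", seed = 3)
  expect_equal(cv_h$r_squared, 0.5, tolerance = 0.03)
  # deterministic given the seed
  cv_h2 <- cross_validated_r2(obs_h, design_spec(K = 8, include_sequence = FALSE),
                              variant = "primer_free", seed = 3)
  expect_identical(cv_h$per_round, cv_h2$per_round)
  expect_error(cross_validated_r2(obs0[1:20, ], design_spec(K = 8),
                                  variant = "full"),
               "insufficient")
})

test_that("the full model gains nothing over depth-only on depth-only data", {
  # beta = 0 truth: cross-validated R2 of the full model must not exceed
  # the primer-free model's by more than 0.01
  obs <- toy_obs(20000, logD = log(0.4), gamma = -0.8, sigma = 0.6, K = 10L,
                 seed = 9)
  spec <- design_spec(K = 10)
  cv_full <- cross_validated_r2(obs, spec, "full", seed = 4)
  cv_pf <- cross_validated_r2(obs, spec, "primer_free", seed = 4)
  expect_lt(cv_full$r_squared - cv_pf$r_squared, 0.01)
})

test_that("coefficient profiles reindex to signed offsets", {
  obs <- toy_obs(2000, logD = 0, gamma = -0.5,
                 beta = c(seq_1_A = 1), sigma = 0.2, K = 8L, seed = 10)
  m <- fit_theta_model(build_design(obs, design_spec(K = 8)), "full")
  prof <- coefficient_profile(m)
  expect_equal(nrow(prof), 24L)
  expect_setequal(unique(prof$offset), c(-4:-1, 1:4))
  expect_false(0 %in% prof$offset)
  # planted +1 effect for base A at offset +1 is recovered
  expect_gt(prof$estimate[prof$offset == 1 & prof$base == "A"], 0.8)
  # a K = 80 model exposes 240 rows
  obs80 <- toy_obs(400, logD = 0, gamma = -0.5, K = 80L, seed = 11)
  m80 <- fit_theta_model(build_design(obs80, design_spec(K = 80)), "depth_free")
  expect_equal(nrow(coefficient_profile(m80)), 240L)
  expect_error(coefficient_profile(
    fit_theta_model(build_design(obs, design_spec(K = 8)), "primer_free")),
    "no sequence coefficients")
  # all-zero beta gives an all-zero profile
  m0 <- m
  m0$beta[] <- 0
  expect_true(all(coefficient_profile(m0)$estimate == 0))
})

test_that("models survive the coefficient-file round trip", {
  obs <- toy_obs(2000, logD = log(2), gamma = -0.9,
                 beta = c(seq_3_C = -0.4), sigma = 0.1, K = 8L, seed = 12)
  m <- fit_theta_model(build_design(obs, design_spec(K = 8)), "full",
                       strand = "antisense")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, tmp)
  back <- read_model(tmp)
  expect_equal(back$logD, m$logD)
  expect_equal(back$gamma, m$gamma)
  expect_equal(back$beta, m$beta)
  expect_equal(back$variant, m$variant)
  expect_equal(back$strand, m$strand)
})
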