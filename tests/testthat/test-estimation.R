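test_that("framewise displacement follows the Power formula", {
  # constant motion -> zero FD
  const <- matrix(0.5, 10, 6)
  fd <- framewise_displacement(const)
  expect_equal(fd$fd, rep(0, 10))
  expect_length(fd$flags, 0)
  # single 1.0 mm translation jump: FD = 1.0 at that volume, flagged (>0.9)
  m <- matrix(0, 10, 6)
  m[6:10, 2] <- 1
  fd <- framewise_displacement(m)
  expect_equal(fd$fd[6], 1.0)
  expect_equal(fd$flags, 6L)
  # rotations scale by the 50 mm radius: 0.02 rad -> 1.0 mm
  r <- matrix(0, 10, 6)
  r[4:10, 5] <- 0.02
  fd <- framewise_displacement(r)
  expect_equal(fd$fd[4], 1.0)
  expect_equal(fd$flags, 4L)
  expect_error(framewise_displacement(matrix(0, 5, 4)), "6 columns")
})

test_that("LSS designs group nuisance trials by type and keep 6 motion columns", {
  ev <- toy_run_events(6)
  ev$grain <- c("detailed", "coarse", "coarse", "detailed", "forgotten", "detailed")
  ev$congruency <- c("congruent", "congruent", "incongruent", "incongruent",
                     "congruent", "congruent")
  n_vol <- 60
  motion <- matrix(0, n_vol, 6)
  des <- build_lss_design(ev, 1, motion, integer(0), n_vol, tr = 1.5)
  # all five trial types present among the other 5 trials
  labs <- des$cols
  expect_equal(labs[1], "target")
  expect_setequal(intersect(labs, c("coarse congruent", "coarse incongruent",
                                    "detailed congruent", "detailed incongruent",
                                    "forgotten")),
                  c("coarse congruent", "coarse incongruent",
                    "detailed congruent", "detailed incongruent", "forgotten"))
  expect_true("response" %in% labs)
  # constant-zero motion columns are dropped; nonzero motion contributes 6
  expect_equal(sum(labs %in% c("tx", "ty", "tz", "rx", "ry", "rz")), 0)
  motion2 <- matrix(seq_len(n_vol * 6), n_vol, 6)
  des2 <- build_lss_design(ev, 1, motion2, integer(0), n_vol, tr = 1.5)
  expect_equal(sum(des2$cols %in% c("tx", "ty", "tz", "rx", "ry", "rz")), 6)
  # degenerate grouping: single trial type -> one nuisance column
  ev1 <- toy_run_events(4)
  des1 <- build_lss_design(ev1, 2, motion2, integer(0), n_vol, tr = 1.5)
  expect_equal(sum(des1$cols %in% "detailed congruent"), 1)
  # spike columns, one per flag
  des3 <- build_lss_design(ev, 1, motion2, c(5L, 9L), n_vol, tr = 1.5)
  expect_equal(sum(grepl("^spike_", des3$cols)), 2)
  expect_error(build_lss_design(ev[0, ], 1, motion, integer(0), n_vol, 1.5),
               "empty")
})

test_that("noise-free LSS recovers amplitudes exactly and scales linearly", {
  # exactness requires the data to lie in the LSS model's span: a single
  # non-target trial (its own group) plus target reproduces the full design
  cfg <- tiny_config(2)
  cfg$bold <- list(white_sd = 1e-10, ar1 = 0, drift_amp = 0, tr = 1.5)
  ev <- toy_run_events(2, spacing = 35)
  amp <- matrix(c(1, 2, 4, 8), 2, 2)
  run <- simulate_bold_run(ev, amp, cfg, seed = 1, n_spikes = 0)
  runs <- list(list(data = run$data, motion = run$motion * 0, events = ev, tr = 1.5))
  est <- estimate_all_trials(runs, use_beta = TRUE)
  expect_equal(unname(est$patterns), unname(amp), tolerance = 1e-6)
  # scale equivariance
  run2 <- simulate_bold_run(ev, 2 * amp, cfg, seed = 1, n_spikes = 0)
  runs2 <- list(list(data = run2$data, motion = run2$motion * 0, events = ev, tr = 1.5))
  est2 <- estimate_all_trials(runs2, use_beta = TRUE)
  expect_equal(unname(est2$patterns), 2 * unname(est$patterns), tolerance = 1e-6)
  # group-homogeneous world: 4 trials, two type groups with shared amplitude
  ev4 <- toy_run_events(4, spacing = 35)
  ev4$grain <- c("detailed", "coarse", "detailed", "coarse")
  amp4 <- cbind(c(2, -1), c(0.5, 3), c(2, -1), c(0.5, 3))
  run4 <- simulate_bold_run(ev4, amp4, cfg, seed = 2, n_spikes = 0)
  runs4 <- list(list(data = run4$data, motion = run4$motion * 0, events = ev4, tr = 1.5))
  est4 <- estimate_all_trials(runs4, use_beta = TRUE)
  expect_equal(unname(est4$patterns), unname(amp4), tolerance = 1e-6)
})

test_that("LSS equals the all-trials-separate GLM for two separated trials", {
  cfg <- tiny_config(2)
  cfg$bold <- list(white_sd = 1e-10, ar1 = 0, drift_amp = 0, tr = 1.5)
  ev <- toy_run_events(2, spacing = 32)
  ev$grain <- c("detailed", "coarse")
  set.seed(3)
  amp <- matrix(rnorm(3 * 2), 3, 2)
  run <- simulate_bold_run(ev, amp, cfg, seed = 2, n_spikes = 0)
  runs <- list(list(data = run$data, motion = run$motion * 0, events = ev, tr = 1.5))
  lss <- estimate_all_trials(runs, use_beta = TRUE)
  # full-GLM oracle: every trial its own column, plain OLS via lm()
  n_vol <- ncol(run$data)
  X_full <- hrf_design(ev$onset, ev$dur_cue, n_vol, 1.5)
  resp_on <- c(ev$onset + ev$dur_cue, ev$onset + ev$dur_cue + ev$dur_context_resp)
  resp <- hrf_design(resp_on, rep(2, 4), n_vol, 1.5, groups = rep(1, 4))
  for (v in seq_len(3)) {
    fit <- lm(run$data[v, ] ~ X_full + resp)
    expect_equal(unname(lss$patterns[v, ]),
                 unname(coef(fit)[2:3]), tolerance = 1e-6)
  }
})

test_that("mean beta is unbiased under moderate noise", {
  cfg <- tiny_config(2)
  cfg$bold <- list(white_sd = 0.5, ar1 = 0.2, drift_amp = 0.2, tr = 1.5)
  ev <- toy_run_events(4, spacing = 20)
  ev$grain <- c("detailed", "coarse", "detailed", "coarse")
  # per-type-group shared amplitudes keep the grouped LSS model well specified
  amp <- cbind(c(2, -1), c(0.5, 3), c(2, -1), c(0.5, 3))
  est <- sapply(1:40, function(s) {
    run <- simulate_bold_run(ev, amp, cfg, seed = 100 + s, n_spikes = 0)
    runs <- list(list(data = run$data, motion = run$motion, events = ev, tr = 1.5))
    estimate_all_trials(runs, use_beta = TRUE)$patterns
  })
  mean_beta <- matrix(rowMeans(est), 2, 4)
  mc_se <- matrix(apply(est, 1, sd), 2, 4) / sqrt(40)
  expect_true(all(abs(mean_beta - amp) < 4 * mc_se + 0.05))
})

test_that("spike regressors absorb flagged-volume artifacts", {
  cfg <- tiny_config(2)
  cfg$bold <- list(white_sd = 1e-10, ar1 = 0, drift_amp = 0, tr = 1.5)
  ev <- toy_run_events(2, spacing = 30)
  amp <- matrix(c(1, 2, 3, 4), 2, 2)
  run <- simulate_bold_run(ev, amp, cfg, seed = 5, n_spikes = 0)
  clean <- run$data
  dirty <- clean
  dirty[, 12] <- dirty[, 12] + 500   # huge artifact at volume 12
  des <- build_lss_design(ev, 1, run$motion * 0, 12L, ncol(clean), 1.5)
  fit_clean <- lss_fit(clean, build_lss_design(ev, 1, run$motion * 0, integer(0),
                                               ncol(clean), 1.5))
  fit_dirty <- lss_fit(dirty, des)
  expect_equal(fit_dirty$beta, fit_clean$beta, tolerance = 1e-6)
})

test_that("estimate_all_trials yields one map per scheduled trial", {
  expect_equal(dim(estimate_all_trials(list())$patterns), c(0, 0))
  cfg <- tiny_config(2)
  cfg$bold$white_sd <- 0.2
  ev <- toy_run_events(5, spacing = 14)
  runs <- lapply(1:2, function(r) {
    run <- simulate_bold_run(ev, matrix(1, 2, 5), cfg, seed = r, n_spikes = 0)
    list(data = run$data, motion = run$motion, events = ev, tr = 1.5)
  })
  est <- estimate_all_trials(runs)
  expect_equal(ncol(est$patterns), 10)
  expect_equal(est$meta$run, rep(1:2, each = 5))
  expect_true(all(is.finite(est$patterns)))
})
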