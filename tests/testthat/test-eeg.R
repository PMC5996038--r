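test_that("noiseless epochs invert exactly to the injected kernel", {
  set.seed(1)
  n <- 60
  cov <- data.frame(sig = rnorm(n))
  gen <- eeg_gen_params(entries = list(list(covariate = "sig", onset = 0.2,
                                            peak = 0.25, amplitude = 2,
                                            weights = setNames(rep(1, 9),
                                                               cp_channels()))),
                        noise_sd = 0)
  ep <- simulate_eeg(data.frame(trial = 1:n), cov, gen, seed = 2)
  tc <- encode(ep, cov, zscore = FALSE)
  kern <- 2 * response_kernel(ep$times, 0.2, 0.25)
  expect_equal(unname(tc$beta[1, ]), kern, tolerance = 1e-9)
})

test_that("orthogonal covariates give the same betas fit jointly or alone", {
  # 50 trials, two exactly orthogonal regressors
  n <- 50
  set.seed(3)
  z1 <- scale(rnorm(n))[, 1]
  z2 <- scale(residuals(lm(rnorm(n) ~ z1)))[, 1]
  expect_lt(abs(cor(z1, z2)), 1e-10)
  cov <- data.frame(a = z1, b = z2)
  gen <- eeg_gen_params(entries = list(
    list(covariate = "a", onset = 0.2, peak = 0.3, amplitude = 1,
         weights = setNames(rep(1, 9), cp_channels())),
    list(covariate = "b", onset = 0.35, peak = 0.45, amplitude = 0.7,
         weights = setNames(rep(1, 9), cp_channels()))), noise_sd = 0.5)
  ep <- simulate_eeg(data.frame(trial = 1:n), cov, gen, seed = 4)
  joint <- encode(ep, cov)
  alone_a <- encode(ep, cov["a"])
  alone_b <- encode(ep, cov["b"])
  expect_equal(joint$beta["a", ], alone_a$beta["a", ], tolerance = 1e-9)
  expect_equal(joint$beta["b", ], alone_b$beta["b", ], tolerance = 1e-9)
})

test_that("joint permutation of trials leaves the betas unchanged", {
  set.seed(5)
  n <- 40
  cov <- data.frame(emotion = rnorm(n), shared = rnorm(n))
  ep <- simulate_eeg(data.frame(trial = 1:n), cov, eeg_gen_params(), seed = 6)
  tc1 <- encode(ep, cov)
  perm <- sample(n)
  ep2 <- ep; ep2$data <- ep$data[perm, , , drop = FALSE]
  tc2 <- encode(ep2, cov[perm, ])
  expect_equal(tc1$beta, tc2$beta, tolerance = 1e-9)
})

test_that("collinear or constant covariates are rejected", {
  set.seed(7)
  n <- 30
  cov <- data.frame(a = rnorm(n))
  ep <- simulate_eeg(data.frame(trial = 1:n), cov,
                     eeg_gen_params(entries = list()), seed = 8)
  expect_error(encode(ep, data.frame(a = cov$a, b = cov$a * 1.0000001)),
               "collinear")
  expect_error(encode(ep, data.frame(a = rep(1, n))), "constant")
  expect_error(simulate_eeg(data.frame(trial = 1:n), cov,
                            eeg_gen_params(), seed = 1), "not found")
})

test_that("recovered onsets preserve the injected latency order", {
  tcs <- sim_encoding_cohort(n_subjects = 6, n_trials = 250, seed = 9)
  times <- tcs[[1]]$times
  Bs <- stack_betas(tcs, "shared"); Be <- stack_betas(tcs, "emotion")
  lat <- jackknife_latency(Bs, Be, times)
  expect_lt(lat$latency_ms[["cond1"]], lat$latency_ms[["cond2"]])
  # injected 120 ms apart; recovered within one 10 ms sample
  expect_lt(abs(lat$diff_ms - 120), 10)
  expect_lt(lat$p, 0.01)
  # scaling both conditions leaves the latencies untouched
  lat2 <- jackknife_latency(3 * Bs, 3 * Be, times)
  expect_equal(lat2$latency_ms, lat$latency_ms, tolerance = 1e-9)
  # identical conditions: zero difference, zero statistic
  lat0 <- jackknife_latency(Bs, Bs, times)
  expect_equal(lat0$diff_ms, 0)
  expect_equal(lat0$t, 0)
})

test_that("cluster statistics find real effects and nothing in flat input", {
  # flat zero input: no clusters at all
  flat <- matrix(0, 10, 50)
  cl0 <- group_cluster_test(flat, n_perm = 100, seed = 10)
  expect_identical(nrow(cl0$clusters), 0L)
  # strong injected 100 ms effect: one significant covering cluster
  tcs <- sim_encoding_cohort(n_subjects = 10, n_trials = 250, seed = 11)
  times <- tcs[[1]]$times
  Bs <- stack_betas(tcs, "shared")
  cl <- group_cluster_test(Bs, n_perm = 500, seed = 12, times = times)
  sig <- cl$clusters[cl$clusters$p < 0.05, ]
  expect_identical(nrow(sig), 1L)
  expect_lte(sig$t_start, 0.30)
  expect_gte(sig$t_end, 0.38)
})

test_that("congruence couplings are recovered with their signs", {
  # forward model: +shared, +idio, -stimulus-independent couplings
  set.seed(13)
  n_sub <- 8; n <- 200
  eps <- regs <- vector("list", n_sub)
  cpw <- setNames(rep(1, 9), cp_channels())
  gen <- eeg_gen_params(entries = list(
    list(covariate = "shared", onset = 0.45, peak = 0.5, amplitude = 0.8,
         weights = cpw),
    list(covariate = "idio", onset = 0.45, peak = 0.5, amplitude = 0.8,
         weights = cpw),
    list(covariate = "stim_independent", onset = 0.45, peak = 0.5,
         amplitude = -0.8, weights = cpw)), noise_sd = 1)
  for (s in seq_len(n_sub)) {
    reg <- data.frame(shared = sample(c(-1, 1), n, TRUE),
                      idio = sample(c(-1, 1), n, TRUE),
                      stim_independent = sample(c(-1, 1), n, TRUE))
    eps[[s]] <- simulate_eeg(data.frame(trial = 1:n), reg, gen,
                             seed = 20 + s)
    regs[[s]] <- reg
  }
  cc <- congruence_contrast(eps, regs, at = 0.5)
  expect_gt(cc$tests$shared$statistic, 3)
  expect_gt(cc$tests$idio$statistic, 3)
  expect_lt(cc$tests$stim_independent$statistic, -3)
  expect_equal(cc$at, 0.5, tolerance = 0.011)
})

test_that("response-locked encoding shows up only on congruent trials", {
  # the 'shared' covariate couples to the EEG only when the trial is
  # congruent; emotion strength couples unconditionally
  set.seed(14)
  n_sub <- 8; n <- 240
  eps <- covs <- congs <- vector("list", n_sub)
  cpw <- setNames(rep(1, 9), cp_channels())
  for (s in seq_len(n_sub)) {
    cong <- rep(c(TRUE, FALSE), n / 2)
    cov <- data.frame(shared = rnorm(n), emotion = rnorm(n))
    gencov <- data.frame(shared_cong = cov$shared * cong,
                         emotion = cov$emotion)
    gen <- eeg_gen_params(entries = list(
      list(covariate = "shared_cong", onset = 0.45, peak = 0.5,
           amplitude = 1.5, weights = cpw),
      list(covariate = "emotion", onset = 0.45, peak = 0.5, amplitude = 1,
           weights = cpw)), noise_sd = 1)
    eps[[s]] <- simulate_eeg(data.frame(trial = 1:n), gencov, gen,
                             seed = 40 + s)
    covs[[s]] <- cov
    congs[[s]] <- cong
  }
  sp <- split_encoding_by_congruence(eps, covs, congs, seed = 15)
  d_shared <- mean(sp$cells[, "shared_cong"]) - mean(sp$cells[, "shared_incong"])
  d_emotion <- mean(sp$cells[, "emotion_cong"]) - mean(sp$cells[, "emotion_incong"])
  expect_gt(d_shared, 0.5)
  # emotion encoding is split-independent by construction
  expect_lt(abs(d_emotion), d_shared / 2)
  expect_lt(sp$interaction$p, 0.05)
})
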