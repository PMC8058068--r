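make_events <- function(onsets, conditions, run = 1) {
  data.frame(onset = onsets, duration = 0.3, condition = conditions,
             item_id = sprintf("i%03d", seq_along(onsets)),
             rt_ms = 800, correct = 1)
}

test_that("forward-generated FIR data are inverted exactly, even with overlap", {
  set.seed(21)
  tr <- 2; n_tents <- 8; lags <- (0:7) * tr
  conds <- c("NEW_Strong", "OLD_Strong")
  # 8-14 s ITIs with 14-s response support: responses overlap heavily
  onsets1 <- cumsum(c(4, 8, 10, 8, 12, 8, 14, 8, 10))
  onsets2 <- cumsum(c(4, 10, 8, 8, 14, 12, 8, 8, 8))
  ev <- list(make_events(onsets1, rep(conds, length.out = 9)),
             make_events(onsets2, rep(rev(conds), length.out = 9)))
  run_lengths <- c(80, 80)
  betas <- array(rnorm(3 * 2 * n_tents), dim = c(3, 2, n_tents),
                 dimnames = list(NULL, conds, paste0("lag", lags)))
  runs <- forward_fir_data(ev, betas, lags, run_lengths, tr,
                           intercepts = c(0.7, -0.4))
  fit <- fit_tent_glm(runs, ev, tr = tr)
  expect_lt(max(abs(fit$betas - betas[, fit$conditions, ])), 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("all-zero data give all-zero betas", {
  ev <- make_events(cumsum(c(4, 8, 10, 12, 8, 14, 10, 8)),
                    rep(c("A", "B"), 4))
  fit <- fit_tent_glm(matrix(0, 2, 60), ev, tr = 2)
  expect_true(all(fit$betas == 0))
})

test_that("betas are invariant to adding a constant when a baseline column is present", {
  set.seed(22)
  ev <- make_events(seq(4, 68, by = 8), rep(c("A", "B"), 5)[1:9])
  y <- matrix(rnorm(2 * 50), 2, 50)
  f1 <- fit_tent_glm(y, ev, tr = 2)
  f2 <- fit_tent_glm(y + 5, ev, tr = 2)
  expect_equal(f1$betas, f2$betas, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  # a single trial near the run end leaves later-lag columns empty
  ev <- make_events(c(4, 20), c("A", "B"))
  expect_error(fit_tent_glm(matrix(rnorm(2 * 14), 2, 14), ev, tr = 2),
               "collinear")
})

test_that("off-grid onsets are rejected rather than interpolated", {
  ev <- make_events(c(4, 13), c("A", "A"))
  expect_error(fit_tent_glm(matrix(0, 1, 40), ev, tr = 2), "multiples")
})

test_that("peak beta is the mean of the 4 s and 6 s lags", {
  betas <- array(0, dim = c(1, 1, 8),
                 dimnames = list(NULL, "A", paste0("lag", (0:7) * 2)))
  betas[1, 1, "lag4"] <- 2; betas[1, 1, "lag6"] <- 4
  expect_equal(unname(extract_peak_beta(betas)[1, 1]), 3)
  const <- array(7, dim = dim(betas), dimnames = dimnames(betas))
  expect_equal(unname(extract_peak_beta(const)[1, 1]), 7)
  expect_error(extract_peak_beta(betas, peak_lags = c(4, 5)), "not in")
})

test_that("planted repetition suppression is recovered from peak betas", {
  cfg <- quiet_cfg()          # OLD_Strong amplitude = 0.5 x NEW_Strong in ACC
  sim <- simulate_bold(cfg, 1)
  fit <- fit_tent_glm(sim$runs, sim$events, tr = cfg$tr)
  pk <- extract_peak_beta(fit)
  acc <- which(sim$voxel_map$region == "ACC")[1]
  expect_equal(unname(pk[acc, "OLD_Strong"] / pk[acc, "NEW_Strong"]), 0.5,
               tolerance = 1e-6)
})

test_that("item series average the residual peak window per correct trial", {
  resid <- matrix(0, 1, 30)
  resid[1, 8] <- 10; resid[1, 9] <- 20      # onset 10 s -> +4 s, +6 s
  ev <- data.frame(onset = c(2, 10), duration = 0.3,
                   condition = "NEW_Strong", item_id = c("i1", "i2"),
                   rt_ms = 800, correct = 1, run = 1L)
  fit <- fake_tent_fit(resid, ev, run_lengths = 30L)
  is1 <- extract_item_series(fit)
  expect_equal(as.vector(is1$values), c(0, 15))

  # all-zero residuals give all-zero values
  fit0 <- fake_tent_fit(matrix(0, 2, 30), ev, run_lengths = 30L)
  expect_true(all(extract_item_series(fit0)$values == 0))

  # error trials skipped; trials past the run end dropped and logged
  ev2 <- ev; ev2$correct <- c(0, 1); ev2$onset <- c(2, 56)
  ev2$condition[1] <- "error"      # as relabeled by the GLM stage
  fit2 <- fake_tent_fit(resid, ev2, run_lengths = 30L)
  is2 <- extract_item_series(fit2)
  expect_equal(ncol(is2$values), 0L)
  expect_equal(nrow(is2$dropped), 1L)
})

test_that("shared latent amplitudes make same-region voxels perfectly coupled", {
  cfg <- quiet_cfg(latent_sd = 0.5)
  sim <- simulate_bold(cfg, 1)
  fit <- fit_tent_glm(sim$runs, sim$events, tr = cfg$tr)
  isr <- extract_item_series(fit)
  expect_equal(cor(isr$values[1, ], isr$values[2, ]), 1, tolerance = 1e-9)
})

test_that("item series have exactly zero mean within each condition", {
  cfg <- quiet_cfg(noise_sd = 0.2, latent_sd = 0.5)
  sim <- simulate_bold(cfg, 1)
  fit <- fit_tent_glm(sim$runs, sim$events, tr = cfg$tr)
  isr <- extract_item_series(fit)
  for (cond in unique(isr$condition)) {
    expect_lt(abs(mean(isr$values[1, isr$condition == cond])), 1e-10)
  }
})

test_that("trial patterns equal peak minus baseline and agree with item series", {
  # constant series: pattern identically zero
  ev <- data.frame(onset = c(4, 12), duration = 0.3, condition = "NEW_Strong",
                   item_id = c("i1", "i2"), rt_ms = 800, correct = 1)
  cst <- extract_trial_patterns(matrix(3.3, 2, 20), ev, tr = 2)
  expect_true(all(cst$patterns == 0))

  # impulse of height h in the peak TRs only
  y <- matrix(0, 2, 20)
  y[, c(5, 6)] <- 4.5                       # onset 4 s -> peak at 8 s, 10 s
  imp <- extract_trial_patterns(y, ev[1, ], tr = 2)
  expect_equal(as.vector(imp$patterns), c(4.5, 4.5))

  # first trial of a run without a pre-onset TR is skipped and logged
  ev0 <- data.frame(onset = c(0, 10), duration = 0.3,
                    condition = "NEW_Strong", item_id = c("i1", "i2"),
                    rt_ms = 800, correct = 1)
  tp0 <- extract_trial_patterns(matrix(rnorm(40), 2, 20), ev0, tr = 2)
  expect_equal(nrow(tp0$patterns), 1L)
  expect_equal(nrow(tp0$dropped), 1L)

  # the peak component of the pattern (raw data averaged over the peak
  # window) equals the item-series value plus the fitted condition-mean
  # peak, which is constant within a condition and run; trial lengths are
  # chosen so no preceding response reaches into the peak window
  cfg <- quiet_cfg(latent_sd = 0.5, trial_lengths = c(12, 14))
  sim <- simulate_bold(cfg, 1)
  fit <- fit_tent_glm(sim$runs, sim$events, tr = cfg$tr)
  isr <- extract_item_series(fit)
  ev1 <- sim$events[[1]]
  for (cond in c("NEW_Strong", "OLD_Weak")) {
    rows <- which(ev1$condition == cond)
    if (length(rows) < 2) next
    raw_peak <- vapply(rows, function(i) {
      cols <- ev1$onset[i] / cfg$tr + c(2, 3) + 1
      mean(sim$runs[[1]][1, cols])
    }, 0)
    iv <- isr$values[1, match(ev1$item_id[rows], isr$item_id)]
    d <- raw_peak - iv
    expect_lt(max(abs(d - mean(d))), 1e-9)
  }
})

test_that("noise-free generator patterns recover the planted response", {
  # amplitude x (mean peak kernel - mean baseline kernel contamination);
  # with no noise the pattern is identical across same-region voxels
  cfg <- quiet_cfg()
  sim <- simulate_bold(cfg, 1)
  tp <- extract_trial_patterns(sim$runs, sim$events, tr = cfg$tr)
  expect_equal(tp$patterns[, 1], tp$patterns[, 2], tolerance = 1e-12)
})
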