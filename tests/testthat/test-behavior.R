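test_that("trial filter removes errors and strictly-slow responses", {
  tr <- data.frame(rt = c(500, 1999, 2000, 2001), correct = 1)
  out <- filter_trials(tr)
  expect_equal(out$trials$rt, c(500, 1999, 2000))  # 2000 ms retained
  expect_equal(out$excluded$rt, 2001)
  expect_equal(unname(out$log["slow"]), 1L)

  all_bad <- data.frame(rt = c(600, 700), correct = 0)
  out2 <- filter_trials(all_bad)
  expect_equal(nrow(out2$trials), 0L)
  expect_equal(unname(out2$log["incorrect"]), 2L)

  mixed <- data.frame(rt = c(rep(800, 5), 2500, 3000, 900, 950, 1000),
                      correct = c(rep(1, 7), 0, 0, 0))
  out3 <- filter_trials(mixed)
  expect_equal(nrow(out3$trials), 5L)
  expect_equal(unname(out3$log[c("incorrect", "slow")]), c(3L, 2L))

  expect_warning(filter_trials(mixed[0, ]), "empty")
})

test_that("item norms average correct NEW responses and priming", {
  one <- data.frame(participant = "p1", task = "overt", session = "fmri",
                    item = "a", repetition = c("NEW", "OLD"),
                    rt = c(700, 600), correct = 1)
  n1 <- compute_item_norms(one)
  expect_equal(n1$mean_new_rt, 700)
  expect_equal(n1$mean_priming, 100)

  two <- data.frame(participant = c("p1", "p2"), task = "overt",
                    session = "fmri", item = "a", repetition = "NEW",
                    rt = c(600, 800), correct = 1)
  expect_equal(suppressWarnings(compute_item_norms(two))$mean_new_rt, 700)
})

test_that("leave-one-out norms equal norms on the remaining participants", {
  set.seed(7)
  tr <- expand.grid(participant = c("p1", "p2", "p3"),
                    item = sprintf("i%02d", 1:10),
                    repetition = c("NEW", "OLD"),
                    stringsAsFactors = FALSE)
  tr$task <- "overt"; tr$session <- "fmri"; tr$correct <- 1
  tr$rt <- round(runif(nrow(tr), 500, 1200))
  loo <- compute_item_norms(tr, exclude_participant = "p2")
  oracle <- compute_item_norms(tr[tr$participant != "p2", ])
  expect_equal(loo, oracle)
  # a participant contributing no trials changes nothing
  expect_equal(compute_item_norms(tr, exclude_participant = "ghost"),
               compute_item_norms(tr))
})

test_that("primeability split labels the slow half Strong, with stated tie and odd rules", {
  norms <- data.frame(item = c("a", "b", "c", "d"),
                      mean_new_rt = c(500, 600, 700, 800))
  sp <- primeability_split(norms)
  expect_setequal(sp$item[sp$primeability == "Strong"], c("c", "d"))

  tied <- data.frame(item = c("a", "b", "c", "d"),
                     mean_new_rt = c(500, 600, 600, 800))
  sp2 <- primeability_split(tied)
  expect_equal(as.vector(table(sp2$primeability)), c(2L, 2L))
  expect_setequal(sp2$item[sp2$primeability == "Weak"], c("a", "b"))

  odd <- data.frame(item = c("a", "b", "c"), mean_new_rt = c(1, 2, 3))
  expect_warning(sp3 <- primeability_split(odd), "odd")
  expect_equal(sum(sp3$primeability == "Strong"), 2L)

  expect_error(primeability_split(odd[1, , drop = FALSE]), "2 items")
})

test_that("Cohen's d matches the hand-pooled formula and its symmetries", {
  expect_equal(priming_effect_size(c(600, 620, 640), c(580, 600, 620)), 1.0)
  x <- c(1, 2, 3, 4)
  expect_equal(priming_effect_size(x, x), 0)
  a <- c(700, 750, 820, 900); b <- c(640, 660, 700, 710)
  expect_equal(priming_effect_size(a, b), -priming_effect_size(b, a))
  for (k in c(0.5, 2, 17)) {   # scale invariance
    expect_equal(priming_effect_size(k * a, k * b),
                 priming_effect_size(a, b))
  }
  expect_warning(d0 <- priming_effect_size(rep(5, 3), rep(5, 3)), "zero")
  expect_true(is.na(d0))
  expect_error(priming_effect_size(1, c(2, 3)), ">= 2")
})

test_that("item reliability is a Pearson correlation over shared items", {
  n <- data.frame(item = letters[1:6], mean_new_rt = c(3, 9, 5, 7, 2, 8))
  expect_equal(item_reliability(n, n)$r, 1)
  flipped <- n
  flipped$mean_new_rt <- -(n$mean_new_rt - mean(n$mean_new_rt))
  expect_equal(item_reliability(n, flipped)$r, -1)
  expect_error(item_reliability(n[1:2, ], n[1:2, ]), "3 overlapping")
})

test_that("behavior generator plants the RT-priming structure", {
  # zero slope, zero noise: constant OLD-NEW benefit everywhere
  cfg0 <- quiet_cfg(rt_spec = exact_rt_spec(slope = 0))
  beh0 <- simulate_behavior(cfg0)
  p1 <- beh0$trials[beh0$trials$participant == "overt_01", ]
  per_item <- merge(
    p1[p1$session == "pre", c("item", "rt")],                 # first exposure
    p1[p1$session == "fmri" & p1$repetition == "OLD", c("item", "rt")],
    by = "item", suffixes = c("_new", "_old"))
  expect_true(all(abs(per_item$rt_new - per_item$rt_old - 80) < 1e-9))
  expect_true(all(abs(beh0$ground_truth$items$benefit - 80) < 1e-12))

  # positive slope, zero noise: priming strictly increasing in baseline RT
  cfgs <- quiet_cfg(rt_spec = exact_rt_spec(slope = 0.4))
  gt <- simulate_behavior(cfgs)$ground_truth$items
  ord <- order(gt$new_mean)
  expect_true(all(diff(gt$benefit[ord]) > 0))

  # default config, 40 participants: item mean NEW RT correlates with
  # item priming well above 0.5
  cfg <- sim_config(n_participants_per_task = c(overt = 20, covert = 20),
                    seed = 11L)
  beh <- simulate_behavior(cfg)
  keep <- filter_trials(beh$trials)$trials
  norms <- compute_item_norms(keep)
  expect_gt(cor(norms$mean_new_rt, norms$mean_priming,
                use = "complete.obs"), 0.5)

  # planted Primeability classes recovered exactly in the noise-free limit
  beh_exact <- simulate_behavior(quiet_cfg(rt_spec = exact_rt_spec()))
  keep2 <- filter_trials(beh_exact$trials)$trials
  sp <- primeability_split(compute_item_norms(keep2))
  expect_equal(as.character(sp$primeability),
               beh_exact$ground_truth$items$primeability)
})

test_that("NEW-RT norms are more reliable than priming norms in split halves", {
  # split-half reliability contrast, majority over seeds
  wins <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_participants_per_task = c(overt = 16, covert = 2),
                      seed = 100L + s)
    beh <- simulate_behavior(cfg)
    keep <- filter_trials(beh$trials)$trials
    keep <- keep[keep$task == "overt", ]
    ids <- unique(keep$participant)
    half <- ids[seq_len(length(ids) / 2)]
    na <- compute_item_norms(keep[keep$participant %in% half, ])
    nb <- compute_item_norms(keep[!(keep$participant %in% half), ])
    r_new <- item_reliability(na, nb, "mean_new_rt")$r
    r_prime <- item_reliability(na, nb, "mean_priming")$r
    if (r_new > r_prime) wins <- wins + 1L
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("per-participant priming effect sizes are larger for Strong items", {
  cfg <- sim_config(n_participants_per_task = c(overt = 12, covert = 12),
                    seed = 5L)
  beh <- simulate_behavior(cfg)
  norms <- primeability_split(
    compute_item_norms(filter_trials(beh$trials)$trials))
  dtab <- priming_by_primeability(beh$trials, norms)
  m <- tapply(dtab$d, dtab$primeability, mean, na.rm = TRUE)
  expect_gt(m[["Strong"]], m[["Weak"]])
  expect_gt(m[["all"]], 0)
})
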