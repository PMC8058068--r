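test_that("BH step-up matches the hand-worked example and edge cases", {
  # sorted p vs i*q/m: 0.001 <= 0.0125, 0.02 <= 0.025, 0.03 <= 0.0375, stop
  out <- fdr_bh(c(0.001, 0.02, 0.03, 0.9), q = 0.05)
  expect_equal(out$n_discoveries, 3L)
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$threshold, 0.03)

  expect_equal(fdr_bh(rep(1, 5))$n_discoveries, 0L)
  expect_true(fdr_bh(0.01, q = 0.05)$significant)
  expect_equal(fdr_bh(numeric(0))$n_discoveries, 0L)
  expect_error(fdr_bh(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("BH discoveries are monotone in q", {
  set.seed(61)
  for (i in 1:20) {
    p <- runif(sample(5:30, 1))^2
    q1 <- runif(1, 0.01, 0.2); q2 <- q1 + runif(1, 0, 0.3)
    d1 <- fdr_bh(p, q1)$significant
    d2 <- fdr_bh(p, q2)$significant
    expect_true(all(d2[d1]))   # discoveries(q1) subset of discoveries(q2)
  }
})

test_that("noise-free factorial data are interpolated exactly", {
  cells <- expand.grid(participant = paste0("p", 1:6),
                       repetition = c("OLD", "NEW"),
                       primeability = c("Strong", "Weak"))
  truth <- c(OLD_Strong = 2, OLD_Weak = 1, NEW_Strong = 5, NEW_Weak = 3)
  cells$y <- truth[paste(cells$repetition, cells$primeability, sep = "_")]
  res <- fit_lme(cells, "y")
  am <- res$adjusted_means
  for (i in seq_len(nrow(am))) {
    expect_equal(am$fit[i],
                 unname(truth[paste(am$repetition[i], am$primeability[i],
                                    sep = "_")]),
                 tolerance = 1e-10)
  }
})

test_that("mixed-model F tests equal classical repeated-measures ANOVA on balanced data", {
  set.seed(62)
  n <- 14
  d <- expand.grid(participant = paste0("p", 1:n),
                   repetition = c("OLD", "NEW"),
                   primeability = c("Strong", "Weak"))
  d$y <- rnorm(nrow(d)) + rep(rnorm(n), 4) + (d$repetition == "OLD") * 0.8
  res <- fit_lme(d, "y")
  a <- summary(aov(y ~ repetition * primeability + Error(participant),
                   data = d))[["Error: Within"]][[1]]
  for (term in c("repetition", "primeability", "repetition:primeability")) {
    got <- res$tests[res$tests$term == term, ]
    want <- a[trimws(rownames(a)) == term, ]
    expect_equal(got$F, want[["F value"]], tolerance = 1e-6)
    expect_equal(got$p, want[["Pr(>F)"]], tolerance = 1e-6)
    expect_equal(got$df2, 3 * (n - 1), tolerance = 1e-6)
  }
})

test_that("fit_lme is invariant to row order and participant relabeling", {
  set.seed(63)
  d <- expand.grid(participant = paste0("p", 1:10),
                   repetition = c("OLD", "NEW"),
                   primeability = c("Strong", "Weak"))
  d$y <- rnorm(nrow(d)) + rep(rnorm(10), 4)
  r1 <- fit_lme(d, "y")
  r2 <- fit_lme(d[sample(nrow(d)), ], "y")
  expect_equal(r1$tests, r2$tests, tolerance = 1e-8)
  d3 <- d; d3$participant <- paste0("zz_", d3$participant)
  r3 <- fit_lme(d3, "y")
  expect_equal(r1$tests$F, r3$tests$F, tolerance = 1e-8)
})

test_that("covariate adjustment shifts the reported condition means", {
  set.seed(64)
  d <- expand.grid(participant = paste0("p", 1:20),
                   repetition = c("OLD", "NEW"),
                   primeability = c("Strong", "Weak"))
  d$snr <- runif(nrow(d), 1, 3) + (d$repetition == "OLD") * 1.5
  d$y <- 0.5 * d$snr + rnorm(nrow(d), sd = 0.05) + rep(rnorm(20, sd = 0.2), 4)
  unadj <- fit_lme(d, "y")
  adj <- fit_lme(d, "y", covariates = "snr")
  gap <- function(res) {
    m <- res$adjusted_means
    mean(m$fit[m$repetition == "OLD"]) - mean(m$fit[m$repetition == "NEW"])
  }
  expect_gt(abs(gap(unadj)), 0.5)     # driven by the covariate imbalance
  expect_lt(abs(gap(adj)), 0.2)       # largely removed by adjustment
})

test_that("condition contrasts localize a planted Strong-only effect", {
  set.seed(65)
  d <- expand.grid(participant = paste0("p", 1:24),
                   repetition = c("OLD", "NEW"),
                   primeability = c("Strong", "Weak"))
  d$y <- rnorm(nrow(d), sd = 0.5) + rep(rnorm(24), 4) +
    (d$repetition == "OLD" & d$primeability == "Strong") * 1.2
  cc <- condition_contrasts(d, "y")
  expect_true(cc$significant[cc$primeability == "Strong"])
  expect_false(cc$significant[cc$primeability == "Weak"])
  # the contrast estimate is the difference of cell means
  strong <- d[d$primeability == "Strong", ]
  expect_equal(cc$estimate[cc$primeability == "Strong"],
               mean(strong$y[strong$repetition == "OLD"]) -
                 mean(strong$y[strong$repetition == "NEW"]),
               tolerance = 1e-12)
  expect_error(condition_contrasts(d, "y", family = character(0)), "empty")
})

test_that("brain-behavior correlations match closed-form partial r", {
  set.seed(66)
  n <- 40
  z <- rnorm(n)
  x <- 0.6 * z + rnorm(n)
  y <- 0.5 * z + 0.3 * x + rnorm(n)
  plain <- brain_behavior_cor(x, y)
  ct <- cor.test(x, y)
  expect_equal(plain$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(plain$p, ct$p.value, tolerance = 1e-10)

  part <- brain_behavior_cor(x, y, partial_out = z)
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  r_formula <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  expect_equal(part$r, r_formula, tolerance = 1e-12)
  expect_equal(part$df, n - 3L)
})
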