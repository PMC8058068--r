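test_that("implied covariance follows the recursive-model identity", {
  # no edges: covariance is the residual covariance
  m0 <- path_model(matrix(integer(0), 0, 2), p = 3, psi = c(1, 2, 3))
  expect_equal(implied_covariance(m0), diag(c(1, 2, 3)))

  # two-node chain, coefficient 0.5, unit residuals (hand algebra)
  A <- matrix(0, 2, 2); A[2, 1] <- 0.5
  expect_equal(implied_covariance(A, psi = c(1, 1)),
               matrix(c(1, 0.5, 0.5, 1.25), 2))

  # permutation equivariance
  mod <- random_path_model(4, 3, seed = 41)
  sig <- implied_covariance(mod$A, psi = mod$psi)
  perm <- c(3, 1, 4, 2)
  sig_p <- implied_covariance(mod$A[perm, perm], psi = mod$psi[perm])
  expect_equal(sig_p, sig[perm, perm], tolerance = 1e-12)

  # cyclic structures rejected
  Ac <- matrix(0, 2, 2); Ac[1, 2] <- Ac[2, 1] <- 0.3
  expect_error(implied_covariance(Ac, psi = c(1, 1)), "acyclic")
})

test_that("fitting the exact implied covariance recovers the model", {
  for (s in 1:5) {
    p <- sample(3:5, 1)
    k <- sample(2:min(4, p * (p - 1) / 2), 1)
    mod <- random_path_model(p, k, seed = 400 + s)
    sigma <- implied_covariance(mod$A, psi = mod$psi)
    fit <- fit_path_model(sigma, n = 1000, edges = mod$edges)
    expect_true(fit$converged)
    expect_lt(fit$fml, 1e-8)
    expect_lt(max(abs(fit$A - mod$A)), 1e-4)
    expect_lt(max(abs(fit$psi - mod$psi)), 1e-4)
  }
})

test_that("a just-identified structure reproduces any covariance exactly", {
  set.seed(42)
  x <- matrix(rnorm(200 * 3), 200, 3) %*% matrix(rnorm(9), 3)
  S <- cov(x)
  # saturated recursive model: full lower-triangular edge set
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3))
  fit <- fit_path_model(S, n = 200, edges = edges)
  expect_lt(abs(fit$fml), 1e-8)
  expect_equal(fit$df, 0)
  expect_lt(abs(fit$chisq), 1e-5)
})

test_that("sampled data give estimates near the truth", {
  mod <- random_path_model(3, 2, seed = 43)
  ss <- sem_sample(mod$A, mod$psi, n = 5000, seed = 44)
  fit <- fit_path_model(cov(ss$sample), n = 5000, edges = mod$edges)
  expect_lt(max(abs(fit$A - mod$A)), 0.1)
})

test_that("model search prefers the generating structure on exact data", {
  # diagonal covariance: the empty model is optimal
  s_diag <- diag(c(1, 2, 1.5))
  fr <- model_search(s_diag, n = 500, method = "forest", max_edges = 3)
  expect_equal(nrow(fr$best_edges), 0L)

  # exact covariance of a 2-edge model: true structure attains the best
  # AIC (up to Markov-equivalent ties), and tree search does at least as
  # well as the truth
  mod <- random_path_model(3, 2, seed = 45)
  sigma <- implied_covariance(mod$A, psi = mod$psi)
  fr2 <- model_search(sigma, n = 1000, method = "forest")
  true_aic <- fit_path_model(sigma, 1000, mod$edges)$aic
  expect_lt(abs(true_aic - min(fr2$ranking$aic)), 1e-6)

  tr <- model_search(sigma, n = 1000, method = "tree")
  expect_lte(tr$best$aic, true_aic + 1e-6)
  # tree result appears in the forest ranking (forest is exhaustive)
  expect_gte(tr$best$aic, min(fr2$ranking$aic) - 1e-6)

  # enumeration guard
  expect_error(model_search(diag(8), n = 100, method = "forest",
                            max_models = 10), "guard")
})

test_that("AIC penalty bound holds between nested structures", {
  set.seed(46)
  x <- matrix(rnorm(300 * 4), 300, 4) %*% matrix(rnorm(16), 4)
  S <- cov(x)
  sub <- rbind(c(1, 2), c(2, 3))
  super <- rbind(sub, c(1, 4), c(3, 4))
  f_sub <- fit_path_model(S, 300, sub)
  f_super <- fit_path_model(S, 300, super)
  expect_lte(f_super$aic, f_sub$aic + 2 * (nrow(super) - nrow(sub)) + 1e-6)
})

test_that("per-condition parameterization respects planted structure", {
  # identical covariance across conditions: identical parameters
  mod <- random_path_model(3, 2, seed = 47)
  ss <- sem_sample(mod$A, mod$psi, n = 400, seed = 48)
  series <- t(ss$sample)
  cond <- rep(condition_levels <- c("OLD_Strong", "OLD_Weak",
                                    "NEW_Strong", "NEW_Weak"), each = 100)
  # use the SAME 100 trials for every condition label
  pp <- list(participant = "p1", task = "overt",
             series = series[, rep(1:100, 4)], condition = cond,
             correct = rep(1L, 400))
  out <- fit_per_condition(list(pp), mod$edges, min_trials = 10)
  par_by_cond <- split(out$parameters$coefficient, out$parameters$condition)
  for (cc in names(par_by_cond)[-1]) {
    expect_equal(par_by_cond[[cc]], par_by_cond[[1]], tolerance = 1e-6)
  }
  # under-sized cells are flagged, not fatal
  pp2 <- pp; pp2$condition <- rep(c("OLD_Strong", "NEW_Strong"), c(395, 5))
  out2 <- fit_per_condition(list(pp2), mod$edges, min_trials = 10)
  expect_true("too_few_trials" %in% out2$excluded$reason)
})

test_that("model structure validation rejects inadmissible inputs", {
  expect_error(path_model(rbind(c(1, 1)), p = 3), "self-edges")
  expect_error(path_model(rbind(c(1, 2), c(2, 1)), p = 2), "acyclic")
  expect_error(path_model(rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 1)), p = 3),
               "acyclic")
  expect_error(fit_path_model(diag(2) - 2, n = 100,
                              edges = rbind(c(1, 2))), "positive definite")
  expect_error(fit_path_model(diag(3), n = 2, edges = rbind(c(1, 2))),
               "exceed")
})
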