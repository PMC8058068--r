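# Shared fixture builders; everything is generated in code at test time.

# Small, fast study configuration; noise-free by default so recovery tests
# are exact, override as needed.
quiet_cfg <- function(..., n_participants_per_task = c(overt = 2, covert = 2),
                      n_items = 40, n_runs = 2, trials_per_run = 20,
                      noise_sd = 0, latent_sd = 0, global_signal_sd = 0,
                      error_rate = 0, slow_rate = 0,
                      region_spec = default_region_spec(n_voxels = 2),
                      seed = 42L) {
  sim_config(n_participants_per_task = n_participants_per_task,
             n_items = n_items, n_runs = n_runs,
             trials_per_run = trials_per_run, noise_sd = noise_sd,
             latent_sd = latent_sd, global_signal_sd = global_signal_sd,
             error_rate = error_rate, slow_rate = slow_rate,
             region_spec = region_spec, seed = seed, ...)
}

# Noise-free behavioral RT spec (optionally zero benefit slope).
exact_rt_spec <- function(slope = 0.35) {
  list(new_mean = 900, new_sd = 120, benefit_mean = 80,
       benefit_slope = slope, benefit_sd = 0, participant_sd = 0,
       residual_sd = 0, covert_shift = -250)
}

# Independent forward construction of an FIR dataset: place the given betas
# directly as stick responses (one value per condition x lag added at
# onset + lag), plus per-run intercepts. This is the oracle for the
# forward-inverse GLM test and never goes through the package's generator.
forward_fir_data <- function(events, betas, lags, run_lengths, tr,
                             intercepts = rep(0, length(run_lengths))) {
  n_vox <- dim(betas)[1]
  conds <- dimnames(betas)[[2]]
  runs <- vector("list", length(run_lengths))
  for (r in seq_along(run_lengths)) {
    y <- matrix(rep(intercepts[r], n_vox * run_lengths[r]), n_vox)
    ev <- events[[r]]
    for (i in seq_len(nrow(ev))) {
      ci <- match(ev$condition[i], conds)
      for (l in seq_along(lags)) {
        col <- ev$onset[i] / tr + lags[l] / tr + 1
        if (col <= run_lengths[r]) {
          y[, col] <- y[, col] + betas[, ci, l]
        }
      }
    }
    runs[[r]] <- y
  }
  runs
}

# Random acyclic path model on p nodes with k edges; coefficients in
# [0.3, 0.9] with random sign, residual variances in [0.5, 1.5].
random_path_model <- function(p, k, seed) {
  set.seed(seed)
  # order nodes; only forward edges are acyclic
  perm <- sample(p)
  pairs <- t(combn(p, 2))                       # i < j in the order
  pick <- pairs[sample(nrow(pairs), k), , drop = FALSE]
  edges <- cbind(perm[pick[, 1]], perm[pick[, 2]])  # from earlier to later
  coefs <- runif(k, 0.3, 0.9) * sample(c(-1, 1), k, replace = TRUE)
  A <- matrix(0, p, p)
  A[cbind(edges[, 2], edges[, 1])] <- coefs
  psi <- runif(p, 0.5, 1.5)
  list(A = A, psi = psi, edges = edges, coefs = coefs)
}

# Minimal hand-built tent_glm-like object for item-series unit tests.
fake_tent_fit <- function(residuals, events, run_lengths, tr = 2) {
  ev <- events
  ev$onset_idx <- as.integer(ev$onset / tr)
  ev$run <- ev$run %||% 1L
  structure(list(residuals = residuals, events = ev,
                 run_lengths = run_lengths, tr = tr),
            class = "tent_glm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
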