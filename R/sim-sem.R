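#' Sample from a recursive path model
#'
#' Draws independent observations from the Gaussian structural model
#' x = A x + e, e ~ N(0, Psi), whose population covariance is
#' (I - A)^{-1} Psi (I - A)^{-T}. Used as the ground-truth oracle for the
#' structural equation modeling stage.
#'
#' @param A p x p path-coefficient matrix, `A[i, j]` the coefficient of the
#'   edge j -> i; must be acyclic with zero diagonal.
#' @param psi residual variances (length-p vector or diagonal matrix), all
#'   positive.
#' @param n number of rows to draw.
#' @param seed optional integer seed.
#' @return list with `sample` (n x p matrix), `sigma` (the exact population
#'   covariance), `A` and `psi`.
#' @export
sem_sample <- function(A, psi, n, seed = NULL) {
  A <- as.matrix(A)
  p <- nrow(A)
  if (is.matrix(psi)) psi <- diag(psi)
  if (any(psi <= 0)) stop("residual variances must be > 0", call. = FALSE)
  if (any(diag(A) != 0) || !is_acyclic(A != 0)) {
    stop("path structure must be acyclic with no self-edges", call. = FALSE)
  }
  stop_if_not_count(n, "n")
  iia <- solve(diag(p) - A)
  sigma <- iia %*% diag(psi, p) %*% t(iia)
  x <- with_seed(seed, {
    e <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(psi), p)
    e %*% t(iia)
  })
  colnames(x) <- colnames(sigma) <- rownames(sigma) <- colnames(A)
  list(sample = x, sigma = sigma, A = A, psi = psi)
}

#' Generate single-trial voxel patterns with known similarity structure
#'
#' Each trial's pattern is a shared condition template (weighted by
#' `template_overlap`) plus an item-specific component plus trialwise noise,
#' mimicking a peak-minus-baseline response pattern: the trial noise is the
#' difference of a peak noise draw and a baseline noise draw, each with SD
#' `noise_sd`. Matching baseline patterns (pure noise, SD `noise_sd`) are
#' returned for the signal-to-noise estimator, whose expectation under this
#' construction is `snr_expected`.
#'
#' @param n_trials,n_voxels pattern set dimensions (`n_voxels >= 2`).
#' @param template_overlap in `[0, 1]`; weight of the shared template. The
#'   item-specific component gets weight `sqrt(1 - template_overlap^2)` so
#'   the signal variance stays `signal_sd^2`.
#' @param signal_sd,noise_sd standard deviations of the signal components
#'   and of each noise draw across voxels.
#' @param mean_response mean evoked response added to every voxel of every
#'   trial pattern (the spatial-mean amplitude a real ROI would show);
#'   defaults to `signal_sd` so the mean response scales with the signal,
#'   making the amplitude covariate informative as it is in real data.
#' @param seed optional integer seed.
#' @return list with `patterns` (trials x voxels), `baselines` (trials x
#'   voxels pure-noise patterns), `template`, `true_correlation` (population
#'   pattern-to-pattern correlation), `snr_signal` (the noise-free signal
#'   variance ratio `signal_sd^2 / (2 noise_sd^2)`), and `snr_expected`
#'   (`snr_signal + 1`, what the trialwise variance-ratio estimator targets
#'   because the trial patterns themselves carry a difference of two noise
#'   draws; the estimator is an upper bound on `snr_signal`).
#' @export
pattern_set <- function(n_trials, n_voxels, template_overlap = 0.5,
                        signal_sd = 1, noise_sd = 0.5,
                        mean_response = signal_sd, seed = NULL) {
  stop_if_not_count(n_trials, "n_trials")
  if (n_voxels < 2) stop("`n_voxels` must be >= 2", call. = FALSE)
  stop_if_not_nonneg(c(signal_sd, noise_sd), "signal_sd/noise_sd")
  if (template_overlap < 0 || template_overlap > 1) {
    stop("`template_overlap` must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    template <- rnorm(n_voxels, 0, signal_sd)
    item <- matrix(rnorm(n_trials * n_voxels, 0, signal_sd), n_trials)
    signal <- template_overlap * matrix(template, n_trials, n_voxels,
                                        byrow = TRUE) +
      sqrt(1 - template_overlap^2) * item
    trial_noise <- matrix(rnorm(n_trials * n_voxels, 0, noise_sd), n_trials) -
      matrix(rnorm(n_trials * n_voxels, 0, noise_sd), n_trials)
    patterns <- mean_response + signal + trial_noise
    baselines <- matrix(rnorm(n_trials * n_voxels, 0, noise_sd), n_trials)
    sig_var <- signal_sd^2
    noise_var <- 2 * noise_sd^2
    true_cor <- template_overlap^2 * sig_var / (sig_var + noise_var)
    snr_signal <- if (noise_sd > 0) sig_var / noise_var else Inf
    list(patterns = patterns, baselines = baselines, template = template,
         true_correlation = true_cor, snr_signal = snr_signal,
         snr_expected = if (noise_sd > 0) snr_signal + 1 else Inf)
  })
}
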