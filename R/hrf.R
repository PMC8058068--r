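#' Gamma-variate hemodynamic response function
#'
#' Evaluates `h(t) = h0 + a * t^b * exp(-t / c)`: `h0` is a baseline
#' offset, `a` scales the height, `b` (> 0) sets the rise and `c` (> 0, in
#' seconds) the exponential decay. The function peaks at `t = b * c`.
#'
#' @param t non-negative times (s).
#' @param h0,a,b,c parameters; `b, c > 0`.
#' @return h(t), vectorized over `t`.
#' @export
gamma_variate <- function(t, h0, a, b, c) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (b <= 0 || c <= 0) stop("`b` and `c` must be positive", call. = FALSE)
  h0 + a * ifelse(t == 0, 0, exp(b * log(t) - t / c))
}

#' Peak time of a gamma-variate response
#'
#' The time at which the derivative of `h(t)` vanishes: `t_peak = b * c`.
#'
#' @param params list or vector with `a`, `b`, `c` (`h0` ignored).
#' @return scalar peak time in seconds.
#' @export
peak_time <- function(params) {
  a <- params[["a"]]; b <- params[["b"]]; c <- params[["c"]]
  if (is.null(a) || a == 0) stop("peak undefined for a = 0", call. = FALSE)
  if (b <= 0 || c <= 0) stop("`b` and `c` must be positive", call. = FALSE)
  b * c
}

# Profiled least squares: for fixed (b, c), h0 and a enter linearly, so
# solve them exactly by OLS of y on [1, t^b exp(-t/c)].
hrf_linear_solve <- function(y, t, b, c) {
  g <- ifelse(t == 0, 0, exp(b * log(t) - t / c))
  X <- cbind(1, g)
  fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(list(h0 = mean(y), a = 0, sse = sum((y - mean(y))^2)))
  }
  r <- y - X %*% fit$coefficients
  list(h0 = fit$coefficients[1], a = fit$coefficients[2], sse = sum(r^2))
}

hrf_sse <- function(par, y, t) {
  sum((gamma_variate(t, par[1], par[2], exp(par[3]), exp(par[4])) - y)^2)
}

# Analytic gradient of the SSE in (h0, a, log b, log c).
hrf_sse_grad <- function(par, y, t) {
  h0 <- par[1]; a <- par[2]; b <- exp(par[3]); c <- exp(par[4])
  g <- ifelse(t == 0, 0, exp(b * log(t) - t / c))
  r <- h0 + a * g - y
  dgb <- ifelse(t == 0, 0, g * log(pmax(t, .Machine$double.xmin)))
  dgc <- g * t / c^2
  2 * c(sum(r), sum(r * g), sum(r * a * dgb) * b, sum(r * a * dgc) * c)
}

#' Fit a gamma-variate response to FIR betas
#'
#' Least-squares fit of the gamma-variate response over `(h0, a, b, c)`:
#' a coarse grid over log-spaced `(b, c)` ranges (with the linear
#' parameters `h0`, `a` solved exactly at each grid point), followed by
#' gradient-descent fine-tuning with backtracking line search from the best
#' grid point, run until the relative SSE change falls below `tol` or the
#' iteration cap is reached. The gradient steps are taken along the
#' normalized gradient in `(h0, a, log b, log c)`, which keeps the descent
#' path invariant to rescaling the data.
#'
#' @param betas response values at the FIR lags (>= 5 points).
#' @param lags lag times in seconds (non-negative; default 0-14 s step 2).
#' @param b_range,c_range grid ranges for the rise exponent and the decay
#'   time constant (s).
#' @param n_grid grid resolution per parameter (log-spaced).
#' @param max_grad_iter gradient-descent iteration cap.
#' @param tol relative SSE convergence tolerance.
#' @return object of class `hrf_fit`: `params` (`h0`, `a`, `b`, `c`),
#'   `t_peak` (`b * c`), `sse`, `grid_sse`, `n_iterations`, `degenerate`
#'   (flat-data flag), `converged`.
#' @export
fit_hrf <- function(betas, lags = seq(0, 14, by = 2),
                    b_range = c(0.5, 8), c_range = c(0.25, 6),
                    n_grid = 16, max_grad_iter = 300, tol = 1e-10) {
  y <- as.numeric(betas)
  if (anyNA(y)) stop("NA in `betas`", call. = FALSE)
  if (length(y) != length(lags)) stop("`betas`/`lags` length mismatch",
                                      call. = FALSE)
  if (length(y) < 5) stop("need >= 5 lag points", call. = FALSE)
  if (any(lags < 0)) stop("lags must be non-negative", call. = FALSE)
  if (var(y) == 0) {
    return(structure(list(
      params = c(h0 = y[1], a = 0, b = 1, c = 1), t_peak = NA_real_,
      sse = 0, grid_sse = 0, n_iterations = 0L, degenerate = TRUE,
      converged = TRUE), class = "hrf_fit"))
  }
  # fit on unit-scaled data so the result is exactly equivariant under
  # rescaling of the betas (h0 and a scale; b, c, t_peak unchanged)
  y_scale <- sd(y)
  y <- y / y_scale
  bs <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = n_grid))
  cs <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_grid))
  best <- NULL
  for (b in bs) for (c in cs) {
    lin <- hrf_linear_solve(y, lags, b, c)
    if (is.null(best) || lin$sse < best$sse) {
      best <- list(par = c(lin$h0, lin$a, log(b), log(c)), sse = lin$sse)
    }
  }
  grid_sse <- best$sse
  par <- best$par
  sse <- grid_sse
  iter <- 0L
  converged <- FALSE
  while (iter < max_grad_iter) {
    iter <- iter + 1L
    gr <- hrf_sse_grad(par, y, lags)
    gn <- sqrt(sum(gr^2))
    if (!is.finite(gn) || gn == 0) { converged <- TRUE; break }
    dir <- -gr / gn
    step <- 1
    new_sse <- Inf
    for (bt in 1:40) {
      cand <- par + step * dir
      new_sse <- hrf_sse(cand, y, lags)
      if (is.finite(new_sse) && new_sse < sse) break
      step <- step / 2
    }
    if (!is.finite(new_sse) || new_sse >= sse) { converged <- TRUE; break }
    rel <- (sse - new_sse) / max(sse, .Machine$double.eps)
    par <- cand
    sse <- new_sse
    # re-solve the linear parameters exactly at the new (b, c)
    lin <- hrf_linear_solve(y, lags, exp(par[3]), exp(par[4]))
    if (lin$sse <= sse) {
      par[1:2] <- c(lin$h0, lin$a)
      rel <- max(rel, (sse - lin$sse) / max(sse, .Machine$double.eps))
      sse <- lin$sse
    }
    if (rel < tol) { converged <- TRUE; break }
  }
  params <- c(h0 = unname(par[1]) * y_scale, a = unname(par[2]) * y_scale,
              b = unname(exp(par[3])), c = unname(exp(par[4])))
  structure(list(params = params,
                 t_peak = unname(params["b"] * params["c"]),
                 sse = sse * y_scale^2, grid_sse = grid_sse * y_scale^2,
                 n_iterations = iter,
                 degenerate = abs(params["a"]) < 1e-10,
                 converged = converged),
            class = "hrf_fit")
}

#' @exportS3Method base::print
print.hrf_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma-variate fit: h0=%.4g a=%.4g b=%.3g c=%.3g | t_peak=%.3f s, SSE=%.3g (%d iter)%s\n",
    x$params["h0"], x$params["a"], x$params["b"], x$params["c"], x$t_peak,
    x$sse, x$n_iterations, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
coef.hrf_fit <- function(object, ...) object$params

#' Peak-time contrasts across conditions and regions
#'
#' Submits fitted peak times to the shared linear mixed-effects analysis
#' (Task x Repetition x Primeability fixed effects, participant random
#' intercept), per region, reporting the Repetition main effect and the
#' Repetition x Primeability interaction with FDR correction across
#' regions.
#'
#' @param fits data.frame with columns `participant`, `task`, `repetition`,
#'   `primeability`, `roi`, `t_peak` (degenerate fits already excluded).
#' @param q FDR level for the across-region correction.
#' @return data.frame per region and term: F, df, p, and FDR significance.
#' @export
peak_time_contrasts <- function(fits, q = 0.05) {
  rois <- unique(fits$roi)
  rows <- list()
  for (roi in rois) {
    d <- fits[fits$roi == roi & is.finite(fits$t_peak), , drop = FALSE]
    res <- fit_lme(d, dv = "t_peak")
    for (term in c("repetition", "repetition:primeability")) {
      tr <- res$tests[res$tests$term == term, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, term = term, F = tr$F, df1 = tr$df1, df2 = tr$df2,
        p = tr$p)
    }
  }
  out <- do.call(rbind, rows)
  for (term in unique(out$term)) {
    sel <- out$term == term
    out$significant[sel] <- fdr_bh(out$p[sel], q = q)$significant
  }
  out
}
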