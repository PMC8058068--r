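# Map event onsets (seconds, run-relative) to 0-based TR indices, insisting
# on exact alignment with the TR grid: the slow event-related design places
# every onset on the grid, and silent interpolation would bias peak
# extraction.
onset_index <- function(onset, tr) {
  idx <- onset / tr
  if (any(abs(idx - round(idx)) > 1e-9)) {
    stop("event onsets must be multiples of the TR", call. = FALSE)
  }
  as.integer(round(idx))
}

# Relabel incorrect (or slow, if `rt_ceiling_ms` given) trials as the
# error-regressor condition.
events_with_errors <- function(events, rt_ceiling_ms = 2000) {
  ev <- events
  bad <- rep(FALSE, nrow(ev))
  if ("correct" %in% names(ev)) bad <- bad | !as.logical(ev$correct)
  if (!is.null(rt_ceiling_ms) && "rt_ms" %in% names(ev)) {
    bad <- bad | (!is.na(ev$rt_ms) & ev$rt_ms > rt_ceiling_ms)
  }
  ev$condition <- as.character(ev$condition)
  ev$condition[bad] <- "error"
  ev
}

#' Fit an FIR ("TENT") deconvolution GLM
#'
#' Ordinary least squares per voxel on a design with one stick regressor per
#' condition x post-onset lag (default 8 lags, 0 to 14 s at TR = 2 s), plus
#' a per-run polynomial baseline block (default order 0, i.e. an intercept,
#' since inputs are assumed de-noised). No response shape is assumed: the
#' per-lag betas estimate the hemodynamic response empirically. Incorrect
#' and slow trials are modeled as a separate `error` condition of no
#' interest.
#'
#' @param runs a voxels x timepoints matrix or a list of them (one per run).
#' @param events per-run event table(s) with `onset` (s), `condition`, and
#'   optionally `correct` and `rt_ms` used to relabel error trials.
#' @param tr repetition time in seconds.
#' @param n_tents number of post-onset lags modeled (lags `0:(n_tents-1) *
#'   tr`).
#' @param polort per-run polynomial detrend order (0 = intercept only).
#' @param rt_ceiling_ms responses slower than this are treated as error
#'   trials (NULL to disable).
#' @return object of class `tent_glm` with `betas` (voxels x conditions x
#'   lags array), `lags`, `conditions`, `residuals` (voxels x total
#'   timepoints), `events` (row-bound, with run and global onset index),
#'   `run_lengths`, `tr`.
#' @export
fit_tent_glm <- function(runs, events, tr, n_tents = 8, polort = 0,
                         rt_ceiling_ms = 2000) {
  if (is.matrix(runs)) runs <- list(runs)
  if (is.data.frame(events)) events <- list(events)
  stopifnot(length(runs) == length(events), tr > 0, n_tents >= 1)
  run_lengths <- vapply(runs, ncol, 0L)
  offsets <- c(0L, cumsum(run_lengths))[seq_along(runs)]
  ev <- do.call(rbind, lapply(seq_along(events), function(r) {
    e <- events_with_errors(events[[r]], rt_ceiling_ms)
    if (is.unsorted(e$onset, strictly = TRUE)) {
      stop(sprintf("onsets must be strictly increasing within run %d", r),
           call. = FALSE)
    }
    e$run <- r
    e$onset_idx <- onset_index(e$onset, tr) + offsets[r]
    e
  }))
  conditions <- sort(unique(ev$condition))
  n_time <- sum(run_lengths)
  lags <- (seq_len(n_tents) - 1) * tr

  # stick regressors: one column per condition x lag
  stick_cols <- vector("list", length(conditions) * n_tents)
  names_out <- character(length(stick_cols))
  ci <- 0L
  run_of_t <- rep(seq_along(runs), run_lengths)
  for (cond in conditions) {
    ons <- ev$onset_idx[ev$condition == cond]
    runs_of <- ev$run[ev$condition == cond]
    for (l in seq_len(n_tents) - 1L) {
      ci <- ci + 1L
      col <- numeric(n_time)
      idx <- ons + l + 1L          # 1-based global index at lag l
      ok <- run_of_t[pmin(idx, n_time)] == runs_of & idx <= n_time
      col[idx[ok]] <- col[idx[ok]] + 1
      stick_cols[[ci]] <- col
      names_out[ci] <- sprintf("%s@%g", cond, l * tr)
    }
  }
  X <- do.call(cbind, stick_cols)
  colnames(X) <- names_out
  # per-run polynomial baseline block
  base_cols <- NULL
  for (r in seq_along(runs)) {
    tt <- seq_len(run_lengths[r])
    B <- outer(scale(tt, scale = FALSE)[, 1] / max(1, run_lengths[r] / 2),
               0:polort, `^`)
    blk <- matrix(0, n_time, ncol(B))
    blk[(offsets[r] + 1):(offsets[r] + run_lengths[r]), ] <- B
    colnames(blk) <- sprintf("run%d_poly%d", r, 0:polort)
    base_cols <- cbind(base_cols, blk)
  }
  X <- cbind(X, base_cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Y <- t(do.call(cbind, runs))              # time x voxels
  B <- qr.coef(qrX, Y)                      # coefficients x voxels
  resid <- t(Y - X %*% B)                   # voxels x time

  n_vox <- nrow(resid)
  betas <- array(NA_real_, dim = c(n_vox, length(conditions), n_tents),
                 dimnames = list(NULL, conditions, paste0("lag", lags)))
  for (i in seq_along(conditions)) {
    for (j in seq_len(n_tents)) {
      betas[, i, j] <- B[sprintf("%s@%g", conditions[i], lags[j]), ]
    }
  }
  structure(list(betas = betas, lags = lags, conditions = conditions,
                 residuals = resid, events = ev, run_lengths = run_lengths,
                 tr = tr, rank = qrX$rank, n_regressors = ncol(X)),
            class = "tent_glm")
}

#' @exportS3Method base::print
print.tent_glm <- function(x, ...) {
  cat(sprintf(
    "FIR deconvolution fit: %d voxels, %d conditions x %d lags (0-%g s), %d TRs\n",
    dim(x$betas)[1], length(x$conditions), length(x$lags), max(x$lags),
    sum(x$run_lengths)))
  invisible(x)
}

#' @export
coef.tent_glm <- function(object, ...) object$betas

#' @export
residuals.tent_glm <- function(object, ...) object$residuals

#' Peak response amplitude from FIR betas
#'
#' Averages the two lags flanking the typical hemodynamic peak (default the
#' 3rd and 4th lags, 4 s and 6 s, i.e. activity 4-8 s post onset) per voxel
#' and condition.
#'
#' @param fit a `tent_glm` object (or a voxels x conditions x lags array
#'   with lag dimnames `lag<seconds>`).
#' @param peak_lags lags (seconds) to average.
#' @return voxels x conditions matrix of peak amplitudes.
#' @export
extract_peak_beta <- function(fit, peak_lags = c(4, 6)) {
  betas <- if (inherits(fit, "tent_glm")) fit$betas else fit
  lag_names <- paste0("lag", peak_lags)
  if (!all(lag_names %in% dimnames(betas)[[3]])) {
    stop(sprintf("requested lags (%s s) not in the tent grid",
                 paste(peak_lags, collapse = ", ")), call. = FALSE)
  }
  out <- apply(betas[, , lag_names, drop = FALSE], c(1, 2), mean)
  out
}

#' Single-trial item series from GLM residuals
#'
#' For each correct trial and voxel, averages the residual time series (task
#' data with the condition-mean responses removed) at the two peak
#' timepoints (onset + 4 s and onset + 6 s by default), yielding the ordered
#' vector of single-trial peak responses that all trial-level connectivity
#' is computed on. Trials relabeled `error` are skipped, as are trials whose
#' peak window extends past the end of their run (logged).
#'
#' @param fit a `tent_glm` object.
#' @param peak_offsets offsets in TRs after the onset TR (default `c(2, 3)`,
#'   i.e. +4 s and +6 s at TR = 2 s).
#' @return object of class `item_series`: `values` (voxels x kept trials),
#'   `condition`, `item_id`, `trial` (row index into `fit$events`),
#'   `dropped` (logged skipped trials).
#' @export
extract_item_series <- function(fit, peak_offsets = c(2, 3)) {
  stopifnot(inherits(fit, "tent_glm"))
  ev <- fit$events
  run_ends <- cumsum(fit$run_lengths)
  keep <- ev$condition != "error"
  idx_hi <- ev$onset_idx + max(peak_offsets) + 1L
  in_run <- idx_hi <= run_ends[ev$run]
  dropped <- ev[keep & !in_run, , drop = FALSE]
  use <- which(keep & in_run)
  vals <- vapply(use, function(i) {
    cols <- ev$onset_idx[i] + peak_offsets + 1L
    rowMeans(fit$residuals[, cols, drop = FALSE])
  }, numeric(nrow(fit$residuals)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(fit$residuals))
  structure(list(values = vals, condition = ev$condition[use],
                 item_id = ev$item_id[use], trial = use, dropped = dropped),
            class = "item_series")
}

#' @exportS3Method base::print
print.item_series <- function(x, ...) {
  cat(sprintf("Item series: %d voxels x %d trials (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Single-trial peak-minus-baseline voxel patterns
#'
#' Computed on de-noised data prior to removal of condition means: per trial
#' and voxel, the mean of the two peak timepoints (onset + 4 s, + 6 s) minus
#' the mean of the trial's first timepoint (0-2 s) and the timepoint before
#' onset (-2-0 s). The per-trial baseline patterns are returned alongside
#' for the signal-to-noise estimator. Trials lacking a pre-onset timepoint
#' or a complete peak window are skipped and logged; error trials excluded.
#'
#' @param runs voxels x time matrix or list of per-run matrices (pre-GLM).
#' @param events per-run event tables (see [fit_tent_glm()]).
#' @param tr repetition time (s).
#' @param roi optional voxel indices restricting the patterns.
#' @param rt_ceiling_ms slow-trial relabeling ceiling (NULL to disable).
#' @return list with `patterns` (trials x voxels), `baselines` (trials x
#'   voxels), `condition`, `item_id`, `dropped`.
#' @export
extract_trial_patterns <- function(runs, events, tr, roi = NULL,
                                   rt_ceiling_ms = 2000) {
  if (is.matrix(runs)) runs <- list(runs)
  if (is.data.frame(events)) events <- list(events)
  pat <- list(); bas <- list(); cond <- character(); item <- character()
  dropped <- list()
  for (r in seq_along(runs)) {
    data <- runs[[r]]
    if (!is.null(roi)) data <- data[roi, , drop = FALSE]
    ev <- events_with_errors(events[[r]], rt_ceiling_ms)
    onset <- onset_index(ev$onset, tr)        # 0-based
    for (i in seq_len(nrow(ev))) {
      if (ev$condition[i] == "error") next
      pk <- onset[i] + c(2L, 3L) + 1L
      bl <- onset[i] + c(-1L, 0L) + 1L
      if (any(bl < 1L) || any(pk > ncol(data))) {
        dropped[[length(dropped) + 1L]] <- cbind(ev[i, , drop = FALSE], run = r)
        next
      }
      pat[[length(pat) + 1L]] <- rowMeans(data[, pk, drop = FALSE]) -
        rowMeans(data[, bl, drop = FALSE])
      bas[[length(bas) + 1L]] <- rowMeans(data[, bl, drop = FALSE])
      cond <- c(cond, ev$condition[i])
      item <- c(item, if ("item_id" %in% names(ev)) ev$item_id[i] else NA)
    }
  }
  list(patterns = do.call(rbind, pat), baselines = do.call(rbind, bas),
       condition = cond, item_id = item,
       dropped = if (length(dropped)) do.call(rbind, dropped) else NULL)
}
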