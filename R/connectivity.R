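#' Task-responsive voxel mask
#'
#' One-sample t-test per voxel of single-trial peak responses (or peak
#' betas) against zero, retaining voxels responding above baseline. Two
#' threshold policies are exposed: a fixed voxelwise p (the study-style
#' choice, e.g. p < 1e-4) or a Benjamini-Hochberg FDR level.
#'
#' @param values voxels x trials matrix of peak responses (>= 2 trials).
#' @param policy list: `mode` `"fdr"` or `"fixed_p"`, with `q` (FDR level)
#'   or `p` (voxelwise alpha).
#' @return logical voxel mask; attributes `p` (per-voxel p-values) and
#'   `excluded` (zero-variance voxels, never included).
#' @export
task_responsive_mask <- function(values,
                                 policy = list(mode = "fdr", q = 0.05)) {
  stopifnot(ncol(values) >= 2)
  n <- ncol(values)
  m <- rowMeans(values)
  s <- apply(values, 1, sd)
  zero_var <- s == 0 | !is.finite(s)
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  p[zero_var] <- NA
  sig <- rep(FALSE, nrow(values))
  ok <- !zero_var
  if (identical(policy$mode, "fixed_p")) {
    sig[ok] <- p[ok] < policy$p
  } else {
    sig[ok] <- fdr_bh(p[ok], q = policy$q)$significant
  }
  mask <- sig & m > 0                      # above baseline only
  if (any(zero_var)) {
    warning(sprintf("%d zero-variance voxel(s) excluded from the mask",
                    sum(zero_var)))
  }
  attr(mask, "p") <- p
  attr(mask, "excluded") <- which(zero_var)
  mask
}

#' Whole-brain connectedness of item series
#'
#' For each voxel, the average Pearson correlation of its item series with
#' the item series of every voxel in a cohort (typically the
#' task-responsive voxels), self-correlations excluded — a univariate
#' reduction of the all-pairs correlation structure, akin to degree
#' centrality. Computed within one condition's trials.
#'
#' @param series voxels x trials matrix (>= 3 trials).
#' @param cohort logical mask or integer indices of cohort voxels.
#' @return numeric vector (one value per voxel, in `[-1, 1]`); constant
#'   voxels are dropped from the cohort, get `NA`, and are listed in the
#'   `excluded` attribute.
#' @export
connectedness <- function(series, cohort = seq_len(nrow(series))) {
  if (ncol(series) < 3) stop("need >= 3 trials", call. = FALSE)
  if (is.logical(cohort)) cohort <- which(cohort)
  if (length(cohort) == 0) stop("cohort is empty", call. = FALSE)
  s <- apply(series, 1, sd)
  constant <- which(s == 0 | !is.finite(s))
  cohort <- setdiff(cohort, constant)
  if (length(cohort) == 0) stop("cohort has no non-constant voxels",
                                call. = FALSE)
  R <- suppressWarnings(cor(t(series)))
  out <- rep(NA_real_, nrow(series))
  for (v in setdiff(seq_len(nrow(series)), constant)) {
    others <- setdiff(cohort, v)
    if (length(others) == 0) next
    out[v] <- mean(R[v, others])
  }
  attr(out, "excluded") <- constant
  out
}

#' Seed-based item-series correlation map
#'
#' Averages the item series over the seed voxels and correlates that seed
#' series with every voxel's item series, returning Fisher z-transformed
#' values. Correlations of magnitude 1 are clipped at `atanh(1 - 1e-7)`
#' with a warning so that the map stays finite.
#'
#' @param series voxels x trials matrix.
#' @param seed voxel indices (or logical mask) defining the seed region.
#' @return list with `z` (per-voxel Fisher z), `r` (raw correlations), and
#'   `seed_series` (the averaged seed item series).
#' @export
seed_map <- function(series, seed) {
  if (is.logical(seed)) seed <- which(seed)
  if (length(seed) < 1) stop("seed has no voxels", call. = FALSE)
  seed_series <- colMeans(series[seed, , drop = FALSE])
  r <- suppressWarnings(
    as.vector(cor(seed_series, t(series))))
  clip <- 1 - 1e-7
  if (any(abs(r) >= clip, na.rm = TRUE)) {
    warning("correlations of magnitude ~1 clipped before Fisher transform")
    r <- pmin(pmax(r, -clip), clip)
  }
  list(z = atanh(r), r = r, seed_series = seed_series)
}

#' Global correlation level (GCOR)
#'
#' The mean of all N^2 entries of the voxel-pair correlation matrix,
#' self-pairs included, used as a per-condition nuisance covariate for
#' residual global artifacts. Computed by the fast identity: GCOR equals
#' the squared Euclidean norm of the average of the de-meaned,
#' unit-normalized voxel series.
#'
#' @param series voxels x samples matrix (>= 2 samples). Constant voxels
#'   are excluded with a warning before computation.
#' @return scalar in `[0, 1]`.
#' @export
compute_gcor <- function(series) {
  stopifnot(nrow(series) >= 1, ncol(series) >= 2)
  s <- apply(series, 1, sd)
  constant <- s == 0 | !is.finite(s)
  if (any(constant)) {
    warning(sprintf("%d constant voxel(s) excluded from GCOR",
                    sum(constant)))
    series <- series[!constant, , drop = FALSE]
    if (nrow(series) == 0) stop("no non-constant voxels", call. = FALSE)
  }
  u <- series - rowMeans(series)
  u <- u / sqrt(rowSums(u^2))
  g <- colMeans(u)
  sum(g^2)
}

#' Sample a spherical ROI on the voxel grid
#'
#' Members are all voxels whose center-to-center Euclidean distance (mm,
#' via the grid affine) from the sphere center is at most `radius`
#' (inclusive), intersected with a brain mask when given.
#'
#' @param center_mm length-3 center in mm.
#' @param radius_mm sphere radius in mm (default 6).
#' @param affine 4x4 voxel-index-to-mm affine (0-based indices).
#' @param dim volume dimensions (3 integers); voxels indexed
#'   `0:(dim-1)`.
#' @param mask optional logical array of `dim` marking in-brain voxels.
#' @return data.frame of member voxels: integer indices `i`, `j`, `k` and
#'   mm coordinates `x`, `y`, `z`.
#' @export
sample_sphere_roi <- function(center_mm, radius_mm = 6, affine, dim,
                              mask = NULL) {
  stopifnot(length(center_mm) == 3, radius_mm >= 0)
  # center voxel index (continuous), then search a bounding box
  inv <- solve(affine)
  cidx <- (inv %*% c(center_mm, 1))[1:3]
  if (any(cidx < -0.5) || any(cidx > dim - 0.5)) {
    stop("sphere center lies outside the volume", call. = FALSE)
  }
  step <- sqrt(colSums(affine[1:3, 1:3]^2))
  halfwidth <- ceiling(radius_mm / step) + 1
  rng <- lapply(1:3, function(a) {
    max(0, floor(cidx[a] - halfwidth[a])):min(dim[a] - 1,
                                              ceiling(cidx[a] + halfwidth[a]))
  })
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  mm <- t(affine %*% rbind(t(grid), 1))[, 1:3, drop = FALSE]
  d <- sqrt(rowSums(sweep(mm, 2, center_mm)^2))
  inside <- d <= radius_mm + 1e-9
  if (!is.null(mask)) {
    inside <- inside & mask[grid + 1L]
  }
  if (!any(inside)) stop("sphere contains no voxels inside the mask",
                         call. = FALSE)
  out <- data.frame(grid[inside, , drop = FALSE],
                    x = mm[inside, 1], y = mm[inside, 2], z = mm[inside, 3])
  rownames(out) <- NULL
  out
}

#' Per-condition connectedness table for one participant
#'
#' Convenience wrapper running [connectedness()] and [compute_gcor()]
#' within each condition's trials of an item series.
#'
#' @param series an `item_series` (or list with `values` and `condition`).
#' @param cohort cohort voxels passed to [connectedness()].
#' @param min_trials conditions with fewer correct trials are skipped.
#' @return data.frame: `condition`, `voxel`, `connectedness`, `gcor`.
#' @export
connectedness_by_condition <- function(series, cohort = NULL,
                                       min_trials = 3) {
  vals <- series$values
  if (is.null(cohort)) cohort <- seq_len(nrow(vals))
  out <- list()
  for (cond in unique(series$condition)) {
    cols <- series$condition == cond
    if (sum(cols) < min_trials) next
    sub <- vals[, cols, drop = FALSE]
    cn <- connectedness(sub, cohort)
    g <- compute_gcor(sub)
    out[[cond]] <- data.frame(condition = cond,
                              voxel = seq_len(nrow(vals)),
                              connectedness = cn, gcor = g)
  }
  do.call(rbind, out)
}
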