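# Amplitude-normalized gamma-variate response kernel. Shape follows
# h(t) = a t^b exp(-t/c) with c = t_peak / b, rescaled so the peak value is
# 1 at t = t_peak, and truncated beyond `support` so that an FIR window of
# the same length spans the response exactly.
gamma_kernel <- function(t, b, t_peak, support) {
  k <- numeric(length(t))
  ok <- t > 0 & t <= support
  tt <- t[ok]
  k[ok] <- exp(b * log(tt / t_peak) + b - b * tt / t_peak)
  k
}

# Directed coupling matrix for one condition: A[to, from] = weight.
coupling_matrix <- function(coupling_spec, region_names, condition) {
  p <- length(region_names)
  A <- matrix(0, p, p, dimnames = list(region_names, region_names))
  if (!is.null(coupling_spec) && nrow(coupling_spec) > 0L) {
    for (e in seq_len(nrow(coupling_spec))) {
      A[coupling_spec$to[e], coupling_spec$from[e]] <-
        coupling_spec[[condition]][e]
    }
  }
  A
}

# Latent per-trial regional amplitudes: independent fluctuations propagated
# along the condition-specific coupling graph, z = (I - A)^{-1} eps.
draw_latents <- function(n_trials, conditions, config) {
  region_names <- vapply(config$region_spec, `[[`, "", "name")
  p <- length(region_names)
  z <- matrix(0, n_trials, p, dimnames = list(NULL, region_names))
  eps <- matrix(rnorm(n_trials * p, 0, config$latent_sd), n_trials, p)
  for (cond in unique(conditions)) {
    rows <- which(conditions == cond)
    A <- coupling_matrix(config$coupling_spec, region_names, cond)
    z[rows, ] <- eps[rows, , drop = FALSE] %*% t(solve(diag(p) - A))
  }
  z
}

# Cubic block of voxel grid indices for one region on a 3-mm grid.
region_voxel_grid <- function(center_mm, n_voxels, vox_mm = 3) {
  side <- ceiling(n_voxels^(1 / 3))
  steps <- seq_len(side) - 1L - floor((side - 1L) / 2)   # integer offsets
  off <- as.matrix(expand.grid(steps, steps, steps))
  off <- off[seq_len(n_voxels), , drop = FALSE]
  idx <- sweep(off, 2, round(center_mm / vox_mm), `+`)
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Simulate a slow event-related BOLD dataset for one participant
#'
#' Each voxel's time series is a sum over trials of a condition- and
#' region-specific amplitude times a gamma-variate response (with the
#' region's condition-specific peak latency), where the amplitude carries a
#' latent per-trial fluctuation propagated along the configured coupling
#' graph; a global nuisance signal shared by all voxels and white
#' measurement noise are added on top. Trial onsets fall on the TR grid,
#' jittered over the configured trial lengths, so the design is identifiable
#' by an FIR deconvolution spanning `kernel_support`.
#'
#' @param config a [sim_config()].
#' @param participant participant index (1-based across overt then covert
#'   participants; determines task, item assignment and seed stream).
#' @return object of class `bold_sim`: `runs` (list of voxels x timepoints
#'   matrices), `events` (list of per-run data.frames with `onset`,
#'   `duration`, `condition`, `item_id`, `rt_ms`, `correct`), `tr`,
#'   `voxel_map` (voxel/region/grid-index table), `affine` (4x4 index-to-mm),
#'   and `ground_truth` (planted amplitudes, latencies, latents and trial
#'   conditions).
#' @export
simulate_bold <- function(config, participant = 1L) {
  stopifnot(inherits(config, "sim_config"))
  ids <- participant_ids(config)
  stopifnot(participant >= 1L, participant <= length(ids))
  gt_items <- item_ground_truth(config)
  rep_lab <- assign_items(config, participant, gt_items)
  task <- if (participant <= config$n_participants_per_task[["overt"]]) {
    "overt"
  } else "covert"
  rs <- config$rt_spec
  region_names <- vapply(config$region_spec, `[[`, "", "name")
  tr <- config$tr

  with_seed(child_seed(config$seed, 3000L + participant), {
    item_order <- sample(config$n_items)
    condition <- condition_label(rep_lab[item_order],
                                 gt_items$primeability[item_order])
    z <- draw_latents(config$n_items, condition, config)
    p_eff <- rnorm(1, 0, rs$participant_sd)
    shift <- if (task == "covert") rs$covert_shift else 0
    base <- ifelse(rep_lab[item_order] == "OLD",
                   gt_items$new_mean[item_order] - gt_items$benefit[item_order],
                   gt_items$new_mean[item_order])
    rt <- draw_rt(config$n_items, base + shift, rs, p_eff)
    err <- runif(config$n_items) < config$error_rate
    slow <- !err & runif(config$n_items) < config$slow_rate
    rt[slow] <- pmax(rt[slow] + 1400, 2001)
    correct <- as.integer(!err)

    lengths <- sample(config$trial_lengths, config$n_items, replace = TRUE)
    lead_in <- 2 * tr
    pad <- config$kernel_support + 2 * tr
    runs <- vector("list", config$n_runs)
    events <- vector("list", config$n_runs)
    amp_mat <- do.call(rbind, lapply(config$region_spec, `[[`, "amplitude"))
    tpk_mat <- do.call(rbind, lapply(config$region_spec, `[[`, "t_peak"))
    rownames(amp_mat) <- rownames(tpk_mat) <- region_names
    b_vec <- vapply(config$region_spec, `[[`, 0, "b")

    for (r in seq_len(config$n_runs)) {
      sel <- ((r - 1) * config$trials_per_run + 1):(r * config$trials_per_run)
      onsets <- lead_in + c(0, cumsum(lengths[sel][-length(sel)]))
      n_t <- as.integer((lead_in + sum(lengths[sel]) + pad) / tr)
      times <- (seq_len(n_t) - 1) * tr
      region_ts <- matrix(0, length(region_names), n_t,
                          dimnames = list(region_names, NULL))
      for (j in seq_along(sel)) {
        tl <- sel[j]
        cond <- condition[tl]
        for (g in seq_along(region_names)) {
          amp <- amp_mat[g, cond] + z[tl, g]
          kern <- gamma_kernel(times - onsets[j], b_vec[g],
                               tpk_mat[g, cond], config$kernel_support)
          region_ts[g, ] <- region_ts[g, ] + amp * kern
        }
      }
      nv_per <- vapply(config$region_spec, function(r) as.integer(r$n_voxels),
                       0L)
      data <- region_ts[rep(seq_along(region_names), nv_per), , drop = FALSE]
      global <- rnorm(n_t, 0, config$global_signal_sd)
      data <- sweep(data, 2, global, `+`) +
        matrix(rnorm(length(data), 0, config$noise_sd), nrow(data))
      rownames(data) <- NULL
      runs[[r]] <- data
      events[[r]] <- data.frame(
        onset = onsets, duration = 0.3, condition = condition[sel],
        item_id = gt_items$item[item_order[sel]],
        rt_ms = round(rt[sel], 1), correct = correct[sel],
        stringsAsFactors = FALSE)
    }

    voxel_map <- do.call(rbind, lapply(seq_along(config$region_spec),
      function(g) {
        reg <- config$region_spec[[g]]
        idx <- region_voxel_grid(reg$center, reg$n_voxels)
        data.frame(region = reg$name, idx)
      }))
    voxel_map$voxel <- seq_len(nrow(voxel_map))
    affine <- diag(c(3, 3, 3, 1))

    structure(list(
      participant = ids[participant], task = task,
      runs = runs, events = events, tr = tr,
      voxel_map = voxel_map, affine = affine,
      ground_truth = list(
        items = gt_items, amplitude = amp_mat, t_peak = tpk_mat, b = b_vec,
        coupling = config$coupling_spec, condition = condition,
        latents = z, trial_lengths = lengths, correct = correct)
    ), class = "bold_sim")
  })
}

#' Simulate region-level item series for a group of participants
#'
#' Generates the latent trial-amplitude structure of [simulate_bold()]
#' directly at the region level (one peak value per trial and region, plus
#' measurement noise), skipping voxel time series. This is the generator
#' used for group-level connectivity and SEM studies, where only the item
#' series matter; coupling acts on latent trial amplitudes because that is
#' the quantity trial-peak connectivity measures.
#'
#' @param config a [sim_config()].
#' @param n_participants number of simulated participants (split across
#'   tasks in proportion to the config; default the config total).
#' @return list with `participants` (each: `participant`, `task`, `series`
#'   regions x trials matrix, `condition`, `correct`) and `ground_truth`.
#' @export
simulate_item_series <- function(config, n_participants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_participants)) {
    n_participants <- sum(config$n_participants_per_task)
  }
  gt_items <- item_ground_truth(config)
  region_names <- vapply(config$region_spec, `[[`, "", "name")
  amp_mat <- do.call(rbind, lapply(config$region_spec, `[[`, "amplitude"))
  rownames(amp_mat) <- region_names
  n_overt <- round(n_participants *
                     config$n_participants_per_task[["overt"]] /
                     sum(config$n_participants_per_task))
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    rep_lab <- assign_items(config, i, gt_items)
    out[[i]] <- with_seed(child_seed(config$seed, 5000L + i), {
      item_order <- sample(config$n_items)
      condition <- condition_label(rep_lab[item_order],
                                   gt_items$primeability[item_order])
      z <- draw_latents(config$n_items, condition, config)
      series <- t(amp_mat[, condition, drop = FALSE]) + z +
        matrix(rnorm(config$n_items * length(region_names), 0,
                     config$noise_sd), config$n_items)
      correct <- as.integer(runif(config$n_items) >= config$error_rate)
      list(participant = sprintf("sim_%03d", i),
           task = if (i <= n_overt) "overt" else "covert",
           series = t(series), condition = condition, correct = correct)
    })
  }
  list(participants = out,
       ground_truth = list(items = gt_items, amplitude = amp_mat,
                           coupling = config$coupling_spec))
}
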