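#' Default region specification for the synthetic study
#'
#' Seven regions mirror the network studied in slow event-related object
#' naming: a right temporoparietal node, anterior cingulate, right fusiform,
#' right superior temporal, right putamen, left frontal and left fusiform.
#' Each region carries per-condition peak amplitudes (percent signal change)
#' and per-condition hemodynamic peak latencies. The four
#' repetition-suppression regions (`ACC`, `rFus`, `lFront`, `lFus`) respond
#' at roughly half amplitude to repeated (OLD) items, more so for Strong
#' Primeable items; `lFus` and `lFront` additionally peak ~0.6 s earlier for
#' OLD items. Amplitude units are arbitrary signal units; latency in seconds.
#'
#' @param n_voxels number of voxels per region (arranged as a cubic block).
#' @return list of region definitions (name, center, n_voxels, amplitude and
#'   t_peak per condition, gamma shape `b`).
#' @export
default_region_spec <- function(n_voxels = 27) {
  amp <- function(os, ow, ns, nw) {
    c(OLD_Strong = os, OLD_Weak = ow, NEW_Strong = ns, NEW_Weak = nw)
  }
  tp <- function(old, new) {
    c(OLD_Strong = old, OLD_Weak = old, NEW_Strong = new, NEW_Weak = new)
  }
  centers <- list(rTP = c(50, 40, 40), ACC = c(2, 30, 40),
                  rFus = c(40, -50, -10), rSTG = c(55, -20, 5),
                  rPut = c(25, 5, 0), lFront = c(-45, 20, 25),
                  lFus = c(-40, -50, -10))
  rs   <- amp(0.50, 0.60, 1.00, 1.00)   # repetition suppression, Strong > Weak
  flat <- amp(1.00, 1.00, 1.00, 1.00)
  spec <- list(
    list(name = "rTP",    amplitude = flat, t_peak = tp(5.0, 5.0)),
    list(name = "ACC",    amplitude = rs,   t_peak = tp(5.0, 5.0)),
    list(name = "rFus",   amplitude = rs,   t_peak = tp(5.0, 5.0)),
    list(name = "rSTG",   amplitude = flat, t_peak = tp(5.0, 5.0)),
    list(name = "rPut",   amplitude = flat, t_peak = tp(5.0, 5.0)),
    list(name = "lFront", amplitude = rs,   t_peak = tp(4.6, 5.0)),
    list(name = "lFus",   amplitude = rs,   t_peak = tp(4.4, 5.0))
  )
  lapply(spec, function(r) {
    r$center <- centers[[r$name]]
    r$n_voxels <- n_voxels
    r$b <- 2.5   # gamma rise exponent; decay c follows from t_peak = b * c
    r
  })
}

#' Default directed coupling specification
#'
#' Trial-amplitude coupling between regions, with condition-dependent
#' weights carrying the planted Repetition x Primeability interaction: the
#' rTP -> ACC edge couples more strongly for OLD than NEW items in the
#' Strong Primeable condition, while ACC -> rFus and rSTG -> rTP couple more
#' weakly for OLD items in the Weak Primeable condition.
#'
#' @return data.frame with `from`, `to` and one weight column per condition.
#' @export
default_coupling_spec <- function() {
  data.frame(
    from = c("rTP", "ACC", "rSTG"),
    to   = c("ACC", "rFus", "rTP"),
    OLD_Strong = c(0.80, 0.35, 0.35),
    OLD_Weak   = c(0.30, 0.15, 0.15),
    NEW_Strong = c(0.30, 0.35, 0.35),
    NEW_Weak   = c(0.40, 0.40, 0.40)
  )
}

#' Default response-time specification
#'
#' Item baseline NEW naming times are drawn around 900 ms (SD 120 ms across
#' items, typical of overt picture naming); the expected priming benefit for
#' an item grows with its baseline NEW RT (slope 0.35 ms benefit per ms of
#' baseline RT above the item-population mean, around a mean benefit of
#' 80 ms), which is what makes slow-named items "strongly primeable". The
#' scatter of item benefits about that regression is exposed as
#' `benefit_sd` since real data only constrain it loosely.
#'
#' @return list of RT-model parameters (all in ms).
#' @export
default_rt_spec <- function() {
  list(new_mean = 900, new_sd = 120,
       benefit_mean = 80, benefit_slope = 0.35, benefit_sd = 20,
       participant_sd = 60, residual_sd = 110,
       covert_shift = -250)   # button presses run 200-300 ms faster
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic behavioral + BOLD generator. Defaults
#' reproduce the study conditions the analyses assume: 200 items split
#' OLD/NEW 100/100, 5 runs of 40 slow event-related trials at TR = 2 s with
#' trial lengths jittered over 8/10/12/14 s, seven coupled regions, and a
#' 5% error rate plus occasional >2000 ms responses to exercise filtering.
#'
#' @param n_participants_per_task named count vector `c(overt=, covert=)`.
#' @param n_items number of stimuli (even; half OLD, half NEW per
#'   participant).
#' @param n_runs,trials_per_run scanner run structure;
#'   `n_runs * trials_per_run` must equal `n_items`.
#' @param tr repetition time in seconds.
#' @param trial_lengths jitter set in seconds; positive multiples of `tr`.
#' @param region_spec list of region definitions, see
#'   [default_region_spec()].
#' @param coupling_spec directed trial-amplitude coupling, see
#'   [default_coupling_spec()].
#' @param noise_sd white measurement noise SD per voxel timepoint (signal
#'   units).
#' @param latent_sd SD of the latent per-trial regional amplitude
#'   fluctuations that coupling propagates.
#' @param global_signal_sd SD of the shared global nuisance signal (gives
#'   GCOR variance to explain).
#' @param rt_spec response-time model, see [default_rt_spec()].
#' @param error_rate,slow_rate planted fractions of incorrect trials and of
#'   correct trials slower than 2000 ms.
#' @param kernel_support response support in seconds; the trial response is
#'   truncated here so the FIR window spans it exactly.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants_per_task = c(overt = 30, covert = 30),
                       n_items = 200,
                       n_runs = 5,
                       trials_per_run = 40,
                       tr = 2,
                       trial_lengths = c(8, 10, 12, 14),
                       region_spec = default_region_spec(),
                       coupling_spec = default_coupling_spec(),
                       noise_sd = 0.25,
                       latent_sd = 0.5,
                       global_signal_sd = 0.1,
                       rt_spec = default_rt_spec(),
                       error_rate = 0.05,
                       slow_rate = 0.02,
                       kernel_support = 14,
                       seed = 1L) {
  stop_if_not_count(n_items, "n_items")
  stop_if_not_count(n_runs, "n_runs")
  stop_if_not_count(trials_per_run, "trials_per_run")
  if (n_items %% 2L != 0L) stop("`n_items` must be even", call. = FALSE)
  if (any(n_participants_per_task < 1)) {
    stop("participant counts must be positive", call. = FALSE)
  }
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (any(trial_lengths <= 0) ||
      any(abs(trial_lengths / tr - round(trial_lengths / tr)) > 1e-9)) {
    stop("`trial_lengths` must be positive multiples of `tr`", call. = FALSE)
  }
  if (length(region_spec) < 1L) stop("`region_spec` is empty", call. = FALSE)
  stop_if_not_nonneg(noise_sd, "noise_sd")
  stop_if_not_nonneg(latent_sd, "latent_sd")
  stop_if_not_nonneg(global_signal_sd, "global_signal_sd")
  stop_if_not_nonneg(c(error_rate, slow_rate), "error/slow rates")
  if (!is.null(coupling_spec) && nrow(coupling_spec) > 0L) {
    w <- as.matrix(coupling_spec[, condition_levels(), drop = FALSE])
    if (any(!is.finite(w))) stop("coupling weights must be finite", call. = FALSE)
    nm <- vapply(region_spec, `[[`, "", "name")
    if (!all(coupling_spec$from %in% nm) || !all(coupling_spec$to %in% nm)) {
      stop("coupling_spec names regions absent from region_spec", call. = FALSE)
    }
  }
  if (n_runs * trials_per_run != n_items) {
    stop("`n_runs * trials_per_run` must equal `n_items`", call. = FALSE)
  }
  structure(list(
    n_participants_per_task = n_participants_per_task,
    n_items = as.integer(n_items), n_runs = as.integer(n_runs),
    trials_per_run = as.integer(trials_per_run), tr = tr,
    trial_lengths = trial_lengths, region_spec = region_spec,
    coupling_spec = coupling_spec, noise_sd = noise_sd,
    latent_sd = latent_sd, global_signal_sd = global_signal_sd,
    rt_spec = rt_spec, error_rate = error_rate, slow_rate = slow_rate,
    kernel_support = kernel_support, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  participants: %s\n",
              paste(names(x$n_participants_per_task),
                    x$n_participants_per_task, sep = "=", collapse = ", ")))
  cat(sprintf("  items: %d  runs: %d x %d trials  TR: %gs  lengths: %s s\n",
              x$n_items, x$n_runs, x$trials_per_run, x$tr,
              paste(x$trial_lengths, collapse = "/")))
  cat(sprintf("  regions: %d  coupled edges: %d  noise_sd: %g  seed: %d\n",
              length(x$region_spec),
              if (is.null(x$coupling_spec)) 0L else nrow(x$coupling_spec),
              x$noise_sd, x$seed))
  invisible(x)
}
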