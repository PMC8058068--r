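# Item-level ground truth shared by the behavioral and BOLD generators.
# Drawn from the config seed alone so that behavior and imaging for the same
# config agree on item properties and on the planted Primeability classes.
item_ground_truth <- function(config) {
  rs <- config$rt_spec
  with_seed(child_seed(config$seed, 1L), {
    item <- sprintf("item_%03d", seq_len(config$n_items))
    new_mean <- rnorm(config$n_items, rs$new_mean, rs$new_sd)
    benefit <- rs$benefit_mean +
      rs$benefit_slope * (new_mean - rs$new_mean) +
      rnorm(config$n_items, 0, rs$benefit_sd)
    ord <- order(new_mean, item)
    primeability <- rep("Strong", config$n_items)
    primeability[ord[seq_len(config$n_items %/% 2L)]] <- "Weak"
    data.frame(item = item, new_mean = new_mean, benefit = benefit,
               primeability = primeability, stringsAsFactors = FALSE)
  })
}

participant_ids <- function(config) {
  n <- config$n_participants_per_task
  c(sprintf("overt_%02d", seq_len(n[["overt"]])),
    sprintf("covert_%02d", seq_len(n[["covert"]])))
}

# Per-participant item assignment: a seeded balanced permutation assigns half
# the items to OLD (named before scanning) and half to NEW, stratified within
# the planted Primeability classes so the four condition cells come out
# (near-)equal — emulating list counterbalancing across participants.
assign_items <- function(config, participant_index, gt = NULL) {
  if (is.null(gt)) gt <- item_ground_truth(config)
  with_seed(child_seed(config$seed, 1000L + participant_index), {
    rep_lab <- rep("NEW", config$n_items)
    for (cls in unique(gt$primeability)) {
      idx <- which(gt$primeability == cls)
      old <- sample(idx, length(idx) %/% 2L)
      rep_lab[old] <- "OLD"
    }
    rep_lab
  })
}

draw_rt <- function(n, base, rs, p_eff) {
  pmax(250, base + p_eff + rnorm(n, 0, rs$residual_sd))
}

#' Simulate behavioral naming data with planted item effects
#'
#' Generates per-participant, per-item response times for a pre-scan overt
#' naming session, the in-scanner session (overt voice or covert button
#' press), and, for covert participants, a post-scan overt session. Each
#' item's expected priming benefit increases with its baseline NEW naming
#' time (slope from `rt_spec`), the structure that motivates the
#' Primeability median split. A configurable fraction of trials is planted
#' incorrect or slower than 2000 ms to exercise the filtering paths.
#'
#' @param config a [sim_config()].
#' @return list with `trials` (columns `participant`, `task`, `session`,
#'   `item`, `repetition`, `rt`, `correct`) and `ground_truth` (per-item
#'   true NEW mean, true benefit, planted Primeability class, and the
#'   `rt_spec` used).
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gt <- item_ground_truth(config)
  rs <- config$rt_spec
  ids <- participant_ids(config)
  tasks <- rep(c("overt", "covert"), config$n_participants_per_task)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rep_lab <- assign_items(config, i, gt)
    rows[[i]] <- with_seed(child_seed(config$seed, 2000L + i), {
      p_eff <- rnorm(1, 0, rs$participant_sd)
      old_idx <- which(rep_lab == "OLD")
      task <- tasks[i]
      shift <- if (task == "covert") rs$covert_shift else 0
      # pre-scan: first (NEW) exposure of the to-be-OLD items, named aloud
      pre <- data.frame(
        participant = ids[i], task = task, session = "pre",
        item = gt$item[old_idx], repetition = "NEW",
        rt = draw_rt(length(old_idx), gt$new_mean[old_idx], rs, p_eff),
        correct = 1L, stringsAsFactors = FALSE)
      # scanner session: all items, OLD primed, covert responses shifted
      base <- ifelse(rep_lab == "OLD", gt$new_mean - gt$benefit, gt$new_mean)
      fmri <- data.frame(
        participant = ids[i], task = task, session = "fmri",
        item = gt$item, repetition = rep_lab,
        rt = draw_rt(config$n_items, base + shift, rs, p_eff),
        correct = 1L, stringsAsFactors = FALSE)
      out <- rbind(pre, fmri)
      if (task == "covert") {
        # post-scan overt naming of all items, OLD/NEW relative to pre-scan
        post <- data.frame(
          participant = ids[i], task = task, session = "post",
          item = gt$item, repetition = rep_lab,
          rt = draw_rt(config$n_items, base, rs, p_eff),
          correct = 1L, stringsAsFactors = FALSE)
        out <- rbind(out, post)
      }
      n <- nrow(out)
      err <- runif(n) < config$error_rate
      slow <- !err & runif(n) < config$slow_rate
      out$correct[err] <- 0L
      out$rt[slow] <- pmax(out$rt[slow] + 1400, 2001)
      out
    })
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials,
       ground_truth = list(items = gt, rt_spec = rs, seed = config$seed))
}
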