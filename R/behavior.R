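#' Filter naming trials for behavioral and GLM analyses
#'
#' Removes incorrect trials and trials with response times strictly slower
#' than a ceiling (default 2000 ms; a trial at exactly the ceiling is kept).
#' Slow trials are the ones most likely to contaminate multiple TRs with
#' speech artifact, so downstream GLM stages treat them like error trials:
#' the returned exclusion log carries enough information to relabel them.
#'
#' @param trials data.frame of trial records with at least columns `rt`
#'   (milliseconds) and `correct` (logical or 0/1). Missing RTs on correct
#'   trials are excluded and logged.
#' @param rt_ceiling_ms positive scalar; trials with `rt > rt_ceiling_ms`
#'   are excluded.
#' @return list with `trials` (the retained rows), `excluded` (the removed
#'   rows with a `reason` column, one of `"incorrect"`, `"slow"`,
#'   `"missing_rt"`), and `log` (a named count per reason).
#' @export
filter_trials <- function(trials, rt_ceiling_ms = 2000) {
  if (!is.numeric(rt_ceiling_ms) || length(rt_ceiling_ms) != 1L ||
      rt_ceiling_ms <= 0) {
    stop("`rt_ceiling_ms` must be a single positive number", call. = FALSE)
  }
  if (nrow(trials) == 0L) {
    warning("empty trial table; nothing to filter")
    return(list(trials = trials,
                excluded = cbind(trials, reason = character(0)),
                log = c(incorrect = 0L, slow = 0L, missing_rt = 0L)))
  }
  correct <- as.logical(trials$correct)
  reason <- rep(NA_character_, nrow(trials))
  reason[!correct] <- "incorrect"
  reason[correct & is.na(trials$rt)] <- "missing_rt"
  reason[correct & !is.na(trials$rt) & trials$rt > rt_ceiling_ms] <- "slow"
  keep <- is.na(reason)
  excluded <- trials[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  log <- c(incorrect = sum(reason == "incorrect", na.rm = TRUE),
           slow = sum(reason == "slow", na.rm = TRUE),
           missing_rt = sum(reason == "missing_rt", na.rm = TRUE))
  list(trials = trials[keep, , drop = FALSE], excluded = excluded, log = log)
}

#' Item-level normative response times
#'
#' Computes, per item, the group-mean correct first-exposure (NEW) response
#' time and the mean priming benefit (NEW minus OLD), averaging across
#' contributing participants. First exposure means the pre-scanner first
#' presentation or a NEW trial during scanning. Only overt-naming sessions
#' contribute by default, since button-press times run systematically faster.
#'
#' @param trials filtered trial table with columns `participant`, `item`,
#'   `task` (`"overt"`/`"covert"`), `repetition` (`"NEW"`/`"OLD"`), `rt`,
#'   `correct`, and optionally `session` (`"pre"`, `"fmri"`, `"post"`).
#' @param overt_only restrict to overt naming responses (scanner task
#'   `"overt"`, or post-scan overt sessions of covert participants).
#' @param exclude_participant optional participant id(s) omitted from the
#'   norms (leave-one-out norms, so item classification can be independent
#'   of the held-out participant's own data).
#' @return data.frame of class `item_norms`: `item`, `mean_new_rt`,
#'   `mean_priming`, `n_new`, `n_old`. Items with no contributing NEW
#'   response get `NA` and a warning.
#' @export
compute_item_norms <- function(trials, overt_only = TRUE,
                               exclude_participant = NULL) {
  x <- trials
  if (!is.null(exclude_participant)) {
    x <- x[!(x$participant %in% exclude_participant), , drop = FALSE]
  }
  if (overt_only && "task" %in% names(x)) {
    overt_row <- x$task == "overt"
    if ("session" %in% names(x)) {
      # post-scan sessions are named aloud regardless of scanner task
      overt_row <- overt_row | x$session %in% c("pre", "post")
    }
    x <- x[overt_row, , drop = FALSE]
  }
  x <- x[as.logical(x$correct) & !is.na(x$rt), , drop = FALSE]
  items <- sort(unique(trials$item))
  mean_by <- function(rows) {
    agg <- tapply(rows$rt, rows$item, mean)
    n <- tapply(rows$rt, rows$item, length)
    list(mean = agg, n = n)
  }
  new <- mean_by(x[x$repetition == "NEW", , drop = FALSE])
  old <- mean_by(x[x$repetition == "OLD", , drop = FALSE])
  out <- data.frame(
    item = items,
    mean_new_rt = as.numeric(new$mean[as.character(items)]),
    mean_priming = as.numeric(new$mean[as.character(items)]) -
      as.numeric(old$mean[as.character(items)]),
    n_new = as.integer(ifelse(is.na(new$n[as.character(items)]), 0L,
                              new$n[as.character(items)])),
    n_old = as.integer(ifelse(is.na(old$n[as.character(items)]), 0L,
                              old$n[as.character(items)]))
  )
  if (any(out$n_new == 0L)) {
    warning(sprintf("%d item(s) have no contributing NEW response; norms NA",
                    sum(out$n_new == 0L)))
  }
  class(out) <- c("item_norms", "data.frame")
  out
}

#' Median split of items into Strong and Weak Primeable
#'
#' Items are rank-ordered by mean NEW response time; the slowest half is
#' labeled `Strong` (slow-to-name items show the largest subsequent priming)
#' and the fastest half `Weak`. Ties at the median are broken by item id
#' ascending (stable and platform-independent). With an odd item count the
#' Strong class receives the extra item and a warning is emitted.
#'
#' @param norms `item_norms` table (or any data.frame with `item` and
#'   `mean_new_rt`).
#' @return the input with a `primeability` factor column added.
#' @export
primeability_split <- function(norms) {
  if (nrow(norms) < 2L) stop("need at least 2 items to split", call. = FALSE)
  if (any(is.na(norms$mean_new_rt))) {
    stop("cannot split on undefined norms (NA mean_new_rt)", call. = FALSE)
  }
  if (nrow(norms) %% 2L == 1L) {
    warning("odd item count: Strong class receives the extra item")
  }
  ord <- order(norms$mean_new_rt, norms$item)  # slowest last
  n_weak <- nrow(norms) %/% 2L
  lab <- rep("Strong", nrow(norms))
  lab[ord[seq_len(n_weak)]] <- "Weak"
  norms$primeability <- factor(lab, levels = c("Strong", "Weak"))
  norms
}

#' Priming effect size (Cohen's d)
#'
#' The difference in means (NEW minus OLD) divided by the two-sample pooled
#' standard deviation (Bessel-corrected), so that positive values indicate
#' priming (faster repeated naming).
#'
#' @param new_rts,old_rts numeric vectors of correct-trial response times
#'   (>= 2 values each).
#' @return scalar d; `NA` with a warning if the pooled SD is zero.
#' @export
priming_effect_size <- function(new_rts, old_rts) {
  new_rts <- new_rts[!is.na(new_rts)]
  old_rts <- old_rts[!is.na(old_rts)]
  n1 <- length(new_rts); n2 <- length(old_rts)
  if (n1 < 2L || n2 < 2L) {
    stop("need >= 2 response times per group", call. = FALSE)
  }
  pooled <- sqrt(((n1 - 1) * var(new_rts) + (n2 - 1) * var(old_rts)) /
                   (n1 + n2 - 2))
  if (pooled == 0) {
    warning("pooled SD is zero; effect size undefined")
    return(NA_real_)
  }
  (mean(new_rts) - mean(old_rts)) / pooled
}

#' Test-retest reliability of item norms
#'
#' Pearson correlation across items of a normative field (`mean_new_rt` or
#' `mean_priming`) between two independently computed norm tables, e.g. from
#' the overt and covert experiments or from split halves of the participants.
#'
#' @param norms_a,norms_b `item_norms` tables sharing an item set.
#' @param field column to correlate.
#' @return list with `r`, `n` (overlapping items) and `p` (two-sided).
#' @export
item_reliability <- function(norms_a, norms_b, field = "mean_new_rt") {
  m <- merge(norms_a[, c("item", field)], norms_b[, c("item", field)],
             by = "item", suffixes = c("_a", "_b"))
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need >= 3 overlapping items", call. = FALSE)
  ct <- cor.test(m[[paste0(field, "_a")]], m[[paste0(field, "_b")]])
  list(r = unname(ct$estimate), n = nrow(m), p = ct$p.value)
}

#' Per-participant priming effect sizes by Primeability
#'
#' Convenience wrapper: filters trials, applies item Primeability labels and
#' returns one Cohen's d per participant x Primeability cell (plus a pooled
#' `all` cell), the quantity correlated with neural measures across
#' participants.
#'
#' @param trials trial table (see [compute_item_norms()]).
#' @param norms `item_norms` with a `primeability` column.
#' @param rt_ceiling_ms passed to [filter_trials()].
#' @return data.frame `participant`, `primeability` (`Strong`/`Weak`/`all`),
#'   `d`, `n_new`, `n_old`.
#' @export
priming_by_primeability <- function(trials, norms, rt_ceiling_ms = 2000) {
  keep <- filter_trials(trials, rt_ceiling_ms)$trials
  keep <- keep[keep$session %in% c("fmri", "post") | !("session" %in% names(keep)), ,
               drop = FALSE]
  lab <- setNames(as.character(norms$primeability), norms$item)
  keep$primeability <- lab[as.character(keep$item)]
  out <- list()
  for (p in unique(keep$participant)) {
    px <- keep[keep$participant == p, , drop = FALSE]
    for (cls in c("Strong", "Weak", "all")) {
      cx <- if (cls == "all") px else px[px$primeability == cls, , drop = FALSE]
      new_rt <- cx$rt[cx$repetition == "NEW"]
      old_rt <- cx$rt[cx$repetition == "OLD"]
      d <- if (length(new_rt) >= 2L && length(old_rt) >= 2L) {
        suppressWarnings(priming_effect_size(new_rt, old_rt))
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        participant = p, primeability = cls, d = d,
        n_new = length(new_rt), n_old = length(old_rt))
    }
  }
  do.call(rbind, out)
}
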