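# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All generator functions route randomness through this so that a fixed
# config + seed yields byte-identical output regardless of ambient RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

stop_if_not_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer, got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  invisible(as.integer(x))
}

stop_if_not_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and >= 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Condition-label helpers
#'
#' The experiment crosses Repetition (`OLD`/`NEW`) with Primeability
#' (`Strong`/`Weak`); condition cells are labeled `"OLD_Strong"` etc.
#' `condition_levels()` lists the four cells, `condition_label()` builds
#' labels from the two factors and `split_condition()` recovers the factors
#' from labels.
#'
#' @param repetition,primeability character vectors of factor levels.
#' @param condition character vector of cell labels.
#' @return `condition_levels()` and `condition_label()` return character
#'   vectors; `split_condition()` a data.frame with `repetition` and
#'   `primeability`.
#' @export
condition_levels <- function() {
  c("OLD_Strong", "OLD_Weak", "NEW_Strong", "NEW_Weak")
}

#' @rdname condition_levels
#' @export
condition_label <- function(repetition, primeability) {
  paste(repetition, primeability, sep = "_")
}

#' @rdname condition_levels
#' @export
split_condition <- function(condition) {
  parts <- strsplit(as.character(condition), "_", fixed = TRUE)
  data.frame(
    repetition   = vapply(parts, `[`, "", 1L),
    primeability = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}
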