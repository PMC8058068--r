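as_design_factors <- function(data) {
  for (col in c("task", "repetition", "primeability", "participant")) {
    if (col %in% names(data)) data[[col]] <- factor(data[[col]])
  }
  data
}

# Type-III F tests for a fixed-effects fallback fit, by model comparison
# with sum-to-zero contrasts.
lm_type3 <- function(data, formula_fixed, terms_wanted) {
  mf <- lm(formula_fixed, data = data,
           contrasts = lapply(
             Filter(function(v) is.factor(data[[v]]),
                    setNames(nm = all.vars(formula_fixed[-2]))),
             function(...) "contr.sum"))
  X <- model.matrix(mf)
  asg <- attr(X, "assign")
  labels <- attr(terms(mf), "term.labels")
  y <- model.response(model.frame(mf))
  rss_full <- sum(residuals(mf)^2)
  df_resid <- mf$df.residual
  rows <- list()
  for (i in seq_along(labels)) {
    cols <- which(asg == i)
    Xr <- X[, -cols, drop = FALSE]
    fit_r <- lm.fit(Xr, y)
    rss_r <- sum(fit_r$residuals^2)
    Fv <- ((rss_r - rss_full) / length(cols)) / (rss_full / df_resid)
    p <- if (df_resid > 0 && rss_full > 0) {
      pf_upper(Fv, length(cols), df_resid)
    } else NA_real_
    rows[[i]] <- data.frame(term = tolower(labels[i]), F = Fv,
                            df1 = length(cols), df2 = df_resid, p = p)
  }
  list(tests = do.call(rbind, rows), model = mf)
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Linear mixed-effects test of a factorial condition design
#'
#' Fits `dv ~ task * repetition * primeability (+ covariates) +
#' (1 | participant)` with sum-to-zero factor contrasts and returns
#' per-term F tests with Satterthwaite denominator degrees of freedom.
#' Task is dropped from the fixed effects automatically when only one task
#' is present. If the mixed model cannot be fit (e.g. zero residual
#' variance in noise-free data), the function degrades to the
#' fixed-effects model with exact type-III F tests and flags the fallback.
#'
#' @param data long-format data.frame with `participant`, `repetition`,
#'   `primeability`, optionally `task`, the dependent variable and any
#'   covariates.
#' @param dv name of the dependent-variable column.
#' @param covariates character vector of nuisance covariate columns (e.g.
#'   `"gcor"`, `"mean_beta"`, `"snr"`).
#' @return object of class `lme_result`: `tests` (term, F, df1, df2, p),
#'   `adjusted_means` (condition means at covariate means), `coefficients`,
#'   `converged`, `singular`, `method` (`"lmer"` or `"lm"`).
#' @export
fit_lme <- function(data, dv, covariates = NULL) {
  data <- as_design_factors(as.data.frame(data))
  data <- data[is.finite(data[[dv]]), , drop = FALSE]
  if (var(data[[dv]]) == 0) stop("constant dependent variable", call. = FALSE)
  has_task <- "task" %in% names(data) && nlevels(data$task) > 1
  fixed <- if (has_task) "task * repetition * primeability" else
    "repetition * primeability"
  if (length(covariates)) {
    fixed <- paste(fixed, "+", paste(covariates, collapse = " + "))
  }
  if (has_task && nlevels(droplevels(data$task)) > 1) {
    n_per_task <- table(unique(data[, c("participant", "task")])$task)
    if (any(n_per_task < 2)) stop("need >= 2 participants per task",
                                  call. = FALSE)
  }
  f_mixed <- as.formula(paste(dv, "~", fixed, "+ (1 | participant)"))
  f_fixed <- as.formula(paste(dv, "~", fixed))
  old_opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_opts))
  m <- tryCatch(
    suppressWarnings(suppressMessages(
      lmerTest::lmer(f_mixed, data = data, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(m)) {
    at <- tryCatch(suppressWarnings(suppressMessages(
      anova(m, type = 3, ddf = "Satterthwaite"))), error = function(e) NULL)
  }
  if (is.null(m) || is.null(at) || any(!is.finite(at[["F value"]]))) {
    fb <- lm_type3(data, f_fixed, NULL)
    tests <- fb$tests
    model <- fb$model
    method <- "lm"
    converged <- TRUE
    singular <- NA
  } else {
    tests <- data.frame(term = tolower(rownames(at)), F = at[["F value"]],
                        df1 = at$NumDF, df2 = at$DenDF, p = at[["Pr(>F)"]])
    model <- m
    method <- "lmer"
    msgs <- m@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
    singular <- lme4::isSingular(m)
  }
  rownames(tests) <- NULL
  # condition means adjusted to covariate means (averaged over task)
  grid <- expand.grid(repetition = levels(data$repetition),
                      primeability = levels(data$primeability))
  cells <- grid
  if (has_task) {
    grid <- merge(grid, data.frame(task = levels(data$task)))
  }
  for (cv in covariates) grid[[cv]] <- mean(data[[cv]])
  grid$participant <- data$participant[1]
  pred <- if (method == "lmer") {
    predict(model, newdata = grid, re.form = NA)
  } else {
    predict(model, newdata = grid)
  }
  grid$fit <- pred
  adj <- aggregate(fit ~ repetition + primeability, data = grid, FUN = mean)
  structure(list(tests = tests, adjusted_means = adj,
                 coefficients = if (method == "lmer") lme4::fixef(model) else
                   coef(model),
                 converged = converged, singular = singular, method = method,
                 n_obs = nrow(data)),
            class = "lme_result")
}

#' @exportS3Method base::print
print.lme_result <- function(x, ...) {
  cat(sprintf("Factorial mixed-model tests (%s, n = %d):\n", x$method,
              x$n_obs))
  print(transform(x$tests, F = round(F, 3), df2 = round(df2, 1),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: sorted p-values are compared with
#' `i * q / m` and every p-value at or below the largest passing one is
#' declared a discovery.
#'
#' @param p p-values in `(0, 1]` (NAs tolerated, never discovered).
#' @param q FDR level.
#' @return list with `significant` (logical, same length as `p`),
#'   `threshold` (largest discovered p, `NA` if none) and `n_discoveries`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(list(significant = logical(0), threshold = NA_real_,
                n_discoveries = 0L))
  }
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  sig <- !is.na(p) & p.adjust(p, method = "BH") <= q
  list(significant = sig,
       threshold = if (any(sig)) max(p[sig]) else NA_real_,
       n_discoveries = sum(sig))
}

#' Follow-up repetition contrasts within Primeability classes
#'
#' Paired OLD-versus-NEW contrasts of a participant-level measure computed
#' separately within the Strong and the Weak Primeable condition, the
#' follow-up family used once a Repetition x Primeability interaction is
#' established; corrected by FDR within the family.
#'
#' @param data long data.frame with `participant`, `repetition`,
#'   `primeability` and the dependent variable.
#' @param dv dependent-variable column name.
#' @param family Primeability classes tested (non-empty).
#' @param q FDR level within the family.
#' @return data.frame: `primeability`, `estimate` (mean OLD - NEW), `t`,
#'   `df`, `p`, `significant`.
#' @export
condition_contrasts <- function(data, dv, family = c("Strong", "Weak"),
                                q = 0.05) {
  if (length(family) == 0) stop("contrast family is empty", call. = FALSE)
  rows <- list()
  for (cls in family) {
    d <- data[data$primeability == cls, , drop = FALSE]
    agg <- aggregate(d[[dv]], by = list(participant = d$participant,
                                        repetition = d$repetition), FUN = mean)
    w <- merge(agg[agg$repetition == "OLD", c("participant", "x")],
               agg[agg$repetition == "NEW", c("participant", "x")],
               by = "participant", suffixes = c("_old", "_new"))
    diff <- w$x_old - w$x_new
    if (all(diff == 0)) {
      rows[[cls]] <- data.frame(primeability = cls, estimate = 0,
                                t = 0, df = length(diff) - 1, p = 1)
      next
    }
    tt <- t.test(diff)
    rows[[cls]] <- data.frame(primeability = cls, estimate = mean(diff),
                              t = unname(tt$statistic),
                              df = unname(tt$parameter), p = tt$p.value)
  }
  out <- do.call(rbind, rows)
  out$significant <- fdr_bh(out$p, q = q)$significant
  rownames(out) <- NULL
  out
}

#' Brain-behavior (partial) Pearson correlation
#'
#' Pearson correlation between two participant-level vectors, optionally
#' partialling out one or more covariates by residualizing both variables
#' on them (e.g. removing repetition-suppression magnitude from a
#' priming-coupling correlation).
#'
#' @param x,y numeric vectors (participants).
#' @param partial_out optional numeric matrix/vector of covariates.
#' @return list with `r`, `df`, `p` (two-sided).
#' @export
brain_behavior_cor <- function(x, y, partial_out = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(partial_out)) {
    partial_out <- as.matrix(partial_out)
    ok <- ok & apply(is.finite(partial_out), 1, all)
  }
  x <- x[ok]; y <- y[ok]
  k <- 0L
  if (!is.null(partial_out)) {
    z <- partial_out[ok, , drop = FALSE]
    k <- ncol(z)
    x <- residuals(lm(x ~ z))
    y <- residuals(lm(y ~ z))
  }
  n <- length(x)
  if (n < k + 3) stop("too few complete observations", call. = FALSE)
  r <- cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}
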