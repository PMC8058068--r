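# Acyclicity check on a logical adjacency matrix (edge[i, j]: j -> i),
# by repeatedly peeling nodes with no remaining parents.
is_acyclic <- function(adj) {
  adj <- adj != 0
  remaining <- seq_len(nrow(adj))
  while (length(remaining) > 0) {
    no_parent <- remaining[rowSums(adj[remaining, remaining, drop = FALSE]) == 0]
    if (length(no_parent) == 0) return(FALSE)
    remaining <- setdiff(remaining, no_parent)
  }
  TRUE
}

edges_to_A <- function(edges, p, coef = NULL) {
  A <- matrix(0, p, p)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      A[edges[e, 2], edges[e, 1]] <- if (is.null(coef)) 1 else coef[e]
    }
  }
  A
}

#' Construct a recursive path model
#'
#' A directed path structure among `p` regions with coefficients `A` (the
#' entry `A[i, j]` is the coefficient of the edge j -> i) and diagonal
#' residual variances `psi`. Only recursive (acyclic) models without
#' self-edges are admitted.
#'
#' @param edges two-column matrix of directed edges (from, to), as integer
#'   region indices.
#' @param p number of regions.
#' @param A optional coefficient matrix consistent with `edges`.
#' @param psi residual variances (default unit).
#' @param names optional region names.
#' @return object of class `path_model`.
#' @export
path_model <- function(edges, p, A = NULL, psi = rep(1, p), names = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2])) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  if (is.null(A)) A <- edges_to_A(edges, p)
  if (!is_acyclic(A)) stop("path structure must be acyclic", call. = FALSE)
  n_free <- nrow(edges) + p
  if (n_free > p * (p + 1) / 2) {
    stop("model has more free parameters than covariance moments",
         call. = FALSE)
  }
  structure(list(p = p, edges = edges, A = A, psi = psi,
                 names = if (is.null(names)) paste0("R", seq_len(p)) else names),
            class = "path_model")
}

#' Model-implied covariance of a recursive path model
#'
#' For x = A x + e with diagonal residual covariance Psi, the population
#' covariance is (I - A)^{-1} Psi (I - A)^{-T}.
#'
#' @param model a `path_model`, or a coefficient matrix `A` (then `psi`
#'   must be given).
#' @param psi residual variances when `model` is a matrix.
#' @return p x p symmetric positive definite covariance matrix.
#' @export
implied_covariance <- function(model, psi = NULL) {
  if (inherits(model, "path_model")) {
    A <- model$A; psi <- model$psi
  } else {
    A <- as.matrix(model)
    if (is.null(psi)) stop("`psi` required when passing a matrix", call. = FALSE)
  }
  p <- nrow(A)
  if (!is_acyclic(A)) stop("path structure must be acyclic", call. = FALSE)
  iia <- solve(diag(p) - A)
  iia %*% diag(psi, p) %*% t(iia)
}

# Maximum-likelihood discrepancy between sample covariance S and implied
# covariance Sigma: F = log det Sigma - log det S + tr(S Sigma^{-1}) - p.
fml <- function(S, sigma) {
  p <- nrow(S)
  ld <- determinant(sigma, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  as.numeric(ld$modulus) - as.numeric(determinant(S, TRUE)$modulus) +
    sum(diag(S %*% solve(sigma))) - p
}

# Node-wise closed-form ML estimates for a recursive model with diagonal
# Psi: each region is regressed on its parents using S. Exact ML for this
# model class; used as a warm start for the quasi-Newton polish and as the
# scoring engine of the model search.
sem_regression_fit <- function(S, edges, p) {
  A <- matrix(0, p, p)
  psi <- numeric(p)
  for (i in seq_len(p)) {
    pa <- edges[edges[, 2] == i, 1]
    if (length(pa) == 0) {
      psi[i] <- S[i, i]
    } else {
      coefs <- solve(S[pa, pa, drop = FALSE], S[pa, i])
      A[i, pa] <- coefs
      psi[i] <- S[i, i] - sum(coefs * S[pa, i])
    }
  }
  list(A = A, psi = pmax(psi, .Machine$double.eps))
}

#' Fit a recursive path model to a sample covariance
#'
#' Minimizes the maximum-likelihood discrepancy
#' `F = log|Sigma(theta)| - log|S| + tr(S Sigma(theta)^{-1}) - p` over the
#' free path coefficients and (log) residual variances by multi-start
#' quasi-Newton (BFGS) minimization, started from the node-wise regression
#' solution and from the empty model `A = 0`, `Psi = diag(S)`.
#' Non-convergence is reported in the `converged` flag, not fatal.
#'
#' @param S sample covariance (or correlation) matrix, symmetric positive
#'   definite.
#' @param n sample size used for the chi-square statistic (`n > p`).
#' @param edges two-column (from, to) edge matrix defining the structure.
#' @param names optional region names.
#' @return object of class `sem_fit`: `A`, `psi`, `fml`, `chisq`
#'   (`(n-1) * fml`), `df` (`p(p+1)/2 - |edges| - p`), `aic`
#'   (`chisq - 2 df`), `converged`, `n`, `edges`.
#' @export
fit_path_model <- function(S, n, edges, names = colnames(S)) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (any(abs(S - t(S)) > 1e-8)) stop("S must be symmetric", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("S must be positive definite", call. = FALSE)
  if (n <= p) stop("`n` must exceed the number of regions", call. = FALSE)
  edges <- matrix(as.integer(edges), ncol = 2)
  model0 <- path_model(edges, p)   # validates structure
  k <- nrow(edges)

  obj <- function(par) {
    A <- edges_to_A(edges, p, par[seq_len(k)])
    psi <- exp(par[k + seq_len(p)])
    fml(S, implied_covariance(A, psi))
  }
  starts <- list(c(rep(0, k), log(diag(S))))
  reg <- sem_regression_fit(S, edges, p)
  starts <- c(starts,
              list(c(if (k > 0) reg$A[cbind(edges[, 2], edges[, 1])] else numeric(0),
                     log(reg$psi))))
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) {
    return(structure(list(A = NULL, psi = NULL, fml = NA_real_,
                          chisq = NA_real_, df = NA_real_, aic = NA_real_,
                          converged = FALSE, n = n, edges = edges,
                          names = model0$names),
                     class = "sem_fit"))
  }
  A <- edges_to_A(edges, p, best$par[seq_len(k)])
  psi <- exp(best$par[k + seq_len(p)])
  f <- max(0, best$value)
  df <- p * (p + 1) / 2 - (k + p)
  chisq <- (n - 1) * f
  dimnames(A) <- list(names, names)
  structure(list(A = A, psi = setNames(psi, names), fml = f, chisq = chisq,
                 df = df, aic = chisq - 2 * df, converged = converged,
                 n = n, edges = edges, names = model0$names),
            class = "sem_fit")
}

#' @exportS3Method base::print
print.sem_fit <- function(x, ...) {
  cat(sprintf(
    "Recursive SEM fit: %d regions, %d edges | F_ML = %.3g, chi2(%.0f) = %.3g, AIC = %.3g%s\n",
    length(x$psi), nrow(x$edges), x$fml, x$df, x$chisq, x$aic,
    if (x$converged) "" else "  [NOT converged]"))
  if (nrow(x$edges) > 0) {
    nm <- if (!is.null(colnames(x$A))) colnames(x$A) else x$names
    for (e in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -> %s : %.4f\n", nm[x$edges[e, 1]], nm[x$edges[e, 2]],
                  x$A[x$edges[e, 2], x$edges[e, 1]]))
    }
  }
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, ...) {
  if (nrow(object$edges) == 0) return(numeric(0))
  nm <- if (!is.null(colnames(object$A))) colnames(object$A) else object$names
  setNames(object$A[cbind(object$edges[, 2], object$edges[, 1])],
           sprintf("%s->%s", nm[object$edges[, 1]], nm[object$edges[, 2]]))
}

all_directed_edges <- function(p) {
  g <- expand.grid(from = seq_len(p), to = seq_len(p))
  as.matrix(g[g$from != g$to, ])
}

# Score one structure on (S, n): chi2 - 2 df via the closed-form fit.
score_structure <- function(S, n, edges, p) {
  reg <- sem_regression_fit(S, edges, p)
  f <- fml(S, implied_covariance(reg$A, reg$psi))
  df <- p * (p + 1) / 2 - (nrow(edges) + p)
  (n - 1) * f - 2 * df
}

#' AIC-guided search for the optimal path structure
#'
#' `tree` growth starts from the edgeless model and repeatedly adds the
#' single admissible edge (keeping the structure acyclic and identified)
#' that most improves the AIC, stopping when no addition improves it.
#' `forest` growth exhaustively enumerates acyclic edge sets up to
#' `max_edges` and ranks them by AIC (feasible only for small networks; the
#' enumeration is guarded). The AIC convention is the model AIC
#' `chi2 - 2 df`; any fixed monotone variant ranks models identically for
#' fixed `S` and `n`.
#'
#' @param S pooled sample covariance/correlation matrix.
#' @param n pooled sample size.
#' @param method `"tree"` or `"forest"`.
#' @param max_edges maximum number of edges considered.
#' @param max_models guard on the number of structures the forest may
#'   enumerate.
#' @return list with `best` (a `sem_fit` of the AIC-optimal structure),
#'   `best_edges`, and `ranking` (data.frame of structures and AICs,
#'   forest mode only).
#' @export
model_search <- function(S, n, method = c("tree", "forest"),
                         max_edges = NULL, max_models = 2e5) {
  method <- match.arg(method)
  S <- as.matrix(S)
  p <- nrow(S)
  cand <- all_directed_edges(p)
  if (is.null(max_edges)) max_edges <- p * (p + 1) / 2 - p
  max_edges <- min(max_edges, p * (p + 1) / 2 - p)
  if (method == "tree") {
    edges <- matrix(integer(0), 0, 2)
    best_aic <- score_structure(S, n, edges, p)
    repeat {
      if (nrow(edges) >= max_edges) break
      gain <- NULL
      for (i in seq_len(nrow(cand))) {
        e <- cand[i, ]
        if (any(edges[, 1] == e[1] & edges[, 2] == e[2])) next
        trial <- rbind(edges, e)
        if (!is_acyclic(edges_to_A(trial, p))) next
        aic <- score_structure(S, n, trial, p)
        if (is.finite(aic) && aic < best_aic - 1e-9 &&
            (is.null(gain) || aic < gain$aic)) {
          gain <- list(edge = e, aic = aic)
        }
      }
      if (is.null(gain)) break
      edges <- rbind(edges, gain$edge)
      best_aic <- gain$aic
    }
    # backward pruning: growth can commit early to an edge that a later
    # addition makes redundant; dropping such edges only improves the AIC
    prune <- function(edges, aic) {
      repeat {
        if (nrow(edges) == 0) break
        gain <- NULL
        for (i in seq_len(nrow(edges))) {
          a <- score_structure(S, n, edges[-i, , drop = FALSE], p)
          if (is.finite(a) && a < aic - 1e-9 &&
              (is.null(gain) || a < gain$aic)) {
            gain <- list(i = i, aic = a)
          }
        }
        if (is.null(gain)) break
        edges <- edges[-gain$i, , drop = FALSE]
        aic <- gain$aic
      }
      list(edges = edges, aic = aic)
    }
    pr <- prune(edges, best_aic)
    edges <- pr$edges; best_aic <- pr$aic
    # orientation polish: a collider in the generating model can leave the
    # growth path stuck in the wrong equivalence class; try reversing each
    # edge (AIC tie allowed) and re-pruning, keeping strict improvements
    repeat {
      improved <- FALSE
      for (i in seq_len(nrow(edges))) {
        cand <- edges
        cand[i, ] <- rev(cand[i, ])
        if (any(duplicated(rbind(cand)))) next
        if (!is_acyclic(edges_to_A(cand, p))) next
        aic_c <- score_structure(S, n, cand, p)
        if (!is.finite(aic_c) || aic_c > best_aic + 1e-9) next
        pr <- prune(cand, aic_c)
        if (pr$aic < best_aic - 1e-9) {
          edges <- pr$edges; best_aic <- pr$aic; improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    rownames(edges) <- NULL
    return(list(best = fit_path_model(S, n, edges), best_edges = edges,
                ranking = NULL))
  }
  # forest: exhaustive enumeration of acyclic edge subsets
  n_cand <- nrow(cand)
  n_models <- sum(choose(n_cand, 0:max_edges))
  if (n_models > max_models) {
    stop(sprintf(paste0("forest enumeration of %g structures exceeds the ",
                        "guard (%g); use method = \"tree\" or lower ",
                        "`max_edges`"), n_models, max_models), call. = FALSE)
  }
  rows <- list()
  for (k in 0:max_edges) {
    sets <- if (k == 0) list(integer(0)) else
      asplit(combn(n_cand, k), 2)
    for (sel in sets) {
      edges <- cand[sel, , drop = FALSE]
      if (!is_acyclic(edges_to_A(edges, p))) next
      aic <- score_structure(S, n, edges, p)
      rows[[length(rows) + 1L]] <- list(edges = edges, aic = aic)
    }
  }
  aics <- vapply(rows, `[[`, 0, "aic")
  ord <- order(aics)
  ranking <- data.frame(
    rank = seq_along(ord),
    n_edges = vapply(rows[ord], function(r) nrow(r$edges), 0L),
    aic = aics[ord],
    edges = vapply(rows[ord], function(r) {
      if (nrow(r$edges) == 0) "" else
        paste(sprintf("%d->%d", r$edges[, 1], r$edges[, 2]), collapse = ",")
    }, ""))
  best_edges <- rows[[ord[1]]]$edges
  rownames(best_edges) <- NULL
  list(best = fit_path_model(S, n, best_edges), best_edges = best_edges,
       ranking = ranking)
}

#' Parameterize a fixed structure per participant and condition
#'
#' Computes the correlation (or covariance) matrix of the region item
#' series within each participant x condition cell and fits the given
#' structure to it. Cells with too few trials or non-converging fits are
#' flagged and excluded from the parameter table (logged in `excluded`).
#'
#' @param series_list output of [simulate_item_series()]`$participants`, or
#'   any list of elements with `participant`, `task`, `series` (regions x
#'   trials), `condition`, and optionally `correct`.
#' @param edges structure to parameterize (from, to).
#' @param min_trials minimum correct trials per condition cell.
#' @param input `"correlation"` (default, the functional-connectivity
#'   scale) or `"covariance"`.
#' @return list with `parameters` (long data.frame: participant, task,
#'   condition, edge label, coefficient, plus `gcor` per cell) and
#'   `excluded` (flagged cells).
#' @export
fit_per_condition <- function(series_list, edges, min_trials = 10,
                              input = c("correlation", "covariance")) {
  input <- match.arg(input)
  rows <- list(); excluded <- list()
  for (pp in series_list) {
    ok_trial <- if (is.null(pp$correct)) rep(TRUE, length(pp$condition)) else
      as.logical(pp$correct)
    for (cond in unique(pp$condition)) {
      cols <- pp$condition == cond & ok_trial
      flag <- function(why) {
        excluded[[length(excluded) + 1L]] <<- data.frame(
          participant = pp$participant, condition = cond, reason = why)
      }
      if (sum(cols) < min_trials) { flag("too_few_trials"); next }
      x <- t(pp$series[, cols, drop = FALSE])
      S <- if (input == "correlation") cor(x) else cov(x)
      fit <- tryCatch(fit_path_model(S, sum(cols), edges),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { flag("non_convergence"); next }
      cf <- coef(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pp$participant,
        task = if (is.null(pp$task)) NA_character_ else pp$task,
        condition = cond, edge = names(cf), coefficient = unname(cf),
        gcor = compute_gcor(pp$series[, cols, drop = FALSE]))
    }
  }
  list(parameters = do.call(rbind, rows),
       excluded = if (length(excluded)) do.call(rbind, excluded) else NULL)
}
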