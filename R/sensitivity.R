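## Sensitivity analysis of the post-transient vessel-radius dynamics:
## amplitude metrics, one-at-a-time sweeps, Latin hypercube sampling with
## partial rank correlation coefficients, and local (tornado) elasticities.

#' Post-transient radius metrics
#'
#' Discards the settling interval [0, T0), computes the time-weighted
#' (trapezoidal) mean Rbar over [T0, t_end] and the oscillation amplitude
#' A = max |R(t) - Rbar| over the same window.
#'
#' @param t times (s), strictly increasing; @param R radii (um).
#' @param T0 transient cut (s, default 5); @param t_end window end
#'   (default 60).
#' @return list(Rbar, A).
#' @export
post_transient_metrics <- function(t, R, T0 = 5, t_end = 60) {
  keep <- t >= T0 & t <= t_end
  if (sum(keep) < 2) stop("post-transient window is empty")
  tt <- t[keep]; rr <- R[keep]
  w <- diff(tt)
  Rbar <- sum(w * (head(rr, -1) + rr[-1]) / 2) / (tt[length(tt)] - tt[1])
  list(Rbar = Rbar, A = max(abs(rr - Rbar)))
}

#' Relative amplitude change
#'
#' Delta A = 100 (A/A0 - 1) percent.
#' @param A amplitude; @param A0 baseline amplitude (> 0).
#' @export
delta_A <- function(A, A0) {
  stopifnot(A0 > 0)
  100 * (A / A0 - 1)
}

## default model runner: wall mechanics under the frozen periodic drive;
## x is a named vector with any of dp, E_act, E_pas.
default_model_runner <- function(T0 = 5, t_end = 60) {
  nvc <- nvc_params(TRUE)
  function(x) {
    tr <- run_wall_model(
      dp = if ("dp" %in% names(x)) x[["dp"]] else nvc[["dp_wall"]],
      E_act = if ("E_act" %in% names(x)) x[["E_act"]] else nvc[["E_act"]],
      E_pas = if ("E_pas" %in% names(x)) x[["E_pas"]] else nvc[["E_pas"]],
      t_end_s = t_end)
    tr
  }
}

#' One-at-a-time sensitivity sweep
#'
#' Scales one parameter at a time by \code{n_factors} equally spaced
#' factors over [0.7, 1.3] (the others at baseline), recomputes the
#' post-transient amplitude with identical solver settings, and reports
#' Delta A per (parameter, factor).
#'
#' @param runner function(named parameter vector) -> data.frame with
#'   \code{t_s}, \code{R_um}; default the frozen-drive wall model.
#' @param baseline named vector of baseline parameter values.
#' @param n_factors number of factors (default 10).
#' @param T0,t_end metrics window (s).
#' @return data.frame (param, factor, value, A, deltaA_pct).
#' @export
oat_sweep <- function(runner = default_model_runner(),
                      baseline = sensitivity_baseline(),
                      n_factors = 10, T0 = 5, t_end = 60) {
  tr0 <- runner(baseline)
  A0 <- post_transient_metrics(tr0$t_s, tr0$R_um, T0, t_end)$A
  factors <- seq(0.7, 1.3, length.out = n_factors)
  out <- list()
  for (pn in names(baseline)) {
    for (f in factors) {
      x <- baseline
      x[[pn]] <- baseline[[pn]] * f
      A <- tryCatch({
        tr <- runner(x)
        post_transient_metrics(tr$t_s, tr$R_um, T0, t_end)$A
      }, error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(
        param = pn, factor = f, value = baseline[[pn]] * f, A = A,
        deltaA_pct = if (is.na(A)) NA_real_ else delta_A(A, A0))
    }
  }
  res <- do.call(rbind, out)
  attr(res, "A0") <- A0
  res
}

#' Baseline wall-mechanics parameters for the sensitivity study
#' @return named vector (dp, E_act, E_pas) from the registry.
#' @export
sensitivity_baseline <- function() {
  nvc <- nvc_params(TRUE)
  c(dp = nvc[["dp_wall"]], E_act = nvc[["E_act"]], E_pas = nvc[["E_pas"]])
}

#' Latin hypercube sample
#'
#' Each column is stratified: exactly one draw falls in each of the n
#' equiprobable bins, with independent random permutations per column and
#' uniform placement within bins. Ranges default to +-30 percent around
#' the baseline.
#'
#' @param n number of samples (>= number of parameters).
#' @param ranges 2 x k matrix (rows: lower, upper) or NULL for +-30
#'   percent around \code{baseline}.
#' @param baseline named baseline vector (used when ranges is NULL).
#' @param seed optional RNG seed.
#' @return n x k matrix with named columns.
#' @export
lhs_sample <- function(n = 200, ranges = NULL,
                       baseline = sensitivity_baseline(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ranges)) {
    ranges <- rbind(lower = baseline * 0.7, upper = baseline * 1.3)
  }
  k <- ncol(ranges)
  if (n < k) stop("need at least as many samples as parameters")
  U <- vapply(seq_len(k), function(j) {
    (sample.int(n) - stats::runif(n)) / n
  }, numeric(n))
  X <- sweep(U, 2, ranges[2, ] - ranges[1, ], "*")
  X <- sweep(X, 2, ranges[1, ], "+")
  colnames(X) <- colnames(ranges)
  X
}

#' Partial rank correlation coefficients
#'
#' Ranks all columns (average ranks on ties), then computes for each
#' parameter the correlation between the residuals of its ranks and of the
#' response ranks after regressing both on the remaining parameters'
#' ranks.
#'
#' @param X design matrix (samples x parameters).
#' @param y response vector.
#' @return named vector of PRCCs.
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant design column")
  Rx <- apply(X, 2, rank)
  ry <- rank(y)
  k <- ncol(X)
  out <- numeric(k)
  for (j in seq_len(k)) {
    others <- Rx[, -j, drop = FALSE]
    if (ncol(others) == 0) {
      rx_res <- Rx[, j] - mean(Rx[, j])
      ry_res <- ry - mean(ry)
    } else {
      rx_res <- stats::lsfit(others, Rx[, j])$residuals
      ry_res <- stats::lsfit(others, ry)$residuals
    }
    out[j] <- stats::cor(rx_res, ry_res)
  }
  names(out) <- colnames(X)
  out
}

#' Global LHS/PRCC study of the wall response
#'
#' Draws an LHS design over +-30 percent hyperrectangles, evaluates the
#' post-transient amplitude for every sample, and summarises main effects
#' with PRCCs.
#'
#' @inheritParams oat_sweep
#' @param n number of LHS samples (default 200).
#' @param seed RNG seed for the design.
#' @return list(design, deltaA_pct, prcc, A0).
#' @export
lhs_prcc_study <- function(runner = default_model_runner(),
                           baseline = sensitivity_baseline(), n = 200,
                           seed = 1, T0 = 5, t_end = 60) {
  tr0 <- runner(baseline)
  A0 <- post_transient_metrics(tr0$t_s, tr0$R_um, T0, t_end)$A
  X <- lhs_sample(n, baseline = baseline, seed = seed)
  dA <- apply(X, 1, function(row) {
    tr <- runner(stats::setNames(row, colnames(X)))
    delta_A(post_transient_metrics(tr$t_s, tr$R_um, T0, t_end)$A, A0)
  })
  list(design = X, deltaA_pct = dA, prcc = prcc(X, dA), A0 = A0)
}

#' Local elasticities (tornado)
#'
#' Symmetric +-10 percent central differences at baseline:
#' S = (p0/A0) (A(+) - A(-)) / (p0 (f+ - f-)).
#'
#' @inheritParams oat_sweep
#' @return named vector of elasticities S.
#' @export
local_elasticity <- function(runner = default_model_runner(),
                             baseline = sensitivity_baseline(),
                             T0 = 5, t_end = 60) {
  tr0 <- runner(baseline)
  A0 <- post_transient_metrics(tr0$t_s, tr0$R_um, T0, t_end)$A
  if (A0 == 0) stop("baseline amplitude is zero; elasticity undefined")
  f <- c(0.9, 1.1)
  S <- vapply(names(baseline), function(pn) {
    As <- vapply(f, function(ff) {
      x <- baseline; x[[pn]] <- baseline[[pn]] * ff
      tr <- runner(x)
      post_transient_metrics(tr$t_s, tr$R_um, T0, t_end)$A
    }, numeric(1))
    (baseline[[pn]] / A0) * (As[2] - As[1]) /
      (baseline[[pn]] * (f[2] - f[1]))
  }, numeric(1))
  S
}
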