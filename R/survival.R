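# Survival machinery: Kaplan-Meier, k-group log-rank, Cox partial likelihood
# with Efron tie handling, and the maximally selected log-rank cutpoint used
# to dichotomize scores.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i/n_i)`; subjects censored
#' at an event time are counted in the risk set for that time.
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicator.
#' @return An object of class `km_curve`: `times` (distinct event times,
#'   increasing), `survival`, `at_risk`, `events`.
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stop("empty input")
  if (any(time < 0) || !all(event %in% c(0, 1))) stop("invalid survival input")
  ev_times <- sort(unique(time[event == 1]))
  if (!length(ev_times)) {
    return(structure(list(times = numeric(0), survival = numeric(0),
                          at_risk = integer(0), events = integer(0)),
                     class = "km_curve"))
  }
  at_risk <- vapply(ev_times, function(t) sum(time >= t), integer(1))
  d <- vapply(ev_times, function(t) sum(time == t & event == 1), integer(1))
  surv <- cumprod(1 - d / at_risk)
  structure(list(times = ev_times, survival = surv,
                 at_risk = at_risk, events = d),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a [kaplan_meier()] curve.
#' @param t times at which to evaluate S(t).
#' @return Survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$times <= tt)
    if (i == 0L) 1 else km$survival[i]
  }, numeric(1))
}

# Per-event-time k-group tables: observed, expected and the hypergeometric
# covariance contribution. Shared by logrank_test and maxstat.
.logrank_oe <- function(time, event, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    nj <- vapply(levels(groups), function(g) sum(at_risk & groups == g), numeric(1))
    dj <- vapply(levels(groups), function(g) sum(time == t & event == 1 & groups == g), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(nj / n, nrow = k) - tcrossprod(nj / n))
    }
  }
  list(O = O, E = E, V = V, k = k, levels = levels(groups))
}

#' Log-rank test for k groups
#'
#' The standard observed-minus-expected statistic with hypergeometric
#' variance at each distinct event time, referred to chi-square with
#' (groups - 1) degrees of freedom.
#'
#' @param time,event survival data.
#' @param groups per-sample group labels (2 or more non-empty groups).
#' @return A list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, groups) {
  tab <- table(groups)
  if (length(tab) < 2L || any(tab == 0L)) stop("need >= 2 non-empty groups")
  oe <- .logrank_oe(time, event, groups)
  k <- oe$k
  u <- (oe$O - oe$E)[-k]
  Vsub <- oe$V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(as.numeric(crossprod(u, solve(Vsub, u))),
                   error = function(e) {
                     s <- svd(Vsub)
                     pos <- s$d > max(s$d) * 1e-10
                     as.numeric(crossprod(u, s$v[, pos, drop = FALSE] %*%
                       ((1 / s$d[pos]) * crossprod(s$u[, pos, drop = FALSE], u))))
                   })
  if (!is.finite(chi2)) chi2 <- 0
  df <- k - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Standardized two-group log-rank statistic z = (O1 - E1)/sqrt(V11); NA when
# the variance vanishes (all events on one side of every risk set).
.logrank_z <- function(time, event, in_group1) {
  oe <- .logrank_oe(time, event, ifelse(in_group1, "g1", "g2"))
  v <- oe$V[1L, 1L]
  if (v <= 0) return(NA_real_)
  as.numeric(oe$O[1L] - oe$E[1L]) / sqrt(v)
}

#' Cox proportional-hazards fit (Efron ties)
#'
#' Newton-Raphson maximization of the Efron-tie partial log-likelihood;
#' convergence when the log-likelihood change falls below 1e-9 or after 50
#' iterations. Wald standard errors come from the observed information.
#' Factor covariates are one-hot coded against their first level. Monotone
#' likelihood (perfect separation) is detected by a coefficient escaping
#' beyond 20 in absolute value; the coefficient is capped there and flagged
#' `converged = FALSE`.
#'
#' @param time,event survival data (>= 1 event required).
#' @param covariates numeric matrix or data.frame of covariates (constant
#'   columns are an error).
#' @return A `data.frame` (class `cox_result`) with one row per coefficient:
#'   `covariate`, `beta`, `hr`, `ci_low`, `ci_high`, `p`, `converged`, `n`,
#'   `n_events`; log-likelihood attached as attribute `"loglik"`.
#' @export
cox_fit <- function(time, event, covariates) {
  if (sum(event) < 1L) stop("at least one event required")
  X <- .cox_design(covariates)
  if (nrow(X) != length(time)) stop("covariate rows must match samples")
  if (any(!is.finite(X))) stop("covariates must be finite")
  const <- apply(X, 2L, function(x) stats::var(x) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "))

  p <- ncol(X)
  beta <- rep(0, p)
  ll_old <- .cox_loglik(beta, time, event, X)$ll
  converged <- FALSE
  for (iter in seq_len(50L)) {
    der <- .cox_loglik(beta, time, event, X)
    step <- tryCatch(solve(der$info, der$grad), error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + step
    ll_new <- .cox_loglik(beta_new, time, event, X)$ll
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll_old) && halvings < 20L) {
      step <- step / 2
      beta_new <- beta + step
      ll_new <- .cox_loglik(beta_new, time, event, X)$ll
      halvings <- halvings + 1L
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < 1e-9) { converged <- TRUE; ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  capped <- abs(beta) > 20
  if (any(capped)) {
    beta[capped] <- sign(beta[capped]) * 20
    converged <- FALSE
    warning("monotone likelihood suspected; coefficient(s) capped at |20|: ",
            paste(colnames(X)[capped], collapse = ", "))
  }
  info <- .cox_loglik(beta, time, event, X)$info
  se <- sqrt(diag(tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p))))
  z <- beta / se
  zq <- stats::qnorm(0.975)
  out <- data.frame(covariate = colnames(X), beta = beta, hr = exp(beta),
                    ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
                    se = se, p = 2 * stats::pnorm(-abs(z)),
                    converged = converged, n = length(time),
                    n_events = sum(event), row.names = NULL)
  class(out) <- c("cox_result", "data.frame")
  attr(out, "loglik") <- ll_old
  out
}

.cox_design <- function(covariates) {
  if (is.matrix(covariates)) {
    X <- covariates
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    storage.mode(X) <- "double"
    return(X)
  }
  if (is.numeric(covariates)) {
    return(matrix(covariates, ncol = 1L, dimnames = list(NULL, "x")))
  }
  df <- as.data.frame(covariates)
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1L); colnames(m) <- nm; m
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) stop("constant covariate(s): ", nm)
      m <- vapply(levels(f)[-1L], function(l) as.numeric(f == l),
                  numeric(length(f)))
      colnames(m) <- paste0(nm, levels(f)[-1L]); m
    }
  })
  do.call(cbind, cols)
}

# Efron partial log-likelihood with gradient and observed information.
.cox_loglik <- function(beta, time, event, X) {
  eta <- as.numeric(X %*% beta)
  eta <- pmin(pmax(eta, -500), 500)
  w <- exp(eta)
  p <- ncol(X)
  ll <- 0; grad <- rep(0, p); info <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    dead <- time == t & event == 1
    d <- sum(dead)
    S0R <- sum(w[risk])
    S1R <- colSums(X[risk, , drop = FALSE] * w[risk])
    XR <- X[risk, , drop = FALSE]
    S2R <- crossprod(XR * sqrt(w[risk]))
    S0D <- sum(w[dead])
    S1D <- colSums(X[dead, , drop = FALSE] * w[dead])
    XD <- X[dead, , drop = FALSE]
    S2D <- crossprod(XD * sqrt(w[dead]))
    ll <- ll + sum(eta[dead])
    grad <- grad + colSums(X[dead, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      phi0 <- S0R - f * S0D
      phi1 <- S1R - f * S1D
      phi2 <- S2R - f * S2D
      ll <- ll - log(phi0)
      grad <- grad - phi1 / phi0
      info <- info + phi2 / phi0 - tcrossprod(phi1) / phi0^2
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Univariate Cox screen over many covariates
#'
#' Fits a separate one-covariate Cox model per column and flags those with
#' Wald p below the threshold.
#'
#' @param time,event survival data.
#' @param X numeric matrix, one column per candidate covariate (e.g. genes in
#'   columns).
#' @param p_threshold Wald p cutoff for `keep` (default 0.05).
#' @return A `data.frame` with one row per covariate: the [cox_fit()] fields
#'   plus `keep`.
#' @export
cox_screen <- function(time, event, X, p_threshold = 0.05) {
  stopifnot(is.matrix(X))
  rows <- lapply(seq_len(ncol(X)), function(j) {
    r <- tryCatch(
      cox_fit(time, event, X[, j, drop = FALSE]),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    r$covariate <- colnames(X)[j]
    r
  })
  out <- do.call(rbind, rows)
  out$keep <- !is.na(out$p) & out$p < p_threshold & out$converged
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic at every distinct
#' score value inside the quantile window (groups: score above vs at-or-below
#' the candidate) and returns the candidate maximizing its absolute value;
#' ties are broken toward the score median. The statistic's selection-induced
#' inflation is deliberately not corrected: the cutpoint only defines groups.
#'
#' @param score per-sample numeric score.
#' @param time,event survival data, aligned with `score`.
#' @param quantile_window quantile bounds delimiting candidate cutpoints
#'   (default `c(0.1, 0.9)`).
#' @return An object of class `cutpoint_result`: `cutpoint`, `max_statistic`
#'   (absolute standardized statistic), `statistic` (signed),
#'   `candidates_evaluated`, `quantile_window`.
#' @export
maxstat_cutpoint <- function(score, time, event, quantile_window = c(0.1, 0.9)) {
  n <- length(score)
  if (n < 10L) stop("need >= 10 samples")
  if (length(time) != n || length(event) != n) stop("inputs must align")
  qs <- stats::quantile(score, quantile_window, names = FALSE)
  cand <- sort(unique(score[score >= qs[1] & score <= qs[2]]))
  cand <- cand[cand < max(score)]  # cutting at the maximum empties one group
  if (!length(cand)) stop("no candidate cutpoints inside the quantile window")
  z <- vapply(cand, function(cc) .logrank_z(time, event, score > cc), numeric(1))
  ok <- is.finite(z)
  if (!any(ok))
    stop("no valid candidate: log-rank variance vanishes at every cutpoint")
  cand <- cand[ok]; z <- z[ok]
  best <- abs(z) >= max(abs(z)) - 1e-12
  med <- stats::median(score)
  pick <- which(best)[which.min(abs(cand[best] - med))]
  structure(list(cutpoint = cand[pick], max_statistic = abs(z[pick]),
                 statistic = z[pick], candidates_evaluated = length(cand),
                 quantile_window = quantile_window),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("cutpoint %.4g (|z| = %.3f over %d candidates, window %.0f%%-%.0f%%)\n",
              x$cutpoint, x$max_statistic, x$candidates_evaluated,
              100 * x$quantile_window[1], 100 * x$quantile_window[2]))
  invisible(x)
}
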