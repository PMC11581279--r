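#' Dummy-encode a cohort for proportional-hazards regression
#'
#' Expands the selected categorical variables into indicator columns, one per
#' non-reference level, in codebook order (the reference level of each
#' variable maps to an all-zero block). For the default 13-variable codebook
#' this yields 25 columns.
#'
#' @param x A [cohort()].
#' @param variables Codebook variables to encode (default: all).
#' @return An object of class `"cox_design"`: list with the indicator matrix
#'   `X` (one row per record), integer `time`, binary `event`, and a
#'   `columns` data frame describing each column's variable and level.
#' @export
dummy_encode <- function(x, variables = names(x$codebook)) {
  stopifnot(inherits(x, "cohort"))
  if (!all(variables %in% names(x$codebook)))
    stop("unknown variable(s): ",
         paste(setdiff(variables, names(x$codebook)), collapse = ", "))
  variables <- names(x$codebook)[sort(match(variables, names(x$codebook)))]
  n <- nrow(x$data)
  blocks <- list(); info <- list()
  for (v in variables) {
    lev <- x$codebook[[v]]$levels
    ref <- x$codebook[[v]]$ref
    nonref <- setdiff(seq_along(lev), ref)
    b <- matrix(0, n, length(nonref))
    for (j in seq_along(nonref)) b[, j] <- as.numeric(x$data[[v]] == nonref[j])
    colnames(b) <- paste0(v, "=", lev[nonref])
    blocks[[v]] <- b
    info[[v]] <- data.frame(variable = v, level = lev[nonref],
                            name = colnames(b))
  }
  X <- do.call(cbind, blocks)
  structure(list(X = X, time = x$data$follow_up_months, event = x$data$event,
                 columns = do.call(rbind, c(info, list(make.row.names = FALSE)))),
            class = "cox_design")
}

# Negative log partial likelihood with gradient and Hessian in one pass.
# Efron's correction subtracts the fraction l/d of the tied-death sums from
# the risk-set sums for the l-th of d tied events; Breslow uses fraction 0.
pl_derivs <- function(beta, X, time, event, ties = "efron",
                      want_derivs = TRUE) {
  n <- length(time); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  Xo <- X[ord, , drop = FALSE]; to <- time[ord]; wo <- w[ord]
  cum0 <- cumsum(wo)
  cum1 <- wo * Xo
  for (j in seq_len(p)) cum1[, j] <- cumsum(cum1[, j])
  if (want_derivs) {
    cum2 <- wo * Xo[, rep(seq_len(p), times = p), drop = FALSE] *
      Xo[, rep(seq_len(p), each = p), drop = FALSE]
    for (j in seq_len(p * p)) cum2[, j] <- cumsum(cum2[, j])
  }
  ev_times <- sort(unique(time[event == 1L]))
  nll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
  for (t in ev_times) {
    dead <- which(time == t & event == 1L)
    d <- length(dead)
    r <- sum(to >= t)                    # risk-set size in descending order
    s0 <- cum0[r]
    s1 <- cum1[r, ]
    s0d <- sum(w[dead])
    s1d <- colSums(X[dead, , drop = FALSE] * w[dead])
    nll <- nll - sum(eta[dead])
    grad <- grad - colSums(X[dead, , drop = FALSE])
    if (want_derivs) {
      s2 <- matrix(cum2[r, ], p, p)
      s2d <- crossprod(X[dead, , drop = FALSE] * w[dead],
                       X[dead, , drop = FALSE])
    }
    frac <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    for (l in seq_len(d)) {
      e0 <- s0 - frac[l] * s0d
      e1 <- s1 - frac[l] * s1d
      nll <- nll + log(e0)
      grad <- grad + e1 / e0
      if (want_derivs) {
        e2 <- s2 - frac[l] * s2d
        hess <- hess + e2 / e0 - tcrossprod(e1 / e0)
      }
    }
  }
  list(nll = nll, grad = grad, hess = hess)
}

#' Negative log partial likelihood
#'
#' Evaluates the negative log Cox partial likelihood at a coefficient vector,
#' with Efron or Breslow handling of tied event times. At `beta = 0` with all
#' event times distinct this is the sum of the logs of the risk-set sizes;
#' with no events it is zero.
#'
#' @param beta Coefficient vector (length = number of design columns).
#' @param design A [dummy_encode()] design.
#' @param ties `"efron"` or `"breslow"`.
#' @return Scalar negative log partial likelihood.
#' @export
negative_log_partial_likelihood <- function(beta, design, ties = "efron") {
  stopifnot(inherits(design, "cox_design"))
  ties <- match.arg(ties, c("efron", "breslow"))
  if (length(beta) != ncol(design$X))
    stop("beta has length ", length(beta), ", design has ",
         ncol(design$X), " columns")
  pl_derivs(beta, design$X, design$time, design$event, ties,
            want_derivs = FALSE)$nll
}

#' Gradient of the negative log partial likelihood
#'
#' @inheritParams negative_log_partial_likelihood
#' @return Numeric score vector (gradient of the negative log likelihood).
#' @export
partial_likelihood_gradient <- function(beta, design, ties = "efron") {
  stopifnot(inherits(design, "cox_design"))
  ties <- match.arg(ties, c("efron", "breslow"))
  pl_derivs(beta, design$X, design$time, design$event, ties)$grad
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood `h(t, X) = h0(t) exp(beta' X)` by
#' Newton-Raphson with step-halving (the objective never decreases across
#' iterations), on the dummy-coded design of the selected variables.
#' Convergence is declared when the maximum absolute score component falls
#' below `tol`. Columns constant in the data are dropped with a warning; the
#' covariance is the inverse observed information at the optimum.
#'
#' @param x A [cohort()] with at least one event.
#' @param variables Codebook variables to include (default: all).
#' @param ties Tie correction: `"efron"` (default) or `"breslow"`. The two
#'   coincide when all event times are distinct.
#' @param tol Convergence threshold on the score (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50), with up to 10
#'   step-halvings per iteration.
#' @return An object of class `"cox_ph"` with components `coefficients`,
#'   `se`, `vcov`, `loglik` (fitted), `loglik_null`, `iter`, `converged`,
#'   `ties`, `design`, `dropped` and the codebook.
#' @seealso [summary.cox_ph()], [predict.cox_ph()], [breslow_baseline()]
#' @export
cox_ph <- function(x, variables = names(x$codebook),
                   ties = c("efron", "breslow"), tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(x, "cohort"))
  ties <- match.arg(ties)
  design <- dummy_encode(x, variables)
  if (sum(design$event) < 1L) stop("need at least one event to fit")
  keep <- apply(design$X, 2, function(col) stats::var(col) > 0)
  dropped <- colnames(design$X)[!keep]
  if (length(dropped))
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
  X <- design$X[, keep, drop = FALSE]
  p <- ncol(X)
  if (p == 0L) stop("no non-constant covariate columns to fit")
  beta <- numeric(p)
  cur <- pl_derivs(beta, X, design$time, design$event, ties)
  ll0 <- -cur$nll
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$hess, -cur$grad), error = function(e)
      stop("singular information matrix (possible monotone likelihood/",
           "separation); cannot take Newton step"))
    halved <- 0L; accepted <- FALSE
    repeat {
      cand <- beta + step
      new <- pl_derivs(cand, X, design$time, design$event, ties)
      if (is.finite(new$nll) &&
          new$nll <= cur$nll + 1e-10 * (abs(cur$nll) + 1)) {
        accepted <- TRUE
        break
      }
      halved <- halved + 1L
      if (halved > 10L) break
      step <- step / 2
    }
    if (!accepted) {
      # objective cannot be improved beyond floating precision; converged if
      # the score is numerically negligible at this likelihood scale
      converged <- max(abs(cur$grad)) < 1e-5 * (abs(cur$nll) + 1)
      break
    }
    beta <- cand; cur <- new
  }
  if (!converged && max(abs(cur$grad)) < tol) converged <- TRUE
  if (!converged)
    warning("Newton-Raphson did not converge in ", max_iter,
            " iterations (max score ", signif(max(abs(cur$grad)), 3), ")")
  vc <- solve(cur$hess)
  cf <- stats::setNames(rep(NA_real_, ncol(design$X)), colnames(design$X))
  cf[keep] <- beta
  se <- stats::setNames(rep(NA_real_, ncol(design$X)), colnames(design$X))
  se[keep] <- sqrt(diag(vc))
  structure(list(coefficients = cf, se = se, vcov = vc,
                 loglik = -cur$nll, loglik_null = ll0,
                 iter = iter, converged = converged, ties = ties,
                 design = design, kept = keep, dropped = dropped,
                 codebook = x$codebook, variables = unique(design$columns$variable),
                 horizon = x$horizon),
            class = "cox_ph")
}

#' @export
coef.cox_ph <- function(object, ...) object$coefficients

#' @export
vcov.cox_ph <- function(object, ...) object$vcov

#' @export
logLik.cox_ph <- function(object, ...) {
  structure(object$loglik, df = sum(object$kept), class = "logLik")
}

#' Hazard ratios of a fitted Cox model
#'
#' @param fit A fitted [cox_ph()] model.
#' @return Named vector `exp(coef)`, one per dummy column.
#' @export
hazard_ratios <- function(fit) {
  stopifnot(inherits(fit, "cox_ph"))
  exp(stats::coef(fit))
}

#' Wald statistics of a fitted Cox model
#'
#' @param fit A fitted [cox_ph()] model.
#' @return Data frame with `z = coef / se` and the two-sided normal `p`.
#' @export
wald_statistics <- function(fit) {
  stopifnot(inherits(fit, "cox_ph"))
  if (any(fit$se[fit$kept] == 0)) stop("zero standard error")
  z <- fit$coefficients / fit$se
  data.frame(name = names(fit$coefficients), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))))
}

#' @export
print.cox_ph <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): %d records, %d events\n",
              x$ties, length(x$design$time), sum(x$design$event)))
  cat(sprintf("  log-likelihood %.3f (null %.3f), %d iterations%s\n",
              x$loglik, x$loglik_null, x$iter,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(stats::coef(x), 4))
  invisible(x)
}

#' Coefficient table of a fitted Cox model
#'
#' The familiar per-level regression table: one row per level of each fitted
#' variable, reference rows carrying coefficient 0 and hazard ratio 1, other
#' rows `coef`, `exp(coef)`, `se(coef)`, `z` and the two-sided `p`.
#'
#' @param object A fitted [cox_ph()] model.
#' @param ... Unused.
#' @return Data frame of class `"summary.cox_ph"`.
#' @export
summary.cox_ph <- function(object, ...) {
  wz <- wald_statistics(object)
  rows <- list()
  for (v in object$variables) {
    lev <- object$codebook[[v]]$levels
    ref <- object$codebook[[v]]$ref
    for (j in seq_along(lev)) {
      if (j == ref) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev[j], coef = 0, `exp.coef` = 1,
          `se.coef` = NA_real_, z = NA_real_, p = NA_real_)
      } else {
        nm <- paste0(v, "=", lev[j])
        cf <- object$coefficients[nm]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev[j], coef = unname(cf),
          `exp.coef` = unname(exp(cf)), `se.coef` = unname(object$se[nm]),
          z = wz$z[wz$name == nm], p = wz$p[wz$name == nm])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.cox_ph", "data.frame")
  out
}

#' @export
print.summary.cox_ph <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$coef <- round(y$coef, 3); y$exp.coef <- round(y$exp.coef, 3)
  y$se.coef <- round(y$se.coef, 4); y$z <- round(y$z, 3)
  y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Univariate Cox likelihood-ratio screen
#'
#' Fits a Cox model on the single variable `v` and reports the
#' likelihood-ratio statistic `LR = 2 (loglik_fitted - loglik_null)` with
#' `df = observed levels - 1` and the chi-square p-value — the standard
#' one-variable-at-a-time screen used before a multivariate fit.
#'
#' @param x A [cohort()].
#' @param v A codebook variable with at least two observed levels.
#' @param ties Tie correction, as in [cox_ph()].
#' @return Data frame with `variable`, `LR`, `df`, `p`.
#' @export
univariate_lr_test <- function(x, v, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(unique(x$data[[v]])) < 2L)
    stop("variable '", v, "' has a single observed level")
  fit <- suppressWarnings(cox_ph(x, variables = v, ties = ties))
  df <- sum(fit$kept)
  lr <- 2 * (fit$loglik - fit$loglik_null)
  data.frame(variable = v, LR = lr, df = df,
             p = stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Breslow estimator of the baseline survival
#'
#' Cumulative baseline hazard increments `d_t / sum_{i in risk set} exp(eta_i)`
#' at each event time, cumulated and exponentiated into the baseline survival
#' `S0(t) = exp(-H0(t))` — the survival of a patient at the reference level of
#' every variable. At `beta = 0` this reduces to the Nelson-Aalen estimator.
#'
#' @param fit A fitted [cox_ph()] model.
#' @return Data frame of class `"baseline_survival"` with `time` (ordered
#'   event times), `hazard` (cumulative `H0`) and `survival` (`S0`).
#' @export
breslow_baseline <- function(fit) {
  stopifnot(inherits(fit, "cox_ph"))
  eta <- drop(fit$design$X[, fit$kept, drop = FALSE] %*%
                fit$coefficients[fit$kept])
  w <- exp(eta)
  time <- fit$design$time; event <- fit$design$event
  ev_times <- sort(unique(time[event == 1L]))
  inc <- vapply(ev_times, function(t)
    sum(event[time == t]) / sum(w[time >= t]), numeric(1))
  H0 <- cumsum(inc)
  out <- data.frame(time = ev_times, hazard = H0, survival = exp(-H0))
  class(out) <- c("baseline_survival", "data.frame")
  out
}

# Step-function evaluation of S0 at time t (1 before the first event time).
baseline_survival_at <- function(baseline, t) {
  vapply(t, function(ti) {
    i <- findInterval(ti, baseline$time)
    if (i == 0L) 1 else baseline$survival[i]
  }, numeric(1))
}

#' Predicted survival probability at a horizon
#'
#' `S(horizon | X) = S0(horizon) ^ exp(beta' X)` for each record of a cohort,
#' using the Breslow baseline of the fit. A horizon beyond the last observed
#' event time is flagged with a warning and the last baseline value carried
#' forward.
#'
#' @param fit A fitted [cox_ph()] model.
#' @param x A [cohort()] coded against the fit's codebook.
#' @param horizon Months at which survival is evaluated (default the fit's
#'   follow-up horizon, 60).
#' @param baseline Optionally a precomputed [breslow_baseline()].
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @export
predict_survival_probability <- function(fit, x, horizon = fit$horizon,
                                         baseline = breslow_baseline(fit)) {
  stopifnot(inherits(fit, "cox_ph"), inherits(x, "cohort"))
  if (horizon > max(fit$design$time))
    warning("horizon ", horizon, " beyond observed follow-up; ",
            "carrying the last baseline value forward")
  s0 <- baseline_survival_at(baseline, horizon)
  d <- dummy_encode(x, fit$variables)
  eta <- drop(d$X[, fit$kept, drop = FALSE] %*% fit$coefficients[fit$kept])
  s0^exp(eta)
}

#' Predictions from a fitted Cox model
#'
#' @param object A fitted [cox_ph()] model.
#' @param newdata A [cohort()] to predict for.
#' @param type `"lp"` for the linear predictor, `"risk"` for `exp(lp)`,
#'   `"survival"` for the `horizon`-month survival probability.
#' @param horizon Months for `type = "survival"` (default the fit's horizon).
#' @param ... Unused.
#' @return Numeric vector, one value per record.
#' @export
predict.cox_ph <- function(object, newdata, type = c("lp", "risk", "survival"),
                           horizon = object$horizon, ...) {
  type <- match.arg(type)
  if (type == "survival")
    return(predict_survival_probability(object, newdata, horizon))
  d <- dummy_encode(newdata, object$variables)
  eta <- drop(d$X[, object$kept, drop = FALSE] %*%
                object$coefficients[object$kept])
  if (type == "lp") eta else exp(eta)
}
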