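#' Empirical state distribution of a variable
#'
#' Relative frequency of each level of `v` in the cohort (the `P(V = j)`
#' column of the importance table).
#'
#' @param x A non-empty [cohort()].
#' @param v A codebook variable name.
#' @return Probability vector over the variable's levels (sums to 1).
#' @export
state_distribution <- function(x, v) {
  stopifnot(inherits(x, "cohort"))
  if (!v %in% names(x$codebook)) stop("unknown variable: ", v)
  if (!nrow(x$data)) stop("empty cohort")
  k <- length(x$codebook[[v]]$levels)
  cnt <- tabulate(x$data[[v]], nbins = k)
  stats::setNames(cnt / sum(cnt), x$codebook[[v]]$levels)
}

#' Empirical conditional five-year survival per level
#'
#' For each level `j` of `v`, the fraction of records at that level whose
#' five-year label is Alive (the `P(Alive | V = j)` column). Indeterminate
#' records are excluded; a level with no determinate records gets `NA`.
#'
#' @inheritParams state_distribution
#' @return Numeric vector of per-level Alive fractions (possibly `NA`).
#' @export
conditional_survival <- function(x, v) {
  stopifnot(inherits(x, "cohort"))
  if (!v %in% names(x$codebook)) stop("unknown variable: ", v)
  lab <- five_year_label(x)
  keep <- lab != "Indeterminate"
  k <- length(x$codebook[[v]]$levels)
  lev <- x$data[[v]][keep]
  alive <- lab[keep] == "Alive"
  out <- vapply(seq_len(k), function(j) {
    sel <- lev == j
    if (!any(sel)) NA_real_ else mean(alive[sel])
  }, numeric(1))
  stats::setNames(out, x$codebook[[v]]$levels)
}

#' Mean multi-state Fussell-Vesely importance of a variable
#'
#' A network-based importance measure adapted from reliability engineering.
#' With `q_j = P(Dead | V = j)` obtained by exact inference in the fitted TAN
#' (marginalizing the attribute tree), and `q* = min_j q_j` the most
#' favorable state's death probability, the per-state Fussell-Vesely ratio is
#'
#' `FV_j = (q_j - q*) / q_j`
#'
#' — the fraction of the death probability at state `j` attributable to the
#' variable not being in its most favorable state — and
#'
#' `MMFV(v) = (1/m) * sum_j FV_j`
#'
#' averaged equally over the variable's `m` states. The value lies in
#' `[0, 1)` and equals 0 exactly when the variable is independent of the
#' class under the model.
#'
#' @param model A fitted [tan_bayes()] model.
#' @param v An attribute of the model.
#' @return Non-negative scalar in `[0, 1)`.
#' @export
mmfv <- function(model, v) {
  stopifnot(inherits(model, "tan_bayes"))
  if (!v %in% model$attributes) stop("variable '", v, "' not in the model")
  marg <- tan_attr_marginals(model)[[v]]        # 2 x k: P(V=j | class)
  pa <- model$prior["Alive"] * marg[1L, ]
  pd <- model$prior["Dead"] * marg[2L, ]
  q <- pd / (pa + pd)                           # P(Dead | V = j)
  qstar <- min(q)
  fv <- ifelse(q > 0, (q - qstar) / q, 0)
  mean(fv)
}

#' Rank variables by importance
#'
#' Orders variables by descending importance value; ties are broken by the
#' input (codebook) order, so rank 1 is the most important variable.
#'
#' @param values Named numeric vector of non-negative importance values.
#' @return Data frame with columns `variable`, `mmfv` and `rank` (a
#'   permutation of `1..length(values)`), sorted by rank.
#' @export
rank_variables <- function(values) {
  if (!length(values)) stop("need at least one value")
  ord <- order(-values, seq_along(values))
  data.frame(variable = names(values)[ord],
             mmfv = unname(values[ord]),
             rank = seq_along(values))
}

#' Importance table for a fitted TAN model
#'
#' One row per model attribute and level: the empirical state distribution
#' `P(V = j)` and conditional survival `P(Alive | V = j)` computed on the
#' supplied cohort, together with the model-based [mmfv()] value and rank of
#' the variable (repeated across its levels).
#'
#' @param x The [cohort()] the empirical columns are computed on (typically
#'   the training set).
#' @param model A fitted [tan_bayes()] model.
#' @return Data frame of class `"importance_table"` with columns `variable`,
#'   `level`, `p_state`, `p_alive`, `mmfv`, `rank`.
#' @export
importance_table <- function(x, model) {
  stopifnot(inherits(x, "cohort"), inherits(model, "tan_bayes"))
  vals <- vapply(model$attributes, function(v) mmfv(model, v), numeric(1))
  rk <- rank_variables(vals)
  rows <- lapply(model$attributes, function(v) {
    ps <- state_distribution(x, v)
    pa <- conditional_survival(x, v)
    data.frame(variable = v, level = x$codebook[[v]]$levels,
               p_state = unname(ps), p_alive = unname(pa),
               mmfv = vals[[v]], rank = rk$rank[rk$variable == v])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Forward variable selection over the importance ranking
#'
#' Given variables ranked by importance, evaluates nested top-`k` attribute
#' sets by stratified `folds`-fold cross-validated classification accuracy of
#' the TAN on the training cohort's determinate records, and returns the
#' top-`k` set with the highest mean fold accuracy (ties go to the smaller
#' `k`). This is the guard against over- and under-fitting when deciding how
#' many ranked variables the network should carry.
#'
#' @param x Training [cohort()].
#' @param ranked Variables in descending importance order.
#' @param k_grid Candidate numbers of variables (subset of
#'   `1..length(ranked)`).
#' @param folds Number of stratified folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param alpha Smoothing constant passed to [tan_bayes()].
#' @return The selected variables (a prefix of `ranked`), with the per-`k`
#'   mean accuracies attached as attribute `"cv_accuracy"`.
#' @export
select_top_k <- function(x, ranked, k_grid = seq_along(ranked), folds = 5L,
                         seed = 1L, alpha = 1) {
  stopifnot(inherits(x, "cohort"))
  if (!all(k_grid >= 1L & k_grid <= length(ranked)))
    stop("k_grid must be a subset of 1..length(ranked)")
  if (folds < 2L) stop("need at least 2 folds")
  lab <- five_year_label(x)
  det <- which(lab != "Indeterminate")
  cls <- lab[det]
  fold <- integer(length(det))
  with_local_seed(seed, for (cl in c("Alive", "Dead")) {
    idx <- which(cls == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  })
  if (any(vapply(seq_len(folds), function(f)
    length(unique(cls[fold == f])) < 2L, logical(1))))
    stop("a fold contains a single class; use fewer folds or more data")
  k_grid <- sort(unique(as.integer(k_grid)))
  acc <- vapply(k_grid, function(k) {
    vars <- ranked[seq_len(k)]
    mean(vapply(seq_len(folds), function(f) {
      tr <- subset_cohort(x, det[fold != f])
      te <- subset_cohort(x, det[fold == f])
      m <- tan_bayes(tr, vars, alpha = alpha, root = vars[1L])
      pred <- predict(m, te, type = "class")
      mean(as.character(pred) == as.character(five_year_label(te)))
    }, numeric(1)))
  }, numeric(1))
  best <- k_grid[which.max(acc)]   # which.max takes the first (smallest k) on ties
  structure(ranked[seq_len(best)],
            cv_accuracy = stats::setNames(acc, k_grid))
}
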