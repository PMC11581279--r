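#' Coded patient cohort
#'
#' A cohort couples a [codebook()] with a data frame of patient records. Each
#' record holds one integer level index per codebook variable (1-based,
#' validated against the codebook), the follow-up time in whole months
#' (1 to 60: follow-up is administratively truncated at five years) and a
#' binary death indicator `event`.
#'
#' @param data A data frame with one integer column per codebook variable
#'   (named as in the codebook) plus `follow_up_months` and `event`.
#' @param cb The [codebook()] the records are coded against.
#' @param horizon Administrative follow-up horizon in months (default 60).
#' @return An object of class `"cohort"`: a list with elements `codebook`,
#'   `data` and `horizon`.
#' @export
cohort <- function(data, cb, horizon = 60L) {
  stopifnot(inherits(cb, "codebook"))
  data <- as.data.frame(data)
  need <- c(names(cb), "follow_up_months", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- data[need]
  if (nrow(data)) {
    for (v in names(cb)) {
      x <- data[[v]]
      bad <- which(is.na(x) | x < 1L | x > length(cb[[v]]$levels) | x != floor(x))
      if (length(bad))
        stop("row ", bad[1L], ": invalid level code ", x[bad[1L]],
             " for variable '", v, "'")
      data[[v]] <- as.integer(x)
    }
    fu <- data$follow_up_months
    bad <- which(is.na(fu) | fu < 1L | fu > horizon | fu != floor(fu))
    if (length(bad))
      stop("row ", bad[1L], ": follow_up_months must be an integer in [1, ",
           horizon, "], got ", fu[bad[1L]])
    ev <- data$event
    bad <- which(!(ev %in% c(0L, 1L)))
    if (length(bad))
      stop("row ", bad[1L], ": event must be 0 or 1, got ", ev[bad[1L]])
    data$follow_up_months <- as.integer(fu)
    data$event <- as.integer(ev)
  }
  rownames(data) <- NULL
  structure(list(codebook = cb, data = data, horizon = as.integer(horizon)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  lab <- five_year_label(x)
  cat("Cohort:", nrow(x$data), "records,", length(x$codebook), "variables\n")
  if (nrow(x$data))
    cat(sprintf("  5-year status: %d dead, %d alive, %d indeterminate\n",
                sum(lab == "Dead"), sum(lab == "Alive"), sum(lab == "Indeterminate")))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  print(object)
  for (v in names(object$codebook)) {
    p <- state_distribution(object, v)
    cat(sprintf("  %-22s %s\n", v,
                paste(sprintf("%s %.3f", object$codebook[[v]]$levels, p),
                      collapse = ", ")))
  }
  invisible(object)
}

n_records <- function(x) nrow(x$data)

#' Five-year survival label
#'
#' Classifies each record as `Dead` (died within the horizon), `Alive`
#' (survived the full horizon under follow-up) or `Indeterminate` (censored
#' alive before the horizon, so the five-year status is unknown).
#' Indeterminate records are excluded from classification metrics but retained
#' for Cox fitting and concordance, which use the censored times directly.
#'
#' @param x A [cohort()].
#' @return Factor with levels `Alive`, `Dead`, `Indeterminate`.
#' @export
five_year_label <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ev <- x$data$event
  fu <- x$data$follow_up_months
  out <- ifelse(ev == 1L, "Dead", ifelse(fu >= x$horizon, "Alive", "Indeterminate"))
  factor(out, levels = c("Alive", "Dead", "Indeterminate"))
}

#' Read and write cohorts as coded CSV
#'
#' The CSV holds one header row and one row per record; level columns store
#' 0-based integer codes (the sidecar codebook supplies the labels), plus
#' `follow_up_months` and `event`. Rows with codes that do not map to the
#' codebook are rejected with their row number.
#'
#' @param path CSV file path.
#' @param cb The [codebook()] to decode level columns against.
#' @param horizon Administrative horizon in months (default 60).
#' @return `read_cohort()` returns a [cohort()]; `write_cohort()` invisibly
#'   returns `path`.
#' @export
read_cohort <- function(path, cb, horizon = 60L) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c(names(cb), "follow_up_months", "event")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (v in names(cb)) raw[[v]] <- raw[[v]] + 1L  # 0-based on disk
  cohort(raw, cb, horizon = horizon)
}

#' @rdname read_cohort
#' @param x A [cohort()].
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  out <- x$data
  for (v in names(x$codebook)) out[[v]] <- out[[v]] - 1L
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a cohort into training and testing sets
#'
#' Randomly partitions the records into a training set of size
#' `round-half-up(n * train_fraction)` and a test set holding the rest. The
#' permutation is drawn from a local RNG stream seeded by `seed`, so the same
#' seed always reproduces the same split and the caller's RNG state is left
#' untouched.
#'
#' @param x A [cohort()].
#' @param train_fraction Proportion of records assigned to training
#'   (0 < fraction <= 1). A 618-record cohort at 0.75 yields 464/154.
#' @param seed Integer seed for the split permutation.
#' @return List with elements `train` and `test`, both cohorts.
#' @export
split_cohort <- function(x, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  n <- n_records(x)
  if (n < 1L) stop("cannot split an empty cohort")
  if (!(train_fraction > 0 && train_fraction <= 1))
    stop("train_fraction must be in (0, 1]")
  n_train <- min(n, floor(n * train_fraction + 0.5))  # round half up
  perm <- with_local_seed(seed, sample.int(n))
  idx <- perm[seq_len(n_train)]
  list(train = subset_cohort(x, sort(idx)),
       test = subset_cohort(x, sort(setdiff(seq_len(n), idx))))
}

subset_cohort <- function(x, idx) {
  out <- x
  out$data <- x$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

# Run expr under a temporary RNG state seeded by `seed`; restores the caller's
# state afterwards so package randomness never perturbs the global stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: one user-facing seed per run, one derived
# stream per pipeline stage. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}
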