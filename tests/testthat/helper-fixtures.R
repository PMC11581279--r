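# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, exhaustive enumeration) and share no code with the implementation.

toy_codebook <- function(nvar = 2, nlev = 2) {
  vars <- lapply(seq_len(nvar), function(i)
    list(levels = paste0("L", seq_len(if (length(nlev) > 1) nlev[i] else nlev))))
  names(vars) <- paste0("v", seq_len(nvar))
  codebook(vars)
}

# Cohort from an explicit matrix of level indices plus outcome columns.
# Determinate outcomes only unless months/event supplied.
toy_cohort <- function(levels_mat, event, months = NULL, cb = NULL) {
  levels_mat <- as.matrix(levels_mat)
  if (is.null(cb)) {
    ks <- apply(levels_mat, 2, max)
    cb <- toy_codebook(ncol(levels_mat), pmax(ks, 2))
  }
  df <- as.data.frame(levels_mat)
  names(df) <- names(cb)
  df$event <- as.integer(event)
  df$follow_up_months <- if (is.null(months))
    ifelse(df$event == 1L, 30L, 60L) else as.integer(months)
  cohort(df, cb)
}

# Random determinate cohort: uniform iid levels, Bernoulli deaths.
random_cohort <- function(n, nvar, nlev, seed, p_dead = 0.4) {
  set.seed(seed)
  m <- matrix(0L, n, nvar)
  for (j in seq_len(nvar)) m[, j] <- sample.int(nlev, n, replace = TRUE)
  toy_cohort(m, event = rbinom(n, 1, p_dead),
             months = NULL)
}

# --- oracles --------------------------------------------------------------

# Conditional mutual information by direct triple-loop summation (bits).
cmi_oracle <- function(x, a, b) {
  lab <- as.character(five_year_label(x))
  keep <- lab != "Indeterminate"
  av <- x$data[[a]][keep]; bv <- x$data[[b]][keep]; cv <- lab[keep]
  N <- sum(keep)
  ka <- length(x$codebook[[a]]$levels); kb <- length(x$codebook[[b]]$levels)
  total <- 0
  for (cl in c("Alive", "Dead")) for (j in seq_len(ka)) for (k in seq_len(kb)) {
    pabc <- sum(av == j & bv == k & cv == cl) / N
    if (pabc == 0) next
    pc <- sum(cv == cl) / N
    pac <- sum(av == j & cv == cl) / N
    pbc <- sum(bv == k & cv == cl) / N
    total <- total + pabc * log2((pabc / pc) / ((pac / pc) * (pbc / pc)))
  }
  total
}

# All labelled spanning trees on n nodes via Pruefer sequences (n^(n-2)).
all_spanning_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1, 2), 1, 2)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(seqs)), function(r) pruefer_to_tree(seqs[r, ], n))
}

pruefer_to_tree <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (i in seq_along(pr)) {
    leaf <- min(which(degree == 1L))
    edges[i, ] <- c(leaf, pr[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[pr[i]] <- degree[pr[i]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# Maximum spanning-tree weight by exhaustive enumeration.
max_tree_weight_oracle <- function(w) {
  n <- nrow(w)
  max(vapply(all_spanning_trees(n), function(e)
    sum(w[e]), numeric(1)))
}

# TAN posterior by brute-force enumeration of the full joint distribution:
# sum the unnormalized joint over every attribute configuration (sanity that
# it normalizes) and evaluate P(class, x) directly from prior and CPTs.
tan_joint_prob <- function(model, cls_idx, lev) {
  p <- model$prior[cls_idx]
  for (vi in seq_along(model$attributes)) {
    v <- model$attributes[vi]
    cpt <- model$cpts[[v]]
    if (is.matrix(cpt)) p <- p * cpt[cls_idx, lev[vi]]
    else {
      pv <- which(model$attributes == model$parent[[v]])
      p <- p * cpt[cls_idx, lev[pv], lev[vi]]
    }
  }
  unname(p)
}

posterior_oracle <- function(model, lev) {
  pa <- tan_joint_prob(model, 1L, lev)
  pd <- tan_joint_prob(model, 2L, lev)
  pa / (pa + pd)
}

# AUC as the Mann-Whitney pair count with ties counted one half.
auc_oracle <- function(scores, truth) {
  truth <- as.character(truth)
  pos <- scores[truth == "Alive"]; neg <- scores[truth == "Dead"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Youden threshold by brute force over observed scores.
youden_oracle <- function(scores, truth) {
  truth <- as.character(truth)
  best_j <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- mean(scores[truth == "Alive"] >= t)
    spec <- mean(scores[truth == "Dead"] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-15) { best_j <- j; best_t <- t }
  }
  best_t
}

# Harrell C by enumeration over all ordered pairs.
c_index_oracle <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!(time[i] < time[j] && event[i] == 1)) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# Central finite differences of the negative log partial likelihood.
numeric_gradient <- function(f, beta, h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- h
    (f(beta + e) - f(beta - e)) / (2 * h)
  }, numeric(1))
}

# Golden-section minimization of a 1-D function.
golden_section <- function(f, lower, upper, tol = 1e-10) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  while (abs(b - a) > tol) {
    if (f(c) < f(d)) b <- d else a <- c
    c <- b - phi * (b - a); d <- a + phi * (b - a)
  }
  (a + b) / 2
}
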