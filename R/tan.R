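#' Class-conditional mutual information between two coded variables
#'
#' Computes `I(a; b | class)` in bits from the empirical frequencies of the
#' determinate (Alive/Dead) records:
#' `sum_c sum_j sum_k P(a=j, b=k, c) * log2( P(a=j, b=k | c) / (P(a=j|c) P(b=k|c)) )`,
#' with `0 * log(0)` terms contributing zero. These conditional mutual
#' informations are the edge weights of the TAN attribute tree.
#'
#' @param x A [cohort()] with both classes present.
#' @param a,b Distinct codebook variable names.
#' @return Non-negative scalar (bits), up to floating-point tolerance.
#' @export
conditional_mutual_information <- function(x, a, b) {
  stopifnot(inherits(x, "cohort"))
  if (identical(a, b)) stop("'a' and 'b' must differ")
  for (v in c(a, b))
    if (!v %in% names(x$codebook)) stop("unknown variable: ", v)
  lab <- five_year_label(x)
  keep <- lab != "Indeterminate"
  if (!any(keep)) stop("no determinate records")
  cls <- factor(as.character(lab[keep]), levels = c("Alive", "Dead"))
  av <- factor(x$data[[a]][keep], levels = seq_along(x$codebook[[a]]$levels))
  bv <- factor(x$data[[b]][keep], levels = seq_along(x$codebook[[b]]$levels))
  n <- table(av, bv, cls)
  N <- sum(n)
  cmi <- 0
  for (ci in 1:2) {
    nc <- sum(n[, , ci])
    if (nc == 0) next
    pj <- rowSums(n[, , ci]) / nc
    pk <- colSums(n[, , ci]) / nc
    pjk <- n[, , ci] / nc
    term <- pjk * log2(pjk / outer(pj, pk))
    term[!is.finite(term)] <- 0
    cmi <- cmi + (nc / N) * sum(term)
  }
  cmi
}

#' Maximum-weight spanning tree over attributes
#'
#' Kruskal's algorithm on the complete graph with the supplied symmetric edge
#' weights, maximizing total weight. Ties between equal-weight edges are
#' broken lexicographically by node order, so the tree is deterministic across
#' runs and platforms.
#'
#' @param weights Symmetric numeric matrix of finite pairwise weights with
#'   dimnames naming the attributes (diagonal ignored).
#' @return A two-column character matrix of undirected edges
#'   (`length(attributes) - 1` rows; zero rows for a single attribute).
#' @export
max_weight_spanning_tree <- function(weights) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  nodes <- rownames(weights)
  m <- nrow(weights)
  if (m == 1L) return(matrix(character(0), 0, 2))
  if (any(!is.finite(weights[upper.tri(weights)])))
    stop("all pairwise weights must be finite")
  ij <- which(upper.tri(weights), arr.ind = TRUE)
  ord <- order(-weights[ij], ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- matrix(character(0), 0, 2)
  for (e in seq_len(nrow(ij))) {
    a <- find(ij[e, 1]); b <- find(ij[e, 2])
    if (a != b) {
      parent[a] <- b
      edges <- rbind(edges, nodes[c(ij[e, 1], ij[e, 2])])
      if (nrow(edges) == m - 1L) break
    }
  }
  if (nrow(edges) != m - 1L) stop("weights did not yield a spanning tree")
  dimnames(edges) <- NULL
  edges
}

#' Orient an undirected tree away from a root
#'
#' Breadth-first orientation: every edge points from the node nearer the root
#' to the node farther from it, so each non-root attribute receives exactly
#' one attribute parent.
#'
#' @param edges Two-column matrix of undirected edges (may have zero rows).
#' @param root Root node name; must occur in the tree (or be the only node).
#' @param nodes Optional complete node set (defaults to the nodes in `edges`
#'   plus `root`), used to verify the edges form a tree.
#' @return Named character vector mapping each non-root node to its parent.
#' @export
orient_tree <- function(edges, root, nodes = NULL) {
  if (is.null(nodes))
    nodes <- if (nrow(edges)) unique(as.vector(edges)) else root
  if (!root %in% nodes) stop("root '", root, "' not among the nodes")
  if (nrow(edges) != length(nodes) - 1L)
    stop("edges do not form a tree on ", length(nodes), " nodes")
  adj <- lapply(stats::setNames(nodes, nodes), function(...) character(0))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (!a %in% nodes || !b %in% nodes) stop("edge endpoint not among nodes")
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  visited <- stats::setNames(logical(length(nodes)), nodes)
  queue <- root
  visited[root] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!visited[nb]) {
      visited[nb] <- TRUE
      parent[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  if (!all(visited)) stop("edges do not form a connected tree")
  parent[names(parent) != root]
}

#' Fit a tree-augmented naive Bayes survival classifier
#'
#' Learns the TAN structure and parameters for the binary five-year survival
#' class (Alive/Dead) from the determinate records of a training cohort:
#' (i) class-conditional mutual information is computed for every attribute
#' pair; (ii) these weights define a complete undirected graph over the
#' attributes; (iii) a maximum-weight spanning tree is extracted; (iv) the
#' tree is oriented away from a root attribute, and every attribute
#' additionally receives the class as a parent. Conditional probability
#' tables are estimated with additive (Laplace) smoothing `alpha`.
#'
#' When `root` is `NULL`, a provisional model rooted at the first attribute is
#' fitted and the final root is the attribute with the largest [mmfv()]
#' importance; for unsmoothed fits any root encodes the same joint
#' distribution, so the choice only fixes the parametrization.
#'
#' @param x Training [cohort()] with both classes present among determinate
#'   records.
#' @param attributes Codebook variables to include (default: all).
#' @param alpha Additive smoothing pseudo-count (default 1, Laplace). With
#'   `alpha > 0` every CPT entry — hence every posterior — is strictly inside
#'   (0, 1).
#' @param root Optional attribute name to root the tree at.
#' @return An object of class `"tan_bayes"`: structure (root, attribute
#'   parents, undirected tree), class prior, CPTs, smoothing constant and the
#'   codebook.
#' @seealso [predict.tan_bayes()], [posterior_alive()], [mmfv()]
#' @export
tan_bayes <- function(x, attributes = names(x$codebook), alpha = 1, root = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!length(attributes)) stop("need at least one attribute")
  if (!all(attributes %in% names(x$codebook)))
    stop("unknown attribute(s): ",
         paste(setdiff(attributes, names(x$codebook)), collapse = ", "))
  attributes <- names(x$codebook)[sort(match(attributes, names(x$codebook)))]
  if (alpha < 0) stop("alpha must be >= 0")
  lab <- five_year_label(x)
  keep <- lab != "Indeterminate"
  cls <- factor(as.character(lab[keep]), levels = c("Alive", "Dead"))
  if (length(unique(cls)) < 2L)
    stop("training data must contain both Alive and Dead records")
  if (length(attributes) > 1L) {
    w <- matrix(0, length(attributes), length(attributes),
                dimnames = list(attributes, attributes))
    for (i in seq_along(attributes)[-1]) for (j in seq_len(i - 1L)) {
      w[j, i] <- w[i, j] <-
        conditional_mutual_information(x, attributes[j], attributes[i])
    }
    edges <- max_weight_spanning_tree(w)
  } else edges <- matrix(character(0), 0, 2)
  fit_at_root <- function(r) {
    parent <- orient_tree(edges, r, nodes = attributes)
    estimate_tan_cpts(x$data[keep, , drop = FALSE], cls, x$codebook,
                      attributes, r, parent, edges, alpha, x$horizon)
  }
  if (is.null(root)) {
    provisional <- fit_at_root(attributes[1L])
    imp <- vapply(attributes, function(v) mmfv(provisional, v), numeric(1))
    root <- attributes[which.max(imp)]
  } else if (!root %in% attributes) stop("root must be one of the attributes")
  fit_at_root(root)
}

estimate_tan_cpts <- function(df, cls, cb, attributes, root, parent, edges,
                              alpha, horizon) {
  n <- length(cls)
  nc <- table(cls)
  prior <- (as.numeric(nc) + alpha) / (n + 2 * alpha)
  names(prior) <- names(nc)
  cpts <- list()
  for (v in attributes) {
    k <- length(cb[[v]]$levels)
    vv <- factor(df[[v]], levels = seq_len(k))
    if (v == root || is.na(parent[v])) {
      cnt <- table(cls, vv)                       # class x level
      cpt <- (cnt + alpha) / (rowSums(cnt) + k * alpha)
      cpts[[v]] <- matrix(cpt, 2, k, dimnames = list(c("Alive", "Dead"), NULL))
    } else {
      pv <- parent[[v]]
      kp <- length(cb[[pv]]$levels)
      pvv <- factor(df[[pv]], levels = seq_len(kp))
      cnt <- table(cls, pvv, vv)                  # class x parent x level
      tot <- apply(cnt, c(1, 2), sum)
      cpt <- array(0, dim = c(2, kp, k), dimnames = list(c("Alive", "Dead")))
      for (ci in 1:2) for (pj in seq_len(kp))
        cpt[ci, pj, ] <- (cnt[ci, pj, ] + alpha) / (tot[ci, pj] + k * alpha)
      cpts[[v]] <- cpt
    }
  }
  structure(list(class_levels = c("Alive", "Dead"), attributes = attributes,
                 root = root, parent = parent, edges = edges, prior = prior,
                 cpts = cpts, alpha = alpha, codebook = cb, horizon = horizon,
                 n_train = n),
            class = "tan_bayes")
}

#' @export
print.tan_bayes <- function(x, ...) {
  cat("Tree-augmented naive Bayes classifier\n")
  cat(sprintf("  %d attributes, root '%s', alpha = %g, fitted on %d records\n",
              length(x$attributes), x$root, x$alpha, x$n_train))
  cat(sprintf("  class prior: Alive %.3f, Dead %.3f\n",
              x$prior["Alive"], x$prior["Dead"]))
  np <- x$parent[!is.na(x$parent)]
  if (length(np))
    cat("  attribute tree:", paste(sprintf("%s -> %s", np, names(np)),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tan_bayes <- function(object, ...) {
  print(object)
  imp <- vapply(object$attributes, function(v) mmfv(object, v), numeric(1))
  cat("\nVariable importance (MMFV):\n")
  tab <- rank_variables(imp)
  print(tab, row.names = FALSE)
  invisible(tab)
}

# log P(class, x) for each record and both classes; rows of `data` are level
# indices against the model's codebook.
tan_log_joint <- function(model, data) {
  n <- nrow(data)
  ll <- matrix(rep(log(model$prior), each = n), n, 2,
               dimnames = list(NULL, model$class_levels))
  for (v in model$attributes) {
    lev <- data[[v]]
    if (any(is.na(lev) | lev < 1L | lev > length(model$codebook[[v]]$levels)))
      stop("level index out of range for variable '", v, "'")
    cpt <- model$cpts[[v]]
    if (is.matrix(cpt)) {
      ll[, 1] <- ll[, 1] + log(cpt[1L, lev])
      ll[, 2] <- ll[, 2] + log(cpt[2L, lev])
    } else {
      pv <- data[[model$parent[[v]]]]
      kp <- dim(cpt)[2]; k <- dim(cpt)[3]
      ll[, 1] <- ll[, 1] + log(cpt[cbind(1L, pv, lev)])
      ll[, 2] <- ll[, 2] + log(cpt[cbind(2L, pv, lev)])
    }
  }
  ll
}

#' Posterior probability of five-year survival
#'
#' Exact inference in the fitted TAN:
#' `P(Alive | x) = P(Alive) prod_v CPT_v / sum_c P(c) prod_v CPT_v`,
#' computed in log space. Strictly inside (0, 1) whenever the model was
#' smoothed with `alpha > 0`.
#'
#' @param model A fitted [tan_bayes()] model.
#' @param x A [cohort()] coded against the model's codebook.
#' @return Numeric vector of posterior Alive probabilities, one per record.
#' @export
posterior_alive <- function(model, x) {
  stopifnot(inherits(model, "tan_bayes"), inherits(x, "cohort"))
  ll <- tan_log_joint(model, x$data)
  mx <- pmax(ll[, 1], ll[, 2])
  pa <- exp(ll[, 1] - mx)
  pd <- exp(ll[, 2] - mx)
  unname(pa / (pa + pd))
}

#' Predict five-year survival status
#'
#' @param object A fitted [tan_bayes()] model.
#' @param newdata A [cohort()] to predict for.
#' @param type `"posterior"` for `P(Alive | x)`, `"class"` for the thresholded
#'   Alive/Dead label.
#' @param threshold Decision threshold on the Alive posterior (default 0.5);
#'   a posterior exactly equal to the threshold predicts Alive.
#' @param ... Unused.
#' @return Numeric vector of posteriors, or a factor with levels Alive/Dead.
#' @export
predict.tan_bayes <- function(object, newdata, type = c("posterior", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- posterior_alive(object, newdata)
  if (type == "posterior") return(p)
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  factor(ifelse(p >= threshold, "Alive", "Dead"), levels = c("Alive", "Dead"))
}

# Marginal P(attribute = j | class) for every attribute, by propagating from
# the root down the attribute tree (children condition only on their single
# attribute parent given the class).
tan_attr_marginals <- function(model) {
  out <- list()
  order <- topo_order(model)
  for (v in order) {
    cpt <- model$cpts[[v]]
    if (is.matrix(cpt)) {
      out[[v]] <- cpt
    } else {
      pm <- out[[model$parent[[v]]]]          # 2 x kp
      k <- dim(cpt)[3]
      m <- matrix(0, 2, k)
      for (ci in 1:2) m[ci, ] <- pm[ci, ] %*% cpt[ci, , ]
      out[[v]] <- m
    }
  }
  out
}

topo_order <- function(model) {
  ord <- model$root
  rest <- setdiff(model$attributes, ord)
  while (length(rest)) {
    nxt <- rest[vapply(rest, function(v) model$parent[[v]] %in% ord, logical(1))]
    if (!length(nxt)) stop("attribute parents do not form a rooted tree")
    ord <- c(ord, nxt)
    rest <- setdiff(rest, nxt)
  }
  ord
}
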