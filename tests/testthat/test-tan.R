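test_that("conditional mutual information matches hand cases and the oracle", {
  # v1 and v2 identical copies, uniform over 2 levels within each class
  m <- rbind(c(1, 1), c(2, 2), c(1, 1), c(2, 2))
  x <- toy_cohort(rbind(m, m), event = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(conditional_mutual_information(x, "v1", "v2"), 1.0)
  # exact conditional independence via product counts within each class
  grid <- as.matrix(expand.grid(v1 = 1:2, v2 = 1:2))
  x2 <- toy_cohort(rbind(grid, grid), event = rep(c(1, 0), each = 4))
  expect_equal(conditional_mutual_information(x2, "v1", "v2"), 0.0)
  # random cohort against the triple-loop summation oracle
  x3 <- random_cohort(200, 2, 3, seed = 42)
  expect_equal(conditional_mutual_information(x3, "v1", "v2"),
               cmi_oracle(x3, "v1", "v2"), tolerance = 1e-12)
  expect_gte(conditional_mutual_information(x3, "v1", "v2"), -1e-12)
  expect_error(conditional_mutual_information(x3, "v1", "v1"), "must differ")
  expect_error(conditional_mutual_information(x3, "v1", "nope"), "unknown")
})

test_that("maximum-weight spanning tree is optimal and deterministic", {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 0.5
  w["A", "C"] <- w["C", "A"] <- 0.3
  w["B", "C"] <- w["C", "B"] <- 0.1
  e <- max_weight_spanning_tree(w)
  key <- apply(e, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(key, c("A-B", "A-C"))
  expect_identical(nrow(max_weight_spanning_tree(w[1, 1, drop = FALSE])), 0L)
  w["A", "B"] <- w["B", "A"] <- Inf
  expect_error(max_weight_spanning_tree(w), "finite")
})

test_that("spanning-tree weight equals exhaustive enumeration for n <= 6", {
  for (n in 3:6) for (rep in 1:3) {
    set.seed(n * 100 + rep)
    w <- matrix(0, n, n, dimnames = list(paste0("x", 1:n), paste0("x", 1:n)))
    w[upper.tri(w)] <- runif(n * (n - 1) / 2)
    w <- w + t(w)
    e <- max_weight_spanning_tree(w)
    got <- sum(w[cbind(e[, 1], e[, 2])])
    expect_equal(got, max_tree_weight_oracle(w), tolerance = 1e-12)
  }
})

test_that("tree orientation points every edge away from the root", {
  path <- rbind(c("A", "B"), c("B", "C"))
  par <- orient_tree(path, "A")
  expect_identical(par, c(B = "A", C = "B"))
  star <- rbind(c("X", "a"), c("X", "b"), c("X", "c"))
  par <- orient_tree(star, "X")
  expect_true(all(par == "X") && setequal(names(par), c("a", "b", "c")))
  for (rep in 1:100) {
    set.seed(rep)
    n <- sample(2:10, 1)
    e <- pruefer_to_tree(sample.int(n, max(n - 2, 0), replace = TRUE), n)
    e <- matrix(paste0("n", e), ncol = 2)
    root <- paste0("n", sample.int(n, 1))
    par <- orient_tree(e, root)
    expect_length(par, n - 1L)        # every non-root has exactly one parent
    expect_false(root %in% names(par))
  }
  expect_error(orient_tree(path, "Z"), "not among")
  expect_error(orient_tree(path[1, , drop = FALSE], "A",
                           nodes = c("A", "B", "C")), "tree")
})

test_that("TAN fitting smooths CPTs by the Laplace rule", {
  # v2 level 2 never observed with class Dead at v1 = 1
  m <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 2), c(1, 2))
  x <- toy_cohort(m, event = c(1, 1, 1, 0, 0))
  fit <- tan_bayes(x, alpha = 1, root = "v1")
  cpt <- fit$cpts$v2     # class x parent(v1) x level
  # Dead stratum at v1=1: m = 3 observations, k = 2 levels, zero cell -> 1/(m+k)
  expect_equal(unname(cpt["Dead", 1, 2]), 1 / (3 + 2))
  expect_equal(unname(cpt["Dead", 1, 1]), (3 + 1) / (3 + 2))
  # every CPT row sums to 1
  for (v in fit$attributes) {
    c3 <- fit$cpts[[v]]
    if (is.matrix(c3)) expect_equal(unname(rowSums(c3)), c(1, 1), tolerance = 1e-12)
    else for (ci in 1:2) expect_equal(unname(rowSums(c3[ci, , ])),
                                      rep(1, dim(c3)[2]), tolerance = 1e-12)
  }
  expect_error(tan_bayes(toy_cohort(m, event = rep(1, 5))), "both")
})

test_that("two attributes always join by the single possible tree edge", {
  x <- random_cohort(50, 2, 2, seed = 3)
  fit <- tan_bayes(x)
  expect_identical(nrow(fit$edges), 1L)
  expect_setequal(as.vector(fit$edges), c("v1", "v2"))
})

test_that("structure learning recovers a strongly dependent generating tree", {
  # generating TAN: class -> all, attribute tree v1 -> v2 -> v3, near-copy CPTs
  set.seed(2024)
  n <- 5000
  cls <- rbinom(n, 1, 0.4)                       # 1 = dead
  flip <- function(src, p_copy) ifelse(runif(n) < p_copy, src, 3L - src)
  v1 <- ifelse(runif(n) < 0.7 - 0.3 * cls, 1L, 2L)
  v2 <- flip(v1, 0.9)
  v3 <- flip(v2, 0.9)
  v4 <- ifelse(runif(n) < 0.5 + 0.2 * cls, 1L, 2L)  # class-only parent
  x <- toy_cohort(cbind(v1, v2, v3, v4), event = cls)
  fit <- tan_bayes(x)
  key <- apply(fit$edges, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true(all(c("v1-v2", "v2-v3") %in% key))
  expect_false("v1-v3" %in% key)
})

test_that("posterior inference equals brute-force joint enumeration", {
  x <- random_cohort(300, 4, 3, seed = 8)
  fit <- tan_bayes(x, alpha = 1)
  set.seed(9)
  for (rep in 1:20) {
    lev <- sample.int(3, 4, replace = TRUE)
    rec <- toy_cohort(matrix(lev, 1), event = 0L, cb = x$codebook)
    expect_equal(posterior_alive(fit, rec), posterior_oracle(fit, lev),
                 tolerance = 1e-12)
  }
  # smoothed posteriors are never exactly 0 or 1
  p <- posterior_alive(fit, x)
  expect_true(all(p > 0 & p < 1))
})

test_that("a class-independent model returns the prior as posterior", {
  x <- random_cohort(100, 3, 2, seed = 5)
  fit <- tan_bayes(x, alpha = 1)
  for (v in fit$attributes) {
    cpt <- fit$cpts[[v]]
    if (is.matrix(cpt)) cpt[2, ] <- cpt[1, ]
    else cpt[2, , ] <- cpt[1, , ]
    fit$cpts[[v]] <- cpt
  }
  p <- posterior_alive(fit, x)
  expect_equal(p, rep(unname(fit$prior["Alive"]), nrow(x$data)),
               tolerance = 1e-12)
})

test_that("the joint distribution is invariant to the chosen root (unsmoothed)", {
  # cover every (class, level, level) cell so alpha = 0 has no empty strata
  grid <- as.matrix(expand.grid(1:2, 1:2, 1:2, 1:2))
  x <- toy_cohort(rbind(grid, grid, grid[rep(1:8, 2), ]),
                  event = c(rep(1, 16), rep(0, 32)))
  set.seed(31)
  recs <- toy_cohort(matrix(sample.int(2, 400, replace = TRUE), 100, 4),
                     event = integer(100), cb = x$codebook)
  base <- NULL
  for (r in names(x$codebook)) {
    fit <- tan_bayes(x, alpha = 0, root = r)
    p <- posterior_alive(fit, recs)
    if (is.null(base)) base <- p
    else expect_lt(max(abs(p - base)), 1e-10)
  }
})

test_that("thresholding predicts Alive on ties and matches the Bayes rule", {
  x <- random_cohort(200, 3, 2, seed = 12)
  fit <- tan_bayes(x)
  p <- posterior_alive(fit, x)
  pred <- predict(fit, x, type = "class", threshold = 0.5)
  expect_identical(as.character(pred), ifelse(p >= 0.5, "Alive", "Dead"))
  # tie rule: posterior exactly at the threshold predicts Alive
  thr <- p[7]
  expect_identical(as.character(predict(fit, x, type = "class",
                                        threshold = thr)[7]), "Alive")
  expect_error(predict(fit, x, type = "class", threshold = 1.5), "threshold")
})
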