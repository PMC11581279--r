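#' Read / write generator parameters as YAML
#'
#' Serializes a [generator_params()] object — codebook, sampling plan
#' (marginals and parent-conditional tables), per-level log-hazard
#' coefficients, Weibull baseline, horizon and early-censoring rate — to the
#' same structured-text format used for codebooks.
#'
#' @param params A [generator_params()] object.
#' @param path File path.
#' @return `read_generator_params()` returns a [generator_params()] object;
#'   `write_generator_params()` invisibly returns `path`.
#' @export
write_generator_params <- function(params, path) {
  stopifnot(inherits(params, "generator_params"))
  plan <- lapply(params$plan, function(p) {
    if (!is.null(p$marginal)) list(marginal = as.numeric(p$marginal))
    else list(parent = p$parent,
              table = lapply(seq_len(nrow(p$table)),
                             function(i) as.numeric(p$table[i, ])))
  })
  yaml::write_yaml(list(
    codebook = lapply(params$codebook, function(v)
      list(levels = v$levels, ref = v$ref)),
    plan = plan,
    coefficients = lapply(params$coefficients, as.numeric),
    shape = params$shape, scale = params$scale,
    horizon = params$horizon, early_censoring = params$early_censoring
  ), path, precision = 17L)
  invisible(path)
}

#' @rdname write_generator_params
#' @export
read_generator_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  cb <- codebook(raw$codebook)
  plan <- lapply(raw$plan, function(p) {
    if (!is.null(p$marginal)) list(marginal = as.numeric(p$marginal))
    else list(parent = p$parent, table = do.call(rbind, p$table))
  })
  generator_params(cb, plan, lapply(raw$coefficients, as.numeric),
                   shape = raw$shape, scale = raw$scale,
                   horizon = raw$horizon,
                   early_censoring = raw$early_censoring)
}

#' Read / write a fitted TAN model as YAML
#'
#' Serializes a [tan_bayes()] model — structure (root, attribute parents,
#' undirected tree), class prior, conditional probability tables, smoothing
#' constant and codebook — to a structured text document, e.g. for golden-file
#' comparisons. The round trip reproduces identical posteriors.
#'
#' @param model A fitted [tan_bayes()] model.
#' @param path File path.
#' @return `read_tan_model()` returns a `"tan_bayes"` object;
#'   `write_tan_model()` invisibly returns `path`.
#' @export
write_tan_model <- function(model, path) {
  stopifnot(inherits(model, "tan_bayes"))
  cpts <- lapply(model$cpts, function(cpt) {
    if (is.matrix(cpt)) list(kind = "root", rows = lapply(1:2, function(i)
      as.numeric(cpt[i, ])))
    else list(kind = "child", dim = dim(cpt),
              values = as.numeric(cpt))
  })
  yaml::write_yaml(list(
    attributes = model$attributes, root = model$root,
    parent = as.list(model$parent),
    edges = lapply(seq_len(nrow(model$edges)),
                   function(i) as.character(model$edges[i, ])),
    prior = as.numeric(model$prior), alpha = model$alpha,
    horizon = model$horizon, n_train = model$n_train,
    cpts = cpts,
    codebook = lapply(model$codebook, function(v)
      list(levels = v$levels, ref = v$ref))
  ), path, precision = 17L)
  invisible(path)
}

#' @rdname write_tan_model
#' @export
read_tan_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- yaml::read_yaml(path)
  cls <- c("Alive", "Dead")
  cpts <- lapply(raw$cpts, function(cpt) {
    if (cpt$kind == "root") {
      m <- do.call(rbind, cpt$rows)
      dimnames(m) <- list(cls, NULL)
      m
    } else array(as.numeric(cpt$values), dim = unlist(cpt$dim),
                 dimnames = list(cls, NULL, NULL))
  })
  names(cpts) <- names(raw$cpts)
  parent <- unlist(raw$parent)
  edges <- if (length(raw$edges))
    do.call(rbind, raw$edges) else matrix(character(0), 0, 2)
  structure(list(class_levels = cls, attributes = raw$attributes,
                 root = raw$root, parent = parent, edges = edges,
                 prior = stats::setNames(as.numeric(raw$prior), cls),
                 cpts = cpts, alpha = raw$alpha,
                 codebook = codebook(raw$codebook), horizon = raw$horizon,
                 n_train = raw$n_train),
            class = "tan_bayes")
}
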