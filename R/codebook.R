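#' Variable codebook for coded registry cohorts
#'
#' A codebook is an ordered collection of categorical variables, each with an
#' ordered set of level labels and a designated reference level (the baseline
#' category that dummy coding maps to an all-zero block). All cohort records
#' are coded as integer level indices against a codebook.
#'
#' @param variables A named list. Each element describes one variable and is a
#'   list with components `levels` (character vector of at least two uniquely
#'   named level labels, in display order) and optionally `ref` (integer index
#'   of the reference level, default 1).
#' @return An object of class `"codebook"`: a named list of variable entries,
#'   each with `name`, `levels` and `ref`.
#' @examples
#' cb <- codebook(list(
#'   exposure = list(levels = c("No", "Yes")),
#'   grade    = list(levels = c("low", "mid", "high"), ref = 1)
#' ))
#' n_levels(cb)
#' @export
codebook <- function(variables) {
  if (!is.list(variables) || length(variables) < 1L)
    stop("'variables' must be a non-empty list")
  nm <- names(variables)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every variable must be named")
  if (anyDuplicated(nm))
    stop("duplicate variable name: ", nm[duplicated(nm)][1L])
  vars <- lapply(seq_along(variables), function(i) {
    v <- variables[[i]]
    lev <- as.character(v$levels)
    if (length(lev) < 2L)
      stop("variable '", nm[i], "' must have at least 2 levels")
    if (anyDuplicated(lev))
      stop("variable '", nm[i], "' has duplicated level labels")
    ref <- if (is.null(v$ref)) 1L else as.integer(v$ref)
    if (is.na(ref) || ref < 1L || ref > length(lev))
      stop("variable '", nm[i], "': reference level index ", ref,
           " not among its ", length(lev), " levels")
    list(name = nm[i], levels = lev, ref = ref)
  })
  names(vars) <- nm
  structure(vars, class = "codebook")
}

#' Default endometrial-cancer codebook
#'
#' The built-in coding scheme of 13 clinicopathological variables used
#' throughout the package: patient age group, primary tumor site, tumor grade,
#' histological type, FIGO tumor stage, radiotherapy/surgery sequence,
#' radiotherapy, chemotherapy, lymph-node resection, lymph-node metastasis,
#' tumor size, depth of myometrial invasion and distant metastasis. The first
#' level of each variable is its reference category.
#'
#' @return A [codebook()] with 13 variables and 38 levels in total.
#' @export
ec_codebook <- function() {
  codebook(list(
    age = list(levels = c("<50", "50-59", "60-69", "70-79", ">80")),
    tumor_site = list(levels = c("Fundus of the uterus", "Rest of uterine cavity")),
    tumor_grade = list(levels = c("High differentiation", "Middle differentiation",
                                  "Low differentiation", "Undifferentiation")),
    histological_type = list(levels = c("Endometrioid carcinoma", "Serous carcinoma",
                                        "Clear cell carcinoma",
                                        "Undifferentiated carcinoma",
                                        "Mixed cell carcinoma")),
    tumor_stage = list(levels = c("I", "II", "III", "IV")),
    rt_surgery_sequence = list(levels = c("Operation only", "Postoperative radiotherapy",
                                          "Preoperative radiotherapy")),
    radiotherapy = list(levels = c("No", "Yes")),
    chemotherapy = list(levels = c("No", "Yes")),
    lymph_node_resection = list(levels = c("No", "Yes")),
    lymph_node_metastasis = list(levels = c("No", "Yes")),
    tumor_size = list(levels = c("<4cm", ">=4cm")),
    depth_of_invasion = list(levels = c("Confined endometrial layer",
                                        "<1/2 Muscular layer", ">=1/2 Muscular layer")),
    distant_metastasis = list(levels = c("No", "Yes"))
  ))
}

#' @export
print.codebook <- function(x, ...) {
  cat("Codebook:", length(x), "variables,", sum(n_levels(x)), "levels\n")
  for (v in x)
    cat(sprintf("  %-22s (%d) %s%s\n", v$name, length(v$levels),
                paste(v$levels, collapse = " | "),
                if (v$ref != 1L) sprintf("  [ref: %s]", v$levels[v$ref]) else ""))
  invisible(x)
}

#' Number of levels per codebook variable
#' @param cb A [codebook()].
#' @return Named integer vector of level counts.
#' @export
n_levels <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  vapply(cb, function(v) length(v$levels), integer(1))
}

#' Read / write a codebook as a YAML document
#'
#' The on-disk format is a YAML mapping from variable name to a mapping with
#' keys `levels` (sequence of labels) and `ref` (1-based reference index).
#'
#' @param path File path.
#' @return `read_codebook()` returns a [codebook()]; `write_codebook()`
#'   invisibly returns `path`.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  codebook(yaml::read_yaml(path))
}

#' @rdname read_codebook
#' @param cb A [codebook()].
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  out <- lapply(cb, function(v) list(levels = v$levels, ref = v$ref))
  yaml::write_yaml(out, path)
  invisible(path)
}
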