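# --- model definition YAML dialect -----------------------------------------
#
# name: antid
# outcome: antid                  # key into the outcome-function registry
# strategies: [{id: s1, label: ...}, ...]
# treatments: [{id: partobulin, label: ...}, ...]
# parameters:
#   - {name: s0, distribution: beta, shape1: 9.5, shape2: 990.5}
#   - {name: or_eff, distribution: lognormal, meanlog: -0.947, sdlog: 0.25}
#   - {name: x, distribution: empirical, samples_file: x.csv, block: eff}
#
# empirical `samples_file` paths resolve relative to the YAML file; a
# `samples` list inline is also accepted.

outcome_registry <- new.env(parent = emptyenv())

#' Register or look up a named outcome function
#'
#' YAML model definitions cannot carry R code; instead their `outcome` field
#' names a function registered here.  The packaged anti-D model is
#' registered as `"antid"` at load time.
#'
#' @param name registry key.
#' @param fn outcome function (see [model_definition()]).
#' @return `register_outcome_fn()` returns `name` invisibly;
#'   `get_outcome_fn()` returns the function.
#' @export
register_outcome_fn <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = outcome_registry)
  invisible(name)
}

#' @rdname register_outcome_fn
#' @export
get_outcome_fn <- function(name) {
  if (!exists(name, envir = outcome_registry))
    abort("no outcome function registered under '", name, "'")
  get(name, envir = outcome_registry)
}

#' Read or write a model definition file
#'
#' Serializes the distribution family and named hyperparameters of every
#' parameter, the strategy and treatment tables and the registered name of
#' the outcome function to YAML (or JSON, by file extension).  Empirical
#' parameters store their samples in a sibling CSV referenced by
#' `samples_file`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param model a [model_definition()] (for writing); its outcome function
#'   must be registered (see [register_outcome_fn()]).
#' @param outcome_name registry key recorded in the file.
#' @return `read_model_definition()` returns a `model_definition`;
#'   `write_model_definition()` returns `path` invisibly.
#' @export
read_model_definition <- function(path) {
  doc <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  need <- c("name", "outcome", "strategies", "treatments", "parameters")
  miss <- setdiff(need, names(doc))
  if (length(miss)) abort("model file missing fields: ",
                          paste(miss, collapse = ", "))
  as_tab <- function(x) data.frame(
    id = vapply(x, function(r) as.character(r$id), ""),
    label = vapply(x, function(r) as.character(r$label %||% r$id), ""),
    stringsAsFactors = FALSE)
  pars <- lapply(doc$parameters, function(p) {
    nm <- p$name; dist <- p$distribution
    hyper <- p[setdiff(names(p), c("name", "distribution", "low", "high",
                                   "description", "source", "samples_file"))]
    if (dist == "empirical" && !is.null(p$samples_file)) {
      sf <- file.path(dirname(path), p$samples_file)
      hyper$samples <- read.csv(sf)[[1]]
    }
    if (!is.null(hyper$samples)) hyper$samples <- as.numeric(hyper$samples)
    do.call(parameter_spec,
            c(list(name = nm, distribution = dist), hyper,
              list(low = p$low, high = p$high,
                   description = p$description %||% "",
                   source = p$source %||% "")))
  })
  model_definition(pars, as_tab(doc$strategies), as_tab(doc$treatments),
                   get_outcome_fn(doc$outcome), name = doc$name)
}

#' @rdname read_model_definition
#' @export
write_model_definition <- function(model, path, outcome_name) {
  stopifnot(inherits(model, "model_definition"))
  ser_par <- function(s) {
    p <- s$params
    if (s$distribution == "empirical") {
      sf <- paste0(s$name, "_samples.csv")
      write.csv(data.frame(value = p$samples),
                file.path(dirname(path), sf), row.names = FALSE)
      p <- c(p[setdiff(names(p), "samples")], list(samples_file = sf))
    }
    c(list(name = s$name, distribution = s$distribution), p,
      if (!is.null(s$low)) list(low = s$low),
      if (!is.null(s$high)) list(high = s$high),
      if (nzchar(s$description)) list(description = s$description),
      if (nzchar(s$source)) list(source = s$source))
  }
  tab_list <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(id = df$id[i], label = df$label[i]))
  doc <- list(name = model$name, outcome = outcome_name,
              strategies = tab_list(model$strategies),
              treatments = tab_list(model$treatments),
              parameters = lapply(model$parameters, ser_par))
  names(doc$parameters) <- NULL
  if (grepl("\\.json$", path))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Path to the packaged anti-D example files
#'
#' `antid.yaml` (model definition), `studies.csv` and `elicitations.csv`
#' (synthetic evidence generated with a fixed seed) live under the package's
#' `extdata`.
#'
#' @param file one of `"antid.yaml"`, `"studies.csv"`, `"elicitations.csv"`.
#' @return absolute path.
#' @export
antid_example_path <- function(file = "antid.yaml") {
  p <- system.file("extdata", file, package = "hteval")
  if (!nzchar(p)) abort("packaged example file not found: ", file)
  p
}
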