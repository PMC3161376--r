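#' Build a named analysis scenario
#'
#' A scenario bundles everything that distinguishes one analysis from
#' another: parameter overrides on the decision model, the meta-analysis
#' configuration, and the run options.  Scenarios serialize losslessly to
#' JSON, so a committee request ("what if we drop study S3?", "what if the
#' products were equally priced?") becomes a small reviewable file that can
#' be replayed at any time.
#'
#' @param name unique name within a scenario store.
#' @param description free text.
#' @param parameter_overrides named list of [parameter_spec()]s replacing
#'   same-named model parameters.
#' @param meta_config a [meta_config()], or `NULL` to skip the evidence
#'   layer.
#' @param run_options a [run_options()].
#' @param provenance named list of free-text source notes per parameter.
#' @param created creation timestamp string (defaults to now).
#' @return list of class `ht_scenario`.
#' @export
scenario <- function(name, description = "",
                     parameter_overrides = list(),
                     meta_config = NULL,
                     run_options = hteval::run_options(),
                     provenance = list(),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(is.character(name), nzchar(name), is.list(parameter_overrides))
  for (nm in names(parameter_overrides)) {
    ov <- parameter_overrides[[nm]]
    if (!inherits(ov, "parameter_spec"))
      abort("override '", nm, "' is not a parameter_spec")
    if (!identical(ov$name, nm))
      abort("override list name '", nm, "' does not match spec name '",
            ov$name, "'")
  }
  structure(list(name = name, description = description,
                 parameter_overrides = parameter_overrides,
                 meta_config = meta_config, run_options = run_options,
                 provenance = provenance, created = created),
            class = "ht_scenario")
}

# --- scenario JSON (lossless round-trip) -----------------------------------

scenario_to_list <- function(s) {
  ser_spec <- function(sp) {
    out <- c(list(name = sp$name, distribution = sp$distribution),
             sp$params,
             list(low = sp$low, high = sp$high,
                  description = sp$description, source = sp$source))
    out[!vapply(out, is.null, logical(1))]
  }
  list(
    name = s$name, description = s$description,
    parameter_overrides = lapply(s$parameter_overrides, ser_spec),
    meta_config = if (!is.null(s$meta_config)) unclass(s$meta_config),
    run_options = unclass(s$run_options),
    provenance = s$provenance, created = s$created
  )
}

scenario_from_list <- function(l) {
  de_spec <- function(sp) {
    hyper <- sp[setdiff(names(sp), c("name", "distribution", "low", "high",
                                     "description", "source"))]
    if (!is.null(hyper$samples)) hyper$samples <- as.numeric(hyper$samples)
    do.call(parameter_spec,
            c(list(name = sp$name, distribution = sp$distribution), hyper,
              list(low = sp$low, high = sp$high,
                   description = sp$description %||% "",
                   source = sp$source %||% "")))
  }
  mc <- if (!is.null(l$meta_config)) {
    m <- l$meta_config
    meta_config(
      selected_study_ids = unlist(m$selected_study_ids),
      include_internal = m$include_internal,
      include_external = m$include_external,
      include_additive = m$include_additive,
      include_proportional = m$include_proportional,
      selected_assessor_ids = unlist(m$selected_assessor_ids),
      method = m$method, mcmc = m$mcmc, priors = m$priors,
      continuity = m$continuity
    )
  }
  ro <- l$run_options
  scenario(
    name = l$name, description = l$description %||% "",
    parameter_overrides = lapply(l$parameter_overrides, de_spec),
    meta_config = mc,
    run_options = run_options(mode = ro$mode, n_sims = ro$n_sims,
                              seed = ro$seed,
                              lambda_grid = unlist(ro$lambda_grid)),
    provenance = l$provenance %||% list(),
    created = l$created
  )
}

#' Store, load and list scenarios
#'
#' Scenarios are stored one JSON file per scenario under `store_path`.
#' Round-trips are lossless: `load_scenario(save_scenario(s))` equals `s`
#' field for field.
#'
#' @param s an [scenario()].
#' @param store_path directory of the scenario store.
#' @param name scenario name to load.
#' @param overwrite allow replacing an existing scenario of the same name.
#' @return `save_scenario()` the file path, invisibly; `load_scenario()` an
#'   `ht_scenario`; `list_scenarios()` a character vector of names in
#'   creation order.
#' @export
save_scenario <- function(s, store_path, overwrite = FALSE) {
  stopifnot(inherits(s, "ht_scenario"))
  dir.create(store_path, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(store_path, paste0(s$name, ".json"))
  if (file.exists(path) && !overwrite)
    abort("scenario '", s$name, "' already exists (use overwrite = TRUE)")
  jsonlite::write_json(scenario_to_list(s), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_scenario
#' @export
load_scenario <- function(name, store_path) {
  path <- if (file.exists(name)) name
          else file.path(store_path, paste0(name, ".json"))
  if (!file.exists(path)) abort("scenario file not found: ", path)
  scenario_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname save_scenario
#' @export
list_scenarios <- function(store_path) {
  files <- list.files(store_path, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) return(character())
  created <- vapply(files, function(f)
    jsonlite::read_json(f)$created %||% "", "")
  sub("\\.json$", "", basename(files))[order(created, basename(files))]
}

#' Run a scenario end to end
#'
#' Applies the scenario's parameter overrides to the base model; when a
#' meta-analysis configuration and study data are present, runs the
#' evidence synthesis and loads the resulting effectiveness into the model;
#' executes the model; computes the economic summary; and optionally runs a
#' tornado analysis.  All outputs are written as CSV under
#' `out_dir/<scenario name>/{meta,psa,econ,tornado}/` together with a
#' `manifest.json` recording the seed, model fingerprint, package version
#' and an md5 hash of every output file.  Identical scenario + inputs +
#' seed reproduce the output tree byte for byte.
#'
#' All component seeds derive deterministically from the scenario's
#' `run_options$seed`.
#'
#' @param base_model a [model_definition()].
#' @param scn an [scenario()].
#' @param st,elic optional `ht_studies` / `ht_elicitations` tables for the
#'   evidence layer.
#' @param out_dir output root; `NULL` skips writing files.
#' @param tornado_outcome optional [outcome_inmb()] / [outcome_icer()]
#'   selector triggering a deterministic tornado analysis.
#' @return list of class `scenario_result` with fields `scenario`, `meta`,
#'   `psa`, `econ`, `tornado`, `paths`.
#' @export
run_scenario <- function(base_model, scn, st = NULL, elic = NULL,
                         out_dir = NULL, tornado_outcome = NULL) {
  stopifnot(inherits(base_model, "model_definition"),
            inherits(scn, "ht_scenario"))
  model <- base_model
  unknown <- setdiff(names(scn$parameter_overrides), names(model$parameters))
  if (length(unknown))
    abort("scenario '", scn$name, "' overrides unknown parameter(s): ",
          paste(unknown, collapse = ", "))
  for (nm in names(scn$parameter_overrides))
    model$parameters[[nm]] <- scn$parameter_overrides[[nm]]
  model$fingerprint <- fingerprint(list(
    model$name, lapply(model$parameters, unclass),
    model$strategies, model$treatments, model$outcome_fn))

  ro <- scn$run_options
  meta <- NULL
  if (!is.null(scn$meta_config) && !is.null(st)) {
    cf <- scn$meta_config
    cf$mcmc$seed <- derive_seed(ro$seed, 1L)
    meta <- run_meta(st, elic, cf)
    model <- attach_effectiveness(model, meta, mode = ro$mode)
  }
  psa_opts <- run_options(mode = ro$mode, n_sims = ro$n_sims,
                          seed = derive_seed(ro$seed, 2L),
                          lambda_grid = ro$lambda_grid)
  psa <- run_model(model, psa_opts)
  econ <- econ_summary(psa)
  trn <- if (!is.null(tornado_outcome)) tornado(model, tornado_outcome)

  paths <- NULL
  if (!is.null(out_dir)) {
    root <- file.path(out_dir, scn$name)
    for (d in c("meta", "psa", "econ", "tornado"))
      dir.create(file.path(root, d), recursive = TRUE, showWarnings = FALSE)
    wrote <- character()
    wcsv <- function(df, rel) {
      p <- file.path(root, rel)
      write.csv(df, p, row.names = FALSE)
      wrote <<- c(wrote, p)
    }
    if (!is.null(meta)) {
      wcsv(forest_data(meta), "meta/forest.csv")
      wcsv(data.frame(
        quantity = c("or", "or_lo", "or_hi", "log_or", "tau"),
        adjusted = c(meta$or_point, meta$or_lo, meta$or_hi,
                     meta$mu_point, meta$tau_point),
        unadjusted = c(meta$unadjusted$or_point, meta$unadjusted$or_lo,
                       meta$unadjusted$or_hi, meta$unadjusted$mu_point,
                       meta$unadjusted$tau_point)), "meta/summary.csv")
    }
    export_psa(psa, file.path(root, "psa/draws.csv"),
               file.path(root, "psa/outcomes.csv"))
    wrote <- c(wrote, file.path(root, c("psa/draws.csv", "psa/outcomes.csv")))
    wcsv(econ$means, "econ/summary.csv")
    wcsv(econ$icer_table, "econ/icer.csv")
    wcsv(econ$inmb, "econ/inmb.csv")
    if (!is.null(econ$ceac))
      wcsv(econ$ceac[c("lambda", "strategy", "treatment", "probability")],
           "econ/ceac.csv")
    if (!is.null(trn)) {
      write_tornado(trn, file.path(root, "tornado/tornado.csv"))
      wrote <- c(wrote, file.path(root, "tornado/tornado.csv"))
    }
    manifest <- list(
      scenario = scn$name,
      seed = ro$seed,
      n_sims = ro$n_sims,
      mode = ro$mode,
      model_fingerprint = model$fingerprint,
      package_version = as.character(packageVersion("hteval")),
      files = lapply(sort(wrote), function(p) list(
        path = substring(p, nchar(root) + 2L),
        md5 = unname(tools::md5sum(p))))
    )
    jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(wrote, file.path(root, "manifest.json"))
  }
  structure(list(scenario = scn, meta = meta, psa = psa, econ = econ,
                 tornado = trn, paths = paths),
            class = "scenario_result")
}

#' Verify a scenario output directory against its manifest
#'
#' @param scenario_dir directory written by [run_scenario()].
#' @return `TRUE` if every listed file matches its recorded md5 hash;
#'   otherwise an error naming the first mismatch.
#' @export
verify_manifest <- function(scenario_dir) {
  man <- jsonlite::read_json(file.path(scenario_dir, "manifest.json"))
  for (f in man$files) {
    p <- file.path(scenario_dir, f$path)
    if (!file.exists(p)) abort("manifest file missing: ", f$path)
    if (!identical(unname(tools::md5sum(p)), f$md5))
      abort("manifest hash mismatch: ", f$path)
  }
  TRUE
}

#' Compare scenario results side by side
#'
#' One row per scenario; columns are the selected metrics plus their
#' difference against the first (reference) scenario.
#'
#' @param results list of `scenario_result`s over identical alternative
#'   sets.
#' @param metrics named list of functions mapping a `scenario_result` to a
#'   scalar; default: mean cost and mean QALY of every alternative, plus
#'   the pooled OR where a meta-analysis was run.
#' @return data.frame, one row per scenario, with `d_<metric>` difference
#'   columns.
#' @export
compare_scenarios <- function(results, metrics = NULL) {
  stopifnot(is.list(results), length(results) >= 2,
            all(vapply(results, inherits, logical(1), "scenario_result")))
  alt_sets <- lapply(results, function(r) alternative_ids(r$psa))
  if (!all(vapply(alt_sets, identical, logical(1), alt_sets[[1]])))
    abort("scenario results cover different strategy/treatment sets")
  if (is.null(metrics)) {
    alts <- alt_sets[[1]]
    metrics <- list()
    for (a in alts) {
      metrics[[paste0("cost_", a)]] <- local({
        aa <- a
        function(r) r$econ$means$cost[r$econ$means$alternative == aa]
      })
      metrics[[paste0("qaly_", a)]] <- local({
        aa <- a
        function(r) r$econ$means$qaly[r$econ$means$alternative == aa]
      })
    }
    if (all(vapply(results, function(r) !is.null(r$meta), logical(1))))
      metrics$pooled_or <- function(r) r$meta$or_point
  }
  tab <- data.frame(
    scenario = vapply(results, function(r) r$scenario$name, ""),
    stringsAsFactors = FALSE
  )
  for (nm in names(metrics))
    tab[[nm]] <- vapply(results, metrics[[nm]], numeric(1))
  for (nm in names(metrics))
    tab[[paste0("d_", nm)]] <- tab[[nm]] - tab[[nm]][1]
  tab
}

#' @export
print.ht_scenario <- function(x, ...) {
  cat("<ht_scenario>", x$name, "\n")
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  cat("  overrides:",
      if (length(x$parameter_overrides))
        paste(names(x$parameter_overrides), collapse = ", ") else "none",
      "\n")
  cat("  mode:", x$run_options$mode, "| n_sims:", x$run_options$n_sims,
      "| seed:", x$run_options$seed, "\n")
  invisible(x)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$scenario$name, "\n")
  if (!is.null(x$meta))
    cat(sprintf("  pooled OR: %.4f [%.4f, %.4f]\n",
                x$meta$or_point, x$meta$or_lo, x$meta$or_hi))
  print(x$econ)
  invisible(x)
}
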