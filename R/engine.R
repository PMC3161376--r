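#' Declare one model parameter
#'
#' A parameter has a distribution family and hyperparameters.  Supported
#' families and their hyperparameters:
#' \describe{
#'   \item{point}{`value` (no uncertainty)}
#'   \item{normal}{`mean`, `sd > 0`}
#'   \item{lognormal}{`meanlog`, `sdlog > 0`}
#'   \item{beta}{`shape1 > 0`, `shape2 > 0`}
#'   \item{gamma}{`shape > 0`, `rate > 0`}
#'   \item{uniform}{`min < max`}
#'   \item{empirical}{`samples` (non-empty finite numeric vector), optional
#'     `block`: parameters sharing a block name are drawn jointly by common
#'     row index, preserving their correlation (e.g. posterior draws)}
#' }
#' `low`/`high` optionally override the one-way range used by the influence
#' layer (default: the 2.5th/97.5th distribution quantiles).
#'
#' @param name identifier, unique within a model.
#' @param distribution family name, see above.
#' @param ... hyperparameters for the family.
#' @param low,high optional deterministic-range bounds for tornado analysis.
#' @param description,source free-text provenance notes.
#' @return list of class `parameter_spec`.
#' @export
parameter_spec <- function(name, distribution, ..., low = NULL, high = NULL,
                           description = "", source = "") {
  params <- list(...)
  families <- c("point", "normal", "lognormal", "beta", "gamma",
                "uniform", "empirical")
  if (!distribution %in% families)
    abort("unknown distribution '", distribution, "' for parameter '",
          name, "'")
  chk <- function(cond, msg) if (!cond) abort("parameter '", name, "': ", msg)
  p <- params
  switch(distribution,
    point = chk(is_scalar_num(p$value), "point needs a finite `value`"),
    normal = chk(is_scalar_num(p$mean) && is_scalar_num(p$sd) && p$sd > 0,
                 "normal needs `mean` and `sd > 0`"),
    lognormal = chk(is_scalar_num(p$meanlog) && is_scalar_num(p$sdlog) &&
                    p$sdlog > 0, "lognormal needs `meanlog` and `sdlog > 0`"),
    beta = chk(is_scalar_num(p$shape1) && is_scalar_num(p$shape2) &&
               p$shape1 > 0 && p$shape2 > 0,
               "beta needs `shape1 > 0` and `shape2 > 0`"),
    gamma = chk(is_scalar_num(p$shape) && is_scalar_num(p$rate) &&
                p$shape > 0 && p$rate > 0,
                "gamma needs `shape > 0` and `rate > 0`"),
    uniform = chk(is_scalar_num(p$min) && is_scalar_num(p$max) &&
                  p$min < p$max, "uniform needs `min < max`"),
    empirical = chk(is.numeric(p$samples) && length(p$samples) > 0 &&
                    all(is.finite(p$samples)),
                    "empirical needs a non-empty finite `samples` vector")
  )
  structure(list(name = name, distribution = distribution, params = params,
                 low = low, high = high,
                 description = description, source = source),
            class = "parameter_spec")
}

#' Central value of a parameter
#'
#' The value used in deterministic mode: the distribution MEAN (point value
#' for `point`, sample mean for `empirical`).  Note this differs from the
#' median for skewed families such as lognormal and gamma.
#'
#' @param spec a [parameter_spec()].
#' @return scalar.
#' @export
central_value <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  p <- spec$params
  switch(spec$distribution,
    point = p$value,
    normal = p$mean,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    beta = p$shape1 / (p$shape1 + p$shape2),
    gamma = p$shape / p$rate,
    uniform = (p$min + p$max) / 2,
    empirical = mean(p$samples)
  )
}

# distribution quantile, used for tornado ranges
param_quantile <- function(spec, prob) {
  p <- spec$params
  switch(spec$distribution,
    point = p$value,
    normal = qnorm(prob, p$mean, p$sd),
    lognormal = qlnorm(prob, p$meanlog, p$sdlog),
    beta = qbeta(prob, p$shape1, p$shape2),
    gamma = qgamma(prob, p$shape, rate = p$rate),
    uniform = qunif(prob, p$min, p$max),
    empirical = unname(quantile(p$samples, prob, type = 7))
  )
}

draw_one <- function(spec, n) {
  p <- spec$params
  switch(spec$distribution,
    point = rep(p$value, n),
    normal = rnorm(n, p$mean, p$sd),
    lognormal = rlnorm(n, p$meanlog, p$sdlog),
    beta = rbeta(n, p$shape1, p$shape2),
    gamma = rgamma(n, p$shape, rate = p$rate),
    uniform = runif(n, p$min, p$max),
    empirical = abort("empirical parameters are drawn block-wise")
  )
}

#' Define a decision model
#'
#' A model is an ordered list of parameters, the strategy and treatment sets,
#' and a pure outcome function.  The outcome function receives one complete
#' named list of parameter values and must return a data.frame with one row
#' per (strategy, treatment) pair, columns `strategy`, `treatment`, `cost`,
#' `qaly` and any further named clinical outcomes — the same columns for
#' every strategy, all finite.
#'
#' @param parameters list of [parameter_spec()]s with unique names.
#' @param strategies,treatments data.frames with columns `id`, `label` (a
#'   character vector of ids is promoted).
#' @param outcome_fn the outcome function.
#' @param name short model name used in output metadata.
#' @return list of class `model_definition`.
#' @export
model_definition <- function(parameters, strategies, treatments, outcome_fn,
                             name = "model") {
  stopifnot(is.list(parameters), is.function(outcome_fn))
  as_idtab <- function(x) {
    if (is.character(x)) x <- data.frame(id = x, label = x,
                                         stringsAsFactors = FALSE)
    stopifnot(all(c("id", "label") %in% names(x)))
    x
  }
  nms <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort("parameter names must be unique")
  names(parameters) <- nms
  m <- structure(list(name = name, parameters = parameters,
                      strategies = as_idtab(strategies),
                      treatments = as_idtab(treatments),
                      outcome_fn = outcome_fn),
                 class = "model_definition")
  m$fingerprint <- fingerprint(list(name, lapply(parameters, unclass),
                                    m$strategies, m$treatments, outcome_fn))
  m
}

#' Options of a model run
#'
#' @param mode `"deterministic"` (one evaluation at central values) or
#'   `"stochastic"` (probabilistic sensitivity analysis over `n_sims` seeded
#'   draws).
#' @param n_sims number of simulations in stochastic mode.
#' @param seed integer RNG seed.
#' @param lambda_grid strictly ascending non-negative willingness-to-pay
#'   grid (currency per QALY); default 0 to 50,000 in steps of 500.
#' @return list of class `run_options`.
#' @export
run_options <- function(mode = c("deterministic", "stochastic"),
                        n_sims = 1000, seed = 1L,
                        lambda_grid = seq(0, 50000, by = 500)) {
  mode <- match.arg(mode)
  stopifnot(is_count(n_sims), n_sims >= 1, length(lambda_grid) >= 1,
            all(lambda_grid >= 0), !is.unsorted(lambda_grid, strictly = TRUE))
  structure(list(mode = mode, n_sims = as.integer(n_sims),
                 seed = as.integer(seed), lambda_grid = lambda_grid),
            class = "run_options")
}

#' Draw seeded parameter vectors
#'
#' Every parameter draws from its own RNG substream (derived
#' deterministically from the run seed and the parameter's position), so
#' parameters are sampled independently and replacing one parameter's
#' distribution never perturbs the draws of the others.  Empirical
#' parameters sharing a `block` name are the exception: the block is
#' sampled by one common row index per simulation (with replacement), so
#' whatever joint structure the stored samples carry — e.g. correlated
#' posterior draws — is preserved across the block.
#'
#' @param model a [model_definition()].
#' @param options a [run_options()] (stochastic mode).
#' @return data.frame with `n_sims` rows, one column per parameter, in model
#'   parameter order.
#' @export
draw_parameters <- function(model, options) {
  stopifnot(inherits(model, "model_definition"),
            inherits(options, "run_options"))
  n <- options$n_sims
  specs <- model$parameters
  # group empirical parameters into blocks (solo empiricals = own block)
  block_of <- vapply(specs, function(s) {
    if (s$distribution != "empirical") NA_character_
    else s$params$block %||% s$name
  }, character(1))
  idx <- list()
  for (b in unique(stats::na.omit(block_of))) {
    members <- which(block_of == b)
    lens <- vapply(specs[members], function(s) length(s$params$samples),
                   integer(1))
    if (length(unique(lens)) > 1L)
      abort("empirical block '", b, "': sample vectors of unequal length")
    set.seed(derive_seed(options$seed, 100000L + members[1]))
    idx[[b]] <- sample.int(lens[1], n, replace = TRUE)
  }
  cols <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (s$distribution == "empirical")
      return(s$params$samples[idx[[block_of[[s$name]]]]])
    set.seed(derive_seed(options$seed, 100L + i))
    draw_one(s, n)
  })
  out <- as.data.frame(cols, optional = TRUE)
  names(out) <- names(specs)
  out
}

#' Evaluate a decision model
#'
#' Deterministic mode evaluates the outcome function once at the central
#' (mean) parameter values; stochastic mode evaluates it for each seeded
#' parameter draw.  Results are assembled into a `psa_result` carrying the
#' draws that produced them, so downstream layers can relate outcomes back
#' to inputs.
#'
#' @param model a [model_definition()].
#' @param options a [run_options()].
#' @return list of class `psa_result` with fields `draws` (n_sims x
#'   n_params), `outcomes` (long data.frame: `sim`, `strategy`, `treatment`,
#'   `cost`, `qaly`, clinical outcomes), `outcome_names`, `options`,
#'   `model_fingerprint`.
#' @export
run_model <- function(model, options = run_options()) {
  stopifnot(inherits(model, "model_definition"),
            inherits(options, "run_options"))
  draws <- if (options$mode == "deterministic") {
    cv <- lapply(model$parameters, central_value)
    as.data.frame(cv, optional = TRUE)
  } else {
    draw_parameters(model, options)
  }
  eval_draws(model, draws, options)
}

# evaluate the outcome function over given parameter draws
eval_draws <- function(model, draws, options) {
  n <- nrow(draws)
  key_cols <- c("strategy", "treatment", "cost", "qaly")
  res <- vector("list", n)
  ref_names <- NULL
  for (i in seq_len(n)) {
    out <- model$outcome_fn(as.list(draws[i, , drop = FALSE]))
    if (!is.data.frame(out) || !all(key_cols %in% names(out)))
      abort("outcome_fn must return a data.frame with columns ",
            paste(key_cols, collapse = ", "), " (draw ", i, ")")
    if (is.null(ref_names)) ref_names <- names(out)
    else if (!identical(names(out), ref_names))
      abort("outcome_fn returned inconsistent outcome keys at draw ", i)
    num <- out[setdiff(names(out), c("strategy", "treatment"))]
    if (!all(vapply(num, function(col) all(is.finite(col)), logical(1))))
      abort("outcome_fn returned non-finite values at draw ", i)
    out$sim <- i
    res[[i]] <- out
  }
  outcomes <- as.data.frame(data.table::rbindlist(res))
  outcomes <- outcomes[c("sim", setdiff(names(outcomes), "sim"))]
  structure(list(
    draws = draws, outcomes = outcomes,
    outcome_names = setdiff(ref_names, c("strategy", "treatment")),
    options = options, model_fingerprint = model$fingerprint
  ), class = "psa_result")
}

# alternatives = strategy:treatment combinations, in model order
alternative_ids <- function(psa) {
  unique(paste(psa$outcomes$strategy, psa$outcomes$treatment, sep = ":"))
}

# n_sims x n_alternatives matrix of one outcome
outcome_matrix <- function(psa, outcome) {
  stopifnot(inherits(psa, "psa_result"))
  if (!outcome %in% psa$outcome_names)
    abort("unknown outcome '", outcome, "'")
  oc <- psa$outcomes
  alt <- paste(oc$strategy, oc$treatment, sep = ":")
  levels <- unique(alt)
  m <- matrix(NA_real_, nrow = max(oc$sim), ncol = length(levels),
              dimnames = list(NULL, levels))
  for (a in levels) m[, a] <- oc[[outcome]][alt == a]
  m
}

#' Export a PSA result to CSV
#'
#' Writes one CSV of parameter draws and one of outcomes in long format
#' (`sim,strategy,treatment,outcome,value`).
#'
#' @param psa a `psa_result`.
#' @param draws_path,outcomes_path output file paths.
#' @return invisibly, the two paths.
#' @export
export_psa <- function(psa, draws_path, outcomes_path) {
  stopifnot(inherits(psa, "psa_result"))
  write.csv(psa$draws, draws_path, row.names = FALSE)
  oc <- psa$outcomes
  long <- do.call(rbind, lapply(psa$outcome_names, function(k) {
    data.frame(sim = oc$sim, strategy = oc$strategy,
               treatment = oc$treatment, outcome = k, value = oc[[k]],
               stringsAsFactors = FALSE)
  }))
  write.csv(long, outcomes_path, row.names = FALSE)
  invisible(c(draws_path, outcomes_path))
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> mode =", x$options$mode,
      "| n_sims =", x$options$n_sims,
      "| seed =", x$options$seed, "\n")
  cat("  alternatives:", paste(alternative_ids(x), collapse = ", "), "\n")
  cat("  outcomes:", paste(x$outcome_names, collapse = ", "), "\n")
  invisible(x)
}
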