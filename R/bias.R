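#' Assemble a validated table of bias elicitations
#'
#' One row is one assessor's elicited distribution for one bias acting on one
#' study.  `nature` classifies the bias as `internal` (lack of rigor of the
#' study itself) or `external` (limited relevance to the target question);
#' `action` says whether it shifts the log odds ratio additively or scales
#' the treatment effect proportionally.  For additive biases `mean` is a
#' log-OR shift; for proportional biases it is the multiplicative factor on
#' the effect (and must be non-zero).
#'
#' @param assessor_id,study_id,bias_id character identifiers.
#' @param nature `"internal"` or `"external"`.
#' @param action `"additive"` or `"proportional"`.
#' @param mean elicited mean of the bias distribution.
#' @param variance elicited variance, `>= 0`.
#' @return A `data.frame` of class `ht_elicitations`.
#' @export
elicitations <- function(assessor_id, study_id, bias_id, nature, action,
                         mean, variance) {
  df <- data.frame(
    assessor_id = as.character(assessor_id),
    study_id = as.character(study_id),
    bias_id = as.character(bias_id),
    nature = as.character(nature), action = as.character(action),
    mean = as.numeric(mean), variance = as.numeric(variance),
    stringsAsFactors = FALSE
  )
  if (!all(df$nature %in% c("internal", "external")))
    abort("nature must be 'internal' or 'external'")
  if (!all(df$action %in% c("additive", "proportional")))
    abort("action must be 'additive' or 'proportional'")
  if (any(df$variance < 0)) abort("elicited variance must be >= 0")
  if (any(df$action == "proportional" & df$mean == 0))
    abort("proportional bias mean must be non-zero")
  class(df) <- c("ht_elicitations", "data.frame")
  df
}

#' @rdname read_studies
#' @export
read_elicitations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("assessor_id", "study_id", "bias_id", "nature", "action",
            "mean", "variance")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("elicitations file missing columns: ",
                          paste(miss, collapse = ", "))
  elicitations(df$assessor_id, df$study_id, df$bias_id, df$nature,
               df$action, df$mean, df$variance)
}

#' @rdname read_studies
#' @export
write_elicitations <- function(x, path) {
  stopifnot(inherits(x, "ht_elicitations"))
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Configuration of a meta-analysis run
#'
#' Bundles every interactive choice of the evidence-synthesis layer: which
#' studies to pool, which bias natures (internal/external) and actions
#' (additive/proportional) to adjust for, which assessors' elicitations to
#' include, the synthesis method, MCMC settings and priors.
#'
#' `mcmc$iterations` counts *retained* posterior draws, collected after
#' `mcmc$burn_in` discarded warm-up sweeps.  Default priors are vague:
#' `mu ~ Normal(0, 10^4)` on the pooled log OR and `tau ~ Uniform(0, 5)` on
#' the between-study SD.
#'
#' @param selected_study_ids character vector of study ids to pool, or `NULL`
#'   for all included studies.
#' @param include_internal,include_external adjust for biases of that nature?
#' @param include_additive,include_proportional adjust for biases of that
#'   action?
#' @param selected_assessor_ids assessors whose elicitations enter pooling,
#'   or `NULL` for all.
#' @param method `"dl"` (DerSimonian-Laird) or `"bayes"` (Gibbs sampler).
#' @param mcmc list with `iterations` (retained draws), `burn_in`, `seed`.
#' @param priors list with `mu_mean`, `mu_var` (> 0) and `tau_upper` (>= 0;
#'   0 pins the between-study SD at zero, i.e. a fixed-effect model).
#' @param continuity continuity correction forwarded to [compute_log_or()].
#' @return list of class `meta_config`.
#' @export
meta_config <- function(selected_study_ids = NULL,
                        include_internal = TRUE, include_external = TRUE,
                        include_additive = TRUE, include_proportional = TRUE,
                        selected_assessor_ids = NULL,
                        method = c("dl", "bayes"),
                        mcmc = list(iterations = 5000, burn_in = 1000,
                                    seed = 1L),
                        priors = list(mu_mean = 0, mu_var = 1e4,
                                      tau_upper = 5),
                        continuity = 0.5) {
  method <- match.arg(method)
  mcmc <- modifyList(list(iterations = 5000, burn_in = 1000, seed = 1L), mcmc)
  priors <- modifyList(list(mu_mean = 0, mu_var = 1e4, tau_upper = 5), priors)
  if (mcmc$iterations <= 0 || mcmc$burn_in < 0)
    abort("mcmc settings must satisfy iterations > 0, burn_in >= 0")
  if (mcmc$burn_in >= mcmc$iterations)
    abort("mcmc burn_in must be smaller than the retained iteration count")
  if (priors$mu_var <= 0 || priors$tau_upper < 0)
    abort("priors must satisfy mu_var > 0, tau_upper >= 0")
  structure(list(
    selected_study_ids = selected_study_ids,
    include_internal = isTRUE(include_internal),
    include_external = isTRUE(include_external),
    include_additive = isTRUE(include_additive),
    include_proportional = isTRUE(include_proportional),
    selected_assessor_ids = selected_assessor_ids,
    method = method, mcmc = mcmc, priors = priors,
    continuity = continuity
  ), class = "meta_config")
}

#' Pool bias elicitations over assessors
#'
#' For each retained (study, bias) pair the selected assessors' elicited
#' distributions are combined as an equal-weight mixture: pooled mean
#' `mbar = mean(m_a)` and pooled variance `vbar = mean(v_a + m_a^2) - mbar^2`
#' (the mixture's exact second moment).  Biases whose nature or action is
#' deselected in `config` are dropped entirely; a (study, bias) pair whose
#' assessors are all deselected is dropped with a warning.
#'
#' @param elic an `ht_elicitations` table.
#' @param config a [meta_config()].
#' @return data.frame with one row per pooled (study, bias):
#'   `study_id, bias_id, nature, action, mean, variance, n_assessors`.
#' @export
pool_assessors <- function(elic, config = meta_config()) {
  stopifnot(inherits(elic, "ht_elicitations"))
  keep_nature <- c("internal", "external")[c(config$include_internal,
                                             config$include_external)]
  keep_action <- c("additive", "proportional")[c(config$include_additive,
                                                 config$include_proportional)]
  e <- elic[elic$nature %in% keep_nature & elic$action %in% keep_action, ,
            drop = FALSE]
  empty <- data.frame(study_id = character(), bias_id = character(),
                      nature = character(), action = character(),
                      mean = numeric(), variance = numeric(),
                      n_assessors = integer(), stringsAsFactors = FALSE)
  if (!nrow(e)) return(empty)

  pair_key <- paste(e$study_id, e$bias_id, sep = "\r")
  sel <- if (is.null(config$selected_assessor_ids)) rep(TRUE, nrow(e)) else
    e$assessor_id %in% config$selected_assessor_ids
  lost <- setdiff(unique(pair_key), unique(pair_key[sel]))
  if (length(lost)) {
    ids <- unique(sub("\r", ":", lost))
    warning("no selected assessor elicited bias ", paste(ids, collapse = ", "),
            "; dropped", call. = FALSE)
  }
  e <- e[sel, , drop = FALSE]
  if (!nrow(e)) return(empty)

  pooled <- lapply(split(e, paste(e$study_id, e$bias_id, sep = "\r")),
                   function(g) {
    if (length(unique(g$action)) > 1L || length(unique(g$nature)) > 1L)
      abort("bias '", g$bias_id[1], "' on study '", g$study_id[1],
            "' has inconsistent nature/action across assessors")
    mbar <- mean(g$mean)
    vbar <- mean(g$variance + g$mean^2) - mbar^2
    data.frame(study_id = g$study_id[1], bias_id = g$bias_id[1],
               nature = g$nature[1], action = g$action[1],
               mean = mbar, variance = max(vbar, 0),
               n_assessors = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out[order(out$study_id, out$bias_id), , drop = FALSE]
}

#' Bias-adjust one study's log odds ratio
#'
#' Additive biases combine to a total shift `alpha = sum(means)` with
#' variance `var_alpha = sum(variances)` (independence); proportional biases
#' combine to a factor `pi = prod(means)` with delta-method variance
#' `var_pi = pi^2 * sum(variance / mean^2)`.  The adjusted effect is
#' `y_adj = (y - alpha)/pi` with first-order propagated variance
#' `var_adj = (se^2 + var_alpha)/pi^2 + (y - alpha)^2 * var_pi / pi^4`.
#'
#' @param y,se unadjusted log odds ratio and standard error (`se > 0`).
#' @param additive,proportional data.frames of pooled biases with columns
#'   `mean` and `variance` (as returned by [pool_assessors()]), possibly
#'   zero-row.
#' @param study_id optional id carried through to the result.
#' @return list of class `adjusted_study` with fields `study_id`, `y_adj`,
#'   `var_adj`, `alpha`, `var_alpha`, `pi`, `var_pi`.
#' @export
adjust_study <- function(y, se, additive = NULL, proportional = NULL,
                         study_id = NA_character_) {
  stopifnot(is_scalar_num(y), is_scalar_num(se), se > 0)
  am <- if (is.null(additive)) numeric() else additive$mean
  av <- if (is.null(additive)) numeric() else additive$variance
  pm <- if (is.null(proportional)) numeric() else proportional$mean
  pv <- if (is.null(proportional)) numeric() else proportional$variance
  if (any(pm == 0))
    abort("proportional pooled bias mean of 0: adjustment undefined")
  alpha <- sum(am); var_alpha <- sum(av)
  pi_f <- prod(pm); var_pi <- if (length(pm)) pi_f^2 * sum(pv / pm^2) else 0
  y_adj <- (y - alpha) / pi_f
  var_adj <- (se^2 + var_alpha) / pi_f^2 +
    (y - alpha)^2 * var_pi / pi_f^4
  structure(list(study_id = study_id, y_adj = y_adj, var_adj = var_adj,
                 alpha = alpha, var_alpha = var_alpha,
                 pi = pi_f, var_pi = var_pi),
            class = "adjusted_study")
}
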