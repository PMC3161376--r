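#' Default parameters of the anti-D prophylaxis example model
#'
#' The packaged example mirrors the structure of routine antenatal anti-D
#' prophylaxis (AADP) for RhD-negative pregnant women: an RhD-negative woman
#' carrying an RhD-positive fetus may become sensitized; sensitization risks
#' haemolytic disease of the newborn (HDN) in a subsequent pregnancy, with
#' possible fetal loss.  Prophylaxis lowers the sensitization odds by a
#' single effectiveness odds ratio shared by all four products.  The numbers
#' are openly synthetic fixture choices with realistic magnitudes; they do
#' not reproduce any appraisal's inputs.
#'
#' Fields: `s0` baseline sensitization probability without AADP; `or_eff`
#' odds ratio of sensitization under AADP; `p_prim` proportion
#' primigravidae; `p_subseq` probability of a subsequent RhD-positive
#' pregnancy given sensitization; `p_affected` probability that fetus is
#' affected by HDN; `p_loss` probability of fetal loss given affected;
#' `q_affected`, `q_loss` QALY losses per affected fetus / per loss;
#' `ly_loss` life-years lost per fetal loss; `d_eff`, `d_cost` annual
#' discount rates; `t_lag` years to the subsequent pregnancy; `n_doses`
#' doses per covered pregnancy; `c_dose` named per-treatment cost per dose;
#' `c_admin` administration cost per dose; `c_sens` lifetime management cost
#' per sensitized woman; `c_hdn` cost per affected fetus; `cohort` women per
#' run.
#'
#' @param ... overrides of the defaults by name.
#' @return named list of class `antid_parameters`.
#' @export
antid_parameters <- function(...) {
  p <- list(
    s0 = 0.0095, or_eff = 0.4, p_prim = 0.4, p_subseq = 0.7,
    p_affected = 0.6, p_loss = 0.05, q_affected = 2, q_loss = 25,
    ly_loss = 75, d_eff = 0.035, d_cost = 0.035, t_lag = 2, n_doses = 2,
    c_dose = c(partobulin = 27.5, dgam = 25, rhophylac = 32, winrho = 30),
    c_admin = 5, c_sens = 2900, c_hdn = 15000, cohort = 100000
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    abort("unknown anti-D parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  probs <- c("s0", "p_prim", "p_subseq", "p_affected", "p_loss")
  for (nm in probs)
    if (p[[nm]] <= 0 || p[[nm]] >= 1)
      abort("parameter '", nm, "' must lie in (0, 1)")
  if (p$or_eff <= 0) abort("or_eff must be > 0")
  if (p$d_eff < 0 || p$d_eff >= 1 || p$d_cost < 0 || p$d_cost >= 1)
    abort("discount rates must lie in [0, 1)")
  nonneg <- c("q_affected", "q_loss", "ly_loss", "c_admin", "c_sens",
              "c_hdn")
  for (nm in nonneg)
    if (p[[nm]] < 0) abort("parameter '", nm, "' must be >= 0")
  if (any(p$c_dose < 0)) abort("c_dose must be >= 0")
  if (p$t_lag <= 0) abort("t_lag must be > 0")
  if (!is_count(p$n_doses) || p$n_doses < 1) abort("n_doses must be a positive integer")
  if (!is_count(p$cohort) || p$cohort < 1) abort("cohort must be a positive integer")
  structure(p, class = "antid_parameters")
}

#' Clinical and economic outcomes of the anti-D example model
#'
#' Three strategies — s1: conventional management (no AADP), s2: AADP to
#' primigravidae only, s3: AADP to all RhD-negative pregnant women — give
#' coverages `cov = 0, p_prim, 1`.  The sensitization probability under
#' prophylaxis is `expit(logit(s0) + log(or_eff))`; sensitizations, affected
#' fetuses (discounted to the subsequent pregnancy at `t_lag` years) and
#' fetal losses cascade from it.  QALYs and life-years are reported as
#' negative losses so that "more is better" holds uniformly downstream.
#' Costs comprise prophylaxis doses, lifetime management of sensitized women
#' and HDN management, the latter two discounted at `d_cost`.
#'
#' @param params an [antid_parameters()] list.
#' @param treatments treatment ids to evaluate (default: those named in
#'   `params$c_dose`).
#' @return data.frame with one row per (strategy, treatment): `strategy`,
#'   `treatment`, `cost`, `qaly`, `ly`, `sensitizations`, `affected`,
#'   `losses`.
#' @export
antid_outcomes <- function(params = antid_parameters(),
                           treatments = names(params$c_dose)) {
  p <- params
  unknown <- setdiff(treatments, names(p$c_dose))
  if (length(unknown))
    abort("unknown treatment id(s): ", paste(unknown, collapse = ", "))
  cov <- c(s1 = 0, s2 = p$p_prim, s3 = 1)
  p_treated <- plogis(qlogis(p$s0) + log(p$or_eff))
  delta_e <- (1 + p$d_eff)^(-p$t_lag)
  delta_c <- (1 + p$d_cost)^(-p$t_lag)
  rows <- lapply(names(cov), function(s) {
    sens <- p$cohort * (cov[[s]] * p_treated + (1 - cov[[s]]) * p$s0)
    affected <- sens * p$p_subseq * p$p_affected * delta_e
    lost <- affected * p$p_loss
    qaly_loss <- affected * p$q_affected + lost * p$q_loss
    ly_lost <- lost * p$ly_loss
    data.frame(
      strategy = s, treatment = treatments,
      cost = p$cohort * cov[[s]] * p$n_doses *
        (unname(p$c_dose[treatments]) + p$c_admin) +
        sens * p$c_sens * delta_c + affected * p$c_hdn * delta_c,
      qaly = -qaly_loss, ly = -ly_lost,
      sensitizations = sens, affected = affected, losses = lost,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The anti-D example as an engine model definition
#'
#' Wraps [antid_outcomes()] in a [model_definition()] whose parameter
#' distributions have MEANS equal to the [antid_parameters()] defaults, so
#' the deterministic run reproduces the documented default arithmetic
#' exactly.  Spreads (fixture choices): beta distributions for
#' probabilities, gamma for costs and QALY losses, lognormal for the
#' effectiveness OR, uniform 0-7% for the effectiveness discount rate;
#' structural quantities (`t_lag`, doses, cohort, unit administration cost,
#' life-years per loss, cost discount rate) are point masses.
#'
#' @return a `model_definition` with strategies s1-s3 and treatments
#'   partobulin, dgam, rhophylac, winrho.
#' @export
antid_model <- function() {
  d <- antid_parameters()
  sdlog <- 0.25
  pars <- list(
    parameter_spec("s0", "beta", shape1 = 9.5, shape2 = 990.5,
                   description = "baseline sensitization probability"),
    parameter_spec("or_eff", "lognormal",
                   meanlog = log(d$or_eff) - sdlog^2 / 2, sdlog = sdlog,
                   description = "effectiveness odds ratio (all products)"),
    parameter_spec("p_prim", "beta", shape1 = 40, shape2 = 60,
                   description = "proportion primigravidae"),
    parameter_spec("p_subseq", "beta", shape1 = 70, shape2 = 30,
                   description = "subsequent RhD+ pregnancy | sensitized"),
    parameter_spec("p_affected", "beta", shape1 = 60, shape2 = 40,
                   description = "fetus affected by HDN | sensitized"),
    parameter_spec("p_loss", "beta", shape1 = 5, shape2 = 95,
                   description = "fetal loss | affected"),
    parameter_spec("q_affected", "gamma", shape = 16, rate = 8,
                   description = "QALY loss per affected fetus"),
    parameter_spec("q_loss", "gamma", shape = 25, rate = 1,
                   description = "QALY loss per fetal loss"),
    parameter_spec("ly_loss", "point", value = d$ly_loss),
    parameter_spec("d_eff", "uniform", min = 0, max = 0.07,
                   description = "annual discount rate, effects"),
    parameter_spec("d_cost", "point", value = d$d_cost),
    parameter_spec("t_lag", "point", value = d$t_lag),
    parameter_spec("n_doses", "point", value = d$n_doses),
    parameter_spec("c_dose_partobulin", "point", value = d$c_dose[["partobulin"]]),
    parameter_spec("c_dose_dgam", "point", value = d$c_dose[["dgam"]]),
    parameter_spec("c_dose_rhophylac", "point", value = d$c_dose[["rhophylac"]]),
    parameter_spec("c_dose_winrho", "point", value = d$c_dose[["winrho"]]),
    parameter_spec("c_admin", "point", value = d$c_admin),
    parameter_spec("c_sens", "gamma", shape = 100, rate = 100 / d$c_sens,
                   description = "lifetime cost per sensitized woman"),
    parameter_spec("c_hdn", "gamma", shape = 25, rate = 25 / d$c_hdn,
                   description = "cost per affected fetus"),
    parameter_spec("cohort", "point", value = d$cohort)
  )
  model_definition(
    parameters = pars,
    strategies = data.frame(
      id = c("s1", "s2", "s3"),
      label = c("Conventional management", "AADP to primigravidae",
                "AADP to all RhD-negative women"),
      stringsAsFactors = FALSE),
    treatments = data.frame(
      id = c("partobulin", "dgam", "rhophylac", "winrho"),
      label = c("Partobulin", "D-Gam", "Rhophylac", "WinRho"),
      stringsAsFactors = FALSE),
    outcome_fn = antid_outcome_fn,
    name = "antid"
  )
}

# outcome function of the anti-D model: flat engine parameters -> outcomes
antid_outcome_fn <- function(pars) {
  ap <- antid_parameters(
    s0 = pars$s0, or_eff = pars$or_eff, p_prim = pars$p_prim,
    p_subseq = pars$p_subseq, p_affected = pars$p_affected,
    p_loss = pars$p_loss, q_affected = pars$q_affected,
    q_loss = pars$q_loss, ly_loss = pars$ly_loss,
    d_eff = pars$d_eff, d_cost = pars$d_cost, t_lag = pars$t_lag,
    n_doses = pars$n_doses,
    c_dose = c(partobulin = pars$c_dose_partobulin,
               dgam = pars$c_dose_dgam,
               rhophylac = pars$c_dose_rhophylac,
               winrho = pars$c_dose_winrho),
    c_admin = pars$c_admin, c_sens = pars$c_sens, c_hdn = pars$c_hdn,
    cohort = pars$cohort
  )
  antid_outcomes(ap)
}

#' Load a synthesized effectiveness estimate into a model
#'
#' Replaces the model's `or_eff` parameter with the result of a meta-analysis
#' run.  For a Bayesian result with posterior draws and `mode =
#' "stochastic"`, the exponentiated `mu` draws are registered as an empirical
#' parameter so the full posterior uncertainty (and any correlation with
#' other members of the same block) propagates into the PSA.  For a DL
#' result in stochastic mode, `or_eff` becomes lognormal with `meanlog` at
#' the DL point and `sdlog` at its standard error, with a notice.  In
#' deterministic mode the parameter becomes a point mass at the handoff
#' value ([handoff_or()]).
#'
#' @param model a [model_definition()] containing a parameter named
#'   `or_eff`.
#' @param meta_result a `meta_result` from [run_meta()].
#' @param mode `"deterministic"` or `"stochastic"`.
#' @return the modified `model_definition` (fingerprint updated).
#' @export
attach_effectiveness <- function(model, meta_result,
                                 mode = c("stochastic", "deterministic")) {
  stopifnot(inherits(model, "model_definition"),
            inherits(meta_result, "meta_result"))
  mode <- match.arg(mode)
  if (!"or_eff" %in% names(model$parameters))
    abort("model has no 'or_eff' parameter to attach effectiveness to")
  spec <- if (mode == "deterministic") {
    parameter_spec("or_eff", "point", value = handoff_or(meta_result),
                   source = "meta-analysis handoff (point)")
  } else if (!is.null(meta_result$mu_samples)) {
    parameter_spec("or_eff", "empirical",
                   samples = exp(meta_result$mu_samples),
                   source = "meta-analysis posterior draws")
  } else {
    message("DL result in stochastic mode: or_eff set lognormal(mu, SE)")
    se <- (meta_result$mu_hi - meta_result$mu_lo) / (2 * 1.96)
    parameter_spec("or_eff", "lognormal", meanlog = meta_result$mu_point,
                   sdlog = se, source = "meta-analysis DL estimate")
  }
  model$parameters[["or_eff"]] <- spec
  model$fingerprint <- fingerprint(list(
    model$name, lapply(model$parameters, unclass),
    model$strategies, model$treatments, model$outcome_fn))
  model
}
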