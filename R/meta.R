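#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments synthesis on the log odds ratio scale.  With
#' fixed-effect weights `w_i = 1/var_i` and `Q = sum w_i (y_i - yhat_FE)^2`,
#' the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; the pooled mean
#' uses random-effects weights `w*_i = 1/(var_i + tau2)` and its 95% interval
#' is `point +/- 1.96 / sqrt(sum w*)`.
#'
#' @param y numeric vector of study log odds ratios.
#' @param v numeric vector of their variances (`> 0`).
#' @param study_id optional ids for the per-study table.
#' @return list of class `meta_result`; see [run_meta()] for the fields.
#' @export
dl_meta <- function(y, v, study_id = NULL) {
  k <- length(y)
  if (k < 1L) abort("dl_meta needs at least one study")
  stopifnot(length(v) == k, all(is.finite(y)), all(is.finite(v)), all(v > 0))
  if (is.null(study_id)) study_id <- paste0("S", seq_len(k))
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  tau2 <- if (k == 1L) 0 else {
    q <- sum(w * (y - y_fe)^2)
    denom <- sum(w) - sum(w^2) / sum(w)
    max(0, (q - (k - 1)) / denom)
  }
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se_mu <- 1 / sqrt(sum(ws))
  new_meta_result(
    method = "dl", study_id = study_id, y = y, v = v,
    weights = ws / sum(ws),
    mu_point = mu, mu_lo = mu - 1.96 * se_mu, mu_hi = mu + 1.96 * se_mu,
    tau_point = sqrt(tau2), mu_samples = NULL, tau_samples = NULL
  )
}

#' Bayesian random-effects meta-analysis by Gibbs sampling
#'
#' Normal-normal hierarchical model: `y_i ~ N(theta_i, v_i)`,
#' `theta_i ~ N(mu, tau^2)`, `mu ~ N(mu_mean, mu_var)`,
#' `tau ~ Uniform(0, tau_upper)`.  `theta_i` and `mu` have conjugate normal
#' full conditionals; `tau` is updated by slice sampling (stepping-out with a
#' fixed cap of 50 expansion steps per side, then shrinkage).  Reported
#' points are posterior medians with central 95% credible intervals, and the
#' retained `mu` draws are kept for downstream use as an empirical
#' effectiveness block.
#'
#' `tau_upper = 0` pins the between-study SD at zero; the hierarchy then
#' collapses to `y_i ~ N(mu, v_i)` and `mu` is drawn iid from its conjugate
#' posterior (the theta-based chain freezes in that limit, so the collapsed
#' sampler is the correct one, not a shortcut).  A single study likewise
#' fixes `tau = 0` with a warning.
#'
#' @param y,v study log odds ratios and variances.
#' @param config a [meta_config()]; `mcmc` and `priors` are honoured,
#'   `method` is ignored.
#' @param study_id optional ids.
#' @return list of class `meta_result` with `mu_samples` attached.
#' @export
bayes_meta <- function(y, v, config = meta_config(method = "bayes"),
                       study_id = NULL) {
  k <- length(y)
  if (k < 1L) abort("bayes_meta needs at least one study")
  stopifnot(length(v) == k, all(is.finite(y)), all(is.finite(v)), all(v > 0))
  if (is.null(study_id)) study_id <- paste0("S", seq_len(k))
  mc <- config$mcmc; pr <- config$priors
  if (mc$iterations <= 0) abort("mcmc iterations must be positive")
  n_keep <- as.integer(mc$iterations)
  n_burn <- as.integer(mc$burn_in)
  set.seed(as.integer(mc$seed))

  tau_upper <- pr$tau_upper
  if (k == 1L && tau_upper > 0) {
    warning("single study: between-study SD fixed at 0", call. = FALSE)
    tau_upper <- 0
  }

  if (tau_upper == 0) {
    # collapsed fixed-effect model: conjugate posterior, iid draws
    prec <- sum(1 / v) + 1 / pr$mu_var
    mean_post <- (sum(y / v) + pr$mu_mean / pr$mu_var) / prec
    mu_draws <- rnorm(n_keep, mean_post, sqrt(1 / prec))
    tau_draws <- rep(0, n_keep)
  } else {
    mu_draws <- numeric(n_keep)
    tau_draws <- numeric(n_keep)
    w0 <- 1 / v
    mu <- sum(w0 * y) / sum(w0)
    tau <- tau_upper / 2
    theta <- y
    total <- n_burn + n_keep
    for (it in seq_len(total)) {
      tau2 <- tau^2
      prec_i <- 1 / v + 1 / tau2
      theta <- rnorm(k, (y / v + mu / tau2) / prec_i, sqrt(1 / prec_i))
      prec_mu <- k / tau2 + 1 / pr$mu_var
      mu <- rnorm(1, (sum(theta) / tau2 + pr$mu_mean / pr$mu_var) / prec_mu,
                  sqrt(1 / prec_mu))
      tau <- slice_tau(tau, sum((theta - mu)^2), k, tau_upper)
      if (it > n_burn) {
        mu_draws[it - n_burn] <- mu
        tau_draws[it - n_burn] <- tau
      }
    }
  }

  ci <- unname(quantile(mu_draws, c(0.025, 0.975), type = 7))
  tau_med <- median(tau_draws)
  ws <- 1 / (v + tau_med^2)
  new_meta_result(
    method = "bayes", study_id = study_id, y = y, v = v,
    weights = ws / sum(ws),
    mu_point = median(mu_draws), mu_lo = ci[1], mu_hi = ci[2],
    tau_point = tau_med, mu_samples = mu_draws, tau_samples = tau_draws
  )
}

# slice sampler for tau | theta, mu on (0, upper]
# target: f(tau) propto tau^(-k) exp(-S / (2 tau^2))
slice_tau <- function(tau0, S, k, upper, width = upper / 20,
                      max_steps = 50L) {
  logf <- function(t) {
    if (t <= 0 || t > upper) return(-Inf)
    -k * log(t) - S / (2 * t^2)
  }
  ly <- logf(tau0) - rexp(1)
  if (!is.finite(ly)) abort("tau slice bracket failure: degenerate state")
  # stepping-out, capped
  lo <- tau0 - width * runif(1)
  hi <- lo + width
  j <- floor(max_steps * runif(1))
  m <- max_steps - 1L - j
  while (j > 0 && lo > 0 && logf(lo) > ly) { lo <- lo - width; j <- j - 1 }
  while (m > 0 && hi < upper && logf(hi) > ly) { hi <- hi + width; m <- m - 1 }
  lo <- max(lo, 0); hi <- min(hi, upper)
  # shrinkage
  for (i in 1:1000) {
    t1 <- runif(1, lo, hi)
    if (logf(t1) >= ly) return(t1)
    if (t1 < tau0) lo <- t1 else hi <- t1
  }
  abort("tau slice bracket failure: shrinkage did not terminate")
}

new_meta_result <- function(method, study_id, y, v, weights,
                            mu_point, mu_lo, mu_hi, tau_point,
                            mu_samples, tau_samples,
                            adjusted = NULL, unadjusted = NULL) {
  per_study <- data.frame(
    study_id = study_id, y_adj = y, var_adj = v,
    lo = y - 1.96 * sqrt(v), hi = y + 1.96 * sqrt(v),
    weight = weights, stringsAsFactors = FALSE
  )
  structure(list(
    method = method, per_study = per_study,
    mu_point = mu_point, mu_lo = mu_lo, mu_hi = mu_hi,
    tau_point = tau_point,
    or_point = exp(mu_point), or_lo = exp(mu_lo), or_hi = exp(mu_hi),
    mu_samples = mu_samples, tau_samples = tau_samples,
    adjustment = adjusted, unadjusted = unadjusted
  ), class = "meta_result")
}

#' Run the full evidence-synthesis pipeline
#'
#' Composes study subsetting, conversion of 2x2 counts to log odds ratios,
#' assessor pooling, per-study bias adjustment and synthesis by the method in
#' `config` (`"dl"` or `"bayes"`).  The unadjusted synthesis on the same
#' study subset is always computed alongside and attached as `$unadjusted`
#' (the "grayed-out" companion for forest plots); for the Bayesian method it
#' re-uses the same seed so that turning every bias toggle off reproduces the
#' unadjusted result bit for bit.
#'
#' @param st an `ht_studies` table.
#' @param elic an `ht_elicitations` table, or `NULL` for no adjustment.
#' @param config a [meta_config()].
#' @return list of class `meta_result`: `per_study` (adjusted effects,
#'   variances, intervals, normalized weights), `mu_point`/`mu_lo`/`mu_hi`
#'   (pooled log OR and 95% interval), `tau_point` (between-study SD),
#'   `or_point`/`or_lo`/`or_hi`, `mu_samples` (Bayesian mode only),
#'   `adjustment` (per-study alpha/pi decomposition) and `unadjusted`
#'   (companion result without bias adjustment).
#' @export
run_meta <- function(st, elic = NULL, config = meta_config()) {
  stopifnot(inherits(st, "ht_studies"), inherits(config, "meta_config"))
  sel <- st[st$included, , drop = FALSE]
  if (!is.null(config$selected_study_ids)) {
    unknown <- setdiff(config$selected_study_ids, st$id)
    if (length(unknown))
      abort("unknown study id(s): ", paste(unknown, collapse = ", "))
    sel <- sel[sel$id %in% config$selected_study_ids, , drop = FALSE]
  }
  if (!nrow(sel)) abort("no studies selected")
  eff <- study_effects(sel, config$continuity)

  pooled <- if (is.null(elic)) NULL else {
    if (!all(elic$study_id %in% st$id))
      abort("elicitation references unknown study id(s): ",
            paste(setdiff(elic$study_id, st$id), collapse = ", "))
    pool_assessors(elic, config)
  }

  adj <- lapply(seq_len(nrow(eff)), function(i) {
    b <- if (is.null(pooled) || !nrow(pooled)) NULL else
      pooled[pooled$study_id == eff$study_id[i], , drop = FALSE]
    adjust_study(eff$y[i], eff$se[i],
                 additive = if (!is.null(b)) b[b$action == "additive", ],
                 proportional = if (!is.null(b)) b[b$action == "proportional", ],
                 study_id = eff$study_id[i])
  })
  y_adj <- vapply(adj, `[[`, numeric(1), "y_adj")
  v_adj <- vapply(adj, `[[`, numeric(1), "var_adj")

  fit <- function(yy, vv) {
    if (config$method == "dl") dl_meta(yy, vv, eff$study_id)
    else bayes_meta(yy, vv, config, eff$study_id)
  }
  res <- fit(y_adj, v_adj)
  res$unadjusted <- fit(eff$y, eff$se^2)
  res$adjustment <- data.frame(
    study_id = eff$study_id,
    alpha = vapply(adj, `[[`, numeric(1), "alpha"),
    var_alpha = vapply(adj, `[[`, numeric(1), "var_alpha"),
    pi = vapply(adj, `[[`, numeric(1), "pi"),
    var_pi = vapply(adj, `[[`, numeric(1), "var_pi"),
    stringsAsFactors = FALSE
  )
  res
}

#' Effectiveness handoff value of a synthesis
#'
#' The single odds ratio loaded into a decision model in deterministic mode:
#' the exponentiated DL point estimate for `method = "dl"`, the posterior
#' median OR for `method = "bayes"`.
#'
#' @param result a `meta_result`.
#' @return scalar odds ratio.
#' @export
handoff_or <- function(result) {
  stopifnot(inherits(result, "meta_result"))
  result$or_point
}

#' Forest-plot table of a synthesis
#'
#' Per-study rows (OR point, 95% interval, normalized weight share) plus a
#' pooled row, in both the adjusted and the unadjusted companion variant.
#'
#' @param result a `meta_result` from [run_meta()].
#' @return data.frame with columns `row, study_id, variant, or, lo, hi,
#'   weight` (`weight` is `NA` on pooled rows and sums to 1 across studies
#'   within a variant).
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "meta_result"))
  one <- function(r, variant) {
    ps <- r$per_study
    rbind(
      data.frame(row = ps$study_id, study_id = ps$study_id,
                 variant = variant, or = exp(ps$y_adj),
                 lo = exp(ps$lo), hi = exp(ps$hi),
                 weight = ps$weight, stringsAsFactors = FALSE),
      data.frame(row = "pooled", study_id = NA_character_,
                 variant = variant, or = r$or_point,
                 lo = r$or_lo, hi = r$or_hi, weight = NA_real_,
                 stringsAsFactors = FALSE)
    )
  }
  out <- one(result, "adjusted")
  if (!is.null(result$unadjusted))
    out <- rbind(out, one(result$unadjusted, "unadjusted"))
  rownames(out) <- NULL
  out
}

#' Forest plot with grayed-out unadjusted overlay
#'
#' @param result a `meta_result`.
#' @return a ggplot object.
#' @export
plot_forest <- function(result) {
  fd <- forest_data(result)
  fd$row <- factor(fd$row, levels = rev(unique(fd$row)))
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$or, y = .data$row,
                                   colour = .data$variant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(adjusted = "black",
                                            unadjusted = "grey60")) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.meta_result <- function(x, ...) {
  cat("<meta_result> method =", x$method, "\n")
  cat(sprintf("  pooled OR %.4f  [%.4f, %.4f]   tau = %.4f\n",
              x$or_point, x$or_lo, x$or_hi, x$tau_point))
  cat(sprintf("  pooled log OR %.4f  [%.4f, %.4f]\n",
              x$mu_point, x$mu_lo, x$mu_hi))
  if (!is.null(x$unadjusted))
    cat(sprintf("  unadjusted companion OR %.4f  [%.4f, %.4f]\n",
                x$unadjusted$or_point, x$unadjusted$or_lo,
                x$unadjusted$or_hi))
  cat(" ", nrow(x$per_study), "studies\n")
  invisible(x)
}
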