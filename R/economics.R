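# split "strategy:treatment" alternative ids
split_alt <- function(a) {
  parts <- strsplit(a, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) abort("alternative must be 'strategy:treatment'")
  parts
}

# per-draw vectors of one outcome for one alternative
alt_vector <- function(psa, alt, outcome) {
  m <- outcome_matrix(psa, outcome)
  if (!alt %in% colnames(m)) abort("unknown alternative '", alt, "'")
  m[, alt]
}

#' Incremental net monetary benefit
#'
#' Per draw, `INMB = lambda * (E_a - E_b) - (C_a - C_b)` with effects `E`
#' taken from the `qaly` outcome and costs `C` from `cost`.  The interval is
#' the empirical 2.5/97.5 percentile range of the per-draw values.
#'
#' @param psa a `psa_result`.
#' @param a,b alternative ids, `"strategy:treatment"`.
#' @param lambda willingness to pay per QALY, `>= 0`.
#' @return list with `mean`, `lo`, `hi` and the per-draw vector `draws`.
#' @export
inmb <- function(psa, a, b, lambda) {
  stopifnot(inherits(psa, "psa_result"))
  if (lambda < 0) abort("lambda must be >= 0")
  de <- alt_vector(psa, a, "qaly") - alt_vector(psa, b, "qaly")
  dc <- alt_vector(psa, a, "cost") - alt_vector(psa, b, "cost")
  x <- lambda * de - dc
  ci <- unname(quantile(x, c(0.025, 0.975), type = 7))
  list(mean = mean(x), lo = ci[1], hi = ci[2], draws = x)
}

#' ICER efficiency frontier with dominance and extended dominance
#'
#' Alternatives are sorted by ascending mean cost (ties by descending
#' effect).  An alternative is *dominated* if some other alternative costs
#' no more and yields at least as much effect (equal cost and effect keeps
#' the first-listed alternative).  Among the survivors, an alternative is
#' *extendedly dominated* when the incremental cost-effectiveness ratio of
#' the step reaching it exceeds that of the next step; such alternatives are
#' removed iteratively until the frontier ICERs are strictly increasing.
#'
#' @param mean_costs,mean_effects named numeric vectors over alternatives
#'   (equal names).
#' @return data.frame `alternative, cost, effect, status, icer` where
#'   `status` is one of `frontier`, `dominated`, `extendedly_dominated` and
#'   `icer` is the per-step ratio along the frontier (`NA` on the cheapest
#'   frontier point and on excluded rows).
#' @export
frontier <- function(mean_costs, mean_effects) {
  stopifnot(length(mean_costs) == length(mean_effects),
            length(mean_costs) >= 1,
            all(is.finite(mean_costs)), all(is.finite(mean_effects)))
  alts <- names(mean_costs) %||% paste0("alt", seq_along(mean_costs))
  if (is.null(names(mean_effects))) names(mean_effects) <- alts
  mean_effects <- mean_effects[alts]

  status <- setNames(rep("frontier", length(alts)), alts)
  # simple dominance (first-listed wins exact ties)
  for (i in seq_along(alts)) for (j in seq_along(alts)) {
    if (i == j) next
    ci <- mean_costs[i]; cj <- mean_costs[j]
    ei <- mean_effects[i]; ej <- mean_effects[j]
    if (cj <= ci && ej >= ei && (cj < ci || ej > ei || j < i)) {
      status[i] <- "dominated"
      break
    }
  }
  live <- alts[status == "frontier"]
  ord <- order(mean_costs[live], -mean_effects[live])
  live <- live[ord]
  # extended dominance: drop interior points until ICERs strictly increase
  repeat {
    if (length(live) < 3L) break
    ic <- diff(mean_costs[live]) / diff(mean_effects[live])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    status[live[bad[1] + 1L]] <- "extendedly_dominated"
    live <- live[-(bad[1] + 1L)]
  }
  icer <- setNames(rep(NA_real_, length(alts)), alts)
  if (length(live) > 1L)
    icer[live[-1]] <- diff(mean_costs[live]) / diff(mean_effects[live])
  out <- data.frame(
    alternative = alts, cost = unname(mean_costs[alts]),
    effect = unname(mean_effects[alts]), status = unname(status[alts]),
    icer = unname(icer[alts]), stringsAsFactors = FALSE
  )
  out[order(out$cost, -out$effect), , drop = FALSE]
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, each alternative's probability of being
#' cost-effective is the fraction of draws in which its net monetary benefit
#' `lambda * E - C` is maximal; exact ties share the draw equally among the
#' tied set, so probabilities sum to 1 by construction.
#'
#' @param psa a stochastic `psa_result` with `n_sims >= 2`.
#' @param lambda_grid ascending non-negative willingness-to-pay values
#'   (default: the grid stored in the run options).
#' @return data.frame in long format: `lambda, strategy, treatment,
#'   alternative, probability`.
#' @export
ceac <- function(psa, lambda_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (psa$options$mode != "stochastic" || psa$options$n_sims < 2)
    abort("ceac needs a stochastic run with n_sims >= 2")
  lambda_grid <- lambda_grid %||% psa$options$lambda_grid
  E <- outcome_matrix(psa, "qaly")
  C <- outcome_matrix(psa, "cost")
  alts <- colnames(E)
  res <- lapply(lambda_grid, function(l) {
    nmb <- l * E - C
    best <- nmb == matrixStats_rowMaxs(nmb)
    share <- best / rowSums(best)
    data.frame(lambda = l,
               strategy = vapply(alts, function(a) split_alt(a)[1], ""),
               treatment = vapply(alts, function(a) split_alt(a)[2], ""),
               alternative = alts,
               probability = colMeans(share),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# row maxima without an extra dependency
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))

#' Incremental clinical outcomes and cost per unit
#'
#' For every clinical (non-cost, non-qaly) outcome `k`, reports
#' `delta_k = mean_k(a) - mean_k(b)` and the cost per unit
#' `delta_cost / |delta_k|`, computed from means of draws (not per-draw
#' ratios).  Ratios with `|delta_k| <= eps` are flagged undefined rather
#' than reported.
#'
#' @param psa a `psa_result`.
#' @param a,b distinct alternative ids.
#' @param eps threshold below which a delta is treated as zero (default
#'   1e-9).
#' @return data.frame `outcome, delta, cost_per_unit, defined`.
#' @export
incremental_clinical <- function(psa, a, b, eps = 1e-9) {
  stopifnot(inherits(psa, "psa_result"))
  if (identical(a, b)) abort("a and b must differ")
  dcost <- mean(alt_vector(psa, a, "cost")) - mean(alt_vector(psa, b, "cost"))
  clin <- setdiff(psa$outcome_names, c("cost"))
  rows <- lapply(clin, function(k) {
    dk <- mean(alt_vector(psa, a, k)) - mean(alt_vector(psa, b, k))
    defined <- abs(dk) > eps
    data.frame(outcome = k, delta = dk,
               cost_per_unit = if (defined) dcost / abs(dk) else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Economic summary of a PSA run
#'
#' Bundles per-alternative mean costs and effects, incrementals against a
#' comparator, mean INMB with 95% intervals over the willingness-to-pay
#' grid, the ICER frontier on mean costs/effects, and (stochastic runs) the
#' acceptability curves.
#'
#' @param psa a `psa_result`.
#' @param comparator alternative id differences are taken against (default:
#'   the first alternative).
#' @param lambda_grid willingness-to-pay grid (default: from the run
#'   options).
#' @return list of class `econ_summary` with fields `comparator`, `means`,
#'   `inmb`, `icer_table`, `ceac` (NULL for deterministic runs).
#' @export
econ_summary <- function(psa, comparator = NULL, lambda_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  lambda_grid <- lambda_grid %||% psa$options$lambda_grid
  alts <- alternative_ids(psa)
  comparator <- comparator %||% alts[1]
  if (!comparator %in% alts) abort("unknown comparator '", comparator, "'")
  C <- outcome_matrix(psa, "cost"); E <- outcome_matrix(psa, "qaly")
  means <- data.frame(
    alternative = alts,
    cost = colMeans(C)[alts], qaly = colMeans(E)[alts],
    d_cost = colMeans(C)[alts] - mean(C[, comparator]),
    d_qaly = colMeans(E)[alts] - mean(E[, comparator]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (k in setdiff(psa$outcome_names, c("cost", "qaly"))) {
    M <- outcome_matrix(psa, k)
    means[[paste0("d_", k)]] <- colMeans(M)[alts] - mean(M[, comparator])
  }
  dE <- E - E[, comparator]; dC <- C - C[, comparator]
  inmb_rows <- lapply(lambda_grid, function(l) {
    x <- l * dE - dC
    ci <- apply(x, 2, quantile, probs = c(0.025, 0.975), type = 7)
    data.frame(lambda = l, alternative = alts,
               mean = colMeans(x)[alts],
               lo = ci[1, alts], hi = ci[2, alts],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(list(
    comparator = comparator,
    means = means,
    inmb = do.call(rbind, inmb_rows),
    icer_table = frontier(setNames(means$cost, alts),
                          setNames(means$qaly, alts)),
    ceac = if (psa$options$mode == "stochastic" && psa$options$n_sims >= 2)
      ceac(psa, lambda_grid) else NULL
  ), class = "econ_summary")
}

#' Acceptability-curve plot
#'
#' @param ceac_table the long table from [ceac()] (or `$ceac` of an
#'   [econ_summary()]).
#' @return a ggplot object.
#' @export
plot_ceac <- function(ceac_table) {
  ggplot2::ggplot(ceac_table,
                  ggplot2::aes(x = .data$lambda, y = .data$probability,
                               colour = .data$alternative)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay per QALY",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
print.econ_summary <- function(x, ...) {
  cat("<econ_summary> comparator =", x$comparator, "\n")
  print.data.frame(x$means, row.names = FALSE, digits = 6)
  cat("frontier:\n")
  print.data.frame(x$icer_table, row.names = FALSE, digits = 6)
  invisible(x)
}
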