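#' Outcome selectors for influence analysis
#'
#' An outcome selector maps one model evaluation (the outcome data.frame the
#' model's outcome function returns, or a `psa_result` reduced to means) to
#' a single scalar.  `outcome_inmb()` selects the incremental net monetary
#' benefit of strategy pair `a` vs `b` under one treatment at
#' willingness-to-pay `lambda`; `outcome_icer()` selects the pairwise ICER
#' `delta cost / delta qaly` for the same comparison.  For ICERs the
#' incremental effect is returned alongside so the tornado layer can flag
#' bars whose effect difference changes sign as non-interpretable.
#'
#' @param a,b strategy ids compared (a vs b).
#' @param treatment treatment id.
#' @param lambda willingness to pay (INMB only).
#' @return function of class `outcome_selector` mapping an outcome
#'   data.frame to `c(value = ..., deffect = ...)`, with a `label`
#'   attribute.
#' @export
outcome_inmb <- function(a, b, treatment, lambda) {
  stopifnot(lambda >= 0)
  f <- function(out) {
    ra <- pick_row(out, a, treatment); rb <- pick_row(out, b, treatment)
    de <- ra$qaly - rb$qaly
    c(value = lambda * de - (ra$cost - rb$cost), deffect = de)
  }
  structure(f, class = c("outcome_selector", "function"),
            label = sprintf("INMB, %s vs %s, %s, lambda=%g",
                            a, b, treatment, lambda),
            strategies = c(a, b), treatment = treatment, lambda = lambda,
            kind = "inmb")
}

#' @rdname outcome_inmb
#' @export
outcome_icer <- function(a, b, treatment) {
  f <- function(out) {
    ra <- pick_row(out, a, treatment); rb <- pick_row(out, b, treatment)
    de <- ra$qaly - rb$qaly
    c(value = (ra$cost - rb$cost) / de, deffect = de)
  }
  structure(f, class = c("outcome_selector", "function"),
            label = sprintf("ICER, %s vs %s, %s", a, b, treatment),
            strategies = c(a, b), treatment = treatment, kind = "icer")
}

pick_row <- function(out, strategy, treatment) {
  r <- out[out$strategy == strategy & out$treatment == treatment, ,
           drop = FALSE]
  if (nrow(r) != 1L)
    abort("outcome selector: no unique row for strategy '", strategy,
          "', treatment '", treatment, "'")
  r
}

# one-way range of a parameter: explicit low/high, else 2.5/97.5 quantiles
param_range <- function(spec) {
  low <- spec$low %||% param_quantile(spec, 0.025)
  high <- spec$high %||% param_quantile(spec, 0.975)
  c(low = low, high = high)
}

eval_deterministic <- function(model, values) {
  model$outcome_fn(values)
}

#' Deterministic tornado analysis
#'
#' Each non-point parameter is set in turn to the low then the high end of
#' its one-way range (explicit `low`/`high` on the spec, else its 2.5th and
#' 97.5th distribution quantiles) while all other parameters sit at their
#' central values; the selected outcome is recorded at both ends.  Bars are
#' sorted by descending width (ties broken by parameter name).  Point-mass
#' parameters are skipped.  For ICER outcomes a bar whose incremental
#' effect changes sign between its two ends is flagged non-interpretable.
#'
#' @param model a [model_definition()].
#' @param outcome an [outcome_inmb()] or [outcome_icer()] selector.
#' @param reference optional `psa_result` from which a stochastic reference
#'   bar (mean and 95% interval of the same outcome) is computed.
#' @return list of class `tornado_result`: `bars` (data.frame `parameter,
#'   low_value, high_value, outcome_low, outcome_high, width,
#'   interpretable`), `base_outcome`, `outcome_label`, `reference` (NULL or
#'   `c(mean, lo, hi)`).
#' @export
tornado <- function(model, outcome, reference = NULL) {
  stopifnot(inherits(model, "model_definition"),
            inherits(outcome, "outcome_selector"))
  check_selector(model, outcome)
  centrals <- lapply(model$parameters, central_value)
  base <- outcome(eval_deterministic(model, centrals))
  varied <- Filter(function(s) s$distribution != "point", model$parameters)
  rows <- lapply(varied, function(s) {
    rng <- param_range(s)
    at <- function(v) {
      vals <- centrals; vals[[s$name]] <- v
      outcome(eval_deterministic(model, vals))
    }
    lo <- at(rng[["low"]]); hi <- at(rng[["high"]])
    interpretable <- !(attr(outcome, "kind") == "icer" &&
                         sign(lo[["deffect"]]) != sign(hi[["deffect"]]))
    data.frame(parameter = s$name,
               low_value = rng[["low"]], high_value = rng[["high"]],
               outcome_low = lo[["value"]], outcome_high = hi[["value"]],
               width = abs(hi[["value"]] - lo[["value"]]),
               interpretable = interpretable, stringsAsFactors = FALSE)
  })
  bars <- sort_bars(do.call(rbind, rows))
  ref <- if (!is.null(reference)) psa_reference(reference, outcome)
  structure(list(bars = bars, base_outcome = unname(base[["value"]]),
                 outcome_label = attr(outcome, "label"), reference = ref),
            class = "tornado_result")
}

#' Stochastic tornado analysis
#'
#' The probabilistic counterpart of [tornado()]: for each parameter a full
#' seeded PSA is run with that parameter *fixed* at the low (then high) end
#' of its one-way range while every other parameter is sampled from its
#' distribution; the bar endpoints are the mean outcomes of the two
#' conditional runs.  All conditional runs share one set of seeded draws —
#' only the conditioned column is overwritten — so the sole difference
#' between the two endpoints of a bar is the conditioning itself.  The
#' reference bar is the mean and 95% interval of the outcome under the
#' unconditional PSA.
#'
#' @inheritParams tornado
#' @param options a stochastic [run_options()].
#' @return a `tornado_result` (see [tornado()]) with the unconditional PSA
#'   reference attached.
#' @export
stochastic_tornado <- function(model, outcome, options) {
  stopifnot(inherits(model, "model_definition"),
            inherits(outcome, "outcome_selector"),
            inherits(options, "run_options"))
  if (options$mode != "stochastic")
    abort("stochastic_tornado needs stochastic run options")
  check_selector(model, outcome)
  draws0 <- draw_parameters(model, options)
  base_psa <- eval_draws(model, draws0, options)
  ref <- psa_reference(base_psa, outcome)
  centrals <- lapply(model$parameters, central_value)
  base <- outcome(eval_deterministic(model, centrals))
  varied <- Filter(function(s) s$distribution != "point", model$parameters)
  cond_mean <- function(pname, v) {
    d <- draws0
    d[[pname]] <- v
    mean(psa_outcome_draws(eval_draws(model, d, options), outcome))
  }
  rows <- lapply(varied, function(s) {
    rng <- param_range(s)
    lo <- cond_mean(s$name, rng[["low"]])
    hi <- cond_mean(s$name, rng[["high"]])
    data.frame(parameter = s$name,
               low_value = rng[["low"]], high_value = rng[["high"]],
               outcome_low = lo, outcome_high = hi,
               width = abs(hi - lo), interpretable = TRUE,
               stringsAsFactors = FALSE)
  })
  bars <- sort_bars(do.call(rbind, rows))
  structure(list(bars = bars, base_outcome = unname(base[["value"]]),
                 outcome_label = attr(outcome, "label"), reference = ref),
            class = "tornado_result")
}

# descending width, ties by parameter name; tolerates zero varied parameters
sort_bars <- function(bars) {
  if (is.null(bars))
    bars <- data.frame(parameter = character(), low_value = numeric(),
                       high_value = numeric(), outcome_low = numeric(),
                       outcome_high = numeric(), width = numeric(),
                       interpretable = logical(), stringsAsFactors = FALSE)
  rownames(bars) <- NULL
  bars[order(-bars$width, bars$parameter), , drop = FALSE]
}

check_selector <- function(model, outcome) {
  st <- attr(outcome, "strategies")
  tr <- attr(outcome, "treatment")
  if (!all(st %in% model$strategies$id))
    abort("outcome selector references unknown strategy: ",
          paste(setdiff(st, model$strategies$id), collapse = ", "))
  if (!tr %in% model$treatments$id)
    abort("outcome selector references unknown treatment: ", tr)
}

# per-draw outcome values under a PSA
psa_outcome_draws <- function(psa, outcome) {
  st <- attr(outcome, "strategies"); tr <- attr(outcome, "treatment")
  if (attr(outcome, "kind") == "inmb") {
    a <- paste(st[1], tr, sep = ":"); b <- paste(st[2], tr, sep = ":")
    inmb(psa, a, b, attr(outcome, "lambda"))$draws
  } else {
    a <- paste(st[1], tr, sep = ":"); b <- paste(st[2], tr, sep = ":")
    (alt_vector(psa, a, "cost") - alt_vector(psa, b, "cost")) /
      (alt_vector(psa, a, "qaly") - alt_vector(psa, b, "qaly"))
  }
}

psa_reference <- function(psa, outcome) {
  x <- psa_outcome_draws(psa, outcome)
  ci <- unname(quantile(x, c(0.025, 0.975), type = 7))
  c(mean = mean(x), lo = ci[1], hi = ci[2])
}

#' Tornado plot
#'
#' Horizontal bars from `outcome_low` to `outcome_high`, widest on top, with
#' the base-case marker on every bar and, when available, the stochastic
#' reference bar (mean and 95% interval) at the bottom.  Bars narrower than
#' 1e-12 of the outcome scale are dropped from the plot (they remain in the
#' table).
#'
#' @param x a `tornado_result`.
#' @return a ggplot object.
#' @export
plot_tornado <- function(x) {
  stopifnot(inherits(x, "tornado_result"))
  b <- x$bars
  scale <- max(abs(c(b$outcome_low, b$outcome_high, x$base_outcome)), 1)
  b <- b[b$width >= 1e-12 * scale, , drop = FALSE]
  b$parameter <- factor(b$parameter, levels = rev(b$parameter))
  g <- ggplot2::ggplot(b, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$outcome_low,
                                       xend = .data$outcome_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = x$base_outcome, linetype = 2) +
    ggplot2::labs(x = x$outcome_label, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(x$reference)) {
    rf <- data.frame(parameter = "PSA reference",
                     lo = x$reference[["lo"]], hi = x$reference[["hi"]],
                     mean = x$reference[["mean"]])
    g <- g + ggplot2::geom_errorbarh(
      data = rf, ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                              y = .data$parameter),
      height = 0.3, colour = "grey40", inherit.aes = FALSE)
  }
  g
}

#' Write a tornado table to CSV
#'
#' Columns `parameter,low_value,high_value,outcome_low,outcome_high,width`.
#'
#' @param x a `tornado_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(x, path) {
  stopifnot(inherits(x, "tornado_result"))
  write.csv(x$bars[c("parameter", "low_value", "high_value",
                     "outcome_low", "outcome_high", "width")],
            path, row.names = FALSE)
  invisible(path)
}

#' @export
print.tornado_result <- function(x, ...) {
  cat("<tornado_result>", x$outcome_label, "\n")
  cat("  base outcome:", format(x$base_outcome), "\n")
  if (!is.null(x$reference))
    cat(sprintf("  PSA reference: %.4g [%.4g, %.4g]\n",
                x$reference[["mean"]], x$reference[["lo"]],
                x$reference[["hi"]]))
  print.data.frame(head(x$bars, 10), row.names = FALSE, digits = 5)
  if (nrow(x$bars) > 10) cat("  ...", nrow(x$bars) - 10, "more bars\n")
  invisible(x)
}
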