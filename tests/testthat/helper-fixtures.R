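# toy two-strategy model: qaly(s2) = c1*p1 + c2*p2 + 0*p3, costs zero;
# strategy s1 is the all-zero comparator.  INMB(s2 vs s1, lambda=1) is then
# linear in the parameters with known coefficients.
toy_linear_model <- function(c1 = 10, c2 = 1) {
  model_definition(
    parameters = list(
      parameter_spec("p1", "uniform", min = 0, max = 1, low = 0, high = 1),
      parameter_spec("p2", "uniform", min = 0, max = 1, low = 0, high = 1),
      parameter_spec("p3", "uniform", min = 0, max = 1, low = 0, high = 1)
    ),
    strategies = c("s1", "s2"), treatments = "t1",
    outcome_fn = function(p) data.frame(
      strategy = c("s1", "s2"), treatment = "t1",
      cost = c(0, 0),
      qaly = c(0, c1 * p$p1 + c2 * p$p2),
      stringsAsFactors = FALSE
    ),
    name = "toy_linear"
  )
}

# all-point model whose outcomes are fully determined
toy_point_model <- function() {
  model_definition(
    parameters = list(
      parameter_spec("a", "point", value = 2),
      parameter_spec("b", "point", value = 3)
    ),
    strategies = c("s1", "s2"), treatments = "t1",
    outcome_fn = function(p) data.frame(
      strategy = c("s1", "s2"), treatment = "t1",
      cost = c(100, 100 + 10 * p$a),
      qaly = c(0, p$a * p$b),
      stringsAsFactors = FALSE
    ),
    name = "toy_point"
  )
}

# construct a psa_result directly from explicit per-alternative cost/qaly
# draws (test scaffolding for the economics layer)
make_psa <- function(costs, qalys, mode = "stochastic") {
  stopifnot(identical(names(costs), names(qalys)))
  n <- length(costs[[1]])
  rows <- lapply(names(costs), function(a) {
    parts <- strsplit(a, ":", fixed = TRUE)[[1]]
    data.frame(sim = seq_len(n), strategy = parts[1], treatment = parts[2],
               cost = costs[[a]], qaly = qalys[[a]], stringsAsFactors = FALSE)
  })
  outcomes <- do.call(rbind, rows)
  outcomes <- outcomes[order(outcomes$sim), ]
  structure(list(
    draws = data.frame(dummy = rep(0, n)),
    outcomes = outcomes, outcome_names = c("cost", "qaly"),
    options = run_options(mode = mode, n_sims = n, seed = 1L),
    model_fingerprint = "test"
  ), class = "psa_result")
}

# independent cost-effectiveness frontier oracle: alternative i lies on the
# frontier iff some willingness-to-pay lambda in [0, Inf) makes it the
# unique net-benefit maximizer (half-plane intersection, O(n^2))
frontier_oracle <- function(costs, effects) {
  n <- length(costs)
  on_frontier <- logical(n)
  for (i in seq_len(n)) {
    lo <- 0; hi <- Inf; feasible <- TRUE
    for (j in seq_len(n)) {
      if (i == j) next
      de <- effects[i] - effects[j]; dc <- costs[i] - costs[j]
      if (de > 0) lo <- max(lo, dc / de)
      else if (de < 0) hi <- min(hi, dc / de)
      else if (dc >= 0) { feasible <- FALSE; break }
    }
    on_frontier[i] <- feasible && lo < hi
  }
  on_frontier
}

example_studies <- function() {
  read_studies(antid_example_path("studies.csv"))
}

example_elicitations <- function() {
  read_elicitations(antid_example_path("elicitations.csv"))
}
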