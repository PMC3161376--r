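test_that("central values equal distribution means", {
  expect_equal(central_value(parameter_spec("x", "point", value = 0.3)), 0.3)
  expect_equal(central_value(parameter_spec("x", "beta", shape1 = 2,
                                            shape2 = 2)), 0.5)
  expect_equal(central_value(parameter_spec("x", "lognormal", meanlog = 0,
                                            sdlog = 0.5)),
               1.13314845, tolerance = 1e-8)  # exp(mu + sigma^2/2)
  expect_equal(central_value(parameter_spec("x", "gamma", shape = 4,
                                            rate = 2)), 2)
  expect_equal(central_value(parameter_spec("x", "uniform", min = 1,
                                            max = 3)), 2)
  expect_equal(central_value(parameter_spec("x", "empirical",
                                            samples = c(1, 2, 3))), 2)
})

test_that("invalid hyperparameters are rejected", {
  expect_error(parameter_spec("x", "beta", shape1 = -1, shape2 = 2), "beta")
  expect_error(parameter_spec("x", "uniform", min = 2, max = 1), "uniform")
  expect_error(parameter_spec("x", "empirical", samples = numeric()),
               "empirical")
  expect_error(parameter_spec("x", "weibull", shape = 1), "unknown")
})

test_that("sample moments converge to analytic moments", {
  specs <- list(
    list(parameter_spec("x", "beta", shape1 = 2, shape2 = 2), 0.5,
         sqrt(0.25 / 5)),
    list(parameter_spec("x", "normal", mean = -1, sd = 2), -1, 2),
    list(parameter_spec("x", "gamma", shape = 9, rate = 3), 3, 1),
    list(parameter_spec("x", "uniform", min = 0, max = 2), 1, 2 / sqrt(12)),
    list(parameter_spec("x", "lognormal", meanlog = 0, sdlog = 0.4),
         exp(0.08), sqrt((exp(0.16) - 1) * exp(0.16)))
  )
  n <- 1e5
  for (s in specs) {
    m <- model_definition(list(s[[1]]), "s1", "t1",
                          function(p) data.frame(strategy = "s1",
                                                 treatment = "t1",
                                                 cost = 0, qaly = 0))
    d <- draw_parameters(m, run_options("stochastic", n_sims = n, seed = 8))
    expect_lt(abs(mean(d$x) - s[[2]]), 3 * s[[3]] / sqrt(n))
  }
  # the spec'd headline case: beta(2,2) mean within 0.005 of 0.5
  m <- model_definition(list(parameter_spec("x", "beta", shape1 = 2,
                                            shape2 = 2)), "s1", "t1",
                        function(p) data.frame(strategy = "s1",
                                               treatment = "t1",
                                               cost = 0, qaly = 0))
  d <- draw_parameters(m, run_options("stochastic", n_sims = n, seed = 9))
  expect_lt(abs(mean(d$x) - 0.5), 0.005)
})

test_that("point-mass models draw constant rows equal to central values", {
  m <- toy_point_model()
  d <- draw_parameters(m, run_options("stochastic", n_sims = 50, seed = 1))
  expect_true(all(d$a == 2) && all(d$b == 3))
})

test_that("empirical blocks preserve joint structure across parameters", {
  set.seed(31)
  src <- sort(rnorm(200))
  m <- model_definition(
    list(parameter_spec("u", "empirical", samples = src, block = "joint"),
         parameter_spec("w", "empirical", samples = 2 * src + 1,
                        block = "joint"),
         parameter_spec("z", "empirical", samples = rev(src),
                        block = "joint")),
    "s1", "t1",
    function(p) data.frame(strategy = "s1", treatment = "t1", cost = 0,
                           qaly = 0)
  )
  d <- draw_parameters(m, run_options("stochastic", n_sims = 2000, seed = 2))
  expect_equal(cor(d$u, d$w), 1)         # perfectly correlated source rows
  expect_equal(d$w, 2 * d$u + 1)
  # within-block rank correlation of draws equals that of the source rows
  expect_equal(cor(src, rev(src), method = "spearman"),
               cor(d$u, d$z, method = "spearman"), tolerance = 0.05)
  # unequal lengths within a block are rejected
  bad <- model_definition(
    list(parameter_spec("u", "empirical", samples = src, block = "b"),
         parameter_spec("w", "empirical", samples = src[1:10], block = "b")),
    "s1", "t1",
    function(p) data.frame(strategy = "s1", treatment = "t1", cost = 0,
                           qaly = 0)
  )
  expect_error(draw_parameters(bad, run_options("stochastic", n_sims = 10,
                                                seed = 1)),
               "unequal length")
})

test_that("stochastic runs of a degenerate model equal the deterministic run", {
  m <- toy_point_model()
  det <- run_model(m, run_options("deterministic"))
  sto <- run_model(m, run_options("stochastic", n_sims = 100, seed = 5))
  for (k in c("cost", "qaly")) {
    dm <- hteval:::outcome_matrix(det, k)
    sm <- hteval:::outcome_matrix(sto, k)
    for (a in colnames(dm)) expect_true(all(sm[, a] == dm[1, a]))
  }
})

test_that("identical seeds give bit-identical PSA results", {
  m <- antid_model()
  r1 <- run_model(m, run_options("stochastic", n_sims = 50, seed = 123))
  r2 <- run_model(m, run_options("stochastic", n_sims = 50, seed = 123))
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$outcomes, r2$outcomes)
  r3 <- run_model(m, run_options("stochastic", n_sims = 50, seed = 124))
  expect_false(identical(r3$outcomes, r1$outcomes))
})

test_that("broken outcome functions are rejected with the draw index", {
  bad_keys <- model_definition(
    list(parameter_spec("x", "point", value = 1)), "s1", "t1",
    function(p) data.frame(strategy = "s1", treatment = "t1", cost = 1)
  )
  expect_error(run_model(bad_keys, run_options("deterministic")), "qaly")
  bad_val <- model_definition(
    list(parameter_spec("x", "uniform", min = 0, max = 1)), "s1", "t1",
    function(p) data.frame(strategy = "s1", treatment = "t1",
                           cost = if (p$x > 0.5) NaN else 1, qaly = 0)
  )
  expect_error(run_model(bad_val, run_options("stochastic", n_sims = 20,
                                              seed = 42)),
               "non-finite values at draw")
})

test_that("model definitions round-trip through YAML", {
  dir <- withr::local_tempdir()
  m <- antid_model()
  # add an empirical parameter to exercise the samples_file path
  m$parameters[["or_eff"]] <- parameter_spec(
    "or_eff", "empirical", samples = exp(rnorm(100, log(0.4), 0.1)))
  path <- file.path(dir, "model.yaml")
  write_model_definition(m, path, "antid")
  m2 <- read_model_definition(path)
  expect_identical(names(m2$parameters), names(m$parameters))
  for (nm in names(m$parameters))
    expect_equal(central_value(m2$parameters[[nm]]),
                 central_value(m$parameters[[nm]]), tolerance = 1e-12)
  expect_equal(m2$strategies, m$strategies)
  expect_equal(m2$treatments, m$treatments)
  # deterministic outcomes identical through the round trip
  d1 <- run_model(m, run_options("deterministic"))
  d2 <- run_model(m2, run_options("deterministic"))
  expect_equal(d1$outcomes, d2$outcomes, tolerance = 1e-12)
})
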