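test_that("INMB limits and identities hold exactly", {
  psa <- make_psa(
    costs = list("s1:t" = c(10, 20, 30), "s2:t" = c(15, 18, 40)),
    qalys = list("s1:t" = c(1, 2, 3), "s2:t" = c(2, 2.5, 3.5))
  )
  same <- inmb(psa, "s1:t", "s1:t", 5000)
  expect_equal(same$draws, c(0, 0, 0))
  cost_only <- inmb(psa, "s2:t", "s1:t", 0)
  expect_equal(cost_only$draws, -(c(15, 18, 40) - c(10, 20, 30)))
  r <- inmb(psa, "s2:t", "s1:t", 100)
  expect_equal(r$draws, 100 * c(1, 0.5, 0.5) - c(5, -2, 10))
  expect_equal(r$mean, mean(r$draws))
  expect_error(inmb(psa, "s2:t", "s1:t", -1), "lambda")
})

test_that("deterministic fixture INMB composes the audited outcome oracle", {
  # frozen oracle values for the default parameter set (see test-antid.R)
  dq <- -921.113133 - (-1210.530001)
  dc <- 8525569.647632 - 7787403.712285
  det <- run_model(antid_model(), run_options("deterministic"))
  r <- inmb(det, "s2:partobulin", "s1:partobulin", 20000)
  expect_equal(r$mean, 20000 * dq - dc, tolerance = 1e-9)
})

test_that("frontier handles trivial, dominated and extended dominance cases", {
  f1 <- frontier(c(A = 0, B = 100), c(A = 0, B = 10))
  expect_equal(f1$status, c("frontier", "frontier"))
  expect_equal(f1$icer[f1$alternative == "B"], 10)

  # B costs 500 for 1 QALY; A->B ICER 500 exceeds B->C ~11.1, so B is
  # extendedly dominated and the frontier jumps A -> C at ICER 60
  f2 <- frontier(c(A = 0, B = 500, C = 600), c(A = 0, B = 1, C = 10))
  expect_equal(f2$status[f2$alternative == "B"], "extendedly_dominated")
  expect_equal(f2$icer[f2$alternative == "C"], 60)

  f3 <- frontier(c(A = 10, B = 5), c(A = 1, B = 2))
  expect_equal(f3$status[f3$alternative == "A"], "dominated")

  # exact tie: first-listed alternative stays on the frontier
  f4 <- frontier(c(A = 10, B = 10), c(A = 1, B = 1))
  expect_equal(f4$status[f4$alternative == "A"], "frontier")
  expect_equal(f4$status[f4$alternative == "B"], "dominated")

  f5 <- frontier(c(only = 42), c(only = 1))
  expect_equal(f5$status, "frontier")
})

test_that("frontier equals the exhaustive support-line oracle", {
  set.seed(60)
  for (rep in 1:300) {
    n <- sample(2:6, 1)
    costs <- setNames(runif(n, 0, 1000), paste0("a", seq_len(n)))
    effects <- setNames(runif(n, 0, 10), names(costs))
    f <- frontier(costs, effects)
    keep <- sort(f$alternative[f$status == "frontier"])
    oracle <- sort(names(costs)[frontier_oracle(costs, effects)])
    expect_identical(keep, oracle)
    # per-step ICERs strictly increase along the frontier
    ic <- f$icer[f$status == "frontier"]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
  }
})

test_that("acceptability probabilities are normalized and split ties", {
  # identical alternatives: 0.5 / 0.5 at every lambda
  x <- c(10, 20, 30)
  psa <- make_psa(costs = list("s1:t" = x, "s2:t" = x),
                  qalys = list("s1:t" = x / 10, "s2:t" = x / 10))
  cc <- ceac(psa, c(0, 10000, 20000))
  expect_true(all(cc$probability == 0.5))

  # constructed draws: a beats b in exactly 73 of 100 draws at lambda 20000
  qa <- c(rep(1, 73), rep(0, 27))
  psa2 <- make_psa(costs = list("a:t" = rep(0, 100), "b:t" = rep(0, 100)),
                   qalys = list("a:t" = qa, "b:t" = rep(0.5, 100)))
  cc2 <- ceac(psa2, 20000)
  expect_equal(cc2$probability[cc2$alternative == "a:t"], 0.73)

  # lambda = 0: the cheapest alternative per draw wins
  psa3 <- make_psa(costs = list("a:t" = c(1, 5, 1, 5), "b:t" = c(2, 2, 2, 2)),
                   qalys = list("a:t" = rep(9, 4), "b:t" = rep(0, 4)))
  cc3 <- ceac(psa3, 0)
  expect_equal(cc3$probability[cc3$alternative == "a:t"], 0.5)

  # normalization on a real PSA
  psa4 <- run_model(antid_model(),
                    run_options("stochastic", n_sims = 200, seed = 3))
  cc4 <- ceac(psa4, c(0, 10000, 30000))
  sums <- as.numeric(tapply(cc4$probability, cc4$lambda, sum))
  expect_equal(sums, rep(1, 3))
})

test_that("probability of the more effective option rises with lambda", {
  set.seed(8)
  n <- 400
  ea <- runif(n, 1, 2); eb <- ea - runif(n, 0.01, 0.5)  # a better always
  psa <- make_psa(costs = list("a:t" = rnorm(n, 120, 30),
                               "b:t" = rnorm(n, 100, 30)),
                  qalys = list("a:t" = ea, "b:t" = eb))
  cc <- ceac(psa, seq(0, 2000, by = 100))
  pa <- cc$probability[cc$alternative == "a:t"]
  expect_true(all(diff(pa) >= 0))
})

test_that("mean INMB sign matches the mean net-benefit ordering", {
  psa <- run_model(antid_model(),
                   run_options("stochastic", n_sims = 300, seed = 10))
  E <- hteval:::outcome_matrix(psa, "qaly")
  C <- hteval:::outcome_matrix(psa, "cost")
  for (l in c(0, 15000, 40000)) {
    nmb <- colMeans(l * E - C)
    r <- inmb(psa, "s3:dgam", "s1:partobulin", l)
    expect_equal(r$mean > 0, nmb[["s3:dgam"]] > nmb[["s1:partobulin"]])
  }
})

test_that("incremental clinical outcomes flag null effects as undefined", {
  x <- c(5, 6, 7)
  psa <- make_psa(costs = list("a:t" = x + 1, "b:t" = x),
                  qalys = list("a:t" = x / 10, "b:t" = x / 10))
  expect_error(incremental_clinical(psa, "a:t", "a:t"), "differ")
  r <- incremental_clinical(psa, "a:t", "b:t")
  qrow <- r[r$outcome == "qaly", ]
  expect_false(qrow$defined)
  expect_true(is.na(qrow$cost_per_unit))

  det <- run_model(antid_model(), run_options("deterministic"))
  ic <- incremental_clinical(det, "s2:partobulin", "s1:partobulin")
  dsens <- ic$delta[ic$outcome == "sensitizations"]
  expect_equal(dsens, 722.871367 - 950.000000, tolerance = 1e-6)
  expect_true(ic$defined[ic$outcome == "sensitizations"])

  null_m <- antid_model()
  null_m$parameters$or_eff <- parameter_spec("or_eff", "point", value = 1)
  det0 <- run_model(null_m, run_options("deterministic"))
  ic0 <- incremental_clinical(det0, "s2:partobulin", "s1:partobulin")
  expect_false(ic0$defined[ic0$outcome == "sensitizations"])
})

test_that("the economic summary assembles coherent components", {
  psa <- run_model(antid_model(),
                   run_options("stochastic", n_sims = 150, seed = 4,
                               lambda_grid = seq(0, 30000, 10000)))
  es <- econ_summary(psa)
  expect_equal(es$comparator, "s1:partobulin")
  expect_equal(es$means$d_cost[1], 0)
  expect_equal(nrow(es$icer_table), 12)
  expect_true(all(es$ceac$probability >= 0 & es$ceac$probability <= 1))
  inmb0 <- es$inmb[es$inmb$lambda == 20000 &
                     es$inmb$alternative == "s2:partobulin", ]
  direct <- inmb(psa, "s2:partobulin", "s1:partobulin", 20000)
  expect_equal(inmb0$mean, direct$mean)
  expect_equal(inmb0$lo, direct$lo)
})
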