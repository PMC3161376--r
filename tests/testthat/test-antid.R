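# frozen independent oracle for the default parameter set: every number
# below was produced by a separate step-by-step evaluation of the model
# arithmetic (odds conversion, discount factors, event cascade, costs),
# outside the package functions
antid_oracle <- list(
  s1 = list(sens = 950.000000, aff = 372.470769, lost = 18.623538,
            qaly = -1210.530001, ly = -1396.765385,
            cost = c(partobulin = 7787403.712285, dgam = 7787403.712285,
                     rhophylac = 7787403.712285, winrho = 7787403.712285)),
  s2 = list(sens = 722.871367, aff = 283.419425, lost = 14.170971,
            qaly = -921.113133, ly = -1062.822846,
            cost = c(partobulin = 8525569.647632, dgam = 8325569.647632,
                     rhophylac = 8885569.647632, winrho = 8725569.647632)),
  s3 = list(sens = 382.178417, aff = 149.842410, lost = 7.492120,
            qaly = -486.987831, ly = -561.909036,
            cost = c(partobulin = 9632818.550653, dgam = 9132818.550653,
                     rhophylac = 10532818.550653, winrho = 10132818.550653))
)

test_that("default outcomes match the independent arithmetic oracle", {
  out <- antid_outcomes()
  tol <- 1e-6  # 6 significant figures
  for (s in names(antid_oracle)) {
    o <- antid_oracle[[s]]
    rows <- out[out$strategy == s, ]
    expect_equal(unique(rows$sensitizations), o$sens, tolerance = tol)
    expect_equal(unique(rows$affected), o$aff, tolerance = tol)
    expect_equal(unique(rows$losses), o$lost, tolerance = tol)
    expect_equal(unique(rows$qaly), o$qaly, tolerance = tol)
    expect_equal(unique(rows$ly), o$ly, tolerance = tol)
    for (t in names(o$cost))
      expect_equal(rows$cost[rows$treatment == t], unname(o$cost[t]),
                   tolerance = tol)
  }
})

test_that("null effectiveness leaves only prophylaxis costs between strategies", {
  p <- antid_parameters(or_eff = 1)
  out <- antid_outcomes(p)
  for (t in names(p$c_dose)) {
    rows <- out[out$treatment == t, ]
    expect_equal(length(unique(round(rows$sensitizations, 9))), 1L)
    expect_equal(length(unique(round(rows$qaly, 9))), 1L)
    cov <- c(s1 = 0, s2 = p$p_prim, s3 = 1)
    extra <- p$cohort * cov * p$n_doses * (p$c_dose[[t]] + p$c_admin)
    base <- rows$cost[rows$strategy == "s1"]
    expect_equal(rows$cost, base + unname(extra[rows$strategy]),
                 tolerance = 1e-12)
  }
})

test_that("the untreated strategy ignores dose cost and effectiveness", {
  a <- antid_outcomes(antid_parameters())
  b <- antid_outcomes(antid_parameters(
    or_eff = 0.9, c_dose = c(partobulin = 999, dgam = 999, rhophylac = 999,
                             winrho = 999)))
  expect_equal(a[a$strategy == "s1", c("cost", "qaly", "sensitizations")],
               b[b$strategy == "s1", c("cost", "qaly", "sensitizations")])
})

test_that("more effective prophylaxis never worsens clinical outcomes", {
  ors <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  prev <- NULL
  for (or in ors) {
    out <- antid_outcomes(antid_parameters(or_eff = or))
    out <- out[out$treatment == "partobulin", ]
    # strategy ordering whenever or < 1
    expect_lte(out$sensitizations[out$strategy == "s3"],
               out$sensitizations[out$strategy == "s2"])
    expect_lte(out$sensitizations[out$strategy == "s2"],
               out$sensitizations[out$strategy == "s1"])
    if (!is.null(prev)) {
      for (s in c("s2", "s3")) {
        expect_lte(out$sensitizations[out$strategy == s],
                   prev$sensitizations[prev$strategy == s])
        expect_lte(out$affected[out$strategy == s],
                   prev$affected[prev$strategy == s])
        expect_gte(out$qaly[out$strategy == s],
                   prev$qaly[prev$strategy == s])
      }
      expect_equal(out[out$strategy == "s1", -(1:2)],
                   prev[prev$strategy == "s1", -(1:2)])
    }
    prev <- out
  }
})

test_that("zero discount rates reproduce undiscounted arithmetic exactly", {
  p <- antid_parameters(d_eff = 0, d_cost = 0)
  out <- antid_outcomes(p)
  r <- out[out$strategy == "s3" & out$treatment == "dgam", ]
  odds1 <- p$s0 / (1 - p$s0) * p$or_eff
  sens <- p$cohort * odds1 / (1 + odds1)
  aff <- sens * p$p_subseq * p$p_affected
  expect_equal(r$sensitizations, sens)
  expect_equal(r$affected, aff)
  expect_equal(r$cost,
               p$cohort * p$n_doses * (p$c_dose[["dgam"]] + p$c_admin) +
                 sens * p$c_sens + aff * p$c_hdn)
})

test_that("invalid parameter values are rejected", {
  expect_error(antid_parameters(s0 = 0), "\\(0, 1\\)")
  expect_error(antid_parameters(or_eff = -1), "or_eff")
  expect_error(antid_parameters(bogus = 1), "unknown")
  expect_error(antid_outcomes(treatments = "nosuch"), "unknown treatment")
})

test_that("the engine wrapper reproduces the documented defaults", {
  det <- run_model(antid_model(), run_options("deterministic"))
  direct <- antid_outcomes()
  oc <- det$outcomes[names(direct)]
  rownames(oc) <- NULL
  expect_equal(oc, direct, tolerance = 1e-9)
})

test_that("degenerate posterior handoff equals a fixed odds ratio", {
  m <- antid_model()
  fake <- dl_meta(log(0.4), 0.04)
  fake$mu_samples <- rep(log(0.4), 500)
  m1 <- attach_effectiveness(m, fake, mode = "stochastic")
  expect_equal(m1$parameters$or_eff$distribution, "empirical")
  r1 <- run_model(m1, run_options("stochastic", n_sims = 100, seed = 6))
  m2 <- m
  m2$parameters$or_eff <- parameter_spec("or_eff", "point", value = 0.4)
  r2 <- run_model(m2, run_options("stochastic", n_sims = 100, seed = 6))
  expect_equal(r1$outcomes$cost, r2$outcomes$cost, tolerance = 1e-12)
  expect_equal(r1$outcomes$qaly, r2$outcomes$qaly, tolerance = 1e-12)
})

test_that("posterior spread widens downstream INMB uncertainty", {
  m <- antid_model()
  med <- log(0.4)
  set.seed(77)
  wide <- dl_meta(med, 0.04)
  wide$mu_samples <- med + rnorm(4000, 0, 0.5)
  narrow <- dl_meta(med, 0.04)
  narrow$mu_samples <- rep(med, 4000)
  opts <- run_options("stochastic", n_sims = 1000, seed = 13)
  v <- vapply(list(narrow, wide), function(mr) {
    psa <- run_model(attach_effectiveness(m, mr, "stochastic"), opts)
    var(inmb(psa, "s2:partobulin", "s1:partobulin", 20000)$draws)
  }, numeric(1))
  expect_gt(v[2], v[1])
})

test_that("a DL result in stochastic mode becomes a lognormal with notice", {
  m <- antid_model()
  dl <- dl_meta(c(-0.9, -1.0), c(0.04, 0.09))
  expect_message(m2 <- attach_effectiveness(m, dl, "stochastic"),
                 "lognormal")
  expect_equal(m2$parameters$or_eff$distribution, "lognormal")
  expect_equal(m2$parameters$or_eff$params$meanlog, dl$mu_point)
})

test_that("deterministic handoff uses the synthesis point estimate", {
  m <- antid_model()
  dl <- dl_meta(c(-0.9, -1.0), c(0.04, 0.09))
  m2 <- attach_effectiveness(m, dl, "deterministic")
  expect_equal(m2$parameters$or_eff$params$value, exp(dl$mu_point))
})
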