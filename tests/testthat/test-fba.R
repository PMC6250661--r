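test_that("FBA reproduces the hand-computed toy optima", {
  expect_equal(fba(make_toy1())$objective, 5)
  expect_equal(fba(make_toy2())$objective, 3)
})

test_that("FBA errors name the failure mode", {
  m <- make_toy1()
  expect_error(fba(m, objective = "nope"), "not in model")
  # unbounded: internal loop reaction with infinite bounds
  m2 <- add_reaction(m, "LOOP", c(A = 0, B1 = 0), lb = -Inf, ub = Inf)
  expect_error(fba(m2, objective = "LOOP"), "unbounded")
})

test_that("pFBA preserves the FBA optimum and minimizes total flux", {
  m <- make_toy2()
  plain <- fba(m)
  pf <- pfba(m)
  expect_equal(pf$objective, plain$objective, tolerance = 1e-8)
  # pFBA flux vector achieves the optimum with no more total flux than FBA
  expect_lte(pf$total_flux, sum(abs(plain$fluxes)) + 1e-6)
  expect_equal(sum(abs(pf$fluxes)), pf$total_flux, tolerance = 1e-8)
  # steady state holds
  expect_equal(max(abs(as.numeric(m$S %*% pf$fluxes))), 0, tolerance = 1e-7)
  # hand solution: EX_A = 12, RGEN = 6, R1 = R2 = 3
  expect_equal(unname(pf$fluxes[c("EX_A", "RGEN", "R1", "R2")]),
               c(12, 6, 3, 3), tolerance = 1e-7)
})

test_that("pFBA zeroes futile cycles that plain flux vectors may carry", {
  m <- make_toy1()
  # a reversible 2-cycle B1 <-> B1c that can carry arbitrary flux
  m <- add_reaction(m, "CYC1", c(B1 = -1, B1c = 1), lb = -1000, ub = 1000)
  m <- add_reaction(m, "CYC2", c(B1c = -1, B1 = 1), lb = -1000, ub = 1000)
  pf <- pfba(m)
  expect_equal(pf$objective, 5)
  expect_equal(unname(pf$fluxes["CYC1"]), 0, tolerance = 1e-8)
  expect_equal(unname(pf$fluxes["CYC2"]), 0, tolerance = 1e-8)
})

test_that("wildtype caps respect flux signs and pin zero fluxes", {
  wt <- c(R1 = 3, R2 = -2, R3 = 0)
  caps <- wildtype_caps(wt)
  expect_equal(caps$lb, c(R1 = 0, R2 = -2, R3 = 0))
  expect_equal(caps$ub, c(R1 = 3, R2 = 0, R3 = 0))
})

test_that("caps only shrink the feasible set: optima are monotone", {
  m <- make_toy2()
  wt <- pfba(m)$fluxes
  caps <- wildtype_caps(wt)
  full <- fba(m)$objective
  capped <- fba(m, caps = caps)$objective
  expect_equal(capped, full, tolerance = 1e-7)  # caps derived from an optimum
  prev <- capped
  for (f in c(0.8, 0.5, 0.2, 0)) {
    cf <- restrict_gene(caps, m, "gE", f, wt)
    cur <- fba(m, caps = cf)$objective
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
  expect_equal(prev, 0, tolerance = 1e-7)       # full knockout of RGEN
})

test_that("restrict_gene at fraction 1 is a no-op and at 0 pins to zero", {
  m <- make_toy2()
  wt <- pfba(m)$fluxes
  caps <- wildtype_caps(wt)
  expect_equal(restrict_gene(caps, m, "gE", 1, wt), caps)
  c0 <- restrict_gene(caps, m, "gE", 0, wt)
  expect_equal(unname(c0$lb["RGEN"]), 0)
  expect_equal(unname(c0$ub["RGEN"]), 0)
  expect_error(restrict_gene(caps, m, "gE", 1.5, wt))
})

test_that("caps never widen native bounds", {
  m <- make_toy1()
  caps <- wildtype_caps(c(EX_A = 50, R1 = 5, R2 = 5, BIOMASS = 5))
  # EX_A cap of 50 exceeds the native ub of 10: uptake stays at 10
  sol <- fba(m, caps = caps)
  expect_equal(sol$objective, 5)
  expect_lte(unname(sol$fluxes["EX_A"]), 10 + 1e-9)
})
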