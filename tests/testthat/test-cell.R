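test_that("transport rate follows dual Michaelis-Menten saturation", {
  u <- ref_universe
  g <- transporter_gene(u, "R", FALSE, promoter = 1, vmax = 1, ks = 0.5,
                        ke = 0.25)
  ## both factors at half saturation
  expect_equal(transport_rate(g, S_conc = 0.5, E_conc = 0.25, T_conc = 1),
               0.25)
  expect_equal(transport_rate(g, 0, 1, 1), 0)
  expect_equal(transport_rate(g, 1, 0, 1), 0)   # no free transport
  expect_equal(transport_rate(g, 1e9, 1e9, 2), 2, tolerance = 1e-6)
})

test_that("catalysis rate uses a shared K over reactants", {
  u <- ref_universe
  one <- enzyme_gene(u, 1L, promoter = 1, vmax = 1, ks = 0.5)   # R -> B2 + E
  expect_equal(enzyme_rate(one, c(R = 0.5), 1, u), 0.5)
  two <- enzyme_gene(u, match("M2 + M5 -> B1", u$labels), 1, 1, ks = 0.3)
  expect_equal(enzyme_rate(two, c(M2 = 0.3, M5 = 0.3), 1, u), 0.25)
  expect_equal(enzyme_rate(two, c(M2 = 0, M5 = 5), 1, u), 0)
  ## stoichiometric-power variant squares the doubled reactant's factor
  dbl <- enzyme_gene(u, match("2 M2 -> B1", u$labels), 1, 1, ks = 0.3)
  expect_equal(enzyme_rate(dbl, c(M2 = 0.3), 1, u), 0.5)
  expect_equal(enzyme_rate(dbl, c(M2 = 0.3), 1, u, stoich_powers = TRUE), 0.25)
})

test_that("rates never exceed vmax times catalyst concentration", {
  u <- ref_universe
  set.seed(21)
  for (k in 1:100) {
    g <- enzyme_gene(u, sample.int(43, 1), promoter = 1,
                     vmax = runif(1, 0.01, 8), ks = runif(1, 0.01, 8))
    conc <- setNames(runif(9, 0, 10), u$metabolites$id)
    P <- runif(1, 0, 5)
    v <- enzyme_rate(g, conc, P, u)
    expect_gte(v, 0)
    expect_lte(v, g[1, "vmax"] * P)
  }
})

test_that("production favours building-block homeostasis", {
  expect_equal(production_rate(0.7, 0.7), 0.49)
  expect_equal(production_rate(0, 3), 0)
  expect_equal(production_rate(1, 0.5), 0.5 / 1.5)
  ## the printed two-deviation form equals the simplified one
  b1 <- 1.3; b2 <- 0.4; m <- (b1 + b2) / 2
  expect_equal(production_rate(b1, b2),
               b1 * b2 / (1 + abs(b1 - m) + abs(b2 - m)))
})

test_that("budget scaling is a saturating fraction", {
  expect_equal(budget_scaling(1, 1), 0.5)
  expect_equal(budget_scaling(3, 0), 1)
  expect_equal(budget_scaling(0, 0), 0)
  b <- seq(0, 5, by = 0.5)
  expect_true(all(diff(budget_scaling(b, 1)) > 0))
})

test_that("toxicity increments only above thresholds", {
  u <- ref_universe
  ids <- u$metabolites$id
  below <- setNames(u$metabolites$toxicity * 0.9, ids)
  expect_equal(toxic_increment(below, u), 0)
  at2x <- setNames(numeric(9), ids)
  at2x["R"] <- 2 * u$metabolites$toxicity[ids == "R"]
  expect_equal(toxic_increment(at2x, u), 1)
  at2x["M4"] <- 2 * u$metabolites$toxicity[ids == "M4"]
  expect_equal(toxic_increment(at2x, u), 2)
  expect_equal(toxic_increment(at2x, u, dt = 0.5), 1)
})

test_that("death hazard starts at the intrinsic rate and saturates", {
  p <- dynamics_params()
  expect_equal(death_probability(0, p), 0.03)
  expect_equal(death_probability(p$s_tox, p), (1 + 0.03) / 2)
  expect_gt(death_probability(1e9, p), 0.999)
})

test_that("an empty cell just decays", {
  u <- ref_universe
  p <- dynamics_params()
  st <- cell_state(u, genome(), vol = 0.3, budget = 0,
                   internal = c(M1 = 0.2))
  pools <- setNames(numeric(9), u$metabolites$id)
  d <- cell_odes(st, pools, u, p, b_pop = 1)
  expect_equal(d$vol, -p$s_shrink * 0.3)
  deg_m1 <- u$metabolites$degradation[u$metabolites$id == "M1"]
  mdiff_m1 <- u$metabolites$diffusion[u$metabolites$id == "M1"]
  dil <- d$vol / 0.3
  expect_equal(unname(d$internal[["M1"]]),
               -deg_m1 * 0.2 - dil * 0.2 - mdiff_m1 * 0.2)
})

test_that("zero budget scaling freezes growth and expression", {
  u <- ref_universe
  p <- dynamics_params()
  st <- cell_state(u, simple_cell_genome(), vol = 0.4, budget = 0)
  pools <- setNames(numeric(9), u$metabolites$id)
  d <- cell_odes(st, pools, u, p, b_pop = 1)
  expect_equal(d$vol, -p$s_shrink * 0.4)
  ## expression term Pr * Bs vanishes; only decay and dilution remain
  expect_equal(d$protein,
               -p$prot_deg * st$protein - (d$vol / st$vol) * st$protein)
})

test_that("compiled integrator matches an independent lsoda solution", {
  skip_if_not_installed("deSolve")
  u <- ref_universe
  p <- dynamics_params()
  g <- simple_cell_genome()
  ids <- u$metabolites$id
  st <- cell_state(u, g, vol = 0.4, budget = 1,
                   internal = setNames(rep(0.3, 9), ids))
  pools <- setNames(rep(0.5, 9), ids); pools["R"] <- 6
  res <- integrate_cell(st, pools, u, p, b_pop = 0.1)
  expect_false(res$failed)
  rhs <- function(t, y, parms) {
    s <- st
    s$internal <- setNames(y[1:9], ids)
    s$budget <- y[[10]]; s$vol <- y[[11]]; s$e_tox <- y[[12]]
    s$protein <- y[13:15]
    d <- cell_odes(s, setNames(y[16:24], ids), u, p, b_pop = 0.1)
    list(unname(c(d$internal, d$budget, d$vol, d$e_tox, d$protein, d$pools)))
  }
  y0 <- unname(c(st$internal, st$budget, st$vol, 0, st$protein, pools))
  out <- deSolve::lsoda(y0, c(0, 1), rhs, NULL, rtol = 1e-10, atol = 1e-12)
  fin <- out[2, -1]
  mine <- unname(c(res$state$internal, res$state$budget, res$state$vol,
                   res$state$e_tox, res$state$protein, res$pools))
  ## default path: tight everywhere except the kinked toxicity integral
  expect_lt(max(abs(mine - fin)[-12]), 5e-4)
  expect_lt(abs(mine[12] - fin[12]), 5e-3)
  ## the explicit integrator resolves the kink too
  res2 <- integrate_cell(st, pools, u, dynamics_params(integrator = "rk45"),
                         b_pop = 0.1)
  mine2 <- unname(c(res2$state$internal, res2$state$budget, res2$state$vol,
                    res2$state$e_tox, res2$state$protein, res2$pools))
  expect_lt(max(abs(mine2 - fin)), 2e-4)
})

test_that("explicit and stiff integrators agree", {
  u <- ref_universe
  ids <- u$metabolites$id
  st <- cell_state(u, simple_cell_genome(), vol = 0.4, budget = 1,
                   internal = c(R = 0.05, E = 0.02))
  pools <- setNames(rep(0.05, 9), ids); pools["R"] <- 1
  r1 <- integrate_cell(st, pools, u, dynamics_params(integrator = "rk45"),
                       b_pop = 0.01)
  r2 <- integrate_cell(st, pools, u,
                       dynamics_params(integrator = "rosenbrock"),
                       b_pop = 0.01)
  expect_equal(r1$state$internal, r2$state$internal, tolerance = 1e-4)
  expect_equal(r1$state$vol, r2$state$vol, tolerance = 1e-5)
})

test_that("transported amounts balance the exchange ledger", {
  ## zero-degradation universe so transported mass is exactly conserved
  mets <- data.frame(
    id = c("R", "B1", "B2", "E", "M1"),
    mclass = c("resource", "building_block", "building_block", "energy",
               "intermediate"),
    diffusion = c(0.02, 0.01, 0.01, 0.05, 0.01), degradation = 0,
    toxicity = 10, mass = 1, influx = c(0.002, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  u0 <- evomicro:::build_universe("conserved", mets,
                                  c("R -> M1 + 2 E", "M1 -> B1 + E",
                                    "M1 -> B2", "2 M1 -> B2"),
                                  importers = c("R", "B1"),
                                  exporters = c("R", "B1"))
  p <- dynamics_params(b_deg = 1e-12)
  g <- genome(transporter_gene(u0, "R", FALSE, 1, 2, 0.5, 0.5))
  st <- cell_state(u0, g, vol = 0.4, budget = 0.5, internal = c(E = 0.5))
  pools <- setNames(c(2, 0, 0, 0, 0), u0$metabolites$id)
  res <- integrate_cell(st, pools, u0, p, b_pop = 1)
  ## importer accumulates internal resource
  expect_gt(res$state$internal[["R"]], 0)
  ## pool loss equals the gain in internal amount (conc x vol), per metabolite
  gain <- res$state$internal * res$state$vol - st$internal * st$vol
  ## clamping concentrations at zero injects mass error at the 1e-5 level
  expect_equal(unname(res$exchange[["R"]]), unname(gain[["R"]]),
               tolerance = 1e-4)
})

test_that("protein expression reaches its analytic steady state", {
  u <- ref_universe
  ## dilution-free setup: start at the volume fixed point, b_pop = 0 keeps
  ## the scaling at 1 while budget > 0, so dP/dt = Pr - prot_deg * P
  p <- dynamics_params(b_deg = 1e-9)
  vol_star <- 1 - p$s_shrink / p$g
  g <- genome(enzyme_gene(u, match("M1 + M2 -> M3", u$labels),
                          promoter = 1.5, vmax = 0.01, ks = 8))
  st <- cell_state(u, g, vol = vol_star, budget = 5, protein = 0)
  pools <- setNames(numeric(9), u$metabolites$id)
  for (k in 1:170) {
    res <- integrate_cell(st, pools, u, p, b_pop = 0)
    st <- res$state
    pools <- res$pools
  }
  expect_equal(st$protein, 1.5 / p$prot_deg, tolerance = 1e-6)
  expect_equal(st$vol, vol_star, tolerance = 1e-6)
})
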