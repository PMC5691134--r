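# FBA core: the LP solve, its status reporting, and model serialization.

test_that("a linear pathway is rate-limited by its sole uptake", {
  m <- linear_pathway_model(u = 10)
  r <- solve_fba(m)
  expect_equal(r$status, "optimal")
  expect_equal(r$biomass_flux, 10)
  # severing the pathway drops biomass to zero
  r0 <- solve_fba(m, flux_bounds("R1", lb = 0, ub = 0))
  expect_equal(r0$status, "optimal")
  expect_equal(r0$biomass_flux, 0)
  # a positive biomass lower bound then makes the problem infeasible
  rinf <- solve_fba(m, rbind(flux_bounds("R1", 0, 0),
                             flux_bounds("BIO", lb = 1)))
  expect_equal(rinf$status, "infeasible")
})

test_that("unknown reactions in overrides are an input error", {
  m <- linear_pathway_model()
  expect_error(solve_fba(m, flux_bounds("NOPE", 0, 0)),
               class = "fbagames_input_error")
})

test_that("a missing exchange bound is reported as unbounded, not clamped", {
  S <- rbind(A = c(SRC = 1, BIO = -1))
  m <- metabolic_network(S, lb = c(SRC = 0, BIO = 0),
                         ub = c(SRC = Inf, BIO = Inf), biomass = "BIO")
  expect_equal(solve_fba(m)$status, "unbounded")
})

test_that("random networks agree with an independent dense LP oracle", {
  set.seed(421)
  for (rep in 1:12) {
    g <- random_network_matrices()
    m <- tryCatch({
      dimnames(g$S) <- list(sprintf("m%d", 1:nrow(g$S)),
                            sprintf("r%d", 1:ncol(g$S)))
      metabolic_network(g$S, stats::setNames(g$lb, colnames(g$S)),
                        stats::setNames(g$ub, colnames(g$S)),
                        biomass = colnames(g$S)[ncol(g$S)])
    }, error = function(e) NULL)
    if (is.null(m)) next
    r <- solve_fba(m)
    o <- oracle_lp(g$S, g$lb, g$ub, g$cvec)
    expect_equal(r$status, o$status)
    if (r$status == "optimal") {
      expect_equal(r$biomass_flux, o$objective, tolerance = 1e-7)
      # mass balance and bounds on the reported flux vector
      expect_lt(max(abs(g$S %*% r$fluxes)), 1e-6)
      expect_true(all(r$fluxes >= g$lb - 1e-6 & r$fluxes <= g$ub + 1e-6))
    }
  }
})

test_that("optimal biomass scales with bounds and is monotone under tightening", {
  set.seed(99)
  for (rep in 1:5) {
    g <- random_network_matrices()
    dimnames(g$S) <- list(sprintf("m%d", 1:nrow(g$S)),
                          sprintf("r%d", 1:ncol(g$S)))
    m <- metabolic_network(g$S, stats::setNames(g$lb, colnames(g$S)),
                           stats::setNames(g$ub, colnames(g$S)),
                           biomass = colnames(g$S)[ncol(g$S)])
    r <- solve_fba(m)
    if (r$status != "optimal") next
    # homogeneity: scaling all bounds by lambda scales the optimum
    lam <- 2.5
    m2 <- m; m2$lb <- lam * m$lb; m2$ub <- lam * m$ub
    r2 <- solve_fba(m2)
    expect_equal(r2$biomass_flux, lam * r$biomass_flux, tolerance = 1e-7)
    # tightening one bound never increases the optimum
    j <- m$reactions[which.max(abs(r$fluxes))]
    m3 <- m; m3$ub[j] <- r$fluxes[j] * 0.5; m3$lb[j] <- min(m3$lb[j], m3$ub[j])
    r3 <- solve_fba(m3)
    if (r3$status == "optimal") {
      expect_lte(r3$biomass_flux, r$biomass_flux + 1e-8)
    }
  }
})

test_that("JSON model round-trip is exact and schema errors are caught", {
  fx <- make_sucrose_fixture(0.5, 0.4, glucose_medium = 1)
  path <- tempfile(fileext = ".json")
  write_model(fx$model, path)
  m2 <- read_model(path)
  expect_equal(m2$stoich, fx$model$stoich)
  expect_equal(m2$lb, fx$model$lb)
  expect_equal(m2$ub, fx$model$ub)
  expect_equal(m2$biomass, fx$model$biomass)
  expect_equal(m2$exchanges, fx$model$exchanges)
  expect_equal(m2$genes, fx$model$genes)
  # same optimum after the round trip
  expect_equal(solve_fba(m2)$biomass_flux, solve_fba(fx$model)$biomass_flux)

  bad <- tempfile(fileext = ".json")
  writeLines('{"metabolites": ["a"], "reactions": []}', bad)
  expect_error(read_model(bad), "biomass", class = "fbagames_input_error")
})

test_that("minimal SBML import maps species, reactions, bounds and objective", {
  sbml <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1">',
    '<model id="toy">',
    '<listOfParameters>',
    '  <parameter id="lb_m10" value="-10" constant="true"/>',
    '  <parameter id="ub_1000" value="1000" constant="true"/>',
    '</listOfParameters>',
    '<listOfSpecies>',
    '  <species id="A" compartment="c"/>',
    '  <species id="B" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '  <reaction id="EX_A" reversible="true" fbc:lowerFluxBound="lb_m10">',
    '    <listOfReactants>',
    '      <speciesReference species="A" stoichiometry="1"/>',
    '    </listOfReactants>',
    '  </reaction>',
    '  <reaction id="R1" reversible="false">',
    '    <listOfReactants>',
    '      <speciesReference species="A" stoichiometry="1"/>',
    '    </listOfReactants>',
    '    <listOfProducts>',
    '      <speciesReference species="B" stoichiometry="2"/>',
    '    </listOfProducts>',
    '  </reaction>',
    '  <reaction id="GROWTH" reversible="false" fbc:upperFluxBound="ub_1000">',
    '    <listOfReactants>',
    '      <speciesReference species="B" stoichiometry="1"/>',
    '    </listOfReactants>',
    '  </reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '  <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '    <fbc:listOfFluxObjectives>',
    '      <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>',
    '    </fbc:listOfFluxObjectives>',
    '  </fbc:objective>',
    '</fbc:listOfObjectives>',
    '</model>',
    '</sbml>'), sbml)
  m <- read_model(sbml, format = "sbml")
  expect_equal(length(m$metabolites), 2L)
  expect_equal(length(m$reactions), 3L)
  expect_equal(m$biomass, "GROWTH")
  expect_equal(unname(m$lb["EX_A"]), -10)
  expect_equal(unname(m$stoich["B", "R1"]), 2)
  # uptake of 10 A yields 20 B yields growth 20
  expect_equal(solve_fba(m)$biomass_flux, 20)
})
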