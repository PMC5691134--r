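# Genotype construction, constraint translation, and sustainable leakiness.

test_that("gene deletions map to reaction sets by union", {
  aa <- make_two_amino_acid_fixture()
  g <- from_gene_deletions(aa$model, "synA")
  expect_equal(g$deleted_reactions, "SYN_A")
  g2 <- from_gene_deletions(aa$model, c("synA", "synB"))
  expect_setequal(g2$deleted_reactions, c("SYN_A", "SYN_B"))
  expect_error(from_gene_deletions(aa$model, "nope"),
               class = "fbagames_input_error")

  # a reaction mapped by several genes is deleted when any of them is
  m <- aa$model
  m$genes <- list(g1 = c("SYN_A", "SYN_B"), g2 = "SYN_B")
  g3 <- from_gene_deletions(m, "g1")
  expect_setequal(g3$deleted_reactions, c("SYN_A", "SYN_B"))
})

test_that("an empty genotype solves exactly like the plain model", {
  aa <- make_two_amino_acid_fixture()
  plain <- solve_fba(aa$model)
  viag <- fbagames:::solve_genotype(aa$model, genotype("WT"))
  expect_equal(viag$biomass_flux, plain$biomass_flux)
})

test_that("deletion, forced leak and uptake constraints act as specified", {
  aa <- make_two_amino_acid_fixture()
  # strain 10: B synthesis deleted, leaks A at 0.1, B supplied by a partner
  g10 <- from_gene_deletions(aa$model, "synB", label = "10",
                             leaky = c(aaA = 0.1))
  r <- fbagames:::solve_genotype(aa$model, g10, c(aaB = 2))
  expect_equal(r$status, "optimal")
  expect_equal(unname(r$fluxes["SYN_B"]), 0)
  expect_gte(r$fluxes[["EX_aaA"]], 0.1)
  expect_gt(r$biomass_flux, 0)

  # double deletion with no supply: biomass collapses
  g00 <- from_gene_deletions(aa$model, c("synA", "synB"), label = "00")
  r00 <- fbagames:::solve_genotype(aa$model, g00)
  expect_true(r00$status == "infeasible" ||
                (r00$status == "optimal" && r00$biomass_flux < 1e-6))

  expect_error(apply_genotype(aa$model, genotype("bad", "BIOMASS")),
               "biomass", class = "fbagames_input_error")
  expect_error(apply_genotype(aa$model, genotype("bad", leaky = c(prec = 1))),
               "exchange", class = "fbagames_input_error")
})

test_that("maximum sustainable leakiness matches the closed-form budget", {
  # one unit of carbon yields one precursor; biomass consumes three
  # precursor-equivalents per unit (A + B + direct), so with uptake 10 the
  # entire budget can go to leaked A: e_max = 10 at a zero growth floor
  aa <- make_two_amino_acid_fixture()
  e1 <- max_sustainable_leakiness(aa$model, genotype("11"), "aaA",
                                  viability = 0, tol = 1e-3)
  expect_equal(e1, 10, tolerance = 1e-3)

  # halving tol moves the estimate by no more than the previous tol
  e2 <- max_sustainable_leakiness(aa$model, genotype("11"), "aaA",
                                  viability = 0, tol = 5e-4)
  expect_lt(abs(e2 - e1), 1e-3 + 1e-9)

  # metabolite the genotype cannot make: e_max = 0
  g01 <- from_gene_deletions(aa$model, "synA", label = "01",
                             uptakes = c(aaA = 1))
  expect_equal(max_sustainable_leakiness(aa$model, g01, "aaA"), 0)

  # non-viable genotype at e = 0 is an input error
  g00 <- from_gene_deletions(aa$model, c("synA", "synB"), label = "00")
  expect_error(max_sustainable_leakiness(aa$model, g00, "aaA"),
               "no sustainable leakiness", class = "fbagames_input_error")
})

test_that("the bisection bracket is tight: feasible at e_max, not beyond", {
  aa <- make_two_amino_acid_fixture(cost_A = 1.5, cost_B = 0.8)
  tol <- 1e-3
  for (met in c("aaA", "aaB")) {
    emax <- max_sustainable_leakiness(aa$model, genotype("11"), met,
                                      tol = tol)
    at <- function(e) {
      g <- genotype("11", leaky = stats::setNames(e, met))
      r <- fbagames:::solve_genotype(aa$model, g)
      r$status == "optimal" && r$biomass_flux >= 1e-6
    }
    expect_true(at(emax))
    expect_false(at(emax + 2 * tol))
  }
})

test_that("payoff is monotone: non-increasing in own leak, non-decreasing in supply", {
  aa <- make_two_amino_acid_fixture()
  biomass_at <- function(e, u) {
    g <- genotype("11", leaky = c(aaA = e))
    r <- fbagames:::solve_genotype(aa$model, g, c(aaB = u))
    if (r$status != "optimal") -Inf else r$biomass_flux
  }
  es <- seq(0, 9, by = 1.5)
  vals_e <- vapply(es, biomass_at, numeric(1), u = 0)
  expect_true(all(diff(vals_e) <= 1e-8))
  vals_u <- vapply(seq(0, 4, by = 0.8), function(u) biomass_at(4, u),
                   numeric(1))
  expect_true(all(diff(vals_u) >= -1e-8))
})
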