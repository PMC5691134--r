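# Synthetic toy metabolic models that structurally emulate the study
# systems: an invertase-style public-good network and a two-amino-acid
# biosynthesis network with optional pathway coupling.  Coefficients are
# small integers so every payoff has a hand-checkable LP solution.

#' Sucrose public-good fixture
#'
#' A minimal network for a producer/non-producer public-good game: sucrose
#' is hydrolyzed by an invertase-like reaction costing \code{atp_cost} ATP
#' per sucrose.  A fraction \code{leak_fraction} of the hydrolysis products
#' diffuses away as a public good (encoded directly in the reaction
#' stoichiometry as an obligatorily exported pool); the complement is
#' captured privately.  The producer (WT) carries the hydrolysis gene
#' \code{suc2}, is committed to hydrolyzing at full capacity through its
#' forced public-good export, and makes the diffusible share available to
#' interaction partners; the non-producer (MT) has the gene deleted and can
#' only grow on the shared pool plus any free glucose in the medium.
#' Catabolism has a capacity-limited high-yield route plus an unbounded
#' low-yield overflow route, so growth returns are concave but strictly
#' increasing in sugar supply.
#'
#' @param atp_cost ATP consumed per sucrose hydrolyzed (the invertase
#'   production cost x); >= 0.
#' @param leak_fraction fraction e of hydrolysis products lost as a public
#'   good, in [0, 1] (capture efficiency is \code{1 - leak_fraction}).
#' @param carbon_uptake sucrose uptake bound (mmol/gDW/h).
#' @param glucose_medium free glucose in the medium (mmol/gDW/h); 0 for a
#'   sucrose-only medium, raise it to study glucose supplementation.
#' @param cat_capacity flux capacity of the high-yield catabolic route.
#' @return List with \code{model} (a \code{\link{metabolic_network}}),
#'   \code{genotypes} (list \code{WT}, \code{MT}) and \code{params}.
#' @export
make_sucrose_fixture <- function(atp_cost, leak_fraction,
                                 carbon_uptake = 10, glucose_medium = 0,
                                 cat_capacity = 6) {
  if (atp_cost < 0) stop_input("atp_cost must be >= 0")
  if (leak_fraction < 0 || leak_fraction > 1) {
    stop_input("leak_fraction must lie in [0, 1]")
  }
  e <- leak_fraction
  mets <- c("suc", "glc", "hex", "hexout", "hexshared", "atp")
  rxns <- c("EX_suc", "EX_glc", "GLC_UPT", "HYD", "EX_hexout",
            "EX_hexshared", "SHARED_UPT", "CAT", "CAT_OVF", "BIOMASS",
            "ATPM", "HEX_OVF")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["suc", "EX_suc"] <- -1
  S["glc", "EX_glc"] <- -1
  S[c("glc", "hex"), "GLC_UPT"] <- c(-1, 1)
  # the e-fraction of hydrolysis products leaves as the public good
  S[c("suc", "atp", "hex", "hexout"), "HYD"] <-
    c(-1, -atp_cost, 2 * (1 - e), 2 * e)
  S["hexout", "EX_hexout"] <- -1
  S["hexshared", "EX_hexshared"] <- -1
  S[c("hexshared", "hex"), "SHARED_UPT"] <- c(-1, 1)
  S[c("hex", "atp"), "CAT"] <- c(-1, 2)
  S[c("hex", "atp"), "CAT_OVF"] <- c(-1, 1)  # low-yield overflow catabolism
  S[c("hex", "atp"), "BIOMASS"] <- c(-1, -1)
  S["atp", "ATPM"] <- -1     # non-growth ATP dissipation
  S["hex", "HEX_OVF"] <- -1  # surplus sugar is never growth-limiting
  lb <- c(EX_suc = -carbon_uptake, EX_glc = -glucose_medium, GLC_UPT = 0,
          HYD = 0, EX_hexout = 0, EX_hexshared = 0, SHARED_UPT = 0, CAT = 0,
          CAT_OVF = 0, BIOMASS = 0, ATPM = 0, HEX_OVF = 0)
  ub <- c(EX_suc = 0, EX_glc = 0, GLC_UPT = Inf, HYD = Inf, EX_hexout = Inf,
          EX_hexshared = Inf, SHARED_UPT = Inf, CAT = cat_capacity,
          CAT_OVF = Inf, BIOMASS = Inf, ATPM = Inf, HEX_OVF = Inf)
  model <- metabolic_network(S, lb, ub, biomass = "BIOMASS",
                             exchanges = c(suc = "EX_suc", glc = "EX_glc",
                                           hexout = "EX_hexout",
                                           hexshared = "EX_hexshared"),
                             genes = list(suc2 = "HYD"))
  leak_flux <- 2 * e * carbon_uptake  # full hydrolysis of the uptake bound
  # hexout and hexshared are the same physical commons, split so that each
  # independent FBA problem counts it once: the forced hexout export commits
  # the producer to full hydrolysis; hexshared carries what partners may draw.
  wt <- genotype("WT", leaky = c(hexout = leak_flux),
                 provides = c(hexshared = leak_flux))
  mt <- from_gene_deletions(model, "suc2", label = "MT")
  list(model = model, genotypes = list(WT = wt, MT = mt),
       params = list(atp_cost = atp_cost, leak_fraction = leak_fraction,
                     carbon_uptake = carbon_uptake,
                     glucose_medium = glucose_medium,
                     cat_capacity = cat_capacity, leak_flux = leak_flux))
}

#' Two-amino-acid cross-feeding fixture
#'
#' A carbon source is catabolized to a biosynthetic precursor plus ATP; two
#' amino acids A and B are synthesized from the precursor at ATP costs
#' \code{cost_A} and \code{cost_B}, and biomass requires both amino acids,
#' precursor and ATP.  Four genotypes arise from deleting the synthesis
#' genes: the full producer \code{"11"} (leaks both amino acids), the
#' partial producers \code{"10"} and \code{"01"} (each auxotrophic for one
#' amino acid, leaking the other) and the double auxotroph \code{"00"}.
#'
#' Pathway coupling variants:
#' \describe{
#'   \item{none}{independent A and B pathways.}
#'   \item{pleiotropy}{A's synthesis consumes the committed intermediate of
#'     B's pathway, so deleting B's gene also abolishes A synthesis (the
#'     \code{"10"} strain behaves like \code{"00"}); imported B cannot
#'     re-enter the committed pool.}
#'   \item{epistasis}{A's pathway co-produces a side metabolite required for
#'     biomass; strains lacking it must run an expensive salvage route, so a
#'     retained single pathway is worth more than naive cost accounting
#'     suggests.}
#' }
#'
#' @param cost_A,cost_B ATP cost per amino acid synthesized; > 0.
#' @param coupling \code{"none"}, \code{"pleiotropy"} or \code{"epistasis"}.
#' @param carbon_uptake carbon-source uptake bound (mmol/gDW/h).
#' @param salvage_cost ATP cost of the side-product salvage route
#'   (epistasis variant only).
#' @return List with \code{model}, \code{genotypes(leak_A, leak_B)} (a
#'   function returning the four genotypes at absolute leak fluxes),
#'   \code{e_max} (named vector: maximal sustainable leak flux of the full
#'   producer for each amino acid, leaked alone) and \code{params}.
#' @export
make_two_amino_acid_fixture <- function(cost_A = 1, cost_B = 1,
                                        coupling = c("none", "pleiotropy",
                                                     "epistasis"),
                                        carbon_uptake = 10,
                                        salvage_cost = 2) {
  coupling <- match.arg(coupling)
  if (cost_A <= 0 || cost_B <= 0) stop_input("amino acid costs must be > 0")
  mets <- c("carb", "prec", "aaA", "aaB", "atp")
  if (coupling == "pleiotropy") mets <- c(mets, "aaBint")
  if (coupling == "epistasis") mets <- c(mets, "side")
  rxns <- c("EX_carb", "CATB", "SYN_A", "SYN_B", "EX_aaA", "EX_aaB",
            "BIOMASS", "ATPM")
  if (coupling == "pleiotropy") rxns <- c(rxns, "SEC_B")
  if (coupling == "epistasis") rxns <- c(rxns, "SALVAGE", "DEG_side")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["carb", "EX_carb"] <- -1
  S[c("carb", "prec", "atp"), "CATB"] <- c(-1, 1, 2)
  S["aaA", "EX_aaA"] <- -1
  S["aaB", "EX_aaB"] <- -1
  S[c("aaA", "aaB", "prec", "atp"), "BIOMASS"] <- c(-1, -1, -1, -1)
  S["atp", "ATPM"] <- -1  # non-growth ATP dissipation
  if (coupling == "pleiotropy") {
    # B's pathway makes a committed intermediate; A's synthesis drains it
    S[c("prec", "atp", "aaBint"), "SYN_B"] <- c(-1, -cost_B, 1)
    S[c("aaBint", "aaB"), "SEC_B"] <- c(-1, 1)
    S[c("prec", "aaBint", "atp", "aaA"), "SYN_A"] <- c(-1, -1, -cost_A, 1)
  } else {
    S[c("prec", "atp", "aaA"), "SYN_A"] <- c(-1, -cost_A, 1)
    S[c("prec", "atp", "aaB"), "SYN_B"] <- c(-1, -cost_B, 1)
    if (coupling == "epistasis") {
      S["side", "SYN_A"] <- 1
      S[c("prec", "atp", "side"), "SALVAGE"] <- c(-2, -salvage_cost, 1)
      S["side", "DEG_side"] <- -1   # overflow sink: excess side is degraded
      S["side", "BIOMASS"] <- -1
    }
  }
  lb <- stats::setNames(numeric(length(rxns)), rxns)
  ub <- stats::setNames(rep(Inf, length(rxns)), rxns)
  lb["EX_carb"] <- -carbon_uptake; ub["EX_carb"] <- 0
  model <- metabolic_network(S, lb, ub, biomass = "BIOMASS",
                             exchanges = c(carb = "EX_carb", aaA = "EX_aaA",
                                           aaB = "EX_aaB"),
                             genes = list(synA = "SYN_A", synB = "SYN_B"))
  wt <- genotype("11")
  e_max <- c(
    aaA = max_sustainable_leakiness(model, wt, "aaA"),
    aaB = max_sustainable_leakiness(model, wt, "aaB"))
  genotypes <- function(leak_A, leak_B) {
    if (leak_A < 0 || leak_B < 0) stop_input("leak rates must be >= 0")
    list(
      "11" = genotype("11", leaky = c(aaA = leak_A, aaB = leak_B)),
      "10" = from_gene_deletions(model, "synB", label = "10",
                                 leaky = c(aaA = leak_A)),
      "01" = from_gene_deletions(model, "synA", label = "01",
                                 leaky = c(aaB = leak_B)),
      "00" = from_gene_deletions(model, c("synA", "synB"), label = "00"))
  }
  list(model = model, genotypes = genotypes, e_max = e_max,
       params = list(cost_A = cost_A, cost_B = cost_B, coupling = coupling,
                     carbon_uptake = carbon_uptake,
                     salvage_cost = salvage_cost))
}

#' Random viable network fixture
#'
#' Generates a random sparse stoichiometric network guaranteed to support a
#' positive biomass flux: a linear uptake-to-biomass backbone is laid down
#' first and random side reactions (always allowed to carry zero flux) are
#' added on top.  Useful as a property-test input generator.
#'
#' @param n_metabolites,n_reactions network size; must allow the backbone
#'   (at least 2 metabolites and 4 reactions).
#' @param seed integer seed; the same seed reproduces the same network.
#'   Mandatory: the generator never touches the global RNG stream.
#' @return A \code{\link{metabolic_network}} with positive optimal biomass.
#' @export
make_random_viable_fixture <- function(n_metabolites = 8, n_reactions = 12,
                                       seed) {
  if (missing(seed)) stop_input("seed is required")
  if (n_metabolites < 2 || n_reactions < 4) {
    stop_input("need at least 2 metabolites and 4 reactions")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(n_metabolites))
  n_chain <- min(n_metabolites, n_reactions - 2L)
  rxns <- c("EX_in", sprintf("R%02d", seq_len(n_chain - 1L)), "BIOMASS")
  n_extra <- n_reactions - length(rxns)
  rxns <- c(rxns, if (n_extra > 0) sprintf("X%02d", seq_len(n_extra)))
  S <- matrix(0, n_metabolites, length(rxns), dimnames = list(mets, rxns))
  S[1, "EX_in"] <- -1
  for (i in seq_len(n_chain - 1L)) {
    S[c(i, i + 1L), sprintf("R%02d", i)] <- c(-1, 1)
  }
  S[n_chain, "BIOMASS"] <- -1
  lb <- stats::setNames(rep(0, length(rxns)), rxns)
  ub <- stats::setNames(rep(10, length(rxns)), rxns)
  lb["EX_in"] <- -10; ub["EX_in"] <- 0
  for (j in grep("^X", rxns, value = TRUE)) {
    k <- sample(2:3, 1)
    picked <- sample(n_metabolites, k)
    S[picked, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    if (stats::runif(1) < 0.4) lb[j] <- -10
  }
  metabolic_network(S, lb, ub, biomass = "BIOMASS",
                    exchanges = stats::setNames("EX_in", mets[1]))
}
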