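# Genotypes: reaction deletions, forced leakage, and uptake allowances,
# expressed as constraint overrides on the FBA problem.
#
# Constraint semantics per exchange metabolite i: a forced net export
# v_EX_i >= e_i for every leaked metabolite, and an uptake allowance
# v_EX_i >= -u_i for every metabolite available from partners or the medium.
# Both are lower bounds on the same exchange flux, so when a genotype leaks a
# metabolite its forced export dominates any allowance (max(e_i, -u_i) = e_i):
# committed leakage is never offset by supply.  Goods a genotype sheds
# structurally (through reaction stoichiometry rather than a forced exchange)
# are declared in `provides`, which feeds partner availability only.

#' Define a genotype
#'
#' A genotype is a strain derived from the model's wild type by reaction
#' deletions, forced secretion ("leakiness") of specific metabolites, and
#' standing uptake allowances (e.g., for medium components beyond the model
#' defaults).
#'
#' @param label short strain label, e.g. \code{"WT"}, \code{"01"}.
#' @param deleted_reactions character vector of reaction ids whose flux is
#'   fixed to zero.
#' @param leaky named numeric vector: metabolite id -> forced net export flux
#'   e_i >= 0 (mmol/gDW/h).
#' @param uptakes named numeric vector: metabolite id -> maximum uptake flux
#'   u_i >= 0 the genotype may draw in any context.
#' @param provides named numeric vector: metabolite id -> flux shed
#'   structurally (through reaction stoichiometry, e.g. a public good split
#'   off during hydrolysis) and therefore available to interaction partners
#'   without a forced-export constraint on this genotype.
#' @return An object of class \code{genotype}.
#' @export
genotype <- function(label, deleted_reactions = character(),
                     leaky = numeric(), uptakes = numeric(),
                     provides = numeric()) {
  if ((length(leaky) && is.null(names(leaky))) ||
      (length(uptakes) && is.null(names(uptakes))) ||
      (length(provides) && is.null(names(provides)))) {
    stop_input("leaky, uptakes and provides must be named by metabolite")
  }
  if (any(leaky < 0) || any(uptakes < 0) || any(provides < 0)) {
    stop_input("leak rates, uptake allowances and provided fluxes must be >= 0")
  }
  structure(list(label = as.character(label),
                 deleted_reactions = unique(as.character(deleted_reactions)),
                 leaky = leaky, uptakes = uptakes, provides = provides),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("<genotype> %s\n", x$label))
  if (length(x$deleted_reactions))
    cat("  deleted:", paste(x$deleted_reactions, collapse = ", "), "\n")
  if (length(x$leaky))
    cat("  leaky:  ", paste(sprintf("%s=%.4g", names(x$leaky), x$leaky),
                            collapse = ", "), "\n")
  if (length(x$uptakes))
    cat("  uptakes:", paste(sprintf("%s=%.4g", names(x$uptakes), x$uptakes),
                            collapse = ", "), "\n")
  if (length(x$provides))
    cat("  provides:", paste(sprintf("%s=%.4g", names(x$provides), x$provides),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Build a genotype from gene deletions
#'
#' Maps deleted genes to reactions through the model's gene map and deletes
#' the union: a reaction is removed if any deleted gene maps to it, with no
#' boolean gene-protein-reaction logic.
#'
#' @param model a \code{\link{metabolic_network}} with a \code{genes} map.
#' @param genes character vector of gene ids to delete.
#' @param label strain label (default: genes joined by \code{"-"}).
#' @inheritParams genotype
#' @return A \code{\link{genotype}}.
#' @export
from_gene_deletions <- function(model, genes, label = NULL,
                                leaky = numeric(), uptakes = numeric()) {
  unknown <- setdiff(genes, names(model$genes))
  if (length(unknown)) {
    stop_input("unknown genes: %s", paste(unknown, collapse = ", "))
  }
  rxns <- unique(unlist(model$genes[genes], use.names = FALSE))
  if (is.null(rxns)) rxns <- character()
  genotype(label = if (is.null(label)) paste(genes, collapse = "-") else label,
           deleted_reactions = rxns, leaky = leaky, uptakes = uptakes)
}

#' Constrain an FBA problem to a genotype
#'
#' Translates a genotype into flux-bound overrides: deleted reactions are
#' fixed to zero; each leaky metabolite's exchange flux is bounded below by
#' its forced net export; each available metabolite's exchange flux is
#' allowed down to minus its total uptake allowance (standing allowances plus
#' \code{extra_supply}, typically partner leakage).
#'
#' @param model a \code{\link{metabolic_network}}.
#' @param g a \code{\link{genotype}}.
#' @param extra_supply named numeric vector of additional metabolite
#'   availability (mmol/gDW/h), added to the genotype's own allowances.
#' @return A \code{\link{flux_bounds}} data frame, ready for
#'   \code{\link{solve_fba}}.
#' @export
apply_genotype <- function(model, g, extra_supply = numeric()) {
  bad <- setdiff(g$deleted_reactions, model$reactions)
  if (length(bad)) {
    stop_input("genotype %s deletes unknown reactions: %s", g$label,
               paste(bad, collapse = ", "))
  }
  if (model$biomass %in% g$deleted_reactions) {
    stop_input("genotype %s deletes the biomass reaction", g$label)
  }
  cons <- NULL
  if (length(g$deleted_reactions)) {
    cons <- flux_bounds(g$deleted_reactions, lb = 0, ub = 0)
  }
  supply <- g$uptakes
  for (met in names(extra_supply)) {
    supply[met] <- (if (met %in% names(supply)) supply[[met]] else 0) +
      extra_supply[[met]]
  }
  mets <- union(union(names(g$leaky), names(supply)), names(g$provides))
  for (met in mets) {
    if (!met %in% names(model$exchanges)) {
      stop_input("genotype %s: metabolite %s has no exchange reaction",
                 g$label, met)
    }
    if (met %in% names(g$leaky)) {
      # forced export dominates any allowance: max(e, -u) = e
      cons <- rbind(cons, flux_bounds(model$exchanges[[met]],
                                      lb = g$leaky[[met]]))
    } else if (met %in% names(supply)) {
      cons <- rbind(cons, flux_bounds(model$exchanges[[met]],
                                      lb = -supply[[met]]))
    }
  }
  if (is.null(cons)) cons <- flux_bounds(character(0))
  cons
}

# One genotype-constrained FBA solve; shared by the payoff engine.
solve_genotype <- function(model, g, extra_supply = numeric()) {
  solve_fba(model, apply_genotype(model, g, extra_supply))
}

#' Maximum sustainable leakiness
#'
#' Finds the largest forced net export e of \code{metabolite} at which the
#' genotype's FBA problem remains feasible with biomass at or above the
#' viability threshold, by bisection.  Leakiness beyond this value is
#' "unsustainable": the strain cannot both grow and honor the export.
#'
#' The upper end of the initial bracket is determined by a secretion-capacity
#' LP (maximize the exchange flux under the genotype's constraints), which is
#' guaranteed to bracket the answer.
#'
#' @param model a \code{\link{metabolic_network}}.
#' @param g a \code{\link{genotype}}; must be viable at e = 0.
#' @param metabolite metabolite id with an exchange reaction.
#' @param tol absolute bisection tolerance in flux units; default 1e-4 times
#'   the initial bracket width.
#' @param viability minimum biomass flux (1/h) counted as growth.
#' @return The maximal sustainable export flux (mmol/gDW/h); 0 when the
#'   genotype cannot secrete the metabolite at all.
#' @export
max_sustainable_leakiness <- function(model, g, metabolite, tol = NULL,
                                      viability = 1e-6) {
  if (!metabolite %in% names(model$exchanges)) {
    stop_input("metabolite %s has no exchange reaction", metabolite)
  }
  g0 <- g
  g0$leaky <- g$leaky[setdiff(names(g$leaky), metabolite)]
  base <- solve_genotype(model, g0)
  if (base$status != "optimal" || base$biomass_flux < viability) {
    stop_input("genotype %s has no sustainable leakiness: non-viable at e = 0",
               g$label)
  }
  # secretion capacity: max v_EX_met under genotype constraints (no viability)
  ex <- model$exchanges[[metabolite]]
  cons <- apply_genotype(model, g0)
  lb <- model$lb; ub <- model$ub
  for (i in seq_len(nrow(cons))) {
    j <- cons$reaction[i]
    if (!is.na(cons$lb[i])) lb[j] <- cons$lb[i]
    if (!is.na(cons$ub[i])) ub[j] <- cons$ub[i]
  }
  cap <- lp_solve(as.numeric(model$reactions == ex), model$stoich,
                  numeric(length(model$metabolites)), lb, ub, maximize = TRUE)
  if (cap$status == "unbounded") {
    stop_input("secretion of %s is unbounded; add an exchange upper bound",
               metabolite)
  }
  if (cap$status != "optimal" || cap$objective <= 0) return(0)
  hi <- cap$objective
  feasible_at <- function(e) {
    gg <- g0
    gg$leaky <- c(g0$leaky, stats::setNames(e, metabolite))
    r <- solve_genotype(model, gg)
    r$status == "optimal" && r$biomass_flux >= viability
  }
  if (is.null(tol)) tol <- 1e-4 * hi
  if (feasible_at(hi)) return(hi)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible_at(mid)) lo <- mid else hi <- mid
  }
  lo
}
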