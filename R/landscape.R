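# Parameter-grid scans: per-cell payoff games, Nash sets and game classes,
# plus the sustainable-leakiness and cross-feeding-only region masks.

#' Classify a two-strategy producer/non-producer game
#'
#' Maps the Nash set of a symmetric two-strategy game onto the canonical
#' game classes, with C the producer (cooperator) and D the non-producer:
#' \itemize{
#'   \item \code{non_viable}: every payoff is at the death rate.
#'   \item \code{snowdrift}: Nash set is exactly \{(C,D), (D,C)\}
#'     (coexistence).
#'   \item \code{mutually_beneficial}: (C,C) is Nash and (D,D) is not.
#'   \item \code{prisoners_dilemma}: (D,D) is the only Nash profile and
#'     mutual production would pay more (a_CC > a_DD).
#'   \item \code{producer_dominance}: none of the above and the
#'     non-producer is non-viable in every profile.
#'   \item \code{other}: any remaining payoff ordering.
#' }
#'
#' @param nash a \code{\link{find_nash_ilp}} result for the game.
#' @param game the symmetric two-strategy \code{\link{payoff_game}}.
#' @param cooperator,defector strategy labels of the producer and
#'   non-producer.
#' @param viability minimum payoff counted as growth.
#' @return An object of class \code{game_class}: list with \code{label} and
#'   \code{nash_profiles}.
#' @export
classify_game <- function(nash, game, cooperator, defector,
                          viability = 1e-6) {
  labels <- game$strategies[[1]]
  if (length(labels) != 2L) {
    stop_input(paste("classify_game handles 2-strategy games; classify",
                     "pairwise sub-games (restrict_game) for larger ones"))
  }
  if (!all(c(cooperator, defector) %in% labels)) {
    stop_input("cooperator/defector labels not in the game")
  }
  A <- game$payoffs[[1]]
  a <- function(i, j) A[i, j]
  eqs <- nash_profile_strings(nash)
  has <- function(p, q) paste(p, q, sep = ",") %in% eqs
  C <- cooperator; D <- defector
  label <-
    if (all(A < viability)) "non_viable"
    else if (setequal(eqs, c(paste(C, D, sep = ","), paste(D, C, sep = ","))))
      "snowdrift"
    else if (has(C, C) && !has(D, D)) "mutually_beneficial"
    else if (setequal(eqs, paste(D, D, sep = ",")) && a(C, C) > a(D, D))
      "prisoners_dilemma"
    else if (all(A[D, ] < viability) && all(A[D, ] <= a(D, D) + 1e-12))
      "producer_dominance"
    else "other"
  structure(list(label = label, nash_profiles = nash$equilibria),
            class = "game_class")
}

#' @export
print.game_class <- function(x, ...) {
  cat("<game_class>", x$label, "\n")
  invisible(x)
}

#' Scan a two-parameter grid of games
#'
#' For every grid cell, \code{factory} is called with the two named axis
#' values and must return a list with \code{model}, \code{genotypes} (list
#' of \code{\link{genotype}}s) and optionally \code{cooperator},
#' \code{defector} (enables classification of two-strategy cells) and
#' \code{full_producer} (label whose unassisted payoff -- honoring its leak
#' with no partner supply -- defines the sustainable region).  The payoff game, Nash set, and game class are
#' recorded per cell.  The scan is deterministic: no randomness enters any
#' stage.
#'
#' @param factory cell-builder function, called as
#'   \code{factory(axis1 = value1, axis2 = value2)} with the axis names.
#' @param axis1,axis2 lists \code{list(name = "...", values = numeric)}.
#' @param order number of players per cell game.
#' @param death_rate,viability payoff-engine constants.
#' @param aggregation partner-supply aggregation rule, see
#'   \code{\link{build_payoff_tensor}}.
#' @return An object of class \code{game_landscape}: list with \code{cells}
#'   (data frame: axis values, game class label, JSON-encoded Nash
#'   profiles, full-producer payoff and viability), \code{nash} and
#'   \code{games} (per-cell lists, row-aligned with \code{cells}) and
#'   \code{axes}.
#' @export
scan_landscape <- function(factory, axis1, axis2, order = 2,
                           death_rate = -0.05, viability = 1e-6,
                           aggregation = "sum") {
  stopifnot(is.list(axis1), is.list(axis2),
            !is.null(axis1$name), !is.null(axis2$name))
  grid <- expand.grid(a1 = axis1$values, a2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  n_cell <- nrow(grid)
  cells <- data.frame(grid$a1, grid$a2,
                      game_class = NA_character_,
                      nash_profiles = NA_character_,
                      n_viable_nash = NA_integer_,
                      producer_payoff = NA_real_,
                      producer_viable = NA,
                      stringsAsFactors = FALSE)
  names(cells)[1:2] <- c(axis1$name, axis2$name)
  nash_list <- vector("list", n_cell)
  game_list <- vector("list", n_cell)
  for (i in seq_len(n_cell)) {
    args <- stats::setNames(list(grid$a1[i], grid$a2[i]),
                            c(axis1$name, axis2$name))
    cell <- tryCatch(do.call(factory, args), error = function(e) {
      stop_internal("factory failed at cell (%s=%g, %s=%g): %s",
                    axis1$name, grid$a1[i], axis2$name, grid$a2[i],
                    conditionMessage(e))
    })
    game <- tryCatch(
      build_payoff_tensor(cell$model, unname(cell$genotypes), order = order,
                          death_rate = death_rate, viability = viability,
                          aggregation = aggregation),
      error = function(e) {
        stop_internal("payoff solve failed at cell (%s=%g, %s=%g): %s",
                      axis1$name, grid$a1[i], axis2$name, grid$a2[i],
                      conditionMessage(e))
      })
    nash <- find_nash_ilp(game)
    nash_list[[i]] <- nash
    game_list[[i]] <- game
    cells$nash_profiles[i] <- as.character(
      jsonlite::toJSON(nash_profile_strings(nash)))
    cells$n_viable_nash[i] <- sum(nash_viable(nash, viability))
    if (!is.null(cell$full_producer)) {
      fp <- which(vapply(cell$genotypes, function(g) g$label,
                         character(1)) == cell$full_producer)
      if (!length(fp)) stop_input("full_producer label not among genotypes")
      # unassisted: the producer must honor its leak with no partner supply
      cells$producer_payoff[i] <- genotype_payoff(
        cell$model, cell$genotypes[[fp[1]]], numeric(), death_rate, viability)
      cells$producer_viable[i] <- cells$producer_payoff[i] >= viability
    }
    if (!is.null(cell$cooperator) && length(cell$genotypes) == 2L) {
      cls <- classify_game(nash, game, cell$cooperator, cell$defector,
                           viability = viability)
      cells$game_class[i] <- cls$label
    }
  }
  structure(list(cells = cells, nash = nash_list, games = game_list,
                 axes = list(axis1 = axis1, axis2 = axis2)),
            class = "game_landscape")
}

#' @export
print.game_landscape <- function(x, ...) {
  ax <- x$axes
  cat(sprintf("<game_landscape> %d x %d grid (%s x %s)\n",
              length(ax$axis1$values), length(ax$axis2$values),
              ax$axis1$name, ax$axis2$name))
  if (!all(is.na(x$cells$game_class))) {
    print(table(x$cells$game_class, useNA = "no"))
  }
  invisible(x)
}

#' Sustainable-leakiness region of a landscape
#'
#' The cells at which the full producer still sustains growth: its payoff
#' at its declared leak levels, without any partner-supplied metabolites,
#' is at or above the viability threshold.  Returns a
#' logical matrix (axis1 values in rows, axis2 in columns).
#'
#' @param landscape a \code{\link{scan_landscape}} result whose factory set
#'   \code{full_producer}.
#' @param viability minimum payoff counted as growth.
#' @return Logical matrix mask over the grid.
#' @export
sustainable_region <- function(landscape, viability = 1e-6) {
  cells <- landscape$cells
  if (all(is.na(cells$producer_payoff))) {
    stop_input("landscape carries no full-producer payoffs")
  }
  ax <- landscape$axes
  matrix(cells$producer_payoff >= viability,
         nrow = length(ax$axis1$values),
         dimnames = list(ax$axis1$values, ax$axis2$values))
}

#' Write a landscape to TSV
#'
#' One row per grid cell: both axis values, game class, JSON-encoded Nash
#' profiles, number of fully viable equilibria, and the full-producer
#' payoff/viability flag.
#'
#' @param landscape a \code{game_landscape}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.table(landscape$cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default leakiness axis
#'
#' Evenly spaced leakiness levels from 0 to 100 percent of the full
#' producer's maximal sustainable leak; the default 21 levels (5-percent
#' steps) give a 441-cell two-axis grid.
#'
#' @param levels number of grid levels per axis.
#' @return Numeric vector of percentages.
#' @export
leakiness_grid <- function(levels = 21) {
  seq(0, 100, length.out = levels)
}

#' The 20 proteinogenic amino acids
#' @return Character vector of three-letter names.
#' @export
amino_acids <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
}

#' Enumerate unordered amino-acid pairs
#'
#' All unordered pairs of distinct names, minus explicit exclusions, in
#' deterministic lexicographic order.
#'
#' @param amino_acids character vector of distinct names.
#' @param exclusions list of length-2 character vectors (unordered) to
#'   drop; every exclusion must be a pair of the input set.
#' @return Data frame with columns \code{a} and \code{b}.
#' @export
#' @examples
#' nrow(enumerate_amino_acid_pairs(amino_acids(),
#'                                 exclusions = list(c("Ala", "Ile"))))
enumerate_amino_acid_pairs <- function(amino_acids, exclusions = list()) {
  if (anyDuplicated(amino_acids)) stop_input("duplicate amino acid names")
  aa <- sort(amino_acids)
  pairs <- t(utils::combn(aa, 2))
  keys <- paste(pairs[, 1], pairs[, 2], sep = "|")
  for (ex in exclusions) {
    if (length(ex) != 2L) stop_input("each exclusion must be a pair")
    k <- paste(sort(ex), collapse = "|")
    if (!k %in% keys) {
      stop_input("exclusion (%s) is not a pair of the input set",
                 paste(ex, collapse = ", "))
    }
    keys_keep <- keys != k
    pairs <- pairs[keys_keep, , drop = FALSE]
    keys <- keys[keys_keep]
  }
  data.frame(a = pairs[, 1], b = pairs[, 2], stringsAsFactors = FALSE)
}

#' Grid-cell factories for the bundled fixtures
#'
#' \code{sucrose_factory} returns a factory over axes \code{atp_cost_x}
#' (invertase cost) and \code{capture_efficiency_e} (fraction of hydrolysis
#' products captured privately; the leaked fraction is its complement).
#' \code{two_amino_acid_factory} returns a factory over axes
#' \code{leakiness_A} and \code{leakiness_B}, expressed as percentages of
#' the full producer's maximal sustainable leak flux for each amino acid
#' (converted internally to absolute fluxes).
#'
#' @param glucose_medium free glucose in the medium for every cell.
#' @param carbon_uptake carbon-source uptake bound.
#' @param cat_capacity catabolic capacity (sucrose fixture).
#' @return A function suitable as the \code{factory} argument of
#'   \code{\link{scan_landscape}}.
#' @export
sucrose_factory <- function(glucose_medium = 2, carbon_uptake = 10,
                            cat_capacity = 6) {
  function(atp_cost_x, capture_efficiency_e) {
    fx <- make_sucrose_fixture(atp_cost = atp_cost_x,
                               leak_fraction = 1 - capture_efficiency_e,
                               carbon_uptake = carbon_uptake,
                               glucose_medium = glucose_medium,
                               cat_capacity = cat_capacity)
    list(model = fx$model, genotypes = fx$genotypes,
         cooperator = "WT", defector = "MT", full_producer = "WT")
  }
}

#' @rdname sucrose_factory
#' @param fixture a \code{\link{make_two_amino_acid_fixture}} result; the
#'   model and its leakiness calibration are shared across all cells.
#' @export
two_amino_acid_factory <- function(fixture) {
  function(leakiness_A, leakiness_B) {
    if (min(leakiness_A, leakiness_B) < 0 ||
        max(leakiness_A, leakiness_B) > 100) {
      stop_input("leakiness axes are percentages in [0, 100]")
    }
    g <- fixture$genotypes(leakiness_A / 100 * fixture$e_max[["aaA"]],
                           leakiness_B / 100 * fixture$e_max[["aaB"]])
    list(model = fixture$model, genotypes = g, full_producer = "11")
  }
}
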