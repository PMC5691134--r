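# Payoff engine: growth-rate payoffs for every strategy profile of an
# n-player game, one genotype-specific FBA solve per (focal, partners) pair.

#' Construct a game from payoff matrices or arrays
#'
#' Low-level constructor for game objects.  \code{matrix_game} builds a
#' two-player game from the row player's payoff matrix \code{A} and the
#' column player's matrix \code{B} (defaults to \code{t(A)}, a symmetric
#' game).  \code{payoff_game} accepts one payoff array per player for
#' arbitrary player counts.
#'
#' @param A,B numeric payoff matrices for the row and column player.
#' @param labels list of strategy label vectors, one per player (recycled
#'   from dimnames when available).
#' @param death_rate payoff assigned to non-viable strains in FBA-derived
#'   games; \code{NA} for abstract games.
#' @return An object of class \code{payoff_game} with fields
#'   \code{n_players}, \code{strategies} (list of label vectors),
#'   \code{payoffs} (list of arrays, \code{payoffs[[s]][i1, ..., in]} is
#'   player s's payoff at that profile), \code{death_rate} and
#'   \code{symmetric}.
#' @export
#' @examples
#' pd <- matrix_game(rbind(c(3, 0), c(5, 1)), labels = c("C", "D"))
#' find_nash(pd)
matrix_game <- function(A, B = t(A), labels = NULL, death_rate = NA_real_) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop_input("A and B must have equal dimensions")
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(A))) rownames(A)
              else paste0("s", seq_len(nrow(A)))
  }
  if (!is.list(labels)) labels <- list(labels, labels[seq_len(ncol(A))])
  payoff_game(list(A, B), strategies = labels, death_rate = death_rate,
              symmetric = isTRUE(all.equal(A, t(B), check.attributes = FALSE)))
}

#' @rdname matrix_game
#' @param payoffs list of numeric arrays, one per player, all with dimension
#'   \code{sapply(strategies, length)}.
#' @param strategies list of strategy label vectors, one per player.
#' @param symmetric logical: single-population game whose payoff arrays are
#'   slot permutations of the first (required by the replicator dynamics).
#' @export
payoff_game <- function(payoffs, strategies, death_rate = NA_real_,
                        symmetric = FALSE) {
  n <- length(payoffs)
  if (n < 2) stop_input("a game needs at least 2 players")
  if (length(strategies) != n) {
    stop_input("need one strategy label vector per player")
  }
  sizes <- vapply(strategies, length, integer(1))
  payoffs <- lapply(payoffs, function(a) {
    a <- if (is.null(dim(a))) array(a, dim = sizes) else as.array(a)
    if (!identical(as.integer(dim(a)), as.integer(sizes))) {
      stop_input("payoff array dimensions must match strategy counts")
    }
    if (anyNA(a)) stop_input("payoff arrays must be complete (no NA entries)")
    dimnames(a) <- strategies
    a
  })
  structure(list(n_players = n, strategies = strategies, payoffs = payoffs,
                 death_rate = death_rate, symmetric = symmetric),
            class = "payoff_game")
}

#' @export
print.payoff_game <- function(x, ...) {
  cat(sprintf("<payoff_game> %d players, strategies: %s%s\n", x$n_players,
              paste(vapply(x$strategies, length, integer(1)), collapse = "x"),
              if (x$symmetric) " (symmetric)" else ""))
  if (x$n_players == 2 && length(x$strategies[[1]]) <= 6) {
    cat("player 1 payoffs:\n")
    print(x$payoffs[[1]])
  }
  invisible(x)
}

#' Pairwise payoffs of two interacting genotypes
#'
#' Solves two independent FBA problems, one per genotype, each assuming
#' availability of the metabolites leaked (or structurally shed, see the
#' \code{provides} field of \code{\link{genotype}}) by the other.  The payoff is the optimal biomass flux, or the death
#' rate when the problem is infeasible or growth falls below the viability
#' threshold.
#'
#' @param model a \code{\link{metabolic_network}}.
#' @param k,k_prime \code{\link{genotype}} objects.
#' @param death_rate negative payoff (1/h) for non-viable strains.
#' @param viability minimum biomass flux counted as growth.
#' @return Named numeric vector of length 2: the payoff of \code{k} facing
#'   \code{k_prime}, and of \code{k_prime} facing \code{k}.
#' @export
pairwise_payoff <- function(model, k, k_prime, death_rate = -0.05,
                            viability = 1e-6) {
  c(stats::setNames(
    genotype_payoff(model, k, shed_fluxes(k_prime), death_rate, viability),
    k$label),
    stats::setNames(
      genotype_payoff(model, k_prime, shed_fluxes(k), death_rate, viability),
      k_prime$label))
}

# What a genotype makes available to its partners: forced leaks plus
# structurally shed goods.
shed_fluxes <- function(g) {
  out <- g$leaky
  for (met in names(g$provides)) {
    out[met] <- (if (met %in% names(out)) out[[met]] else 0) + g$provides[[met]]
  }
  out
}

genotype_payoff <- function(model, g, supply, death_rate, viability,
                            cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    sup <- if (length(supply)) supply[order(names(supply))] else numeric()
    key <- paste(g$label, paste(names(sup), signif(sup, 12), collapse = ";"),
                 sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  res <- solve_genotype(model, g, supply)
  if (res$status == "unbounded") {
    stop_internal("unbounded FBA problem for genotype %s", g$label)
  }
  pay <- if (res$status == "optimal" && res$biomass_flux >= viability) {
    res$biomass_flux
  } else {
    death_rate
  }
  if (!is.null(key)) cache[[key]] <- pay
  pay
}

#' Build the payoff tensor of an n-player genotype game
#'
#' For every ordered strategy profile the focal genotype's FBA problem is
#' solved with metabolite availability aggregated over its partners' declared
#' leak rates, and the optimal biomass flux (or the death rate) recorded.
#' Solves are cached on the (genotype, availability) signature, so symmetric
#' profiles do not repeat LP work.
#'
#' @param model a \code{\link{metabolic_network}}.
#' @param genotypes list of \code{\link{genotype}} objects (the shared
#'   strategy set of all players).
#' @param order number of players n >= 2.
#' @param aggregation how partner leaks combine into availability:
#'   \code{"sum"} (each consumer may draw the full leaked flux of every
#'   partner; default) or \code{"split"} (each partner's leak is divided
#'   evenly among its n-1 co-players).
#' @inheritParams pairwise_payoff
#' @return A symmetric \code{\link{payoff_game}} whose entry
#'   \code{payoffs[[1]][k, k2, ..., kn]} is the growth payoff of genotype k
#'   facing partners k2, ..., kn.
#' @export
build_payoff_tensor <- function(model, genotypes, order = 2,
                                death_rate = -0.05, viability = 1e-6,
                                aggregation = c("sum", "split")) {
  aggregation <- match.arg(aggregation)
  if (order < 2) stop_input("order must be >= 2")
  if (!length(genotypes)) stop_input("genotypes must be nonempty")
  labels <- unname(vapply(genotypes, function(g) g$label, character(1)))
  if (anyDuplicated(labels)) stop_input("genotype labels must be unique")
  K <- length(genotypes)
  A <- array(NA_real_, dim = rep(K, order))
  cache <- new.env(parent = emptyenv())
  idx <- as.matrix(expand.grid(rep(list(seq_len(K)), order)))
  for (r in seq_len(nrow(idx))) {
    prof <- idx[r, ]
    partners <- prof[-1]
    supply <- numeric()
    for (p in partners) {
      lk <- shed_fluxes(genotypes[[p]])
      for (met in names(lk)) {
        supply[met] <- (if (met %in% names(supply)) supply[[met]] else 0) +
          lk[[met]]
      }
    }
    if (aggregation == "split" && length(supply)) {
      supply <- supply / (order - 1)
    }
    A[matrix(prof, 1)] <- genotype_payoff(model, genotypes[[prof[1]]], supply,
                                          death_rate, viability, cache)
  }
  # player s's payoff at a profile = focal payoff with slot s moved first
  payoffs <- lapply(seq_len(order), function(s) {
    aperm(A, c(s, setdiff(seq_len(order), s)))
  })
  payoff_game(payoffs, strategies = rep(list(labels), order),
              death_rate = death_rate, symmetric = TRUE)
}

#' Read and write payoff games
#'
#' JSON is the lossless interchange format (player count, strategy labels,
#' all payoff arrays, death rate).  TSV is supported for symmetric games:
#' rows are the focal strategy, columns the opponent profile (labels joined
#' by \code{"|"}), cells the focal payoff.
#'
#' @param game a \code{\link{payoff_game}}.
#' @param path output file.
#' @param format \code{"json"} or \code{"tsv"}; guessed from the extension.
#' @return \code{write_payoffs} returns \code{path} invisibly;
#'   \code{read_payoffs} a \code{\link{payoff_game}}.
#' @export
write_payoffs <- function(game, path, format = c("guess", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "tsv") {
    if (!game$symmetric) stop_input("TSV payoff export requires a symmetric game")
    A <- game$payoffs[[1]]
    K <- dim(A)[1]; n <- game$n_players
    M <- matrix(A, nrow = K)
    opp <- as.matrix(expand.grid(rep(game$strategies[1], n - 1)))
    colnames(M) <- apply(opp, 1, paste, collapse = "|")
    rownames(M) <- game$strategies[[1]]
    utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    doc <- list(n_players = game$n_players, strategies = game$strategies,
                death_rate = game$death_rate, symmetric = game$symmetric,
                payoffs = lapply(game$payoffs, function(a) {
                  list(dim = dim(a), values = as.vector(a))
                }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_payoffs
#' @export
read_payoffs <- function(path, format = c("guess", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character")
    labels <- df[[1]]  # kept as character: strain labels may look numeric
    M <- as.matrix(as.data.frame(lapply(df[-1], as.numeric)))
    colnames(M) <- colnames(df)[-1]
    rownames(M) <- labels
    K <- length(labels)
    n <- 1L + length(strsplit(colnames(M)[1], "|", fixed = TRUE)[[1]])
    A <- array(as.numeric(M), dim = rep(K, n))
    payoffs <- lapply(seq_len(n), function(s) {
      aperm(A, c(s, setdiff(seq_len(n), s)))
    })
    return(payoff_game(payoffs, strategies = rep(list(labels), n),
                       symmetric = TRUE))
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  strategies <- if (is.matrix(doc$strategies)) {
    lapply(seq_len(nrow(doc$strategies)), function(i) doc$strategies[i, ])
  } else {
    as.list(doc$strategies)
  }
  if (is.data.frame(doc$payoffs)) {
    payoffs <- lapply(seq_len(nrow(doc$payoffs)), function(i) {
      array(doc$payoffs$values[[i]], dim = doc$payoffs$dim[[i]])
    })
  } else {
    payoffs <- lapply(doc$payoffs, function(p) array(p$values, dim = p$dim))
  }
  payoff_game(payoffs, strategies = strategies,
              death_rate = if (is.null(doc$death_rate)) NA_real_
                           else doc$death_rate,
              symmetric = isTRUE(doc$symmetric))
}

# Restrict a symmetric game to a subset of strategies (by label).
restrict_game <- function(game, labels) {
  if (!game$symmetric) stop_input("restrict_game needs a symmetric game")
  all_lab <- game$strategies[[1]]
  keep <- match(labels, all_lab)
  if (anyNA(keep)) {
    stop_input("unknown strategy labels: %s",
               paste(labels[is.na(keep)], collapse = ", "))
  }
  n <- game$n_players
  sub <- lapply(game$payoffs, function(a) {
    do.call(`[`, c(list(a), rep(list(keep), n), list(drop = FALSE)))
  })
  payoff_game(sub, strategies = rep(list(labels), n),
              death_rate = game$death_rate, symmetric = TRUE)
}
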