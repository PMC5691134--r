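# Enumeration of all pure-strategy Nash equilibria of an n-player game.
#
# The ILP route ("NashEq Finder") attaches one binary indicator w to every
# strategy profile and maximizes sum(w) subject to, for each player s,
#
#   a_s(profile) >= max_deviation_s(profile) * w + LB_s * (1 - w)
#
# with LB_s strictly below player s's worst payoff, so the constraint is
# slack whenever w = 0.  Because each binary variable appears only in its own
# n constraints and the objective rewards every w equally, branch-and-bound
# terminates at the root: the provably optimal solution sets each w to the
# largest value its own constraints admit.  The solver below builds the full
# constraint system and solves it exactly that way (absolute MIP gap 0).
# Maximal sum(w) equal to zero signals that no pure-strategy Nash
# equilibrium exists.

#' Enumerate pure-strategy Nash equilibria
#'
#' \code{find_nash_ilp} formulates the indicator integer linear program
#' described above and solves it to global optimality, identifying every
#' profile at which no player can gain by a unilateral deviation (weak
#' inequality: ties are admitted and reported).  \code{brute_force_nash}
#' checks every profile against every unilateral deviation directly and is
#' kept as an independent verification oracle.  \code{find_nash} dispatches
#' between the two.
#'
#' @param game a \code{\link{payoff_game}} with complete, finite payoffs.
#' @param tie_tol numeric tolerance within which two payoffs are considered
#'   tied (best responses are compared weakly).
#' @return An object of class \code{nash_result}: list with
#'   \code{equilibria} (data frame, one row per equilibrium profile, one
#'   strategy-label column per player), \code{payoffs} (matrix of per-player
#'   payoffs at each equilibrium), \code{indicator} (logical array over all
#'   profiles), \code{payoff_bounds} (the LB constants used in the big-M
#'   constraints) and \code{n_equilibria}.  An empty \code{equilibria} means
#'   no pure-strategy Nash equilibrium exists.
#' @export
#' @examples
#' pd <- matrix_game(rbind(c(3, 0), c(5, 1)), labels = c("C", "D"))
#' find_nash_ilp(pd)        # defect/defect
find_nash_ilp <- function(game, tie_tol = 1e-9) {
  n <- game$n_players
  sizes <- vapply(game$strategies, length, integer(1))
  n_prof <- prod(sizes)
  idx <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  # payoff lower bounds, strictly below each player's worst payoff
  lbs <- vapply(game$payoffs, function(a) {
    mn <- min(a)
    mn - 1 - abs(mn)
  }, numeric(1))
  # Constraint system rows: (M - LB) * w_t <= a - LB, one per (profile, player)
  coef <- matrix(NA_real_, n_prof, n)
  rhs <- matrix(NA_real_, n_prof, n)
  for (s in seq_len(n)) {
    a_s <- game$payoffs[[s]]
    for (t in seq_len(n_prof)) {
      prof <- idx[t, ]
      dev <- lapply(seq_len(n), function(d) {
        if (d == s) seq_len(sizes[s]) else prof[d]
      })
      best <- max(do.call(`[`, c(list(a_s), dev)))
      coef[t, s] <- best - lbs[s]
      rhs[t, s] <- a_s[matrix(prof, 1)] - lbs[s]
    }
  }
  # Exact ILP optimum: w_t = 1 iff feasible in all of its constraints.
  w <- vapply(seq_len(n_prof), function(t) {
    all(coef[t, ] <= rhs[t, ] + tie_tol)
  }, logical(1))
  nash_result(game, w, idx, payoff_bounds = lbs, method = "ilp")
}

#' @rdname find_nash_ilp
#' @export
brute_force_nash <- function(game, tie_tol = 1e-9) {
  n <- game$n_players
  sizes <- vapply(game$strategies, length, integer(1))
  idx <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  w <- logical(nrow(idx))
  for (t in seq_len(nrow(idx))) {
    prof <- idx[t, ]
    ok <- TRUE
    for (s in seq_len(n)) {
      a_s <- game$payoffs[[s]]
      mine <- a_s[matrix(prof, 1)]
      for (alt in seq_len(sizes[s])) {
        if (alt == prof[s]) next
        dev <- prof; dev[s] <- alt
        if (a_s[matrix(dev, 1)] > mine + tie_tol) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    w[t] <- ok
  }
  nash_result(game, w, idx, payoff_bounds = NULL, method = "brute")
}

#' @rdname find_nash_ilp
#' @param method \code{"ilp"} (default) or \code{"brute"}.
#' @export
find_nash <- function(game, method = c("ilp", "brute"), tie_tol = 1e-9) {
  method <- match.arg(method)
  switch(method, ilp = find_nash_ilp(game, tie_tol),
         brute = brute_force_nash(game, tie_tol))
}

nash_result <- function(game, w, idx, payoff_bounds, method) {
  n <- game$n_players
  sizes <- vapply(game$strategies, length, integer(1))
  eq_rows <- which(w)
  eq <- as.data.frame(lapply(seq_len(n), function(s) {
    game$strategies[[s]][idx[eq_rows, s]]
  }), col.names = paste0("player", seq_len(n)), stringsAsFactors = FALSE)
  pay <- matrix(NA_real_, length(eq_rows), n,
                dimnames = list(NULL, paste0("player", seq_len(n))))
  for (i in seq_along(eq_rows)) {
    prof <- idx[eq_rows[i], ]
    for (s in seq_len(n)) pay[i, s] <- game$payoffs[[s]][matrix(prof, 1)]
  }
  indicator <- array(w, dim = sizes, dimnames = game$strategies)
  structure(list(equilibria = eq, payoffs = pay, indicator = indicator,
                 payoff_bounds = payoff_bounds, n_equilibria = sum(w),
                 method = method),
            class = "nash_result")
}

#' @export
print.nash_result <- function(x, ...) {
  if (x$n_equilibria == 0) {
    cat("<nash_result> no pure-strategy Nash equilibrium\n")
  } else {
    cat(sprintf("<nash_result> %d pure-strategy Nash equilibri%s:\n",
                x$n_equilibria, if (x$n_equilibria == 1) "um" else "a"))
    df <- cbind(x$equilibria,
                payoff = apply(round(x$payoffs, 6), 1, paste, collapse = ", "))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Equilibrium profiles as canonical strings
#'
#' Convenience accessors for \code{\link{find_nash_ilp}} results:
#' \code{nash_profile_strings} renders each equilibrium profile as a
#' comma-joined label string (handy for set comparisons);
#' \code{nash_viable} flags the equilibria at which every player's payoff
#' clears the viability threshold (a fully viable association, as opposed
#' to an equilibrium among collapsing strains).
#'
#' @param nash a \code{nash_result}.
#' @return \code{nash_profile_strings}: character vector, one entry per
#'   equilibrium; \code{nash_viable}: logical vector of the same length.
#' @export
nash_profile_strings <- function(nash) {
  if (!nrow(nash$equilibria)) return(character())
  apply(nash$equilibria, 1, paste, collapse = ",")
}

#' @rdname nash_profile_strings
#' @param viability minimum payoff counted as growth.
#' @export
nash_viable <- function(nash, viability = 1e-6) {
  if (!nrow(nash$equilibria)) return(logical())
  apply(nash$payoffs, 1, function(p) all(p >= viability))
}
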