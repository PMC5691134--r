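# Evolutionary dynamics: the replicator equation extended to higher-order
# games,
#   dx_k/dt = (f_k(x) - phi(x)) x_k
#   f_k(x)  = sum_k' a_kk' x_k' + sum_k' sum_k'' a_kk'k'' x_k' x_k'' + ...
#   phi(x)  = sum_k f_k(x) x_k
# where x is the vector of genotype frequencies on the simplex.

#' Replicator fitnesses and right-hand side
#'
#' \code{replicator_fitness} evaluates each strategy's expected payoff
#' f_k(x) against a community at frequencies \code{x} (polynomial in x for
#' higher-order games); \code{replicator_rhs} returns the replicator
#' derivative (f_k(x) - phi(x)) x_k with phi the mean community fitness.
#'
#' @param x numeric frequency vector on the simplex.
#' @param game a symmetric \code{\link{payoff_game}}.
#' @return \code{replicator_fitness}: named vector f; \code{replicator_rhs}:
#'   named vector dx/dt (components sum to zero analytically).
#' @export
replicator_fitness <- function(x, game) {
  if (!game$symmetric) {
    stop_input("replicator dynamics requires a symmetric (single-population) game")
  }
  K <- length(game$strategies[[1]])
  if (length(x) != K) {
    stop_input("frequency vector length %d does not match %d strategies",
               length(x), K)
  }
  A <- game$payoffs[[1]]
  # contract partner dimensions one by one: f = A x x ... x
  M <- A
  for (d in seq_len(game$n_players - 1L)) {
    M <- matrix(M, nrow = length(M) / K) %*% x
  }
  stats::setNames(as.vector(M), game$strategies[[1]])
}

#' @rdname replicator_fitness
#' @export
replicator_rhs <- function(x, game) {
  f <- replicator_fitness(x, game)
  phi <- sum(f * x)
  (f - phi) * x
}

#' Integrate the replicator dynamics
#'
#' Adaptive integration (deSolve, lsoda) of the replicator equation from an
#' initial frequency vector.  The state is renormalized onto the simplex
#' only when numerical drift exceeds 1e-8.  An equilibrium is declared when
#' the max-norm of dx/dt stays below \code{tol} over the last ten reported
#' states.
#'
#' @param x0 initial frequencies (must lie on the simplex within 1e-8).
#' @param game a symmetric \code{\link{payoff_game}}.
#' @param t_max integration horizon (h).
#' @param tol equilibrium detection tolerance on the max-norm of dx/dt.
#' @param n_steps number of reported time points.
#' @param rtol,atol integrator tolerances.
#' @return An object of class \code{replicator_trajectory}: list with
#'   \code{times}, \code{states} (matrix, one row per time, one column per
#'   strategy), \code{mean_fitness}, \code{equilibrium} (named frequency
#'   vector, or \code{NULL} when not converged) and \code{converged}.
#' @export
integrate_replicator <- function(x0, game, t_max = 500, tol = 1e-7,
                                 n_steps = 400, rtol = 1e-8, atol = 1e-10) {
  K <- length(game$strategies[[1]])
  if (abs(sum(x0) - 1) > 1e-8 || any(x0 < -1e-12)) {
    stop_input("x0 must lie on the probability simplex")
  }
  x0 <- pmax(x0, 0); x0 <- x0 / sum(x0)
  rhs <- function(t, x, parms) {
    drift <- sum(x) - 1
    if (abs(drift) > 1e-8) x <- x / sum(x)
    list(replicator_rhs(x, game))
  }
  times <- seq(0, t_max, length.out = n_steps + 1L)
  sol <- deSolve::ode(y = stats::setNames(x0, game$strategies[[1]]),
                      times = times, func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- game$strategies[[1]]
  states[states < 0 & states > -1e-10] <- 0
  mean_fit <- apply(states, 1, function(x) {
    sum(replicator_fitness(x, game) * x)
  })
  norms <- apply(states, 1, function(x) max(abs(replicator_rhs(x, game))))
  window <- 10L
  tail_ok <- length(norms) > window &&
    all(norms[seq(length(norms) - window + 1L, length(norms))] < tol)
  structure(list(times = sol[, 1], states = states, mean_fitness = mean_fit,
                 equilibrium = if (tail_ok) states[nrow(states), ] else NULL,
                 converged = tail_ok, labels = game$strategies[[1]]),
            class = "replicator_trajectory")
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  cat(sprintf("<replicator_trajectory> %d strategies, t in [0, %g]\n",
              ncol(x$states), max(x$times)))
  if (x$converged) {
    cat("  equilibrium:",
        paste(sprintf("%s=%.4f", x$labels, x$equilibrium), collapse = ", "),
        "\n")
  } else {
    cat("  not converged by t_max\n")
  }
  invisible(x)
}

#' Write a trajectory as CSV (time, x_1, ..., x_K)
#' @param traj a \code{replicator_trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' In silico invasion experiment
#'
#' A low-frequency set of invader genotypes is introduced into a resident
#' community.  Residents are first equilibrated among themselves (replicator
#' dynamics on the restricted game, from uniform frequencies) unless
#' \code{resident_freq} is supplied; their equilibrium frequencies are then
#' scaled by \code{1 - invasion_fraction} and the invaders share
#' \code{invasion_fraction} equally.
#'
#' @param game a symmetric \code{\link{payoff_game}} covering residents and
#'   invaders.
#' @param residents,invaders character vectors of strategy labels, disjoint.
#' @param invasion_fraction initial total invader frequency, in (0, 0.5).
#' @param resident_freq optional named frequencies of the residents
#'   (bypasses pre-equilibration).
#' @inheritParams integrate_replicator
#' @return A \code{replicator_trajectory} over the union of residents and
#'   invaders (equilibrium frequencies are the pie-chart values of an
#'   invasion experiment).
#' @export
invade <- function(game, residents, invaders, invasion_fraction = 0.01,
                   resident_freq = NULL, t_max = 500, tol = 1e-7,
                   n_steps = 400) {
  labels <- game$strategies[[1]]
  unknown <- setdiff(c(residents, invaders), labels)
  if (length(unknown)) {
    stop_input("unknown strategy labels: %s", paste(unknown, collapse = ", "))
  }
  if (length(intersect(residents, invaders))) {
    stop_input("residents and invaders must be disjoint")
  }
  if (invasion_fraction <= 0 || invasion_fraction >= 0.5) {
    stop_input("invasion_fraction must lie in (0, 0.5)")
  }
  if (is.null(resident_freq)) {
    if (length(residents) == 1L) {
      resident_freq <- stats::setNames(1, residents)
    } else {
      sub <- restrict_game(game, residents)
      pre <- integrate_replicator(rep(1 / length(residents),
                                      length(residents)), sub,
                                  t_max = t_max, tol = tol)
      resident_freq <- stats::setNames(
        pre$states[nrow(pre$states), ], residents)
    }
  }
  resident_freq <- resident_freq / sum(resident_freq)
  x0 <- stats::setNames(numeric(length(labels)), labels)
  x0[residents] <- (1 - invasion_fraction) * resident_freq[residents]
  x0[invaders] <- invasion_fraction / length(invaders)
  integrate_replicator(x0, game, t_max = t_max, tol = tol, n_steps = n_steps)
}

#' Invasion scenario presets for the four-genotype amino-acid game
#'
#' Named resident/invader splits for the standard genotype labels
#' \code{"11"}, \code{"10"}, \code{"01"}, \code{"00"}:
#' \describe{
#'   \item{triple_invasion}{00, 01 and 10 simultaneously invade a resident
#'     11 population.}
#'   \item{two_step}{10 and 00 invade a pre-equilibrated 11 + 01 community
#'     (second step of progressive prototrophy loss).}
#'   \item{cross_feeder_invasion}{01 and 10 invade a resident 11 population.}
#' }
#'
#' @param name scenario name.
#' @return List with \code{residents} and \code{invaders} label vectors.
#' @export
invasion_scenario <- function(name = c("triple_invasion", "two_step",
                                       "cross_feeder_invasion")) {
  name <- match.arg(name)
  switch(name,
    triple_invasion = list(residents = "11", invaders = c("00", "01", "10")),
    two_step = list(residents = c("11", "01"), invaders = c("10", "00")),
    cross_feeder_invasion = list(residents = "11", invaders = c("01", "10")))
}

#' Selection coefficient of a mutant against a resident
#'
#' For a two-strategy game, evaluates s = (f_MT(x) - f_WT(x)) / phi(x) at
#' the community state implied by the mutant/resident frequency ratio.
#' Negative frequency dependence appears as s decreasing in the ratio; s
#' crosses zero exactly at an interior replicator equilibrium.
#'
#' @param game a symmetric two-strategy \code{\link{payoff_game}}.
#' @param freq_ratio mutant-to-resident frequency ratio x_MT / x_WT > 0.
#' @param mutant,resident strategy labels (defaults: second and first).
#' @return The dimensionless selection coefficient.
#' @export
selection_coefficient <- function(game, freq_ratio, mutant = NULL,
                                  resident = NULL) {
  labels <- game$strategies[[1]]
  if (length(labels) != 2L) {
    stop_input("selection_coefficient requires a 2-strategy game")
  }
  if (freq_ratio <= 0) stop_input("freq_ratio must be > 0")
  if (is.null(resident)) resident <- labels[1]
  if (is.null(mutant)) mutant <- labels[2]
  x <- stats::setNames(numeric(2), labels)
  x[mutant] <- freq_ratio / (1 + freq_ratio)
  x[resident] <- 1 / (1 + freq_ratio)
  f <- replicator_fitness(x, game)
  phi <- sum(f * x)
  if (phi <= 0) {
    stop_input("mean fitness is non-positive at this composition (non-viable reference community)")
  }
  unname((f[mutant] - f[resident]) / phi)
}
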