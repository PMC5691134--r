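# Shared test helpers: an independent LP oracle (scipy's HiGHS via the
# system python) and random problem generators.

# Solve max c'v s.t. S v = 0, lb <= v <= ub with an independent dense LP
# solver.  Returns list(status, objective).
oracle_lp <- function(S, lb, ub, cvec) {
  dir <- tempfile("lporacle")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::write.csv(S, file.path(dir, "S.csv"), row.names = FALSE)
  utils::write.csv(data.frame(lb = lb, ub = ub, c = cvec),
                   file.path(dir, "b.csv"), row.names = FALSE)
  script <- file.path(dir, "solve.py")
  writeLines(c(
    "import numpy as np, pandas as pd, sys",
    "from scipy.optimize import linprog",
    sprintf("d = %s", deparse(dir)),
    "S = pd.read_csv(d + '/S.csv').values",
    "b = pd.read_csv(d + '/b.csv')",
    "bounds = [(l if np.isfinite(l) else None, u if np.isfinite(u) else None)",
    "          for l, u in zip(b['lb'], b['ub'])]",
    "r = linprog(-b['c'].values, A_eq=S, b_eq=np.zeros(S.shape[0]),",
    "            bounds=bounds, method='highs')",
    "status = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(r.status, 'failed')",
    "print(status, -r.fun if r.status == 0 else 'nan')"), script)
  out <- system2("python", script, stdout = TRUE)
  parts <- strsplit(trimws(out[length(out)]), " ")[[1]]
  list(status = parts[1], objective = suppressWarnings(as.numeric(parts[2])))
}

# Random n-player game with K strategies per player.
random_game <- function(n, K, digits = 3) {
  pays <- lapply(seq_len(n), function(s) {
    array(round(stats::runif(K^n), digits), dim = rep(K, n))
  })
  payoff_game(pays, strategies = rep(list(paste0("s", seq_len(K))), n))
}

# Canonical 2x2 games (row player payoff matrices; symmetric partners).
canonical_pd <- function() {
  matrix_game(rbind(c(3, 0), c(5, 1)), labels = c("C", "D"))
}
canonical_snowdrift <- function() {
  matrix_game(rbind(c(2, 1), c(3, 0)), labels = c("C", "D"))
}
canonical_harmony <- function() {
  matrix_game(rbind(c(4, 3), c(2, 1)), labels = c("C", "D"))
}
matching_pennies <- function() {
  matrix_game(rbind(c(1, -1), c(-1, 1)),
              B = rbind(c(-1, 1), c(1, -1)), labels = c("H", "T"))
}

# Tiny linear-pathway model: A_ext -(EX_A)-> A -(R1)-> B -> biomass, with
# uptake bound u on the exchange (negative flux = uptake).
linear_pathway_model <- function(u = 10) {
  S <- rbind(A = c(EX_A = -1, R1 = -1, BIO = 0),
             B = c(EX_A = 0, R1 = 1, BIO = -1))
  metabolic_network(S,
                    lb = c(EX_A = -u, R1 = 0, BIO = 0),
                    ub = c(EX_A = 0, R1 = Inf, BIO = Inf),
                    biomass = "BIO", exchanges = c(A = "EX_A"))
}

# Random sparse mass-balance network used for LP cross-checks; may be
# feasible or infeasible depending on draw.
random_network_matrices <- function(nm = 8, nr = 12) {
  S <- matrix(0, nm, nr)
  for (j in seq_len(nr)) {
    k <- sample(2:3, 1)
    idx <- sample(nm, k)
    S[idx, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  lb <- ifelse(stats::runif(nr) < 0.5, 0, -10)
  ub <- rep(10, nr)
  cvec <- numeric(nr)
  cvec[nr] <- 1
  list(S = S, lb = lb, ub = ub, cvec = cvec)
}
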