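# Dense two-phase simplex for small linear programs.
#
# FBA problems on toy networks are tiny (tens of variables), dense, and often
# degenerate.  This solver uses Bland's anti-cycling rule throughout, so it is
# slow per pivot but guaranteed to terminate, which matters more here than
# speed.

#' Solve a small dense linear program
#'
#' Maximizes (or minimizes) \code{obj \%*\% x} subject to \code{Aeq \%*\% x ==
#' beq} and \code{lb <= x <= ub}.  Bounds may be infinite; \code{lb[j] ==
#' ub[j]} fixes a variable.  This is the backbone of \code{\link{solve_fba}}.
#'
#' @param obj numeric objective vector.
#' @param Aeq numeric equality-constraint matrix (may have zero rows).
#' @param beq numeric right-hand side of the equality constraints.
#' @param lb,ub numeric bounds, \code{-Inf}/\code{Inf} allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol numeric feasibility/pivot tolerance.
#'
#' @return A list with \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}), and for optimal solutions
#'   \code{objective} and the primal solution \code{x}.
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), ncol = n)
  stopifnot(length(beq) == nrow(Aeq), length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  if (!maximize) {
    res <- lp_solve(-obj, Aeq, beq, lb, ub, maximize = TRUE, tol = tol)
    if (res$status == "optimal") res$objective <- -res$objective
    return(res)
  }

  # --- convert to standard form: A y = b, y >= 0 -----------------------------
  # Each original variable becomes one or two nonnegative columns plus an
  # optional slack row for a finite upper bound.
  cols <- list()   # per standard-form column: original index, sign, offset use
  shift <- numeric(n)       # x_j = shift_j + sign_j * y_cols
  sgn <- numeric(n)
  fixed <- lb == ub
  free_split <- numeric(0)  # columns of the negative part of free variables
  col_of <- vector("list", n)

  A_cols <- list(); c_std <- numeric(0)
  add_col <- function(a, cc) {
    A_cols[[length(A_cols) + 1L]] <<- a
    c_std[length(c_std) + 1L] <<- cc
    length(A_cols)
  }
  b <- beq
  ub_row_var <- integer(0); ub_row_val <- numeric(0)
  for (j in seq_len(n)) {
    aj <- Aeq[, j, drop = TRUE]
    if (fixed[j]) {
      b <- b - aj * lb[j]
      shift[j] <- lb[j]; sgn[j] <- 0
    } else if (is.finite(lb[j])) {
      b <- b - aj * lb[j]
      shift[j] <- lb[j]; sgn[j] <- 1
      col_of[[j]] <- add_col(aj, obj[j])
      if (is.finite(ub[j])) {
        ub_row_var <- c(ub_row_var, col_of[[j]])
        ub_row_val <- c(ub_row_val, ub[j] - lb[j])
      }
    } else if (is.finite(ub[j])) {
      # x = ub - y, y >= 0
      b <- b - aj * ub[j]
      shift[j] <- ub[j]; sgn[j] <- -1
      col_of[[j]] <- add_col(-aj, -obj[j])
    } else {
      # free: x = y+ - y-
      shift[j] <- 0; sgn[j] <- 1
      col_of[[j]] <- add_col(aj, obj[j])
      free_split[length(free_split) + 1L] <- add_col(-aj, -obj[j])
      names(free_split)[length(free_split)] <- as.character(j)
    }
  }
  ncol_main <- length(A_cols)
  m_eq <- length(b)
  m_ub <- length(ub_row_var)
  m <- m_eq + m_ub
  nn <- ncol_main + m_ub   # upper-bound rows get one slack each
  A <- matrix(0, m, nn)
  for (k in seq_len(ncol_main)) A[seq_len(m_eq), k] <- A_cols[[k]]
  cc <- c(c_std, numeric(m_ub))
  bb <- c(b, ub_row_val)
  if (m_ub > 0) {
    for (r in seq_len(m_ub)) {
      A[m_eq + r, ub_row_var[r]] <- 1
      A[m_eq + r, ncol_main + r] <- 1
    }
  }
  neg <- bb < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; bb[neg] <- -bb[neg] }

  res <- simplex_two_phase(A, bb, cc, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = NULL))
  }
  y <- res$x
  x <- shift
  for (j in seq_len(n)) {
    if (fixed[j]) next
    x[j] <- shift[j] + sgn[j] * y[col_of[[j]]]
  }
  if (length(free_split)) {
    for (k in seq_along(free_split)) {
      j <- as.integer(names(free_split)[k])
      x[j] <- x[j] - y[free_split[k]]
    }
  }
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# Two-phase tableau simplex with Bland's rule.
# Solves: maximize c'y subject to A y = b (b >= 0), y >= 0.
simplex_two_phase <- function(A, b, cc, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # no constraints: optimum at 0 unless a positive cost is unbounded
    if (any(cc > tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(n), objective = 0))
  }
  # Phase 1: artificial variables form the initial basis.
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  n_tot <- n + m
  # phase-1 objective row: minimize sum of artificials == maximize -sum.
  # Reduced-cost row is c_B B^-1 [A | b] - [c | 0], priced out over the basis.
  obj1 <- c(numeric(n), rep(-1, m))
  Tb <- rbind(Tb, c(-obj1, 0))
  for (i in seq_len(m)) Tb[m + 1L, ] <- Tb[m + 1L, ] + obj1[basis[i]] * Tb[i, ]
  st <- simplex_iterate(Tb, basis, n_tot, tol, allow_cols = seq_len(n_tot))
  Tb <- st$Tb; basis <- st$basis
  if (st$status == "unbounded") return(list(status = "infeasible"))
  phase1_obj <- Tb[m + 1L, n_tot + 1L]
  if (phase1_obj < -1e-7) return(list(status = "infeasible"))
  # Drive remaining artificial variables out of the basis where possible.
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      pc <- which(abs(Tb[i, seq_len(n)]) > tol)
      if (length(pc)) {
        Tb <- simplex_pivot(Tb, i, pc[1L])
        basis[i] <- pc[1L]
      }
      # else: redundant row; artificial stays basic at value 0 (harmless)
    }
  }
  # Phase 2 objective row.
  Tb[m + 1L, ] <- c(-cc, rep(0, m), 0)
  for (i in seq_len(m)) {
    if (basis[i] <= n) Tb[m + 1L, ] <- Tb[m + 1L, ] + cc[basis[i]] * Tb[i, ]
  }
  st <- simplex_iterate(Tb, basis, n_tot, tol, allow_cols = seq_len(n))
  Tb <- st$Tb; basis <- st$basis
  if (st$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  for (i in seq_len(m)) if (basis[i] <= n) x[basis[i]] <- Tb[i, n_tot + 1L]
  list(status = "optimal", x = x, objective = Tb[m + 1L, n_tot + 1L])
}

# Bland's rule iterations on a tableau whose last row is the (maximization)
# objective; entering columns restricted to allow_cols.
simplex_iterate <- function(Tb, basis, n_tot, tol, allow_cols) {
  m <- nrow(Tb) - 1L
  rhs <- n_tot + 1L
  repeat {
    red <- Tb[m + 1L, allow_cols]
    ent_rel <- which(red < -tol)
    if (!length(ent_rel)) {
      return(list(status = "optimal", Tb = Tb, basis = basis))
    }
    pc <- allow_cols[ent_rel[1L]]           # Bland: smallest index
    col <- Tb[seq_len(m), pc]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", Tb = Tb, basis = basis))
    ratios <- Tb[pos, rhs] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    pr <- cand[which.min(basis[cand])]      # Bland: smallest basis index
    Tb <- simplex_pivot(Tb, pr, pc)
    basis[pr] <- pc
  }
}

simplex_pivot <- function(Tb, pr, pc) {
  piv <- Tb[pr, pc]
  Tb[pr, ] <- Tb[pr, ] / piv
  other <- setdiff(seq_len(nrow(Tb)), pr)
  Tb[other, ] <- Tb[other, ] - outer(Tb[other, pc], Tb[pr, ])
  Tb
}
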