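# Flux balance analysis: maximize the biomass flux subject to steady-state
# mass balance S v = 0 and flux bounds LB <= v <= UB.

#' Flux bound overrides
#'
#' Builds the constraint table accepted by \code{\link{solve_fba}}.  Each row
#' overrides the bounds of one reaction; \code{NA} keeps the model bound.
#' Setting \code{lb == ub} fixes a flux.
#'
#' @param reaction character vector of reaction ids.
#' @param lb,ub numeric vectors (recycled) of replacement bounds.
#' @return A data frame with columns \code{reaction}, \code{lb}, \code{ub}.
#' @export
#' @examples
#' flux_bounds("R1", lb = 0, ub = 0)  # knock out R1
flux_bounds <- function(reaction, lb = NA_real_, ub = NA_real_) {
  n <- length(reaction)
  data.frame(reaction = as.character(reaction),
             lb = rep_len(as.numeric(lb), n),
             ub = rep_len(as.numeric(ub), n), stringsAsFactors = FALSE)
}

#' Solve the FBA linear program
#'
#' Maximizes the flux through the model's biomass reaction subject to
#' steady-state mass balance for every metabolite and the (possibly
#' overridden) flux bounds.  The LP is solved with the package's dense
#' two-phase simplex at a feasibility tolerance of 1e-9.
#'
#' @param model a \code{\link{metabolic_network}}.
#' @param constraints optional data frame from \code{\link{flux_bounds}}
#'   overriding reaction bounds.  Unknown reaction ids are an input error.
#' @return An object of class \code{fba_result}: a list with \code{status}
#'   (\code{"optimal"}, \code{"infeasible"} or \code{"unbounded"}), and when
#'   optimal, \code{biomass_flux} (1/h) and the named flux vector
#'   \code{fluxes}.  An unbounded LP is reported as such rather than clamped:
#'   it signals a missing exchange bound in the model.
#' @export
solve_fba <- function(model, constraints = NULL) {
  validate_model(model)
  lb <- model$lb
  ub <- model$ub
  if (!is.null(constraints)) {
    unknown <- setdiff(constraints$reaction, model$reactions)
    if (length(unknown)) {
      stop_input("constraints reference unknown reactions: %s",
                 paste(unknown, collapse = ", "))
    }
    for (i in seq_len(nrow(constraints))) {
      j <- constraints$reaction[i]
      if (!is.na(constraints$lb[i])) lb[j] <- constraints$lb[i]
      if (!is.na(constraints$ub[i])) ub[j] <- constraints$ub[i]
    }
  }
  obj <- as.numeric(model$reactions == model$biomass)
  res <- lp_solve(obj, model$stoich, numeric(length(model$metabolites)),
                  lb, ub, maximize = TRUE, tol = 1e-9)
  if (res$status == "optimal") {
    v <- stats::setNames(res$x, model$reactions)
    imbalance <- max(abs(model$stoich %*% v))
    if (imbalance > 1e-6) {
      stop_internal("LP solution violates mass balance (max |Sv| = %g)", imbalance)
    }
    structure(list(status = "optimal", biomass_flux = res$objective,
                   fluxes = v), class = "fba_result")
  } else if (res$status %in% c("infeasible", "unbounded")) {
    structure(list(status = res$status, biomass_flux = NA_real_, fluxes = NULL),
              class = "fba_result")
  } else {
    stop_internal("LP solver failure: status %s", res$status)
  }
}

#' @export
print.fba_result <- function(x, ...) {
  if (x$status == "optimal") {
    cat(sprintf("<fba_result> optimal, biomass flux = %.6g /h\n", x$biomass_flux))
  } else {
    cat(sprintf("<fba_result> %s\n", x$status))
  }
  invisible(x)
}
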