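# Metabolic network container and its JSON/SBML interchange formats.

stop_input <- function(...) {
  stop(structure(class = c("fbagames_input_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_internal <- function(...) {
  stop(structure(class = c("fbagames_internal_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' Construct a stoichiometric metabolic model
#'
#' A \code{metabolic_network} couples a stoichiometric matrix with flux
#' bounds, a biomass (objective) reaction, exchange reactions, and a
#' gene-to-reaction map.  Exchange fluxes follow the convention that positive
#' flux is secretion and negative flux is uptake, so a medium component is a
#' metabolite whose exchange reaction has a negative lower bound.
#'
#' @param stoich numeric matrix, metabolites in rows, reactions in columns,
#'   with dimnames giving their identifiers.  Dense storage; models handled
#'   by this package are small.
#' @param lb,ub named numeric vectors of lower/upper flux bounds
#'   (mmol/gDW/h), one entry per reaction.  \code{-Inf}/\code{Inf} allowed.
#' @param biomass identifier of the biomass reaction.
#' @param exchanges named character vector mapping metabolite ids to their
#'   exchange reaction ids.  Each exchange reaction must have exactly one
#'   nonzero stoichiometric entry (coefficient -1 on its metabolite).
#' @param genes named list mapping gene ids to character vectors of reaction
#'   ids (simple many-to-many map; no boolean gene-protein-reaction logic).
#'
#' @return An object of class \code{metabolic_network}.
#' @seealso \code{\link{solve_fba}}, \code{\link{read_model}}
#' @export
#' @examples
#' # A -> B -> biomass, fed by an exchange reaction for A
#' S <- matrix(c(-1, 1, 0,
#'               0, -1, 1,
#'               0, 0, -1), nrow = 3,
#'             dimnames = list(c("A", "B", "C"),
#'                             c("R1", "R2", "BIO")))
#' S <- cbind(S, EX_A = c(-1, 0, 0))
#' m <- metabolic_network(S,
#'   lb = c(R1 = 0, R2 = 0, BIO = 0, EX_A = -10),
#'   ub = c(R1 = 1000, R2 = 1000, BIO = 1000, EX_A = 0),
#'   biomass = "BIO", exchanges = c(A = "EX_A"))
#' solve_fba(m)$biomass_flux
metabolic_network <- function(stoich, lb, ub, biomass, exchanges = character(),
                              genes = list()) {
  if (is.null(dimnames(stoich)) || is.null(rownames(stoich)) ||
      is.null(colnames(stoich))) {
    stop_input("stoich must have metabolite row names and reaction column names")
  }
  mets <- rownames(stoich)
  rxns <- colnames(stoich)
  lb <- lb[rxns]; ub <- ub[rxns]
  model <- structure(list(
    metabolites = mets,
    reactions = rxns,
    stoich = stoich,
    lb = stats::setNames(as.numeric(lb), rxns),
    ub = stats::setNames(as.numeric(ub), rxns),
    biomass = biomass,
    exchanges = exchanges,
    genes = genes
  ), class = "metabolic_network")
  validate_model(model)
  model
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: bound ordering, membership of the
#' biomass reaction, exchange reactions touching exactly one metabolite, and
#' gene map entries referring to known reactions.
#'
#' @param model a \code{metabolic_network}.
#' @return The model, invisibly, if valid; otherwise an input error listing
#'   the offending fields.
#' @export
validate_model <- function(model) {
  problems <- character()
  if (anyNA(model$lb) || anyNA(model$ub)) {
    problems <- c(problems, "missing lb/ub entries for some reactions")
  } else if (any(model$lb > model$ub)) {
    bad <- model$reactions[model$lb > model$ub]
    problems <- c(problems, paste0("lb > ub for: ", paste(bad, collapse = ", ")))
  }
  if (length(model$biomass) != 1L || !model$biomass %in% model$reactions) {
    problems <- c(problems, "biomass reaction not in reaction set")
  }
  if (length(model$exchanges)) {
    if (is.null(names(model$exchanges))) {
      problems <- c(problems, "exchanges must be named by metabolite")
    } else {
      for (met in names(model$exchanges)) {
        rx <- model$exchanges[[met]]
        if (!met %in% model$metabolites || !rx %in% model$reactions) {
          problems <- c(problems, paste0("exchange ", met, " -> ", rx,
                                         " references unknown ids"))
          next
        }
        nz <- which(model$stoich[, rx] != 0)
        if (length(nz) != 1L || rownames(model$stoich)[nz] != met) {
          problems <- c(problems, paste0(
            "exchange reaction ", rx,
            " must have exactly one nonzero entry, on ", met))
        }
      }
    }
  }
  for (g in names(model$genes)) {
    miss <- setdiff(model$genes[[g]], model$reactions)
    if (length(miss)) {
      problems <- c(problems, paste0("gene ", g, " maps to unknown reactions: ",
                                     paste(miss, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop_input("invalid metabolic model:\n  - %s",
               paste(problems, collapse = "\n  - "))
  }
  invisible(model)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites, %d reactions\n",
              length(x$metabolites), length(x$reactions)))
  cat("  biomass:  ", x$biomass, "\n")
  cat("  exchanges:", if (length(x$exchanges))
    paste(names(x$exchanges), collapse = ", ") else "(none)", "\n")
  if (length(x$genes))
    cat("  genes:    ", paste(names(x$genes), collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a metabolic model
#'
#' The canonical interchange format is a JSON document with keys
#' \code{metabolites}, \code{reactions} (each \code{\{id, stoich, lb, ub\}}),
#' \code{biomass}, \code{exchanges}, and \code{genes}.  SBML Level 3 import
#' is best-effort: species become metabolites, reactions carry FBC bounds
#' when present (defaults \code{-1000}/\code{1000}, or \code{0} lower for
#' irreversible reactions), and the FBC objective becomes the biomass
#' reaction.
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"sbml"} (read only); guessed from the
#'   file extension when missing.
#' @return \code{read_model} returns a \code{metabolic_network};
#'   \code{write_model} returns \code{path} invisibly.  Writing then reading
#'   a model under the JSON schema reproduces it exactly.
#' @export
read_model <- function(path, format = c("guess", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "sbml") return(read_sbml_model(path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("metabolites", "reactions", "biomass")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop_input("model JSON missing required fields: %s", paste(miss, collapse = ", "))
  }
  mets <- unlist(doc$metabolites)
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  S <- matrix(0, length(mets), length(rxn_ids), dimnames = list(mets, rxn_ids))
  lb <- ub <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  for (r in doc$reactions) {
    st <- unlist(r$stoich)
    unknown <- setdiff(names(st), mets)
    if (length(unknown)) {
      stop_input("reaction %s references unknown metabolites: %s",
                 r$id, paste(unknown, collapse = ", "))
    }
    S[names(st), r$id] <- as.numeric(st)
    lb[r$id] <- if (is.null(r$lb)) -1000 else as.numeric(r$lb)
    ub[r$id] <- if (is.null(r$ub)) 1000 else as.numeric(r$ub)
  }
  exchanges <- if (!is.null(doc$exchanges)) {
    stats::setNames(vapply(doc$exchanges, as.character, character(1)),
                    names(doc$exchanges))
  } else character()
  genes <- if (!is.null(doc$genes)) {
    lapply(doc$genes, function(v) as.character(unlist(v)))
  } else list()
  metabolic_network(S, lb, ub, biomass = as.character(doc$biomass),
                    exchanges = exchanges, genes = genes)
}

#' @rdname read_model
#' @param model a \code{metabolic_network} to serialize.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  rxns <- lapply(model$reactions, function(j) {
    nz <- which(model$stoich[, j] != 0)
    list(id = j,
         stoich = as.list(stats::setNames(model$stoich[nz, j],
                                          model$metabolites[nz])),
         lb = model$lb[[j]], ub = model$ub[[j]])
  })
  doc <- list(metabolites = as.list(model$metabolites),
              reactions = rxns,
              biomass = model$biomass,
              exchanges = as.list(model$exchanges),
              genes = model$genes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# SBML Level 3 (FBC) import, namespace-agnostic via local-name() XPath.
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  mets <- xml2::xml_attr(sp, "id")
  if (!length(mets)) stop_input("SBML file has no species")
  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  rxns <- xml2::xml_attr(rx_nodes, "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- stats::setNames(numeric(length(rxns)), rxns)
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    for (ref in xml2::xml_find_all(
           node, "./*[local-name()='listOfReactants']/*")) {
      met <- xml2::xml_attr(ref, "species")
      coef <- xml2::xml_attr(ref, "stoichiometry")
      S[met, i] <- S[met, i] - if (is.na(coef)) 1 else as.numeric(coef)
    }
    for (ref in xml2::xml_find_all(
           node, "./*[local-name()='listOfProducts']/*")) {
      met <- xml2::xml_attr(ref, "species")
      coef <- xml2::xml_attr(ref, "stoichiometry")
      S[met, i] <- S[met, i] + if (is.na(coef)) 1 else as.numeric(coef)
    }
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[i] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]]
             else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
  }
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  biomass <- if (!inherits(fo, "xml_missing")) {
    at <- xml2::xml_attrs(fo)
    at[[grep("reaction$", names(at))[1]]]
  } else rxns[length(rxns)]
  # exchange reactions: single nonzero stoichiometric entry
  exch <- character()
  for (j in seq_along(rxns)) {
    nz <- which(S[, j] != 0)
    if (length(nz) == 1L) exch[mets[nz]] <- rxns[j]
  }
  metabolic_network(S, lb, ub, biomass = biomass, exchanges = exch)
}
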