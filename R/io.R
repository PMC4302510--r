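#' Load a metabolic network from a file
#'
#' Reads either SBML Level 3 with the FBC extension or the package's JSON
#' dialect (see [write_network_json()]).  With `format = "auto"` the format
#' is chosen from the file extension (`.xml` / `.sbml` vs `.json`).
#'
#' Bound handling follows cone semantics: the flux cone
#' \eqn{C = \{v \mid Sv = 0, v_r \ge 0, r \in Irr\}} has no finite bounds,
#' so SBML flux bounds are used only for orientation.  A reaction with
#' lower bound \eqn{\ge 0} (or `reversible="false"`) is marked
#' irreversible; a reaction with upper bound \eqn{\le 0} ("irreversible
#' backward") has its column negated and is marked irreversible (the flip
#' is reported via `message()`); finite bound magnitudes are otherwise
#' discarded.  Set `honor_bounds = TRUE` to keep the magnitudes as an
#' attribute `"bounds"` for downstream inspection (they still do not enter
#' the coupling analyses, which are defined on the cone).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"sbml"`, `"json"`.
#' @param honor_bounds keep finite bound magnitudes as an attribute.
#' @return A [metabolic_network()].
#' @export
load_network <- function(path, format = c("auto", "sbml", "json"),
                         honor_bounds = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      xml = "sbml", sbml = "sbml", json = "json",
      stop("cannot infer model format from extension '.", ext,
           "'; pass format explicitly"))
  }
  switch(format,
    sbml = read_network_sbml(path, honor_bounds = honor_bounds),
    json = read_network_json(path)
  )
}

#' Write / read a network in the JSON model dialect
#'
#' The dialect is
#' `{"metabolites": [...], "reactions": [{"id", "stoich": {met: coeff},
#' "reversible": bool, "gpr": "..."}], "genes": [...]}` where `gpr` is
#' optional per reaction.  `read_network_json(write_network_json(net))`
#' is the identity.
#'
#' @param net a [metabolic_network()].
#' @param path file path.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` returns a [metabolic_network()].
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  S <- net$stoich
  rxn_list <- lapply(net$reactions, function(r) {
    col <- S[, r]
    nz <- which(col != 0)
    entry <- list(
      id = r,
      stoich = as.list(stats::setNames(as.numeric(col[nz]),
                                       net$metabolites[nz])),
      reversible = !(r %in% net$irreversible)
    )
    if (!is.null(net$gpr[[r]])) entry$gpr <- format(net$gpr[[r]])
    entry
  })
  obj <- list(metabolites = net$metabolites, reactions = rxn_list,
              genes = net$genes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("failed to parse JSON model '", path, "': ",
                             conditionMessage(e))
  )
  for (field in c("metabolites", "reactions")) {
    if (is.null(obj[[field]])) {
      stop("JSON model is missing the '", field, "' field")
    }
  }
  mets <- vapply(obj$metabolites, as.character, character(1))
  rxn_ids <- vapply(obj$reactions, function(r) as.character(r$id), character(1))
  S <- matrix(0, length(mets), length(rxn_ids), dimnames = list(mets, rxn_ids))
  irr <- character()
  gpr <- list()
  for (r in obj$reactions) {
    id <- as.character(r$id)
    for (m in names(r$stoich)) {
      if (!m %in% mets) {
        stop("reaction '", id, "' references undeclared metabolite '", m, "'")
      }
      S[m, id] <- as.numeric(r$stoich[[m]])
    }
    if (is.null(r$reversible) || !isTRUE(as.logical(r$reversible))) {
      irr <- c(irr, id)
    }
    if (!is.null(r$gpr)) gpr[[id]] <- as.character(r$gpr)
  }
  genes <- if (is.null(obj$genes)) character() else
    vapply(obj$genes, as.character, character(1))
  metabolic_network(mets, rxn_ids, S, irreversible = irr,
                    genes = genes, gpr = gpr)
}

#' Read an SBML Level 3 (FBC) model
#'
#' Parses species, reactions with stoichiometries, flux bounds and
#' `fbc:geneProductAssociation` trees (fallback: `GENE_ASSOCIATION`
#' strings in reaction notes).  Species with `boundaryCondition="true"`
#' are excluded from the mass-balance rows.  See [load_network()] for the
#' bound-to-orientation semantics.
#'
#' @inheritParams load_network
#' @return A [metabolic_network()].
#' @export
read_network_sbml <- function(path, honor_bounds = FALSE) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("failed to parse SBML '", path,
                                           "': ", conditionMessage(e)))
  ln <- function(node, xpath) xml2::xml_find_all(node, xpath)
  attr_local <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", name, "$"), names(at))
    if (length(hit)) at[[hit[1]]] else NA_character_
  }

  species <- ln(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_ids <- vapply(species, attr_local, character(1), "id")
  sp_boundary <- vapply(species, function(s) {
    isTRUE(as.logical(attr_local(s, "boundaryCondition")))
  }, logical(1))
  mets <- sp_ids[!sp_boundary]

  params <- ln(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(
    vapply(params, function(p) as.numeric(attr_local(p, "value")), numeric(1)),
    vapply(params, attr_local, character(1), "id"))

  gps <- ln(doc, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_ids <- vapply(gps, attr_local, character(1), "id")

  rx_nodes <- ln(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx_nodes)) stop("SBML model '", path, "' contains no reactions")
  rxn_ids <- vapply(rx_nodes, attr_local, character(1), "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids in SBML model")

  S <- matrix(0, length(mets), length(rxn_ids), dimnames = list(mets, rxn_ids))
  irr <- character()
  gpr <- list()
  bounds <- matrix(NA_real_, length(rxn_ids), 2,
                   dimnames = list(rxn_ids, c("lb", "ub")))
  for (i in seq_along(rx_nodes)) {
    rn <- rx_nodes[[i]]
    id <- rxn_ids[i]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in ln(rn, paste0("./*[local-name()='", side,
                               "']/*[local-name()='speciesReference']"))) {
        sp <- attr_local(sr, "species")
        coeff <- attr_local(sr, "stoichiometry")
        coeff <- if (is.na(coeff)) 1 else as.numeric(coeff)
        if (sp %in% mets) S[sp, id] <- S[sp, id] + sgn * coeff
      }
    }
    lb_ref <- attr_local(rn, "lowerFluxBound")
    ub_ref <- attr_local(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else NA_real_
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else NA_real_
    rev_attr <- attr_local(rn, "reversible")
    reversible <- if (!is.na(rev_attr)) as.logical(rev_attr) else TRUE
    bounds[id, ] <- c(lb, ub)
    if (!is.na(ub) && ub <= 0) {
      # irreversible backward: flip orientation so flux is non-negative
      S[, id] <- -S[, id]
      irr <- c(irr, id)
      bounds[id, ] <- c(-ub, -lb)
      message("reaction '", id, "' runs backward only; column negated")
    } else if ((!is.na(lb) && lb >= 0) || !reversible) {
      irr <- c(irr, id)
    }

    gpa <- ln(rn, ".//*[local-name()='geneProductAssociation']")
    if (length(gpa)) {
      txt <- sbml_gpa_text(xml2::xml_children(gpa[[1]])[[1]])
      if (nzchar(txt)) gpr[[id]] <- txt
    } else {
      notes <- ln(rn, ".//*[local-name()='notes']")
      if (length(notes)) {
        nt <- xml2::xml_text(notes[[1]])
        m <- regmatches(nt, regexpr("GENE_ASSOCIATION:[^\n<]*", nt))
        if (length(m)) {
          txt <- trimws(sub("GENE_ASSOCIATION:", "", m[1]))
          if (nzchar(txt)) gpr[[id]] <- txt
        }
      }
    }
  }
  net <- metabolic_network(mets, rxn_ids, S, irreversible = irr,
                           genes = gp_ids, gpr = gpr)
  if (honor_bounds) attr(net, "bounds") <- bounds
  net
}

sbml_gpa_text <- function(node) {
  nm <- xml2::xml_name(node)  # local name, prefix stripped by xml2
  if (nm == "geneProductRef") {
    at <- xml2::xml_attrs(node)
    hit <- grep("(^|:)geneProduct$", names(at))
    return(if (length(hit)) at[[hit[1]]] else "")
  }
  if (nm %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), sbml_gpa_text, character(1))
    parts <- parts[nzchar(parts)]
    return(paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")"))
  }
  ""
}
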