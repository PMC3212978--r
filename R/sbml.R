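## Minimal SBML Level 3 (+ fbc v2) support, sufficient for
## constraint-based models: species/compartments, reactions with
## stoichiometry, flux bounds via fbc parameters, GPRs via
## fbc:geneProductAssociation and the active objective marking the
## biomass reaction. Ids are written with the conventional M_/R_/G_
## prefixes and stripped again on read.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sbmlSafe <- function(id) gsub("[^A-Za-z0-9_]", "__", id)

.gprToFbc <- function(node, tree) {
  if (tree$op == "gene") {
    xml2::xml_add_child(node, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", .sbmlSafe(tree$gene)))
  } else {
    child <- xml2::xml_add_child(node, paste0("fbc:", tree$op))
    for (a in tree$args) .gprToFbc(child, a)
  }
}

.sbmlAttr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}

.fbcToGpr <- function(node) {
  nm <- sub("^fbc:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    g <- .sbmlAttr(node, "geneProduct")
    return(sub("^G_", "", g))
  }
  parts <- vapply(xml2::xml_children(node), .fbcToGpr, character(1))
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

.writeModelSBML <- function(model, path) {
  S <- model@stoichiometry
  mets <- rownames(S)
  rxns <- colnames(S)
  doc <- xml2::xml_new_root("sbml",
    xmlns = .SBML_NS, "xmlns:fbc" = .FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model",
    id = .sbmlSafe(model@modelID), "fbc:strict" = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model@metComp))
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")

  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in mets)
    xml2::xml_add_child(sp, "species",
      id = paste0("M_", .sbmlSafe(m)), compartment = model@metComp[[m]],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")

  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  addPar <- function(id, val)
    xml2::xml_add_child(pars, "parameter", id = id,
                        value = format(val, digits = 17), constant = "true")
  for (j in seq_along(rxns)) {
    addPar(paste0("lb_", .sbmlSafe(rxns[j])), model@lowerBounds[[j]])
    addPar(paste0("ub_", .sbmlSafe(rxns[j])), model@upperBounds[[j]])
  }

  if (length(model@genes)) {
    gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model@genes)
      xml2::xml_add_child(gps, "fbc:geneProduct",
        "fbc:id" = paste0("G_", .sbmlSafe(g)), "fbc:label" = g)
  }

  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(rxns)) {
    col <- S[, j]
    rx <- xml2::xml_add_child(rl, "reaction",
      id = paste0("R_", .sbmlSafe(rxns[j])),
      reversible = tolower(as.character(model@lowerBounds[[j]] < 0)),
      fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", .sbmlSafe(rxns[j])),
      "fbc:upperFluxBound" = paste0("ub_", .sbmlSafe(rxns[j])))
    neg <- which(col < 0); pos <- which(col > 0)
    if (length(neg)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in neg)
        xml2::xml_add_child(lr, "speciesReference",
          species = paste0("M_", .sbmlSafe(mets[i])),
          stoichiometry = format(-col[i], digits = 17), constant = "true")
    }
    if (length(pos)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in pos)
        xml2::xml_add_child(lp, "speciesReference",
          species = paste0("M_", .sbmlSafe(mets[i])),
          stoichiometry = format(col[i], digits = 17), constant = "true")
    }
    if (nzchar(model@gpr[[j]])) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      .gprToFbc(gpa, parseGPR(model@gpr[[j]]))
    }
  }

  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective",
                             "fbc:id" = "obj", "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
    "fbc:reaction" = paste0("R_", .sbmlSafe(model@biomassReaction)),
    "fbc:coefficient" = "1")

  xml2::write_xml(doc, path)
  invisible(path)
}

.readModelSBML <- function(path, externalCompartment) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing"))
    stop("format error: no <model> element in ", path)

  spNodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  metIds <- sub("^M_", "", xml2::xml_attr(spNodes, "id"))
  metComp <- stats::setNames(xml2::xml_attr(spNodes, "compartment"), metIds)

  parNodes <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  parVal <- stats::setNames(as.numeric(xml2::xml_attr(parNodes, "value")),
                            xml2::xml_attr(parNodes, "id"))

  gpNodes <- xml2::xml_find_all(mdl,
    ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  genes <- vapply(gpNodes, .sbmlAttr, character(1), name = "label")
  if (all(is.na(genes)))
    genes <- sub("^G_", "", vapply(gpNodes, .sbmlAttr, character(1),
                                   name = "id"))

  rxNodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  rxns <- sub("^R_", "", xml2::xml_attr(rxNodes, "id"))
  nR <- length(rxNodes)
  ii <- integer(); jj <- integer(); xx <- numeric()
  lb <- numeric(nR); ub <- numeric(nR); gpr <- character(nR)
  for (j in seq_len(nR)) {
    rx <- rxNodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx, paste0("./", side, "/speciesReference"))
      if (length(refs)) {
        sps <- sub("^M_", "", xml2::xml_attr(refs, "species"))
        idx <- match(sps, metIds)
        if (anyNA(idx))
          stop("format error: reaction '", rxns[j],
               "' references unknown species '", sps[which(is.na(idx))[1]], "'")
        ii <- c(ii, idx); jj <- c(jj, rep(j, length(idx)))
        xx <- c(xx, sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")))
      }
    }
    lbRef <- .sbmlAttr(rx, "lowerFluxBound")
    ubRef <- .sbmlAttr(rx, "upperFluxBound")
    lb[j] <- if (!is.na(lbRef) && lbRef %in% names(parVal))
      parVal[[lbRef]] else -1000
    ub[j] <- if (!is.na(ubRef) && ubRef %in% names(parVal))
      parVal[[ubRef]] else 1000
    gpa <- xml2::xml_find_first(rx,
      "./*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(gpa, "xml_missing")) "" else {
      s <- .fbcToGpr(xml2::xml_child(gpa))
      sub("^\\((.*)\\)$", "\\1", s)
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(metIds), nR),
                            dimnames = list(metIds, rxns))

  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing"))
    stop("configuration error: no objective (biomass) reaction declared in ",
         path)
  biomass <- sub("^R_", "", .sbmlAttr(fo, "reaction"))

  stoichiometricModel(
    modelID = sub("^$", basename(path), xml2::xml_attr(mdl, "id") %||% ""),
    stoichiometry = S, lowerBounds = lb, upperBounds = ub, gpr = gpr,
    genes = if (length(genes)) genes else NULL,
    biomassReaction = biomass, metComp = metComp,
    externalCompartment = externalCompartment)
}
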