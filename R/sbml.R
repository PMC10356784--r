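# SBML Level 3 core reading/writing with xml2. Covers the subset this
# workflow needs: species, reactions with stoichiometric speciesReferences
# and the reversible flag, gene lists in notes, mass-action kinetic laws
# (MathML products of a rate constant and powered concentrations), and
# interaction networks (modifier-style links with route notes).

SBML_NS   <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
XHTML_NS  <- "http://www.w3.org/1999/xhtml"

sbmlFindAll <- function(doc, xpath) {
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  xml2::xml_find_all(doc, gsub("s:", "s:", xpath, fixed = TRUE), ns)
}

readSbmlModel <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("unparseable SBML file '", path, "': ", conditionMessage(e)))
  spNodes <- sbmlFindAll(doc, ".//s:listOfSpecies/s:species")
  met <- data.frame(
    id = xml2::xml_attr(spNodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(spNodes, "name")), "",
                  xml2::xml_attr(spNodes, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(spNodes, "compartment")), "",
                         xml2::xml_attr(spNodes, "compartment")),
    stringsAsFactors = FALSE)
  rxNodes <- sbmlFindAll(doc, ".//s:listOfReactions/s:reaction")
  reactions <- lapply(rxNodes, function(nd) {
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
    refs <- function(side) {
      rr <- xml2::xml_find_all(nd, paste0("./s:", side, "/s:speciesReference"),
                               ns)
      sp <- xml2::xml_attr(rr, "species")
      st <- as.numeric(xml2::xml_attr(rr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, sp)
    }
    sub <- refs("listOfReactants")
    prod <- refs("listOfProducts")
    st <- c(-sub, prod)
    undeclared <- setdiff(names(st), met$id)
    if (length(undeclared))
      stop("reaction ", xml2::xml_attr(nd, "id"),
           " references undeclared species: ",
           paste(undeclared, collapse = ", "))
    notes <- xml2::xml_text(xml2::xml_find_all(
      nd, ".//*[local-name() = 'p']"))
    genes <- character(0)
    ga <- grep("^\\s*GENE_ASSOCIATION:", notes, value = TRUE)
    if (length(ga))
      genes <- strsplit(trimws(sub("^\\s*GENE_ASSOCIATION:", "", ga[1])),
                        "\\s+")[[1]]
    list(id = xml2::xml_attr(nd, "id"),
         stoichiometry = st,
         reversible = identical(xml2::xml_attr(nd, "reversible"), "true"),
         genes = genes[nzchar(genes)],
         source = "custom")
  })
  dropEmpty <- vapply(reactions, function(rx)
    !any(rx$stoichiometry < 0) || !any(rx$stoichiometry > 0), logical(1))
  if (any(dropEmpty))
    message("dropping ", sum(dropEmpty),
            " boundary/exchange reaction(s) without both substrates and ",
            "products")
  new("MetabolicModel", metabolites = met, reactions = reactions[!dropEmpty],
      organism = "")
}

writeSbmlModel <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "covrecon_model")
  comps <- unique(model@metabolites$compartment)
  comps <- comps[nzchar(comps)]
  if (!length(comps)) comps <- "c"
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model@metabolites))) {
    m <- model@metabolites[i, ]
    cp <- if (nzchar(m$compartment)) m$compartment else comps[1]
    xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                        compartment = cp, hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rx in model@reactions) {
    nd <- xml2::xml_add_child(lr, "reaction", id = rx$id,
                              reversible = tolower(as.character(rx$reversible)))
    if (length(rx$genes)) {
      notes <- xml2::xml_add_child(nd, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
      xml2::xml_add_child(body, "p",
                          paste("GENE_ASSOCIATION:",
                                paste(rx$genes, collapse = " ")))
    }
    st <- rx$stoichiometry
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lra <- xml2::xml_add_child(nd, "listOfReactants")
      for (sp in names(subs))
        xml2::xml_add_child(lra, "speciesReference", species = sp,
                            stoichiometry = format(-subs[[sp]]),
                            constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(nd, "listOfProducts")
      for (sp in names(prods))
        xml2::xml_add_child(lp, "speciesReference", species = sp,
                            stoichiometry = format(prods[[sp]]),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- interaction-network SBML (Jacobian structure export) ----

#' Export a Jacobian structure as an SBML interaction network
#'
#' One SBML species per label; one modifier-style reaction per off-diagonal
#' TRUE mask entry (source metabolite as modifier, target as product),
#' carrying the superpathway annotation (cost, route, contributing reaction
#' ids) in its notes. \code{importInteractionSbml} reads the file back into a
#' \linkS4class{JacobianStructure}.
#'
#' @param structure a \linkS4class{JacobianStructure}
#' @param path output SBML file
#' @export
exportInteractionSbml <- function(structure, path) {
  stopifnot(is(structure, "JacobianStructure"))
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "interaction_network")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "c", constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (lab in structure@labels)
    xml2::xml_add_child(ls, "species", id = lab, compartment = "c",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  off <- maskPositions(structure@mask)
  off <- off[off[, 1L] != off[, 2L], , drop = FALSE]
  if (nrow(off)) {
    lr <- xml2::xml_add_child(mdl, "listOfReactions")
    for (k in seq_len(nrow(off))) {
      i <- off[k, 1L]; j <- off[k, 2L]
      nd <- xml2::xml_add_child(lr, "reaction",
                                id = sprintf("int_%d_%d", j, i),
                                reversible = "false")
      ann <- structure@annotation[[sprintf("%d,%d", i, j)]]
      if (!is.null(ann)) {
        notes <- xml2::xml_add_child(nd, "notes")
        body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
        xml2::xml_add_child(body, "p", paste0("cost: ", format(ann$cost)))
        xml2::xml_add_child(body, "p",
                            paste0("route: ", paste(ann$route,
                                                    collapse = " ")))
        rxs <- unique(unlist(ann$reactions))
        if (length(rxs))
          xml2::xml_add_child(body, "p",
                              paste0("reactions: ",
                                     paste(rxs, collapse = ",")))
      }
      lp <- xml2::xml_add_child(nd, "listOfProducts")
      xml2::xml_add_child(lp, "speciesReference",
                          species = structure@labels[i],
                          stoichiometry = "1", constant = "true")
      lm <- xml2::xml_add_child(nd, "listOfModifiers")
      xml2::xml_add_child(lm, "modifierSpeciesReference",
                          species = structure@labels[j])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname exportInteractionSbml
#' @return \code{importInteractionSbml}: a \linkS4class{JacobianStructure}
#' @export
importInteractionSbml <- function(path) {
  doc <- xml2::read_xml(path)
  labels <- xml2::xml_attr(sbmlFindAll(doc, ".//s:listOfSpecies/s:species"),
                           "id")
  n <- length(labels)
  mask <- diag(TRUE, n)
  annotation <- list()
  rxNodes <- sbmlFindAll(doc, ".//s:listOfReactions/s:reaction")
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  for (nd in rxNodes) {
    src <- xml2::xml_attr(xml2::xml_find_first(
      nd, "./s:listOfModifiers/s:modifierSpeciesReference", ns), "species")
    tgt <- xml2::xml_attr(xml2::xml_find_first(
      nd, "./s:listOfProducts/s:speciesReference", ns), "species")
    i <- match(tgt, labels); j <- match(src, labels)
    if (is.na(i) || is.na(j))
      stop("interaction reaction references unknown species")
    mask[i, j] <- TRUE
    notes <- xml2::xml_text(xml2::xml_find_all(nd,
                                               ".//*[local-name() = 'p']"))
    get <- function(key) {
      v <- grep(paste0("^", key, ": "), notes, value = TRUE)
      if (length(v)) sub(paste0("^", key, ": "), "", v[1]) else NULL
    }
    if (!is.null(get("cost")))
      annotation[[sprintf("%d,%d", i, j)]] <- list(
        source = labels[j], target = labels[i],
        cost = as.numeric(get("cost")),
        route = strsplit(get("route"), " ")[[1]],
        reactions = if (!is.null(get("reactions")))
          strsplit(get("reactions"), ",")[[1]] else character(0))
  }
  jacobianStructure(labels, mask, annotation)
}

# ---- kinetic-model SBML (mass-action dialect) ----

writeKineticSbml <- function(model, path) {
  if (length(model@dependent))
    stop("write the unreduced model as SBML; reduced models carry affine ",
         "dependents that SBML core cannot express (use JSON)")
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "kinetic_model")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "c", constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (sp in model@allSpecies)
    xml2::xml_add_child(ls, "species", id = sp, compartment = "c",
                        initialConcentration = "1",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in seq_along(model@rateConstants)) {
    rid <- names(model@rateConstants)[r]
    nd <- xml2::xml_add_child(lr, "reaction", id = rid, reversible = "false")
    st <- model@stoichiometry[, r]
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lra <- xml2::xml_add_child(nd, "listOfReactants")
      for (sp in names(subs))
        xml2::xml_add_child(lra, "speciesReference", species = sp,
                            stoichiometry = format(-subs[[sp]]),
                            constant = "true")
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(nd, "listOfProducts")
      for (sp in names(prods))
        xml2::xml_add_child(lp, "speciesReference", species = sp,
                            stoichiometry = format(prods[[sp]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(nd, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    act <- which(model@rateExponents[, r] > 0)
    k <- model@rateConstants[r]
    if (!length(act)) {
      xml2::xml_add_child(math, "cn", format(k, digits = 17))
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      xml2::xml_add_child(ap, "cn", format(k, digits = 17))
      for (s in act) {
        e <- model@rateExponents[s, r]
        if (e == 1) {
          xml2::xml_add_child(ap, "ci", model@allSpecies[s])
        } else {
          pw <- xml2::xml_add_child(ap, "apply")
          xml2::xml_add_child(pw, "power")
          xml2::xml_add_child(pw, "ci", model@allSpecies[s])
          xml2::xml_add_child(pw, "cn", format(e))
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

readKineticSbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  species <- xml2::xml_attr(sbmlFindAll(doc,
                                        ".//s:listOfSpecies/s:species"),
                            "id")
  rxNodes <- sbmlFindAll(doc, ".//s:listOfReactions/s:reaction")
  nR <- length(rxNodes)
  S <- matrix(0, length(species), nR,
              dimnames = list(species, xml2::xml_attr(rxNodes, "id")))
  E <- S
  k <- stats::setNames(numeric(nR), colnames(S))
  for (r in seq_len(nR)) {
    nd <- rxNodes[[r]]
    refs <- function(side, sign) {
      rr <- xml2::xml_find_all(nd,
                               paste0("./s:", side, "/s:speciesReference"),
                               ns)
      for (x in rr) {
        sp <- xml2::xml_attr(x, "species")
        st <- as.numeric(xml2::xml_attr(x, "stoichiometry"))
        if (is.na(st)) st <- 1
        S[sp, r] <<- S[sp, r] + sign * st
      }
    }
    refs("listOfReactants", -1)
    refs("listOfProducts", +1)
    math <- xml2::xml_find_first(nd, ".//*[local-name() = 'math']")
    terms <- xml2::xml_find_all(math, "./*[local-name() = 'apply']")
    if (!length(terms)) {
      k[r] <- as.numeric(xml2::xml_text(
        xml2::xml_find_first(math, "./*[local-name() = 'cn']")))
    } else {
      ap <- terms[[1]]
      for (child in xml2::xml_children(ap)) {
        nm <- xml2::xml_name(child)
        if (nm == "cn") k[r] <- as.numeric(xml2::xml_text(child))
        else if (nm == "ci")
          E[trimws(xml2::xml_text(child)), r] <-
            E[trimws(xml2::xml_text(child)), r] + 1
        else if (nm == "apply") {
          ci <- trimws(xml2::xml_text(
            xml2::xml_find_first(child, "./*[local-name() = 'ci']")))
          cn <- as.numeric(xml2::xml_text(
            xml2::xml_find_first(child, "./*[local-name() = 'cn']")))
          E[ci, r] <- cn
        }
      }
    }
  }
  kineticModel(species, S, k, E)
}
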