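# SBML import/export.
#
# Networks are serialized as SBML Level 3 Version 1. Plain SBML does not
# distinguish the five molecular layers, so each species and reaction
# carries a small controlled annotation (namespace urn:refnet:annotation)
# recording its internal id, its type and, for sequence-bearing species,
# the primary sequence. Database cross-references are emitted as MIRIAM
# style identifiers.org resource URIs inside an RDF annotation. Controllers
# are encoded as modifier species references, never as reactants, so the
# stoichiometry stays physical.

REFNET_NS <- "urn:refnet:annotation"
SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

# SBML SIds admit only [A-Za-z_][A-Za-z0-9_]*; internal ids use namespaced
# prefixes like "g:" so they are sanitized here and the verbatim id is kept
# in the annotation for lossless round trips.
sanitize_sid <- function(ids) {
  s <- gsub("[^A-Za-z0-9_]", "_", ids)
  s <- ifelse(grepl("^[A-Za-z_]", s), s, paste0("x_", s))
  # disambiguate collisions deterministically
  while (anyDuplicated(s)) {
    d <- duplicated(s)
    s[d] <- paste0(s[d], "_")
  }
  s
}

miriam_uri <- function(db, accession) {
  sprintf("http://identifiers.org/%s/%s", db, accession)
}

xref_annotation <- function(sid, xr) {
  if (is.null(xr) || nrow(xr) == 0) return("")
  uris <- ifelse(xr$db == "uri", xr$accession, miriam_uri(xr$db, xr$accession))
  paste0(
    sprintf('<rdf:RDF xmlns:rdf="%s" xmlns:bqbiol="%s">', RDF_NS, BQBIOL_NS),
    sprintf('<rdf:Description rdf:about="#%s"><bqbiol:is><rdf:Bag>', sid),
    paste0(sprintf('<rdf:li rdf:resource="%s"/>', xml_escape(uris)),
           collapse = ""),
    "</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF>")
}

#' Write a network as SBML
#'
#' One SBML species is emitted per molecular species and one SBML reaction
#' per interaction; controlling species become modifier references and
#' cross-references become MIRIAM-style annotation URIs. The document is
#' SBML Level 3 Version 1. Round trip through [read_sbml()] is lossless for
#' every field of the network containers.
#'
#' @param network a valid `refnet_network`.
#' @param path file path to write to.
#' @param name model name attribute.
#' @return The path, invisibly.
#' @export
write_sbml <- function(network, path, name = "refnet network") {
  v <- validate_network(network, finalized = FALSE)
  if (nrow(v)) {
    stop("refusing to write invalid network: ", nrow(v),
         " violation(s), e.g. [", v$object_id[1], "] ", v$message[1],
         call. = FALSE)
  }
  sp <- network$species
  ix <- network$interactions
  sp_sid <- sanitize_sid(sp$id)
  names(sp_sid) <- sp$id
  ix_sid <- sanitize_sid(paste0("rx_", ix$id))

  comps <- unique(c("cell", sp$compartment[!is.na(sp$compartment)]))
  comp_sid <- sanitize_sid(comps)
  names(comp_sid) <- comps

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', SBML_NS),
    sprintf('<model id="refnet_model" name="%s">', xml_escape(name)),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" name="%s" constant="true"/>',
            comp_sid, xml_escape(comps)),
    "</listOfCompartments>")

  sp_lines <- character(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    comp <- if (is.na(sp$compartment[i])) "cell" else sp$compartment[i]
    attrs <- sprintf('refnet:id="%s" refnet:speciesType="%s"',
                     xml_escape(sp$id[i]), sp$species_type[i])
    if (!is.na(sp$primary_sequence[i]))
      attrs <- paste(attrs, sprintf('refnet:sequence="%s"',
                                    xml_escape(sp$primary_sequence[i])))
    if (!is.na(sp$compartment[i]))
      attrs <- paste(attrs, 'refnet:hasCompartment="true"')
    nm <- if (is.na(sp$display_name[i])) "" else
      sprintf(' name="%s"', xml_escape(sp$display_name[i]))
    sp_lines[i] <- paste0(
      sprintf('<species id="%s"%s compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">',
              sp_sid[i], nm, comp_sid[[comp]]),
      "<annotation>",
      sprintf('<refnet:object xmlns:refnet="%s" %s/>', REFNET_NS, attrs),
      xref_annotation(sp_sid[i], sp$xrefs[[i]]),
      "</annotation></species>")
  }

  ix_lines <- character(nrow(ix))
  for (i in seq_len(nrow(ix))) {
    sub <- ix$substrates[[i]]
    pro <- ix$products[[i]]
    ctr <- ix$controllers[[i]]
    body <- ""
    if (nrow(sub))
      body <- paste0(body, "<listOfReactants>",
        paste0(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       sp_sid[sub$species], format(sub$coef, digits = 15)),
               collapse = ""), "</listOfReactants>")
    if (nrow(pro))
      body <- paste0(body, "<listOfProducts>",
        paste0(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       sp_sid[pro$species], format(pro$coef, digits = 15)),
               collapse = ""), "</listOfProducts>")
    if (length(ctr))
      body <- paste0(body, "<listOfModifiers>",
        paste0(sprintf('<modifierSpeciesReference species="%s"/>',
                       sp_sid[ctr]), collapse = ""), "</listOfModifiers>")
    ix_lines[i] <- paste0(
      sprintf('<reaction id="%s" reversible="%s" fast="false">',
              ix_sid[i], tolower(as.character(ix$reversible[i]))),
      "<annotation>",
      sprintf('<refnet:object xmlns:refnet="%s" refnet:id="%s" refnet:interactionType="%s"/>',
              REFNET_NS, xml_escape(ix$id[i]), ix$interaction_type[i]),
      "</annotation>", body, "</reaction>")
  }

  lines <- c(lines, "<listOfSpecies>", sp_lines, "</listOfSpecies>",
             if (nrow(ix)) c("<listOfReactions>", ix_lines,
                             "</listOfReactions>"),
             "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

parse_xref_uris <- function(uris) {
  m <- regmatches(uris,
                  regexec("^https?://identifiers\\.org/([^/]+)/(.+)$", uris))
  db <- vapply(m, function(g) if (length(g) == 3) g[2] else "uri", "")
  acc <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) == 3) m[[i]][3] else uris[i]
  }, "")
  xref(db, acc)
}

#' Read a network from SBML
#'
#' Inverse of [write_sbml()] on documents this package wrote. For foreign
#' documents, SBML species, reactions and modifiers map to the
#' corresponding containers; MIRIAM resource URIs are parsed into
#' cross-references and unknown annotation URIs are retained as opaque
#' xrefs (`db = "uri"`). A species without a recognized layer annotation is
#' imported as a metabolite, and the number of such species is reported as
#' a warning and attached as attribute `sbml_warnings`.
#'
#' @param path path to an SBML file.
#' @return A `refnet_network`; attribute `sbml_warnings` counts species
#'   whose type had to be assumed.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("failed to parse SBML document '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")

  n_unannotated <- 0L
  n <- length(sp_nodes)
  ids <- typ <- seqs <- comp <- nm <- character(n)
  xrs <- vector("list", n)
  for (i in seq_len(n)) {
    node <- sp_nodes[[i]]
    sid <- xml2::xml_attr(node, "id")
    ann <- xml2::xml_find_first(node, ".//*[local-name()='object']")
    if (!inherits(ann, "xml_missing") &&
        !is.na(xml2::xml_attr(ann, "speciesType"))) {
      ids[i] <- xml2::xml_attr(ann, "id")
      typ[i] <- xml2::xml_attr(ann, "speciesType")
      seqs[i] <- xml2::xml_attr(ann, "sequence")
      comp[i] <- if (!is.na(xml2::xml_attr(ann, "hasCompartment"))) {
        cnode <- xml2::xml_find_first(doc, sprintf(
          "//*[local-name()='compartment'][@id='%s']",
          xml2::xml_attr(node, "compartment")))
        cn <- xml2::xml_attr(cnode, "name")
        if (is.na(cn)) xml2::xml_attr(node, "compartment") else cn
      } else NA_character_
    } else {
      n_unannotated <- n_unannotated + 1L
      ids[i] <- sid
      typ[i] <- "metabolite"
      seqs[i] <- NA_character_
      comp[i] <- xml2::xml_attr(node, "compartment")
    }
    nm[i] <- xml2::xml_attr(node, "name")
    uris <- xml2::xml_attr(
      xml2::xml_find_all(node, ".//*[local-name()='li']"), "resource")
    xrs[[i]] <- parse_xref_uris(uris[!is.na(uris)])
  }
  sid_to_id <- stats::setNames(ids, xml2::xml_attr(sp_nodes, "id"))

  m <- length(rx_nodes)
  rids <- rtyp <- character(m)
  rev <- logical(m)
  subs <- pros <- ctrs <- vector("list", m)
  part <- function(node, what) {
    refs <- xml2::xml_find_all(node, sprintf(
      "./*[local-name()='listOf%s']/*[local-name()='speciesReference']", what))
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    stoich(unname(sid_to_id[xml2::xml_attr(refs, "species")]), st)
  }
  for (i in seq_len(m)) {
    node <- rx_nodes[[i]]
    ann <- xml2::xml_find_first(node, ".//*[local-name()='object']")
    if (!inherits(ann, "xml_missing") &&
        !is.na(xml2::xml_attr(ann, "interactionType"))) {
      rids[i] <- xml2::xml_attr(ann, "id")
      rtyp[i] <- xml2::xml_attr(ann, "interactionType")
    } else {
      rids[i] <- xml2::xml_attr(node, "id")
      rtyp[i] <- "metabolic_reaction"
    }
    rev[i] <- identical(xml2::xml_attr(node, "reversible"), "true")
    subs[[i]] <- part(node, "Reactants")
    pros[[i]] <- part(node, "Products")
    mods <- xml2::xml_find_all(node,
      "./*[local-name()='listOfModifiers']/*[local-name()='modifierSpeciesReference']")
    ctrs[[i]] <- unname(sid_to_id[xml2::xml_attr(mods, "species")])
  }

  net <- new_network(
    species_table(ids, typ, primary_sequence = seqs, compartment = comp,
                  display_name = nm, xrefs = xrs),
    if (m) interaction_table(rids, rtyp, subs, pros, ctrs, rev)
    else empty_interactions())
  if (n_unannotated > 0)
    warning(n_unannotated,
            " species without a layer annotation imported as metabolites",
            call. = FALSE)
  attr(net, "sbml_warnings") <- n_unannotated
  net
}
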