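# Domain containers for the multi-omic molecular interaction network.
#
# A network holds typed molecular species (gene, transcript, protein,
# protein_complex, metabolite) and typed interactions (transcription,
# translation, metabolic_reaction, complex_assembly, transport, exchange).
# Interactions consume substrates, produce products (both with positive
# stoichiometric coefficients) and may be controlled by species (a gene
# controls its transcription, a transcript its translation, an enzyme its
# metabolic reaction). Control edges are not material flow.

SPECIES_TYPES <- c("gene", "transcript", "protein", "protein_complex",
                   "metabolite")
INTERACTION_TYPES <- c("transcription", "translation", "metabolic_reaction",
                       "complex_assembly", "transport", "exchange")

#' Create a cross-reference table
#'
#' @param db character vector of database names.
#' @param accession character vector of accessions, same length as `db`.
#' @return A data frame with columns `db` and `accession`.
#' @export
xref <- function(db = character(), accession = character()) {
  stopifnot(length(db) == length(accession))
  data.frame(db = as.character(db), accession = as.character(accession),
             stringsAsFactors = FALSE)
}

#' Create a species table
#'
#' Builds the `species` component of a network. Scalar arguments are
#' recycled across `id`.
#'
#' @param id character vector of unique species identifiers.
#' @param species_type one of `"gene"`, `"transcript"`, `"protein"`,
#'   `"protein_complex"`, `"metabolite"` (recycled).
#' @param primary_sequence optional nucleotide or amino-acid sequence;
#'   must be `NA` for complexes and metabolites.
#' @param compartment optional compartment label (metabolites in
#'   compartmentalized models).
#' @param display_name optional human-readable name.
#' @param xrefs optional list of cross-reference tables (see [xref()]),
#'   one per species.
#' @return A data frame with one row per species and a list column `xrefs`.
#' @export
species_table <- function(id, species_type,
                          primary_sequence = NA_character_,
                          compartment = NA_character_,
                          display_name = NA_character_,
                          xrefs = NULL) {
  n <- length(id)
  if (is.null(xrefs)) xrefs <- replicate(n, xref(), simplify = FALSE)
  stopifnot(length(xrefs) == n)
  df <- data.frame(id = as.character(id),
                   species_type = rep_len(as.character(species_type), n),
                   primary_sequence = rep_len(as.character(primary_sequence), n),
                   compartment = rep_len(as.character(compartment), n),
                   display_name = rep_len(as.character(display_name), n),
                   stringsAsFactors = FALSE)
  df$xrefs <- xrefs
  df
}

#' Stoichiometric participant list
#'
#' @param species character vector of species ids.
#' @param coef positive stoichiometric coefficients (recycled).
#' @return A data frame with columns `species` and `coef`.
#' @export
stoich <- function(species = character(), coef = 1) {
  data.frame(species = as.character(species),
             coef = rep_len(as.numeric(coef), length(species)),
             stringsAsFactors = FALSE)
}

#' Create an interaction table
#'
#' @param id character vector of unique interaction identifiers.
#' @param interaction_type one of `"transcription"`, `"translation"`,
#'   `"metabolic_reaction"`, `"complex_assembly"`, `"transport"`,
#'   `"exchange"` (recycled).
#' @param substrates list of participant tables (see [stoich()]).
#' @param products list of participant tables.
#' @param controllers list of character vectors of controlling species ids.
#' @param reversible logical; reversibility is recorded pre-split only and
#'   must be `FALSE` in a finalized network.
#' @return A data frame with one row per interaction and list columns
#'   `substrates`, `products`, `controllers`.
#' @export
interaction_table <- function(id, interaction_type, substrates, products,
                              controllers = NULL, reversible = FALSE) {
  n <- length(id)
  if (is.null(controllers)) controllers <- replicate(n, character(), simplify = FALSE)
  stopifnot(length(substrates) == n, length(products) == n,
            length(controllers) == n)
  df <- data.frame(id = as.character(id),
                   interaction_type = rep_len(as.character(interaction_type), n),
                   reversible = rep_len(as.logical(reversible), n),
                   stringsAsFactors = FALSE)
  df$substrates <- substrates
  df$products <- products
  df$controllers <- controllers
  df[, c("id", "interaction_type", "substrates", "products", "controllers",
         "reversible")]
}

empty_species <- function() species_table(character(), character())
empty_interactions <- function() {
  interaction_table(character(), character(), list(), list(), list())
}

#' Construct a molecular interaction network
#'
#' @param species a species table (see [species_table()]).
#' @param interactions an interaction table (see [interaction_table()]).
#' @return An object of class `refnet_network` with components `species`
#'   and `interactions`.
#' @seealso [validate_network()]
#' @export
new_network <- function(species = empty_species(),
                        interactions = empty_interactions()) {
  structure(list(species = species, interactions = interactions),
            class = "refnet_network")
}

#' Total number of objects in a network
#'
#' Objects are molecular species plus interactions; the damage of a gene
#' knockout is reported as a set of objects.
#'
#' @param network a `refnet_network`.
#' @return Integer count `|species| + |interactions|`.
#' @export
network_size <- function(network) {
  nrow(network$species) + nrow(network$interactions)
}

#' @export
print.refnet_network <- function(x, ...) {
  st <- table(factor(x$species$species_type, levels = SPECIES_TYPES))
  it <- table(factor(x$interactions$interaction_type,
                     levels = INTERACTION_TYPES))
  cat(sprintf("<refnet_network> %d species + %d interactions = %d objects\n",
              nrow(x$species), nrow(x$interactions), network_size(x)))
  cat("  species:     ", paste(sprintf("%s=%d", names(st), st), collapse = " "),
      "\n")
  cat("  interactions:", paste(sprintf("%s=%d", names(it), it), collapse = " "),
      "\n")
  invisible(x)
}

violation <- function(object_id, rule, message) {
  data.frame(object_id = object_id, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() violation(character(), character(), character())

#' Validate a network against its structural invariants
#'
#' Checks id uniqueness and disjointness, the closed type vocabularies,
#' absence of sequences on complexes and metabolites, referential integrity
#' of all substrate/product/controller edges, positivity of stoichiometric
#' coefficients, and the per-type interaction shapes: a transcription has
#' exactly one gene controller and one transcript product, a translation one
#' transcript controller and one protein product, a complex assembly at
#' least two protein substrates and exactly one complex product. In a
#' finalized network every interaction must have `reversible = FALSE`.
#'
#' Violations are returned as data, not raised as conditions.
#'
#' @param network a `refnet_network`.
#' @param finalized if `TRUE` (default), interactions flagged reversible are
#'   reported as violations (reversible reactions must be split into two
#'   irreversible directions before analysis).
#' @return A data frame with columns `object_id`, `rule`, `message`; zero
#'   rows when the network is well formed.
#' @export
validate_network <- function(network, finalized = TRUE) {
  sp <- network$species
  ix <- network$interactions
  out <- list(no_violations())

  dup <- sp$id[duplicated(sp$id)]
  if (length(dup)) out[[length(out) + 1L]] <-
    violation(unique(dup), "species_id_unique", "duplicated species id")
  dup <- ix$id[duplicated(ix$id)]
  if (length(dup)) out[[length(out) + 1L]] <-
    violation(unique(dup), "interaction_id_unique", "duplicated interaction id")
  shared <- intersect(sp$id, ix$id)
  if (length(shared)) out[[length(out) + 1L]] <-
    violation(shared, "id_spaces_disjoint",
              "id used for both a species and an interaction")

  bad <- !(sp$species_type %in% SPECIES_TYPES)
  if (any(bad)) out[[length(out) + 1L]] <-
    violation(sp$id[bad], "species_type",
              paste("unknown species_type:", sp$species_type[bad]))
  bad <- !(ix$interaction_type %in% INTERACTION_TYPES)
  if (any(bad)) out[[length(out) + 1L]] <-
    violation(ix$id[bad], "interaction_type",
              paste("unknown interaction_type:", ix$interaction_type[bad]))

  bad <- sp$species_type %in% c("protein_complex", "metabolite") &
    !is.na(sp$primary_sequence)
  if (any(bad)) out[[length(out) + 1L]] <-
    violation(sp$id[bad], "sequence_absent",
              "complexes and metabolites carry no primary sequence")

  sp_ids <- sp$id
  type_of <- stats::setNames(sp$species_type, sp$id)
  for (k in seq_len(nrow(ix))) {
    iid <- ix$id[k]
    sub <- ix$substrates[[k]]
    pro <- ix$products[[k]]
    ctr <- ix$controllers[[k]]
    refs <- c(sub$species, pro$species, ctr)
    miss <- setdiff(refs, sp_ids)
    if (length(miss)) out[[length(out) + 1L]] <-
      violation(rep(iid, length(miss)), "referential_integrity",
                paste("references unknown species id:", miss))
    if (any(c(sub$coef, pro$coef) <= 0)) out[[length(out) + 1L]] <-
      violation(iid, "positive_coefficient",
                "stoichiometric coefficients must be > 0")

    known_ctr <- ctr[ctr %in% sp_ids]
    known_pro <- pro$species[pro$species %in% sp_ids]
    known_sub <- sub$species[sub$species %in% sp_ids]
    typ <- ix$interaction_type[k]
    if (typ == "transcription") {
      if (length(ctr) != 1L || !identical(unname(type_of[known_ctr]), "gene"))
        out[[length(out) + 1L]] <- violation(iid, "transcription_shape",
          "transcription requires exactly one controller of type gene")
      if (nrow(pro) != 1L || !identical(unname(type_of[known_pro]), "transcript"))
        out[[length(out) + 1L]] <- violation(iid, "transcription_shape",
          "transcription requires exactly one transcript product")
    } else if (typ == "translation") {
      if (length(ctr) != 1L ||
          !identical(unname(type_of[known_ctr]), "transcript"))
        out[[length(out) + 1L]] <- violation(iid, "translation_shape",
          "translation requires exactly one controller of type transcript")
      if (nrow(pro) != 1L || !identical(unname(type_of[known_pro]), "protein"))
        out[[length(out) + 1L]] <- violation(iid, "translation_shape",
          "translation requires exactly one protein product")
    } else if (typ == "complex_assembly") {
      if (nrow(sub) < 2L || !all(type_of[known_sub] == "protein"))
        out[[length(out) + 1L]] <- violation(iid, "assembly_shape",
          "complex assembly requires >= 2 protein substrates")
      if (nrow(pro) != 1L ||
          !identical(unname(type_of[known_pro]), "protein_complex"))
        out[[length(out) + 1L]] <- violation(iid, "assembly_shape",
          "complex assembly requires exactly one complex product")
    }
    if (finalized && isTRUE(ix$reversible[k]))
      out[[length(out) + 1L]] <- violation(iid, "irreversible",
        "finalized networks contain no reversible interactions")
  }
  do.call(rbind, out)
}

#' Stop unless a network validates cleanly
#' @param network a `refnet_network`.
#' @param finalized passed to [validate_network()].
#' @return The network, invisibly.
#' @export
assert_valid_network <- function(network, finalized = TRUE) {
  v <- validate_network(network, finalized = finalized)
  if (nrow(v)) {
    stop("invalid network: ", nrow(v), " violation(s), e.g. [",
         v$object_id[1], "] ", v$message[1], call. = FALSE)
  }
  invisible(network)
}

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
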