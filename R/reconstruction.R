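# Reference-object reconstruction.
#
# Source records emulate database exports: sequence records for genes,
# transcripts and proteins (possibly redundant across databases), link
# tables along the central dogma, EC annotations of proteins, metabolic
# reaction tables and protein-protein interaction (PPI) records. The
# reconstruction merges records with 100% sequence identity into reference
# objects, instantiates the non-documented transcription and translation
# interactions, connects reactions to enzymes through EC numbers, builds
# complex assembly interactions, and finally splits every reversible
# reaction into two irreversible directions.

#' Create a table of sequence source records
#'
#' @param source_db database name.
#' @param accession record accession, unique within its database.
#' @param record_type `"gene"`, `"transcript"` or `"protein"`.
#' @param primary_sequence nonempty sequence string.
#' @return A data frame of source records.
#' @export
source_records <- function(source_db, accession, record_type,
                           primary_sequence) {
  n <- length(accession)
  data.frame(source_db = rep_len(as.character(source_db), n),
             accession = as.character(accession),
             record_type = rep_len(as.character(record_type), n),
             primary_sequence = as.character(primary_sequence),
             stringsAsFactors = FALSE)
}

normalize_sequence <- function(x) toupper(gsub("\\s+", "", x))

type_prefix <- c(gene = "g:", transcript = "tr:", protein = "p:")

#' Merge redundant sequence records into reference species
#'
#' Records of one type whose normalized primary sequences are identical
#' (uppercased, whitespace stripped; identity means exact string equality)
#' are merged into a single reference species whose cross-references are
#' the union of the contributing (database, accession) pairs.
#'
#' @param records a source record table (one `record_type` throughout).
#' @param id_prefix identifier namespace prefix; defaults by record type
#'   (`"g:"`, `"tr:"`, `"p:"`).
#' @return A list with `species` (a species table, one row per distinct
#'   sequence, in order of first appearance) and `map` (a data frame
#'   `source_db`, `accession`, `species_id` covering every input record).
#' @export
merge_species_by_sequence <- function(records, id_prefix = NULL) {
  rt <- unique(records$record_type)
  if (length(rt) != 1L)
    stop("records must all share one record_type, got: ",
         paste(rt, collapse = ", "), call. = FALSE)
  if (is.null(id_prefix)) id_prefix <- type_prefix[[rt]]
  seqs <- normalize_sequence(records$primary_sequence)
  empty <- is.na(seqs) | seqs == ""
  if (any(empty))
    stop("record with empty primary sequence: ",
         paste(records$source_db[empty], records$accession[empty],
               sep = ":", collapse = ", "), call. = FALSE)
  key <- match(seqs, unique(seqs))
  ids <- sprintf("%s%04d", id_prefix, seq_along(unique(seqs)))
  xrs <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    unique(xref(records$source_db[idx], records$accession[idx]))
  })
  species <- species_table(ids, rt, primary_sequence = unique(seqs),
                           xrefs = unname(xrs[as.character(seq_along(ids))]))
  map <- data.frame(source_db = records$source_db,
                    accession = records$accession,
                    species_id = ids[key], stringsAsFactors = FALSE)
  list(species = species, map = map)
}

map_accessions <- function(map, db, accession, what) {
  idx <- match(paste(db, accession, sep = "\r"),
               paste(map$source_db, map$accession, sep = "\r"))
  if (anyNA(idx))
    stop("dangling ", what, " accession: ",
         paste(db[is.na(idx)], accession[is.na(idx)], sep = ":",
               collapse = ", "), call. = FALSE)
  map$species_id[idx]
}

#' Instantiate transcription and translation interactions
#'
#' Databases document genes, transcripts and their links but not the
#' transcription and translation processes themselves, so one transcription
#' is instantiated per (gene, transcript) link -- the gene controls it and
#' the transcript is its sole product -- and one translation per transcript,
#' controlled by the transcript and producing its protein. A transcript
#' merged from k genes therefore receives k transcriptions; a protein
#' without any transcript link stays an orphan species with no producing
#' interaction.
#'
#' @param gene_map,transcript_map,protein_map merge maps from
#'   [merge_species_by_sequence()].
#' @param link_gene_transcript data frame with columns `gene_db`,
#'   `gene_accession`, `transcript_db`, `transcript_accession`.
#' @param link_transcript_protein data frame with columns `transcript_db`,
#'   `transcript_accession`, `protein_db`, `protein_accession`.
#' @return An interaction table of transcriptions and translations.
#' @export
instantiate_central_dogma <- function(gene_map, transcript_map, protein_map,
                                      link_gene_transcript,
                                      link_transcript_protein) {
  gt <- link_gene_transcript
  tp <- link_transcript_protein
  gid <- map_accessions(gene_map, gt$gene_db, gt$gene_accession, "gene")
  tid <- map_accessions(transcript_map, gt$transcript_db,
                        gt$transcript_accession, "transcript")
  pair <- unique(data.frame(gid = gid, tid = tid, stringsAsFactors = FALSE))

  tid2 <- map_accessions(transcript_map, tp$transcript_db,
                         tp$transcript_accession, "transcript")
  pid <- map_accessions(protein_map, tp$protein_db, tp$protein_accession,
                        "protein")
  tx2p <- unique(data.frame(tid = tid2, pid = pid, stringsAsFactors = FALSE))
  multi <- unique(tx2p$tid[duplicated(tx2p$tid)])
  if (length(multi))
    stop("transcript linked to more than one distinct protein: ",
         paste(multi, collapse = ", "), call. = FALSE)
  linked_tx <- unique(pair$tid)
  missing_p <- setdiff(linked_tx, tx2p$tid)
  if (length(missing_p))
    stop("transcript without a protein product: ",
         paste(missing_p, collapse = ", "), call. = FALSE)

  n_txn <- nrow(pair)
  txn <- interaction_table(
    sprintf("ix:txn:%04d", seq_len(n_txn)), "transcription",
    substrates = replicate(n_txn, stoich(), simplify = FALSE),
    products = lapply(pair$tid, stoich),
    controllers = as.list(pair$gid))

  tln_tx <- linked_tx
  tln_p <- tx2p$pid[match(tln_tx, tx2p$tid)]
  n_tln <- length(tln_tx)
  tln <- interaction_table(
    sprintf("ix:tln:%04d", seq_len(n_tln)), "translation",
    substrates = replicate(n_tln, stoich(), simplify = FALSE),
    products = lapply(tln_p, stoich),
    controllers = as.list(tln_tx))
  rbind(txn, tln)
}

#' Create a table of metabolic reaction records
#'
#' Participant strings pack metabolite accessions with coefficients as
#' `"C0001:1;C0002:2"` (coefficient 1 may be omitted).
#'
#' @param accession reaction accessions.
#' @param substrates,products packed participant strings.
#' @param ec_numbers semicolon-separated EC number strings (may be empty).
#' @param reversible logical.
#' @return A data frame of reaction records.
#' @export
reaction_records <- function(accession, substrates, products,
                             ec_numbers = "", reversible = FALSE) {
  n <- length(accession)
  data.frame(accession = as.character(accession),
             substrates = as.character(substrates),
             products = as.character(products),
             ec_numbers = rep_len(as.character(ec_numbers), n),
             reversible = rep_len(as.logical(reversible), n),
             stringsAsFactors = FALSE)
}

unpack_participants <- function(s, prefix = "m:") {
  if (is.na(s) || s == "") return(stoich())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stoich(paste0(prefix, vapply(parts, `[`, "", 1)),
         vapply(parts, function(p) {
           if (length(p) > 1) as.numeric(p[2]) else 1
         }, 0))
}

pack_participants <- function(st, prefix = "m:") {
  if (nrow(st) == 0) return("")
  paste(sprintf("%s:%g", sub(paste0("^", prefix), "", st$species), st$coef),
        collapse = ";")
}

split_ec <- function(ec) strsplit(ec, ".", fixed = TRUE)

check_ec <- function(ecs) {
  ecs <- ecs[!is.na(ecs) & ecs != ""]
  bad <- !grepl("^[0-9]+(\\.([0-9]+|-)){3}$", ecs) &
    !grepl("^([0-9]+|-)(\\.([0-9]+|-)){3}$", ecs)
  if (any(bad))
    stop("malformed EC number: ", paste(ecs[bad], collapse = ", "),
         call. = FALSE)
  ecs
}

# partial ECs with trailing dashes match any completion, on either side
ec_matches <- function(a, b) {
  fa <- split_ec(a)[[1]]
  fb <- split_ec(b)[[1]]
  all(fa == fb | fa == "-" | fb == "-")
}

#' Connect metabolic reactions to their enzymes through EC numbers
#'
#' For each reaction record and each protein annotated with at least one of
#' the record's EC numbers, a separate metabolic reaction interaction is
#' reconstructed with that single protein as controller (isozymes yield
#' parallel reaction copies). An EC with trailing dashes matches any
#' completion. Reaction records matching no annotated protein yield one
#' uncatalyzed interaction with no controller, or are dropped when
#' `uncatalyzed = "drop"`.
#'
#' @param reactions a reaction record table (see [reaction_records()]).
#' @param protein_ec data frame with columns `protein_id` (merged species
#'   ids) and `ec`.
#' @param uncatalyzed `"retain"` (default) or `"drop"`.
#' @param metabolite_prefix namespace prefix for metabolite ids.
#' @return An interaction table of (possibly still reversible) metabolic
#'   reactions; attribute `n_uncatalyzed` counts reaction records without
#'   an enzyme.
#' @export
link_enzymes_by_ec <- function(reactions, protein_ec,
                               uncatalyzed = c("retain", "drop"),
                               metabolite_prefix = "m:") {
  uncatalyzed <- match.arg(uncatalyzed)
  check_ec(protein_ec$ec)
  ids <- character()
  subs <- pros <- ctrs <- list()
  rev <- logical()
  n_unc <- 0L
  k <- 0L
  for (i in seq_len(nrow(reactions))) {
    rec <- reactions[i, ]
    ecs <- check_ec(strsplit(rec$ec_numbers, ";", fixed = TRUE)[[1]])
    enz <- character()
    if (length(ecs) && nrow(protein_ec)) {
      hit <- vapply(seq_len(nrow(protein_ec)), function(j) {
        any(vapply(ecs, ec_matches, TRUE, b = protein_ec$ec[j]))
      }, TRUE)
      enz <- unique(protein_ec$protein_id[hit])
    }
    sub <- unpack_participants(rec$substrates, metabolite_prefix)
    pro <- unpack_participants(rec$products, metabolite_prefix)
    if (length(enz) == 0L) {
      n_unc <- n_unc + 1L
      if (uncatalyzed == "drop") next
      enz <- NA_character_
    }
    for (e in enz) {
      k <- k + 1L
      ids[k] <- sprintf("ix:rxn:%04d", k)
      subs[[k]] <- sub
      pros[[k]] <- pro
      ctrs[[k]] <- if (is.na(e)) character() else e
      rev[k] <- rec$reversible
    }
  }
  out <- if (k) interaction_table(ids, "metabolic_reaction", subs, pros,
                                  ctrs, rev)
  else empty_interactions()
  attr(out, "n_uncatalyzed") <- n_unc
  out
}

#' Build protein complexes and their assembly interactions
#'
#' One complex species and one irreversible assembly interaction is created
#' per distinct member set; records listing the same (sorted) member
#' proteins are deduplicated and their accessions pooled as
#' cross-references of the complex. Member proteins enter as substrates
#' with coefficient 1; no disassembly interaction is created.
#'
#' @param ppi data frame with columns `source_db`, `accession` and a list
#'   column `member_ids` of merged protein species ids (>= 2 each).
#' @return A list with `species` (complex species table) and
#'   `interactions` (assembly interaction table).
#' @export
build_assembly_interactions <- function(ppi) {
  members <- lapply(ppi$member_ids, function(m) sort(unique(m)))
  short <- lengths(members) < 2L
  if (any(short))
    stop("PPI record with fewer than 2 distinct member proteins: ",
         paste(ppi$accession[short], collapse = ", "), call. = FALSE)
  key <- vapply(members, paste, "", collapse = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  u_members <- members[first]
  n <- length(u_members)
  cx_ids <- sprintf("cx:%04d", seq_len(n))
  xrs <- lapply(seq_len(n), function(g) {
    idx <- which(grp == g)
    unique(xref(ppi$source_db[idx], ppi$accession[idx]))
  })
  species <- species_table(cx_ids, "protein_complex", xrefs = xrs)
  inter <- interaction_table(
    sprintf("ix:asm:%04d", seq_len(n)), "complex_assembly",
    substrates = lapply(u_members, stoich),
    products = lapply(cx_ids, stoich),
    controllers = replicate(n, character(), simplify = FALSE))
  list(species = species, interactions = inter)
}

#' Split reversible reactions into irreversible directions
#'
#' Each reversible interaction is replaced by a forward copy (id suffixed
#' `":f"`) and a reverse copy (id suffixed `":r"`, substrates and products
#' swapped, controllers shared); irreversible interactions pass through
#' unchanged. Every output has `reversible = FALSE`.
#'
#' @param interactions an interaction table.
#' @return An interaction table with `2k + m` rows for `k` reversible and
#'   `m` irreversible inputs.
#' @export
split_reversible_reactions <- function(interactions) {
  if (nrow(interactions) == 0 || !any(interactions$reversible))
    return(interactions)
  rows <- vector("list", nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    row <- interactions[i, ]
    if (!isTRUE(row$reversible)) {
      rows[[i]] <- row
      next
    }
    fwd <- row
    fwd$id <- paste0(row$id, ":f")
    fwd$reversible <- FALSE
    bwd <- row
    bwd$id <- paste0(row$id, ":r")
    bwd$substrates <- row$products
    bwd$products <- row$substrates
    bwd$reversible <- FALSE
    rows[[i]] <- rbind(fwd, bwd)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a network from source records
#'
#' Composes the reconstruction pipeline: sequence-identity merging of
#' genes, transcripts and proteins; instantiation of transcriptions and
#' translations; metabolite import; EC-based enzyme linking; complex
#' assembly; and reversible-reaction splitting. The result passes
#' [validate_network()].
#'
#' @param sources a list with components (each optional unless referenced
#'   by another): `genes`, `transcripts`, `proteins` (source record
#'   tables); `link_gene_transcript`, `link_transcript_protein` (link
#'   tables); `protein_ec` (data frame `db`, `accession`, `ec`);
#'   `reactions` (reaction record table); `ppi` (data frame `source_db`,
#'   `accession`, `members` packed as `"db|acc;db|acc"`);
#'   `exchange_metabolites` (character vector of metabolite accessions
#'   with an exchange/uptake process).
#' @param uncatalyzed how to treat reactions matching no enzyme; see
#'   [link_enzymes_by_ec()].
#' @param metabolite_db database name used for metabolite cross-references.
#' @return A finalized `refnet_network`; attribute `merge_maps` holds the
#'   gene/transcript/protein merge maps.
#' @export
assemble_network <- function(sources, uncatalyzed = c("retain", "drop"),
                             metabolite_db = "compounddb") {
  uncatalyzed <- match.arg(uncatalyzed)
  s <- sources
  gm <- merge_species_by_sequence(s$genes)
  tm <- merge_species_by_sequence(s$transcripts)
  pm <- merge_species_by_sequence(s$proteins)
  dogma <- instantiate_central_dogma(gm$map, tm$map, pm$map,
                                     s$link_gene_transcript,
                                     s$link_transcript_protein)

  met_acc <- character()
  rxn <- empty_interactions()
  if (!is.null(s$reactions) && nrow(s$reactions)) {
    pec <- data.frame(protein_id = character(), ec = character())
    if (!is.null(s$protein_ec) && nrow(s$protein_ec)) {
      pec <- data.frame(
        protein_id = map_accessions(pm$map, s$protein_ec$db,
                                    s$protein_ec$accession, "protein"),
        ec = s$protein_ec$ec, stringsAsFactors = FALSE)
    }
    rxn <- link_enzymes_by_ec(s$reactions, pec, uncatalyzed = uncatalyzed)
    met_acc <- unlist(lapply(seq_len(nrow(s$reactions)), function(i) {
      c(unpack_participants(s$reactions$substrates[i], "")$species,
        unpack_participants(s$reactions$products[i], "")$species)
    }))
  }
  met_acc <- unique(c(met_acc, s$exchange_metabolites))
  metabolites <- if (length(met_acc)) {
    species_table(paste0("m:", met_acc), "metabolite",
                  xrefs = lapply(met_acc, function(a) xref(metabolite_db, a)))
  } else empty_species()

  cx_sp <- empty_species()
  asm <- empty_interactions()
  if (!is.null(s$ppi) && nrow(s$ppi)) {
    ppi <- s$ppi
    ppi$member_ids <- lapply(strsplit(ppi$members, ";", fixed = TRUE),
                             function(m) {
      parts <- strsplit(m, "|", fixed = TRUE)
      map_accessions(pm$map, vapply(parts, `[`, "", 1),
                     vapply(parts, `[`, "", 2), "protein")
    })
    built <- build_assembly_interactions(ppi)
    cx_sp <- built$species
    asm <- built$interactions
  }

  exc <- empty_interactions()
  if (length(s$exchange_metabolites)) {
    acc <- s$exchange_metabolites
    exc <- interaction_table(
      paste0("ix:exc:", acc), "exchange",
      substrates = replicate(length(acc), stoich(), simplify = FALSE),
      products = lapply(paste0("m:", acc), stoich),
      controllers = replicate(length(acc), character(), simplify = FALSE))
  }

  interactions <- split_reversible_reactions(
    rbind(dogma, rxn, asm, exc))
  net <- new_network(
    rbind(gm$species, tm$species, pm$species, cx_sp, metabolites),
    interactions)
  assert_valid_network(net)
  attr(net, "merge_maps") <- list(gene = gm$map, transcript = tm$map,
                                  protein = pm$map)
  attr(net, "n_uncatalyzed") <- attr(rxn, "n_uncatalyzed")
  net
}
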