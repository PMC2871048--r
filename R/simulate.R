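# Synthetic networks and knockout studies with planted ground truth.
#
# The generator emulates the shape of database exports feeding the
# reconstruction: layered central-dogma chains (one transcription per
# gene, one translation per transcript), occasional identical coding
# sequences (merged transcripts), proteins redundantly listed across
# pseudo-databases, orphan proteins without a transcript, proteins with a
# second independent route of production, hub-skewed protein complex
# membership with median size 2 and a heavy tail, and an enzyme-catalyzed
# reaction network with exchange reactions. Knockout studies plant a set
# of essential objects; a strain is inviable iff its Boolean damage
# intersects the planted set, optionally flipped by label noise.
# Sequences are random strings over the appropriate alphabet; no
# biological realism is claimed for them.

#' Synthetic network configuration
#'
#' @param n_genes number of genes.
#' @param p_duplicate_cds probability that a gene shares its coding
#'   sequence with an earlier gene (their transcripts merge).
#' @param p_orphan_protein fraction of extra proteins documented without
#'   any transcript.
#' @param p_redundant_protein_route probability that a transcript's
#'   protein is shared with another transcript, giving the protein a
#'   second, independent producing translation.
#' @param n_complex_records number of protein-protein interaction records.
#' @param p_complex_tail,tail_geom_p complex size distribution: size 2
#'   with probability `1 - p_complex_tail`, otherwise `2 + Geom(tail_geom_p)`,
#'   capped at 99 (median 2, heavy tail).
#' @param hub_exponent skew of complex membership sampling (weights
#'   proportional to rank^-hub_exponent; larger = hubbier).
#' @param n_metabolites size of the metabolite pool.
#' @param n_reactions number of metabolic reaction records.
#' @param fraction_reversible fraction of reactions flagged reversible
#'   (split into two directions at assembly).
#' @param fraction_catalyzed fraction of reactions with an EC number and
#'   hence at least one enzyme.
#' @param n_exchange number of metabolites with an exchange (uptake)
#'   process.
#' @param seed integer seed; all generation is reproducible from it.
#' @return A list of class `refnet_network_config`.
#' @export
network_config <- function(n_genes = 200,
                           p_duplicate_cds = 0.01,
                           p_orphan_protein = 0.02,
                           p_redundant_protein_route = 0.03,
                           n_complex_records = 2L * n_genes,
                           p_complex_tail = 0.45,
                           tail_geom_p = 0.25,
                           hub_exponent = 0.8,
                           n_metabolites = 60,
                           n_reactions = 80,
                           fraction_reversible = 0.3,
                           fraction_catalyzed = 0.9,
                           n_exchange = 10,
                           seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              p_duplicate_cds = p_duplicate_cds,
              p_orphan_protein = p_orphan_protein,
              p_redundant_protein_route = p_redundant_protein_route,
              n_complex_records = as.integer(n_complex_records),
              p_complex_tail = p_complex_tail,
              tail_geom_p = tail_geom_p,
              hub_exponent = hub_exponent,
              n_metabolites = as.integer(n_metabolites),
              n_reactions = as.integer(n_reactions),
              fraction_reversible = fraction_reversible,
              fraction_catalyzed = fraction_catalyzed,
              n_exchange = as.integer(n_exchange),
              seed = as.integer(seed))
  probs <- unlist(cfg[grep("^(p_|fraction_)", names(cfg))])
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$n_genes >= 1, cfg$n_complex_records >= 0,
            cfg$n_metabolites >= 0, cfg$n_reactions >= 0,
            cfg$n_exchange <= cfg$n_metabolites)
  if (cfg$n_complex_records > 0 && cfg$n_genes < 2)
    stop("complex records require at least 2 genes/proteins", call. = FALSE)
  structure(cfg, class = "refnet_network_config")
}

# sample from the elements of x even when x has length 1
resample <- function(x, ...) x[sample.int(length(x), ...)]

random_seq <- function(n, len, alphabet) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}

#' Generate database-export-like source records
#'
#' Draws the synthetic biology (sequences, central-dogma links, complex
#' records, reactions, enzyme annotations) and returns it in exactly the
#' shape [assemble_network()] consumes, together with generator
#' bookkeeping: expected per-type counts and the identities of planted
#' structural features (duplicate-CDS groups, redundant-route proteins,
#' orphan proteins).
#'
#' @param config a `refnet_network_config`.
#' @return A list with `sources` (see [assemble_network()]) and
#'   `bookkeeping`.
#' @export
generate_source_records <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    ng <- cfg$n_genes
    dna <- c("A", "C", "G", "T")
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

    gene_acc <- sprintf("GENE%04d", seq_len(ng))
    gene_seq <- random_seq(ng, 60, dna)

    # coding sequences; a duplicate copies an earlier gene's CDS, which
    # merges their transcripts (and forces a shared protein)
    cds <- random_seq(ng, 60, dna)
    dup_src <- rep(NA_integer_, ng)
    if (ng >= 2) {
      dup <- which(stats::runif(ng - 1) < cfg$p_duplicate_cds) + 1L
      for (i in dup) {
        j <- sample.int(i - 1L, 1)
        cds[i] <- cds[j]
        dup_src[i] <- j
      }
    }
    tx_acc <- sprintf("TX%04d", seq_len(ng))
    tx_group <- match(cds, unique(cds))       # merged transcript index
    n_tx <- max(tx_group)

    # one protein sequence per distinct transcript; a redundant route
    # copies another distinct transcript's protein, so the merged protein
    # gains a second producing translation
    prot_of_tx <- random_seq(n_tx, 40, aa)
    redundant <- integer()
    if (n_tx >= 2) {
      cand <- which(stats::runif(n_tx) < cfg$p_redundant_protein_route)
      for (i in cand) {
        donors <- setdiff(seq_len(n_tx), c(i, redundant))
        if (length(donors) == 0) break
        j <- resample(donors, 1)
        prot_of_tx[i] <- prot_of_tx[j]
        redundant <- c(redundant, i)
      }
    }
    prot_group <- match(prot_of_tx, unique(prot_of_tx))
    n_prot_linked <- max(prot_group)
    prot_seq <- unique(prot_of_tx)
    prot_acc <- sprintf("PA%04d", seq_len(n_prot_linked))

    n_orphan <- round(cfg$p_orphan_protein * n_prot_linked)
    orphan_acc <- sprintf("PO%04d", seq_len(n_orphan))
    orphan_seq <- random_seq(n_orphan, 40, aa)

    # redundant cross-database listings of the same amino-acid sequence
    prot_recs <- source_records("protdb_a", prot_acc, "protein", prot_seq)
    in_b <- stats::runif(n_prot_linked) < 0.5
    in_c <- stats::runif(n_prot_linked) < 0.3
    if (any(in_b)) prot_recs <- rbind(prot_recs, source_records(
      "protdb_b", sprintf("PB%04d", which(in_b)), "protein",
      prot_seq[in_b]))
    if (any(in_c)) prot_recs <- rbind(prot_recs, source_records(
      "protdb_c", sprintf("PC%04d", which(in_c)), "protein",
      prot_seq[in_c]))
    if (n_orphan > 0) prot_recs <- rbind(prot_recs, source_records(
      "protdb_b", orphan_acc, "protein", orphan_seq))

    n_prot <- n_prot_linked + n_orphan
    all_prot_acc <- c(prot_acc, orphan_acc)
    all_prot_db <- c(rep("protdb_a", n_prot_linked),
                     rep("protdb_b", n_orphan))

    # complexes: hub-skewed membership, median size 2, heavy tail
    ppi <- NULL
    if (cfg$n_complex_records > 0 && n_prot >= 2) {
      w <- sample(seq_len(n_prot))^(-cfg$hub_exponent)
      sizes <- 2L + ifelse(stats::runif(cfg$n_complex_records) <
                             cfg$p_complex_tail,
                           stats::rgeom(cfg$n_complex_records,
                                        cfg$tail_geom_p), 0L)
      sizes <- pmin(sizes, 99L, n_prot)
      members <- vapply(sizes, function(k) {
        idx <- sample.int(n_prot, k, prob = w)
        paste(paste(all_prot_db[idx], all_prot_acc[idx], sep = "|"),
              collapse = ";")
      }, "")
      ppi <- data.frame(source_db = "ppidb",
                        accession = sprintf("CPX%05d",
                                            seq_len(cfg$n_complex_records)),
                        members = members, stringsAsFactors = FALSE)
    }

    # metabolic reactions with EC-mediated enzyme links
    reactions <- NULL
    protein_ec <- NULL
    used_mets <- character()
    n_rxn_interactions <- 0L
    if (cfg$n_reactions > 0 && cfg$n_metabolites >= 2) {
      met_acc <- sprintf("C%04d", seq_len(cfg$n_metabolites))
      n_ec <- max(1L, round(cfg$n_reactions * 0.6))
      ec_pool <- unique(sprintf("%d.%d.%d.%d",
                                sample(1:6, n_ec, TRUE),
                                sample(1:9, n_ec, TRUE),
                                sample(1:9, n_ec, TRUE),
                                sample(1:99, n_ec, TRUE)))
      # enzymes: 1-2 proteins per EC, drawn from the linked proteins
      pe <- do.call(rbind, lapply(ec_pool, function(ec) {
        k <- sample(1:2, 1)
        idx <- sample.int(n_prot_linked, min(k, n_prot_linked))
        data.frame(db = "protdb_a", accession = prot_acc[idx], ec = ec,
                   stringsAsFactors = FALSE)
      }))
      protein_ec <- unique(pe)
      enzymes_per_ec <- table(protein_ec$ec)

      sub_s <- pro_s <- ecs <- character(cfg$n_reactions)
      rev <- logical(cfg$n_reactions)
      for (i in seq_len(cfg$n_reactions)) {
        ns <- sample(1:3, 1)
        np <- sample(1:3, 1)
        picks <- sample(met_acc, ns + np)
        coef <- function(k) ifelse(stats::runif(k) < 0.85, 1, 2)
        sub_s[i] <- paste(sprintf("%s:%g", picks[seq_len(ns)], coef(ns)),
                          collapse = ";")
        pro_s[i] <- paste(sprintf("%s:%g", picks[ns + seq_len(np)],
                                  coef(np)), collapse = ";")
        ecs[i] <- if (stats::runif(1) < cfg$fraction_catalyzed)
          sample(ec_pool, 1) else ""
        rev[i] <- stats::runif(1) < cfg$fraction_reversible
        used_mets <- c(used_mets, picks)
        n_enz <- if (ecs[i] == "") 1L else
          as.integer(enzymes_per_ec[[ecs[i]]])
        n_rxn_interactions <- n_rxn_interactions +
          n_enz * (1L + as.integer(rev[i]))
      }
      reactions <- reaction_records(sprintf("R%04d",
                                            seq_len(cfg$n_reactions)),
                                    sub_s, pro_s, ecs, rev)
    }

    exchange <- character()
    if (cfg$n_exchange > 0 && cfg$n_metabolites > 0)
      exchange <- sample(sprintf("C%04d", seq_len(cfg$n_metabolites)),
                         cfg$n_exchange)

    sources <- list(
      genes = source_records("nucdb", gene_acc, "gene", gene_seq),
      transcripts = source_records("nucdb", tx_acc, "transcript", cds),
      proteins = prot_recs,
      link_gene_transcript = data.frame(
        gene_db = "nucdb", gene_accession = gene_acc,
        transcript_db = "nucdb", transcript_accession = tx_acc,
        stringsAsFactors = FALSE),
      link_transcript_protein = data.frame(
        transcript_db = "nucdb", transcript_accession = tx_acc,
        protein_db = "protdb_a",
        protein_accession = prot_acc[prot_group[tx_group]],
        stringsAsFactors = FALSE),
      protein_ec = protein_ec,
      reactions = reactions,
      ppi = ppi,
      exchange_metabolites = exchange)

    dup_groups <- split(gene_acc, tx_group)
    dup_groups <- unname(dup_groups[lengths(dup_groups) >= 2])
    redundant_prot <- unique(prot_acc[prot_group[redundant]])
    tx_per_prot <- table(prot_group)
    redundant_prot_ids <- sprintf(
      "p:%04d", as.integer(names(tx_per_prot)[tx_per_prot >= 2]))

    n_complexes <- if (is.null(ppi)) 0L else {
      mem_sets <- vapply(strsplit(ppi$members, ";", fixed = TRUE),
                         function(m) paste(sort(unique(m)), collapse = "\r"),
                         "")
      length(unique(mem_sets))
    }
    bookkeeping <- list(
      n_genes = ng,
      n_transcripts = n_tx,
      n_proteins = n_prot,
      n_complexes = n_complexes,
      n_metabolites = length(unique(c(used_mets, exchange))),
      n_transcriptions = ng,
      n_translations = n_tx,
      n_assemblies = n_complexes,
      n_metabolic_reactions = n_rxn_interactions,
      n_exchanges = cfg$n_exchange,
      duplicate_cds_groups = dup_groups,
      redundant_route_proteins = redundant_prot,
      redundant_route_protein_ids = redundant_prot_ids,
      orphan_proteins = orphan_acc,
      config = cfg)
    list(sources = sources, bookkeeping = bookkeeping)
  })
}

#' Generate a synthetic multi-omic network
#'
#' Draws source records with [generate_source_records()] and assembles
#' them with [assemble_network()], so the direct route and the
#' fixture-file route produce the same network by construction. The
#' result always passes [validate_network()].
#'
#' @param config a `refnet_network_config`.
#' @return A list with `network` (a finalized `refnet_network`),
#'   `bookkeeping` (expected per-type counts and planted structural
#'   features) and `sources` (the underlying records).
#' @export
generate_network <- function(config) {
  gen <- generate_source_records(config)
  network <- assemble_network(gen$sources)
  list(network = network, bookkeeping = gen$bookkeeping,
       sources = gen$sources)
}

#' Knockout study configuration
#'
#' @param n_essential number of planted essential objects.
#' @param planted_types object types the planted set is drawn from
#'   (default `"gene"`).
#' @param n_single,n_double,n_triple numbers of 1-, 2- and 3-gene
#'   knockout strains. Single knockouts cover distinct genes first
#'   (genome-wide coverage when `n_single >= n_genes`).
#' @param label_noise probability of flipping each phenotype label.
#' @param seed integer seed.
#' @return A list of class `refnet_study_config`.
#' @export
study_config <- function(n_essential = 30, planted_types = "gene",
                         n_single = 200, n_double = 600, n_triple = 30,
                         label_noise = 0, seed = 1) {
  stopifnot(label_noise >= 0, label_noise <= 1,
            all(planted_types %in% c(SPECIES_TYPES, INTERACTION_TYPES)))
  structure(list(n_essential = as.integer(n_essential),
                 planted_types = planted_types,
                 n_single = as.integer(n_single),
                 n_double = as.integer(n_double),
                 n_triple = as.integer(n_triple),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "refnet_study_config")
}

#' Generate a knockout study with planted ground truth
#'
#' Plants a set of essential objects, draws single/double/triple knockout
#' strains, computes every strain's Boolean damage, and labels a strain
#' inviable iff its damage intersects the planted set; each label is then
#' flipped with probability `label_noise`. The inverse problem -- recover
#' the planted set from damage plus phenotype -- is exactly what the
#' essentiality score solves, which makes parameter recovery a fair test.
#'
#' @param network a finalized `refnet_network`.
#' @param config a `refnet_study_config`.
#' @param model optional precompiled `refnet_boolean` for `network`.
#' @return A list with `fmatrix` (a `refnet_fmatrix` whose experiments
#'   carry the observed phenotypes) and `truth` (planted object ids,
#'   noise-free phenotypes, flip indicator).
#' @export
generate_phenotypes <- function(network, config, model = NULL) {
  if (is.null(model)) model <- compile_boolean_model(network)
  with_seed(config$seed, {
    genes <- network$species$id[network$species$species_type == "gene"]
    ng <- length(genes)
    objects <- c(network$species$id, network$interactions$id)
    types <- c(network$species$species_type,
               network$interactions$interaction_type)
    pool <- objects[types %in% config$planted_types]
    if (length(pool) < config$n_essential)
      stop("not enough objects of the planted types (", length(pool),
           ") for n_essential = ", config$n_essential, call. = FALSE)
    planted <- sample(pool, config$n_essential)

    singles <- as.list(sample(genes, min(config$n_single, ng)))
    extra <- config$n_single - length(singles)
    if (extra > 0)
      singles <- c(singles, as.list(sample(genes, extra, replace = TRUE)))
    doubles <- replicate(config$n_double, sample(genes, 2),
                         simplify = FALSE)
    triples <- replicate(config$n_triple, sample(genes, 3),
                         simplify = FALSE)
    ko <- c(singles, doubles, triples)
    experiments <- knockout_experiments(
      sprintf("s%05d", seq_along(ko)), ko)

    fm <- batch_damage(model, experiments)
    hit <- unname(Matrix::rowSums(
      fm$blocked[, match(planted, fm$objects), drop = FALSE]) > 0)
    true_phen <- ifelse(hit, "inviable", "viable")
    flip <- stats::runif(length(true_phen)) < config$label_noise
    observed <- ifelse(flip, ifelse(true_phen == "viable", "inviable",
                                    "viable"), true_phen)
    fm$experiments$phenotype <- observed
    list(fmatrix = fm,
         truth = list(planted = planted, true_phenotype = true_phen,
                      flipped = flip, config = config))
  })
}

#' Generate a random toy stoichiometric model
#'
#' Small random models for exercising the flux-balance blocked-reaction
#' machinery: a pool of metabolites, a random set of irreversible internal
#' reactions (1-2 substrates, 1-2 products) and exchange reactions on a
#' random metabolite subset, all with unit-magnitude bounds scaled to
#' `big`. Optionally attaches random GPR rules over a small gene pool.
#'
#' @param n_metabolites,n_internal,n_exchange model size.
#' @param n_genes size of the gene pool for GPR rules (0 = no rules).
#' @param seed integer seed.
#' @return A `refnet_smodel`.
#' @export
generate_stoichiometric_model <- function(n_metabolites = 8,
                                          n_internal = 12,
                                          n_exchange = 3,
                                          n_genes = 4, seed = 1) {
  with_seed(seed, {
    mets <- sprintf("M%02d", seq_len(n_metabolites))
    nr <- n_internal + n_exchange
    S <- matrix(0, n_metabolites, nr,
                dimnames = list(mets, c(sprintf("v%02d", seq_len(n_internal)),
                                        sprintf("EX%02d", seq_len(n_exchange)))))
    for (j in seq_len(n_internal)) {
      ns <- sample(1:2, 1)
      np <- sample(1:2, 1)
      picks <- sample.int(n_metabolites, ns + np)
      S[picks[seq_len(ns)], j] <- -1
      S[picks[ns + seq_len(np)], j] <- 1
    }
    ex_mets <- sample.int(n_metabolites, n_exchange)
    for (k in seq_len(n_exchange)) S[ex_mets[k], n_internal + k] <- -1
    exchange <- c(rep(FALSE, n_internal), rep(TRUE, n_exchange))
    gpr <- rep(NA_character_, nr)
    if (n_genes > 0) {
      pool <- sprintf("g%d", seq_len(n_genes))
      for (j in seq_len(n_internal)) {
        if (stats::runif(1) < 0.5) next
        k <- sample(1:3, 1)
        gs <- sample(pool, min(k, n_genes))
        op <- sample(c(" AND ", " OR "), 1)
        gpr[j] <- paste(gs, collapse = op)
      }
    }
    stoichiometric_model(S, lb = ifelse(exchange, -1000, 0), ub = 1000,
                         exchange = exchange, gpr = gpr)
  })
}
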