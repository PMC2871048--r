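test_that("records with identical sequences merge into one reference species", {
  recs <- source_records(c("nucdb", "nucdb"), c("GENE1", "GENE2"), "gene",
                         c("ATGC", "atg c"))
  out <- merge_species_by_sequence(recs)
  expect_equal(nrow(out$species), 1)
  expect_equal(nrow(out$species$xrefs[[1]]), 2)
  expect_equal(unique(out$map$species_id), out$species$id)

  # one protein listed by three databases
  recs <- source_records(c("protdb_a", "protdb_b", "protdb_c"),
                         c("P1", "X9", "Q3"), "protein", "MKV")
  out <- merge_species_by_sequence(recs)
  expect_equal(nrow(out$species), 1)
  expect_setequal(out$species$xrefs[[1]]$db,
                  c("protdb_a", "protdb_b", "protdb_c"))
})

test_that("distinct sequences map bijectively and merging is idempotent", {
  recs <- source_records("db", sprintf("T%02d", 1:8), "transcript",
                         replicate(8, paste(sample(c("A", "C", "G", "T"),
                                                   20, TRUE),
                                            collapse = "")))
  out <- merge_species_by_sequence(recs)
  expect_equal(nrow(out$species), 8)
  expect_equal(anyDuplicated(out$map$species_id), 0)

  # feeding the merged species back as records changes nothing
  again <- merge_species_by_sequence(
    source_records("merged", out$species$id, "transcript",
                   out$species$primary_sequence))
  expect_equal(again$species$primary_sequence,
               out$species$primary_sequence)
})

test_that("empty sequences are rejected with a named error", {
  recs <- source_records("db", c("A1", "A2"), "gene", c("ATG", ""))
  expect_error(merge_species_by_sequence(recs), "A2")
})

test_that("central dogma instantiation follows the one-per-link rule", {
  mk_map <- function(db, acc, ids) data.frame(
    source_db = db, accession = acc, species_id = ids,
    stringsAsFactors = FALSE)
  gmap <- mk_map("n", c("G1", "G2"), c("g:0001", "g:0002"))
  tmap <- mk_map("n", c("T1", "T2"), c("tr:0001", "tr:0001"))  # merged
  pmap <- mk_map("p", "P1", "p:0001")
  gt <- data.frame(gene_db = "n", gene_accession = c("G1", "G2"),
                   transcript_db = "n", transcript_accession = c("T1", "T2"))
  tp <- data.frame(transcript_db = "n",
                   transcript_accession = c("T1", "T2"),
                   protein_db = "p", protein_accession = "P1")
  ix <- instantiate_central_dogma(gmap, tmap, pmap, gt, tp)
  # two genes sharing one merged transcript: 2 transcriptions, 1 translation
  expect_equal(sum(ix$interaction_type == "transcription"), 2)
  expect_equal(sum(ix$interaction_type == "translation"), 1)
  tln <- ix[ix$interaction_type == "translation", ]
  expect_equal(tln$controllers[[1]], "tr:0001")
  expect_equal(tln$products[[1]]$species, "p:0001")

  expect_error(instantiate_central_dogma(
    gmap, tmap, pmap,
    data.frame(gene_db = "n", gene_accession = "G9",
               transcript_db = "n", transcript_accession = "T1"), tp),
    "dangling")
})

test_that("EC linking creates one reaction copy per matching enzyme", {
  rx <- reaction_records("R1", "C1:1", "C2:1", "5.3.1.9")
  pec <- data.frame(protein_id = c("p:0001", "p:0002"), ec = "5.3.1.9")
  out <- link_enzymes_by_ec(rx, pec)
  expect_equal(nrow(out), 2)
  expect_setequal(unlist(out$controllers), c("p:0001", "p:0002"))
  expect_equal(out$substrates[[1]]$species, "m:C1")

  # no matching enzyme: one uncatalyzed interaction, or dropped
  out <- link_enzymes_by_ec(rx, data.frame(protein_id = "p:0001",
                                           ec = "1.1.1.1"))
  expect_equal(nrow(out), 1)
  expect_length(out$controllers[[1]], 0)
  expect_equal(attr(out, "n_uncatalyzed"), 1)
  out <- link_enzymes_by_ec(rx, data.frame(protein_id = "p:0001",
                                           ec = "1.1.1.1"),
                            uncatalyzed = "drop")
  expect_equal(nrow(out), 0)

  # wildcard EC matches any completion
  out <- link_enzymes_by_ec(rx, data.frame(protein_id = "p:0003",
                                           ec = "5.3.1.-"))
  expect_equal(out$controllers[[1]], "p:0003")

  expect_error(link_enzymes_by_ec(
    reaction_records("R1", "C1:1", "C2:1", "5.3.x"), pec), "malformed EC")
})

test_that("EC linking agrees with a brute-force bipartite match", {
  set.seed(402)
  for (rep in 1:5) {
    ecs <- sprintf("%d.%d.%d.%d", sample(1:3, 6, TRUE), sample(1:3, 6, TRUE),
                   sample(1:3, 6, TRUE), sample(1:5, 6, TRUE))
    rx <- reaction_records(sprintf("R%d", 1:4), "C1:1", "C2:1",
                           vapply(1:4, function(i) {
                             paste(sample(ecs, sample(1:2, 1)),
                                   collapse = ";")
                           }, ""))
    pec <- data.frame(protein_id = sprintf("p:%04d", sample(1:5, 6, TRUE)),
                      ec = sample(ecs, 6, TRUE))
    pec <- unique(pec)
    out <- link_enzymes_by_ec(rx, pec, uncatalyzed = "drop")
    # oracle: enumerate all (reaction, protein) pairs sharing an EC string
    expected <- 0L
    for (i in 1:4) {
      recs <- strsplit(rx$ec_numbers[i], ";")[[1]]
      hits <- unique(pec$protein_id[pec$ec %in% recs])
      expected <- expected + length(hits)
    }
    expect_equal(nrow(out), expected)
  }
})

test_that("assembly interactions are built once per distinct member set", {
  ppi <- data.frame(source_db = "ppidb",
                    accession = c("C1", "C2", "C3"),
                    stringsAsFactors = FALSE)
  ppi$member_ids <- list(c("p:0001", "p:0002"),
                         c("p:0002", "p:0001"),   # duplicate, reordered
                         sprintf("p:%04d", 1:99))
  out <- build_assembly_interactions(ppi)
  expect_equal(nrow(out$species), 2)
  expect_equal(nrow(out$interactions), 2)
  expect_equal(nrow(out$interactions$substrates[[1]]), 2)
  expect_equal(nrow(out$interactions$substrates[[2]]), 99)
  # pooled xrefs of the duplicated record
  expect_setequal(out$species$xrefs[[1]]$accession, c("C1", "C2"))
  # member proteins are substrates with coefficient 1, complex sole product
  expect_true(all(out$interactions$substrates[[1]]$coef == 1))
  expect_equal(out$interactions$products[[1]]$species,
               out$species$id[1])

  bad <- data.frame(source_db = "ppidb", accession = "C9")
  bad$member_ids <- list("p:0001")
  expect_error(build_assembly_interactions(bad), "C9")
})

test_that("reversible reactions split into mirrored irreversible pairs", {
  ix <- interaction_table(
    c("ix:rxn:0001", "ix:rxn:0002"), "metabolic_reaction",
    substrates = list(stoich("m:A", 1), stoich("m:C", 2)),
    products = list(stoich("m:B", 1), stoich("m:D", 1)),
    controllers = list("p:0001", character()),
    reversible = c(TRUE, FALSE))
  out <- split_reversible_reactions(ix)
  expect_equal(nrow(out), 3)
  expect_false(any(out$reversible))
  fwd <- out[out$id == "ix:rxn:0001:f", ]
  bwd <- out[out$id == "ix:rxn:0001:r", ]
  expect_equal(bwd$substrates[[1]], fwd$products[[1]])
  expect_equal(bwd$products[[1]], fwd$substrates[[1]])
  expect_equal(bwd$controllers[[1]], "p:0001")
  # irreversible input passes through unchanged
  expect_equal(out[out$id == "ix:rxn:0002", ]$substrates[[1]]$coef, 2)
  # counting: k reversible + m irreversible -> 2k + m
  ix$reversible <- c(TRUE, TRUE)
  expect_equal(nrow(split_reversible_reactions(ix)), 4)
})

test_that("assembled networks match the generator's bookkeeping", {
  gen <- generate_network(small_network_config(seed = 5))
  net <- gen$network
  bk <- gen$bookkeeping
  expect_equal(nrow(validate_network(net)), 0)
  tt <- table(net$species$species_type)
  ti <- table(net$interactions$interaction_type)
  expect_equal(unname(tt[["gene"]]), bk$n_genes)
  expect_equal(unname(tt[["transcript"]]), bk$n_transcripts)
  expect_equal(unname(tt[["protein"]]), bk$n_proteins)
  expect_equal(unname(tt[["protein_complex"]]), bk$n_complexes)
  expect_equal(unname(tt[["metabolite"]]), bk$n_metabolites)
  expect_equal(unname(ti[["transcription"]]), bk$n_transcriptions)
  expect_equal(unname(ti[["translation"]]), bk$n_translations)
  expect_equal(unname(ti[["complex_assembly"]]), bk$n_assemblies)
  expect_equal(unname(ti[["metabolic_reaction"]]),
               bk$n_metabolic_reactions)
  expect_equal(unname(ti[["exchange"]]), bk$n_exchanges)
  expect_false(any(net$interactions$reversible))
})

test_that("fixture files round-trip into the same assembled network", {
  gen <- generate_source_records(small_network_config(seed = 13))
  dir <- withr::local_tempdir()
  write_source_fixtures(gen$sources, dir)
  src2 <- read_source_fixtures(dir)
  net_direct <- assemble_network(gen$sources)
  net_files <- assemble_network(src2)
  expect_identical(net_files$species$id, net_direct$species$id)
  expect_identical(net_files$species$primary_sequence,
                   net_direct$species$primary_sequence)
  expect_identical(net_files$interactions$id, net_direct$interactions$id)
  for (k in seq_len(nrow(net_direct$interactions))) {
    expect_equal(net_files$interactions$substrates[[k]],
                 net_direct$interactions$substrates[[k]],
                 ignore_attr = TRUE)
    expect_identical(net_files$interactions$controllers[[k]],
                     net_direct$interactions$controllers[[k]])
  }
})

test_that("a minimal one-chain fixture assembles to 5 objects", {
  sources <- list(
    genes = source_records("n", "G1", "gene", "ATGAAA"),
    transcripts = source_records("n", "T1", "transcript", "ATGAAA"),
    proteins = source_records("p", "P1", "protein", "MK"),
    link_gene_transcript = data.frame(
      gene_db = "n", gene_accession = "G1",
      transcript_db = "n", transcript_accession = "T1"),
    link_transcript_protein = data.frame(
      transcript_db = "n", transcript_accession = "T1",
      protein_db = "p", protein_accession = "P1"))
  net <- assemble_network(sources)
  expect_equal(network_size(net), 5)
})

test_that("a duplicated CDS pair collapses to a single transcript", {
  sources <- list(
    genes = source_records("n", c("G1", "G2", "G3"), "gene",
                           c("ATGAAA", "ATGCCC", "ATGGGG")),
    transcripts = source_records("n", c("T1", "T2", "T3"), "transcript",
                                 c("ATGAAA", "ATGAAA", "ATGGGG")),
    proteins = source_records("p", c("P1", "P3"), "protein", c("MK", "MG")),
    link_gene_transcript = data.frame(
      gene_db = "n", gene_accession = c("G1", "G2", "G3"),
      transcript_db = "n", transcript_accession = c("T1", "T2", "T3")),
    link_transcript_protein = data.frame(
      transcript_db = "n", transcript_accession = c("T1", "T2", "T3"),
      protein_db = "p", protein_accession = c("P1", "P1", "P3")))
  net <- assemble_network(sources)
  tt <- table(net$species$species_type)
  expect_equal(unname(tt[["transcript"]]), 2)  # genes - 1
  ti <- table(net$interactions$interaction_type)
  expect_equal(unname(ti[["transcription"]]), 3)
  expect_equal(unname(ti[["translation"]]), 2)
})

test_that("orphan proteins persist as species without producing interactions", {
  sources <- list(
    genes = source_records("n", "G1", "gene", "ATGAAA"),
    transcripts = source_records("n", "T1", "transcript", "ATGAAA"),
    proteins = source_records(c("p", "p"), c("P1", "P2"), "protein",
                              c("MK", "MQ")),
    link_gene_transcript = data.frame(
      gene_db = "n", gene_accession = "G1",
      transcript_db = "n", transcript_accession = "T1"),
    link_transcript_protein = data.frame(
      transcript_db = "n", transcript_accession = "T1",
      protein_db = "p", protein_accession = "P1"))
  net <- assemble_network(sources)
  orphan <- net$species$id[vapply(net$species$xrefs, function(x) {
    "P2" %in% x$accession
  }, TRUE)]
  produced <- unlist(lapply(net$interactions$products,
                            function(p) p$species))
  expect_false(orphan %in% produced)
})
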