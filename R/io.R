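# Fixture-file input/output for reconstruction sources.
#
# Sequence records travel as FASTA (header "db|accession"), everything
# else as TSV, mirroring the flat exports the reconstruction emulates.

fasta_path <- function(dir, what) file.path(dir, paste0(what, ".fasta"))

write_record_fasta <- function(records, path) {
  seqinr::write.fasta(as.list(records$primary_sequence),
                      names = paste(records$source_db, records$accession,
                                    sep = "|"),
                      file.out = path, nbchar = 80)
}

read_record_fasta <- function(path, record_type) {
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           seqtype = "AA")
  parts <- strsplit(names(fa), "|", fixed = TRUE)
  source_records(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
                 record_type, toupper(unlist(fa, use.names = FALSE)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) return(NULL)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = "character",
                    stringsAsFactors = FALSE)
}

#' Write reconstruction sources as fixture files
#'
#' Sequences go to `genes.fasta`, `transcripts.fasta`, `proteins.fasta`;
#' link tables, EC annotations, reaction and PPI tables to TSV; exchange
#' metabolites to a one-column TSV. [read_source_fixtures()] is the
#' inverse.
#'
#' @param sources a sources list (see [assemble_network()]).
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_source_fixtures <- function(sources, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_record_fasta(sources$genes, fasta_path(dir, "genes"))
  write_record_fasta(sources$transcripts, fasta_path(dir, "transcripts"))
  write_record_fasta(sources$proteins, fasta_path(dir, "proteins"))
  write_tsv(sources$link_gene_transcript,
            file.path(dir, "link_gene_transcript.tsv"))
  write_tsv(sources$link_transcript_protein,
            file.path(dir, "link_transcript_protein.tsv"))
  if (!is.null(sources$protein_ec))
    write_tsv(sources$protein_ec, file.path(dir, "protein_ec.tsv"))
  if (!is.null(sources$reactions))
    write_tsv(sources$reactions, file.path(dir, "reactions.tsv"))
  if (!is.null(sources$ppi))
    write_tsv(sources$ppi, file.path(dir, "ppi.tsv"))
  if (length(sources$exchange_metabolites))
    write_tsv(data.frame(accession = sources$exchange_metabolites),
              file.path(dir, "exchange_metabolites.tsv"))
  invisible(dir)
}

#' Read reconstruction sources from fixture files
#'
#' @param dir directory written by [write_source_fixtures()] (or built by
#'   hand in the same layout).
#' @return A sources list consumable by [assemble_network()].
#' @export
read_source_fixtures <- function(dir) {
  reactions <- read_tsv(file.path(dir, "reactions.tsv"))
  if (!is.null(reactions))
    reactions$reversible <- as.logical(reactions$reversible)
  exch <- read_tsv(file.path(dir, "exchange_metabolites.tsv"))
  list(
    genes = read_record_fasta(fasta_path(dir, "genes"), "gene"),
    transcripts = read_record_fasta(fasta_path(dir, "transcripts"),
                                    "transcript"),
    proteins = read_record_fasta(fasta_path(dir, "proteins"), "protein"),
    link_gene_transcript = read_tsv(file.path(dir,
                                              "link_gene_transcript.tsv")),
    link_transcript_protein = read_tsv(file.path(dir,
                                                 "link_transcript_protein.tsv")),
    protein_ec = read_tsv(file.path(dir, "protein_ec.tsv")),
    reactions = reactions,
    ppi = read_tsv(file.path(dir, "ppi.tsv")),
    exchange_metabolites = if (is.null(exch)) character()
    else exch$accession)
}
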