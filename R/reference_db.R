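#' Custom reference-genome database
#'
#' Container for the genomes reads are recruited against: per-genome
#' metadata (species and optional subspecies labels, lengths) plus,
#' optionally, the sequences themselves (required by [toy_align()] but not
#' by the recruitment filters, which work from alignment tables alone).
#'
#' @param genomes data frame with columns `genome_id`, `species`, `length`
#'   and optionally `subspecies` (NA where not applicable).
#' @param sequences optional named character vector or
#'   [Biostrings::DNAStringSet] of genome sequences, names matching
#'   `genome_id`.
#' @return a `reference_db` object: list with `genomes` (data frame) and
#'   `sequences` (`DNAStringSet` or `NULL`).
#' @export
reference_db <- function(genomes, sequences = NULL) {
  stopifnot(is.data.frame(genomes),
            all(c("genome_id", "species", "length") %in% names(genomes)))
  if (!"subspecies" %in% names(genomes)) genomes$subspecies <- NA_character_
  genomes$genome_id <- as.character(genomes$genome_id)
  genomes$species <- as.character(genomes$species)
  if (anyDuplicated(genomes$genome_id)) stop("genome_ids must be unique")
  if (!is.null(sequences)) {
    if (is.character(sequences))
      sequences <- Biostrings::DNAStringSet(sequences)
    if (!all(genomes$genome_id %in% names(sequences)))
      stop("sequences missing for some genome_ids")
    sequences <- sequences[genomes$genome_id]
    if (!all(Biostrings::width(sequences) == genomes$length))
      stop("genome length metadata disagrees with sequence lengths")
  }
  structure(list(genomes = genomes[c("genome_id", "species", "subspecies",
                                     "length")],
                 sequences = sequences),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("Reference DB: %d genomes, %d species, sequences %s\n",
              nrow(x$genomes), length(unique(x$genomes$species)),
              if (is.null(x$sequences)) "absent" else "present"))
  print(x$genomes, ...)
  invisible(x)
}

#' Species -> genome_id index of a reference database
#' @param ref a [reference_db].
#' @return named list mapping each species to its genome ids.
#' @export
species_index <- function(ref) {
  stopifnot(inherits(ref, "reference_db"))
  split(ref$genomes$genome_id, ref$genomes$species)
}

#' Read a reference database from FASTA plus a metadata table
#'
#' @param fasta_path multi-genome FASTA; record ids must match the
#'   metadata `genome_id` column.
#' @param metadata_path TSV with header `genome_id, species, subspecies,
#'   length` (`subspecies`, `length` optional; lengths are taken from the
#'   sequences when absent).
#' @return a [reference_db] with sequences attached.
#' @export
read_reference_db <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs)) # id up to first whitespace
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
  if (!"length" %in% names(meta))
    meta$length <- Biostrings::width(seqs)[match(meta$genome_id, names(seqs))]
  reference_db(meta, seqs)
}

#' Write a reference database to FASTA and metadata TSV
#' @param ref a [reference_db] with sequences.
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, `ref`.
#' @export
write_reference_db <- function(ref, fasta_path, metadata_path) {
  stopifnot(inherits(ref, "reference_db"))
  if (is.null(ref$sequences)) stop("reference_db carries no sequences")
  Biostrings::writeXStringSet(ref$sequences, fasta_path)
  utils::write.table(ref$genomes, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(ref)
}
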