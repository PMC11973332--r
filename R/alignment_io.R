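#' Alignment hit table
#'
#' Canonical in-memory form of read-versus-reference alignments: a data
#' frame with one row per hit and columns `query_id`, `query_length`,
#' `subject_id`, `percent_identity`, `alignment_length`, `query_start`,
#' `query_end`, `subject_start`, `subject_end`, `evalue`, `bitscore`.
#' Coordinates are 1-based inclusive on both query and subject (the blastn
#' convention); reverse-strand hits have `subject_start > subject_end`.
#' `query_length` may be `NA` when the source format does not carry it
#' (12-column blast6); operations that need it error per hit.
#'
#' @param df data frame with (at least) the columns above.
#' @return an `alignment_hits` object (a validated data frame).
#' @export
alignment_hits <- function(df) {
  cols <- c("query_id", "query_length", "subject_id", "percent_identity",
            "alignment_length", "query_start", "query_end",
            "subject_start", "subject_end", "evalue", "bitscore")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing alignment columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[cols]
  df$query_id <- as.character(df$query_id)
  df$subject_id <- as.character(df$subject_id)
  if (nrow(df)) {
    if (any(df$percent_identity < 0 | df$percent_identity > 100))
      stop("percent_identity outside [0, 100]")
    if (any(df$alignment_length < 1)) stop("alignment_length must be >= 1")
    if (any(df$query_start < 1 | df$query_start > df$query_end))
      stop("need 1 <= query_start <= query_end")
    known <- !is.na(df$query_length)
    if (any(df$query_end[known] > df$query_length[known]))
      stop("query_end exceeds query_length")
    if (any(df$bitscore < 0, na.rm = TRUE)) stop("bitscore must be >= 0")
  }
  class(df) <- c("alignment_hits", "data.frame")
  df
}

#' Read an alignment table (blast6 or PAF)
#'
#' Parses tabular alignments into an [alignment_hits] table. blast6 is the
#' 12-column BLAST `-outfmt 6` layout (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), with an
#' optional 13th `qlen` column supplying the query length. PAF rows are
#' converted to 1-based inclusive coordinates; PAF percent identity is
#' residue matches (column 10) over alignment block length (column 11)
#' x 100, and the bitscore is the same monotone match score used by
#' [toy_align()] (PAF carries none of its own).
#'
#' @param path input file.
#' @param dialect `"blast6"` or `"paf"`.
#' @param ref optional [reference_db]; subject ids absent from it are
#'   allowed but counted in the `unknown_subjects` attribute with a
#'   warning.
#' @return [alignment_hits]; an empty file yields an empty table.
#' @export
read_alignment_table <- function(path, dialect = c("blast6", "paf"),
                                 ref = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(alignment_hits(empty_hits_df()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (dialect == "blast6") 12L else 12L
  bad <- which(nf < min_cols)
  if (length(bad))
    stop(sprintf("malformed %s row at line %d of %s (%d fields, need >= %d)",
                 dialect, bad[1L], path, nf[bad[1L]], min_cols))
  num <- function(i) as.numeric(vapply(fields, `[[`, character(1), i))
  chr <- function(i) vapply(fields, `[[`, character(1), i)
  if (dialect == "blast6") {
    has_qlen <- all(nf >= 13L)
    df <- data.frame(
      query_id = chr(1), query_length = if (has_qlen) num(13) else NA_real_,
      subject_id = chr(2), percent_identity = num(3),
      alignment_length = num(4), query_start = num(7), query_end = num(8),
      subject_start = num(9), subject_end = num(10),
      evalue = num(11), bitscore = num(12), stringsAsFactors = FALSE)
  } else {
    nmatch <- num(10); blocklen <- num(11)
    strand <- chr(5)
    if (!all(strand %in% c("+", "-")))
      stop("malformed paf row at line ",
           which(!strand %in% c("+", "-"))[1L], " of ", path,
           " (strand must be + or -)")
    ts <- num(8); te <- num(9) # 0-based half-open target interval
    mm <- blocklen - nmatch
    df <- data.frame(
      query_id = chr(1), query_length = num(2),
      subject_id = chr(6),
      percent_identity = 100 * nmatch / blocklen,
      alignment_length = num(4) - num(3), # overlap on the query
      query_start = num(3) + 1, query_end = num(4),
      subject_start = ifelse(strand == "+", ts + 1, te),
      subject_end = ifelse(strand == "+", te, ts + 1),
      evalue = NA_real_,
      bitscore = pmax(0, 2 * nmatch - 3 * mm), stringsAsFactors = FALSE)
  }
  bad_num <- which(!stats::complete.cases(
    df[c("percent_identity", "alignment_length", "query_start",
         "query_end", "bitscore")]))
  if (length(bad_num))
    stop("malformed ", dialect, " row at line ", bad_num[1L], " of ", path,
         " (non-numeric field)")
  hits <- alignment_hits(df)
  if (!is.null(ref)) {
    unknown <- setdiff(unique(hits$subject_id), ref$genomes$genome_id)
    attr(hits, "unknown_subjects") <- unknown
    if (length(unknown))
      warning(length(unknown), " subject id(s) not in the reference db: ",
              paste(utils::head(unknown, 5), collapse = ", "))
  }
  hits
}

empty_hits_df <- function() {
  data.frame(query_id = character(), query_length = numeric(),
             subject_id = character(), percent_identity = numeric(),
             alignment_length = numeric(), query_start = numeric(),
             query_end = numeric(), subject_start = numeric(),
             subject_end = numeric(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

#' Write alignment hits as 13-column blast6
#'
#' Writes the 12 canonical blast6 columns plus `qlen`, so that
#' `query_length` round-trips. Mismatch and gap counts are not stored in
#' [alignment_hits]; `mismatch` is reconstructed from identity over the
#' alignment length and `gapopen` is written as 0 (the in-package aligner
#' is ungapped).
#'
#' @param hits an [alignment_hits] table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignment_table <- function(hits, path) {
  stopifnot(inherits(hits, "alignment_hits"))
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  rows <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = fmt(hits$percent_identity),
    length = hits$alignment_length,
    mismatch = round(hits$alignment_length *
                       (1 - hits$percent_identity / 100)),
    gapopen = 0L,
    qstart = hits$query_start, qend = hits$query_end,
    sstart = hits$subject_start, send = hits$subject_end,
    evalue = fmt(ifelse(is.na(hits$evalue), 0, hits$evalue)),
    bitscore = fmt(hits$bitscore),
    qlen = ifelse(is.na(hits$query_length), 0, hits$query_length))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimal seed-and-extend aligner for pipeline testing
#'
#' An ungapped seed-and-extend aligner over a k-mer index of the reference
#' genomes, standing in for an external aligner (blastn, minimap2) so that
#' the full recruitment pipeline is exercisable on synthetic data without
#' external software. Both strands are searched; every candidate placement
#' with at least `min_seed_hits` exact k-mer seeds on a common ungapped
#' diagonal is extended across the full read (clipped at genome ends) and
#' reported -- not only the best one, so downstream best-hit selection sees
#' realistic multi-mapping. Percent identity is matches over the extended
#' length x 100 and the bitscore is the deterministic monotone score
#' `max(0, 2 * matches - 3 * mismatches)`.
#'
#' Not a production aligner: no gaps, no E-values (written as `NA`), no
#' seed chaining. Substitution-only divergence (as produced by
#' [make_reference()]) is its valid domain.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet] of
#'   read sequences.
#' @param ref a [reference_db] with sequences.
#' @param k exact seed length, >= 8 (default 15).
#' @param min_seed_hits minimum seeds on a diagonal before extension
#'   (default 2).
#' @return an [alignment_hits] table.
#' @export
toy_align <- function(reads, ref, k = 15L, min_seed_hits = 2L) {
  stopifnot(inherits(ref, "reference_db"))
  if (is.null(ref$sequences))
    stop("toy_align needs reference sequences in the reference_db")
  if (k < 8) stop("seed length k must be >= 8")
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) stop("reads must be named")
  res <- cpp_toy_align(as.character(ref$sequences), ref$genomes$genome_id,
                       unname(reads), names(reads),
                       as.integer(k), as.integer(min_seed_hits))
  res <- as.data.frame(res)
  res$evalue <- rep(NA_real_, nrow(res))
  alignment_hits(res)
}

#' Read a FASTQ or FASTA file as a named character vector of sequences
#' @param path input reads (FASTQ when the extension contains "q").
#' @return named character vector.
#' @export
read_reads <- function(path) {
  fastq <- grepl("f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)
  x <- if (fastq) Biostrings::readDNAStringSet(path, format = "fastq")
       else Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as.character(x)
}

#' Write reads to FASTQ (constant quality) or FASTA
#' @param reads named character vector of sequences.
#' @param path output path; FASTQ when the extension contains "q".
#' @return invisibly, `path`.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  fastq <- grepl("f(ast)?q$", path, ignore.case = TRUE)
  if (fastq) {
    Biostrings::writeXStringSet(x, path, format = "fastq")
  } else {
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}
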