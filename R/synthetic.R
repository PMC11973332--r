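#' Synthetic community simulation configuration
#'
#' Describes the ground-truthed synthetic community the generator emits: a
#' low-diversity, cheese-like community of a few species, one of which is
#' heavily DNA-fragmented (emulating a starter lactococcus whose DNA
#' degrades during ripening), some with near-identical subspecies genomes.
#' Fragment lengths are lognormal per species; a 16S-like target locus of
#' length `target_length` sits at `target_start` on every genome.
#'
#' @param species data frame with one row per species: `species`,
#'   `genome_length` (bp), `abundance` (fractions summing to 1),
#'   `frag_meanlog`, `frag_sdlog` (lognormal fragment-length parameters;
#'   `exp(frag_meanlog)` is the median fragment size in bp),
#'   `n_subspecies`, `subspecies_divergence` (substitution fraction).
#'   The default is a 5-species community of 200 kb genomes at equal
#'   abundance, one species with a 1 kb median fragment size (heavily
#'   fragmented) and 2 subspecies genomes at 1% divergence, the others
#'   intact at 8 kb.
#' @param interspecies_divergence substitution fraction separating species
#'   genomes, in `[0, 0.3]` (default 0.15).
#' @param target_start 1-based start of the amplicon target locus on every
#'   genome (default 1001).
#' @param target_length length of the target locus in bp (default 1500,
#'   the full-length 16S rRNA gene).
#' @param host optional list `(genome_length, abundance)` adding a decoy
#'   host genome contributing `abundance` of all reads (microbial
#'   abundances still sum to 1 among themselves).
#' @param genome_copies total genome copies fragmented across species
#'   (default 300).
#' @param n_short_reads,n_long_reads read depths (defaults 50,000 and
#'   20,000).
#' @param short_read_length maximum merged short-read length, bp (default
#'   500).
#' @param insert_min,insert_max shotgun insert size range, bp (defaults
#'   500-1,500).
#' @param error_rate_short,error_rate_long i.i.d. substitution error rates
#'   (defaults 0.001 and 0.02, post-QC Illumina- and nanopore-like).
#' @param seed integer master seed; all generator randomness derives from
#'   it.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(
    species = default_species_specs(),
    interspecies_divergence = 0.15,
    target_start = 1001, target_length = 1500,
    host = NULL,
    genome_copies = 300,
    n_short_reads = 50000, n_long_reads = 20000,
    short_read_length = 500, insert_min = 500, insert_max = 1500,
    error_rate_short = 0.001, error_rate_long = 0.02,
    seed = 1L) {
  stopifnot(is.data.frame(species),
            all(c("species", "genome_length", "abundance", "frag_meanlog",
                  "frag_sdlog") %in% names(species)))
  if (!"n_subspecies" %in% names(species)) species$n_subspecies <- 1L
  if (!"subspecies_divergence" %in% names(species))
    species$subspecies_divergence <- 0
  if (abs(sum(species$abundance) - 1) > 1e-9)
    stop("species abundances must sum to 1")
  div <- c(interspecies_divergence, species$subspecies_divergence)
  if (any(div < 0 | div > 0.3)) stop("divergences must be in [0, 0.3]")
  if (any(exp(species$frag_meanlog) < 200))
    stop("median fragment size must be >= 200 bp")
  if (target_start < 1) stop("target_start must be >= 1")
  if (!is.null(host))
    stopifnot(is.list(host), host$abundance > 0, host$abundance < 1)
  structure(list(species = species,
                 interspecies_divergence = interspecies_divergence,
                 target_start = as.integer(target_start),
                 target_length = as.integer(target_length),
                 host = host, genome_copies = genome_copies,
                 n_short_reads = n_short_reads, n_long_reads = n_long_reads,
                 short_read_length = as.integer(short_read_length),
                 insert_min = insert_min, insert_max = insert_max,
                 error_rate_short = error_rate_short,
                 error_rate_long = error_rate_long,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default 5-species synthetic community specification
#' @return data frame of per-species simulation parameters (see
#'   [simulation_config()]).
#' @export
default_species_specs <- function() {
  data.frame(
    species = c("starter_A", "starter_B", "nslab_C", "nslab_D", "adjunct_E"),
    genome_length = 200000L,
    abundance = 0.2,
    frag_meanlog = log(c(1000, 8000, 8000, 8000, 8000)),
    frag_sdlog = 0.4,
    n_subspecies = c(2L, 1L, 1L, 1L, 1L),
    subspecies_divergence = c(0.01, 0, 0, 0, 0))
}

random_genome <- function(G) {
  paste(sample(c("A", "C", "G", "T"), G, replace = TRUE), collapse = "")
}

# Substitute round(d * G) distinct positions with a different base.
mutate_genome <- function(seq, d) {
  if (d <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  G <- length(v)
  n_sub <- round(d * G)
  if (n_sub == 0L) return(seq)
  pos <- sample.int(G, n_sub)
  bases <- c("A", "C", "G", "T")
  old <- match(v[pos], bases)
  v[pos] <- bases[(old - 1L + sample.int(3L, n_sub, replace = TRUE)) %% 4L + 1L]
  paste(v, collapse = "")
}

#' Generate a ground-truthed synthetic reference database
#'
#' Builds one ancestral random genome, derives each further species from it
#' at `interspecies_divergence` substitutions, and derives subspecies
#' genomes within a species at `subspecies_divergence`. Substitution-only
#' (no indels), so ungapped alignment is exact on these genomes. All
#' randomness is governed by `cfg$seed`; reruns are byte-identical.
#'
#' @param cfg a [simulation_config].
#' @return list with `ref` (a [reference_db] with sequences), `host` (a
#'   single-genome [reference_db] or `NULL`) and `truth` (a
#'   `synthetic_truth` carrying the config, per-genome target intervals
#'   and per-species fragmentation parameters).
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_private_seed(cfg$seed, {
    sp <- cfg$species
    n_sp <- nrow(sp)
    base <- random_genome(max(sp$genome_length))
    genome_rows <- list(); seqs <- character()
    for (i in seq_len(n_sp)) {
      G <- sp$genome_length[i]
      anc <- substr(base, 1L, G)
      sp_seq <- if (i == 1L) anc
                else mutate_genome(anc, cfg$interspecies_divergence)
      for (j in seq_len(sp$n_subspecies[i])) {
        gid <- sprintf("%s_g%d", sp$species[i], j)
        gseq <- if (j == 1L) sp_seq
                else mutate_genome(sp_seq, sp$subspecies_divergence[i])
        seqs[gid] <- gseq
        genome_rows[[length(genome_rows) + 1L]] <- data.frame(
          genome_id = gid, species = sp$species[i],
          subspecies = if (sp$n_subspecies[i] > 1L) sprintf("ss%d", j)
                       else NA_character_,
          length = G,
          target_start = cfg$target_start,
          target_end = cfg$target_start + cfg$target_length - 1L)
      }
    }
    genomes <- do.call(rbind, genome_rows)
    if (any(genomes$target_end > genomes$length))
      stop("target interval extends past the genome end")
    ref <- reference_db(genomes[c("genome_id", "species", "subspecies",
                                  "length")], seqs)
    host <- NULL
    if (!is.null(cfg$host)) {
      hseq <- random_genome(cfg$host$genome_length)
      host <- reference_db(
        data.frame(genome_id = "host_g1", species = "host",
                   subspecies = NA_character_,
                   length = cfg$host$genome_length),
        c(host_g1 = hseq))
    }
    truth <- structure(
      list(config = cfg, genomes = genomes,
           species = data.frame(species = sp$species,
                                abundance = sp$abundance,
                                frag_meanlog = sp$frag_meanlog,
                                frag_sdlog = sp$frag_sdlog,
                                median_fragment = exp(sp$frag_meanlog)),
           reads = NULL, fragments = NULL),
      class = "synthetic_truth")
    list(ref = ref, host = host, truth = truth)
  })
}

#' Cut genome copies into lognormal fragments
#'
#' Sequential cutting model: fragment lengths are drawn i.i.d. from
#' `lognormal(meanlog, sdlog)` (rounded, minimum 1 bp); the first fragment
#' is truncated by a uniform random phase so the cutting grid is
#' uncorrelated with gene coordinates, and the last fragment is truncated
#' at the genome end. Fragments exactly partition `[1, genome_length]` in
#' every copy, so total bases are conserved. With `sdlog = 0` this reduces
#' to the uniform fragment size `S = exp(meanlog)` idealization of the
#' intactness model.
#'
#' @param genome_length genome length in bp.
#' @param n_copies number of genome copies to cut.
#' @param meanlog,sdlog lognormal parameters of the fragment length.
#' @return data frame with columns `copy_id`, `start`, `end`, `length`,
#'   ordered by copy then position.
#' @export
cut_genome_copies <- function(genome_length, n_copies, meanlog, sdlog) {
  stopifnot(genome_length >= 1, n_copies >= 1)
  G <- genome_length
  draw <- function(n) pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
  l1 <- draw(n_copies)
  cur_end <- pmin(G, ceiling(stats::runif(n_copies) * l1)) # random phase
  chunks <- list(data.frame(copy_id = seq_len(n_copies), start = 1,
                            end = cur_end))
  pos <- cur_end
  active <- which(pos < G)
  while (length(active)) {
    new_end <- pmin(G, pos[active] + draw(length(active)))
    chunks[[length(chunks) + 1L]] <- data.frame(
      copy_id = active, start = pos[active] + 1, end = new_end)
    pos[active] <- new_end
    active <- active[new_end < G]
  }
  out <- do.call(rbind, chunks)
  out <- out[order(out$copy_id, out$start), , drop = FALSE]
  out$length <- out$end - out$start + 1
  rownames(out) <- NULL
  out
}

#' Brute-force intact-target count over explicit fragments
#'
#' Monte-Carlo oracle for [intact_fraction()]: given fragments that
#' partition each genome copy and a target interval (fixed, or one per
#' copy), counts the fraction of copies whose target lies wholly within a
#' single fragment.
#'
#' @param fragments data frame from [cut_genome_copies()] (columns
#'   `copy_id`, `start`, `end`); must exactly partition `[1, G]` per copy.
#' @param target either `c(start, end)` applied to every copy, or a data
#'   frame with columns `copy_id`, `start`, `end`.
#' @return fraction of copies with an intact target.
#' @export
count_intact_targets <- function(fragments, target) {
  stopifnot(is.data.frame(fragments),
            all(c("copy_id", "start", "end") %in% names(fragments)))
  fr <- fragments[order(fragments$copy_id, fragments$start), , drop = FALSE]
  G <- max(fr$end)
  first <- !duplicated(fr$copy_id)
  if (any(fr$start[first] != 1))
    stop("fragments are not a partition: first fragment must start at 1")
  prev_end <- c(0, fr$end[-nrow(fr)])
  if (any(fr$start[!first] != prev_end[!first] + 1))
    stop("fragments are not a partition: gaps or overlaps within a copy")
  last <- !duplicated(fr$copy_id, fromLast = TRUE)
  if (any(fr$end[last] != G))
    stop("fragments are not a partition: copies end at different positions")
  copies <- unique(fr$copy_id)
  if (is.numeric(target) && length(target) == 2L) {
    target <- data.frame(copy_id = copies, start = target[1L],
                         end = target[2L])
  }
  stopifnot(all(c("copy_id", "start", "end") %in% names(target)),
            setequal(target$copy_id, copies))
  if (any(target$start < 1 | target$end > G))
    stop("target interval outside the genome")
  # Offset every copy into its own global coordinate block, then a single
  # findInterval locates the fragment containing each target start.
  copy_index <- match(fr$copy_id, copies)
  glob_start <- (copy_index - 1) * G + fr$start
  t_index <- match(target$copy_id, copies)
  t_glob_start <- (t_index - 1) * G + target$start
  row <- findInterval(t_glob_start, glob_start)
  intact <- fr$end[row] + (copy_index[row] - 1) * G >=
    (t_index - 1) * G + target$end
  mean(intact)
}

#' Fragment genome copies and emit shotgun reads with ground truth
#'
#' Draws genome copies per species in proportion to true abundance (each
#' copy assigned one of the species' subspecies genomes uniformly), cuts
#' every copy into lognormal fragments ([cut_genome_copies()]), and
#' generates two read sets: long reads are the fragments themselves
#' (nanopore-like, optionally subsampled to `n_long_reads` and given
#' i.i.d. substitution errors), and short reads emulate a merged-pair
#' shotgun library -- an insert of `insert_min`-`insert_max` bp is placed
#' uniformly on a fragment chosen with probability proportional to its
#' length (so fragments shorter than the insert floor yield proportionally
#' fewer reads), and the first `short_read_length` bp of the insert, on a
#' random strand, become the read. Every read gets a provenance record.
#'
#' @param ref a [reference_db] from [make_reference()] (with sequences).
#' @param truth the matching `synthetic_truth`.
#' @param host optional host [reference_db] from [make_reference()]; when
#'   the config declares a host, host copies are fragmented and read like
#'   a species.
#' @return list with `short_reads`, `long_reads` (named character
#'   vectors), `fragments` (data frame) and `truth` (updated with
#'   `$reads$short` and `$reads$long` provenance tables).
#' @export
fragment_and_read <- function(ref, truth, host = NULL) {
  stopifnot(inherits(ref, "reference_db"), inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  if (cfg$n_short_reads < 1 && cfg$n_long_reads < 1)
    stop("read depth is zero")
  seqs <- as.character(ref$sequences)
  sp <- cfg$species
  if (!is.null(cfg$host)) {
    if (is.null(host)) stop("config declares a host but none was supplied")
    seqs <- c(seqs, as.character(host$sequences))
    h <- cfg$host$abundance
    sp <- rbind(sp[c("species", "genome_length", "abundance", "frag_meanlog",
                     "frag_sdlog", "n_subspecies", "subspecies_divergence")],
                data.frame(species = "host",
                           genome_length = cfg$host$genome_length,
                           abundance = NA, frag_meanlog = log(8000),
                           frag_sdlog = 0.4, n_subspecies = 1L,
                           subspecies_divergence = 0))
    weights <- c(cfg$species$abundance * (1 - h), h)
  } else {
    weights <- sp$abundance
  }
  gid_by_species <- if (is.null(cfg$host)) species_index(ref) else
    c(species_index(ref), list(host = host$genomes$genome_id))
  with_private_seed(cfg$seed + 1L, {
    frag_list <- list()
    copy_offset <- 0L
    for (i in seq_len(nrow(sp))) {
      n_i <- max(1L, round(cfg$genome_copies * weights[i]))
      fr <- cut_genome_copies(sp$genome_length[i], n_i,
                              sp$frag_meanlog[i], sp$frag_sdlog[i])
      gids <- gid_by_species[[sp$species[i]]]
      genome_of_copy <- sample(gids, n_i, replace = TRUE)
      fr$species <- sp$species[i]
      fr$genome_id <- genome_of_copy[fr$copy_id]
      fr$copy_id <- fr$copy_id + copy_offset
      copy_offset <- copy_offset + n_i
      frag_list[[i]] <- fr
    }
    fragments <- do.call(rbind, frag_list)
    rownames(fragments) <- NULL

    extract <- function(genome_id, start, end) {
      out <- character(length(start))
      for (g in unique(genome_id)) {
        idx <- genome_id == g
        out[idx] <- substring(seqs[[g]], start[idx], end[idx])
      }
      out
    }

    # long reads: fragments as reads
    n_frag <- nrow(fragments)
    take <- if (cfg$n_long_reads >= n_frag) seq_len(n_frag)
            else sort(sample.int(n_frag, cfg$n_long_reads))
    lf <- fragments[take, , drop = FALSE]
    long_seq <- extract(lf$genome_id, lf$start, lf$end)
    long_strand <- sample(c("+", "-"), length(take), replace = TRUE)
    long_seq <- flip_strand(long_seq, long_strand == "-")
    long_seq <- inject_errors(long_seq, cfg$error_rate_long)
    names(long_seq) <- sprintf("L%06d", seq_along(long_seq))
    long_prov <- data.frame(read_id = names(long_seq),
                            species = lf$species, genome_id = lf$genome_id,
                            start = lf$start, end = lf$end,
                            fragment_length = lf$length,
                            read_length = lf$length, strand = long_strand)

    # short reads: insert placed on a length-weighted fragment
    n_s <- cfg$n_short_reads
    short_seq <- character(0); short_prov <- NULL
    if (n_s >= 1) {
      idx <- sample.int(n_frag, n_s, replace = TRUE, prob = fragments$length)
      flen <- fragments$length[idx]
      insert <- pmin(round(stats::runif(n_s, cfg$insert_min, cfg$insert_max)),
                     flen)
      off <- floor(stats::runif(n_s) * (flen - insert + 1))
      ins_start <- fragments$start[idx] + off
      rl <- pmin(cfg$short_read_length, insert)
      strand <- sample(c("+", "-"), n_s, replace = TRUE)
      s <- ifelse(strand == "+", ins_start, ins_start + insert - rl)
      e <- s + rl - 1
      short_seq <- extract(fragments$genome_id[idx], s, e)
      short_seq <- flip_strand(short_seq, strand == "-")
      short_seq <- inject_errors(short_seq, cfg$error_rate_short)
      names(short_seq) <- sprintf("S%06d", seq_len(n_s))
      short_prov <- data.frame(read_id = names(short_seq),
                               species = fragments$species[idx],
                               genome_id = fragments$genome_id[idx],
                               start = s, end = e,
                               fragment_length = flen,
                               read_length = rl, strand = strand)
    }
    truth$fragments <- fragments
    truth$reads <- list(short = short_prov, long = long_prov)
    list(short_reads = short_seq, long_reads = long_seq,
         fragments = fragments, truth = truth)
  })
}

# Reverse-complement the sequences where flip is TRUE.
flip_strand <- function(seqs, flip) {
  if (!any(flip)) return(seqs)
  seqs[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[flip])))
  seqs
}

# i.i.d. substitution errors at the given per-base rate.
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    v <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(v), min(n_err[i], length(v)))
    old <- match(v[pos], bases)
    v[pos] <- bases[(old - 1L + sample.int(3L, length(pos), TRUE)) %% 4L + 1L]
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

#' Simulate amplicon counts under the fragmentation model
#'
#' For each simulated genome copy, the length-`L` target at the genome's
#' target locus is amplifiable iff no cut falls strictly inside it. Cuts
#' follow the same sequential lognormal model as [cut_genome_copies()]
#' (uniform random phase, i.i.d. lengths); only cut positions up to the
#' target end are simulated, which is distributionally identical to
#' cutting the whole genome. Counts are optionally weighted by 16S copy
#' number and converted to relative abundances.
#'
#' @param truth a `synthetic_truth` from [make_reference()].
#' @param L amplicon target length in bp (overrides the configured target
#'   length, e.g. 300 for V4 versus 1500 for full-length).
#' @param copies total genome copies simulated across species (default
#'   100,000), allocated by true abundance.
#' @param use_copy_number weight counts by per-species 16S copy number?
#' @param copy_numbers named integer vector, species -> copy number
#'   (default 1 for all).
#' @return list with `table` (an [abundance_table], mode `"amplicon"`),
#'   `counts` (intact targets per species) and `n_copies` (copies
#'   simulated per species).
#' @export
simulate_amplicon_counts <- function(truth, L, copies = 1e5,
                                     use_copy_number = FALSE,
                                     copy_numbers = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  sp <- cfg$species
  a <- cfg$target_start
  b <- a + L - 1
  if (any(b > sp$genome_length))
    stop("target of length ", L, " extends past a genome end")
  if (is.null(copy_numbers))
    copy_numbers <- setNames(rep(1, nrow(sp)), sp$species)
  counts <- n_copies <- setNames(numeric(nrow(sp)), sp$species)
  with_private_seed(cfg$seed + 2L, {
    for (i in seq_len(nrow(sp))) {
      n <- max(1L, round(copies * sp$abundance[i]))
      n_copies[sp$species[i]] <- n
      mu <- sp$frag_meanlog[i]; sdl <- sp$frag_sdlog[i]
      draw <- function(m) pmax(1, round(stats::rlnorm(m, mu, sdl)))
      l1 <- draw(n)
      cur <- ceiling(stats::runif(n) * l1) # random-phase first cut
      broken <- cur >= a & cur <= b - 1
      repeat {
        idx <- which(!broken & cur < b - 1)
        if (length(idx) == 0L) break
        cur[idx] <- cur[idx] + draw(length(idx))
        broken[idx] <- cur[idx] >= a & cur[idx] <= b - 1
      }
      counts[sp$species[i]] <- sum(!broken)
    }
  })
  w <- counts
  if (use_copy_number) {
    missing <- setdiff(sp$species, names(copy_numbers))
    if (length(missing)) stop("copy_numbers missing for: ",
                              paste(missing, collapse = ", "))
    w <- w * copy_numbers[sp$species]
  }
  if (sum(w) == 0) stop("no intact targets in any species (all S < L?)")
  list(table = abundance_table(w / sum(w), "simulated", "amplicon"),
       counts = counts, n_copies = n_copies)
}

#' Perfect alignment hits from simulation ground truth
#'
#' Converts per-read provenance into the alignment table a perfect aligner
#' would emit (one hit per read, 100% identity to the true source
#' coordinates). Useful for exercising the recruitment and abundance
#' machinery without running an aligner, and as a truth baseline to
#' compare [toy_align()] output against.
#'
#' @param truth a `synthetic_truth` after [fragment_and_read()].
#' @param which `"short"` or `"long"`.
#' @return an [alignment_hits] table.
#' @export
truth_alignment_hits <- function(truth, which = c("short", "long")) {
  which <- match.arg(which)
  prov <- truth$reads[[which]]
  if (is.null(prov)) stop("no ", which, "-read provenance in truth")
  rev <- prov$strand == "-"
  alignment_hits(data.frame(
    query_id = prov$read_id, query_length = prov$read_length,
    subject_id = prov$genome_id, percent_identity = 100,
    alignment_length = prov$read_length,
    query_start = 1, query_end = prov$read_length,
    subject_start = ifelse(rev, prov$end, prov$start),
    subject_end = ifelse(rev, prov$start, prov$end),
    evalue = NA_real_, bitscore = 2 * prov$read_length))
}
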