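#' Recruitment filtering configuration
#'
#' Holds every decision threshold of the recruitment-plotting pipeline.
#' Defaults encode the published procedure: short reads are dropped below
#' 60% identity or 50 bp overlap; long reads below 70% identity or 500 bp
#' length; host reads are removed when both identity and query coverage
#' exceed 60% (strictly); a species needs more than 300 recruited reads
#' (strictly) and well-spread coverage to be retained. "Well-spread" is
#' automated as breadth of coverage over `spread_bins` equal genome bins
#' reaching `spread_min_breadth` (the published criterion was a visual
#' check of the recruitment plots).
#'
#' @param min_identity_short,min_overlap_short short-read filters
#'   (percent, bp).
#' @param min_identity_long,min_read_length_long long-read filters
#'   (percent, bp).
#' @param host_min_identity,host_min_qcov host-removal thresholds
#'   (percent; strict "greater than").
#' @param min_reads_retain retention read-count threshold (strict
#'   "more than").
#' @param spread_bins number of equal genome bins for breadth (>= 10).
#' @param spread_min_breadth minimum fraction of bins with coverage.
#' @param tie_seed integer seed driving reproducible best-hit
#'   tie-breaking.
#' @return a `filter_config` object.
#' @export
filter_config <- function(min_identity_short = 60, min_overlap_short = 50,
                          min_identity_long = 70, min_read_length_long = 500,
                          host_min_identity = 60, host_min_qcov = 60,
                          min_reads_retain = 300, spread_bins = 100,
                          spread_min_breadth = 0.5, tie_seed = 1L) {
  pct <- c(min_identity_short, min_identity_long, host_min_identity,
           host_min_qcov)
  if (any(pct < 0 | pct > 100)) stop("percentages must be in [0, 100]")
  if (spread_bins < 10) stop("spread_bins must be >= 10")
  if (spread_min_breadth < 0 || spread_min_breadth > 1)
    stop("spread_min_breadth must be in [0, 1]")
  structure(list(min_identity_short = min_identity_short,
                 min_overlap_short = min_overlap_short,
                 min_identity_long = min_identity_long,
                 min_read_length_long = min_read_length_long,
                 host_min_identity = host_min_identity,
                 host_min_qcov = host_min_qcov,
                 min_reads_retain = min_reads_retain,
                 spread_bins = as.integer(spread_bins),
                 spread_min_breadth = spread_min_breadth,
                 tie_seed = as.integer(tie_seed)),
            class = "filter_config")
}

#' Identify host-derived reads for removal
#'
#' Flags reads whose alignment against the host genome has both sequence
#' identity and query coverage strictly greater than the configured
#' thresholds (default 60/60); such reads are assumed host-derived, not
#' microbial. Query coverage is `alignment_length / query_length * 100`.
#'
#' @param hits [alignment_hits] of the read set versus the host genome.
#' @param cfg a [filter_config].
#' @return character vector of read ids to exclude.
#' @export
remove_host_hits <- function(hits, cfg = filter_config()) {
  stopifnot(inherits(hits, "alignment_hits"))
  if (nrow(hits) == 0L) return(character())
  if (anyNA(hits$query_length))
    stop("query_length required on every host hit to compute query coverage")
  qcov <- hits$alignment_length / hits$query_length * 100
  hostlike <- hits$percent_identity > cfg$host_min_identity &
    qcov > cfg$host_min_qcov
  unique(hits$query_id[hostlike])
}

#' Identity/overlap quality filter
#'
#' Applies the platform-specific quality filter to an alignment table.
#' Short reads are kept iff identity >= 60% and alignment overlap >= 50 bp;
#' long reads iff identity >= 70% and read length >= 500 bp (defaults from
#' `cfg`). Thresholds are exclusive on the removal side ("lower than" /
#' "shorter than"), so values exactly at a threshold are kept. Row order is
#' preserved and the filter is idempotent.
#'
#' @param hits [alignment_hits].
#' @param platform `"short"` or `"long"`.
#' @param cfg a [filter_config].
#' @return the filtered [alignment_hits].
#' @export
filter_hits <- function(hits, platform = c("short", "long"),
                        cfg = filter_config()) {
  platform <- match.arg(platform)
  stopifnot(inherits(hits, "alignment_hits"))
  if (nrow(hits) == 0L) return(hits)
  keep <- if (platform == "short") {
    hits$percent_identity >= cfg$min_identity_short &
      hits$alignment_length >= cfg$min_overlap_short
  } else {
    if (anyNA(hits$query_length))
      stop("long-read filtering needs query_length on every hit")
    hits$percent_identity >= cfg$min_identity_long &
      hits$query_length >= cfg$min_read_length_long
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-hit selection with reproducible random tie-breaking
#'
#' Keeps, per read, only the hit with the highest bitscore. When several
#' hits share the exact highest bitscore, one is chosen uniformly at
#' random from a generator seeded by `(tie_seed, query_id)`, making the
#' choice reproducible and independent of row order.
#'
#' @param hits filtered [alignment_hits].
#' @param cfg a [filter_config] (supplies `tie_seed`).
#' @return [alignment_hits] with exactly one row per query id.
#' @export
select_best_hits <- function(hits, cfg = filter_config()) {
  stopifnot(inherits(hits, "alignment_hits"))
  if (nrow(hits) == 0L) return(hits)
  best <- tapply(hits$bitscore, hits$query_id, max)
  is_best <- hits$bitscore == best[hits$query_id]
  cand <- hits[is_best, , drop = FALSE]
  n_per_query <- table(cand$query_id)
  tied <- names(n_per_query)[n_per_query > 1L]
  pick <- !duplicated(cand$query_id) # placeholder for untied queries
  if (length(tied)) {
    rows_by_query <- split(seq_len(nrow(cand)), cand$query_id)
    with_private_seed(cfg$tie_seed, {
      for (q in tied) {
        rows <- rows_by_query[[q]]
        # canonical candidate order, so the draw is row-order independent
        rows <- rows[order(cand$subject_id[rows], cand$subject_start[rows],
                           cand$subject_end[rows], cand$query_start[rows])]
        # per-query stream: reproducible under tie_seed
        set.seed((cfg$tie_seed * 48271 + str_hash31(q)) %% 2147483647)
        pick[rows] <- FALSE
        pick[rows[sample.int(length(rows), 1L)]] <- TRUE
      }
    })
  }
  out <- cand[pick, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-genome recruitment profiles
#'
#' Groups best hits by subject genome and summarizes each genome's
#' recruitment: read count, base count (sum of full read lengths) and a
#' per-bin read-count vector over `spread_bins` equal genome bins (each
#' hit is assigned to the bin containing the midpoint of its subject
#' interval). Hits whose subject id is not in the reference database are
#' dropped and counted in the `dropped_unknown` attribute.
#'
#' @param best_hits [alignment_hits], one row per read (see
#'   [select_best_hits()]).
#' @param ref a [reference_db].
#' @param cfg a [filter_config].
#' @return a `recruitment_profiles` object: named list of
#'   `recruitment_profile`s, one per reference genome (genomes without
#'   hits get empty profiles).
#' @export
build_profiles <- function(best_hits, ref, cfg = filter_config()) {
  stopifnot(inherits(best_hits, "alignment_hits"),
            inherits(ref, "reference_db"))
  known <- best_hits$subject_id %in% ref$genomes$genome_id
  dropped <- sum(!known)
  if (dropped > 0)
    message(dropped, " hit(s) dropped: subject not in reference db")
  hits <- best_hits[known, , drop = FALSE]
  profiles <- vector("list", nrow(ref$genomes))
  names(profiles) <- ref$genomes$genome_id
  by_subject <- split(seq_len(nrow(hits)), hits$subject_id)
  for (g in seq_len(nrow(ref$genomes))) {
    gid <- ref$genomes$genome_id[g]
    glen <- ref$genomes$length[g]
    rows <- by_subject[[gid]]
    h <- hits[rows %||% integer(), , drop = FALSE]
    rownames(h) <- NULL
    binw <- glen / cfg$spread_bins
    bins <- integer(cfg$spread_bins)
    if (nrow(h)) {
      mid <- (pmin(h$subject_start, h$subject_end) +
                pmax(h$subject_start, h$subject_end)) / 2
      b <- pmin(cfg$spread_bins, pmax(1L, ceiling(mid / binw)))
      tab <- tabulate(b, nbins = cfg$spread_bins)
      bins <- tab
    }
    profiles[[g]] <- structure(
      list(genome_id = gid, species = ref$genomes$species[g],
           hits = h, read_count = nrow(h),
           base_count = if (nrow(h)) sum(h$query_length) else 0,
           bin_coverage = bins, retained = NA),
      class = "recruitment_profile")
  }
  structure(profiles, dropped_unknown = dropped,
            class = "recruitment_profiles")
}

#' @export
print.recruitment_profile <- function(x, ...) {
  cat(sprintf(
    "Recruitment profile %s (%s): %d reads, %s bases, breadth %.2f\n",
    x$genome_id, x$species, x$read_count,
    format(x$base_count, big.mark = ","),
    mean(x$bin_coverage > 0)))
  invisible(x)
}

#' Species retention by read count and breadth of coverage
#'
#' A species is retained iff the reads recruited by all its genomes pooled
#' exceed `min_reads_retain` (strictly more than 300 by default) and the
#' breadth of coverage of its best-recruiting genome (fraction of genome
#' bins with at least one read) reaches `spread_min_breadth`. Pooling
#' read counts across same-species (subspecies) genomes avoids rejecting a
#' species whose reads are split among near-identical genomes, while
#' breadth on the best single genome keeps the well-spread criterion
#' meaningful.
#'
#' @param profiles [recruitment profiles][build_profiles].
#' @param cfg a [filter_config].
#' @return data frame with one row per species: `reads`, `breadth`,
#'   `best_genome`, `retained`, `reason` (`"ok"`, `"too_few_reads"` or
#'   `"poor_spread"`).
#' @export
retain_species <- function(profiles, cfg = filter_config()) {
  stopifnot(inherits(profiles, "recruitment_profiles"))
  species <- unique(vapply(profiles, `[[`, character(1), "species"))
  rows <- lapply(species, function(sp) {
    ps <- profiles[vapply(profiles, function(p) p$species == sp, logical(1))]
    reads <- sum(vapply(ps, `[[`, numeric(1), "read_count"))
    best <- ps[[which.max(vapply(ps, `[[`, numeric(1), "read_count"))]]
    breadth <- mean(best$bin_coverage > 0)
    enough <- reads > cfg$min_reads_retain
    spread <- breadth >= cfg$spread_min_breadth
    reason <- if (!enough) "too_few_reads"
              else if (!spread) "poor_spread" else "ok"
    data.frame(species = sp, reads = reads, breadth = breadth,
               best_genome = best$genome_id,
               retained = enough && spread, reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Retained species names from a retention report
#' @param verdicts output of [retain_species()].
#' @return character vector of retained species.
#' @export
retained_species <- function(verdicts) verdicts$species[verdicts$retained]

#' Coverage-gap fingerprint of a recruitment profile
#'
#' Reports the genome bins with zero recruited reads. Gaps recurring at
#' the same genomic location across samples fingerprint strain-level
#' deviation from the reference genome; gap calls are refused on
#' under-recruited profiles, where empty bins reflect depth rather than
#' absence.
#'
#' @param profile a single recruitment profile.
#' @param cfg a [filter_config]; profiles with fewer than
#'   `min_reads_retain` reads error.
#' @return a `gap_profile`: list with `genome_id`, `gap_bins` (integer bin
#'   indices) and `n_bins`.
#' @export
detect_coverage_gaps <- function(profile, cfg = filter_config()) {
  stopifnot(inherits(profile, "recruitment_profile"))
  if (profile$read_count < cfg$min_reads_retain)
    stop("insufficient depth for gap calls: ", profile$read_count,
         " reads < ", cfg$min_reads_retain)
  structure(list(genome_id = profile$genome_id,
                 gap_bins = which(profile$bin_coverage == 0),
                 n_bins = length(profile$bin_coverage)),
            class = "gap_profile")
}

#' Jaccard concordance of two gap fingerprints
#'
#' Jaccard index of the zero-coverage bin sets of the same genome in two
#' samples: 1 means gaps at identical locations (consistent strain-level
#' signal), 0 means disjoint gaps. Two gap-free profiles are fully
#' concordant (1).
#'
#' @param a,b `gap_profile`s for the same genome and binning.
#' @return Jaccard index in `[0, 1]`.
#' @export
gap_concordance <- function(a, b) {
  stopifnot(inherits(a, "gap_profile"), inherits(b, "gap_profile"))
  if (a$genome_id != b$genome_id) stop("gap profiles are for different genomes")
  if (a$n_bins != b$n_bins) stop("gap profiles use different binnings")
  u <- union(a$gap_bins, b$gap_bins)
  if (length(u) == 0L) return(1)
  length(intersect(a$gap_bins, b$gap_bins)) / length(u)
}

#' Read-recruitment ratios between same-species genomes
#'
#' For every species represented by several genomes (typically subspecies)
#' computes, per sample, the ratio of reads recruited by each ordered
#' genome pair, then the mean and standard deviation of each ratio across
#' samples. Ratios with a zero denominator are reported as undefined and
#' excluded from the summary.
#'
#' @param profiles_by_sample a named list of
#'   [recruitment profiles][build_profiles] (one per sample), or a single
#'   `recruitment_profiles` object.
#' @param ref a [reference_db].
#' @return list with `ratios` (long data frame: sample, species, genome
#'   pair, counts, ratio, defined flag) and `summary` (per pair:
#'   `mean_ratio`, `sd_ratio`, `n_defined`). Species with a single genome
#'   are skipped.
#' @export
subspecies_ratios <- function(profiles_by_sample, ref) {
  if (inherits(profiles_by_sample, "recruitment_profiles"))
    profiles_by_sample <- list(sample = profiles_by_sample)
  if (is.null(names(profiles_by_sample)))
    names(profiles_by_sample) <- paste0("sample", seq_along(profiles_by_sample))
  idx <- species_index(ref)
  multi <- idx[lengths(idx) >= 2L]
  if (length(multi) == 0L)
    return(list(ratios = NULL, summary = NULL))
  rows <- list()
  for (sid in names(profiles_by_sample)) {
    profs <- profiles_by_sample[[sid]]
    for (sp in names(multi)) {
      gids <- multi[[sp]]
      counts <- vapply(gids, function(g) profs[[g]]$read_count, numeric(1))
      for (i in seq_along(gids)) for (j in seq_along(gids)) {
        if (i == j) next
        defined <- counts[j] > 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, species = sp,
          genome_a = gids[i], genome_b = gids[j],
          reads_a = counts[i], reads_b = counts[j],
          ratio = if (defined) counts[i] / counts[j] else NA_real_,
          defined = defined)
      }
    }
  }
  ratios <- do.call(rbind, rows)
  agg <- split(ratios, paste(ratios$species, ratios$genome_a, ratios$genome_b))
  summary <- do.call(rbind, lapply(agg, function(d) {
    ok <- d$ratio[d$defined]
    data.frame(species = d$species[1L], genome_a = d$genome_a[1L],
               genome_b = d$genome_b[1L],
               mean_ratio = if (length(ok)) mean(ok) else NA_real_,
               sd_ratio = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
               n_samples = nrow(d), n_defined = length(ok))
  }))
  rownames(summary) <- NULL
  list(ratios = ratios, summary = summary)
}

#' Select genera for the custom reference database
#'
#' Keeps the genera with strictly more than `cutoff` (default 0.1%) of all
#' reads assigned to them by an upstream genus-level classification; the
#' custom recruitment database is then built from the type-strain genomes
#' of all species of those genera.
#'
#' @param genus_table data frame with columns `genus` and `fraction`
#'   (assigned-read fractions, summing to at most 1), or a named numeric
#'   vector.
#' @param cutoff retention cutoff as a fraction (default 0.001).
#' @return character vector of genus names.
#' @export
select_reference_genera <- function(genus_table, cutoff = 0.001) {
  if (is.numeric(genus_table) && !is.null(names(genus_table)))
    genus_table <- data.frame(genus = names(genus_table),
                              fraction = as.numeric(genus_table))
  stopifnot(is.data.frame(genus_table),
            all(c("genus", "fraction") %in% names(genus_table)))
  if (nrow(genus_table) == 0L) return(character())
  if (any(genus_table$fraction < 0)) stop("negative genus fraction")
  if (sum(genus_table$fraction) > 1 + 1e-9)
    stop("genus fractions sum to more than 1")
  genus_table$genus[genus_table$fraction > cutoff]
}
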