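#' Relative abundance table
#'
#' A named vector of per-species relative abundance fractions summing to 1,
#' tagged with the sample it describes and the estimation mode:
#' `"read_count"` (one count per recruited short read), `"base_weighted"`
#' (summed base pairs of recruited long reads) or `"amplicon"` (amplicon
#' counts, simulated or predicted).
#'
#' @param fractions named numeric vector, species -> fraction; must be
#'   non-negative and sum to 1 within 1e-9.
#' @param sample_id sample identifier.
#' @param mode one of `"read_count"`, `"base_weighted"`, `"amplicon"`.
#' @param min_read_length minimum read length applied (bp); 0 for
#'   read-count mode.
#' @param minorities_cutoff optional pooling cutoff recorded by
#'   [group_minorities()].
#' @return an `abundance_table` object.
#' @export
abundance_table <- function(fractions, sample_id, mode,
                            min_read_length = 0L,
                            minorities_cutoff = NULL) {
  mode <- match.arg(mode, c("read_count", "base_weighted", "amplicon"))
  stopifnot(is.numeric(fractions), !is.null(names(fractions)),
            !anyNA(fractions))
  if (any(fractions < 0)) stop("abundance fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("abundance fractions must sum to 1 (got ", sum(fractions), ")")
  structure(fractions,
            sample_id = as.character(sample_id), mode = mode,
            min_read_length = as.integer(min_read_length),
            minorities_cutoff = minorities_cutoff,
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: sample %s, mode %s",
              attr(x, "sample_id"), attr(x, "mode")))
  if (attr(x, "mode") == "base_weighted")
    cat(sprintf(", min read length %d bp", attr(x, "min_read_length")))
  cat("\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @method as.data.frame abundance_table
#' @export
as.data.frame.abundance_table <- function(x, ...) {
  data.frame(sample_id = attr(x, "sample_id"),
             species = names(x),
             mode = attr(x, "mode"),
             min_read_length = attr(x, "min_read_length"),
             fraction = as.numeric(x),
             percent = 100 * as.numeric(x),
             row.names = NULL)
}

#' Read-count relative abundances for short-read recruitment
#'
#' Counts recruited reads (one per read, after best-hit selection) per
#' retained species, pooling same-species genomes, and expresses them as
#' fractions of all reads recruited by retained species.
#'
#' @param profiles [recruitment profiles][build_profiles].
#' @param retained character vector of retained species (see
#'   [retain_species()]).
#' @param sample_id sample label stored in the table.
#' @return an [abundance_table] with `mode = "read_count"`.
#' @export
abundance_short <- function(profiles, retained, sample_id = "sample") {
  counts <- species_totals(profiles, retained, what = "reads")
  if (sum(counts) == 0) stop("no reads recruited by any retained species")
  abundance_table(counts / sum(counts), sample_id, "read_count")
}

#' Base-weighted relative abundances for long-read recruitment
#'
#' Sums the full lengths of recruited reads (not just their aligned spans)
#' per retained species, keeping only reads at least `min_read_length` bp
#' long, and normalizes across retained species. Base-weighting corrects
#' for the highly variable read lengths of long-read platforms, which make
#' plain read counts unreliable.
#'
#' @inheritParams abundance_short
#' @param min_read_length minimum read length in bp (default 500, the base
#'   long-read length filter).
#' @return an [abundance_table] with `mode = "base_weighted"`.
#' @export
abundance_long <- function(profiles, retained, min_read_length = 500,
                           sample_id = "sample") {
  bases <- species_totals(profiles, retained, what = "bases",
                          min_read_length = min_read_length)
  if (sum(bases) == 0)
    stop("all recruited reads are shorter than min_read_length = ",
         min_read_length, " bp")
  abundance_table(bases / sum(bases), sample_id, "base_weighted",
                  min_read_length = min_read_length)
}

# Internal: pooled per-species read or base totals over retained species.
species_totals <- function(profiles, retained, what = c("reads", "bases"),
                           min_read_length = 0) {
  what <- match.arg(what)
  stopifnot(inherits(profiles, "recruitment_profiles"))
  retained <- as.character(retained)
  if (length(retained) == 0L) stop("no retained species")
  totals <- setNames(numeric(length(retained)), retained)
  for (p in profiles) {
    if (!p$species %in% retained) next
    if (what == "reads") {
      totals[p$species] <- totals[p$species] + p$read_count
    } else {
      ql <- p$hits$query_length
      if (p$read_count > 0 && anyNA(ql))
        stop("base-weighted abundance needs query_length on every hit ",
             "(genome ", p$genome_id, ")")
      totals[p$species] <- totals[p$species] + sum(ql[ql >= min_read_length])
    }
  }
  totals
}

#' Minimum read-length threshold sweep for base-weighted abundances
#'
#' Recomputes base-weighted abundances while raising the minimum length of
#' the long reads considered, tracing how relative abundances shift as the
#' analysis is restricted to longer DNA fragments. A species whose reads
#' all fall below a threshold stays in the table with fraction 0.
#'
#' @inheritParams abundance_short
#' @param thresholds increasing vector of minimum read lengths in bp;
#'   default 500 (the base filter) then 1,000-10,000 by 1,000.
#' @return a `sweep_result`: list with `thresholds`, `tables` (one
#'   [abundance_table] per threshold) and `retained_bp_fraction`, the
#'   fraction of total base pairs kept at each threshold relative to the
#'   first (base) threshold.
#' @export
length_sweep <- function(profiles, retained,
                         thresholds = c(500, seq(1000, 10000, by = 1000)),
                         sample_id = "sample") {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  base_totals <- NULL
  tables <- vector("list", length(thresholds))
  bp <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    totals <- species_totals(profiles, retained, "bases", thresholds[i])
    if (i == 1L) base_totals <- totals
    if (sum(totals) == 0)
      stop("all recruited reads are shorter than min_read_length = ",
           thresholds[i], " bp")
    tables[[i]] <- abundance_table(totals / sum(totals), sample_id,
                                   "base_weighted",
                                   min_read_length = thresholds[i])
    bp[i] <- sum(totals)
  }
  structure(list(thresholds = thresholds, tables = tables,
                 retained_bp_fraction = bp / bp[1L]),
            class = "sweep_result")
}

#' Recruited read-length distribution for one genome
#'
#' Kernel density estimate of the lengths of reads recruited by a genome,
#' with summary statistics (median and N50). Species-specific differences
#' in these distributions are the signature of species-specific DNA
#' fragmentation.
#'
#' @param profile a single recruitment profile.
#' @param bw kernel bandwidth passed to [stats::density()]; default
#'   `"nrd0"`.
#' @param n number of evaluation points.
#' @return list with `x`, `y` (density, integrating to 1), `median`, `n50`
#'   and `n_reads`.
#' @export
read_length_distribution <- function(profile, bw = "nrd0", n = 512) {
  stopifnot(inherits(profile, "recruitment_profile"))
  len <- profile$hits$query_length
  if (anyNA(len)) stop("query_length missing on some hits")
  if (length(len) < 30)
    stop("need at least 30 recruited reads for a density estimate (got ",
         length(len), ")")
  if (stats::sd(len) == 0) {
    # degenerate case: all reads the same length -> point mass
    d <- list(x = len[1L], y = 1)
  } else {
    d <- stats::density(len, bw = bw, n = n)
  }
  structure(list(x = d$x, y = d$y, median = stats::median(len),
                 n50 = n50(len), n_reads = length(len),
                 genome_id = profile$genome_id, species = profile$species),
            class = "read_length_density")
}

#' N50 of a set of read or fragment lengths
#'
#' The largest length `x` such that reads of length `>= x` contain at least
#' half of all bases.
#'
#' @param lengths numeric vector of lengths in bp.
#' @return the N50 in bp.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Sweep threshold bringing abundances closest to a reference table
#'
#' Finds the minimum-read-length threshold whose base-weighted abundance
#' table is closest (in L1 distance over the union of species, missing
#' species counted as 0) to a reference table, typically amplicon-derived.
#' Ties are broken towards the smallest threshold.
#'
#' @param sweep a `sweep_result` from [length_sweep()].
#' @param reference an [abundance_table] to compare against.
#' @return list with `threshold` (bp) and `distances`, the named
#'   L1-distance profile over all thresholds.
#' @export
closest_threshold <- function(sweep, reference) {
  stopifnot(inherits(sweep, "sweep_result"),
            inherits(reference, "abundance_table"))
  sp_sweep <- names(sweep$tables[[1L]])
  if (length(intersect(sp_sweep, names(reference))) == 0L)
    stop("sweep and reference tables share no species")
  species <- union(sp_sweep, names(reference))
  q <- setNames(numeric(length(species)), species)
  q[names(reference)] <- as.numeric(reference)
  dist <- vapply(sweep$tables, function(tab) {
    p <- setNames(numeric(length(species)), species)
    p[names(tab)] <- as.numeric(tab)
    sum(abs(p - q))
  }, numeric(1))
  names(dist) <- sweep$thresholds
  list(threshold = sweep$thresholds[which.min(dist)], distances = dist)
}

#' Pool minority species into a single category
#'
#' Pools species whose abundance is below `cutoff` in *all* supplied tables
#' into a `"Minorities"` entry, preserving column sums. Used to declutter
#' comparative abundance displays (typical cutoffs: 0.004 or 0.01).
#'
#' @param tables a single [abundance_table] or a list of them compared side
#'   by side.
#' @param cutoff pooling cutoff as a fraction, in (0, 0.5).
#' @param label name of the pooled category.
#' @return the same shape as `tables`, with sub-cutoff species pooled.
#' @export
group_minorities <- function(tables, cutoff, label = "Minorities") {
  if (!(cutoff > 0 && cutoff < 0.5)) stop("cutoff must be in (0, 0.5)")
  single <- inherits(tables, "abundance_table")
  if (single) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, logical(1), "abundance_table")))
  species <- unique(unlist(lapply(tables, names)))
  below_all <- vapply(species, function(s) {
    all(vapply(tables, function(tab)
      (if (s %in% names(tab)) tab[[s]] else 0) < cutoff, logical(1)))
  }, logical(1))
  pooled <- species[below_all]
  out <- lapply(tables, function(tab) {
    keep <- setdiff(names(tab), pooled)
    fr <- as.numeric(tab)[match(keep, names(tab))]
    names(fr) <- keep
    pool_mass <- sum(as.numeric(tab)[names(tab) %in% pooled])
    if (length(pooled) > 0L) fr[label] <- pool_mass
    abundance_table(fr, attr(tab, "sample_id"), attr(tab, "mode"),
                    attr(tab, "min_read_length"), minorities_cutoff = cutoff)
  })
  if (single) out[[1L]] else out
}

#' Paired per-species comparison of two abundance estimation methods
#'
#' For each species, runs a paired t-test of its relative abundance across
#' samples between two methods (for example short-read recruitment versus
#' full-length 16S amplicon sequencing), and optionally a Spearman rank
#' correlation of its method-A abundance against a per-sample covariate
#' (for example ripening time). No multiple-testing correction is applied;
#' the significance flag is the raw p < 0.05.
#'
#' @param tables_a,tables_b lists of [abundance_table]s, named or tagged by
#'   sample id; every sample must appear in both.
#' @param covariate optional numeric vector, one value per sample of
#'   `tables_a`, for the rank correlation.
#' @return data frame with one row per species: `mean_diff` (A minus B),
#'   `t`, `p`, `significant`, and when a covariate is given `rho`, `rho_p`.
#' @export
method_comparison_stats <- function(tables_a, tables_b, covariate = NULL) {
  ids_a <- vapply(tables_a, attr, character(1), "sample_id")
  ids_b <- vapply(tables_b, attr, character(1), "sample_id")
  if (anyDuplicated(ids_a) || anyDuplicated(ids_b))
    stop("duplicate sample ids within a method")
  if (!setequal(ids_a, ids_b))
    stop("samples are not paired: ids differ between methods")
  if (length(ids_a) < 3) stop("need at least 3 paired samples")
  tables_b <- tables_b[match(ids_a, ids_b)]
  if (!is.null(covariate) && length(covariate) != length(ids_a))
    stop("covariate must have one value per sample")
  species <- sort(unique(unlist(c(lapply(tables_a, names),
                                  lapply(tables_b, names)))))
  get_frac <- function(tabs, s)
    vapply(tabs, function(tab) if (s %in% names(tab)) tab[[s]] else 0,
           numeric(1))
  rows <- lapply(species, function(s) {
    a <- get_frac(tables_a, s); b <- get_frac(tables_b, s)
    d <- a - b
    tt <- tryCatch(stats::t.test(a, b, paired = TRUE),
                   error = function(e) NULL) # constant differences
    row <- data.frame(species = s, mean_diff = mean(d),
                      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                      p = if (is.null(tt)) NA_real_ else tt$p.value)
    row$significant <- !is.na(row$p) & row$p < 0.05
    if (!is.null(covariate)) {
      ct <- tryCatch(suppressWarnings(
        stats::cor.test(a, covariate, method = "spearman")),
        error = function(e) NULL)
      row$rho <- if (is.null(ct)) NA_real_ else unname(ct$estimate)
      row$rho_p <- if (is.null(ct)) NA_real_ else ct$p.value
    }
    row
  })
  do.call(rbind, rows)
}
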