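#' Pipeline configuration
#'
#' Bundles every input and tunable of a full recruitment run. Inputs may
#' be given as paths (read at run time) or as in-memory objects; paths are
#' checked up front so a bad configuration fails before any compute.
#'
#' @param ref a [reference_db], or `NULL` to read one from
#'   `reference_fasta` + `metadata`.
#' @param reference_fasta,metadata paths to the reference genomes FASTA
#'   and metadata TSV (used when `ref` is `NULL`).
#' @param alignments [alignment_hits] or a path to an alignment table;
#'   `NULL` to align `reads` with [toy_align()].
#' @param dialect alignment table dialect, `"blast6"` or `"paf"`.
#' @param reads named character vector or FASTQ/FASTA path; needed when
#'   `alignments` is `NULL` and for full read accounting.
#' @param host_alignments optional [alignment_hits] or path: the read set
#'   aligned against the host genome, for host-read removal.
#' @param platform `"short"` (read-count abundances) or `"long"`
#'   (base-weighted abundances plus length sweep).
#' @param filter a [filter_config].
#' @param sweep_thresholds minimum-read-length grid for the long-read
#'   sweep, bp.
#' @param minorities_cutoff optional pooling cutoff for the exported
#'   abundance table (e.g. 0.004 or 0.01).
#' @param sample_id sample label.
#' @param out_dir output directory for TSV exports (`NULL`: no files
#'   written).
#' @param seed integer seed recorded in the manifest; also feeds
#'   `filter$tie_seed` unless that was set explicitly.
#' @param verbose log per-stage read counts?
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(ref = NULL, reference_fasta = NULL,
                            metadata = NULL, alignments = NULL,
                            dialect = c("blast6", "paf"), reads = NULL,
                            host_alignments = NULL,
                            platform = c("short", "long"),
                            filter = filter_config(),
                            sweep_thresholds = c(500, seq(1000, 10000, 1000)),
                            minorities_cutoff = NULL,
                            sample_id = "sample", out_dir = NULL,
                            seed = 1L, verbose = TRUE) {
  dialect <- match.arg(dialect)
  platform <- match.arg(platform)
  cfg_err <- function(...) stop(errorCondition(paste0(...),
                                               class = "fragrec_config_error"))
  if (is.null(ref) && (is.null(reference_fasta) || is.null(metadata)))
    cfg_err("need either `ref` or both `reference_fasta` and `metadata`")
  is_path <- function(x) is.character(x) && length(x) == 1L && is.null(names(x))
  for (p in c(reference_fasta, metadata,
              if (is_path(alignments)) alignments,
              if (is_path(reads)) reads,
              if (is_path(host_alignments)) host_alignments))
    if (!file.exists(p)) cfg_err("no such file: ", p)
  if (is.null(alignments) && is.null(reads))
    cfg_err("need `alignments`, or `reads` to align with toy_align()")
  structure(list(ref = ref, reference_fasta = reference_fasta,
                 metadata = metadata, alignments = alignments,
                 dialect = dialect, reads = reads,
                 host_alignments = host_alignments, platform = platform,
                 filter = filter, sweep_thresholds = sweep_thresholds,
                 minorities_cutoff = minorities_cutoff,
                 sample_id = sample_id, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full recruitment pipeline
#'
#' Executes host removal, quality filtering, best-hit selection, profile
#' building, species retention and abundance estimation (plus the
#' read-length sweep for long reads), logging per-stage read counts and
#' asserting their conservation: every input read is accounted for as
#' recruited, host-removed, filter-removed, unaligned or
#' dropped-unknown-subject. When `cfg$out_dir` is set, results are
#' exported as TSVs together with a manifest recording the seed and a
#' configuration fingerprint; reruns with the same configuration are
#' byte-identical.
#'
#' @param cfg a [pipeline_config].
#' @return list with `best_hits`, `profiles`, `retention`, `abundance`,
#'   `sweep` (long platform only), `gaps`, `ratios`, `counts` and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (cfg$verbose) message("[fragrec] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ref <- stage("reference", {
    if (!is.null(cfg$ref)) cfg$ref
    else read_reference_db(cfg$reference_fasta, cfg$metadata)
  })
  reads <- stage("reads", {
    if (is.character(cfg$reads) && length(cfg$reads) == 1L &&
        is.null(names(cfg$reads)))
      read_reads(cfg$reads)
    else cfg$reads
  })
  hits <- stage("alignments", {
    if (is.null(cfg$alignments)) {
      say("aligning ", length(reads), " reads with toy_align")
      toy_align(reads, ref)
    } else if (is.character(cfg$alignments)) {
      read_alignment_table(cfg$alignments, cfg$dialect, ref)
    } else cfg$alignments
  })
  total_input <- if (!is.null(reads)) length(reads) else NA_integer_
  say("input reads: ", if (is.na(total_input)) "unknown" else total_input,
      "; alignment rows: ", nrow(hits))

  host_ids <- stage("host_removal", {
    if (is.null(cfg$host_alignments)) character()
    else {
      h <- if (is.character(cfg$host_alignments))
        read_alignment_table(cfg$host_alignments, cfg$dialect)
      else cfg$host_alignments
      remove_host_hits(h, cfg$filter)
    }
  })
  hits_nohost <- hits[!hits$query_id %in% host_ids, , drop = FALSE]
  say("host-removed reads: ", length(host_ids))

  filtered <- stage("filter", filter_hits(hits_nohost, cfg$platform,
                                          cfg$filter))
  pre_ids <- unique(hits_nohost$query_id)
  post_ids <- unique(filtered$query_id)
  filter_removed <- length(pre_ids) - length(post_ids)
  say("reads surviving quality filter: ", length(post_ids))

  best <- stage("best_hit", select_best_hits(filtered, cfg$filter))
  profiles <- stage("profiles", build_profiles(best, ref, cfg$filter))
  dropped_unknown <- attr(profiles, "dropped_unknown")
  recruited <- nrow(best) - dropped_unknown

  retention <- stage("retention", retain_species(profiles, cfg$filter))
  for (i in seq_along(profiles))
    profiles[[i]]$retained <-
      retention$retained[match(profiles[[i]]$species, retention$species)]
  kept <- retained_species(retention)
  say("species retained: ", length(kept), "/", nrow(retention))

  counts <- c(input = total_input, aligned = length(unique(hits$query_id)),
              host_removed = length(host_ids),
              filter_removed = filter_removed,
              dropped_unknown_subject = dropped_unknown,
              recruited = recruited)
  if (!is.na(total_input)) {
    aligned_or_host <- union(unique(hits$query_id), host_ids)
    counts["unaligned"] <- total_input - length(aligned_or_host)
    # host-flagged reads may or may not appear in the main table; read-level
    # conservation holds over the union
    accounted <- counts[["host_removed"]] + counts[["unaligned"]] +
      counts[["filter_removed"]] + counts[["dropped_unknown_subject"]] +
      counts[["recruited"]]
    if (accounted != total_input)
      stop("read accounting violated: ", accounted, " accounted vs ",
           total_input, " input")
  }

  result <- list(best_hits = best, profiles = profiles,
                 retention = retention, counts = counts)
  if (length(kept)) {
    result$abundance <- stage("abundance", {
      if (cfg$platform == "short")
        abundance_short(profiles, kept, cfg$sample_id)
      else abundance_long(profiles, kept, cfg$filter$min_read_length_long,
                          cfg$sample_id)
    })
    if (cfg$platform == "long")
      result$sweep <- stage("sweep", length_sweep(profiles, kept,
                                                  cfg$sweep_thresholds,
                                                  cfg$sample_id))
    gaps <- list()
    for (p in profiles)
      if (isTRUE(p$retained) && p$read_count >= cfg$filter$min_reads_retain)
        gaps[[p$genome_id]] <- detect_coverage_gaps(p, cfg$filter)
    result$gaps <- gaps
    result$ratios <- subspecies_ratios(
      setNames(list(profiles), cfg$sample_id), ref)$summary
  } else {
    say("no species retained; abundance skipped")
  }
  result$manifest <- pipeline_manifest(cfg, counts)
  if (!is.null(cfg$out_dir)) export_results(result, cfg)
  result
}

pipeline_manifest <- function(cfg, counts) {
  stamp <- cfg[c("dialect", "platform", "sweep_thresholds",
                 "minorities_cutoff", "sample_id", "seed")]
  stamp$filter <- unclass(cfg$filter)
  c(config_hash = sprintf("%08x",
                          str_hash31(paste(deparse(stamp), collapse = ""))),
    seed = cfg$seed,
    counts[!is.na(counts)])
}

export_results <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(cfg$out_dir, name)
  tsv <- function(df, name) utils::write.table(
    df, out(name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(result$retention, "retention_report.tsv")
  if (!is.null(result$abundance)) {
    ab <- result$abundance
    if (!is.null(cfg$minorities_cutoff))
      ab <- group_minorities(ab, cfg$minorities_cutoff)
    tsv(as.data.frame(ab), "abundance.tsv")
  }
  if (!is.null(result$sweep)) {
    sw <- result$sweep
    long <- do.call(rbind, lapply(seq_along(sw$thresholds), function(i) {
      d <- as.data.frame(sw$tables[[i]])
      d$retained_bp_fraction <- sw$retained_bp_fraction[i]
      d
    }))
    tsv(long, "sweep.tsv")
  }
  if (length(result$gaps %||% list())) {
    gp <- do.call(rbind, lapply(result$gaps, function(g)
      data.frame(genome_id = g$genome_id, bin = seq_len(g$n_bins),
                 covered = !(seq_len(g$n_bins) %in% g$gap_bins))))
    tsv(gp, "gap_profiles.tsv")
  }
  if (!is.null(result$ratios)) tsv(result$ratios, "subspecies_ratios.tsv")
  writeLines(paste(names(result$manifest), unname(result$manifest),
                   sep = "\t"), out("manifest.tsv"))
  invisible(cfg$out_dir)
}

#' Export plot-ready recruitment data for one genome
#'
#' One row per recruited read with its subject-genome position, percent
#' identity and read length -- the coordinates of a recruitment plot.
#' Rows are ordered by position then read id, so repeated exports are
#' byte-identical.
#'
#' @param profile a recruitment profile; must be retained unless
#'   `force = TRUE` (forced exports carry a `not_retained` attribute).
#' @param force export a non-retained profile?
#' @return data frame with columns `read_id`, `subject_position`,
#'   `percent_identity`, `read_length`.
#' @export
export_recruitment_plot <- function(profile, force = FALSE) {
  stopifnot(inherits(profile, "recruitment_profile"))
  if (!isTRUE(profile$retained) && !force)
    stop("profile ", profile$genome_id,
         " is not retained; use force = TRUE to export anyway")
  h <- profile$hits
  df <- data.frame(read_id = h$query_id,
                   subject_position = pmin(h$subject_start, h$subject_end),
                   percent_identity = h$percent_identity,
                   read_length = h$query_length)
  df <- df[order(df$subject_position, df$read_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "not_retained") <- !isTRUE(profile$retained)
  df
}

#' Write a synthetic bundle (genomes, reads, truth) to a directory
#'
#' Materializes a simulated community as files: genomes FASTA + metadata
#' TSV, short/long FASTQ, host FASTA when configured, per-read provenance
#' and species-truth TSVs, and a manifest recording the seed.
#'
#' @param cfg a [simulation_config].
#' @param dir output directory.
#' @return invisibly, the list returned by [fragment_and_read()] with
#'   `ref` and `host` attached.
#' @export
write_synthetic_bundle <- function(cfg, dir) {
  made <- make_reference(cfg)
  sim <- fragment_and_read(made$ref, made$truth, made$host)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_db(made$ref, file.path(dir, "genomes.fasta"),
                     file.path(dir, "genomes.tsv"))
  if (!is.null(made$host))
    write_reference_db(made$host, file.path(dir, "host.fasta"),
                       file.path(dir, "host.tsv"))
  if (length(sim$short_reads))
    write_reads(sim$short_reads, file.path(dir, "short_reads.fastq"))
  if (length(sim$long_reads))
    write_reads(sim$long_reads, file.path(dir, "long_reads.fastq"))
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(sim$truth$reads$short, "truth_short_reads.tsv")
  tsv(sim$truth$reads$long, "truth_long_reads.tsv")
  tsv(sim$truth$species, "truth_species.tsv")
  tsv(sim$truth$genomes, "truth_genomes.tsv")
  writeLines(c(sprintf("seed\t%d", cfg$seed),
               sprintf("genome_copies\t%s", cfg$genome_copies),
               sprintf("n_short_reads\t%s", cfg$n_short_reads),
               sprintf("n_long_reads\t%s", cfg$n_long_reads)),
             file.path(dir, "manifest.tsv"))
  invisible(c(sim, list(ref = made$ref, host = made$host)))
}
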