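# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

# Build an alignment_hits table from compact per-hit arguments.
make_hits <- function(query_id, subject_id = "gA", percent_identity = 100,
                      alignment_length = 100, query_length = 100,
                      query_start = 1, query_end = NULL,
                      subject_start = 1, subject_end = NULL,
                      bitscore = 200, evalue = 1e-10) {
  n <- length(query_id)
  rec <- function(x) rep_len(x, n)
  alignment_length <- rec(alignment_length)
  if (is.null(query_end)) query_end <- rec(query_start) +
    alignment_length - 1
  if (is.null(subject_end)) subject_end <- rec(subject_start) +
    alignment_length - 1
  alignment_hits(data.frame(
    query_id = query_id, query_length = rec(query_length),
    subject_id = rec(subject_id), percent_identity = rec(percent_identity),
    alignment_length = alignment_length, query_start = rec(query_start),
    query_end = query_end, subject_start = rec(subject_start),
    subject_end = subject_end, evalue = rec(evalue),
    bitscore = rec(bitscore)))
}

# Random alignment tables for the filter/best-hit oracle comparisons.
random_hits_table <- function(n_hits, n_queries = ceiling(n_hits / 3),
                              n_subjects = 4) {
  q <- sprintf("r%03d", sample.int(n_queries, n_hits, replace = TRUE))
  qlen <- sample(80:600, n_hits, replace = TRUE)
  alen <- pmax(20, round(qlen * runif(n_hits, 0.3, 1)))
  make_hits(q, subject_id = sprintf("g%d", sample.int(n_subjects, n_hits,
                                                      replace = TRUE)),
            percent_identity = round(runif(n_hits, 40, 100), 1),
            alignment_length = alen, query_length = qlen,
            query_start = 1,
            subject_start = sample.int(5000, n_hits, replace = TRUE),
            bitscore = sample(seq(0, 400, by = 10), n_hits, replace = TRUE))
}

# Exhaustive per-read filter + argmax-bitscore oracle. Returns, per
# surviving query, the row indices (into `hits`) tied for the best score.
brute_force_best <- function(hits, platform, cfg) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    keep[i] <- if (platform == "short")
      hits$percent_identity[i] >= cfg$min_identity_short &&
        hits$alignment_length[i] >= cfg$min_overlap_short
    else
      hits$percent_identity[i] >= cfg$min_identity_long &&
        hits$query_length[i] >= cfg$min_read_length_long
  }
  out <- list()
  for (q in unique(hits$query_id[keep])) {
    rows <- which(keep & hits$query_id == q)
    out[[q]] <- rows[hits$bitscore[rows] == max(hits$bitscore[rows])]
  }
  out
}

# A small two-species community (one fragmented, with subspecies) reused
# across test files; built once per test run.
fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (!is.null(fixture_env$sim)) return(fixture_env$sim)
  spec <- data.frame(
    species = c("frag_sp", "intact_sp"), genome_length = 30000L,
    abundance = c(0.5, 0.5), frag_meanlog = log(c(1000, 8000)),
    frag_sdlog = 0.4, n_subspecies = c(2L, 1L),
    subspecies_divergence = c(0.01, 0))
  cfg <- simulation_config(species = spec, n_short_reads = 4000,
                           n_long_reads = 5000, genome_copies = 60,
                           seed = 42)
  made <- make_reference(cfg)
  sim <- fragment_and_read(made$ref, made$truth)
  fixture_env$sim <- c(sim, list(ref = made$ref, cfg = cfg))
  fixture_env$sim
}

# A uniformly recruited profile with `n` reads over a 100-bin genome.
uniform_profile <- function(n, genome = "gA", glen = 100000,
                            species = "spA", cfg = filter_config()) {
  pos <- floor(runif(n) * (glen - 200)) + 1
  hits <- make_hits(sprintf("u%06d", seq_len(n)), subject_id = genome,
                    subject_start = pos, alignment_length = 150,
                    query_length = 150)
  ref <- reference_db(data.frame(genome_id = genome, species = species,
                                 length = glen))
  build_profiles(hits, ref, cfg)[[genome]]
}
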