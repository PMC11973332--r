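test_that("host removal requires strictly-greater identity and coverage", {
  hits <- make_hits(c("h1", "h2", "h3"), subject_id = "bos",
                    percent_identity = c(75, 60, 95),
                    alignment_length = c(80, 90, 59),
                    query_length = 100)
  # h1: 75/80 -> out; h2: exactly 60 identity -> kept; h3: qcov 59 -> kept
  expect_equal(remove_host_hits(hits), "h1")
  bad <- make_hits("h4", query_length = NA_real_)
  expect_error(remove_host_hits(bad), "query_length")
  expect_equal(remove_host_hits(make_hits(character(0))), character())
})

test_that("host removal on simulated host + microbial reads", {
  set.seed(77)
  host_genome <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE),
                       collapse = "")
  host_ref <- reference_db(data.frame(genome_id = "host", species = "host",
                                      length = 50000),
                           c(host = host_genome))
  starts <- sample.int(49000, 100)
  host_reads <- setNames(substring(host_genome, starts, starts + 299),
                         sprintf("host%03d", 1:100))
  microbial <- setNames(
    vapply(1:900, function(i) paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                                    collapse = ""), character(1)),
    sprintf("mic%03d", 1:900))
  hits <- toy_align(c(host_reads, microbial), host_ref)
  excluded <- remove_host_hits(hits)
  expect_gte(sum(excluded %in% names(host_reads)), 95)
  expect_equal(sum(excluded %in% names(microbial)), 0) # no false exclusions
})

test_that("quality filter boundaries are kept-at-threshold and idempotent", {
  short <- make_hits(c("a", "b", "c"),
                     percent_identity = c(59.9, 60, 60),
                     alignment_length = c(100, 49, 50),
                     query_length = 200)
  kept <- filter_hits(short, "short")
  expect_equal(kept$query_id, "c")
  long <- make_hits(c("x", "y", "z"),
                    percent_identity = c(69.9, 70, 70),
                    alignment_length = 400,
                    query_length = c(600, 600, 499))
  keptl <- filter_hits(long, "long")
  expect_equal(keptl$query_id, "y")
  expect_equal(nrow(filter_hits(make_hits(character(0)), "short")), 0L)
  # idempotence on random tables
  set.seed(8)
  for (rep in 1:5) {
    h <- random_hits_table(120)
    once <- filter_hits(h, "short")
    expect_identical(filter_hits(once, "short"), once)
  }
})

test_that("best-hit selection keeps the top bitscore, one hit per read", {
  hits <- make_hits(c("q1", "q1", "q2"), subject_id = c("gA", "gB", "gA"),
                    bitscore = c(300, 250, 120))
  best <- select_best_hits(hits)
  expect_equal(nrow(best), 2L)
  expect_equal(best$subject_id[best$query_id == "q1"], "gA")
  expect_equal(best$bitscore[best$query_id == "q2"], 120)
})

test_that("tie-breaking is uniform, seeded and order-independent", {
  n <- 10000
  hits <- make_hits(rep(sprintf("q%05d", 1:n), each = 2),
                    subject_id = rep(c("gA", "gB"), n),
                    bitscore = 200)
  cfg <- filter_config(tie_seed = 123)
  best <- select_best_hits(hits, cfg)
  expect_equal(nrow(best), n)
  nA <- sum(best$subject_id == "gA")
  expect_lt(abs(nA - n / 2), 3 * sqrt(n / 4)) # binomial 3-sigma
  # bit-identical on rerun and on a shuffled table
  expect_identical(select_best_hits(hits, cfg), best)
  set.seed(1); shuffled <- hits[sample.int(nrow(hits)), ]
  best_sh <- select_best_hits(alignment_hits(shuffled), cfg)
  best_sh <- best_sh[order(best_sh$query_id), ]; rownames(best_sh) <- NULL
  expect_equal(best_sh$subject_id, best$subject_id)
  # a different tie_seed changes only tied queries
  hits2 <- make_hits(c("t1", "t1", "u1", "u1"),
                     subject_id = c("gA", "gB", "gA", "gB"),
                     bitscore = c(200, 200, 300, 100))
  b1 <- select_best_hits(hits2, filter_config(tie_seed = 1))
  b2 <- select_best_hits(hits2, filter_config(tie_seed = 2))
  expect_equal(b1$subject_id[b1$query_id == "u1"],
               b2$subject_id[b2$query_id == "u1"])
})

test_that("pipeline filter + best-hit equals brute-force enumeration", {
  set.seed(99)
  cfg <- filter_config(tie_seed = 5)
  for (rep in 1:20) {
    hits <- random_hits_table(sample(20:200, 1))
    oracle <- brute_force_best(hits, "short", cfg)
    best <- select_best_hits(filter_hits(hits, "short", cfg), cfg)
    expect_setequal(best$query_id, names(oracle))
    for (i in seq_len(nrow(best))) {
      rows <- oracle[[best$query_id[i]]]
      if (length(rows) == 1L) {
        expect_equal(best$subject_id[i], hits$subject_id[rows])
        expect_equal(best$bitscore[i], hits$bitscore[rows])
      } else {
        expect_true(best$subject_id[i] %in% hits$subject_id[rows])
      }
    }
  }
})

test_that("profiles count reads, bases and bins correctly", {
  ref <- reference_db(data.frame(genome_id = "gA", species = "spA",
                                 length = 100000))
  cfg <- filter_config()
  hits <- make_hits(c("r1", "r2", "r3"),
                    subject_start = c(150, 600, 49500),
                    alignment_length = c(200, 300, 100),
                    query_length = c(200, 300, 100))
  prof <- build_profiles(hits, ref, cfg)[["gA"]]
  expect_equal(prof$read_count, 3L)
  expect_equal(prof$base_count, 600)
  expect_equal(prof$bin_coverage[1], 2L) # midpoints 249.5, 749.5 in bin 1
  expect_equal(prof$bin_coverage[50], 1L) # midpoint 49549.5 in bin 50
  expect_equal(sum(prof$bin_coverage), prof$read_count)
  # unknown subjects dropped with a logged count
  hits2 <- make_hits(c("r1", "r2"), subject_id = c("gA", "gZ"))
  expect_message(p2 <- build_profiles(hits2, ref, cfg), "dropped")
  expect_equal(attr(p2, "dropped_unknown"), 1L)
  expect_equal(p2[["gA"]]$read_count, 1L)
})

test_that("uniform recruitment fills bins within multinomial bounds", {
  set.seed(12)
  prof <- uniform_profile(10000)
  expected <- 10000 / 100
  sigma <- sqrt(10000 * (1 / 100) * (99 / 100))
  expect_true(all(abs(prof$bin_coverage - expected) < 5 * sigma))
})

test_that("species retention applies strict >300 and the breadth surrogate", {
  set.seed(13)
  cfg <- filter_config()
  ref <- reference_db(data.frame(genome_id = c("gA", "gB", "gC"),
                                 species = c("spA", "spB", "spC"),
                                 length = 100000))
  mkhits <- function(n, genome, prefix, clustered = FALSE) {
    pos <- if (clustered) sample(2000:4500, n, TRUE) # 3 bins of 100
           else floor(runif(n) * 99800) + 1
    make_hits(sprintf("%s%05d", prefix, seq_len(n)), subject_id = genome,
              subject_start = pos, alignment_length = 150,
              query_length = 150)
  }
  hits <- alignment_hits(rbind(mkhits(300, "gA", "a"),
                               mkhits(301, "gB", "b"),
                               mkhits(5000, "gC", "c", clustered = TRUE)))
  verdict <- retain_species(build_profiles(hits, ref, cfg), cfg)
  expect_equal(verdict$retained[verdict$species == "spA"], FALSE)
  expect_equal(verdict$reason[verdict$species == "spA"], "too_few_reads")
  expect_equal(verdict$retained[verdict$species == "spB"], TRUE)
  expect_equal(verdict$retained[verdict$species == "spC"], FALSE)
  expect_equal(verdict$reason[verdict$species == "spC"], "poor_spread")
  expect_lt(verdict$breadth[verdict$species == "spC"], 0.05)
  expect_equal(retained_species(verdict), "spB")
})

test_that("retention pools read counts across subspecies genomes", {
  set.seed(14)
  cfg <- filter_config()
  ref <- reference_db(data.frame(genome_id = c("g1", "g2"),
                                 species = "spA",
                                 subspecies = c("ss1", "ss2"),
                                 length = 100000))
  mk <- function(n, genome, prefix)
    make_hits(sprintf("%s%05d", prefix, seq_len(n)), subject_id = genome,
              subject_start = floor(runif(n) * 99800) + 1,
              alignment_length = 150, query_length = 150)
  # 200 + 200 reads: each genome alone is under the 300-read bar
  hits <- alignment_hits(rbind(mk(200, "g1", "x"), mk(200, "g2", "y")))
  verdict <- retain_species(build_profiles(hits, ref, cfg), cfg)
  expect_equal(verdict$reads, 400)
  expect_true(verdict$retained)
})

test_that("coverage gaps are called only at depth, at the right bins", {
  set.seed(15)
  cfg <- filter_config()
  # uniform coverage: no gaps with high probability
  prof <- uniform_profile(10000)
  gaps <- detect_coverage_gaps(prof, cfg)
  expect_equal(length(gaps$gap_bins), 0L)
  # masked bins 40..45 (positions 39001..45000 of a 100 kb genome)
  ref <- reference_db(data.frame(genome_id = "gA", species = "spA",
                                 length = 100000))
  pos <- runif(5000, 0, 1) * 99800 + 1
  mid <- pos + 75
  pos <- pos[!(mid > 39000 & mid <= 45000)]
  hits <- make_hits(sprintf("m%05d", seq_along(pos)), subject_id = "gA",
                    subject_start = floor(pos), alignment_length = 150,
                    query_length = 150)
  prof2 <- build_profiles(hits, ref, cfg)[["gA"]]
  expect_equal(detect_coverage_gaps(prof2, cfg)$gap_bins, 40:45)
  # under-recruited profile refuses gap calls
  prof10 <- uniform_profile(10)
  expect_error(detect_coverage_gaps(prof10, cfg), "insufficient depth")
})

test_that("gap concordance is Jaccard with the empty-sets-agree convention", {
  gp <- function(bins) structure(list(genome_id = "gA", gap_bins = bins,
                                      n_bins = 100), class = "gap_profile")
  expect_equal(gap_concordance(gp(40:45), gp(40:45)), 1)
  expect_equal(gap_concordance(gp(40:45), gp(44:49)), 0.2) # 2 / 10
  expect_equal(gap_concordance(gp(integer()), gp(integer())), 1)
  other <- structure(list(genome_id = "gB", gap_bins = 1:2, n_bins = 100),
                     class = "gap_profile")
  expect_error(gap_concordance(gp(1:2), other), "different genomes")
})

test_that("subspecies ratios report pairwise counts, undefined flags, summaries", {
  ref <- reference_db(data.frame(
    genome_id = c("g1", "g2", "g3"), species = c("spA", "spA", "spB"),
    length = 10000))
  cfg <- filter_config()
  mk <- function(counts, prefix) {
    hits <- make_hits(
      sprintf("%s%04d", prefix, seq_len(sum(counts))),
      subject_id = rep(c("g1", "g2", "g3"), counts),
      subject_start = 10)
    build_profiles(hits, ref, cfg)
  }
  res <- subspecies_ratios(list(s1 = mk(c(500, 100, 7), "a"),
                                s2 = mk(c(91, 100, 7), "b")), ref)
  r <- res$ratios
  expect_equal(r$ratio[r$sample_id == "s1" & r$genome_a == "g1"], 5)
  expect_equal(r$ratio[r$sample_id == "s2" & r$genome_a == "g1"], 0.91)
  expect_false("spB" %in% r$species) # single-genome species skipped
  s <- res$summary
  expect_equal(s$mean_ratio[s$genome_a == "g1"], mean(c(5, 0.91)))
  expect_equal(s$sd_ratio[s$genome_a == "g1"], sd(c(5, 0.91)))
  # zero denominator -> undefined, excluded from summary
  res0 <- subspecies_ratios(mk(c(100, 0, 7), "z"), ref)
  r0 <- res0$ratios
  expect_false(r0$defined[r0$genome_a == "g1" & r0$genome_b == "g2"])
  expect_true(is.na(r0$ratio[r0$genome_a == "g1" & r0$genome_b == "g2"]))
})

test_that("reference genus selection is strictly greater than the cutoff", {
  tab <- data.frame(genus = c("A", "B", "C"),
                    fraction = c(0.5, 0.001, 0.0009))
  expect_equal(select_reference_genera(tab), "A")
  expect_equal(select_reference_genera(c(A = 0.0011)), "A")
  expect_equal(select_reference_genera(data.frame(genus = character(),
                                                  fraction = numeric())),
               character())
  expect_error(select_reference_genera(c(A = -0.1)), "negative")
})
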