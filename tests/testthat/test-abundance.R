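# Build recruitment profiles with given per-species read lengths.
profiles_from_lengths <- function(lengths_by_species) {
  genomes <- data.frame(genome_id = paste0("g_", names(lengths_by_species)),
                        species = names(lengths_by_species),
                        length = 100000)
  ref <- reference_db(genomes)
  rows <- do.call(rbind, lapply(names(lengths_by_species), function(sp) {
    len <- lengths_by_species[[sp]]
    data.frame(q = sprintf("%s_%05d", sp, seq_along(len)),
               s = paste0("g_", sp), len = len)
  }))
  hits <- make_hits(rows$q, subject_id = rows$s, alignment_length = rows$len,
                    query_length = rows$len)
  build_profiles(hits, ref, filter_config())
}

test_that("read-count abundances are normalized counts over retained species", {
  prof <- profiles_from_lengths(list(A = rep(100, 750), B = rep(100, 250),
                                     C = rep(100, 40)))
  tab <- abundance_short(prof, c("A", "B"))
  expect_equal(as.numeric(tab[c("A", "B")]), c(0.75, 0.25))
  expect_false("C" %in% names(tab)) # unretained species contribute nothing
  expect_equal(as.numeric(abundance_short(prof, "A")), 1)
  expect_error(abundance_short(prof, character()), "retained")
  expect_equal(sum(tab), 1)
})

test_that("base-weighted abundances sum read lengths above the threshold", {
  prof <- profiles_from_lengths(list(A = c(2000, 8000), B = 10000))
  t0 <- abundance_long(prof, c("A", "B"), min_read_length = 500)
  expect_equal(as.numeric(t0[c("A", "B")]), c(0.5, 0.5))
  t5 <- abundance_long(prof, c("A", "B"), min_read_length = 5000)
  expect_equal(as.numeric(t5[c("A", "B")]), c(8 / 18, 10 / 18))
  expect_error(abundance_long(prof, c("A", "B"), min_read_length = 20000),
               "shorter than")
  # identical read sets -> equal fractions at every threshold
  prof2 <- profiles_from_lengths(list(X = c(600, 3000, 9000),
                                      Y = c(600, 3000, 9000)))
  for (thr in c(500, 2000, 8000))
    expect_equal(as.numeric(abundance_long(prof2, c("X", "Y"), thr)),
                 c(0.5, 0.5))
})

test_that("length sweep is monotone in retained bases and keeps zeroed species", {
  prof <- profiles_from_lengths(list(A = c(600, 700, 1500),
                                     B = c(5000, 9000)))
  sw <- length_sweep(prof, c("A", "B"),
                     thresholds = c(500, 1000, 2000, 6000))
  expect_equal(sw$retained_bp_fraction[1], 1)
  expect_true(all(diff(sw$retained_bp_fraction) <= 0))
  # species A vanishes at 2000 but stays in the table with fraction 0
  expect_equal(as.numeric(sw$tables[[3]]["A"]), 0)
  expect_equal(as.numeric(sw$tables[[3]]["B"]), 1)
  # all reads >= 10 kb: tables identical, retained fraction constant 1
  prof10 <- profiles_from_lengths(list(A = rep(12000, 5), B = rep(15000, 4)))
  sw10 <- length_sweep(prof10, c("A", "B"),
                       thresholds = c(500, 4000, 10000))
  expect_true(all(sw10$retained_bp_fraction == 1))
  for (tab in sw10$tables)
    expect_equal(as.numeric(tab), as.numeric(sw10$tables[[1]]))
  expect_error(length_sweep(prof, c("A", "B"), thresholds = c(500, 400)),
               "increasing")
})

test_that("equal fragmentation across species is a flat sweep (null case)", {
  spec <- data.frame(species = c("p", "q"), genome_length = 30000L,
                     abundance = c(0.5, 0.5), frag_meanlog = log(4000),
                     frag_sdlog = 0.4)
  cfg <- simulation_config(species = spec, n_short_reads = 0,
                           n_long_reads = 100000, genome_copies = 80,
                           seed = 17)
  made <- make_reference(cfg)
  sim <- fragment_and_read(made$ref, made$truth)
  prof <- build_profiles(truth_alignment_hits(sim$truth, "long"), made$ref,
                         filter_config())
  thresholds <- c(500, 2000, 4000, 6000)
  sw <- length_sweep(prof, c("p", "q"), thresholds)
  # fractions stay at 0.5 at every threshold when fragment-length
  # distributions are identical; the sampling sigma of a base-weighted
  # fraction follows from the delta method on length-weighted counts:
  # Var = p(1-p) E[w^2] / (n E[w]^2) over the retained fragment lengths w
  lens <- unlist(lapply(prof, function(p) p$hits$query_length))
  for (i in seq_along(thresholds)) {
    w <- lens[lens >= thresholds[i]]
    sigma <- sqrt(0.25 * mean(w^2) / (length(w) * mean(w)^2))
    expect_lt(abs(sw$tables[[i]][["p"]] - 0.5), 3 * sigma)
  }
})

test_that("read-length distributions summarize medians and N50", {
  prof <- profiles_from_lengths(list(A = rep(1000, 40)))[["g_A"]]
  d <- read_length_distribution(prof)
  expect_equal(d$median, 1000)
  expect_equal(d$x, 1000) # point mass
  set.seed(30)
  lens <- round(rlnorm(10000, 8, 0.5))
  profL <- profiles_from_lengths(list(A = lens))[["g_A"]]
  dL <- read_length_distribution(profL)
  expect_lt(abs(dL$median - exp(8)) / exp(8), 0.02)
  # density integrates to ~1
  expect_lt(abs(sum(dL$y) * diff(dL$x[1:2]) - 1), 0.01)
  expect_equal(n50(c(1000, 2000, 3000, 4000, 10000)), 10000)
  tiny <- profiles_from_lengths(list(A = rep(500, 10)))[["g_A"]]
  expect_error(read_length_distribution(tiny), "at least 30")
})

test_that("closest_threshold minimizes L1 distance with smallest-wins ties", {
  prof <- profiles_from_lengths(list(A = c(600, 700, 1500),
                                     B = c(5000, 9000)))
  sw <- length_sweep(prof, c("A", "B"), thresholds = c(500, 1000, 2000))
  ref_tab <- sw$tables[[3]]
  res <- closest_threshold(sw, ref_tab)
  expect_equal(res$threshold, 2000)
  expect_equal(unname(res$distances["2000"]), 0)
  # identical tables at all thresholds -> first threshold
  prof10 <- profiles_from_lengths(list(A = rep(12000, 5), B = rep(15000, 4)))
  sw10 <- length_sweep(prof10, c("A", "B"), thresholds = c(500, 4000))
  expect_equal(closest_threshold(sw10, sw10$tables[[1]])$threshold, 500)
  disjoint <- abundance_table(c(Z = 1), "s", "amplicon")
  expect_error(closest_threshold(sw, disjoint), "no species")
})

test_that("minority pooling preserves sums and respects all-table cutoffs", {
  tab <- abundance_table(c(A = 0.97, B = 0.02, C = 0.01), "s1", "read_count")
  g <- group_minorities(tab, 0.04)
  expect_equal(as.numeric(g[c("A", "Minorities")]), c(0.97, 0.03))
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_identical(names(group_minorities(tab, 0.005)),
                   names(tab)) # nothing below cutoff -> unchanged
  # a species above the cutoff in ANY table is not pooled anywhere
  tab2 <- abundance_table(c(A = 0.93, B = 0.06, C = 0.01), "s2", "read_count")
  gg <- group_minorities(list(tab, tab2), 0.04)
  expect_true("B" %in% names(gg[[1]]))
  expect_false("C" %in% names(gg[[1]]))
  expect_error(group_minorities(tab, 0.7), "cutoff")
})

test_that("method comparison flags constructed offsets and rank trends", {
  mk <- function(fracs, id) abundance_table(fracs, id, "read_count")
  ids <- sprintf("s%02d", 1:20)
  set.seed(40)
  tabs_a <- list(); tabs_b <- list()
  ripening <- 1:20
  for (i in 1:20) {
    base <- c(A = 0.5, B = 0.3, C = 0.2)
    noise <- rnorm(3, 0, 0.02)
    a <- pmax(base + c(0.2, -0.1, -0.1) + noise, 0.001)
    b <- pmax(base + rnorm(3, 0, 0.02), 0.001)
    tabs_a[[i]] <- mk(a / sum(a), ids[i])
    tabs_b[[i]] <- mk(b / sum(b), ids[i])
  }
  res <- method_comparison_stats(tabs_a, tabs_b)
  expect_true(res$significant[res$species == "A"])
  expect_gt(res$mean_diff[res$species == "A"], 0.1)
  # identical tables: zero differences, nothing significant
  res0 <- method_comparison_stats(tabs_a, tabs_a)
  expect_true(all(res0$mean_diff == 0))
  expect_false(any(res0$significant))
  # covariate perfectly rank-ordered with abundance -> rho = 1
  tabs_c <- lapply(1:20, function(i) {
    f <- c(A = 0.3 + i / 100, B = 0.7 - i / 100)
    mk(f, ids[i])
  })
  resc <- method_comparison_stats(tabs_c, tabs_c, covariate = ripening)
  expect_equal(resc$rho[resc$species == "A"], 1)
  expect_error(method_comparison_stats(tabs_a[1:3], tabs_b[4:6]),
               "not paired")
  expect_error(method_comparison_stats(tabs_a[1:2], tabs_b[1:2]),
               "at least 3")
})
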