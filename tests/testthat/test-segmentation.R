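# Read filtering, scaling factors, candidate regions, heuristic
# segmentation, posterior likelihoods and FDR locus selection.

test_that("read filters drop out-of-range lengths, heavy multimappers and excluded sequences", {
  reads <- rbind(
    make_reads("chr1", 100, len = 14L),     # too short
    make_reads("chr1", 100, len = 15L),     # shortest allowed
    make_reads("chr1", 100, len = 30L),     # longest allowed
    make_reads("chr1", 100, len = 31L),     # too long
    make_reads("chr1", 100, len = 24L, n_hits = 1000L),
    make_reads("chr1", 100, len = 24L, n_hits = 1001L)
  )
  reads$sequence <- paste0("S", seq_len(nrow(reads)), "ACGTACGTACGTACGT")
  out <- filter_reads(reads)
  expect_equal(nrow(out), 3)
  expect_true(all(out$end - out$start + 1 >= 15))
  expect_true(all(out$n_hits <= 1000))

  excl <- filter_reads(reads, exclusion_seqs = reads$sequence[2])
  expect_equal(nrow(excl), 2)
})

test_that("low-complexity reads with ten identical bases in an eleven-base window are removed", {
  lc <- paste0("CACAAAAAAAAAAAC", "GTGTT")      # 11-window with 10 A
  ok <- paste0("ACGTACGTACGTACGTACGT")
  reads <- make_reads("chr1", c(100, 200), len = 20L,
                      sequence = c(lc, ok))
  out <- filter_reads(reads)
  expect_equal(out$sequence, ok)
})

test_that("scaling factor sums the lowest three quarters of unique-sequence abundances", {
  r <- make_reads("chr1", c(10, 50, 90, 130), len = 21L,
                  count = c(1L, 2L, 3L, 4L),
                  sequence = paste0("SEQ", 1:4))
  expect_equal(compute_scaling_factor(r), 6)   # 1 + 2 + 3
  r$count <- rep(5L, 4)
  expect_equal(compute_scaling_factor(r), 15)  # 5 + 5 + 5
  expect_equal(compute_scaling_factor(r[1, ]), 5)
  r1 <- make_reads("chr1", 10, count = 10L, sequence = "SOLO")
  expect_equal(compute_scaling_factor(r1), 10)
  expect_error(compute_scaling_factor(r[0, ]), class = "empty_library")
})

test_that("multimapping alignment rows of one sequence count once toward the scaling factor", {
  r <- make_reads("chr1", c(10, 500, 900), len = 21L, count = 7L,
                  n_hits = 3L, sequence = "MULTI")
  expect_equal(compute_scaling_factor(r), 7)
})

test_that("candidate regions split at gaps of one hundred nucleotides or more", {
  # gap of 279 uncovered nt -> two regions
  r <- make_reads("chr1", c(1, 300), len = 21L)
  reg <- find_candidate_regions(r)
  expect_equal(nrow(reg), 2)
  # gap of exactly 100 -> split
  r2 <- make_reads("chr1", c(1, 122), len = 21L)   # covered 1-21, 122-142
  expect_equal(nrow(find_candidate_regions(r2)), 2)
  # gap of 99 -> merged
  r3 <- make_reads("chr1", c(1, 121), len = 21L)
  reg3 <- find_candidate_regions(r3)
  expect_equal(nrow(reg3), 1)
  expect_equal(reg3$start, 1)
  expect_equal(reg3$end, 141)
})

test_that("running mean matches a direct window average with edge shrinkage", {
  set.seed(1)
  x <- rpois(200, 3)
  w <- 50L
  got <- srnaloc:::run_mean(x, w)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  want <- vapply(seq_along(x), function(i) {
    lo <- max(1L, i - half_l); hi <- min(length(x), i + half_r)
    mean(x[lo:hi])
  }, 1.0)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("two dense read blocks separated by a long silent gap segment into two loci", {
  starts <- c(seq(1, 97, by = 4), seq(271, 367, by = 4))
  r <- make_reads("chr1", starts, len = 24L, count = 10L,
                  sequence = paste0("B", seq_along(starts)))
  libs <- make_libraries()
  libs <- compute_scaling_factors(r, libs)
  regions <- find_candidate_regions(r)
  cand <- heuristic_segmentation(regions, r, libs, segmentation_params())
  expect_equal(nrow(cand), 2)
  expect_true(cand$end[1] < 271 && cand$start[2] >= 200)
})

test_that("heuristic segmentation is invariant to read order", {
  set.seed(11)
  starts <- sort(sample(1:2000, 120, replace = TRUE))
  r <- make_reads("chr1", starts, len = 24L, count = 5L,
                  sequence = paste0("O", seq_along(starts)))
  libs <- compute_scaling_factors(r, make_libraries())
  regions <- find_candidate_regions(r)
  a <- heuristic_segmentation(regions, r, libs, segmentation_params())
  perm <- sample(nrow(r))
  b <- heuristic_segmentation(regions, r[perm, ], libs,
                              segmentation_params())
  expect_equal(a, b)
})

test_that("cold coverage between hot runs merges only across short sub-threshold gaps", {
  # Two hot stacks bridged by sparse count-1 reads so they share one
  # candidate region; a raised threshold keeps the bridge cold.
  hot1 <- make_reads("chr1", seq(1, 73, by = 4), len = 24L, count = 50L,
                     sequence = paste0("H", 1:19))
  hot2 <- make_reads("chr1", seq(241, 313, by = 4), len = 24L, count = 50L,
                     sequence = paste0("K", 1:19))
  bridge <- make_reads("chr1", seq(120, 220, by = 50), len = 24L,
                       count = 1L, sequence = paste0("W", 1:3))
  r <- rbind(hot1, hot2, bridge)
  libs <- compute_scaling_factors(r, make_libraries())
  params <- segmentation_params()
  # place the threshold between the bridge and the stacks' windowed RPKM
  sg <- libs$scaling_factor
  params$rpkm_threshold <- 2e9 / (50 * sg)   # between bridge and stacks
  regions <- find_candidate_regions(r)
  expect_equal(nrow(regions), 1)
  cand <- heuristic_segmentation(regions, r, libs, params)
  expect_equal(nrow(cand), 2)
})

test_that("posterior expression likelihood separates an expressed group from a silent one", {
  set.seed(3)
  dense <- do.call(rbind, lapply(c("a1", "a2"), function(lib)
    make_reads("chr1", seq(101, 290, by = 6), len = 24L, count = 8L,
               library_id = lib,
               sequence = paste0(lib, "_", seq(101, 290, by = 6)))))
  # both groups share diffuse background so scaling factors exist
  bg <- do.call(rbind, lapply(c("a1", "a2", "b1", "b2"), function(lib)
    make_reads("chr1", seq(1000, 40000, by = 800), len = 24L, count = 1L,
               library_id = lib,
               sequence = paste0(lib, "bg", seq(1000, 40000, by = 800)))))
  r <- rbind(dense, bg)
  libs <- make_libraries(library_id = c("a1", "a2", "b1", "b2"),
                         replicate_group = c("ga", "ga", "gb", "gb"))
  libs <- compute_scaling_factors(r, libs)
  regions <- find_candidate_regions(r)
  loci <- data.frame(chrom = "chr1", start = 101L, end = 313L,
                     stringsAsFactors = FALSE)
  post <- posterior_expression_likelihood(loci, r, libs, regions,
                                          genome_length = 50000)
  expect_gt(post[1, "ga"], 0.9)
  expect_lt(post[1, "gb"], 0.1)
})

test_that("the largest likelihood prefix with mean shortfall within the FDR is selected", {
  loci <- data.frame(chrom = "chr1", start = c(1L, 101L, 201L),
                     end = c(50L, 150L, 250L), stringsAsFactors = FALSE)
  lik <- matrix(c(1.0, 1.0, 0.8), ncol = 1,
                dimnames = list(NULL, "g1"))
  tab <- select_loci(lik, loci, fdr = 0.05)
  expect_equal(nrow(tab$loci), 2)
  expect_equal(tab$loci$start, c(1L, 101L))
})

test_that("FDR selection agrees with brute-force maximal-subset enumeration", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    p <- round(runif(n), 3)
    # non-overlapping loci so merging cannot blur the comparison
    loci <- data.frame(chrom = "chr1",
                       start = seq(1L, by = 200L, length.out = n),
                       end = seq(100L, by = 200L, length.out = n),
                       stringsAsFactors = FALSE)
    lik <- matrix(p, ncol = 1, dimnames = list(NULL, "g1"))
    got <- sort(select_loci(lik, loci, fdr = 0.05)$loci$start)
    want <- loci$start[oracle_select_group(p, 0.05)]
    expect_equal(got, want)
  }
})

test_that("overlapping selections merge to their union with the maximum group likelihood", {
  loci <- data.frame(chrom = "chr1", start = c(1L, 80L),
                     end = c(120L, 200L), stringsAsFactors = FALSE)
  lik <- matrix(c(1.0, 0.2, 0.3, 1.0), nrow = 2,
                dimnames = list(NULL, c("g1", "g2")))
  tab <- select_loci(lik, loci, fdr = 0.05)
  expect_equal(nrow(tab$loci), 1)
  expect_equal(tab$loci$start, 1L)
  expect_equal(tab$loci$end, 200L)
  expect_equal(unname(tab$likelihood[1, ]), c(1.0, 1.0))
})

test_that("expected false positives follow the independence product over groups", {
  one <- estimate_false_positives(matrix(c(0.6, 0.5), nrow = 1))
  expect_equal(one$expected, 0.2, tolerance = 1e-12)
  ten <- estimate_false_positives(matrix(rep(0.95, 10), ncol = 1))
  expect_equal(ten$expected, 0.5, tolerance = 1e-12)
  expect_equal(ten$percent, 5, tolerance = 1e-12)
  empty <- estimate_false_positives(matrix(numeric(0), 0, 2))
  expect_equal(empty$expected, 0)
})

test_that("expression calls require the likelihood to strictly exceed the cutoff", {
  lik <- matrix(c(0.5, 0.5000001, 0.49), nrow = 1)
  expect_equal(unname(call_expression(lik)[1, ]), c(FALSE, TRUE, FALSE))
})

test_that("segmentation of a small simulated study is reproducible under the seed", {
  arch <- default_archetypes(n_loci = 5L)[1:2]
  genome <- generate_genome(n_chrom = 1L, length = 500000L, seed = 5L)
  libs <- default_library_design(n_wt_groups = 2L, libs_per_group = 2L,
                                 depth = 5e3)
  libs <- libs[libs$is_wild_type, ]
  sim <- simulate_libraries(genome, arch, libs, seed = 5L)
  a <- segment_loci(sim$reads, libs, genome_length = 500000)
  b <- segment_loci(sim$reads, libs, genome_length = 500000)
  expect_identical(a$loci$loci, b$loci$loci)
  expect_identical(a$loci$likelihood, b$loci$likelihood)
})
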