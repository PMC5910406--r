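# Categorical locus features: the confidence-interval binning rule and the
# depth-aware feature categorisers built on it.

test_that("a confidence interval inside one partition takes that partition's label", {
  spec <- bin_spec(c(0.2, 0.8), c("low", "moderate", "high"), "low")
  expect_equal(bin_by_confidence_interval(0.5, 0.3, 0.7, spec), "moderate")
  expect_equal(bin_by_confidence_interval(0.05, 0.01, 0.15, spec), "low")
  expect_equal(bin_by_confidence_interval(0.9, 0.85, 0.99, spec), "high")
})

test_that("an interval crossing one threshold resolves toward the default partition", {
  spec <- bin_spec(c(0.2, 0.8), c("low", "moderate", "high"), "low")
  # crosses 0.2: low touches the default itself -> low
  expect_equal(bin_by_confidence_interval(0.2, 0.1, 0.3, spec), "low")
  # crosses 0.8: moderate is nearer the default than high -> moderate
  expect_equal(bin_by_confidence_interval(0.8, 0.7, 0.9, spec), "moderate")
})

test_that("an interval crossing two thresholds is unannotated", {
  spec <- bin_spec(c(0.2, 0.8), c("low", "moderate", "high"), "low")
  expect_equal(bin_by_confidence_interval(0.5, 0.1, 0.9, spec), "unknown")
})

test_that("binning agrees with brute-force partition enumeration on random intervals", {
  set.seed(7)
  for (i in 1:500) {
    n_thr <- sample(1:4, 1)
    thr <- sort(runif(n_thr))
    labels <- paste0("L", seq_len(n_thr + 1))
    di <- sample(n_thr + 1, 1)
    spec <- bin_spec(thr, labels, labels[di])
    a <- sort(runif(2, -0.1, 1.1))
    got <- bin_by_confidence_interval(mean(a), a[1], a[2], spec)
    want <- oracle_bin(a[1], a[2], thr, labels, di)
    expect_equal(got, want)
  }
})

test_that("repetitiveness is zero for uniquely mapping loci and follows the weighted fraction", {
  r0 <- repetitiveness(c(5, 3, 2), c(1, 1, 1))
  expect_equal(r0$point, 0, tolerance = 1e-12)
  expect_equal(r0$label, "low")
  r5 <- repetitiveness(10, 2)
  expect_equal(r5$point, 0.5, tolerance = 1e-12)
  r4 <- repetitiveness(c(4, 6), c(1, 3))
  expect_equal(r4$point, 0.4, tolerance = 1e-12)
  expect_equal(repetitiveness(integer(0), integer(0))$label, "unknown")
})

test_that("a pure 21-nt locus has a high 21/24 ratio and no reads give unknown", {
  expect_equal(ratio_21_24(100, 0)$label, "high")
  expect_equal(ratio_21_24(0, 100)$label, "low")
  expect_equal(ratio_21_24(0, 0)$label, "unknown")
})

test_that("strand ratio folds symmetrically and balanced loci show no bias", {
  expect_equal(strand_ratio(100, 0)$label, "strong")
  expect_equal(strand_ratio(0, 100)$label, "strong")
  expect_equal(strand_ratio(50, 50)$label, "no")
  expect_equal(strand_ratio(0, 0)$label, "unknown")
})

test_that("wilson interval matches the score interval of prop.test without correction", {
  for (x in c(0, 3, 50, 97)) {
    ci <- wilson_ci(x, 100)
    ref <- stats::prop.test(x, 100, correct = FALSE)$conf.int
    expect_equal(unname(ci["lower"]), ref[1], tolerance = 1e-9)
    expect_equal(unname(ci["upper"]), ref[2], tolerance = 1e-9)
  }
})

test_that("poisson rate interval matches the exact test interval", {
  for (k in c(0, 1, 10, 100)) {
    ci <- poisson_rate_ci(k, 1)
    ref <- stats::poisson.test(k)$conf.int
    expect_equal(unname(ci["lower"]), ref[1], tolerance = 1e-9)
    expect_equal(unname(ci["upper"]), ref[2], tolerance = 1e-9)
  }
})

test_that("tissue specificity thresholds at ten and one expressed groups", {
  expect_equal(tissue_specificity(c(10, 5, 1, 0)),
               c("common", "intermediate", "specific", "specific"))
})

test_that("perfectly 21-nt-registered read starts give a significant phasing p-value", {
  starts <- c(1, 22, 43, 64) + 100
  p <- phasing_pvalue(starts, starts + 20, rep("+", 4), 101, 300)
  expect_lt(p, 0.05)
})

test_that("phasing on a short locus or a single position is not evaluable", {
  expect_true(is.na(phasing_pvalue(c(1, 22), c(21, 42), c("+", "+"), 1, 60)))
  expect_true(is.na(phasing_pvalue(5, 25, "+", 1, 100)))
})

test_that("minus-strand 5' positions use the duplex overhang offset", {
  # minus-strand reads whose (end - 2) positions sit on the register
  ends <- c(23, 44, 65, 86) + 200
  p <- phasing_pvalue(ends - 20, ends, rep("-", 4), 201, 400)
  expect_lt(p, 0.05)
})

test_that("phasing category counts significant wild-type groups", {
  expect_equal(phasing_category(rep(0.01, 6)), "high")
  expect_equal(phasing_category(c(0.01, rep(0.5, 5))), "moderate")
  expect_equal(phasing_category(c(rep(0.5, 3), NA)), "none")
})

test_that("a strong cytosine 5' excess is preferred but three reads are not enough", {
  m <- matrix(c(0, 100, 0, 0), 1, dimnames = list(NULL, c("A", "C", "G", "T")))
  got <- five_prime_preference(m)
  expect_equal(got$preferred[[1]], "C")
  expect_equal(got$indicator$fivep_C, "yes")
  # three all-A reads: P(X >= 3) = 0.51^3 = 0.133 under the background
  m3 <- matrix(c(3, 0, 0, 0), 1, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(five_prime_preference(m3)$preferred[[1]], character(0))
})

test_that("methylation category reflects saturated, absent and beta-sampled cytosines", {
  expect_equal(methylation_category(rep(1, 20))$label, "high")
  expect_equal(methylation_category(numeric(0))$label, "unknown")
  set.seed(5)
  props <- stats::rbeta(50, 8, 2)   # mean 0.8, well above the 0.6 bound
  expect_equal(methylation_category(props, seed = 5)$label, "high")
})

test_that("H3 accumulation uses the exact Poisson interval on the per-base rate", {
  expect_equal(h3_category(0, 100)$label, "none")
  dense <- h3_category(100, 100)
  expect_equal(dense$label, "high")
  expect_equal(dense$lower, qchisq(0.025, 200) / 2 / 100, tolerance = 1e-9)
  expect_equal(dense$upper, qchisq(0.975, 202) / 2 / 100, tolerance = 1e-9)
  # the rate scale is per base: doubling reads and width preserves the point
  expect_equal(h3_category(40, 200)$point, h3_category(20, 100)$point)
})

test_that("histone mark proportion is bounded and uninformative counts are unknown", {
  expect_equal(histone_mark_category(50, 0)$label, "high")
  expect_equal(histone_mark_category(0, 50)$label, "low")
  expect_equal(histone_mark_category(1, 1)$label, "unknown")
  expect_equal(histone_mark_category(0, 0)$label, "unknown")
})

test_that("expression-mode dependency follows the mutant-group FDR selection", {
  lab <- dependency_call(mut_likelihoods = c(1, 1, 0.8),
                         mode = "expression")
  expect_equal(lab, c("independent", "independent", "dependent"))
})

test_that("differential dependency separates lost, kept and unsupported loci", {
  off <- matrix(1000, 3, 10)
  wt <- rbind(rep(100L, 10), rep(100L, 10), rep(0L, 10))
  mut <- rbind(rep(0L, 10), rep(100L, 10), c(1L, rep(0L, 9)))
  lab <- dependency_call(wt_counts = wt, mut_counts = mut,
                         wt_offsets = off, mut_offsets = off)
  expect_equal(lab[1], "dependent")
  expect_equal(lab[2], "independent")
  expect_equal(lab[3], "unknown")
})

test_that("annotation overlap requires at least one shared base and derives promoters upstream", {
  loci <- data.frame(chrom = "chr1", start = c(100L, 600L),
                     end = c(200L, 700L), stringsAsFactors = FALSE)
  sets <- list(te = data.frame(chrom = "chr1", start = 200L, end = 300L,
                               stringsAsFactors = FALSE))
  genes <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                      strand = "+", stringsAsFactors = FALSE)
  ov <- annotation_overlap(loci, sets, genes)
  # locus 1 touches the TE at base 200; locus 2 lies in [500, 999] upstream
  expect_equal(ov$overlap_te, c("yes", "no"))
  expect_equal(ov$overlap_promoter, c("no", "yes"))
})
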