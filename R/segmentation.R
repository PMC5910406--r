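# Locus discovery: read filtering, library scaling, candidate regions,
# heuristic RPKM segmentation, two-component posterior expression model,
# FDR selection and false-positive accounting.

#' Default segmentation parameters
#' @return Named list of segmentation constants (see
#'   \code{\link{default_config}}).
#' @export
segmentation_params <- function() default_config()$segmentation

# TRUE for sequences containing an 11-nt window in which at least
# `max_same` positions are the same base.
is_low_complexity <- function(seqs, window = 11L, max_same = 10L) {
  out <- logical(length(seqs))
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    if (L < window) next
    idx <- which(lens == L)
    chars <- matrix(unlist(strsplit(seqs[idx], "")), ncol = L, byrow = TRUE)
    flag <- rep(FALSE, length(idx))
    for (b in c("A", "C", "G", "T")) {
      ind <- chars == b
      cs <- ind
      for (j in 2:L) cs[, j] <- cs[, j - 1] + ind[, j]
      for (s in 1:(L - window + 1)) {
        e <- s + window - 1L
        wsum <- cs[, e] - (if (s > 1) cs[, s - 1] else 0)
        flag <- flag | (wsum >= max_same)
      }
    }
    out[idx] <- flag
  }
  out
}

#' Filter aligned reads before segmentation
#'
#' Retains reads of 15-30 nt mapping to at most 1000 genomic locations,
#' removes low-complexity reads (an 11-nt window in which at least ten
#' positions are the same base) and reads whose sequence is in the
#' exclusion set (known miRNA/tRNA/rRNA sequences).
#'
#' @param reads Aligned read data.frame.
#' @param exclusion_seqs Character vector of sequences to drop.
#' @param params Segmentation parameter list.
#' @return Filtered read data.frame.
#' @export
filter_reads <- function(reads, exclusion_seqs = character(),
                         params = segmentation_params()) {
  len <- reads$end - reads$start + 1L
  keep <- len >= params$min_len & len <= params$max_len &
    reads$n_hits <= params$max_hits &
    !(reads$sequence %in% exclusion_seqs)
  uniq <- unique(reads$sequence[keep])
  lc <- uniq[is_low_complexity(uniq, params$lc_window, params$lc_max_same)]
  if (length(lc)) keep <- keep & !(reads$sequence %in% lc)
  reads[keep, , drop = FALSE]
}

#' Library scaling factor
#'
#' Depth surrogate: the sum of the lowest 75\% of unique-sequence
#' abundances in the library (abundances sorted ascending, the first
#' \code{ceiling(0.75 n)} summed).
#'
#' @param reads Aligned reads of a single library.
#' @return Positive scaling factor.
#' @export
compute_scaling_factor <- function(reads) {
  if (nrow(reads) == 0)
    srnaloc_error("cannot compute a scaling factor for an empty library",
                  "empty_library")
  # one abundance per unique sequence; multimapping alignment rows of the
  # same sequence carry the same redundant count
  ab <- tapply(reads$count, reads$sequence, max)
  ab <- sort(as.numeric(ab))
  sum(ab[seq_len(ceiling(0.75 * length(ab)))])
}

#' Scaling factors for every library
#' @param reads Aligned reads (all libraries).
#' @param libraries Library metadata data.frame with library_id.
#' @return \code{libraries} with a scaling_factor column appended.
#' @export
compute_scaling_factors <- function(reads, libraries) {
  libraries$scaling_factor <- vapply(libraries$library_id, function(id)
    compute_scaling_factor(reads[reads$library_id == id, , drop = FALSE]),
    1.0)
  libraries
}

reads_to_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chrom,
                         IRanges::IRanges(reads$start, reads$end))
}

#' Candidate sRNA regions
#'
#' Maximal intervals of read-covered bases, pooled over all libraries, such
#' that every internal uncovered gap is shorter than \code{max_gap}: a gap
#' of \code{max_gap} or more nt to which no read aligns in any sample
#' splits regions.
#'
#' @param reads Aligned reads (all libraries pooled).
#' @param max_gap Gap threshold in nt (default 100).
#' @return data.frame with chrom, start, end.
#' @export
find_candidate_regions <- function(reads, max_gap = 100L) {
  gr <- GenomicRanges::reduce(reads_to_granges(reads),
                              min.gapwidth = max_gap)
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

# Centered running mean with window shrinkage at the edges.
run_mean <- function(x, w) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(1L, i - half_l)
  hi <- pmin(n, i + half_r)
  before <- numeric(n)
  before[lo > 1L] <- cs[lo[lo > 1L] - 1L]
  (cs[hi] - before) / (hi - lo + 1L)
}

#' Heuristic RPKM segmentation into candidate loci
#'
#' Within candidate regions and separately for each replicate group, finds
#' sub-intervals whose windowed RPKM (window-smoothed per-base coverage
#' scaled to the group's summed library scaling factors) is at least the
#' threshold, merging hot runs across gaps of at most \code{max_gap} nt of
#' sub-threshold RPKM. Candidates are the de-duplicated union over groups.
#'
#' @param regions Candidate regions from
#'   \code{\link{find_candidate_regions}}.
#' @param reads Filtered aligned reads.
#' @param libraries Library metadata with scaling_factor and
#'   replicate_group.
#' @param params Segmentation parameter list.
#' @return data.frame of candidate loci (chrom, start, end).
#' @export
heuristic_segmentation <- function(regions, reads, libraries,
                                   params = segmentation_params()) {
  if (nrow(regions) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  groups <- unique(libraries$replicate_group)
  region_ir <- split(IRanges::IRanges(regions$start, regions$end),
                     factor(regions$chrom,
                            levels = sort(unique(regions$chrom),
                                          method = "radix")))
  found <- list()
  for (g in groups) {
    libs <- libraries[libraries$replicate_group == g, , drop = FALSE]
    sg <- sum(libs$scaling_factor)
    gr_reads <- reads[reads$library_id %in% libs$library_id, , drop = FALSE]
    if (nrow(gr_reads) == 0 || sg <= 0) next
    rgr <- GenomicRanges::resize(reads_to_granges(gr_reads), 1L,
                                 fix = "start")
    cov <- GenomicRanges::coverage(rgr, weight = gr_reads$count)
    for (chrom in intersect(names(cov), names(region_ir))) {
      # windowed RPKM = reads per window per scaled library size, computed
      # from 5' read-end positions on the whole chromosome, then hot runs
      # restricted to candidate regions and merged across sub-threshold gaps
      x <- as.numeric(cov[[chrom]])
      if (!length(x) || !any(x > 0)) next
      rpkm <- run_mean(x, params$smooth_window) * 1e9 / sg
      hot <- IRanges::reduce(
        IRanges::IRanges(rpkm >= params$rpkm_threshold),
        min.gapwidth = params$max_gap + 1L)
      hot <- IRanges::intersect(hot, region_ir[[chrom]])
      # runs narrower than the smoothing window are below the heuristic's
      # resolution (footprints of isolated reads), not loci
      hot <- hot[IRanges::width(hot) >= params$smooth_window]
      if (!length(hot)) next
      found[[length(found) + 1L]] <- data.frame(
        chrom = chrom, start = IRanges::start(hot),
        end = IRanges::end(hot), stringsAsFactors = FALSE)
    }
  }
  if (!length(found))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, found))
  out <- out[order(out$chrom, out$start, out$end, method = "radix"),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-locus per-library read count matrix
#' @param loci data.frame with chrom, start, end.
#' @param reads Aligned reads.
#' @param libraries Library metadata (defines column order).
#' @return Integer matrix loci x libraries of summed redundant counts of
#'   reads overlapping each locus.
#' @export
count_matrix <- function(loci, reads, libraries) {
  lgr <- loci_to_granges(loci)
  rgr <- reads_to_granges(reads)
  hits <- GenomicRanges::findOverlaps(rgr, lgr)
  m <- matrix(0, nrow(loci), nrow(libraries),
              dimnames = list(NULL, libraries$library_id))
  if (length(hits)) {
    lib <- reads$library_id[S4Vectors::queryHits(hits)]
    cnt <- reads$count[S4Vectors::queryHits(hits)]
    loc <- S4Vectors::subjectHits(hits)
    agg <- tapply(cnt, list(loc, lib), sum)
    rows <- as.integer(rownames(agg))
    cols <- match(colnames(agg), libraries$library_id)
    agg[is.na(agg)] <- 0
    m[rows, cols] <- agg
  }
  m
}

#' Posterior likelihood of expression per locus and replicate group
#'
#' Two-component model on scaled counts: per library the count at a locus
#' is negative binomial with mean \code{theta * width * scaling_factor}.
#' The background rate \code{theta0} is estimated from reads outside
#' locus-scale signal; the expressed rate is the per-locus, per-group
#' maximum-likelihood rate floored at a global expressed-rate floor (the
#' mass-weighted lower quartile of rates among clearly-expressed
#' candidates).
#' The posterior probability of expression is computed by Bayes' rule with
#' the mixing proportion re-estimated over \code{bootstrap_cycles}
#' iterations.
#'
#' @param loci Candidate loci data.frame (chrom, start, end).
#' @param reads Filtered aligned reads.
#' @param libraries Library metadata with scaling_factor, replicate_group.
#' @param regions Candidate regions (background = reads outside these).
#' @param genome_length Total genome length in nt (for the background
#'   rate); inferred from the reads when NULL.
#' @param params Segmentation parameter list.
#' @return Numeric matrix loci x replicate groups of posterior expression
#'   probabilities.
#' @export
posterior_expression_likelihood <- function(loci, reads, libraries, regions,
                                            genome_length = NULL,
                                            params = segmentation_params()) {
  groups <- unique(libraries$replicate_group)
  if (nrow(loci) == 0)
    return(matrix(numeric(0), 0, length(groups),
                  dimnames = list(NULL, groups)))
  if (is.null(genome_length))
    genome_length <- sum(tapply(reads$end, reads$chrom, max)) + 1000
  widths <- loci$end - loci$start + 1
  counts <- count_matrix(loci, reads, libraries)

  # The expressed-rate scale is estimated first and independently of the
  # background, as the count-mass-weighted lower quartile of candidate
  # densities: chance clusters of background reads are locally enriched
  # but carry negligible read mass, so they cannot drag this scale down.
  s_all <- sum(libraries$scaling_factor)
  rate_all <- rowSums(counts) / (widths * s_all)
  mass <- rowSums(counts)
  o <- order(rate_all)
  cw <- cumsum(mass[o])
  floor_all <- rate_all[o][match(TRUE, cw >= 0.25 * sum(mass))]

  # Background territory is then everything not within min_fold of the
  # expressed scale. Excluding only locus-scale signal keeps chance
  # clusters of background reads inside the background estimate; removing
  # every locally enriched window instead would bias the background rate
  # toward zero (every read cluster is "enriched" relative to a mostly
  # empty genome).
  reads_gr <- reads_to_granges(reads)
  loci_gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start, loci$end))
  hotset <- rate_all >= floor_all / params$min_fold
  hot_gr <- GenomicRanges::reduce(loci_gr[hotset])
  l_bg <- max(genome_length -
                sum(as.numeric(GenomicRanges::width(hot_gr))), 1)
  outside <- GenomicRanges::countOverlaps(reads_gr, hot_gr) == 0
  n_bg <- sum(reads$count[outside])
  theta0 <- max(n_bg / (l_bg * s_all), 1e-12)

  # per-locus per-group MLE-like rate (mean-matching, adequate for the
  # floor/posterior construction) and global expressed-rate floor
  sg <- vapply(groups, function(g)
    sum(libraries$scaling_factor[libraries$replicate_group == g]), 1.0)
  names(sg) <- groups
  theta1 <- sapply(groups, function(g) {
    libs <- libraries$library_id[libraries$replicate_group == g]
    rowSums(counts[, libs, drop = FALSE]) / (widths * sg[[g]])
  })
  theta1 <- matrix(theta1, nrow = nrow(loci),
                   dimnames = list(NULL, groups))
  # expressed-component floor: q25 of clearly-enriched candidate rates,
  # weighted by read mass so that isolated low-count blobs (which are
  # locally "enriched" by construction) do not drag the floor down
  group_counts <- sapply(groups, function(g) {
    libs <- libraries$library_id[libraries$replicate_group == g]
    rowSums(counts[, libs, drop = FALSE])
  })
  group_counts <- matrix(group_counts, nrow = nrow(loci))
  clear <- theta1 > params$min_fold * theta0
  theta_floor <- params$min_fold * theta0
  if (any(clear)) {
    rts <- theta1[clear]
    wts <- group_counts[clear]
    o <- order(rts)
    cw <- cumsum(wts[o])
    theta_floor <- max(rts[o][match(TRUE, cw >= 0.25 * sum(wts))],
                       theta_floor)
  }

  size <- params$nb_size
  ll <- function(k, mu) stats::dnbinom(k, mu = pmax(mu, 1e-12),
                                       size = size, log = TRUE)
  l0 <- matrix(0, nrow(loci), length(groups),
               dimnames = list(NULL, groups))
  l1 <- l0
  for (g in groups) {
    libs <- libraries[libraries$replicate_group == g, , drop = FALSE]
    mu1_rate <- pmax(theta1[, g], theta_floor)
    for (j in seq_len(nrow(libs))) {
      k <- counts[, libs$library_id[j]]
      l0[, g] <- l0[, g] + ll(k, theta0 * widths * libs$scaling_factor[j])
      l1[, g] <- l1[, g] + ll(k, mu1_rate * widths * libs$scaling_factor[j])
    }
  }
  post <- matrix(0.5, nrow(loci), length(groups),
                 dimnames = list(NULL, groups))
  pi_g <- rep(0.5, length(groups))
  for (cycle in seq_len(params$bootstrap_cycles)) {
    for (gi in seq_along(groups)) {
      lo <- log((1 - pi_g[gi]) / pi_g[gi]) + l0[, gi] - l1[, gi]
      post[, gi] <- 1 / (1 + exp(lo))
      pi_g[gi] <- min(max(mean(post[, gi]), 1e-6), 1 - 1e-6)
    }
  }
  attr(post, "model") <- list(theta0 = theta0, theta_floor = theta_floor,
                              pi = stats::setNames(pi_g, groups))
  post
}

#' Select loci by per-group false discovery rate
#'
#' Within each replicate group, loci are ordered by descending posterior
#' likelihood and the largest prefix whose mean (1 - likelihood) is at most
#' \code{fdr} is retained. The final map is the union over groups, with
#' overlapping selections merged to their union interval (per-group
#' likelihood of a merged locus is the maximum over its constituents).
#'
#' @param likelihoods Matrix loci x groups of posterior probabilities.
#' @param loci Candidate loci data.frame aligned with the matrix rows.
#' @param fdr Target false discovery rate (default 0.05).
#' @return List of class \code{srna_locus_table}: \code{loci} (data.frame
#'   locus_id, chrom, start, end) and \code{likelihood} (matrix).
#' @export
select_loci <- function(likelihoods, loci, fdr = 0.05) {
  selected <- rep(FALSE, nrow(loci))
  # Ties within a group's likelihood ordering are broken by the total
  # evidence across all groups and then by coordinates, so selection is
  # invariant to the order of the candidate rows.
  evidence <- rowSums(likelihoods)
  for (g in seq_len(ncol(likelihoods))) {
    p <- likelihoods[, g]
    ord <- order(-p, -evidence, loci$chrom, loci$start, method = "radix")
    cm <- cumsum(1 - p[ord]) / seq_along(ord)
    n_keep <- max(c(0L, which(cm <= fdr)))
    if (n_keep > 0) selected[ord[seq_len(n_keep)]] <- TRUE
  }
  idx <- which(selected)
  if (!length(idx))
    return(structure(list(
      loci = data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE),
      likelihood = likelihoods[integer(0), , drop = FALSE]),
      class = "srna_locus_table"))
  sel <- loci[idx, , drop = FALSE]
  sel_lik <- likelihoods[idx, , drop = FALSE]
  gr <- GenomicRanges::GRanges(sel$chrom,
                               IRanges::IRanges(sel$start, sel$end))
  red <- GenomicRanges::reduce(gr)
  red <- GenomicRanges::sort(red)
  ov <- GenomicRanges::findOverlaps(gr, red)
  merged_lik <- matrix(0, length(red), ncol(likelihoods),
                       dimnames = list(NULL, colnames(likelihoods)))
  for (h in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[h]
    j <- S4Vectors::subjectHits(ov)[h]
    merged_lik[j, ] <- pmax(merged_lik[j, ], sel_lik[i, ])
  }
  out <- data.frame(
    locus_id = sprintf("ATSL%06d", seq_along(red)),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red), end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  structure(list(loci = out, likelihood = merged_lik),
            class = "srna_locus_table")
}

#' @export
print.srna_locus_table <- function(x, ...) {
  cat("srna_locus_table:", nrow(x$loci), "loci x",
      ncol(x$likelihood), "replicate groups\n")
  invisible(x)
}

#' Expected false positives among selected loci
#'
#' Assuming independence of the expression likelihood over replicate
#' groups, the expected number of selected loci with no true expression is
#' the sum over loci of the product over groups of (1 - likelihood).
#'
#' @param likelihoods Matrix loci x groups of posterior probabilities for
#'   the selected loci.
#' @return List with \code{expected} (count) and \code{percent}
#'   (100 * expected / n loci).
#' @export
estimate_false_positives <- function(likelihoods) {
  if (nrow(likelihoods) == 0) return(list(expected = 0, percent = 0))
  expected <- sum(apply(1 - likelihoods, 1, prod))
  list(expected = expected,
       percent = 100 * expected / nrow(likelihoods))
}

#' Call expression per locus and replicate group
#'
#' A locus is expressed within a replicate group if its posterior
#' likelihood strictly exceeds the cutoff (default 50\%).
#'
#' @param likelihoods Matrix loci x groups.
#' @param cutoff Probability cutoff (default 0.5).
#' @return Logical matrix of the same shape.
#' @export
call_expression <- function(likelihoods, cutoff = 0.5) {
  likelihoods > cutoff
}

#' Run the full segmentation stage
#'
#' Filters reads, computes scaling factors, finds candidate regions,
#' segments heuristically per replicate group, computes posterior
#' expression likelihoods and selects loci by FDR.
#'
#' @param reads Aligned read data.frame (all libraries).
#' @param libraries Library metadata data.frame.
#' @param params Segmentation parameter list.
#' @param exclusion_seqs Sequences to exclude (miRNA/tRNA/rRNA stand-in).
#' @param genome_length Total genome length (optional).
#' @return List: \code{loci} (srna_locus_table), \code{libraries} (with
#'   scaling factors), \code{candidates}, \code{regions},
#'   \code{false_positives}.
#' @export
segment_loci <- function(reads, libraries, params = segmentation_params(),
                         exclusion_seqs = character(),
                         genome_length = NULL) {
  reads <- filter_reads(reads, exclusion_seqs, params)
  libraries <- compute_scaling_factors(reads, libraries)
  regions <- find_candidate_regions(reads, params$max_gap)
  candidates <- heuristic_segmentation(regions, reads, libraries, params)
  lik <- posterior_expression_likelihood(candidates, reads, libraries,
                                         regions, genome_length, params)
  tab <- select_loci(lik, candidates, params$fdr)
  list(loci = tab, libraries = libraries, candidates = candidates,
       regions = regions,
       false_positives = estimate_false_positives(tab$likelihood))
}
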