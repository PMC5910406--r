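# Independent brute-force oracles and small constructors shared by the
# test files. Oracles are written from the rule definitions, not from the
# package internals, so agreement is evidence rather than tautology.

# Brute-force enumeration of the three-way confidence-interval binning
# rule: locate the partitions touched by lower and upper by linear scan
# over the right-closed partition bounds.
oracle_bin <- function(lower, upper, thresholds, labels, default_index,
                       unknown_label = "unknown") {
  bounds <- c(-Inf, thresholds, Inf)
  locate <- function(v) {
    for (i in seq_len(length(bounds) - 1)) {
      if (v > bounds[i] && v <= bounds[i + 1]) return(i)
    }
    length(bounds) - 1L
  }
  b_lo <- locate(lower)
  b_hi <- locate(upper)
  n_crossed <- b_hi - b_lo
  if (n_crossed == 0) return(labels[b_lo])
  if (n_crossed == 1) {
    if (abs(b_lo - default_index) <= abs(b_hi - default_index))
      return(labels[b_lo])
    return(labels[b_hi])
  }
  unknown_label
}

# Brute-force FDR selection: over all subsets of one group's likelihoods,
# the largest subset whose mean (1 - likelihood) is at most fdr; among
# equally large subsets the one with the largest likelihood sum. Feasible
# for n <= 15.
oracle_select_group <- function(p, fdr) {
  n <- length(p)
  best <- integer(0)
  best_sum <- -Inf
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(idx)) next
    if (mean(1 - p[idx]) <= fdr) {
      if (length(idx) > length(best) ||
          (length(idx) == length(best) && sum(p[idx]) > best_sum)) {
        best <- idx
        best_sum <- sum(p[idx])
      }
    }
  }
  sort(best)
}

# Exhaustive assignment oracle: minimum-cost row -> column assignment by
# enumerating all permutations (k <= 6).
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]), 1.0))
}

# Direct entropy/mutual-information evaluation for NMI.
oracle_nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  info <- 0
  for (i in seq_along(pi_)) for (j in seq_along(pj_)) {
    if (pij[i, j] > 0)
      info <- info + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
  }
  if (h(pi_) == 0 || h(pj_) == 0) {
    return(as.numeric(all(a == a[1]) && all(b == b[1])))
  }
  info / sqrt(h(pi_) * h(pj_))
}

# Minimal aligned-read data.frame constructor.
make_reads <- function(chrom, start, len = 24L, strand = "+", count = 1L,
                       n_hits = 1L, library_id = "lib1",
                       sequence = NULL) {
  n <- max(length(chrom), length(start), length(len), length(count))
  chrom <- rep_len(chrom, n); start <- rep_len(as.integer(start), n)
  len <- rep_len(as.integer(len), n)
  if (is.null(sequence))
    sequence <- vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
            collapse = ""), "")
  data.frame(
    sequence = rep_len(sequence, n), chrom = chrom, start = start,
    end = start + len - 1L, strand = rep_len(strand, n),
    count = rep_len(as.integer(count), n),
    n_hits = rep_len(as.integer(n_hits), n),
    library_id = rep_len(library_id, n), stringsAsFactors = FALSE
  )
}

# Single-group library metadata to pair with make_reads.
make_libraries <- function(library_id = "lib1", replicate_group = "g1",
                           genotype = "WT", is_wild_type = TRUE,
                           depth = 1e4) {
  data.frame(library_id = library_id, replicate_group = replicate_group,
             genotype = genotype, is_wild_type = is_wild_type,
             depth = depth, stringsAsFactors = FALSE)
}
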