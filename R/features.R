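# Per-locus categorical features: the generic confidence-interval binning
# rule, depth-aware binomial/Poisson/bootstrap features, mutant dependency
# calls and annotation overlap.

#' Construct a categorical bin specification
#'
#' @param thresholds Strictly increasing numeric thresholds.
#' @param labels Labels, one more than thresholds. Labels may repeat (e.g.
#'   symmetric strand-bias bins that fold to the same name).
#' @param default Default label (must occur in \code{labels}); when it
#'   occurs more than once, \code{default_index} disambiguates.
#' @param default_index Optional integer index of the default bin.
#' @param unknown_label Label used when no annotation can be recorded.
#' @return List of class \code{bin_spec}.
#' @export
bin_spec <- function(thresholds, labels, default,
                     default_index = match(default, labels),
                     unknown_label = "unknown") {
  if (length(labels) != length(thresholds) + 1)
    srnaloc_error("labels must be one longer than thresholds",
                  "invalid_argument")
  if (is.unsorted(thresholds, strictly = TRUE))
    srnaloc_error("thresholds must be strictly increasing",
                  "invalid_argument")
  if (is.na(default_index))
    srnaloc_error("default label not among labels", "invalid_argument")
  structure(list(thresholds = thresholds, labels = labels,
                 default_index = default_index,
                 unknown_label = unknown_label), class = "bin_spec")
}

as_bin_spec <- function(x) {
  if (inherits(x, "bin_spec")) return(x)
  bin_spec(x$thresholds, x$labels, x$default)
}

# Bin index of a point under right-closed partitions (-Inf, t1], (t1, t2]..
bin_index <- function(x, thresholds) {
  1L + vapply(x, function(v) sum(thresholds < v), 1L)
}

#' Bin an interval estimate into a category
#'
#' The three-way rule for depth-dependent features: if the 95\% confidence
#' interval lies wholly within one partition, the locus gets that
#' partition's label; if the interval crosses exactly one threshold, the
#' locus is assigned to whichever of the two touched partitions is nearer
#' the default partition; if it crosses more than one threshold, no
#' annotation is recorded (the unknown label). A degenerate interval
#' (lower = upper) is treated as a point.
#'
#' @param point Point estimate.
#' @param lower,upper Confidence interval bounds (lower <= upper).
#' @param spec A \code{\link{bin_spec}}.
#' @return A single label.
#' @export
bin_by_confidence_interval <- function(point, lower, upper, spec) {
  spec <- as_bin_spec(spec)
  if (lower > upper)
    srnaloc_error("lower bound exceeds upper bound", "invalid_argument")
  b_lo <- bin_index(lower, spec$thresholds)
  b_hi <- bin_index(upper, spec$thresholds)
  crossed <- b_hi - b_lo
  if (crossed == 0) return(spec$labels[b_lo])
  if (crossed == 1) {
    d <- spec$default_index
    pick <- if (abs(b_lo - d) <= abs(b_hi - d)) b_lo else b_hi
    return(spec$labels[pick])
  }
  spec$unknown_label
}

#' Locus width category
#'
#' Widths (end - start + 1) are split into (0, 50], (50, 2000] and
#' (2000, Inf) nt.
#'
#' @param start,end 1-based inclusive locus coordinates (vectorised).
#' @return Character vector of width labels.
#' @export
width_category <- function(start, end) {
  w <- end - start + 1
  ifelse(w <= 50, "(0,50]", ifelse(w <= 2000, "(50,2000]", "(2000,Inf]"))
}

#' 21/24 ratio category
#'
#' Proportion of 21-22 nt reads among 21-24 nt wild-type reads at the
#' locus, with a Wilson 95\% confidence interval binned by the three-way
#' rule (default category "low"). A zero denominator yields unknown.
#'
#' @param n2122 Redundant count of 21-22 nt reads.
#' @param n2324 Redundant count of 23-24 nt reads.
#' @param spec Bin specification (default from \code{default_config()}).
#' @return List with \code{label}, \code{point}, \code{lower},
#'   \code{upper}.
#' @export
ratio_21_24 <- function(n2122, n2324,
                        spec = as_bin_spec(default_config()$bins$ratio_2124)) {
  spec <- as_bin_spec(spec)
  n <- n2122 + n2324
  if (n == 0)
    return(list(label = spec$unknown_label, point = NA_real_,
                lower = NA_real_, upper = NA_real_))
  ci <- wilson_ci(n2122, n)
  list(label = bin_by_confidence_interval(ci["point"], ci["lower"],
                                          ci["upper"], spec),
       point = unname(ci["point"]), lower = unname(ci["lower"]),
       upper = unname(ci["upper"]))
}

#' Strand ratio category
#'
#' Proportion of wild-type reads on the plus strand with a Wilson 95\%
#' confidence interval binned into five symmetric partitions labelled
#' strong/medium/no/medium/strong (default "no"), so the result is folded
#' about 0.5 by construction. Zero reads yield unknown.
#'
#' @param n_plus,n_minus Redundant counts per strand.
#' @param spec Bin specification.
#' @return List with \code{label}, \code{point}, \code{lower},
#'   \code{upper}.
#' @export
strand_ratio <- function(n_plus, n_minus,
                         spec = as_bin_spec(default_config()$bins$strand)) {
  spec <- as_bin_spec(spec)
  n <- n_plus + n_minus
  if (n == 0)
    return(list(label = spec$unknown_label, point = NA_real_,
                lower = NA_real_, upper = NA_real_))
  ci <- wilson_ci(n_plus, n)
  list(label = bin_by_confidence_interval(ci["point"], ci["lower"],
                                          ci["upper"], spec),
       point = unname(ci["point"]), lower = unname(ci["lower"]),
       upper = unname(ci["upper"]))
}

#' Repetitiveness of a locus
#'
#' R = 1 - (sum_i x_i / m_i) / (sum_i x_i), where x_i is the redundant
#' count of the i-th small RNA at the locus and m_i the number of genomic
#' locations its sequence maps to. R is 0 when every read maps uniquely
#' and approaches 1 for heavily multimapping loci. The confidence interval
#' treats sum(x_i / m_i) as effective successes among n = sum(x_i) trials
#' (Wilson); binned with default "low".
#'
#' @param x Redundant counts per small RNA species.
#' @param m Genomic hit counts per species (same length as x).
#' @param spec Bin specification.
#' @return List with \code{label}, \code{point} (R), \code{lower},
#'   \code{upper} (CI on R).
#' @export
repetitiveness <- function(x, m,
                           spec = as_bin_spec(default_config()$bins$repetitiveness)) {
  spec <- as_bin_spec(spec)
  if (length(x) == 0 || sum(x) == 0)
    return(list(label = spec$unknown_label, point = NA_real_,
                lower = NA_real_, upper = NA_real_))
  stopifnot(length(x) == length(m), all(m >= 1))
  n <- sum(x)
  unique_frac <- sum(x / m)
  r <- 1 - unique_frac / n
  ci <- wilson_ci(unique_frac, n)
  lower <- 1 - unname(ci["upper"])
  upper <- 1 - unname(ci["lower"])
  list(label = bin_by_confidence_interval(r, lower, upper, spec),
       point = r, lower = lower, upper = upper)
}

#' Tissue specificity from wild-type expression calls
#'
#' "common" when expressed (posterior likelihood above the expression
#' cutoff) in at least \code{common_min} wild-type replicate groups,
#' "specific" when in at most \code{specific_max}, "intermediate"
#' otherwise.
#'
#' @param n_expressed_groups Number of wild-type replicate groups calling
#'   the locus expressed (vectorised).
#' @param common_min Minimum group count for "common" (default 10).
#' @param specific_max Maximum group count for "specific" (default 1).
#' @return Character vector of tissue labels.
#' @export
tissue_specificity <- function(n_expressed_groups, common_min = 10L,
                               specific_max = 1L) {
  ifelse(n_expressed_groups >= common_min, "common",
         ifelse(n_expressed_groups <= specific_max, "specific",
                "intermediate"))
}

#' Phasing p-value for one set of reads at a locus
#'
#' Tests whether occupied read 5' positions concentrate on a 21-nt
#' register. 5' positions are the read start on the plus strand and the
#' read end minus 2 on the minus strand (the 2 nt overhang of the duplex).
#' The register is anchored at the first (minimum) occupied position;
#' conditional on the anchor, the remaining occupied positions are uniform
#' under the null, so the count of occupied on-register positions follows
#' a hypergeometric distribution whose upper tail is the p-value.
#'
#' @param starts,ends,strands Read coordinates and strands at the locus.
#' @param locus_start,locus_end Locus interval.
#' @param phase Phase length in nt (default 21).
#' @return p-value in (0, 1]; NA when fewer than 2 occupied positions or
#'   the locus is shorter than 3 phase cycles.
#' @export
phasing_pvalue <- function(starts, ends, strands, locus_start, locus_end,
                           phase = 21L) {
  L <- locus_end - locus_start + 1L
  if (L < 3L * phase) return(NA_real_)
  pos <- ifelse(strands == "+", starts, ends - 2L) - locus_start
  pos <- unique(pos[pos >= 0 & pos < L])
  n <- length(pos)
  if (n < 2) return(NA_real_)
  a <- min(pos)
  rest <- pos[pos != a]
  pop <- L - 1L - a                  # positions strictly greater than a
  k_reg <- (L - 1L - a) %/% phase    # on-register positions above anchor
  x <- sum((rest - a) %% phase == 0)
  # P(X >= x) for X ~ Hypergeometric(pop, k_reg, n - 1)
  stats::phyper(x - 1, k_reg, pop - k_reg, n - 1, lower.tail = FALSE)
}

#' Phasing category over wild-type replicate groups
#'
#' "moderate" when the phasing test is significant at \code{alpha} in at
#' least one wild-type group, "high" when significant in more than
#' \code{high_groups} groups, "none" otherwise.
#'
#' @param pvals Numeric vector of per-group phasing p-values (NAs treated
#'   as non-significant).
#' @param alpha Significance level (default 0.05).
#' @param high_groups Group count above which phasing is "high" (default
#'   5).
#' @return A single label.
#' @export
phasing_category <- function(pvals, alpha = 0.05, high_groups = 5L) {
  sig <- sum(pvals < alpha, na.rm = TRUE)
  if (sig > high_groups) "high" else if (sig >= 1) "moderate" else "none"
}

#' 5' base preference per locus
#'
#' Compares the 5' base composition of 21-24 nt wild-type reads at each
#' locus with the genome-wide composition, one one-sided binomial
#' enrichment test per base, Benjamini-Hochberg adjusted across all loci
#' and bases jointly. A base is preferred when its adjusted p-value is
#' below \code{alpha} and the observed proportion exceeds the background.
#'
#' @param base_counts Matrix loci x 4 (columns A, C, G, T) of redundant
#'   5' base counts from 21-24 nt wild-type reads.
#' @param background Named background probabilities over A/C/G/T.
#' @param alpha Adjusted significance level (default 0.05).
#' @return List: \code{preferred} (list of character vectors per locus,
#'   at most 3 bases) and \code{indicator} (data.frame of yes/no columns
#'   fivep_A..fivep_T).
#' @export
five_prime_preference <- function(base_counts,
                                  background = c(A = 0.51, C = 0.09,
                                                 G = 0.17, T = 0.22),
                                  alpha = 0.05) {
  bases <- c("A", "C", "G", "T")
  base_counts <- as.matrix(base_counts[, bases, drop = FALSE])
  n <- rowSums(base_counts)
  praw <- matrix(1, nrow(base_counts), 4, dimnames = list(NULL, bases))
  for (b in bases) {
    has <- n > 0
    praw[has, b] <- stats::pbinom(base_counts[has, b] - 1, n[has],
                                  background[[b]], lower.tail = FALSE)
  }
  padj <- matrix(stats::p.adjust(praw, method = "BH"), nrow(praw),
                 dimnames = dimnames(praw))
  obs_gt <- sweep(base_counts, 1, pmax(n, 1), "/") >
    matrix(background[bases], nrow(base_counts), 4, byrow = TRUE)
  hit <- padj < alpha & obs_gt & n > 0
  preferred <- apply(hit, 1, function(r) bases[r], simplify = FALSE)
  ind <- as.data.frame(ifelse(hit, "yes", "no"), stringsAsFactors = FALSE)
  names(ind) <- paste0("fivep_", bases)
  list(preferred = preferred, indicator = ind)
}

#' Methylation category for one locus and context
#'
#' Percentile bootstrap (B resamples, seeded) of the mean per-cytosine
#' methylation proportion over the cytosines of the given context
#' overlapping the locus, binned by the three-way rule (default "low").
#' Loci without cytosines in the context are unknown.
#'
#' @param proportions Per-cytosine methylation proportions at the locus.
#' @param spec Bin specification.
#' @param B Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List with \code{label}, \code{point}, \code{lower},
#'   \code{upper}.
#' @export
methylation_category <- function(proportions,
                                 spec = as_bin_spec(default_config()$bins$CpG),
                                 B = 1000L, seed = 1L) {
  spec <- as_bin_spec(spec)
  n <- length(proportions)
  if (n == 0)
    return(list(label = spec$unknown_label, point = NA_real_,
                lower = NA_real_, upper = NA_real_))
  m <- mean(proportions)
  if (n == 1 || stats::var(proportions) == 0) {
    lo <- hi <- m
  } else {
    set.seed(seed)
    boots <- rowMeans(matrix(proportions[sample.int(n, n * B,
                                                    replace = TRUE)],
                             nrow = B))
    qs <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(label = bin_by_confidence_interval(m, lo, hi, spec),
       point = m, lower = lo, upper = hi)
}

#' Histone (H3) accumulation category
#'
#' Rate of H3 ChIP reads per base at the locus with an exact Poisson 95\%
#' confidence interval, binned by the three-way rule with default "none".
#' Thresholds are expressed on the per-base rate scale; because the
#' binning rule is invariant to monotone transforms this is equivalent to
#' binning the log rate with log-scale thresholds.
#'
#' @param k Number of H3 reads overlapping the locus.
#' @param width Locus width in nt.
#' @param spec Bin specification (rate-scale thresholds).
#' @return List with \code{label}, \code{point}, \code{lower},
#'   \code{upper} (rates per base).
#' @export
h3_category <- function(k, width,
                        spec = as_bin_spec(default_config()$bins$H3)) {
  spec <- as_bin_spec(spec)
  ci <- poisson_rate_ci(k, width)
  list(label = bin_by_confidence_interval(ci["point"], ci["lower"],
                                          ci["upper"], spec),
       point = unname(ci["point"]), lower = unname(ci["lower"]),
       upper = unname(ci["upper"]))
}

#' Histone mark category relative to H3
#'
#' Proportion of mark reads among mark + H3 reads overlapping the locus,
#' assumed binomial, with a Wilson 95\% confidence interval binned by the
#' three-way rule (default "low"). No overlapping reads of either set
#' yields unknown.
#'
#' @param k_mark,k_h3 Overlapping read counts for the mark and for H3.
#' @param spec Bin specification.
#' @return List with \code{label}, \code{point}, \code{lower},
#'   \code{upper}.
#' @export
histone_mark_category <- function(k_mark, k_h3,
                                  spec = as_bin_spec(default_config()$bins$mark)) {
  spec <- as_bin_spec(spec)
  n <- k_mark + k_h3
  if (n == 0)
    return(list(label = spec$unknown_label, point = NA_real_,
                lower = NA_real_, upper = NA_real_))
  ci <- wilson_ci(k_mark, n)
  list(label = bin_by_confidence_interval(ci["point"], ci["lower"],
                                          ci["upper"], spec),
       point = unname(ci["point"]), lower = unname(ci["lower"]),
       upper = unname(ci["upper"]))
}

# Constrained NB log-likelihood fit for the differential dependency model:
# counts ~ NB(theta * w * s) in WT and NB(delta * theta * w * s) in the
# mutant; maximised over theta > 0 and delta within [dlo, dhi].
nb_loss_loglik <- function(k_wt, off_wt, k_mut, off_mut, dlo, dhi, size) {
  nll <- function(par) {
    theta <- exp(par[1])
    delta <- dlo + (dhi - dlo) * stats::plogis(par[2])
    -sum(stats::dnbinom(k_wt, mu = pmax(theta * off_wt, 1e-12),
                        size = size, log = TRUE)) -
      sum(stats::dnbinom(k_mut, mu = pmax(delta * theta * off_mut, 1e-12),
                         size = size, log = TRUE))
  }
  start_theta <- log(max(sum(k_wt) / sum(off_wt), 1e-8))
  fit <- stats::optim(c(start_theta, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 500))
  -fit$value
}

#' Mutant dependency call
#'
#' Two modes. In \code{mode = "expression"} (DCL2/3/4-style), loci selected
#' as expressed in the mutant replicate group at the given FDR (the
#' cumulative-mean rule on the mutant-group posterior likelihoods) are
#' independent; all others are dependent. In \code{mode = "differential"}
#' (RDR2/PolIV/PolV-style), a per-locus posterior of loss of expression is
#' computed from a constrained negative binomial comparison: the loss
#' model allows the mutant/wild-type rate ratio delta in [0, 0.5], the
#' no-loss model delta in (0.5, 2]; with equal prior mass the posterior of
#' loss follows from the two profile likelihoods. Loci selected at the FDR
#' on the loss posterior are dependent, those selected on the no-loss
#' posterior are independent, the remainder unknown.
#'
#' @param wt_counts Matrix loci x WT libraries of counts (differential
#'   mode).
#' @param mut_counts Matrix loci x mutant libraries of counts.
#' @param wt_offsets,mut_offsets Per-library exposure offsets
#'   (width-independent scaling factors times locus width), matrices
#'   matching the count matrices.
#' @param mut_likelihoods Posterior expression likelihoods of the mutant
#'   group (expression mode), one per locus.
#' @param mode "expression" or "differential".
#' @param fdr Target FDR (default 0.05).
#' @param nb_size NB dispersion (default 5).
#' @return Character vector of labels per locus: dependent / independent /
#'   unknown ("expression" mode never returns unknown).
#' @export
dependency_call <- function(wt_counts = NULL, mut_counts = NULL,
                            wt_offsets = NULL, mut_offsets = NULL,
                            mut_likelihoods = NULL,
                            mode = c("differential", "expression"),
                            fdr = 0.05, nb_size = 5) {
  mode <- match.arg(mode)
  if (mode == "expression") {
    p <- mut_likelihoods
    ord <- order(p, decreasing = TRUE)
    cm <- cumsum(1 - p[ord]) / seq_along(ord)
    n_keep <- max(c(0L, which(cm <= fdr)))
    lab <- rep("dependent", length(p))
    if (n_keep > 0) lab[ord[seq_len(n_keep)]] <- "independent"
    return(lab)
  }
  n <- nrow(wt_counts)
  post_loss <- numeric(n)
  for (l in seq_len(n)) {
    kw <- wt_counts[l, ]; km <- mut_counts[l, ]
    ow <- wt_offsets[l, ]; om <- mut_offsets[l, ]
    if (sum(kw) + sum(km) == 0) { post_loss[l] <- 0.5; next }
    ll_loss <- nb_loss_loglik(kw, ow, km, om, 0, 0.5, nb_size)
    ll_keep <- nb_loss_loglik(kw, ow, km, om, 0.5, 2, nb_size)
    post_loss[l] <- 1 / (1 + exp(ll_keep - ll_loss))
  }
  lab <- rep("unknown", n)
  sel <- function(p) {
    ord <- order(p, decreasing = TRUE)
    cm <- cumsum(1 - p[ord]) / seq_along(ord)
    n_keep <- max(c(0L, which(cm <= fdr)))
    if (n_keep > 0) ord[seq_len(n_keep)] else integer(0)
  }
  s_dep <- sel(post_loss)
  s_ind <- sel(1 - post_loss)
  # a locus admitted by both FDR selections is resolved by its posterior
  both <- intersect(s_dep, s_ind)
  s_dep <- setdiff(s_dep, both[post_loss[both] <= 0.5])
  s_ind <- setdiff(s_ind, both[post_loss[both] > 0.5])
  lab[s_dep] <- "dependent"
  lab[setdiff(s_ind, s_dep)] <- "independent"
  lab
}

#' Annotation overlap indicators
#'
#' A locus overlaps a feature type when at least one base overlaps.
#' Promoters are derived strand-aware as the 500 nt upstream of gene
#' starts.
#'
#' @param loci Locus data.frame (chrom, start, end).
#' @param annotation_sets Named list of GRanges (or data.frames with
#'   chrom/start/end) keyed by feature type.
#' @param genes GRanges (or data.frame) of genes with strand, used to
#'   derive promoters; NULL skips the promoter column.
#' @param promoter_width Upstream extent in nt (default 500).
#' @return data.frame of yes/no columns named overlap_<type>.
#' @export
annotation_overlap <- function(loci, annotation_sets, genes = NULL,
                               promoter_width = 500L) {
  lgr <- loci_to_granges(loci)
  as_gr <- function(x) {
    if (inherits(x, "GRanges")) return(x)
    GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start, x$end),
      strand = if (!is.null(x$strand) &&
                   all(x$strand %in% c("+", "-"))) x$strand else "*")
  }
  out <- data.frame(row.names = seq_len(nrow(loci)))
  for (type in names(annotation_sets)) {
    g <- as_gr(annotation_sets[[type]])
    ov <- GenomicRanges::countOverlaps(lgr, g, ignore.strand = TRUE) > 0
    out[[paste0("overlap_", type)]] <- ifelse(ov, "yes", "no")
  }
  if (!is.null(genes)) {
    ggr <- as_gr(genes)
    prom <- GenomicRanges::promoters(ggr, upstream = promoter_width,
                                     downstream = 0)
    prom <- GenomicRanges::restrict(prom, start = 1L)
    prom <- prom[GenomicRanges::width(prom) > 0]
    ov <- GenomicRanges::countOverlaps(lgr, prom, ignore.strand = TRUE) > 0
    out$overlap_promoter <- ifelse(ov, "yes", "no")
  }
  out
}
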