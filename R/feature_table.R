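# Assembles the complete per-locus categorical feature table from the
# segmentation output and the external data sets.

#' Compute the per-locus feature table
#'
#' Annotates every selected locus with the full set of categorical
#' features: width bin, overlap with long-RNA expression loci, phasing,
#' 21/24 ratio, tissue ubiquity, repetitiveness, strand ratio, DCL2/3/4 and
#' RDR2/PolIV/PolV dependencies, methylation per context, H3 accumulation,
#' histone mark levels, 5' base preference indicators, and annotation
#' overlap indicators. Every locus receives a value for every feature;
#' "unknown" is an explicit category.
#'
#' @param locus_table \code{srna_locus_table} from \code{segment_loci}.
#' @param reads Filtered aligned reads (all libraries).
#' @param libraries Library metadata with scaling_factor, replicate_group,
#'   genotype, is_wild_type.
#' @param annotations Named list of annotation interval sets (data.frames
#'   or GRanges); a \code{gene} entry also drives promoter derivation and
#'   an \code{expression} entry the long-RNA overlap feature.
#' @param methylation Per-cytosine methylation data.frame.
#' @param chip Named list of ChIP read data.frames; must contain H3.
#' @param config Resolved run configuration (see
#'   \code{\link{default_config}}).
#' @param mutant_map Named list mapping dependency feature names to the
#'   genotype of the corresponding mutant replicate group.
#' @return data.frame: locus_id plus one column per feature.
#' @export
compute_feature_table <- function(locus_table, reads, libraries,
                                  annotations = list(),
                                  methylation = NULL, chip = NULL,
                                  config = default_config(),
                                  mutant_map = list(
                                    dcl234 = "dcl234", rdr2 = "rdr2",
                                    polIV = "polIV", polV = "polV")) {
  loci <- locus_table$loci
  lik <- locus_table$likelihood
  n <- nrow(loci)
  fcfg <- config$features
  bins <- config$bins
  lgr <- loci_to_granges(loci)

  wt_libs <- libraries$library_id[libraries$is_wild_type]
  wt_groups <- unique(libraries$replicate_group[libraries$is_wild_type])
  wt_reads <- reads[reads$library_id %in% wt_libs, , drop = FALSE]
  wt_gr <- reads_to_granges(wt_reads)
  ov <- GenomicRanges::findOverlaps(wt_gr, lgr)
  by_locus <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))

  out <- data.frame(locus_id = loci$locus_id, stringsAsFactors = FALSE)
  out$width <- width_category(loci$start, loci$end)

  # expression overlap with external long-RNA loci
  out$expression <- if (!is.null(annotations$expression)) {
    annotation_overlap(loci,
                       annotations["expression"])$overlap_expression
  } else rep("no", n)

  # tissue ubiquity from wild-type expression calls
  expr_calls <- call_expression(
    lik[, intersect(colnames(lik), wt_groups), drop = FALSE],
    config$segmentation$expression_cutoff)
  out$tissue <- tissue_specificity(rowSums(expr_calls),
                                   fcfg$tissue_common_min,
                                   fcfg$tissue_specific_max)

  # read-derived features
  ratio_lab <- character(n); strand_lab <- character(n)
  rep_lab <- character(n); phase_lab <- character(n)
  base_counts <- matrix(0, n, 4,
                        dimnames = list(NULL, c("A", "C", "G", "T")))
  ratio_spec <- as_bin_spec(bins$ratio_2124)
  strand_spec <- as_bin_spec(bins$strand)
  rep_spec <- as_bin_spec(bins$repetitiveness)
  wt_len <- wt_reads$end - wt_reads$start + 1L
  wt_fp <- substr(wt_reads$sequence, 1, 1)
  for (l in seq_len(n)) {
    idx <- by_locus[[as.character(l)]]
    if (is.null(idx)) idx <- integer(0)
    r <- wt_reads[idx, , drop = FALSE]
    len <- wt_len[idx]
    ratio_lab[l] <- ratio_21_24(
      sum(r$count[len %in% 21:22]), sum(r$count[len %in% 23:24]),
      ratio_spec)$label
    strand_lab[l] <- strand_ratio(sum(r$count[r$strand == "+"]),
                                  sum(r$count[r$strand == "-"]),
                                  strand_spec)$label
    if (nrow(r)) {
      sp <- tapply(seq_len(nrow(r)), r$sequence, function(i)
        c(sum(r$count[i]), r$n_hits[i][1]))
      xm <- do.call(rbind, sp)
      rep_lab[l] <- repetitiveness(xm[, 1], xm[, 2], rep_spec)$label
    } else {
      rep_lab[l] <- rep_spec$unknown_label
    }
    el <- idx[len %in% 21:24]
    if (length(el)) {
      tab <- tapply(wt_reads$count[el], wt_fp[el], sum)
      base_counts[l, names(tab)] <- tab
    }
    # phasing per wild-type replicate group
    pvals <- vapply(wt_groups, function(g) {
      libs <- libraries$library_id[libraries$replicate_group == g]
      rg <- r[r$library_id %in% libs, , drop = FALSE]
      if (nrow(rg) == 0) return(NA_real_)
      phasing_pvalue(rg$start, rg$end, rg$strand, loci$start[l],
                     loci$end[l], fcfg$phase_length)
    }, 1.0)
    phase_lab[l] <- phasing_category(pvals, fcfg$phasing_alpha,
                                     fcfg$phasing_high_groups)
  }
  out$phasing <- phase_lab
  out$ratio_2124 <- ratio_lab
  out$repetitiveness <- rep_lab
  out$strand <- strand_lab

  # 5' base preference against the genome-wide wild-type composition
  elig <- wt_len >= 21 & wt_len <= 24
  bg_tab <- tapply(wt_reads$count[elig], wt_fp[elig], sum)
  bg <- fcfg$background_five_prime
  if (length(bg_tab)) {
    observed <- stats::setNames(rep(0, 4), c("A", "C", "G", "T"))
    observed[names(bg_tab)] <- bg_tab
    if (sum(observed) > 0) bg <- observed / sum(observed)
  }
  fp <- five_prime_preference(base_counts, bg, fcfg$fivep_alpha)
  out <- cbind(out, fp$indicator)

  # dependency features
  mut_groups <- unique(libraries$replicate_group[!libraries$is_wild_type])
  widths <- loci$end - loci$start + 1
  all_counts <- count_matrix(loci, reads, libraries)
  offsets <- outer(widths, libraries$scaling_factor)
  colnames(offsets) <- libraries$library_id
  for (feat in names(mutant_map)) {
    genotype <- mutant_map[[feat]]
    grp <- unique(libraries$replicate_group[libraries$genotype == genotype])
    if (!length(grp) || !all(grp %in% colnames(lik))) {
      out[[feat]] <- rep("unknown", n)
      next
    }
    if (feat == "dcl234") {
      out[[feat]] <- dependency_call(
        mut_likelihoods = lik[, grp[1]], mode = "expression",
        fdr = config$segmentation$fdr)
    } else {
      mut_libs <- libraries$library_id[libraries$genotype == genotype]
      out[[feat]] <- dependency_call(
        wt_counts = all_counts[, wt_libs, drop = FALSE],
        mut_counts = all_counts[, mut_libs, drop = FALSE],
        wt_offsets = offsets[, wt_libs, drop = FALSE],
        mut_offsets = offsets[, mut_libs, drop = FALSE],
        mode = "differential", fdr = config$segmentation$fdr,
        nb_size = config$segmentation$nb_size)
    }
  }

  # methylation per context
  if (!is.null(methylation)) {
    for (ctx in c("CpG", "CHG", "CHH")) {
      spec <- as_bin_spec(bins[[ctx]])
      mc <- methylation[methylation$context == ctx, , drop = FALSE]
      mgr <- GenomicRanges::GRanges(mc$chrom,
                                    IRanges::IRanges(mc$pos, mc$pos))
      mov <- GenomicRanges::findOverlaps(mgr, lgr)
      by_loc <- split(S4Vectors::queryHits(mov),
                      S4Vectors::subjectHits(mov))
      lab <- character(n)
      for (l in seq_len(n)) {
        idx <- by_loc[[as.character(l)]]
        props <- if (is.null(idx)) numeric(0) else mc$proportion[idx]
        lab[l] <- methylation_category(
          props, spec, B = fcfg$meth_bootstrap,
          seed = derive_seed(config$seed, paste0("meth_", ctx, "_", l))
        )$label
      }
      out[[ctx]] <- lab
    }
  } else {
    out$CpG <- out$CHG <- out$CHH <- rep("unknown", n)
  }

  # histone accumulation and marks
  if (!is.null(chip) && "H3" %in% names(chip)) {
    h3_gr <- GenomicRanges::GRanges(
      chip$H3$chrom, IRanges::IRanges(chip$H3$start, chip$H3$end))
    k_h3 <- GenomicRanges::countOverlaps(lgr, h3_gr)
    h3_spec <- as_bin_spec(bins$H3)
    out$H3 <- vapply(seq_len(n), function(l)
      h3_category(k_h3[l], widths[l], h3_spec)$label, "")
    mark_spec <- as_bin_spec(bins$mark)
    for (mark in setdiff(names(chip), "H3")) {
      mgr <- GenomicRanges::GRanges(
        chip[[mark]]$chrom,
        IRanges::IRanges(chip[[mark]]$start, chip[[mark]]$end))
      k_m <- GenomicRanges::countOverlaps(lgr, mgr)
      out[[mark]] <- vapply(seq_len(n), function(l)
        histone_mark_category(k_m[l], k_h3[l], mark_spec)$label, "")
    }
  }

  # annotation overlap indicators (held out from MCA by default)
  ann_sets <- annotations[setdiff(names(annotations), "expression")]
  if (length(ann_sets) || !is.null(annotations$gene)) {
    ov_df <- annotation_overlap(loci, ann_sets, genes = annotations$gene)
    out <- cbind(out, ov_df)
  }
  rownames(out) <- NULL
  out
}
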