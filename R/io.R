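# Readers/writers for the pipeline's file contracts. Internal coordinates
# are 1-based inclusive throughout; BED is emitted/consumed 0-based
# half-open with the conversion done by rtracklayer at a single point.

ALIGNMENT_COLS <- c("sequence", "chrom", "start", "end", "strand", "count",
                    "n_hits", "library_id")

#' Read an aligned small RNA read table
#'
#' Reads the tab-separated alignment contract: one row per read stack with
#' columns sequence, chrom, start, end (1-based inclusive), strand (+/-),
#' count (redundant sequenced copies), n_hits (genomic locations for the
#' sequence) and library_id.
#'
#' @param path Path to a TSV file with a header row.
#' @return data.frame of typed aligned reads.
#' @export
read_alignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(ALIGNMENT_COLS, names(df))
  if (length(missing))
    srnaloc_error(paste("alignment table missing column(s):",
                        paste(missing, collapse = ", ")), "format_error")
  df <- df[, ALIGNMENT_COLS]
  validate_alignments(df)
  df
}

validate_alignments <- function(df) {
  bad <- which(df$end < df$start)
  if (length(bad))
    srnaloc_error(paste0("end < start at row(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "validation_error")
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    srnaloc_error(paste0("invalid strand (must be + or -) at row(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "validation_error")
  bad <- which(df$n_hits < 1 | df$count < 1)
  if (length(bad))
    srnaloc_error(paste0("count and n_hits must be >= 1; bad row(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "validation_error")
  invisible(df)
}

#' Write an aligned read table
#' @param reads data.frame of aligned reads.
#' @param path Output TSV path.
#' @export
write_alignments <- function(reads, path) {
  utils::write.table(reads[, ALIGNMENT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a locus table to GRanges
#' @param loci data.frame with chrom, start, end (1-based inclusive) and
#'   optionally locus_id.
#' @return GRanges with locus_id in mcols when present.
#' @export
loci_to_granges <- function(loci) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end)
  )
  if (!is.null(loci$locus_id)) S4Vectors::mcols(gr)$locus_id <- loci$locus_id
  gr
}

#' Write selected loci as BED6
#'
#' Internal 1-based inclusive intervals are emitted as 0-based half-open
#' BED records; the name column carries the locus id. Reading the file back
#' with \code{\link{read_loci_bed}} restores the internal coordinates
#' exactly.
#'
#' @param loci data.frame with locus_id, chrom, start, end.
#' @param path Output BED path.
#' @export
write_loci_bed <- function(loci, path) {
  gr <- loci_to_granges(loci)
  names(gr) <- loci$locus_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read loci from a BED file
#' @param path BED path (0-based half-open on disk).
#' @return data.frame with locus_id, chrom, start, end (1-based inclusive).
#' @export
read_loci_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(
    locus_id = if (!is.null(gr$name)) gr$name else
      sprintf("L%06d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Map raw annotation types onto the classes the feature stage consumes.
annotation_class <- function(type) {
  gene_like <- c("gene", "ncRNA", "pseudogene", "rRNA", "tRNA")
  te_prefix <- c("DNA", "LINE", "LTR", "RC", "RathE", "SINE")
  vapply(type, function(t) {
    if (t %in% gene_like) return("gene")
    if (any(startsWith(t, te_prefix))) return("TE")
    if (t %in% c("IR", "inverted_repeat")) return("IR")
    if (t %in% c("NAT", "lincRNA", "easiRNA", "mobile", "expression"))
      return(t)
    "custom"
  }, "")
}

#' Read genomic annotations
#'
#' Accepts GFF3 (type taken from the GFF type column) or BED (type taken
#' from the name column). Returns interval sets keyed by raw feature type;
#' unknown types pass through as custom categories.
#'
#' @param path GFF3 (.gff/.gff3) or BED (.bed) file.
#' @return Named list of GRanges keyed by feature type; empty list for an
#'   empty file.
#' @export
read_annotations <- function(path) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  gr <- tryCatch(
    if (is_gff) rtracklayer::import.gff3(path) else
      rtracklayer::import.bed(path),
    error = function(e) GenomicRanges::GRanges()
  )
  if (length(gr) == 0) return(list())
  type <- if (is_gff) as.character(gr$type) else as.character(gr$name)
  # radix-sorted levels keep the set order independent of the locale
  sets <- split(gr, factor(type, levels = sort(unique(type),
                                               method = "radix")))
  out <- stats::setNames(lapply(names(sets), function(t) {
    g <- sets[[t]]
    S4Vectors::mcols(g) <- NULL
    g
  }), names(sets))
  unknown <- names(out)[annotation_class(names(out)) == "custom"]
  if (length(unknown))
    message("annotation types passed through as custom categories: ",
            paste(unknown, collapse = ", "))
  out
}

#' Write annotation sets as GFF3
#' @param sets Named list of data.frames (chrom, start, end, strand, type)
#'   or a single such data.frame.
#' @param path Output GFF3 path.
#' @export
write_annotations_gff3 <- function(sets, path) {
  if (is.data.frame(sets)) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s)
    s[, c("chrom", "start", "end", "strand", "type")]))
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$source <- "srnaloc"
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read per-cytosine methylation proportions
#'
#' @param path TSV with columns chrom, pos, context (CpG/CHG/CHH),
#'   proportion (in [0, 1]) and coverage.
#' @return data.frame of typed methylation records.
#' @export
read_methylation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "context", "proportion", "coverage")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    srnaloc_error(paste("methylation table missing column(s):",
                        paste(missing, collapse = ", ")), "format_error")
  bad <- which(df$proportion < 0 | df$proportion > 1)
  if (length(bad))
    srnaloc_error(paste0("methylation proportion outside [0, 1] at row(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "validation_error")
  bad <- which(!df$context %in% c("CpG", "CHG", "CHH"))
  if (length(bad))
    srnaloc_error(paste0("unknown methylation context at row(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")),
                  "validation_error")
  df[, needed]
}

#' Write a methylation table
#' @param meth data.frame of methylation records.
#' @param path Output TSV path.
#' @export
write_methylation <- function(meth, path) {
  utils::write.table(meth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write ChIP reads as BED
#' @param reads data.frame with chrom, start, end, strand.
#' @param path Output BED path.
#' @export
write_chip_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start, reads$end),
    strand = reads$strand
  )
  names(gr) <- sprintf("read%06d", seq_along(gr))
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read ChIP reads from BED
#' @param path BED path.
#' @return data.frame with chrom, start, end, strand (1-based inclusive).
#' @export
read_chip_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write / read a per-locus feature table
#' @param ft data.frame, locus_id plus categorical feature columns.
#' @param path TSV path.
#' @export
write_feature_table <- function(ft, path) {
  df <- as.data.frame(lapply(ft, as.character), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read and resolve a run configuration
#'
#' Reads a YAML configuration, fills in defaults for unset values, and
#' returns the resolved list. \code{default_config()} documents every
#' tunable.
#'
#' @param path YAML file path, or NULL for defaults only.
#' @return Named list configuration.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Default run configuration
#'
#' Segmentation constants follow the published procedure (15-30 nt size
#' selection, 1000-hit cap, 11-nt/10-same-base low-complexity rule, 100 nt
#' gap, RPKM threshold 1000, FDR 0.05, 50\% expression cutoff, 3 bootstrap
#' cycles). Bin thresholds are calibrated on the synthetic archetypes and
#' documented in the methods vignette.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(n_chrom = 2L, length = 10000000L),
    simulate = list(n_loci = 200L, background_rate = 0.005,
                    n_wt_groups = 10L, libs_per_group = 3L, depth = 2e4),
    segmentation = list(
      min_len = 15L, max_len = 30L, max_hits = 1000L,
      lc_window = 11L, lc_max_same = 10L, max_gap = 100L,
      rpkm_threshold = 1000, smooth_window = 50L,
      fdr = 0.05, expression_cutoff = 0.5, bootstrap_cycles = 3L,
      nb_size = 5, min_fold = 3
    ),
    bins = list(
      ratio_2124 = list(thresholds = c(0.2, 0.8),
                        labels = c("low", "moderate", "high"),
                        default = "low"),
      repetitiveness = list(thresholds = c(0.3, 0.7),
                            labels = c("low", "moderate", "high"),
                            default = "low"),
      strand = list(thresholds = c(0.1, 0.35, 0.65, 0.9),
                    labels = c("strong", "medium", "no", "medium",
                               "strong"),
                    default = "no"),
      CpG = list(thresholds = c(0.2, 0.6),
                 labels = c("low", "moderate", "high"), default = "low"),
      CHG = list(thresholds = c(0.4), labels = c("low", "high"),
                 default = "low"),
      CHH = list(thresholds = c(0.4), labels = c("low", "high"),
                 default = "low"),
      H3 = list(thresholds = c(0.02, 0.1, 0.25),
                labels = c("none", "low", "moderate", "high"),
                default = "none"),
      mark = list(thresholds = c(0.3, 0.7),
                  labels = c("low", "moderate", "high"), default = "low")
    ),
    features = list(
      tissue_common_min = 10L, tissue_specific_max = 1L,
      phasing_alpha = 0.05, phasing_high_groups = 5L, phase_length = 21L,
      fivep_alpha = 0.05, meth_bootstrap = 1000L,
      background_five_prime = c(A = 0.51, C = 0.09, G = 0.17, T = 0.22)
    ),
    classification = list(
      held_out = c("overlap_gene", "overlap_promoter", "overlap_TE",
                   "overlap_IR", "overlap_NAT", "overlap_lincRNA",
                   "overlap_easiRNA", "overlap_mobile"),
      k_range = 1:6, dims = NULL, stability_B = 25L, gap_B = 25L,
      kmeans_restarts = 25L, fixed_k = NULL
    )
  )
}

#' Write the resolved configuration as YAML
#' @param cfg Configuration list.
#' @param path Output YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
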