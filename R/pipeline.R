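# Orchestration: simulate -> segment -> annotate -> classify -> report,
# all stages communicating through files in a run directory.

#' Run the full pipeline
#'
#' Executes the stages in order inside \code{outdir}, writing each stage's
#' outputs as TSV/BED/GFF3 plus a manifest (resolved config echo, seeds
#' and file checksums). Stages whose outputs already exist are skipped
#' unless \code{force}, so a run can be resumed or a single stage redone.
#'
#' @param config Resolved configuration list (see
#'   \code{\link{default_config}}) or a YAML path.
#' @param outdir Run directory (created if needed).
#' @param stages Stages to run, subset of simulate/segment/annotate/
#'   classify/report, in pipeline order.
#' @param force Re-run stages whose outputs exist (default FALSE).
#' @return Invisibly, a list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(config = default_config(), outdir = "srnaloc_run",
                         stages = c("simulate", "segment", "annotate",
                                    "classify", "report"),
                         force = FALSE) {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(outdir, ...)
  write_config(config, path("config_resolved.yaml"))
  res <- list(config = config)

  if ("simulate" %in% stages &&
      (force || !file.exists(path("alignments.tsv")))) {
    genome <- generate_genome(config$genome$n_chrom, config$genome$length,
                              config$seed)
    groups <- default_library_design(config$simulate$n_wt_groups,
                                     config$simulate$libs_per_group,
                                     config$simulate$depth)
    arch <- default_archetypes(
      config$simulate$n_loci,
      wt_groups = unique(groups$replicate_group[groups$is_wild_type]))
    sim <- simulate_libraries(genome, arch, groups, config$seed,
                              config$simulate$background_rate)
    meth <- simulate_methylation(genome, sim$truth, arch, config$seed)
    chip <- simulate_chip(genome, sim$truth, arch, config$seed)
    anns <- simulate_annotations(sim$truth, arch)
    write_alignments(sim$reads, path("alignments.tsv"))
    utils::write.table(sim$groups, path("libraries.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$loci, path("truth_loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_methylation(meth, path("methylation.tsv"))
    for (mark in names(chip))
      write_chip_bed(chip[[mark]], path(paste0("chip_", mark, ".bed")))
    write_annotations_gff3(anns[vapply(anns, nrow, 1L) > 0],
                           path("annotations.gff3"))
    utils::write.table(
      data.frame(chrom = genome$chromosomes$chrom,
                 length = genome$chromosomes$length),
      path("genome.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    res$simulate <- sim
  }

  if ("segment" %in% stages &&
      (force || !file.exists(path("loci.bed")))) {
    reads <- read_alignments(path("alignments.tsv"))
    libraries <- utils::read.delim(path("libraries.tsv"),
                                   stringsAsFactors = FALSE)
    gl <- sum(utils::read.delim(path("genome.tsv"))$length)
    seg <- segment_loci(reads, libraries, config$segmentation,
                        genome_length = gl)
    write_loci_bed(seg$loci$loci, path("loci.bed"))
    lik <- as.data.frame(seg$loci$likelihood)
    lik <- cbind(locus_id = seg$loci$loci$locus_id, lik)
    utils::write.table(lik, path("likelihoods.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(seg$libraries, path("libraries_scaled.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fp <- seg$false_positives
    utils::write.table(
      data.frame(n_loci = nrow(seg$loci$loci),
                 expected_false_positives = fp$expected,
                 percent = fp$percent),
      path("false_positives.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    res$segment <- seg
  }

  if ("annotate" %in% stages &&
      (force || !file.exists(path("feature_table.tsv")))) {
    if (!file.exists(path("annotations.gff3")))
      srnaloc_error("annotate stage requires annotations.gff3",
                    "missing_input")
    loci_df <- read_loci_bed(path("loci.bed"))
    likdf <- utils::read.delim(path("likelihoods.tsv"),
                               stringsAsFactors = FALSE)
    lik <- as.matrix(likdf[, -1, drop = FALSE])
    locus_table <- structure(list(loci = loci_df, likelihood = lik),
                             class = "srna_locus_table")
    reads <- read_alignments(path("alignments.tsv"))
    libraries <- utils::read.delim(path("libraries_scaled.tsv"),
                                   stringsAsFactors = FALSE)
    reads <- filter_reads(reads, params = config$segmentation)
    ann_raw <- read_annotations(path("annotations.gff3"))
    meth <- read_methylation(path("methylation.tsv"))
    chip_files <- list.files(outdir, "^chip_.*\\.bed$")
    chip <- stats::setNames(
      lapply(chip_files, function(f) read_chip_bed(path(f))),
      sub("^chip_(.*)\\.bed$", "\\1", chip_files))
    ft <- compute_feature_table(locus_table, reads, libraries, ann_raw,
                                meth, chip, config)
    write_feature_table(ft, path("feature_table.tsv"))
    res$annotate <- ft
  }

  if ("classify" %in% stages &&
      (force || !file.exists(path("classes.tsv")))) {
    ft <- read_feature_table(path("feature_table.tsv"))
    cls <- classify_loci(ft, config)
    utils::write.table(
      data.frame(locus_id = ft$locus_id,
                 class = as.character(cls$clustering$assignments)),
      path("classes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(dim = seq_along(cls$mca$eigenvalues),
                 eigenvalue = cls$mca$eigenvalues,
                 variance_pct = cls$mca$explained_variance),
      path("mca_variance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(cls$gap$table, path("gap_statistic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cls$validation))
      utils::write.table(cls$validation, path("validation_nmi.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cls$enrichment, path("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cls$paragons, path("paragons.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$classify <- cls
  }

  if ("report" %in% stages) {
    res$report <- report_run(outdir)
    writeLines(res$report$text, path("report.txt"))
  }

  manifest <- data.frame(
    file = list.files(outdir),
    md5 = unname(tools::md5sum(file.path(outdir, list.files(outdir)))),
    stringsAsFactors = FALSE)
  manifest <- manifest[manifest$file != "manifest.tsv", ]
  utils::write.table(manifest, path("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Percentage of loci, at printed precision
#'
#' Helper for reporting: 100 * count / total rounded to \code{digits}
#' decimals, matching the precision used in prose summaries.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places (default 1).
#' @return Rounded percentage.
#' @export
ubiquity_percent <- function(count, total, digits = 1) {
  if (total == 0) return(0)
  round(100 * count / total, digits)
}

#' Summarise a completed run
#'
#' Locus counts per replicate group, the false-positive estimate, ubiquity
#' histograms (number of replicate groups in which each locus is
#' expressed, overall and wild-type only), class sizes, top enrichments
#' and paragons.
#'
#' @param outdir Run directory of a completed pipeline.
#' @param expression_cutoff Posterior cutoff for an expression call.
#' @return List of summary tables plus a formatted \code{text} rendering.
#' @export
report_run <- function(outdir, expression_cutoff = 0.5) {
  path <- function(...) file.path(outdir, ...)
  likdf <- utils::read.delim(path("likelihoods.tsv"),
                             stringsAsFactors = FALSE)
  lik <- as.matrix(likdf[, -1, drop = FALSE])
  libraries <- utils::read.delim(path("libraries_scaled.tsv"),
                                 stringsAsFactors = FALSE)
  wt_groups <- unique(libraries$replicate_group[libraries$is_wild_type])
  calls <- call_expression(lik, expression_cutoff)
  n_loci <- nrow(lik)
  per_group <- colSums(calls)
  ubiq_all <- table(factor(rowSums(calls), levels = 0:ncol(calls)))
  wt_calls <- calls[, intersect(colnames(lik), wt_groups), drop = FALSE]
  ubiq_wt <- table(factor(rowSums(wt_calls), levels = 0:ncol(wt_calls)))
  fp <- utils::read.delim(path("false_positives.tsv"))
  single <- sum(rowSums(calls) == 1)
  all_groups <- sum(rowSums(calls) == ncol(calls))
  lines <- c(
    sprintf("%d loci selected across %d replicate groups", n_loci,
            ncol(calls)),
    sprintf("estimated false positives: %.1f (%.2f%%)",
            fp$expected_false_positives, fp$percent),
    sprintf("%d (%.1f%%) loci expressed in exactly one replicate group",
            single, ubiquity_percent(single, n_loci)),
    sprintf("%d (%.2f%%) loci expressed in all %d replicate groups",
            all_groups, ubiquity_percent(all_groups, n_loci, 2),
            ncol(calls)))
  out <- list(n_loci = n_loci, per_group = per_group,
              ubiquity = as.data.frame(ubiq_all),
              ubiquity_wt = as.data.frame(ubiq_wt),
              false_positives = fp)
  if (file.exists(path("classes.tsv"))) {
    classes <- utils::read.delim(path("classes.tsv"),
                                 stringsAsFactors = FALSE)
    out$class_sizes <- table(classes$class)
    lines <- c(lines, paste("class sizes:",
                            paste(names(out$class_sizes),
                                  out$class_sizes, sep = "=",
                                  collapse = ", ")))
    enr <- utils::read.delim(path("enrichment.tsv"),
                             stringsAsFactors = FALSE)
    top <- enr[enr$sign == "enriched", ]
    top <- top[order(top$p_adj), ]
    out$top_enrichments <- utils::head(top, 10)
    par <- utils::read.delim(path("paragons.tsv"),
                             stringsAsFactors = FALSE)
    out$paragons <- par
    lines <- c(lines, paste("paragons:",
                            paste(par$class, par$locus_id, sep = ":",
                                  collapse = ", ")))
  }
  out$text <- lines
  out
}
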