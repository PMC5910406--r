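#' Generate a toy genome with chromosomal zones
#'
#' Builds a small genome description for simulation: each chromosome is
#' partitioned into three contiguous zones (arm, pericentromere, centromere)
#' mimicking the large-scale organisation along which distinct small RNA
#' locus classes distribute (gene-associated loci on arms, PolV-dependent
#' loci pericentromeric, PolV-independent loci centromeric).
#'
#' @param n_chrom Number of chromosomes (positive integer).
#' @param length Length of each chromosome in nt (>= 10000).
#' @param seed Integer seed; recorded for provenance and used to jitter the
#'   zone boundaries slightly so the partition is not always proportionally
#'   identical.
#' @return An object of class \code{srna_genome}: a list with
#'   \code{chromosomes} (data.frame chrom/length) and \code{zones}
#'   (data.frame chrom/zone/start/end, 1-based inclusive).
#' @export
generate_genome <- function(n_chrom = 2L, length = 10000000L, seed = 1L) {
  if (!is.numeric(length) || length(length) != 1 || length < 10000)
    srnaloc_error("chromosome length must be a single value >= 10000",
                  "invalid_argument")
  if (!is.numeric(n_chrom) || n_chrom < 1)
    srnaloc_error("n_chrom must be a positive integer", "invalid_argument")
  n_chrom <- as.integer(n_chrom)
  length <- as.integer(length)
  set.seed(derive_seed(seed, "genome"))
  chroms <- paste0("chr", seq_len(n_chrom))
  zones <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    # arm ~50%, pericentromere ~30%, centromere ~20%, jittered +/- 2%
    b1 <- round(length * (0.50 + stats::runif(1, -0.02, 0.02)))
    b2 <- round(length * (0.80 + stats::runif(1, -0.02, 0.02)))
    data.frame(
      chrom = chroms[i],
      zone = c("arm", "pericentromere", "centromere"),
      start = c(1L, b1 + 1L, b2 + 1L),
      end = c(b1, b2, length),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      chromosomes = data.frame(chrom = chroms, length = length,
                               stringsAsFactors = FALSE),
      zones = zones,
      seed = seed
    ),
    class = "srna_genome"
  )
}

#' @export
print.srna_genome <- function(x, ...) {
  cat("srna_genome:", nrow(x$chromosomes), "chromosome(s) of",
      x$chromosomes$length[1], "nt;", nrow(x$zones), "zones\n")
  invisible(x)
}
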