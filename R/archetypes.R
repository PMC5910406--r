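#' Define a synthetic locus class archetype
#'
#' An archetype describes the generative signature of one planted class of
#' small RNA loci: read length spectrum, strand bias, 5' base composition,
#' multimapping behaviour, which replicate groups express it, how expression
#' responds to biogenesis-pathway mutants, context-specific cytosine
#' methylation, and ChIP mark accumulation.
#'
#' @param name Class label.
#' @param n_loci Number of loci to plant.
#' @param width_range Length-2 integer vector, locus width range in nt.
#' @param size_profile Named probability vector over read lengths (names are
#'   lengths within 15..30); must sum to 1.
#' @param strand_bias Proportion of locus reads on the plus strand, in
#'   [0.5, 1].
#' @param five_prime_probs Named probability vector over A/C/G/T for the
#'   read 5' base; must sum to 1.
#' @param multimap_mean Mean of the (shifted geometric) distribution of
#'   genomic hit counts; 1 means essentially unique mappers.
#' @param expression_groups Character vector of wild-type replicate groups
#'   in which the class is expressed (others see background only).
#' @param mutant_loss Named numeric vector, mutant genotype -> retained
#'   expression fraction in [0, 1].
#' @param meth_level Named numeric vector, methylation context (CpG, CHG,
#'   CHH) -> mean within-locus methylation proportion.
#' @param mark_rates Named numeric vector, ChIP mark -> reads per base at
#'   loci of this class. An \code{H3} entry sets histone accumulation.
#' @param mean_expression Mean per-library read total at reference depth.
#' @param zone Genomic zone ("arm", "pericentromere", "centromere") in which
#'   loci of this class are placed.
#' @param overlap_features Character vector of annotation types loci of this
#'   class are placed inside (e.g. "gene", "promoter", "TE", "IR").
#' @param nb_size Negative-binomial dispersion (size) for read totals.
#' @return An object of class \code{srna_archetype}.
#' @export
archetype <- function(name, n_loci, width_range, size_profile, strand_bias,
                      five_prime_probs, multimap_mean = 1,
                      expression_groups = character(),
                      mutant_loss = numeric(), meth_level = numeric(),
                      mark_rates = numeric(), mean_expression = 80,
                      zone = "arm", overlap_features = character(),
                      nb_size = 5) {
  stopifnot(length(width_range) == 2, all(width_range > 0),
            width_range[1] <= width_range[2])
  if (abs(sum(size_profile) - 1) > 1e-9)
    srnaloc_error("size_profile must sum to 1", "invalid_argument")
  if (abs(sum(five_prime_probs) - 1) > 1e-9)
    srnaloc_error("five_prime_probs must sum to 1", "invalid_argument")
  if (any(mutant_loss < 0 | mutant_loss > 1))
    srnaloc_error("mutant_loss fractions must be in [0, 1]",
                  "invalid_argument")
  stopifnot(strand_bias >= 0.5, strand_bias <= 1)
  structure(list(
    name = name, n_loci = as.integer(n_loci),
    width_range = as.integer(width_range),
    size_profile = size_profile, strand_bias = strand_bias,
    five_prime_probs = five_prime_probs[c("A", "C", "G", "T")],
    multimap_mean = multimap_mean,
    expression_groups = expression_groups,
    mutant_loss = mutant_loss, meth_level = meth_level,
    mark_rates = mark_rates, mean_expression = mean_expression,
    zone = zone, overlap_features = overlap_features, nb_size = nb_size
  ), class = "srna_archetype")
}

#' Default synthetic archetypes
#'
#' Three well-separated locus classes covering the major divisions observed
#' among plant small RNA loci:
#' \itemize{
#'   \item \code{gene21}: short, 21-22 nt dominated, strongly strand-biased,
#'     uniquely mapping, 5'-C enriched, unmethylated, expressed in a few
#'     tissues, independent of DCL2/3/4, RDR2, PolIV and PolV; placed on
#'     chromosome arms overlapping genes. Mimics PTGS-like / miRNA-adjacent
#'     loci.
#'   \item \code{rddm_polv}: 23-24 nt dominated, unbiased strand, 5'-A
#'     enriched, low multimapping, highly methylated in all contexts,
#'     dependent on DCL2/3/4, RDR2, PolIV and PolV; pericentromeric,
#'     promoter-overlapping. Mimics canonical PolV-dependent RdDM loci.
#'   \item \code{het_ir}: 23-24 nt dominated, heavily multimapping (high
#'     repetitiveness), methylated, dependent on RDR2/PolIV but independent
#'     of PolV and of DCL2/3/4, with high H3 and H3K9me2; centromeric,
#'     TE/inverted-repeat overlapping. Mimics PolV-independent
#'     heterochromatic siRNA loci.
#' }
#'
#' @param n_loci Number of loci per archetype (default 200).
#' @param wt_groups Character vector of wild-type replicate group names the
#'   design uses (default \code{paste0("wt", 1:10)}).
#' @return List of three \code{srna_archetype} objects.
#' @export
default_archetypes <- function(n_loci = 200L,
                               wt_groups = paste0("wt", 1:10)) {
  sp21 <- c(`20` = 0.05, `21` = 0.60, `22` = 0.25, `23` = 0.05, `24` = 0.05)
  sp24 <- c(`21` = 0.03, `22` = 0.02, `23` = 0.20, `24` = 0.70, `25` = 0.05)
  list(
    archetype(
      name = "gene21", n_loci = n_loci, width_range = c(150L, 400L),
      size_profile = sp21, strand_bias = 0.95,
      five_prime_probs = c(A = 0.20, C = 0.60, G = 0.10, T = 0.10),
      multimap_mean = 1.05,
      expression_groups = wt_groups[1:3],
      mutant_loss = c(dcl234 = 1, rdr2 = 1, polIV = 1, polV = 1),
      meth_level = c(CpG = 0.05, CHG = 0.03, CHH = 0.03),
      mark_rates = c(H3 = 0.05, H3K9me2 = 0.01, H3K4me3 = 0.30),
      mean_expression = 80, zone = "arm",
      overlap_features = c("gene")
    ),
    archetype(
      name = "rddm_polv", n_loci = n_loci, width_range = c(150L, 600L),
      size_profile = sp24, strand_bias = 0.52,
      five_prime_probs = c(A = 0.70, C = 0.05, G = 0.10, T = 0.15),
      multimap_mean = 1.3,
      expression_groups = wt_groups,
      mutant_loss = c(dcl234 = 0.02, rdr2 = 0.02, polIV = 0.02,
                      polV = 0.05),
      meth_level = c(CpG = 0.80, CHG = 0.60, CHH = 0.70),
      mark_rates = c(H3 = 0.05, H3K9me2 = 0.05, H3K4me3 = 0.01),
      mean_expression = 100, zone = "pericentromere",
      overlap_features = c("promoter")
    ),
    archetype(
      name = "het_ir", n_loci = n_loci, width_range = c(200L, 600L),
      size_profile = sp24, strand_bias = 0.52,
      five_prime_probs = c(A = 0.40, C = 0.10, G = 0.25, T = 0.25),
      multimap_mean = 10,
      expression_groups = wt_groups,
      mutant_loss = c(dcl234 = 1, rdr2 = 0.02, polIV = 0.02, polV = 1),
      meth_level = c(CpG = 0.85, CHG = 0.70, CHH = 0.60),
      mark_rates = c(H3 = 0.40, H3K9me2 = 0.40, H3K4me3 = 0.02),
      mean_expression = 100, zone = "centromere",
      overlap_features = c("TE", "IR")
    )
  )
}

#' Default library design
#'
#' Wild-type replicate groups of two libraries each, with sequencing depth
#' varying across groups (emulating the strong dependence of locus discovery
#' on depth), plus one mutant replicate group of two libraries for each of
#' dcl2/3/4, rdr2, polIV and polV.
#'
#' @param n_wt_groups Number of wild-type replicate groups (default 10).
#' @param libs_per_group Libraries per replicate group (default 2).
#' @param depth Reference total read count per library (default 2e4).
#' @return data.frame with columns library_id, replicate_group, genotype,
#'   is_wild_type, depth.
#' @export
default_library_design <- function(n_wt_groups = 10L, libs_per_group = 3L,
                                   depth = 2e4) {
  wt_groups <- paste0("wt", seq_len(n_wt_groups))
  # depth varies 0.5x..1.5x across wild-type groups
  gdepth <- depth * seq(0.5, 1.5, length.out = n_wt_groups)
  wt <- do.call(rbind, lapply(seq_len(n_wt_groups), function(g) {
    data.frame(
      library_id = paste0(wt_groups[g], "_r", seq_len(libs_per_group)),
      replicate_group = wt_groups[g], genotype = "WT",
      is_wild_type = TRUE, depth = gdepth[g], stringsAsFactors = FALSE
    )
  }))
  muts <- c("dcl234", "rdr2", "polIV", "polV")
  mu <- do.call(rbind, lapply(muts, function(m) {
    data.frame(
      library_id = paste0(m, "_r", seq_len(libs_per_group)),
      replicate_group = m, genotype = m,
      is_wild_type = FALSE, depth = depth, stringsAsFactors = FALSE
    )
  }))
  rbind(wt, mu)
}
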