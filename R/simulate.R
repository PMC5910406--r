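# Read-level, methylation and ChIP simulators for the planted-class study
# design. All randomness flows from a single integer seed via derive_seed().

# Vectorised random sequence generation with a fixed 5' base.
rand_seqs <- function(lens, first_base) {
  n <- length(lens)
  if (n == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  total <- sum(lens - 1L)
  tail_chars <- sample(bases, total, replace = TRUE)
  idx <- rep.int(seq_len(n), lens - 1L)
  tails <- vapply(split(tail_chars, factor(idx, levels = seq_len(n))),
                  paste, collapse = "", FUN.VALUE = "")
  paste0(first_base, tails)
}

# Place archetype loci inside their target zones, non-overlapping and
# separated by at least min_gap nt. Errors if an archetype does not fit.
place_loci <- function(genome, archetypes, seed, min_gap = 1000L) {
  set.seed(derive_seed(seed, "placement"))
  out <- list()
  id <- 0L
  for (a in archetypes) {
    zones <- genome$zones[genome$zones$zone == a$zone, , drop = FALSE]
    if (nrow(zones) == 0)
      srnaloc_error(paste0("no zone '", a$zone, "' for archetype ", a$name),
                    "placement_failure")
    zi <- 1L
    cursor <- zones$start[zi] + min_gap
    placed <- 0L
    rows <- vector("list", a$n_loci)
    while (placed < a$n_loci) {
      w <- sample(seq(a$width_range[1], a$width_range[2]), 1L)
      gap <- min_gap + sample.int(1500L, 1L)
      if (cursor + w - 1L > zones$end[zi]) {
        zi <- zi + 1L
        if (zi > nrow(zones))
          srnaloc_error(paste0("cannot place all loci of archetype ",
                               a$name), "placement_failure")
        cursor <- zones$start[zi] + min_gap
        next
      }
      placed <- placed + 1L
      id <- id + 1L
      rows[[placed]] <- data.frame(
        locus_id = sprintf("SIM%06d", id), chrom = zones$chrom[zi],
        start = cursor, end = cursor + w - 1L, class_name = a$name,
        stringsAsFactors = FALSE
      )
      cursor <- cursor + w - 1L + gap
    }
    out[[a$name]] <- do.call(rbind, rows)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate small RNA libraries with planted loci
#'
#' Places the archetypes' loci in their target genomic zones and draws read
#' stacks for every library in the design. Per-locus per-library totals are
#' negative binomial with mean proportional to library depth; mutant
#' libraries scale the mean by the archetype's retained expression fraction.
#' Reads carry lengths, strands, 5' bases and genomic hit counts drawn from
#' the archetype distributions; a low rate of background reads is scattered
#' uniformly across the genome.
#'
#' @param genome \code{srna_genome} from \code{\link{generate_genome}}.
#' @param archetypes List of \code{srna_archetype}.
#' @param groups Library design data.frame (see
#'   \code{\link{default_library_design}}).
#' @param seed Integer seed.
#' @param background_rate Background reads as a fraction of library depth
#'   (default 0.005, i.e. 0.5\%).
#' @param bg_five_prime Background 5' base composition; defaults to the
#'   genome-wide wild-type composition A 51\%, C 9\%, G 17\%, T 22\%.
#' @return List with \code{reads} (AlignedRead data.frame), \code{truth}
#'   (list: \code{loci} data.frame with planted classes,
#'   \code{expected_counts} loci x libraries matrix of NB means),
#'   \code{totals} (realised read totals per library) and \code{groups}.
#' @export
simulate_libraries <- function(genome, archetypes, groups, seed = 1L,
                               background_rate = 0.005,
                               bg_five_prime = c(A = 0.51, C = 0.09,
                                                 G = 0.17, T = 0.22)) {
  loci <- place_loci(genome, archetypes, seed)
  set.seed(derive_seed(seed, "reads"))
  arch_by_name <- stats::setNames(archetypes,
                                  vapply(archetypes, `[[`, "", "name"))
  ref_depth <- stats::median(groups$depth)

  # Per-locus stack structure (shared across libraries: the same sRNA
  # species recur between samples).
  n_loci <- nrow(loci)
  stack_info <- vector("list", n_loci)
  base_rel <- exp(stats::rnorm(n_loci, 0, 0.25))
  for (l in seq_len(n_loci)) {
    a <- arch_by_name[[loci$class_name[l]]]
    w <- loci$end[l] - loci$start[l] + 1L
    n_stacks <- min(20L, max(6L, w %/% 30L))
    lens <- as.integer(sample(names(a$size_profile), n_stacks, replace = TRUE,
                              prob = a$size_profile))
    # stacks tile the locus from end to end with jitter, so the planted
    # interval is the actual expressed extent
    rel <- if (n_stacks > 1) (seq_len(n_stacks) - 1) / (n_stacks - 1) else 0.5
    jit <- stats::runif(n_stacks, -0.5, 0.5) * (w / n_stacks)
    offs <- pmin(pmax(round(rel * (w - lens) + jit), 0), pmax(w - lens, 0))
    starts <- loci$start[l] + as.integer(offs)
    strands <- ifelse(stats::runif(n_stacks) < a$strand_bias, "+", "-")
    fp <- sample(c("A", "C", "G", "T"), n_stacks, replace = TRUE,
                 prob = a$five_prime_probs)
    p_hit <- min(1, 1 / a$multimap_mean)
    m <- 1L + stats::rgeom(n_stacks, p_hit)
    wts <- stats::rgamma(n_stacks, 1)
    stack_info[[l]] <- data.frame(
      sequence = rand_seqs(lens, fp), chrom = loci$chrom[l],
      start = starts, end = starts + lens - 1L, strand = strands,
      n_hits = m, weight = wts / sum(wts), stringsAsFactors = FALSE
    )
  }

  expected <- matrix(0, n_loci, nrow(groups),
                     dimnames = list(loci$locus_id, groups$library_id))
  read_parts <- list()
  totals <- numeric(nrow(groups))
  for (j in seq_len(nrow(groups))) {
    lib <- groups[j, ]
    depth_factor <- lib$depth / ref_depth
    lib_rows <- list()
    for (l in seq_len(n_loci)) {
      a <- arch_by_name[[loci$class_name[l]]]
      retention <- if (lib$is_wild_type) {
        if (lib$replicate_group %in% a$expression_groups) 1 else 0
      } else {
        if (lib$genotype %in% names(a$mutant_loss))
          unname(a$mutant_loss[lib$genotype]) else 1
      }
      mu <- a$mean_expression * base_rel[l] * depth_factor * retention
      expected[l, j] <- mu
      if (mu <= 0) next
      total <- stats::rnbinom(1, mu = mu, size = a$nb_size)
      if (total == 0) next
      st <- stack_info[[l]]
      cnt <- as.vector(stats::rmultinom(1, total, st$weight))
      keep <- cnt > 0
      if (!any(keep)) next
      df <- st[keep, c("sequence", "chrom", "start", "end", "strand",
                       "n_hits")]
      df$count <- cnt[keep]
      lib_rows[[length(lib_rows) + 1L]] <- df
    }
    # background noise reads
    n_bg <- stats::rpois(1, background_rate * lib$depth)
    if (n_bg > 0) {
      chrom_idx <- sample.int(nrow(genome$chromosomes), n_bg, replace = TRUE)
      lens <- sample(15:30, n_bg, replace = TRUE,
                     prob = c(rep(1, 5), 2, 6, 4, 2, 6, 2, rep(1, 5)))
      starts <- vapply(genome$chromosomes$length[chrom_idx] - lens + 1L,
                       function(m) sample.int(m, 1L), 1L)
      fp <- sample(c("A", "C", "G", "T"), n_bg, replace = TRUE,
                   prob = bg_five_prime[c("A", "C", "G", "T")])
      lib_rows[[length(lib_rows) + 1L]] <- data.frame(
        sequence = rand_seqs(lens, fp),
        chrom = genome$chromosomes$chrom[chrom_idx],
        start = starts, end = starts + lens - 1L,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        n_hits = 1L + stats::rgeom(n_bg, 0.9),
        count = 1L, stringsAsFactors = FALSE
      )
    }
    if (length(lib_rows)) {
      df <- do.call(rbind, lib_rows)
      df$library_id <- lib$library_id
      totals[j] <- sum(df$count)
      read_parts[[length(read_parts) + 1L]] <- df
    }
  }
  reads <- do.call(rbind, read_parts)
  rownames(reads) <- NULL
  reads <- reads[, c("sequence", "chrom", "start", "end", "strand", "count",
                     "n_hits", "library_id")]
  list(
    reads = reads,
    truth = list(loci = loci, expected_counts = expected),
    totals = data.frame(library_id = groups$library_id, total = totals,
                        stringsAsFactors = FALSE),
    groups = groups
  )
}

#' Simulate per-cytosine methylation proportions
#'
#' Scatters cytosines of each context at a configurable density inside the
#' planted loci, plus a sparse genome-wide background sample, and draws
#' per-cytosine methylation proportions from a Beta distribution centred on
#' the archetype's context mean inside planted loci and on the background
#' mean elsewhere. Restricting dense coverage to the loci keeps file sizes
#' proportional to the planted signal rather than to genome length; locus
#' methylation summaries only use within-locus cytosines. A mean of exactly
#' 0 or 1 yields the degenerate proportion.
#'
#' @param genome \code{srna_genome}.
#' @param truth Truth list from \code{\link{simulate_libraries}}.
#' @param archetypes List of \code{srna_archetype}.
#' @param seed Integer seed.
#' @param background Background mean methylation proportion (default 0.05).
#' @param density Named vector of cytosines per base per context (applied
#'   inside planted loci).
#' @param background_sites Number of genome-wide background cytosines per
#'   context per chromosome (default 5000, capped at 0.2\% of the
#'   chromosome).
#' @param concentration Beta concentration (shape1 + shape2), default 10.
#' @param coverage_mean Mean read coverage per cytosine, default 20.
#' @return data.frame with columns chrom, pos, context, proportion, coverage.
#' @export
simulate_methylation <- function(genome, truth, archetypes, seed = 1L,
                                 background = 0.05,
                                 density = c(CpG = 0.02, CHG = 0.02,
                                             CHH = 0.06),
                                 background_sites = 5000L,
                                 concentration = 10, coverage_mean = 20) {
  set.seed(derive_seed(seed, "methylation"))
  arch_by_name <- stats::setNames(archetypes,
                                  vapply(archetypes, `[[`, "", "name"))
  loci <- truth$loci
  parts <- list()
  for (ctx in names(density)) {
    for (ci in seq_len(nrow(genome$chromosomes))) {
      chrom <- genome$chromosomes$chrom[ci]
      len <- genome$chromosomes$length[ci]
      lc0 <- loci[loci$chrom == chrom, , drop = FALSE]
      dense <- integer(0)
      if (nrow(lc0)) {
        dense <- unlist(lapply(seq_len(nrow(lc0)), function(l) {
          w <- lc0$end[l] - lc0$start[l] + 1L
          k <- stats::rpois(1, w * density[[ctx]])
          if (k == 0) return(integer(0))
          lc0$start[l] + sample.int(w, min(k, w)) - 1L
        }))
      }
      n_bg <- min(as.integer(background_sites), round(len * 0.002))
      pos <- sort(unique(c(dense, sample.int(len, n_bg))))
      n <- length(pos)
      if (n == 0) next
      mean_p <- rep(background, n)
      lc <- loci[loci$chrom == chrom, , drop = FALSE]
      if (nrow(lc)) {
        hit <- findInterval(pos, lc$start)
        inside <- hit >= 1 & pos <= lc$end[pmax(hit, 1L)]
        if (any(inside)) {
          cls <- lc$class_name[hit[inside]]
          lvl <- vapply(cls, function(cn) {
            a <- arch_by_name[[cn]]
            if (ctx %in% names(a$meth_level)) unname(a$meth_level[ctx])
            else background
          }, 1.0)
          mean_p[inside] <- lvl
        }
      }
      prop <- ifelse(
        mean_p <= 0, 0,
        ifelse(mean_p >= 1, 1,
               stats::rbeta(n, mean_p * concentration,
                            (1 - mean_p) * concentration))
      )
      parts[[length(parts) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, context = ctx, proportion = prop,
        coverage = 1L + stats::rpois(n, coverage_mean - 1),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate ChIP read sets for H3 and histone marks
#'
#' Draws Poisson read counts per planted locus at the archetype's per-base
#' rate for each mark, plus uniform background reads genome-wide. An H3 set
#' is always generated (it is the denominator for mark proportions).
#'
#' @param genome \code{srna_genome}.
#' @param truth Truth list from \code{\link{simulate_libraries}}.
#' @param archetypes List of \code{srna_archetype}.
#' @param seed Integer seed.
#' @param background_rate Background ChIP reads per base (default 0.001).
#' @param read_width ChIP read width in nt (default 75).
#' @return Named list of data.frames (chrom, start, end, strand), one per
#'   mark; always contains \code{H3}.
#' @export
simulate_chip <- function(genome, truth, archetypes, seed = 1L,
                          background_rate = 0.001, read_width = 75L) {
  set.seed(derive_seed(seed, "chip"))
  arch_by_name <- stats::setNames(archetypes,
                                  vapply(archetypes, `[[`, "", "name"))
  marks <- unique(c("H3", unlist(lapply(archetypes,
                                        function(a) names(a$mark_rates)))))
  loci <- truth$loci
  out <- list()
  for (mark in marks) {
    parts <- list()
    # background
    for (ci in seq_len(nrow(genome$chromosomes))) {
      chrom <- genome$chromosomes$chrom[ci]
      len <- genome$chromosomes$length[ci]
      n <- stats::rpois(1, background_rate * len)
      if (n > 0) {
        starts <- sample.int(max(1L, len - read_width), n)
        parts[[length(parts) + 1L]] <- data.frame(
          chrom = chrom, start = starts, end = starts + read_width - 1L,
          strand = sample(c("+", "-"), n, replace = TRUE),
          stringsAsFactors = FALSE
        )
      }
    }
    # locus-level signal
    for (l in seq_len(nrow(loci))) {
      a <- arch_by_name[[loci$class_name[l]]]
      rate <- if (mark %in% names(a$mark_rates)) unname(a$mark_rates[mark])
              else 0
      if (rate <= 0) next
      w <- loci$end[l] - loci$start[l] + 1L
      n <- stats::rpois(1, rate * w)
      if (n == 0) next
      starts <- loci$start[l] + sample.int(w, n, replace = TRUE) - 1L
      parts[[length(parts) + 1L]] <- data.frame(
        chrom = loci$chrom[l], start = starts,
        end = starts + read_width - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    df <- if (length(parts)) do.call(rbind, parts) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    rownames(df) <- NULL
    out[[mark]] <- df
  }
  out
}

#' Write annotation files implied by the planted loci
#'
#' Produces annotation interval sets consistent with the archetypes'
#' \code{overlap_features}: a gene (plus implied promoter) behind each
#' gene-overlapping locus, a TE superfamily interval and an inverted repeat
#' behind TE/IR-overlapping loci, and a long-RNA expression locus behind
#' gene-associated loci. Genes are oriented so that promoter-overlapping
#' archetype loci fall in the 500 nt upstream of a gene start.
#'
#' @param truth Truth list from \code{\link{simulate_libraries}}.
#' @param archetypes List of \code{srna_archetype}.
#' @return Named list of data.frames (chrom, start, end, strand, type).
#' @export
simulate_annotations <- function(truth, archetypes) {
  arch_by_name <- stats::setNames(archetypes,
                                  vapply(archetypes, `[[`, "", "name"))
  loci <- truth$loci
  genes <- list(); tes <- list(); irs <- list(); expr <- list()
  for (l in seq_len(nrow(loci))) {
    a <- arch_by_name[[loci$class_name[l]]]
    ov <- a$overlap_features
    if ("gene" %in% ov) {
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = loci$chrom[l], start = loci$start[l] - 20L,
        end = loci$end[l] + 20L, strand = "+", type = "gene",
        stringsAsFactors = FALSE)
      expr[[length(expr) + 1L]] <- data.frame(
        chrom = loci$chrom[l], start = loci$start[l] - 20L,
        end = loci$end[l] + 20L, strand = "+", type = "expression",
        stringsAsFactors = FALSE)
    }
    if ("promoter" %in% ov) {
      # plus-strand gene starting just downstream: promoter = 500 nt
      # upstream of the gene start covers the locus
      gs <- loci$end[l] + 50L
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = loci$chrom[l], start = gs, end = gs + 400L, strand = "+",
        type = "gene", stringsAsFactors = FALSE)
    }
    if ("TE" %in% ov) {
      tes[[length(tes) + 1L]] <- data.frame(
        chrom = loci$chrom[l], start = loci$start[l] - 10L,
        end = loci$end[l] + 10L, strand = "+", type = "LTR/Gypsy",
        stringsAsFactors = FALSE)
    }
    if ("IR" %in% ov) {
      irs[[length(irs) + 1L]] <- data.frame(
        chrom = loci$chrom[l], start = loci$start[l],
        end = loci$end[l], strand = "+", type = "IR",
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), type = character(),
               stringsAsFactors = FALSE)
  list(gene = bind(genes), TE = bind(tes), IR = bind(irs),
       expression = bind(expr))
}

#' Simulate a categorical feature table directly from archetype signatures
#'
#' Draws a per-locus categorical feature table from the class-conditional
#' level distributions implied by the archetypes, bypassing read-level
#' simulation. Each feature takes its class signature level with probability
#' \code{1 - noise} and a uniformly random other level otherwise. Used to
#' study the classification stage (MCA, clustering, model selection) in
#' isolation and at scale.
#'
#' @param archetypes List of \code{srna_archetype}.
#' @param seed Integer seed.
#' @param noise Per-feature label noise rate (default 0.05).
#' @return List with \code{features} (data.frame, locus_id + feature
#'   columns) and \code{classes} (character vector of planted class names).
#' @export
simulate_feature_table <- function(archetypes, seed = 1L, noise = 0.05) {
  set.seed(derive_seed(seed, "feature_table"))
  sigs <- lapply(archetypes, archetype_feature_signature)
  vocab <- feature_level_vocabulary()
  n_tot <- sum(vapply(archetypes, `[[`, 1L, "n_loci"))
  classes <- rep(vapply(archetypes, `[[`, "", "name"),
                 vapply(archetypes, `[[`, 1L, "n_loci"))
  out <- data.frame(locus_id = sprintf("SIM%06d", seq_len(n_tot)),
                    stringsAsFactors = FALSE)
  for (f in names(vocab)) {
    levels <- vocab[[f]]
    sig <- unlist(lapply(seq_along(archetypes), function(i)
      rep(sigs[[i]][[f]], archetypes[[i]]$n_loci)))
    flip <- stats::runif(n_tot) < noise
    val <- sig
    if (any(flip)) {
      val[flip] <- vapply(sig[flip], function(s)
        sample(setdiff(levels, s), 1L), "")
    }
    out[[f]] <- factor(val, levels = levels)
  }
  list(features = out, classes = classes)
}

# Canonical feature levels used by the default configuration.
feature_level_vocabulary <- function() {
  list(
    width = c("(0,50]", "(50,2000]", "(2000,Inf]"),
    expression = c("yes", "no"),
    phasing = c("none", "moderate", "high"),
    ratio_2124 = c("low", "moderate", "high", "unknown"),
    tissue = c("specific", "intermediate", "common"),
    repetitiveness = c("low", "moderate", "high", "unknown"),
    strand = c("no", "medium", "strong", "unknown"),
    dcl234 = c("dependent", "independent"),
    rdr2 = c("independent", "unknown", "dependent"),
    polIV = c("independent", "unknown", "dependent"),
    polV = c("independent", "unknown", "dependent"),
    CpG = c("low", "moderate", "high", "unknown"),
    CHG = c("low", "high", "unknown"),
    CHH = c("low", "high", "unknown"),
    H3 = c("none", "low", "moderate", "high"),
    H3K9me2 = c("low", "moderate", "high", "unknown"),
    H3K4me3 = c("low", "moderate", "high", "unknown"),
    fivep_A = c("yes", "no"), fivep_C = c("yes", "no"),
    fivep_G = c("yes", "no"), fivep_T = c("yes", "no")
  )
}

# Expected feature level per archetype under the default binning config.
archetype_feature_signature <- function(a) {
  ml <- function(ctx, thr) {
    v <- if (ctx %in% names(a$meth_level)) unname(a$meth_level[ctx]) else 0.05
    if (length(thr) == 2) {
      if (v <= thr[1]) "low" else if (v <= thr[2]) "moderate" else "high"
    } else {
      if (v <= thr[1]) "low" else "high"
    }
  }
  dep <- function(g) {
    r <- if (g %in% names(a$mutant_loss)) unname(a$mutant_loss[g]) else 1
    if (r <= 0.5) "dependent" else "independent"
  }
  p2124 <- sum(a$size_profile[names(a$size_profile) %in% c("21", "22")]) /
    sum(a$size_profile[names(a$size_profile) %in% c("21", "22", "23", "24")])
  rate_h3 <- if ("H3" %in% names(a$mark_rates)) unname(a$mark_rates["H3"])
             else 0
  mark_prop <- function(m) {
    km <- if (m %in% names(a$mark_rates)) unname(a$mark_rates[m]) else 0
    p <- if (km + rate_h3 > 0) km / (km + rate_h3) else NA
    if (is.na(p)) "unknown" else if (p <= 0.3) "low"
    else if (p <= 0.7) "moderate" else "high"
  }
  list(
    width = "(50,2000]",
    expression = if ("gene" %in% a$overlap_features) "yes" else "no",
    phasing = "none",
    ratio_2124 = if (p2124 >= 0.8) "high" else if (p2124 >= 0.2) "moderate"
                 else "low",
    tissue = if (length(a$expression_groups) >= 10) "common"
             else if (length(a$expression_groups) > 1) "intermediate"
             else "specific",
    repetitiveness = {
      p <- min(1, 1 / a$multimap_mean)
      e_inv_m <- if (p >= 1) 1 else -p / (1 - p) * log(p)
      r <- 1 - e_inv_m
      if (r <= 0.3) "low" else if (r <= 0.7) "moderate" else "high"
    },
    strand = if (a$strand_bias >= 0.9) "strong"
             else if (a$strand_bias >= 0.65) "medium" else "no",
    dcl234 = dep("dcl234"), rdr2 = dep("rdr2"), polIV = dep("polIV"),
    polV = dep("polV"),
    CpG = ml("CpG", c(0.2, 0.6)), CHG = ml("CHG", c(0.4)),
    CHH = ml("CHH", c(0.4)),
    H3 = if (rate_h3 <= 0.02) "none" else if (rate_h3 <= 0.1) "low"
         else if (rate_h3 <= 0.25) "moderate" else "high",
    H3K9me2 = mark_prop("H3K9me2"), H3K4me3 = mark_prop("H3K4me3"),
    fivep_A = if (a$five_prime_probs["A"] > 0.55) "yes" else "no",
    fivep_C = if (a$five_prime_probs["C"] > 0.3) "yes" else "no",
    fivep_G = if (a$five_prime_probs["G"] > 0.3) "yes" else "no",
    fivep_T = if (a$five_prime_probs["T"] > 0.3) "yes" else "no"
  )
}
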