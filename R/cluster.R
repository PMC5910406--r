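# Clustering of the MCA coordinates: k-means with k-means++ restarts,
# gap-statistic and bootstrap-stability model selection, NMI validation,
# enrichment tests, class hierarchy and paragons.

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (i in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1, ] <- x[sample(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i + 1, ])^2))
  }
  centers
}

#' K-means clustering of reduced coordinates
#'
#' Best of \code{restarts} k-means++ initializations (Lloyd iterations via
#' \code{stats::kmeans}) by within-cluster sum of squares, deterministic
#' under the seed. Class labels LC1..LCk are assigned by descending
#' cluster size.
#'
#' @param coords Numeric matrix (loci x dimensions), already truncated to
#'   the retained dimensions.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 25).
#' @return Object of class \code{srna_clustering}: k, dims, assignments
#'   (factor LC1..LCk), centroids, inertia (within-cluster SS), sizes.
#' @export
kmeans_cluster <- function(coords, k, seed = 1L, restarts = 25L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k > n) srnaloc_error("more clusters than loci", "invalid_argument")
  set.seed(derive_seed(seed, paste0("kmeans", k)))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(coords, k)
    init <- init + stats::rnorm(length(init), 0, 1e-10)  # avoid duplicates
    fit <- suppressWarnings(
      stats::kmeans(coords, centers = init, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  ord <- order(-as.numeric(table(factor(best$cluster, levels = 1:k))))
  relab <- match(best$cluster, ord)
  labels <- factor(paste0("LC", relab), levels = paste0("LC", 1:k))
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("LC", 1:k)
  structure(list(
    k = as.integer(k), dims = ncol(coords), assignments = labels,
    centroids = centroids, inertia = best$tot.withinss,
    sizes = as.numeric(table(labels))
  ), class = "srna_clustering")
}

#' @export
print.srna_clustering <- function(x, ...) {
  cat("srna_clustering: k =", x$k, "on", x$dims, "dims; sizes:",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Gap statistic for cluster number selection
#'
#' Tibshirani's gap statistic: Gap(k) = mean_b log W_k(reference_b) -
#' log W_k(data), with W_k the within-cluster sum of squares and the
#' reference distribution uniform over the data's bounding box. The
#' estimate is the smallest k with Gap(k) >= Gap(k+1) - s_{k+1} (1-SE
#' rule); the full curve is returned so a more conservative choice can be
#' made.
#'
#' @param coords Numeric matrix (loci x dims).
#' @param k_range Candidate cluster numbers (default 1:8).
#' @param B_ref Number of uniform reference datasets (default 25).
#' @param seed Integer seed.
#' @param restarts K-means restarts per fit (default 10).
#' @return List: \code{table} (data.frame k, logW, E_logW, gap, se) and
#'   \code{k_hat}.
#' @export
gap_statistic <- function(coords, k_range = 1:8, B_ref = 25L, seed = 1L,
                          restarts = 10L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  eps <- 1e-12
  if (all(apply(coords, 2, stats::var) < eps))
    return(list(table = data.frame(k = 1, logW = -Inf, E_logW = -Inf,
                                   gap = 0, se = 0), k_hat = 1L))
  wss <- function(x, k, s) {
    if (k == 1) {
      sum(sweep(x, 2, colMeans(x))^2)
    } else {
      kmeans_cluster(x, k, seed = s, restarts = restarts)$inertia
    }
  }
  logW <- vapply(k_range, function(k)
    log(max(wss(coords, k, derive_seed(seed, paste0("gapdata", k))), eps)),
    1.0)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  set.seed(derive_seed(seed, "gapref"))
  ref_logW <- matrix(0, B_ref, length(k_range))
  for (b in seq_len(B_ref)) {
    ref <- sapply(seq_along(lo), function(j)
      stats::runif(n, lo[j], hi[j]))
    for (ki in seq_along(k_range)) {
      ref_logW[b, ki] <- log(max(
        wss(ref, k_range[ki],
            derive_seed(seed, paste0("gapref", b, "_", ki))), eps))
    }
  }
  E_logW <- colMeans(ref_logW)
  se <- apply(ref_logW, 2, stats::sd) * sqrt(1 + 1 / B_ref)
  gap <- E_logW - logW
  k_hat <- k_range[length(k_range)]
  for (i in seq_len(length(k_range) - 1)) {
    if (gap[i] >= gap[i + 1] - se[i + 1]) { k_hat <- k_range[i]; break }
  }
  list(table = data.frame(k = k_range, logW = logW, E_logW = E_logW,
                          gap = gap, se = se),
       k_hat = as.integer(k_hat))
}

#' Normalised mutual information between two labelings
#'
#' I(A;B) / sqrt(H(A) H(B)). Defined as 1 for two identical constant
#' labelings and 0 when either labeling is constant otherwise.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return NMI in [0, 1].
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    srnaloc_error("label vectors differ in length", "invalid_argument")
  tab <- table(labels_a, labels_b)
  pij <- tab / sum(tab)
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (ha == 0 && hb == 0) {
    return(if (all(as.character(labels_a) == as.character(labels_b))) 1
           else 0)
  }
  if (ha == 0 || hb == 0) return(0)
  expected <- outer(pi_, pj_)
  nz <- pij > 0
  info <- sum(pij[nz] * log(pij[nz] / expected[nz]))
  max(0, min(1, info / sqrt(ha * hb)))
}

#' Bootstrap stability of clusterings across dimension/cluster choices
#'
#' For each (d, k): fit a reference MCA + k-means clustering; then B times,
#' resample loci with replacement, refit MCA and k-means on the resample,
#' match resample clusters to reference clusters by maximum-agreement
#' (Hungarian) assignment over the shared loci, and record per reference
#' cluster the proportion of shared loci that preserve their cluster. The
#' recommended d is the smallest at which the target k reaches a median
#' preservation of at least \code{stable_min}.
#'
#' @param indicator Result of \code{\link{build_indicator_matrix}}.
#' @param k_range Candidate cluster numbers.
#' @param dims_range Candidate dimension counts.
#' @param B Bootstrap resamples (default 25).
#' @param seed Integer seed.
#' @param target_k k whose stability drives the recommendation (default
#'   max of k_range).
#' @param stable_min Median preservation regarded as stable (default 0.8).
#' @param restarts K-means restarts (default 10).
#' @return List: \code{stability} (data.frame d, k, cluster, median, and
#'   quartiles of preservation), \code{recommended_d},
#'   \code{variance_curve}.
#' @export
select_dimensions <- function(indicator, k_range = 2:6, dims_range = 1:6,
                              B = 25L, seed = 1L, target_k = max(k_range),
                              stable_min = 0.8, restarts = 10L) {
  mca <- fit_mca(indicator)
  dims_range <- dims_range[dims_range <= ncol(mca$row_coords)]
  n <- nrow(indicator$Z)
  rows <- list()
  for (d in dims_range) {
    ref_coords <- mca$row_coords[, seq_len(d), drop = FALSE]
    for (k in k_range) {
      if (k > n) next
      ref <- kmeans_cluster(ref_coords, k,
                            seed = derive_seed(seed, paste0("ref", d, k)),
                            restarts = restarts)
      pres <- matrix(NA_real_, B, k)
      for (b in seq_len(B)) {
        set.seed(derive_seed(seed, paste0("boot", d, "_", k, "_", b)))
        idx <- sample.int(n, n, replace = TRUE)
        Zb <- indicator$Z[idx, , drop = FALSE]
        keep_cols <- colSums(Zb) > 0
        mca_b <- fit_mca(list(Z = Zb[, keep_cols, drop = FALSE],
                              categories = NULL))
        db <- min(d, ncol(mca_b$row_coords))
        cl_b <- kmeans_cluster(mca_b$row_coords[, seq_len(db),
                                                drop = FALSE], k,
                               seed = derive_seed(seed,
                                                  paste0("bk", d, k, b)),
                               restarts = restarts)
        shared <- !duplicated(idx)
        ref_lab <- as.integer(ref$assignments[idx[shared]])
        new_lab <- as.integer(cl_b$assignments[shared])
        agree <- table(factor(new_lab, levels = 1:k),
                       factor(ref_lab, levels = 1:k))
        perm <- solve_assignment(max(agree) - as.matrix(agree))
        mapped <- perm[new_lab]
        for (cl in seq_len(k)) {
          in_cl <- ref_lab == cl
          if (any(in_cl))
            pres[b, cl] <- mean(mapped[in_cl] == cl)
        }
      }
      qs <- apply(pres, 2, stats::quantile, c(0.25, 0.5, 0.75),
                  na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        d = d, k = k, cluster = paste0("LC", 1:k),
        q25 = qs[1, ], median = qs[2, ], q75 = qs[3, ])
    }
  }
  stab <- do.call(rbind, rows)
  rownames(stab) <- NULL
  rec <- NA_integer_
  for (d in sort(unique(stab$d))) {
    sub <- stab[stab$d == d & stab$k == target_k, ]
    if (nrow(sub) &&
        isTRUE(stats::median(sub$median, na.rm = TRUE) >= stable_min)) {
      rec <- d; break
    }
  }
  list(stability = stab, recommended_d = rec,
       variance_curve = mca$explained_variance)
}

#' Per-class feature enrichment
#'
#' For every (class, feature level) pair, a two-sided Fisher's exact test
#' on the 2x2 contingency of class membership against level membership,
#' Benjamini-Hochberg adjusted over all pairs; the sign of association is
#' the side of the odds ratio.
#'
#' @param assignments Factor of class labels per locus.
#' @param feature_table data.frame of categorical features (may include
#'   held-out annotation overlap columns).
#' @param features Columns to test; defaults to every column but locus_id.
#' @return data.frame: class, feature, level, odds_ratio, p, p_adj, sign.
#' @export
enrichment_tests <- function(assignments, feature_table,
                             features = NULL) {
  if (is.null(features))
    features <- setdiff(names(feature_table), "locus_id")
  classes <- levels(factor(assignments))
  rows <- list()
  for (f in features) {
    v <- as.character(feature_table[[f]])
    for (lv in sort(unique(v), method = "radix")) {
      has <- v == lv
      if (!any(has) || all(has)) next
      for (cl in classes) {
        inc <- assignments == cl
        a <- sum(inc & has); b <- sum(inc & !has)
        c_ <- sum(!inc & has); d <- sum(!inc & !has)
        ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, feature = f, level = lv,
          odds_ratio = unname(ft$estimate), p = ft$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$sign <- ifelse(out$odds_ratio > 1, "enriched", "depleted")
  rownames(out) <- NULL
  out
}

#' Class hierarchy flows between clusterings at different k
#'
#' For each cluster of the higher-k clustering, the distribution of its
#' members over the clusters of the next lower-k clustering; proportions
#' per source cluster sum to 1.
#'
#' @param clusterings List of \code{srna_clustering} on identical loci,
#'   any order (sorted by k internally, flows go from higher to lower k).
#' @return data.frame: from_k, to_k, from, to, proportion.
#' @export
class_hierarchy <- function(clusterings) {
  ns <- vapply(clusterings, function(cl) length(cl$assignments), 1L)
  if (length(unique(ns)) != 1)
    srnaloc_error("clusterings cover different locus sets",
                  "invalid_argument")
  ks <- vapply(clusterings, `[[`, 1L, "k")
  ord <- order(ks, decreasing = TRUE)
  clusterings <- clusterings[ord]
  ks <- ks[ord]
  rows <- list()
  for (i in seq_len(length(clusterings) - 1)) {
    hi <- clusterings[[i]]; lo <- clusterings[[i + 1]]
    tab <- table(hi$assignments, lo$assignments)
    prop <- tab / pmax(rowSums(tab), 1)
    for (from in rownames(prop)) for (to in colnames(prop)) {
      rows[[length(rows) + 1L]] <- data.frame(
        from_k = hi$k, to_k = lo$k, from = from, to = to,
        proportion = as.numeric(prop[from, to]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paragon loci per class
#'
#' The n loci of each class nearest (Euclidean) to the class centroid in
#' the clustering's reduced coordinates; ties broken by locus id order.
#'
#' @param clustering \code{srna_clustering}.
#' @param coords Coordinates used for the clustering (loci x dims).
#' @param locus_ids Character vector of locus ids aligned with rows.
#' @param n_per_class Number of paragons per class (default 1).
#' @return data.frame: class, locus_id, distance.
#' @export
find_paragons <- function(clustering, coords, locus_ids,
                          n_per_class = 1L) {
  coords <- as.matrix(coords)[, seq_len(clustering$dims), drop = FALSE]
  rows <- list()
  for (cl in rownames(clustering$centroids)) {
    idx <- which(clustering$assignments == cl)
    if (!length(idx)) next
    d <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2,
                            clustering$centroids[cl, ])^2))
    ord <- order(d, locus_ids[idx])
    take <- ord[seq_len(min(n_per_class, length(ord)))]
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, locus_id = locus_ids[idx][take], distance = d[take],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify loci from a feature table
#'
#' Convenience wrapper over the classification stage: builds the indicator
#' matrix (annotation overlap columns held out), fits MCA, selects the
#' number of dimensions if not fixed, selects k, clusters and derives
#' enrichment and paragons. The number of classes is taken from the gap
#' statistic's one-standard-error rule when that rule lands inside the
#' scanned range; when it runs to a boundary (no interior elbow), k is
#' chosen as the clustering sharing the most information (mean NMI) with
#' the held-out annotation-overlap columns.
#'
#' @param feature_table data.frame with locus_id and feature columns.
#' @param config Resolved configuration.
#' @param seed Integer seed (defaults to the config seed).
#' @return List: mca, indicator, dims, gap, validation (per-k mean NMI
#'   against held-out annotation columns, NULL when the gap rule decided),
#'   clustering, enrichment, paragons.
#' @export
classify_loci <- function(feature_table, config = default_config(),
                          seed = config$seed) {
  ccfg <- config$classification
  indicator <- build_indicator_matrix(feature_table,
                                      exclude = ccfg$held_out)
  mca <- fit_mca(indicator)
  d <- ccfg$dims
  if (is.null(d)) {
    # variance elbow: keep dimensions whose share of inertia stands clear
    # of the noise floor (twice the median share across the spectrum);
    # trailing noise dimensions dilute the cluster geometry and flatten
    # the gap-statistic curve past the true k
    ev <- mca$explained_variance
    d <- min(max(2L, sum(ev > 2 * stats::median(ev))),
             ncol(mca$row_coords))
  }
  coords <- mca$row_coords[, seq_len(d), drop = FALSE]
  gap <- gap_statistic(coords, k_range = ccfg$k_range, B_ref = ccfg$gap_B,
                       seed = derive_seed(seed, "gap"))
  validation <- NULL
  k <- ccfg$fixed_k
  if (is.null(k)) {
    k <- gap$k_hat
    if (k <= 1L || k >= max(ccfg$k_range)) {
      # The one-standard-error rule found no interior elbow: a handful of
      # outlying loci (e.g. sparse loci whose features are mostly unknown)
      # elongate the uniform reference box and push the rule to a boundary
      # of the scanned range. In that case fall back to the held-out
      # annotation standard: choose the k whose clustering shares the most
      # information with the annotation-overlap columns that were excluded
      # from the MCA for exactly this purpose.
      held <- intersect(ccfg$held_out, colnames(feature_table))
      ks <- setdiff(ccfg$k_range, 1L)
      if (length(held) && length(ks)) {
        score <- vapply(ks, function(kk) {
          cl <- kmeans_cluster(coords, kk,
                               seed = derive_seed(seed, "cluster"),
                               restarts = ccfg$kmeans_restarts)
          mean(vapply(held, function(h)
            nmi(cl$assignments, as.character(feature_table[[h]])), 1.0))
        }, 1.0)
        validation <- data.frame(k = ks, mean_nmi = score)
        k <- ks[which.max(score)]
      } else {
        k <- max(k, 2L)
      }
    }
  }
  clustering <- kmeans_cluster(coords, k,
                               seed = derive_seed(seed, "cluster"),
                               restarts = ccfg$kmeans_restarts)
  enrichment <- enrichment_tests(clustering$assignments, feature_table)
  paragons <- find_paragons(clustering, coords, feature_table$locus_id)
  list(mca = mca, indicator = indicator, dims = d, gap = gap,
       validation = validation, clustering = clustering,
       enrichment = enrichment, paragons = paragons)
}
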