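# Indicator coding, MCA, clustering, cluster-number selection and the
# validation machinery (NMI, enrichment, hierarchy, paragons).

test_that("disjunctive coding yields one column per level and row sums equal the feature count", {
  ft <- data.frame(locus_id = paste0("L", 1:6),
                   a = c("x", "y", "z", "x", "y", "z"),
                   b = c("p", "q", "p", "q", "p", "q"),
                   stringsAsFactors = FALSE)
  ind <- build_indicator_matrix(ft)
  expect_equal(ncol(ind$Z), 5)
  expect_true(all(rowSums(ind$Z) == 2))
  expect_identical(ind$Z, build_indicator_matrix(ft)$Z)
})

test_that("an unknown level is coded as an ordinary column", {
  ft <- data.frame(locus_id = c("L1", "L2"),
                   ratio = c("unknown", "high"),
                   strand = c("no", "strong"), stringsAsFactors = FALSE)
  ind <- build_indicator_matrix(ft)
  expect_true("ratio.unknown" %in% colnames(ind$Z))
  expect_equal(unname(ind$Z[1, "ratio.unknown"]), 1)
})

test_that("a single-level feature is dropped with a warning", {
  ft <- data.frame(locus_id = c("L1", "L2"), a = c("x", "y"),
                   b = c("same", "same"), stringsAsFactors = FALSE)
  expect_warning(ind <- build_indicator_matrix(ft), "single observed level")
  expect_equal(ind$n_features, 1)
})

test_that("total inertia of a complete indicator equals categories over features minus one", {
  set.seed(2)
  ft <- data.frame(locus_id = paste0("L", 1:40),
                   a = sample(c("x", "y", "z"), 40, replace = TRUE),
                   b = sample(c("p", "q"), 40, replace = TRUE),
                   c = sample(c("u", "v", "w", "t"), 40, replace = TRUE),
                   stringsAsFactors = FALSE)
  ind <- build_indicator_matrix(ft)
  mca <- fit_mca(ind)
  J <- ncol(ind$Z); Q <- ind$n_features
  expect_equal(mca$total_inertia, J / Q - 1, tolerance = 1e-10)
  expect_equal(sum(mca$explained_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(mca$eigenvalues) <= 1e-12))
})

test_that("MCA eigenvalues match brute-force eigendecomposition of the residual cross-product", {
  ft <- data.frame(locus_id = paste0("L", 1:6),
                   a = c("x", "x", "y", "y", "z", "z"),
                   b = c("p", "q", "p", "q", "p", "q"),
                   stringsAsFactors = FALSE)
  ind <- build_indicator_matrix(ft)
  Z <- ind$Z
  N <- sum(Z); P <- Z / N
  r <- rowSums(P); cc <- colSums(P)
  S <- sweep(sweep(P - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  ev_oracle <- sort(eigen(t(S) %*% S, symmetric = TRUE)$values,
                    decreasing = TRUE)
  mca <- fit_mca(ind)
  got <- mca$eigenvalues
  expect_equal(got, ev_oracle[seq_along(got)], tolerance = 1e-10)
})

test_that("squared distances in full principal coordinates equal chi-square distances", {
  set.seed(9)
  ft <- data.frame(locus_id = paste0("L", 1:20),
                   a = sample(c("x", "y", "z"), 20, replace = TRUE),
                   b = sample(c("p", "q"), 20, replace = TRUE),
                   c = sample(c("u", "v", "w"), 20, replace = TRUE),
                   stringsAsFactors = FALSE)
  ind <- build_indicator_matrix(ft)
  mca <- fit_mca(ind)
  Z <- ind$Z
  prof <- Z / rowSums(Z)                  # row profiles
  cc <- colSums(Z) / sum(Z)               # column masses
  chi2 <- function(i, j) sum((prof[i, ] - prof[j, ])^2 / cc)
  for (pair in list(c(1, 2), c(3, 10), c(5, 20))) {
    d2 <- sum((mca$row_coords[pair[1], ] - mca$row_coords[pair[2], ])^2)
    expect_equal(d2, chi2(pair[1], pair[2]), tolerance = 1e-8)
  }
})

test_that("k-means at k=1 returns the global mean and the total sum of squares", {
  set.seed(4)
  x <- matrix(rnorm(60), 30, 2)
  cl <- kmeans_cluster(x, 1)
  expect_equal(as.numeric(cl$centroids), colMeans(x), tolerance = 1e-9)
  expect_equal(cl$inertia, sum(sweep(x, 2, colMeans(x))^2),
               tolerance = 1e-9)
})

test_that("three separated blobs partition exactly with size-ordered labels", {
  set.seed(6)
  x <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
             matrix(rnorm(60, 5, 0.1), ncol = 2),
             matrix(rnorm(30, -5, 0.1), ncol = 2))
  truth <- rep(c("a", "b", "c"), c(50, 30, 15))
  cl <- kmeans_cluster(x, 3, seed = 6)
  expect_equal(nmi(cl$assignments, truth), 1)
  expect_equal(cl$sizes, c(50, 30, 15))
  expect_equal(as.character(cl$assignments[1]), "LC1")
})

test_that("k-means is deterministic under the seed", {
  set.seed(8)
  x <- matrix(rnorm(200), 100, 2)
  a <- kmeans_cluster(x, 4, seed = 11)
  b <- kmeans_cluster(x, 4, seed = 11)
  expect_identical(a$assignments, b$assignments)
  expect_equal(a$inertia, b$inertia)
})

test_that("gap statistic finds one cluster in a uniform blob and three in separated blobs", {
  set.seed(13)
  blob <- matrix(runif(400), 200, 2)
  expect_equal(gap_statistic(blob, k_range = 1:5, seed = 13)$k_hat, 1L)
  three <- rbind(matrix(rnorm(140, 0, 0.15), ncol = 2),
                 matrix(rnorm(140, 4, 0.15), ncol = 2),
                 cbind(rnorm(70, 0, 0.15), rnorm(70, 4, 0.15)))
  expect_equal(gap_statistic(three, k_range = 1:5, seed = 13)$k_hat, 3L)
})

test_that("within-cluster dispersion never increases with k", {
  set.seed(14)
  x <- matrix(rnorm(300), 150, 2)
  tab <- gap_statistic(x, k_range = 1:6, seed = 14)$table
  expect_true(all(diff(tab$logW) <= 1e-9))
})

test_that("NMI is one for identical, zero for independent labelings and matches the entropy oracle", {
  a <- rep(c("x", "y"), each = 4)
  expect_equal(nmi(a, a), 1)
  # product contingency: each combination equally populated
  b <- rep(c("p", "q"), 4)
  expect_equal(nmi(a, b), 0)
  # contingency [[3,1],[1,3]]
  a2 <- rep(c("x", "x", "y", "y"), c(3, 1, 1, 3))
  b2 <- rep(c("p", "q", "p", "q"), c(3, 1, 1, 3))
  expect_equal(nmi(a2, b2), as.numeric(oracle_nmi(a2, b2)),
               tolerance = 1e-12)
  expect_equal(nmi(rep("z", 5), rep("z", 5)), 1)
  expect_error(nmi(a, a[1:3]), class = "invalid_argument")
})

test_that("assignment solver reaches the brute-force minimum cost", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n)
    a <- solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 oracle_assignment_cost(cost), tolerance = 1e-12)
  }
})

test_that("a level exclusive to one class is strongly enriched at the hypergeometric p", {
  assignments <- factor(rep(c("LC1", "LC2"), each = 10))
  ft <- data.frame(locus_id = paste0("L", 1:20),
                   f = rep(c("hit", "miss"), each = 10),
                   stringsAsFactors = FALSE)
  enr <- enrichment_tests(assignments, ft)
  row <- enr[enr$class == "LC1" & enr$level == "hit", ]
  expect_equal(row$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(row$sign, "enriched")
  miss <- enr[enr$class == "LC1" & enr$level == "miss", ]
  expect_equal(miss$sign, "depleted")
})

test_that("a uniformly spread level is not significant after adjustment", {
  set.seed(19)
  assignments <- factor(rep(c("LC1", "LC2"), each = 50))
  ft <- data.frame(locus_id = paste0("L", 1:100),
                   f = sample(rep(c("u", "v"), 50)),
                   stringsAsFactors = FALSE)
  enr <- enrichment_tests(assignments, ft)
  expect_true(all(enr$p_adj > 0.05))
})

test_that("hierarchy flows are proportions summing to one and respect nesting", {
  x <- matrix(c(rnorm(100, 0, 0.05), rnorm(100, 3, 0.05),
                rnorm(100, 6, 0.05), rnorm(100, 9, 0.05)), ncol = 2)
  k4 <- kmeans_cluster(x, 4, seed = 3)
  k2 <- kmeans_cluster(x, 2, seed = 3)
  fl <- class_hierarchy(list(k2, k4))
  expect_equal(fl$from_k[1], 4)
  sums <- tapply(fl$proportion, fl$from, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # the four tight blobs nest perfectly into the two super-blobs
  expect_true(all(fl$proportion %in% c(0, 1)))
})

test_that("paragons are the loci nearest their class centroid with id tie-breaking", {
  coords <- matrix(c(0, 0, 0.1, 0, -0.1, 0, 5, 0), ncol = 2, byrow = TRUE)
  cl <- kmeans_cluster(coords, 2, seed = 2)
  ids <- c("L1", "L2", "L3", "L4")
  par <- find_paragons(cl, coords, ids)
  expect_equal(nrow(par), 2)
  expect_true("L1" %in% par$locus_id)   # exact centroid of the triplet
  expect_true("L4" %in% par$locus_id)   # singleton class returns itself
  # symmetric pair equidistant from their centroid: lower id wins
  pair <- matrix(c(0, 0, 1, 0, 10, 10, 11, 10), ncol = 2, byrow = TRUE)
  cl2 <- kmeans_cluster(pair, 2, seed = 2)
  par2 <- find_paragons(cl2, pair, c("La", "Lb", "Lc", "Ld"))
  expect_setequal(par2$locus_id, c("La", "Lc"))
})

test_that("bootstrap stability is high for planted classes and low for noise", {
  set.seed(23)
  n_per <- 30
  lv <- function(base, alt) c(rep(base, n_per), rep(alt, n_per),
                              sample(c(base, alt), n_per, replace = TRUE))
  ft <- data.frame(
    locus_id = paste0("L", 1:(3 * n_per)),
    a = c(rep("x", n_per), rep("y", n_per), rep("z", n_per)),
    b = c(rep("p", n_per), rep("q", n_per), rep("r", n_per)),
    c = c(rep("u", n_per), rep("v", n_per), rep("w", n_per)),
    stringsAsFactors = FALSE)
  ind <- build_indicator_matrix(ft)
  sel <- select_dimensions(ind, k_range = 3, dims_range = 1:3, B = 20L,
                           seed = 23, target_k = 3)
  d2 <- sel$stability[sel$stability$d == 2, ]
  expect_gte(median(d2$median), 0.9)
  expect_lte(sel$recommended_d, 2)

  noise <- data.frame(
    locus_id = paste0("N", 1:60),
    a = sample(c("x", "y"), 60, replace = TRUE),
    b = sample(c("p", "q"), 60, replace = TRUE),
    c = sample(c("u", "v"), 60, replace = TRUE),
    stringsAsFactors = FALSE)
  seln <- select_dimensions(build_indicator_matrix(noise), k_range = 3,
                            dims_range = 2, B = 20L, seed = 24,
                            target_k = 3)
  expect_lt(median(seln$stability$median), 0.7)
})

test_that("classify_loci honours a pinned cluster number", {
  set.seed(27)
  sim <- simulate_feature_table(default_archetypes(n_loci = 40L),
                                seed = 27)
  cfg <- default_config()
  cfg$classification$fixed_k <- 5L
  cls <- classify_loci(sim$features, cfg)
  expect_equal(cls$clustering$k, 5L)
  expect_equal(length(cls$clustering$assignments), nrow(sim$features))
})
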