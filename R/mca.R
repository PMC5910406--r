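# Multiple correspondence analysis: correspondence analysis of the
# complete disjunctive (indicator) coding of the categorical feature table.

#' Build the complete disjunctive indicator matrix
#'
#' One column per observed (feature, level) pair; each locus row has a 1 in
#' exactly one column per feature, so row sums equal the number of
#' features. "unknown" is a real level, not missing data. Features with a
#' single observed level carry no information and are dropped with a
#' warning.
#'
#' @param feature_table data.frame with locus_id and categorical columns.
#' @param include Character vector of feature columns to code; defaults to
#'   every column except locus_id.
#' @param exclude Character vector of columns to hold out (e.g. annotation
#'   overlap indicators kept for validation).
#' @return List: \code{Z} (numeric indicator matrix, columns named
#'   feature.level), \code{categories} (data.frame feature/level),
#'   \code{n_features}.
#' @export
build_indicator_matrix <- function(feature_table, include = NULL,
                                   exclude = character()) {
  cols <- if (is.null(include))
    setdiff(names(feature_table), "locus_id") else include
  cols <- setdiff(cols, exclude)
  blocks <- list(); cats <- list()
  for (f in cols) {
    v <- as.character(feature_table[[f]])
    levels <- sort(unique(v), method = "radix")
    if (length(levels) < 2) {
      warning("feature '", f, "' has a single observed level; dropped")
      next
    }
    m <- matrix(0, length(v), length(levels),
                dimnames = list(NULL, paste(f, levels, sep = ".")))
    m[cbind(seq_along(v), match(v, levels))] <- 1
    blocks[[f]] <- m
    cats[[f]] <- data.frame(feature = f, level = levels,
                            stringsAsFactors = FALSE)
  }
  if (!length(blocks))
    srnaloc_error("no codable features (need >= 2 observed levels)",
                  "invalid_argument")
  list(Z = do.call(cbind, blocks), categories = do.call(rbind, cats),
       n_features = length(blocks))
}

#' Fit multiple correspondence analysis
#'
#' Correspondence analysis of the indicator matrix: with P = Z / N, row
#' masses r and column masses c, the standardized residual matrix
#' S = Dr^{-1/2} (P - r c') Dc^{-1/2} is decomposed by SVD. Eigenvalues
#' are the squared singular values; row principal coordinates are
#' Dr^{-1/2} U D; explained variance is each eigenvalue over the total
#' inertia. For a complete disjunctive table of Q features and J observed
#' categories the total inertia is J/Q - 1. No Benzecri/Greenacre
#' eigenvalue correction is applied.
#'
#' @param indicator Result of \code{\link{build_indicator_matrix}} or a
#'   plain 0/1 indicator matrix.
#' @param tol Eigenvalues below \code{tol} are dropped.
#' @return Object of class \code{srna_mca}: eigenvalues,
#'   explained_variance (percent), row_coords, col_coords, masses,
#'   categories, total_inertia.
#' @export
fit_mca <- function(indicator, tol = 1e-10) {
  if (is.list(indicator) && !is.null(indicator$Z)) {
    Z <- indicator$Z
    categories <- indicator$categories
  } else {
    Z <- as.matrix(indicator)
    categories <- data.frame(feature = NA_character_,
                             level = colnames(Z),
                             stringsAsFactors = FALSE)
  }
  if (nrow(Z) < ncol(Z))
    warning("fewer loci than categories; trailing dimensions are noise")
  N <- sum(Z)
  P <- Z / N
  r <- rowSums(P)
  cc <- colSums(P)
  S <- sweep(sweep(P - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  sv <- svd(S)
  ev <- sv$d^2
  keep <- which(ev > tol)
  ev <- ev[keep]
  row_coords <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/") %*%
    diag(sv$d[keep], length(keep))
  col_coords <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cc), "/") %*%
    diag(sv$d[keep], length(keep))
  dimnames(row_coords) <- list(NULL, paste0("dim", seq_along(keep)))
  dimnames(col_coords) <- list(colnames(Z), paste0("dim", seq_along(keep)))
  total_inertia <- sum(sv$d^2)
  structure(list(
    eigenvalues = ev,
    explained_variance = 100 * ev / total_inertia,
    row_coords = row_coords, col_coords = col_coords,
    masses = list(row = r, col = cc),
    categories = categories, total_inertia = total_inertia
  ), class = "srna_mca")
}

#' @export
print.srna_mca <- function(x, ...) {
  cat("srna_mca:", nrow(x$row_coords), "loci,",
      length(x$eigenvalues), "dimensions; top variance%:",
      paste(round(utils::head(x$explained_variance, 5), 1),
            collapse = ", "), "\n")
  invisible(x)
}
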