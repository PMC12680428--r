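#' PCA of imputed genotype dosages
#'
#' Column-centers (optionally unit-variance scales) the dosage matrix and
#' takes the singular value decomposition; scores are left singular vectors
#' times singular values, eigenvalues are squared singular values divided by
#' `n - 1`.
#'
#' @param X Numeric individuals x loci matrix with no missing cells (see
#'   [impute_within_population()]), or a [genotype_matrix] (imputed
#'   internally).
#' @param scaling `"center_unit"` (default) or `"center"`. Constant columns
#'   contribute zero after unit scaling.
#'
#' @return A list of class `genotype_pca` with `scores`, `loadings`,
#'   `eigenvalues`, `prop_var` and `scaling`.
#' @export
pca_genotypes <- function(X, scaling = c("center_unit", "center")) {
  scaling <- match.arg(scaling)
  if (inherits(X, "genotype_matrix")) X <- impute_within_population(X)
  if (anyNA(X)) stop("X has missing cells; impute first")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (scaling == "center_unit") {
    s <- apply(Xc, 2, stats::sd)
    s[s == 0] <- 1                        # constant loci contribute zero
    Xc <- sweep(Xc, 2, s, "/")
  }
  if (all(abs(Xc) < 1e-12)) stop("constant matrix: PCA undefined")
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  rownames(scores) <- rownames(X)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(X)
  eig <- d^2 / (nrow(Xc) - 1)
  structure(list(scores = scores, loadings = loadings, eigenvalues = eig,
                 prop_var = eig / sum(eig), scaling = scaling),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d axes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$eigenvalues), 100 * x$prop_var[1],
              if (length(x$prop_var) > 1) 100 * x$prop_var[2] else NA))
  invisible(x)
}

#' Permutation test of structure recovered by a SNP subset
#'
#' Compares the first principal component of a PCA restricted to a locus
#' subset against the full-panel PC1: the statistic is the squared Pearson
#' correlation of the two score vectors after sign alignment (the SVD sign
#' being arbitrary, each subset PC is flipped to maximize the correlation).
#' The null distribution is built from random subsets of the same size;
#' the p-value uses the add-one convention.
#'
#' @param X Imputed numeric dosage matrix (individuals x loci) or a
#'   [genotype_matrix].
#' @param subset_loci Locus ids (matching `colnames`) or column indices;
#'   at least 2.
#' @param n_perm Number of random subsets (default 10000).
#' @param axis Principal component to compare (default 1); with
#'   `method = "procrustes"`, the number of leading axes compared.
#' @param scaling Passed to [pca_genotypes()].
#' @param method `"pc_cor"` (default; squared correlation of one PC) or
#'   `"procrustes"` (multi-axis Procrustes correlation of the leading
#'   `axis` score matrices, via [vegan::protest()]'s statistic).
#'
#' @return A list of class `pc_subset_test` with `r_squared`, `p`, `n_perm`
#'   and the `null_r_squared` vector.
#' @export
pc_subset_correlation_test <- function(X, subset_loci, n_perm = 10000,
                                       axis = 1, scaling = "center_unit",
                                       method = c("pc_cor", "procrustes")) {
  method <- match.arg(method)
  if (inherits(X, "genotype_matrix")) X <- impute_within_population(X)
  if (is.character(subset_loci)) {
    subset_idx <- match(subset_loci, colnames(X))
    if (anyNA(subset_idx)) stop("unknown locus id in `subset_loci`")
  } else subset_idx <- as.integer(subset_loci)
  if (length(subset_idx) < 2) stop("subset must contain at least 2 loci")

  full_pca <- pca_genotypes(X, scaling)
  full <- full_pca$scores[, axis]
  score_r2 <- function(idx) {
    sub <- pca_genotypes(X[, idx, drop = FALSE], scaling)$scores
    if (method == "procrustes") {
      k <- min(max(axis), ncol(sub))
      pr <- vegan::procrustes(full_pca$scores[, seq_len(k), drop = FALSE],
                              sub[, seq_len(k), drop = FALSE],
                              symmetric = TRUE)
      return(1 - pr$ss)                  # squared Procrustes correlation
    }
    if (ncol(sub) < axis) return(0)
    stats::cor(full, sub[, axis])^2      # sign alignment is implicit in r^2
  }
  obs <- score_r2(subset_idx)
  k <- length(subset_idx)
  null <- vapply(seq_len(n_perm), function(i)
    score_r2(sample(ncol(X), k)), numeric(1))
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  structure(list(r_squared = obs, p = p, n_perm = n_perm,
                 null_r_squared = null),
            class = "pc_subset_test")
}

#' @export
print.pc_subset_test <- function(x, ...) {
  cat(sprintf("PC subset correlation: R^2 = %.3f, permutation p = %.4g (%d subsets)\n",
              x$r_squared, x$p, x$n_perm))
  invisible(x)
}
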