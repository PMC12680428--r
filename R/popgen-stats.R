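#' Observed and expected heterozygosity and F_IS
#'
#' Per-locus observed heterozygosity is the fraction of heterozygotes among
#' non-missing calls; expected heterozygosity is Nei's unbiased
#' within-population gene diversity `2 p (1 - p) * 2n / (2n - 1)`. Population
#' values are means over loci, overall values unweighted means over
#' populations, and `F_IS = 1 - H_o / H_e` wherever `H_e > 0`.
#'
#' @param G A [genotype_matrix].
#' @param unbiased Use Nei's small-sample correction for H_e (default
#'   `TRUE`); `FALSE` gives plain `2pq`.
#'
#' @return A list of class `diversity_stats` with a `per_population` data
#'   frame (`population`, `n`, `Ho`, `He`, `Fis`) and an `overall` list.
#' @export
heterozygosity_stats <- function(G, unbiased = TRUE) {
  v <- gt_numeric(G)
  pops <- sort(unique(G$population_labels))
  if (!any(table(G$population_labels) >= 2))
    stop("need at least one population with two or more individuals")
  res <- data.frame(population = pops, n = NA_real_, Ho = NA_real_,
                    He = NA_real_, Fis = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pops)) {
    sub <- v[G$population_labels == pops[i], , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    use <- n_obs >= if (unbiased) 2 else 1
    res$n[i] <- nrow(sub)
    if (nrow(sub) < 2 && unbiased) next     # H_e undefined, flagged as NA
    ho <- colSums(sub == 1, na.rm = TRUE) / n_obs
    p <- colSums(sub, na.rm = TRUE) / (2 * n_obs)
    he <- 2 * p * (1 - p)
    if (unbiased) he <- he * (2 * n_obs) / (2 * n_obs - 1)
    res$Ho[i] <- mean(ho[use])
    res$He[i] <- mean(he[use])
    res$Fis[i] <- if (res$He[i] > 0) 1 - res$Ho[i] / res$He[i] else NA_real_
  }
  overall <- list(Ho = mean(res$Ho, na.rm = TRUE),
                  He = mean(res$He, na.rm = TRUE))
  overall$Fis <- if (overall$He > 0) 1 - overall$Ho / overall$He else NA_real_
  structure(list(per_population = res, overall = overall),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("diversity_stats (%d populations): Ho = %.4f, He = %.4f, Fis = %.4f\n",
              nrow(x$per_population), x$overall$Ho, x$overall$He,
              x$overall$Fis))
  invisible(x)
}

# Weir & Cockerham (1984) per-locus variance components a (among
# populations), b (among individuals within populations) and c (within
# individuals), for the loci of a numeric dosage matrix split by `pops`.
wc_components <- function(v, pops) {
  pop_levels <- sort(unique(pops))
  L <- ncol(v)
  a <- b <- cc <- rep(NA_real_, L)
  n_mat <- h_mat <- p_mat <- matrix(NA_real_, length(pop_levels), L)
  for (i in seq_along(pop_levels)) {
    sub <- v[pops == pop_levels[i], , drop = FALSE]
    n_mat[i, ] <- colSums(!is.na(sub))
    p_mat[i, ] <- colSums(sub, na.rm = TRUE) / (2 * n_mat[i, ])
    h_mat[i, ] <- colSums(sub == 1, na.rm = TRUE) / n_mat[i, ]
  }
  for (l in seq_len(L)) {
    use <- which(n_mat[, l] > 0)
    r <- length(use)
    if (r < 2) next
    n_i <- n_mat[use, l]; p_i <- p_mat[use, l]; h_i <- h_mat[use, l]
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (nbar <= 1 || nc <= 0) next
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc[l] <- hbar / 2
  }
  data.frame(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST
#'
#' Multilocus Weir & Cockerham (1984) theta as the ratio of summed
#' among-population variance components to summed total components (not the
#' mean of per-locus ratios), with optional pairwise population estimates
#' computed on each population pair alone. Negative pairwise estimates are
#' reported as-is.
#'
#' @param G A [genotype_matrix].
#' @param mode `"global"` or `"pairwise"` (pairwise also returns the global
#'   estimate).
#'
#' @return A list of class `fst_result` with `global`, `per_locus`
#'   (components and per-locus theta) and, in pairwise mode, a symmetric
#'   `pairwise` matrix.
#' @export
wc_fst <- function(G, mode = c("global", "pairwise")) {
  mode <- match.arg(mode)
  pops <- G$population_labels
  if (length(unique(pops)) < 2) stop("need at least two populations")
  v <- gt_numeric(G)
  comp <- wc_components(v, pops)
  tot <- comp$a + comp$b + comp$c
  usable <- !is.na(tot) & tot > 0
  if (!any(usable))
    stop("F_ST undefined: all loci monomorphic or unusable")
  global <- sum(comp$a[usable]) / sum(tot[usable])
  per_locus <- data.frame(locus_id = G$locus_ids, comp,
                          fst = ifelse(usable, comp$a / tot, NA_real_),
                          stringsAsFactors = FALSE)
  pairwise <- NULL
  if (mode == "pairwise") {
    lev <- sort(unique(pops))
    pairwise <- matrix(0, length(lev), length(lev),
                       dimnames = list(lev, lev))
    for (i in seq_along(lev)[-length(lev)]) {
      for (j in seq((i + 1), length(lev))) {
        rows <- pops %in% lev[c(i, j)]
        cij <- wc_components(v[rows, , drop = FALSE], pops[rows])
        tij <- cij$a + cij$b + cij$c
        ok <- !is.na(tij) & tij > 0
        pairwise[i, j] <- pairwise[j, i] <-
          if (any(ok)) sum(cij$a[ok]) / sum(tij[ok]) else NA_real_
      }
    }
  }
  structure(list(global = global, per_locus = per_locus,
                 pairwise = pairwise),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("fst_result: global Weir-Cockerham F_ST = %.4f (%d loci)\n",
              x$global, sum(!is.na(x$per_locus$fst))))
  invisible(x)
}

#' Linearize F_ST for isolation-by-distance tests
#'
#' @param fst F_ST value(s) or matrix.
#' @return `fst / (1 - fst)`.
#' @export
fst_linearize <- function(fst) fst / (1 - fst)

#' Geodesic distance matrix on the WGS84 ellipsoid
#'
#' Pairwise Vincenty ellipsoid distances (metres) between population
#' coordinates; pairs where the Vincenty iteration fails to converge fall
#' back to Karney's algorithm.
#'
#' @param coords Data frame with columns `population`, `lat`, `lon`
#'   (WGS84 decimal degrees).
#' @return Symmetric matrix of distances in metres with zero diagonal.
#' @export
geodesic_distances <- function(coords) {
  n <- nrow(coords)
  D <- matrix(0, n, n, dimnames = list(coords$population, coords$population))
  pts <- cbind(coords$lon, coords$lat)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- suppressWarnings(
        geosphere::distVincentyEllipsoid(pts[i, ], pts[j, ]))
      if (is.na(d)) d <- geosphere::distGeo(pts[i, ], pts[j, ])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Environmental Mahalanobis distances on the first two PCs
#'
#' Standardizes the environmental variables, runs a PCA, and computes
#' pairwise Mahalanobis distances between populations on the first two
#' component scores using the score covariance.
#'
#' @param env Environment data frame (a `population` column plus numeric
#'   variables; `scenario` is ignored).
#' @return Symmetric distance matrix with population dimnames.
#' @export
env_distances <- function(env) {
  X <- env_numeric(env)
  if (nrow(X) < 3) stop("need at least three populations")
  if (ncol(X) < 2) stop("need at least two environmental variables")
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  if (sum(pc$sdev > 1e-10) < 2)
    stop("environmental table has rank < 2")
  sc <- pc$x[, 1:2, drop = FALSE]
  S_inv <- solve(stats::cov(sc))
  n <- nrow(sc)
  D <- matrix(0, n, n, dimnames = list(env$population, env$population))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sc[i, ] - sc[j, ]
      D[i, j] <- D[j, i] <- sqrt(drop(t(d) %*% S_inv %*% d))
    }
  }
  D
}

# Numeric variable block of an environment table.
env_numeric <- function(env, variables = NULL) {
  drop_cols <- c("population", "scenario")
  vars <- setdiff(names(env), drop_cols)
  if (!is.null(variables)) {
    missing_v <- setdiff(variables, vars)
    if (length(missing_v) > 0)
      stop("variables absent from env table: ",
           paste(missing_v, collapse = ", "))
    vars <- variables
  }
  X <- as.matrix(env[, vars, drop = FALSE])
  if (!is.numeric(X)) stop("environmental variables must be numeric")
  rownames(X) <- env$population
  X
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal distance entries with a
#' permutation p-value (rows and columns of the second matrix permuted
#' jointly; add-one convention), as implemented by [vegan::mantel()].
#'
#' @param D1,D2 Symmetric distance matrices of identical shape (or `dist`
#'   objects).
#' @param n_perm Number of permutations (default 999).
#' @return A list of class `mantel_result` with `r`, `p` and `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999) {
  d1 <- stats::as.dist(D1)
  d2 <- stats::as.dist(D2)
  if (length(d1) != length(d2)) stop("distance matrices differ in shape")
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0)
    stop("Mantel r undefined for a constant distance matrix")
  m <- vegan::mantel(d1, d2, method = "pearson", permutations = n_perm)
  structure(list(r = unname(m$statistic), p = m$signif, n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
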