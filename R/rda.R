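#' Redundancy analysis (RDA) and partial RDA
#'
#' Constrained ordination of a multivariate response on a predictor block:
#' the column-centered response is regressed on the standardized predictors
#' by multivariate least squares and the fitted values are decomposed by
#' SVD, giving canonical eigenvalues (squared singular values over `n - 1`),
#' site scores and per-locus loadings. With a conditioning block `Z`
#' (partial RDA), response and predictors are first residualized on the
#' standardized conditioning variables; the reported R-squared is then
#' semipartial (constrained variance over the *total* response variance) and
#' the adjusted R-squared is the difference of Ezekiel-adjusted values of
#' the combined `[X Z]` and `Z`-only models, matching the convention of
#' variance partitioning.
#'
#' @param Y Response matrix (e.g. populations x loci allele frequencies) or
#'   a `pop_allele_freq`.
#' @param X Predictor matrix or data frame (standardized internally; the
#'   standardization constants are stored for later scenario projection).
#' @param Z Optional conditioning matrix or data frame.
#'
#' @return A list of class `rda_model`: `coefficients`, `eigenvalues`,
#'   `site_scores`, `loadings`, `biplot_scores`, `r_squared`,
#'   `adj_r_squared`, `rank`, plus the stored inputs and standardization
#'   constants.
#' @export
rda_fit <- function(Y, X, Z = NULL) {
  if (inherits(Y, "pop_allele_freq")) Y <- Y$freq
  Y <- as.matrix(Y)
  Xr <- as_predictor_matrix(X)
  if (nrow(Y) != nrow(Xr)) stop("Y and X rows are not aligned")
  n <- nrow(Y)
  x_center <- colMeans(Xr)
  x_scale <- apply(Xr, 2, stats::sd)
  if (any(x_scale == 0)) stop("constant predictor column")
  Xs <- scale(Xr, center = x_center, scale = x_scale)
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  ss_total <- sum(Yc^2)

  Zs <- NULL
  if (!is.null(Z)) {
    Zr <- as_predictor_matrix(Z)
    if (nrow(Zr) != n) stop("Y and Z rows are not aligned")
    Zs <- scale(Zr)
    qz <- qr(cbind(1, Zs))
    Yc <- qr.resid(qz, Yc)
    Xs <- qr.resid(qz, Xs)
    # predictors absorbed by the conditioning block carry no information;
    # their numerical-noise residuals must not define canonical axes
    keep_x <- sqrt(colSums(Xs^2)) > 1e-7 * sqrt(n - 1)
    Xs <- Xs[, keep_x, drop = FALSE]
  }
  p <- qr(Xs)$rank
  if (is.null(Z) && n <= p)
    stop("need more sites than predictors for an unconditioned RDA")

  qx <- qr(Xs)
  B <- qr.coef(qx, Yc)
  B[is.na(B)] <- 0
  fitted <- Xs %*% B
  sv <- svd(fitted)
  keep <- sv$d > max(sv$d, 1e-12) * 1e-8
  d <- sv$d[keep]
  eig <- d^2 / (n - 1)
  site_scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  rownames(site_scores) <- rownames(Y)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(Y)
  biplot <- suppressWarnings(stats::cor(Xs, site_scores))
  biplot[is.na(biplot)] <- 0

  r2 <- sum(fitted^2) / ss_total
  if (is.null(Z)) {
    adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  } else {
    # difference of Ezekiel-adjusted combined and conditioning-only models
    adj_of <- function(M) {
      qm <- qr(M)
      f <- qr.fitted(qm, sweep(Y, 2, y_center))
      rr <- sum(f^2) / ss_total
      pp <- qr(M)$rank - 1
      1 - (1 - rr) * (n - 1) / (n - pp - 1)
    }
    adj <- adj_of(cbind(1, Xs0 = scale(as_predictor_matrix(X)), Zs)) -
      adj_of(cbind(1, Zs))
  }
  structure(list(coefficients = B, eigenvalues = eig,
                 site_scores = site_scores, loadings = loadings,
                 biplot_scores = biplot, r_squared = r2,
                 adj_r_squared = adj, rank = p, n = n,
                 Y = Y, Yc = Yc, Xs = Xs, Zs = Zs,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center,
                 predictor_names = colnames(Xr)),
            class = "rda_model")
}

as_predictor_matrix <- function(X) {
  if (is.data.frame(X)) {
    num <- vapply(X, is.numeric, logical(1))
    X <- as.matrix(X[, num, drop = FALSE])
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf(
    "rda_model: %d axes, R^2 = %.4f, adjusted R^2 = %.4f (n = %d, rank %d)\n",
    length(x$eigenvalues), x$r_squared, x$adj_r_squared, x$n, x$rank))
  invisible(x)
}

#' Sequential permutation tests of RDA axes
#'
#' Tests axis `k` by permuting rows of the response residuals left after
#' removing the structure of the first `k - 1` canonical axes, refitting,
#' and comparing the permuted axis-`k` eigenvalue with the observed one
#' (add-one convention).
#'
#' @param model An `rda_model`.
#' @param n_perm Number of permutations (default 999; below 99 a warning is
#'   raised).
#' @param max_axes Number of leading axes to test (default all).
#' @return Numeric vector of per-axis p-values.
#' @export
anova_axes <- function(model, n_perm = 999, max_axes = NULL) {
  if (n_perm < 99) warning("fewer than 99 permutations")
  n_axes <- length(model$eigenvalues)
  if (!is.null(max_axes)) n_axes <- min(n_axes, max_axes)
  Yc <- model$Yc
  Xs <- model$Xs
  n <- nrow(Yc)
  qx <- qr(Xs)
  fitted <- qr.fitted(qx, Yc)
  sv <- svd(fitted)
  p_out <- numeric(n_axes)
  for (k in seq_len(n_axes)) {
    if (k == 1) {
      base <- matrix(0, n, ncol(Yc))
    } else {
      idx <- seq_len(k - 1)
      base <- sv$u[, idx, drop = FALSE] %*%
        diag(sv$d[idx], k - 1) %*% t(sv$v[, idx, drop = FALSE])
    }
    resid_k <- Yc - base
    obs <- model$eigenvalues[k]
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Yb <- base + resid_k[sample.int(n), , drop = FALSE]
      Yb <- sweep(Yb, 2, colMeans(Yb))
      fb <- qr.fitted(qx, Yb)
      db <- svd(fb, nu = 0, nv = 0)$d
      eb <- if (length(db) >= k) db[k]^2 / (n - 1) else 0
      if (eb >= obs) hits <- hits + 1L
    }
    p_out[k] <- (hits + 1) / (n_perm + 1)
  }
  p_out
}

#' Variance partitioning between environment and geography
#'
#' Adjusted-R-squared partition of the response between two predictor
#' blocks: `a` is the environment-exclusive fraction, `c` the
#' geography-exclusive fraction, `b` the confounded fraction, with
#' `a + b + c` equal (exactly, by construction) to the adjusted R-squared of
#' the combined model.
#'
#' @param Y Response matrix or `pop_allele_freq`.
#' @param X_env Environmental predictor block.
#' @param X_geo Geographic predictor block (e.g. selected dbMEMs).
#' @return A list of class `variance_partition` with fractions `a`, `b`,
#'   `c`, `unexplained`, the block-wise adjusted and raw R-squared values.
#' @export
variance_partition <- function(Y, X_env, X_geo) {
  m_env <- rda_fit(Y, X_env)
  m_geo <- rda_fit(Y, X_geo)
  comb <- cbind(as_predictor_matrix(X_env), as_predictor_matrix(X_geo))
  m_all <- rda_fit(Y, comb)
  a <- m_all$adj_r_squared - m_geo$adj_r_squared
  c_ <- m_all$adj_r_squared - m_env$adj_r_squared
  b <- m_all$adj_r_squared - a - c_
  structure(list(a = a, b = b, c = c_,
                 unexplained = 1 - m_all$adj_r_squared,
                 adj_r2 = c(env = m_env$adj_r_squared,
                            geo = m_geo$adj_r_squared,
                            combined = m_all$adj_r_squared),
                 raw_r2 = c(env = m_env$r_squared,
                            geo = m_geo$r_squared,
                            combined = m_all$r_squared)),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance_partition (adjusted R^2 fractions)\n")
  cat(sprintf("  env exclusive [a]: %7.4f\n", x$a))
  cat(sprintf("  confounded    [b]: %7.4f\n", x$b))
  cat(sprintf("  geo exclusive [c]: %7.4f\n", x$c))
  cat(sprintf("  unexplained      : %7.4f\n", x$unexplained))
  invisible(x)
}

#' RDA loading outliers
#'
#' Flags loci whose loading on any retained canonical axis lies more than
#' `sd_mult` standard deviations from that axis's mean loading (the SD is
#' taken over all loci, prospective outliers included), and annotates each
#' flagged locus with the environmental variable most correlated with its
#' population frequencies.
#'
#' @param model An `rda_model` fitted on population frequencies.
#' @param sd_mult Cutoff in standard deviations (default 2.5).
#' @param axes Integer vector of retained axes (e.g. those significant under
#'   [anova_axes()]); an empty vector yields an empty set with a warning.
#' @param env Optional environment table used for the per-locus annotation;
#'   defaults to the model's predictor block.
#'
#' @return A data frame of class `rda_outliers` with columns `locus_id`,
#'   `axis`, `loading` and `best_predictor`.
#' @export
rda_outliers <- function(model, sd_mult = 2.5, axes = 1L, env = NULL) {
  if (length(axes) == 0) {
    warning("no significant axes: empty outlier set")
    return(structure(data.frame(locus_id = character(0), axis = integer(0),
                                loading = numeric(0),
                                best_predictor = character(0)),
                     class = c("rda_outliers", "data.frame")))
  }
  axes <- axes[axes <= length(model$eigenvalues)]
  hits <- list()
  for (k in axes) {
    ld <- model$loadings[, k]
    z <- abs(ld - mean(ld)) > sd_mult * stats::sd(ld)
    if (any(z))
      hits[[length(hits) + 1]] <- data.frame(
        locus_id = rownames(model$loadings)[z], axis = k,
        loading = ld[z], stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(locus_id = character(0), axis = integer(0),
               loading = numeric(0))
  out <- out[!duplicated(out$locus_id), , drop = FALSE]  # union over axes
  Xann <- if (is.null(env)) model$Xs else scale(env_numeric(env))
  out$best_predictor <- vapply(out$locus_id, function(l) {
    fr <- model$Y[, l]
    cors <- abs(suppressWarnings(stats::cor(fr, Xann)))
    cors[is.na(cors)] <- 0
    colnames(Xann)[which.max(cors)]
  }, character(1))
  rownames(out) <- NULL
  structure(out, class = c("rda_outliers", "data.frame"))
}

#' Consensus of the three outlier panels
#'
#' Exact three-way intersection (the potential adaptive variants, PAV) with
#' all pairwise intersections for a Venn summary, plus the two-of-three
#' union used for sensitivity analyses.
#'
#' @param set_fst,set_pca,set_rda Character vectors of locus ids flagged by
#'   the F_ST scan, the PC Mahalanobis scan and the RDA loading scan.
#' @return A list of class `consensus_outliers` with `pav`, `two_of_three`,
#'   `pairwise` (list) and `counts`.
#' @export
consensus_outliers <- function(set_fst, set_pca, set_rda) {
  pav <- Reduce(intersect, list(set_fst, set_pca, set_rda))
  pw <- list(fst_pca = intersect(set_fst, set_pca),
             fst_rda = intersect(set_fst, set_rda),
             pca_rda = intersect(set_pca, set_rda))
  two <- sort(unique(unlist(pw)))
  structure(list(pav = sort(pav), two_of_three = two, pairwise = pw,
                 counts = c(fst = length(set_fst), pca = length(set_pca),
                            rda = length(set_rda), pav = length(pav),
                            two_of_three = length(two))),
            class = "consensus_outliers")
}

#' @export
print.consensus_outliers <- function(x, ...) {
  cat(sprintf(
    "consensus_outliers: %d / %d / %d method-wise; PAV = %d, two-of-three = %d\n",
    x$counts["fst"], x$counts["pca"], x$counts["rda"], x$counts["pav"],
    x$counts["two_of_three"]))
  invisible(x)
}
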