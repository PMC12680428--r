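#' Storey q-values
#'
#' False-discovery-rate adjusted significance with the simple tail estimate
#' of the null proportion, `pi0 = min(1, mean(p > 0.5) / 0.5)`, followed by
#' the step-up construction `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` on the
#' sorted p-values.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
storey_qvalues <- function(p_values) {
  p <- p_values
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Trimmed chi-square F_ST outlier scan
#'
#' Fits a scaled chi-square model `F_ST ~ (Fbar / df) * chi^2_df` to the
#' central (two-sided trimmed) part of the uncorrected per-locus F_ST
#' distribution — the putatively neutral loci — and calls outliers from the
#' right tail of the fitted distribution at a q-value threshold. The mean
#' parameter `Fbar` is profiled as the trimmed mean; `df` is fitted by
#' bounded scalar maximum likelihood on the trimmed (truncated) sample. Loci
#' with pooled expected heterozygosity below `h_min` are excluded from both
#' fitting and calling.
#'
#' The per-locus uncorrected F_ST is the sample-size-weighted among-population
#' variance of allele frequencies divided by `pbar (1 - pbar)`; it retains
#' the binomial sampling component, which the fitted `(df, Fbar)` absorb.
#'
#' @param G A [genotype_matrix].
#' @param trim Fraction trimmed from each tail before fitting (default 0.05).
#' @param h_min Minimum pooled expected heterozygosity (default 0.1).
#' @param q_threshold Outlier q-value threshold (default 0.05).
#'
#' @return A list of class `outflank_fit`: `df`, `fst_bar`, `trim`,
#'   and a `per_locus` data frame (`locus_id`, `he`, `fst`, `p`, `q`,
#'   `outlier`).
#' @export
outflank_scan <- function(G, trim = 0.05, h_min = 0.1, q_threshold = 0.05) {
  pops <- G$population_labels
  if (length(unique(pops)) < 2) stop("need at least two populations")
  v <- gt_numeric(G)
  pop_levels <- sort(unique(pops))
  r <- length(pop_levels)
  n_mat <- p_mat <- matrix(NA_real_, r, ncol(v))
  for (i in seq_len(r)) {
    sub <- v[pops == pop_levels[i], , drop = FALSE]
    n_mat[i, ] <- colSums(!is.na(sub))
    p_mat[i, ] <- colSums(sub, na.rm = TRUE) / (2 * n_mat[i, ])
  }
  w <- n_mat
  pm <- p_mat
  pm[n_mat == 0] <- 0                      # zero weight, value irrelevant
  pbar <- colSums(w * pm) / colSums(w)
  r_eff <- colSums(n_mat > 0)
  nbar <- colSums(n_mat) / pmax(r_eff, 1)
  s2 <- colSums(w * (sweep(pm, 2, pbar))^2) / ((r_eff - 1) * nbar)
  he <- 2 * pbar * (1 - pbar)
  fst <- ifelse(he > 0, s2 / (pbar * (1 - pbar)), NA_real_)

  eligible <- is.finite(fst) & he >= h_min
  fit <- fit_trimmed_chisq(fst[eligible], trim = trim)
  df_hat <- fit$df
  fbar <- fit$fst_bar

  p_val <- rep(NA_real_, length(fst))
  p_val[eligible] <- stats::pchisq(fst[eligible] * df_hat / fbar, df_hat,
                                   lower.tail = FALSE)
  q_val <- rep(NA_real_, length(fst))
  q_val[eligible] <- storey_qvalues(p_val[eligible])
  per_locus <- data.frame(locus_id = G$locus_ids, he = he, fst = fst,
                          p = p_val, q = q_val,
                          outlier = !is.na(q_val) & q_val <= q_threshold,
                          stringsAsFactors = FALSE)
  structure(list(df = df_hat, fst_bar = fbar, trim = c(trim, trim),
                 q_threshold = q_threshold, per_locus = per_locus),
            class = "outflank_fit")
}

#' @export
print.outflank_fit <- function(x, ...) {
  cat(sprintf(
    "outflank_fit: df = %.2f, mean F_ST = %.4f, %d outliers at q <= %.2f\n",
    x$df, x$fst_bar, sum(x$per_locus$outlier, na.rm = TRUE), x$q_threshold))
  invisible(x)
}

#' Fit a scaled chi-square to the trimmed core of an F_ST distribution
#'
#' Maximum-likelihood fit of `x ~ (Fbar / df) * chi^2_df` to the sample
#' between its `trim` and `1 - trim` quantiles, using the truncated-density
#' likelihood. `Fbar` is profiled as the trimmed mean; `df` is found by
#' bounded scalar optimization (tolerance 1e-8).
#'
#' @param fst_values Per-locus F_ST values.
#' @param trim Fraction trimmed from each tail (default 0.05).
#' @return A list with `df`, `fst_bar` and the trim bounds `lo`, `hi`.
#' @export
fit_trimmed_chisq <- function(fst_values, trim = 0.05) {
  x <- fst_values[is.finite(fst_values)]
  lo <- stats::quantile(x, trim, names = FALSE)
  hi <- stats::quantile(x, 1 - trim, names = FALSE)
  core <- x[x >= lo & x <= hi]
  if (length(core) < 50)
    stop("fewer than 50 loci inside the trim; fit unstable")
  fbar <- mean(core)
  negll <- function(df) {
    rate <- df / fbar
    denom <- stats::pchisq(hi * rate, df) - stats::pchisq(lo * rate, df)
    if (denom <= 0) return(1e10)
    -(sum(stats::dchisq(core * rate, df, log = TRUE)) +
        length(core) * log(rate) - length(core) * log(denom))
  }
  opt <- stats::optimize(negll, interval = c(0.5, 1000), tol = 1e-8)
  list(df = opt$minimum, fst_bar = fbar, lo = lo, hi = hi)
}

#' Automated Cattell scree rule
#'
#' Retains leading components while the drop between successive eigenvalues
#' exceeds a stated fraction of the total variance.
#'
#' @param eigenvalues Eigenvalues sorted descending.
#' @param threshold Drop-ratio threshold as a fraction of total variance
#'   (default 0.05).
#' @return Number of retained components (at least 1).
#' @export
cattell_k <- function(eigenvalues, threshold = 0.05) {
  if (length(eigenvalues) < 2) return(1L)
  drops <- -diff(eigenvalues) / sum(eigenvalues)
  k <- which(drops < threshold)
  if (length(k) == 0) length(eigenvalues) else max(1L, k[1])
}

#' Principal-component Mahalanobis outlier scan
#'
#' Dosages are centered and scaled per locus by `sqrt(2 phat (1 - phat))`,
#' the individuals are decomposed by PCA, and each locus is regressed on the
#' first `K` component scores. The per-locus vector of regression z-scores is
#' summarised as a Mahalanobis distance under the empirical (optionally
#' robust minimum-covariance-determinant) covariance; the genomic inflation
#' factor rescales the statistic, `lambda = median(D^2) / median(chi^2_K)`,
#' and p-values come from the upper chi-square tail of `D^2 / lambda`.
#'
#' @param G A [genotype_matrix] or an imputed numeric dosage matrix.
#' @param K Number of principal components retained (`NULL` applies
#'   [cattell_k()] to the scree).
#' @param robust Use the minimum-covariance-determinant estimate of the
#'   z-score covariance (default `FALSE`).
#' @param q_threshold Outlier q-value threshold (default 0.05).
#'
#' @return A list of class `pcadapt_result`: `K`, `lambda`, `eigenvalues`,
#'   and `per_locus` (`locus_id`, `stat`, `p`, `q`, `outlier`).
#' @export
pcadapt_scan <- function(G, K = NULL, robust = FALSE, q_threshold = 0.05) {
  locus_ids <- if (inherits(G, "genotype_matrix")) G$locus_ids else colnames(G)
  X <- if (inherits(G, "genotype_matrix")) impute_within_population(G) else G
  if (anyNA(X)) stop("dosage matrix has missing cells; impute first")
  n <- nrow(X)
  phat <- colMeans(X) / 2
  sdv <- sqrt(2 * phat * (1 - phat))
  keep <- sdv > 1e-12
  Xs <- sweep(sweep(X, 2, 2 * phat), 2, pmax(sdv, 1e-12), "/")
  sv <- svd(Xs)
  eig <- sv$d^2 / (n - 1)
  if (is.null(K)) K <- cattell_k(eig)
  if (K >= n) stop("K must be smaller than the number of individuals")
  if (K < 1 || K >= min(n, ncol(X))) stop("K out of range")

  U <- sv$u[, seq_len(K), drop = FALSE]     # orthonormal score directions
  B <- crossprod(U, Xs)                     # K x L regression coefficients
  rss <- colSums(Xs^2) - colSums(B^2)
  sigma2 <- rss / pmax(n - K - 1, 1)
  Z <- t(B) / sqrt(pmax(sigma2, 1e-300))    # L x K z-scores
  Z <- Z[keep, , drop = FALSE]

  if (robust) {
    rob <- MASS::cov.rob(Z, method = "mcd")
    covZ <- rob$cov; ctrZ <- rob$center
  } else {
    covZ <- stats::cov(Z); ctrZ <- colMeans(Z)
  }
  d2 <- stats::mahalanobis(Z, center = ctrZ, cov = covZ)
  lambda <- stats::median(d2) / stats::qchisq(0.5, K)
  p <- stats::pchisq(d2 / lambda, K, lower.tail = FALSE)

  stat <- p_all <- q_all <- rep(NA_real_, length(locus_ids))
  stat[keep] <- d2
  p_all[keep] <- p
  q_all[keep] <- storey_qvalues(p)
  per_locus <- data.frame(locus_id = locus_ids, stat = stat, p = p_all,
                          q = q_all,
                          outlier = !is.na(q_all) & q_all <= q_threshold,
                          stringsAsFactors = FALSE)
  structure(list(K = K, lambda = lambda, eigenvalues = eig,
                 q_threshold = q_threshold, per_locus = per_locus),
            class = "pcadapt_result")
}

#' @export
print.pcadapt_result <- function(x, ...) {
  cat(sprintf(
    "pcadapt_result: K = %d, lambda = %.3f, %d outliers at q <= %.2f\n",
    x$K, x$lambda, sum(x$per_locus$outlier, na.rm = TRUE), x$q_threshold))
  invisible(x)
}

#' Write per-locus scan results as TSV
#'
#' Joins the per-locus tables of the three scans on locus id.
#'
#' @param outflank An `outflank_fit`.
#' @param pcadapt A `pcadapt_result`.
#' @param rda_loci Character vector of RDA-flagged locus ids (optional).
#' @param path Output TSV path.
#' @return Invisibly, the merged data frame.
#' @export
write_scan_results <- function(outflank, pcadapt, rda_loci = character(0),
                               path) {
  out <- data.frame(locus_id = outflank$per_locus$locus_id,
                    fst = outflank$per_locus$fst,
                    p_outflank = outflank$per_locus$p,
                    q_outflank = outflank$per_locus$q,
                    flag_outflank = outflank$per_locus$outlier,
                    stat_pcadapt = pcadapt$per_locus$stat,
                    p_pcadapt = pcadapt$per_locus$p,
                    q_pcadapt = pcadapt$per_locus$q,
                    flag_pcadapt = pcadapt$per_locus$outlier,
                    flag_rda = outflank$per_locus$locus_id %in% rda_loci,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
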