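#' Collinearity pruning of environmental predictors
#'
#' Two passes: while any pair of variables has `|r| >= r_max`, drop the
#' variable with the highest mean absolute correlation among the variables
#' involved in violating pairs; then, while any variance inflation factor
#' reaches `vif_max`, drop the highest-VIF variable.
#'
#' @param env Environment data frame (`population`/`scenario` columns are
#'   ignored) or numeric matrix.
#' @param r_max Pairwise correlation ceiling (default 0.7).
#' @param vif_max VIF ceiling (default 10).
#' @return A list with `retained` (character vector) and `dropped`
#'   (data frame `variable`, `reason`, `value`).
#' @export
vif_prune <- function(env, r_max = 0.7, vif_max = 10) {
  X <- if (is.data.frame(env)) env_numeric(env) else as.matrix(env)
  if (ncol(X) < 2) stop("need at least two variables")
  vars <- colnames(X)
  dropped <- data.frame(variable = character(0), reason = character(0),
                        value = numeric(0), stringsAsFactors = FALSE)
  repeat {
    R <- abs(stats::cor(X[, vars, drop = FALSE]))
    diag(R) <- 0
    if (all(R < r_max, na.rm = TRUE)) break
    offenders <- unique(c(row(R)[R >= r_max], col(R)[R >= r_max]))
    mean_abs <- rowMeans(R)[offenders]
    worst <- vars[offenders[which.max(mean_abs)]]
    dropped <- rbind(dropped, data.frame(
      variable = worst, reason = "pairwise_correlation",
      value = max(R[vars == worst, ]), stringsAsFactors = FALSE))
    vars <- setdiff(vars, worst)
    if (length(vars) < 2) break
  }
  while (length(vars) >= 2) {
    R <- stats::cor(X[, vars, drop = FALSE])
    Ri <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(Ri)) {
      # exactly collinear set: drop the variable most predictable from rest
      stop("variables are exactly collinear; cannot compute VIF")
    }
    vif <- diag(Ri)
    if (max(vif) < vif_max) break
    worst <- vars[which.max(vif)]
    dropped <- rbind(dropped, data.frame(
      variable = worst, reason = "vif", value = max(vif),
      stringsAsFactors = FALSE))
    vars <- setdiff(vars, worst)
  }
  if (length(vars) == 0) stop("all variables dropped: fully collinear input")
  list(retained = vars, dropped = dropped)
}

#' Distance-based Moran eigenvector maps (dbMEM)
#'
#' Spatial eigenfunction basis from the geodesic distance matrix: distances
#' beyond the truncation threshold (the longest edge of the minimum spanning
#' tree) are replaced by four times the threshold, the truncated matrix is
#' Gower-centered (`-D^2/2`, double-centered) and eigen-decomposed, and the
#' eigenvectors with positive eigenvalue are retained.
#'
#' @param coords Coordinates data frame (`population`, `lat`, `lon`).
#' @return A list of class `dbmem_basis`: `vectors` (sites x axes,
#'   orthonormal), `values` (positive eigenvalues), `threshold` (metres),
#'   `n_candidate` (`n - 1` non-trivial axes before the positivity filter).
#' @export
dbmem_basis <- function(coords) {
  if (nrow(coords) < 3) stop("need at least three sites")
  D <- geodesic_distances(coords)
  off <- D[upper.tri(D)]
  if (any(off == 0)) stop("duplicate coordinates: zero off-diagonal distance")
  st <- vegan::spantree(stats::as.dist(D))
  t_trunc <- max(st$dist)
  Dt <- D
  Dt[Dt > t_trunc] <- 4 * t_trunc
  A <- -0.5 * Dt^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  Gmat <- J %*% A %*% J
  e <- eigen((Gmat + t(Gmat)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  nontrivial <- abs(e$values) > tol       # centering removes one dimension
  pos <- e$values > tol
  vectors <- e$vectors[, pos, drop = FALSE]
  rownames(vectors) <- coords$population
  colnames(vectors) <- paste0("MEM", seq_len(ncol(vectors)))
  structure(list(vectors = vectors, values = e$values[pos],
                 threshold = t_trunc, n_candidate = sum(nontrivial)),
            class = "dbmem_basis")
}

#' @export
print.dbmem_basis <- function(x, ...) {
  cat(sprintf(
    "dbmem_basis: %d positive axes of %d candidates, truncation %.1f km\n",
    ncol(x$vectors), x$n_candidate, x$threshold / 1000))
  invisible(x)
}

#' Forward selection of predictors with a double stopping criterion
#'
#' Classic two-criterion forward selection for constrained ordination: at
#' each step the candidate adding the largest adjusted R-squared enters if
#' its permutation p-value (rows of the current residuals permuted) is below
#' `alpha` and the cumulative adjusted R-squared does not exceed that of the
#' global model containing every candidate; selection stops otherwise.
#'
#' @param response Response matrix (or `pop_allele_freq`).
#' @param candidates Matrix of candidate predictors (e.g. dbMEM vectors).
#' @param alpha Entry significance level (default 0.05).
#' @param n_perm Permutations per entry test (default 999).
#' @return A list with `selected` (column names, in entry order),
#'   `adj_r_squared` (cumulative), and `global_adj_r_squared`.
#' @export
forward_select <- function(response, candidates, alpha = 0.05,
                           n_perm = 999) {
  if (inherits(response, "pop_allele_freq")) response <- response$freq
  Y <- sweep(as.matrix(response), 2, colMeans(as.matrix(response)))
  C <- as_predictor_matrix(candidates)
  if (is.null(colnames(C))) colnames(C) <- paste0("V", seq_len(ncol(C)))
  if (!all(is.finite(C))) stop("candidates must be finite")
  n <- nrow(Y)
  ss_total <- sum(Y^2)

  adjr2 <- function(idx) {
    if (length(idx) == 0) return(0)
    qx <- qr(cbind(1, C[, idx, drop = FALSE]))
    p <- qx$rank - 1
    if (n - p - 1 <= 0) return(NA_real_)
    r2 <- sum(qr.fitted(qx, Y)^2) / ss_total
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  global_adj <- adjr2(seq_len(ncol(C)))
  if (is.na(global_adj)) {
    warning("global adjusted R^2 undefined (candidates >= n - 1); ",
            "global stopping guard disabled")
    global_adj <- Inf
  }

  selected <- integer(0)
  cum_adj <- 0
  repeat {
    remaining <- setdiff(seq_len(ncol(C)), selected)
    if (length(remaining) == 0) break
    gains <- vapply(remaining, function(j) adjr2(c(selected, j)), numeric(1))
    if (all(is.na(gains))) break
    best <- remaining[which.max(gains)]
    new_adj <- max(gains, na.rm = TRUE)
    if (!is.finite(new_adj) || new_adj <= cum_adj) break
    if (new_adj > global_adj) break

    # permutation test of the entering variable given the current model
    q_sel <- qr(cbind(1, C[, selected, drop = FALSE]))
    Yres <- qr.resid(q_sel, Y)
    xres <- qr.resid(q_sel, C[, best])
    ss_obs <- sum(stats::lm.fit(cbind(xres), Yres)$fitted.values^2)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Yb <- Yres[sample.int(n), , drop = FALSE]
      ssb <- sum(stats::lm.fit(cbind(xres), Yb)$fitted.values^2)
      if (ssb >= ss_obs) hits <- hits + 1L
    }
    p_val <- (hits + 1) / (n_perm + 1)
    if (p_val >= alpha) break
    selected <- c(selected, best)
    cum_adj <- new_adj
  }
  list(selected = colnames(C)[selected], adj_r_squared = cum_adj,
       global_adj_r_squared = global_adj)
}

#' Binomial GLM of genotype on an environmental gradient
#'
#' Logistic regression `log(p / (1 - p)) = b0 + b1 * env` fitted by
#' iteratively reweighted least squares. The default coding treats each
#' diploid genotype as two Bernoulli trials (dosage successes out of 2);
#' the alternative `"homozygote"` coding contrasts the two homozygote
#' classes, dropping heterozygotes.
#'
#' @param dosages Integer dosages in \{0, 1, 2\} (missing values dropped).
#' @param env_values Environmental values aligned with `dosages`.
#' @param coding `"allele_count"` (default) or `"homozygote"`.
#'
#' @return A list of class `glm_gea`: `beta0`, `beta1`, `odds_ratio`, `se`,
#'   `z`, `p`, `converged`.
#' @export
glm_binomial_gea <- function(dosages, env_values,
                             coding = c("allele_count", "homozygote")) {
  coding <- match.arg(coding)
  keep <- !is.na(dosages) & dosages != GT_MISSING & !is.na(env_values)
  d <- dosages[keep]; e <- env_values[keep]
  if (length(d) < 10) stop("need at least 10 individuals")
  if (stats::sd(e) == 0) stop("environmental values are constant")
  if (coding == "allele_count") {
    succ <- d; fail <- 2 - d
  } else {
    hom <- d != 1
    succ <- as.integer(d[hom] == 2); fail <- 1L - succ
    e <- e[hom]
  }
  fit <- suppressWarnings(
    stats::glm(cbind(succ, fail) ~ e, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  co <- summary(fit)$coefficients
  boundary <- fit$boundary || any(abs(stats::coef(fit)) > 20)
  converged <- fit$converged && !boundary
  structure(list(beta0 = co[1, 1],
                 beta1 = if (nrow(co) > 1) co[2, 1] else NA_real_,
                 odds_ratio = if (nrow(co) > 1) exp(co[2, 1]) else NA_real_,
                 se = if (nrow(co) > 1) co[2, 2] else NA_real_,
                 z = if (nrow(co) > 1 && converged) co[2, 3] else NA_real_,
                 p = if (nrow(co) > 1 && converged) co[2, 4] else NA_real_,
                 converged = converged),
            class = "glm_gea")
}

#' @export
print.glm_gea <- function(x, ...) {
  cat(sprintf(
    "glm_gea: beta1 = %.4f (OR = %.3f), z = %.2f, p = %.3g%s\n",
    x$beta1, x$odds_ratio, x$z, x$p,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}
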