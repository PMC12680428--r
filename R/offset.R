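#' Two-stage allele-frequency / environment calibration
#'
#' Stage 1 fits a redundancy analysis of the (typically PAV-restricted)
#' population allele frequencies on the standardized environmental
#' predictors. Stage 2 maps each locus's stage-1 linear prediction back to
#' the observed frequency through a binomial logistic regression weighted by
#' the observed allele counts, which bounds every later prediction inside
#' (0, 1). Loci fixed across all populations are skipped at stage 2 and
#' flagged; their predictions fall back to the observed mean frequency.
#'
#' @param freqs A `pop_allele_freq` (restrict to the consensus panel first)
#'   or a populations x loci frequency matrix.
#' @param env Current-climate environment table; the standardization
#'   constants computed here are reused verbatim for any future scenario.
#' @param variables Optional character vector naming the predictor columns
#'   to use (default: every numeric column).
#'
#' @return A list of class `allele_env_model` with the stage-1 `rda_model`
#'   and a stage-2 coefficient table.
#' @export
fit_allele_env_model <- function(freqs, env, variables = NULL) {
  if (inherits(freqs, "pop_allele_freq")) {
    P <- freqs$freq
    W <- freqs$n_alleles
  } else {
    P <- as.matrix(freqs)
    W <- matrix(20, nrow(P), ncol(P), dimnames = dimnames(P))
  }
  if (nrow(P) < 3) stop("need at least three populations")
  X <- env_numeric(env, variables)
  if (!identical(rownames(P), rownames(X)))
    X <- X[match(rownames(P), rownames(X)), , drop = FALSE]
  stage1 <- rda_fit(P, X)
  lp <- stage1_linear_prediction(stage1, X)

  L <- ncol(P)
  coef2 <- data.frame(locus_id = colnames(P),
                      intercept = NA_real_, slope = NA_real_,
                      ok = FALSE, stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    p_obs <- P[, l]; w <- W[, l]
    use <- !is.na(p_obs) & w > 0
    if (sum(use) < 3 || stats::sd(p_obs[use]) == 0 ||
        all(p_obs[use] %in% c(0, 1))) next
    fit <- tryCatch(suppressWarnings(
      stats::glm(p_obs[use] ~ lp[use, l], family = stats::binomial(),
                 weights = w[use],
                 control = stats::glm.control(epsilon = 1e-10,
                                              maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    coef2$intercept[l] <- stats::coef(fit)[1]
    coef2$slope[l] <- stats::coef(fit)[2]
    coef2$ok[l] <- TRUE
  }
  fallback <- colMeans(P, na.rm = TRUE)
  structure(list(stage1 = stage1, stage2 = coef2,
                 fallback = pmin(pmax(fallback, 1e-6), 1 - 1e-6),
                 variables = colnames(X)),
            class = "allele_env_model")
}

# Stage-1 fitted frequencies (linear scale) at arbitrary environments,
# using the calibration standardization constants.
stage1_linear_prediction <- function(stage1, X_new) {
  Xs <- scale(X_new[, names(stage1$x_center), drop = FALSE],
              center = stage1$x_center, scale = stage1$x_scale)
  sweep(Xs %*% stage1$coefficients, 2, stage1$y_center, "+")
}

#' @export
print.allele_env_model <- function(x, ...) {
  cat(sprintf(
    "allele_env_model: %d loci (%d calibrated), %d predictors, stage-1 R^2 = %.3f\n",
    nrow(x$stage2), sum(x$stage2$ok), length(x$variables),
    x$stage1$r_squared))
  invisible(x)
}

#' Predict population allele frequencies under a new environment
#'
#' Applies the stage-1 linear model at the new (future) environment —
#' standardized with the *current-climate* constants stored in the model —
#' then the stage-2 per-locus inverse-logit calibration, so predictions lie
#' strictly inside (0, 1).
#'
#' @param model An `allele_env_model`.
#' @param future_env Environment table containing every calibration
#'   variable.
#' @return A `pop_allele_freq` of predicted frequencies (`n_alleles` is NA).
#' @export
predict_future_frequencies <- function(model, future_env) {
  missing_v <- setdiff(model$variables, names(future_env))
  if (length(missing_v) > 0)
    stop("future environment lacks variable(s): ",
         paste(missing_v, collapse = ", "))
  X <- env_numeric(future_env, model$variables)
  lp <- stage1_linear_prediction(model$stage1, X)
  out <- matrix(NA_real_, nrow(lp), ncol(lp),
                dimnames = list(future_env$population,
                                model$stage2$locus_id))
  for (l in seq_len(ncol(lp))) {
    if (model$stage2$ok[l]) {
      out[, l] <- stats::plogis(model$stage2$intercept[l] +
                                  model$stage2$slope[l] * lp[, l])
    } else {
      out[, l] <- model$fallback[l]
    }
  }
  structure(list(freq = out,
                 n_alleles = matrix(NA_integer_, nrow(out), ncol(out),
                                    dimnames = dimnames(out)),
                 populations = rownames(out),
                 locus_ids = colnames(out)),
            class = "pop_allele_freq")
}

#' Risk of nonadaptedness (RONA) offset
#'
#' Per population, the mean over loci of the absolute difference between
#' current and predicted future allele frequencies,
#' `1/n * sum_i |p_i - p_i*|`.
#'
#' @param current,predicted `pop_allele_freq` objects or frequency matrices
#'   of identical shape.
#' @return Named numeric vector of per-population offsets, with the
#'   per-locus absolute shifts attached as attribute `"per_locus"`.
#' @export
rona_offset <- function(current, predicted) {
  P0 <- if (inherits(current, "pop_allele_freq")) current$freq
        else as.matrix(current)
  P1 <- if (inherits(predicted, "pop_allele_freq")) predicted$freq
        else as.matrix(predicted)
  if (!all(dim(P0) == dim(P1)))
    stop("current and predicted frequency matrices differ in shape")
  d <- abs(P0 - P1)
  out <- rowMeans(d, na.rm = TRUE)
  attr(out, "per_locus") <- d
  out
}

#' RDA adaptive-index offset
#'
#' For each retained canonical axis the adaptive index of a site is the sum
#' over predictors of the axis biplot score times the standardized
#' environmental value; the offset is the Euclidean distance between the
#' current and future index vectors. Both environments are standardized
#' with the model's current-climate constants.
#'
#' @param model An `rda_model` (e.g. the stage-1 model of
#'   [fit_allele_env_model()]).
#' @param env_now,env_future Environment tables.
#' @param axes Integer vector of retained axes (default 1).
#' @return Named numeric vector of per-population offsets.
#' @export
adaptive_index_offset <- function(model, env_now, env_future, axes = 1L) {
  axes <- axes[axes <= length(model$eigenvalues)]
  if (length(axes) == 0) stop("no retained axes")
  std <- function(env) {
    X <- env_numeric(env, names(model$x_center))
    scale(X, center = model$x_center, scale = model$x_scale)
  }
  B <- model$biplot_scores[, axes, drop = FALSE]
  idx_now <- std(env_now) %*% B
  idx_fut <- std(env_future) %*% B
  out <- sqrt(rowSums((idx_now - idx_fut)^2))
  names(out) <- env_now$population
  out
}

#' Assemble a long offset table
#'
#' @param ... Named numeric vectors of per-population offsets; names of the
#'   arguments are `method:scenario` pairs supplied via `method` and
#'   `scenario` instead.
#' @param method,scenario Character scalars recycled across the populations
#'   of each vector.
#' @param offsets Named list mapping `list(method = , scenario = , values = )`
#'   entries; used by [run_pipeline()].
#' @return Data frame `population, scenario, method, offset`.
#' @export
offset_table <- function(offsets) {
  do.call(rbind, lapply(offsets, function(o)
    data.frame(population = names(o$values), scenario = o$scenario,
               method = o$method, offset = unname(o$values),
               stringsAsFactors = FALSE)))
}

#' Decile classes of an offset vector
#'
#' Bins raw offsets into `n` quantile classes (1 = lowest) for map-style
#' display.
#'
#' @param x Numeric offsets.
#' @param n Number of classes (default 10).
#' @return Integer class per element.
#' @export
offset_classes <- function(x, n = 10) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n + 1),
                               na.rm = TRUE))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Inverse-distance-weighted surface
#'
#' `value(x) = sum(w_i v_i) / sum(w_i)` with `w_i = d(x, x_i)^(-power)`;
#' a grid node coincident with a data point returns that point's value.
#' Distances are planar on an equirectangular projection at the mean
#' latitude (kilometres) by default, or geodesic metres.
#'
#' @param points Data frame with `lat`, `lon` columns.
#' @param values Numeric data values, one per point.
#' @param grid Data frame with `lat`, `lon` of the prediction nodes.
#' @param power Inverse-distance exponent (default 2).
#' @param geodesic Use ellipsoid distances instead of the planar projection
#'   (default `FALSE`).
#' @return `grid` with an added `value` column.
#' @export
idw_surface <- function(points, values, grid, power = 2, geodesic = FALSE) {
  if (nrow(points) == 0) stop("no data points")
  if (length(values) != nrow(points))
    stop("`values` must have one entry per point")
  if (geodesic) {
    dfun <- function(g) geosphere::distGeo(
      cbind(points$lon, points$lat), c(g["lon"], g["lat"]))
  } else {
    mlat <- mean(c(points$lat, grid$lat)) * pi / 180
    km <- function(lat, lon) cbind(lon * 111.32 * cos(mlat), lat * 110.57)
    P <- km(points$lat, points$lon)
    dfun <- function(g) {
      gk <- km(g["lat"], g["lon"])
      sqrt((P[, 1] - gk[1])^2 + (P[, 2] - gk[2])^2)
    }
  }
  vals <- apply(as.matrix(grid[, c("lat", "lon")]), 1, function(g) {
    d <- dfun(g)
    hit <- d < 1e-9
    if (any(hit)) return(values[which(hit)[1]])
    w <- d^(-power)
    sum(w * values) / sum(w)
  })
  out <- grid
  out$value <- vals
  out
}
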