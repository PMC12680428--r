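#' Specification of a synthetic clinal landscape panel
#'
#' Parameters of the generative model used for self-contained testing of the
#' whole pipeline: neutral loci follow the Balding-Nichols model (population
#' allele frequencies Beta-distributed around an ancestral frequency with a
#' tunable F_ST), adaptive loci follow logistic clines in mean annual
#' temperature, and genotypes are drawn at Hardy-Weinberg proportions within
#' populations.
#'
#' @param n_pops Number of populations along the transect (default 39).
#' @param inds_per_pop Integer range of per-population sample sizes
#'   (default `c(5, 23)`); sizes are drawn as `min + Binomial(max - min,
#'   (10 - min)/(max - min))` so the median sits near 10.
#' @param n_neutral Number of neutral loci (default 2000).
#' @param n_adaptive Number of clinal (adaptive) loci (default 20).
#' @param target_fst Balding-Nichols F for the neutral background
#'   (default 0.017).
#' @param env_gradient Per-population mean annual temperature in degrees C,
#'   or a length-2 range interpolated linearly north to south
#'   (default `c(-2, 9)`).
#' @param cline_b Logit-frequency slope per degree C of the adaptive clines
#'   (default 0.25; scalar or one value per adaptive locus).
#' @param cline_a Logit intercepts of the clines; `NULL` (default) draws the
#'   half-frequency temperature of each clinal locus uniformly over the
#'   middle half of the gradient.
#' @param missing_rate Fraction of genotype calls set missing uniformly at
#'   random (default 0.03).
#' @param fst_distance_decay When `TRUE`, neutral deviations from the
#'   ancestral frequency are spatially autocorrelated along the transect so
#'   the panel shows isolation by distance; default `FALSE` (exchangeable
#'   populations).
#' @param coord_jitter Standard deviation (degrees) of longitude jitter
#'   around the transect meridian (default 0).
#' @param seed Integer seed; the whole panel is reproducible from it.
#'
#' @return A list of class `landscape_panel_spec`.
#' @export
landscape_panel_spec <- function(n_pops = 39, inds_per_pop = c(5, 23),
                                 n_neutral = 2000, n_adaptive = 20,
                                 target_fst = 0.017,
                                 env_gradient = c(-2, 9),
                                 cline_b = 0.25, cline_a = NULL,
                                 missing_rate = 0.03,
                                 fst_distance_decay = FALSE,
                                 coord_jitter = 0,
                                 seed = 1L) {
  if (n_pops < 2) stop("`n_pops` must be at least 2")
  if (target_fst <= 0 || target_fst >= 1) stop("`target_fst` must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)")
  if (length(env_gradient) == 2)
    env_gradient <- seq(env_gradient[1], env_gradient[2], length.out = n_pops)
  if (length(env_gradient) != n_pops)
    stop("`env_gradient` must have length 2 or `n_pops`")
  structure(list(n_pops = n_pops, inds_per_pop = inds_per_pop,
                 n_neutral = n_neutral, n_adaptive = n_adaptive,
                 target_fst = target_fst, env_gradient = env_gradient,
                 cline_b = cline_b, cline_a = cline_a,
                 missing_rate = missing_rate,
                 fst_distance_decay = fst_distance_decay,
                 coord_jitter = coord_jitter,
                 seed = as.integer(seed)),
            class = "landscape_panel_spec")
}

#' Simulate a clinal landscape genotype panel
#'
#' Draws a full synthetic study: genotypes ([genotype_matrix]), a current
#' environment table (eight variables led by `mean_temp`), WGS84 transect
#' coordinates, and a truth table of the planted clinal loci.
#'
#' Neutral population frequencies follow Balding-Nichols:
#' `p ~ Beta(pi (1 - F)/F, (1 - pi)(1 - F)/F)` with ancestral
#' `pi ~ Uniform(0.05, 0.95)` and `F = target_fst`. Adaptive frequencies are
#' `plogis(a + b * temp)`. Genotypes are `Binomial(2, p)`; dosages are then
#' re-oriented to count the panel-wide minor allele (the truth table records
#' flipped loci, whose effective cline slope is `-b`).
#'
#' @param spec A [landscape_panel_spec].
#' @return A list of class `landscape_panel` with elements `genotypes`,
#'   `env`, `coords`, `loci_info` and `spec`.
#' @export
simulate_landscape_panel <- function(spec = landscape_panel_spec()) {
  if (!inherits(spec, "landscape_panel_spec"))
    stop("`spec` must be a landscape_panel_spec")
  set.seed(spec$seed)
  n_pops <- spec$n_pops
  temps <- spec$env_gradient
  rng <- spec$inds_per_pop
  sizes <- if (length(rng) == 2 && rng[2] > rng[1])
    rng[1] + stats::rbinom(n_pops, rng[2] - rng[1],
                           min(max((10 - rng[1]) / (rng[2] - rng[1]), 0), 1))
  else rep_len(rng[1], n_pops)
  pop_names <- sprintf("P%02d", seq_len(n_pops))
  L <- spec$n_neutral + spec$n_adaptive
  locus_ids <- c(sprintf("neut_%04d", seq_len(spec$n_neutral)),
                 if (spec$n_adaptive > 0)
                   sprintf("clin_%03d", seq_len(spec$n_adaptive)))

  # population frequencies
  Fst <- spec$target_fst
  pfreq <- matrix(NA_real_, n_pops, L)
  pi0 <- stats::runif(spec$n_neutral, 0.05, 0.95)
  if (spec$fst_distance_decay) {
    # logit-scale Gaussian field with exponential decay along the transect
    pos <- seq(0, 1, length.out = n_pops)
    Sig <- exp(-as.matrix(stats::dist(pos)) / 0.3)
    R <- chol(Sig + diag(1e-10, n_pops))
    for (l in seq_len(spec$n_neutral)) {
      # delta-method sd on the logit scale so that var(p) ~ p q F
      sd_logit <- sqrt(Fst / (pi0[l] * (1 - pi0[l])))
      u <- drop(crossprod(R, stats::rnorm(n_pops))) * sd_logit
      pfreq[, l] <- stats::plogis(stats::qlogis(pi0[l]) + u)
    }
  } else {
    sh1 <- pi0 * (1 - Fst) / Fst
    sh2 <- (1 - pi0) * (1 - Fst) / Fst
    for (l in seq_len(spec$n_neutral))
      pfreq[, l] <- stats::rbeta(n_pops, sh1[l], sh2[l])
  }
  b <- rep_len(spec$cline_b, max(spec$n_adaptive, 1L))
  if (spec$n_adaptive > 0) {
    if (is.null(spec$cline_a)) {
      span <- range(temps)
      mid <- stats::runif(spec$n_adaptive,
                          span[1] + 0.25 * diff(span),
                          span[2] - 0.25 * diff(span))
      a <- -b[seq_len(spec$n_adaptive)] * mid
    } else a <- rep_len(spec$cline_a, spec$n_adaptive)
    for (j in seq_len(spec$n_adaptive))
      pfreq[, spec$n_neutral + j] <- stats::plogis(a[j] + b[j] * temps)
  } else a <- numeric(0)

  # genotypes at Hardy-Weinberg within populations
  N <- sum(sizes)
  values <- matrix(0L, N, L)
  pop_of <- rep(pop_names, sizes)
  row0 <- cumsum(c(0, sizes))
  for (k in seq_len(n_pops)) {
    rows <- (row0[k] + 1):row0[k + 1]
    values[rows, ] <- stats::rbinom(length(rows) * L, 2L,
                                    rep(pfreq[k, ], each = length(rows)))
  }
  if (spec$missing_rate > 0) {
    miss <- stats::runif(length(values)) < spec$missing_rate
    values[miss] <- GT_MISSING
  }
  ind_ids <- sprintf("%s_i%02d", pop_of, unlist(lapply(sizes, seq_len)))

  G <- orient_minor(values, ind_ids, pop_of, locus_ids,
                    allele1 = rep("A", L), allele2 = rep("G", L))
  flipped <- G$alleles[, "minor"] != "A"

  loci_info <- data.frame(
    locus_id = locus_ids,
    type = rep(c("neutral", "adaptive"),
               c(spec$n_neutral, spec$n_adaptive)),
    cline_a = c(rep(NA_real_, spec$n_neutral), a),
    cline_b = c(rep(NA_real_, spec$n_neutral),
                b[seq_len(spec$n_adaptive)]),
    flipped = flipped,
    stringsAsFactors = FALSE)
  loci_info$effective_b <- ifelse(loci_info$flipped,
                                  -loci_info$cline_b, loci_info$cline_b)

  env <- make_env_table(pop_names, temps)
  lat <- seq(68, 49, length.out = n_pops)
  lon <- rep(24, n_pops)
  if (spec$coord_jitter > 0)
    lon <- lon + stats::rnorm(n_pops, 0, spec$coord_jitter)
  coords <- data.frame(population = pop_names, lat = lat, lon = lon,
                       stringsAsFactors = FALSE)

  structure(list(genotypes = G, env = env, coords = coords,
                 loci_info = loci_info, spec = spec),
            class = "landscape_panel")
}

# Eight environmental variables in the style of a bioclim + soil table;
# mean_temp carries the gradient, the others are weakly correlated noise.
make_env_table <- function(pop_names, temps) {
  n <- length(pop_names)
  data.frame(
    population = pop_names,
    mean_temp = temps,
    mean_dr = 8 + stats::rnorm(n, 0, 1),
    temp_s = 6 - 0.3 * temps + stats::rnorm(n, 0, 1.5),
    perc_dry_m = 30 + 1.5 * temps + stats::rnorm(n, 0, 8),
    perc_wet_q = 250 + stats::rnorm(n, 0, 30),
    ph = 5.5 + 0.05 * temps + stats::rnorm(n, 0, 0.3),
    wet = 160 - 2 * temps + stats::rnorm(n, 0, 10),
    carbon = stats::rnorm(n, 3, 0.5),
    scenario = "current",
    stringsAsFactors = FALSE)
}

#' @export
print.landscape_panel <- function(x, ...) {
  cat(sprintf(
    "landscape_panel: %d populations, %d individuals, %d loci (%d clinal)\n",
    x$spec$n_pops, nrow(x$genotypes$values), ncol(x$genotypes$values),
    sum(x$loci_info$type == "adaptive")))
  invisible(x)
}

#' Shift climatic variables of an environment table
#'
#' Adds per-population deltas to the named climatic variables; all other
#' variables are copied unchanged (non-climatic predictors are retained at
#' their present values) and the scenario label is set.
#'
#' @param env Environment data frame with a `population` column.
#' @param delta_by_pop Data frame with a `population` column and one column
#'   per climatic variable to shift; must cover every population of `env`.
#' @param scenario Scenario label of the returned table.
#'
#' @return The shifted environment table.
#' @export
shift_climate <- function(env, delta_by_pop, scenario = "future") {
  if (!"population" %in% names(delta_by_pop))
    stop("`delta_by_pop` needs a `population` column")
  missing_pop <- setdiff(env$population, delta_by_pop$population)
  if (length(missing_pop) > 0)
    stop("populations missing from delta table: ",
         paste(missing_pop, collapse = ", "))
  vars <- setdiff(names(delta_by_pop), "population")
  unknown <- setdiff(vars, names(env))
  if (length(unknown) > 0)
    stop("delta variables absent from env table: ",
         paste(unknown, collapse = ", "))
  out <- env
  idx <- match(env$population, delta_by_pop$population)
  for (v in vars) out[[v]] <- env[[v]] + delta_by_pop[[v]][idx]
  out$scenario <- scenario
  out
}

#' North-weighted warming deltas for the three SSP scenarios
#'
#' Builds `mean_temp` deltas that increase with latitude (northern
#' populations warm more), with overall severity ordered
#' SSP126 < SSP245 < SSP585.
#'
#' @param coords Coordinates data frame (`population`, `lat`, `lon`).
#' @param scenario One of `"ssp126"`, `"ssp245"`, `"ssp585"`.
#' @return A delta table usable with [shift_climate()].
#' @export
climate_scenario_deltas <- function(coords,
                                    scenario = c("ssp126", "ssp245", "ssp585")) {
  scenario <- match.arg(scenario)
  northness <- (coords$lat - min(coords$lat)) /
    max(diff(range(coords$lat)), 1e-9)
  base <- switch(scenario, ssp126 = c(1, 1), ssp245 = c(2, 1.5),
                 ssp585 = c(3, 2))
  data.frame(population = coords$population,
             mean_temp = base[1] + base[2] * northness,
             stringsAsFactors = FALSE)
}

#' Write a synthetic panel to disk as analysis-ready fixtures
#'
#' Emits PLINK PED/MAP, a population-map TSV, environment CSVs (current plus
#' any requested scenarios) and a coordinates CSV, such that
#' [load_genotypes()] round-trips the dosage matrix exactly.
#'
#' @param panel A `landscape_panel`.
#' @param directory Output directory (created if absent).
#' @param scenarios Character vector of scenario names for
#'   [climate_scenario_deltas()] future tables (default none).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_fixture <- function(panel, directory, scenarios = character(0)) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  G <- panel$genotypes
  paths <- list(
    ped = file.path(directory, "panel.ped"),
    map = file.path(directory, "panel.map"),
    pop_map = file.path(directory, "popmap.tsv"),
    env_current = file.path(directory, "env_current.csv"),
    coords = file.path(directory, "coords.csv"))

  map <- data.frame(chr = 1L, id = G$locus_ids, cm = 0,
                    bp = seq_along(G$locus_ids))
  utils::write.table(map, paths$map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  v <- G$values
  minor <- G$alleles[, "minor"]; major <- G$alleles[, "major"]
  lines <- vapply(seq_len(nrow(v)), function(i) {
    d <- v[i, ]
    a1 <- ifelse(d == GT_MISSING, "0", ifelse(d >= 1, minor, major))
    a2 <- ifelse(d == GT_MISSING, "0", ifelse(d == 2, minor, major))
    paste(c(G$population_labels[i], G$individual_ids[i], "0", "0", "0",
            "-9", as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(lines, paths$ped)

  utils::write.table(
    data.frame(individual = G$individual_ids,
               population = G$population_labels),
    paths$pop_map, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(panel$env, paths$env_current, row.names = FALSE)
  utils::write.csv(panel$coords, paths$coords, row.names = FALSE)

  for (sc in scenarios) {
    fut <- shift_climate(panel$env,
                         climate_scenario_deltas(panel$coords, sc),
                         scenario = sc)
    p <- file.path(directory, sprintf("env_%s.csv", sc))
    utils::write.csv(fut, p, row.names = FALSE)
    paths[[paste0("env_", sc)]] <- p
  }
  invisible(paths)
}
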