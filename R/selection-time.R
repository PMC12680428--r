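#' One-generation allele-frequency change under dominant selection
#'
#' The deterministic single-locus response with a fully dominant favoured
#' allele (h = 0): `delta_p = s p q^2 / (1 - s q^2)` with `q = 1 - p`.
#'
#' @param p Current frequency of the favoured allele, in `[0, 1]`.
#' @param s Selection coefficient against the disfavoured homozygote, in
#'   `[0, 1)`.
#' @return Frequency change over one generation.
#' @export
delta_p_one_generation <- function(p, s) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(s < 0 | s >= 1)) stop("s must lie in [0, 1)")
  q <- 1 - p
  denom <- 1 - s * q^2
  if (any(denom <= 0)) stop("mean fitness non-positive: s * q^2 >= 1")
  s * p * q^2 / denom
}

#' Generations needed for a cumulative frequency shift
#'
#' Iterates the one-generation recursion from `p0` and returns the smallest
#' completed generation count `T` at which the cumulative gain reaches
#' `delta_p_target` (`T = 0` for a zero target). The shift is unreachable if
#' `p0 + delta_p_target > 1` or the generation cap is exhausted; this is
#' flagged, not an error.
#'
#' @param p0 Starting frequency of the favoured allele, in (0, 1).
#' @param s Selection coefficient, in `[0, 1)`.
#' @param delta_p_target Required cumulative gain (>= 0).
#' @param max_generations Iteration cap (default 1e5).
#' @return A list with `generations` (integer, `NA` if unreachable),
#'   `reachable`, and `p_final`.
#' @export
generations_to_shift <- function(p0, s, delta_p_target,
                                 max_generations = 1e5) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (delta_p_target < 0) stop("delta_p_target must be non-negative")
  if (delta_p_target == 0)
    return(list(generations = 0L, reachable = TRUE, p_final = p0))
  if (p0 + delta_p_target > 1)
    return(list(generations = NA_integer_, reachable = FALSE,
                p_final = p0))
  p <- p0
  for (t in seq_len(max_generations)) {
    p <- p + delta_p_one_generation(p, s)
    if (p - p0 >= delta_p_target)
      return(list(generations = as.integer(t), reachable = TRUE,
                  p_final = p))
  }
  list(generations = NA_integer_, reachable = FALSE, p_final = p)
}

#' Convert generations to calendar years
#'
#' @param T Generation count(s).
#' @param generation_time_years Years per generation (20 or 25 for a
#'   long-lived conifer).
#' @return Years.
#' @export
years_from_generations <- function(T, generation_time_years = 25) {
  if (any(T < 0, na.rm = TRUE)) stop("T must be non-negative")
  T * generation_time_years
}

#' Selection-time grid
#'
#' Evaluates [generations_to_shift()] over the full cross-product of
#' starting frequencies, selection coefficients and target shifts, with
#' year conversions at 20 and 25 years per generation. The summary reports,
#' per target, the minimum and maximum generation count over the `s` grid
#' at the reference starting frequency `p0 = 0.4` (or the nearest grid
#' value).
#'
#' @param p0_grid Starting frequencies.
#' @param s_grid Selection coefficients.
#' @param targets Cumulative frequency-shift targets.
#' @param max_generations Iteration cap per cell.
#' @return A list of class `selection_sim_result` with `grid` (data frame
#'   `p0, s, target, generations, years20, years25, reachable`) and
#'   `summary`.
#' @export
simulate_selection_grid <- function(p0_grid = seq(0.01, 0.9, by = 0.01),
                                    s_grid = seq(0.1, 0.9, by = 0.1),
                                    targets = c(0.06, 0.27),
                                    max_generations = 1e5) {
  if (length(p0_grid) == 0 || length(s_grid) == 0 || length(targets) == 0)
    stop("grids must be nonempty")
  grid <- expand.grid(p0 = p0_grid, s = s_grid, target = targets,
                      KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(p0, s, tg) {
    r <- generations_to_shift(p0, s, tg, max_generations)
    c(r$generations, r$reachable)
  }, grid$p0, grid$s, grid$target)
  grid$generations <- as.integer(res[1, ])
  grid$reachable <- as.logical(res[2, ])
  grid$years20 <- years_from_generations(grid$generations, 20)
  grid$years25 <- years_from_generations(grid$generations, 25)

  ref_p0 <- p0_grid[which.min(abs(p0_grid - 0.4))]
  summ <- do.call(rbind, lapply(targets, function(tg) {
    sub <- grid[grid$target == tg & grid$p0 == ref_p0 & grid$reachable, ]
    data.frame(target = tg, p0 = ref_p0,
               min_generations = min(sub$generations),
               max_generations = max(sub$generations),
               min_years25 = min(sub$generations) * 25,
               max_years25 = max(sub$generations) * 25)
  }))
  structure(list(grid = grid, summary = summ), class = "selection_sim_result")
}

#' @export
print.selection_sim_result <- function(x, ...) {
  cat("selection_sim_result\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
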