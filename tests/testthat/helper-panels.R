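# Shared fixtures: small synthetic panels and tiny hand-built genotype
# matrices. Everything is generated in code; nothing is read from disk.

small_panel <- function(seed = 3, n_neutral = 500, n_adaptive = 20, ...) {
  simulate_landscape_panel(
    landscape_panel_spec(n_neutral = n_neutral, n_adaptive = n_adaptive,
                         seed = seed, ...))
}

# One default panel reused across test files (built once per run).
default_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- small_panel()
    cache
  }
})

# Tiny genotype matrix from an integer matrix and population labels.
make_gt <- function(values, pops) {
  values <- as.matrix(values)
  genotype_matrix(values,
                  individual_ids = sprintf("i%02d", seq_len(nrow(values))),
                  population_labels = pops,
                  locus_ids = sprintf("L%03d", seq_len(ncol(values))))
}

# Balding-Nichols dosage panel without clines (missing-free), for estimator
# oracles.
bn_panel <- function(n_pops, n_per_pop, n_loci, F, seed) {
  simulate_landscape_panel(landscape_panel_spec(
    n_pops = n_pops, inds_per_pop = c(n_per_pop, n_per_pop),
    n_neutral = n_loci, n_adaptive = 0, target_fst = F,
    missing_rate = 0, seed = seed))
}

# Restrict a pop_allele_freq to a locus subset.
freq_subset <- function(freqs, loci) {
  idx <- match(loci, freqs$locus_ids)
  freqs$freq <- freqs$freq[, idx, drop = FALSE]
  freqs$n_alleles <- freqs$n_alleles[, idx, drop = FALSE]
  freqs$locus_ids <- loci
  freqs
}
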