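#' Missing-genotype sentinel
#'
#' Integer code used for missing genotype calls inside the dosage matrix of a
#' [genotype_matrix]. A reserved integer outside \{0, 1, 2\} is used rather
#' than `NA` so that the matrix stays a plain integer matrix.
#'
#' @format An integer scalar, `-9L`.
#' @export
GT_MISSING <- -9L

#' Diploid genotype matrix with population labels
#'
#' Container for a biallelic SNP panel coded as minor-allele dosages.
#' `values[i, l]` counts copies (0, 1, 2) of the panel-wide minor allele of
#' locus `l` carried by individual `i`; missing calls hold [GT_MISSING].
#'
#' @param values Integer matrix, individuals x loci; entries in \{0, 1, 2\}
#'   or [GT_MISSING].
#' @param individual_ids Character vector of unique individual identifiers.
#' @param population_labels Character vector, one population per individual.
#' @param locus_ids Character vector of unique locus identifiers.
#' @param alleles Character matrix with columns `minor` and `major`, one row
#'   per locus, or `NULL` when allele characters are unknown (e.g. simulated
#'   dosages).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, individual_ids, population_labels,
                            locus_ids, alleles = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) != length(individual_ids))
    stop("`individual_ids` must match the number of rows of `values`")
  if (nrow(values) != length(population_labels))
    stop("`population_labels` must have one entry per individual")
  if (ncol(values) != length(locus_ids))
    stop("`locus_ids` must match the number of columns of `values`")
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique")
  if (anyDuplicated(locus_ids))
    stop("locus ids must be unique")
  ok <- values == 0L | values == 1L | values == 2L | values == GT_MISSING
  if (!all(ok))
    stop("genotype values must be in {0, 1, 2} or the missing sentinel")
  if (!is.null(alleles)) {
    alleles <- as.matrix(alleles)
    if (nrow(alleles) != length(locus_ids) || ncol(alleles) != 2L)
      stop("`alleles` must be a loci x 2 (minor, major) character matrix")
    dimnames(alleles) <- list(locus_ids, c("minor", "major"))
  }
  dimnames(values) <- list(individual_ids, locus_ids)
  structure(
    list(values = values,
         individual_ids = as.character(individual_ids),
         population_labels = as.character(population_labels),
         locus_ids = as.character(locus_ids),
         alleles = alleles),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(x$values == GT_MISSING)
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci, %d populations, %.1f%% missing\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$population_labels)), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

# Dosages as a numeric matrix with NA for the missing sentinel.
gt_numeric <- function(G) {
  v <- G$values
  v[v == GT_MISSING] <- NA_integer_
  storage.mode(v) <- "double"
  v
}

# Subset a genotype_matrix by individual and/or locus index.
gt_subset <- function(G, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_along(G$individual_ids)
  if (is.null(loci)) loci <- seq_along(G$locus_ids)
  genotype_matrix(G$values[ind, loci, drop = FALSE],
                  G$individual_ids[ind],
                  G$population_labels[ind],
                  G$locus_ids[loci],
                  if (is.null(G$alleles)) NULL else
                    G$alleles[loci, , drop = FALSE])
}

# Per-locus frequency of the counted allele among non-missing calls.
gt_counted_freq <- function(G) {
  v <- gt_numeric(G)
  colSums(v, na.rm = TRUE) / (2 * colSums(!is.na(v)))
}

# Per-locus minor allele frequency (folded).
gt_maf <- function(G) {
  f <- gt_counted_freq(G)
  pmin(f, 1 - f)
}
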