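#' Read genotypes from PLINK PED/MAP or VCF
#'
#' Parses a diploid biallelic SNP panel into a [genotype_matrix] whose
#' dosages count the panel-wide minor allele. PED files are whitespace
#' delimited with the six mandatory leading columns (family, individual,
#' father, mother, sex, phenotype) followed by two allele characters per
#' locus; the companion `.map` file supplies locus identifiers. VCF records
#' must be biallelic SNPs; multiallelic records are skipped with a warning.
#'
#' Missing calls (`0 0` in PED, `./.` or `.|.` in VCF) map to [GT_MISSING].
#' The minor allele is the panel-wide less frequent allele; an exact 50/50
#' tie is broken towards the lexicographically smaller character so dosage
#' signs are reproducible.
#'
#' @param path Path to the `.ped` or `.vcf` file.
#' @param format `"ped"` or `"vcf"`.
#' @param pop_map Population map: a data frame with columns `individual` and
#'   `population`, or the path of a tab-separated file with that header.
#'   Every individual in the genotype file must be covered.
#' @param map_path Optional path of the `.map` file (defaults to `path` with
#'   its extension replaced).
#'
#' @return A [genotype_matrix].
#' @export
load_genotypes <- function(path, format = c("ped", "vcf"), pop_map,
                           map_path = NULL) {
  format <- match.arg(format)
  pop_map <- read_pop_map(pop_map)
  parsed <- switch(format,
                   ped = parse_ped(path, map_path),
                   vcf = parse_vcf(path))
  unknown <- setdiff(parsed$individual_ids, pop_map$individual)
  if (length(unknown) > 0)
    stop("individuals missing from the population map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  pops <- pop_map$population[match(parsed$individual_ids, pop_map$individual)]
  orient_minor(parsed$dosage, parsed$individual_ids, pops,
               parsed$locus_ids, parsed$allele1, parsed$allele2)
}

read_pop_map <- function(pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1L)
    pop_map <- utils::read.delim(pop_map, header = TRUE,
                                 stringsAsFactors = FALSE)
  if (!all(c("individual", "population") %in% names(pop_map)))
    stop("population map needs columns `individual` and `population`")
  pop_map$individual <- as.character(pop_map$individual)
  pop_map$population <- as.character(pop_map$population)
  if (anyDuplicated(pop_map$individual))
    stop("duplicated individuals in population map")
  pop_map
}

# Re-orient raw counted-allele dosages so they count the panel-wide minor
# allele; ties at MAF 0.5 go to the lexicographically smaller character.
orient_minor <- function(dosage, individual_ids, pops, locus_ids,
                         allele1, allele2) {
  storage.mode(dosage) <- "integer"
  na <- dosage == GT_MISSING
  d <- dosage
  d[na] <- NA_integer_
  f <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  flip <- f > 0.5 | (f == 0.5 & allele1 > allele2)
  flip[is.na(flip)] <- FALSE
  if (any(flip)) {
    sub <- dosage[, flip, drop = FALSE]
    keep_na <- sub == GT_MISSING
    sub <- 2L - sub
    sub[keep_na] <- GT_MISSING
    dosage[, flip] <- sub
  }
  minor <- ifelse(flip, allele2, allele1)
  major <- ifelse(flip, allele1, allele2)
  genotype_matrix(dosage, individual_ids, pops, locus_ids,
                  cbind(minor = minor, major = major))
}

parse_ped <- function(path, map_path = NULL) {
  if (is.null(map_path))
    map_path <- sub("\\.ped$", ".map", path)
  if (!file.exists(map_path))
    stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  locus_ids <- as.character(map[[2]])
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n_loci <- length(locus_ids)
  ids <- character(length(lines))
  a1 <- matrix("", length(lines), n_loci)
  a2 <- matrix("", length(lines), n_loci)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * n_loci)
      stop(sprintf("malformed PED line %d: %d fields, expected %d",
                   i, length(tok), 6 + 2 * n_loci))
    ids[i] <- tok[2]
    gt <- tok[-(1:6)]
    a1[i, ] <- gt[seq(1, length(gt), by = 2)]
    a2[i, ] <- gt[seq(2, length(gt), by = 2)]
  }
  dosage <- matrix(GT_MISSING, length(lines), n_loci)
  allele_minor <- character(n_loci)
  allele_major <- character(n_loci)
  for (l in seq_len(n_loci)) {
    x1 <- a1[, l]; x2 <- a2[, l]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop(sprintf("locus %s has more than two alleles", locus_ids[l]))
    if (length(alleles) == 0) {          # all missing
      allele_minor[l] <- "0"; allele_major[l] <- "0"
      next
    }
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    counted <- alleles[1]                 # dosage counts alleles[1] for now
    dosage[!miss, l] <- (x1[!miss] == counted) + (x2[!miss] == counted)
    allele_minor[l] <- alleles[1]
    allele_major[l] <- alleles[2]
  }
  list(dosage = dosage, individual_ids = ids, locus_ids = locus_ids,
       allele1 = allele_minor, allele2 = allele_major)
}

parse_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the `vcfR` package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  ref <- vcfR::getREF(v)
  ids <- vcfR::getID(v)
  if (anyNA(ids))
    ids[is.na(ids)] <- paste0(vcfR::getCHROM(v)[is.na(ids)], "_",
                              vcfR::getPOS(v)[is.na(ids)])
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic VCF record(s) skipped")
    v <- v[!multi, ]
    alt <- alt[!multi]; ref <- ref[!multi]; ids <- ids[!multi]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  indiv <- colnames(gt)
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(GT_MISSING, length(g))
    out[g == "0/0"] <- 0L
    out[g == "0/1" | g == "1/0"] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  dosage <- t(apply(gt, 1, code))        # loci x individuals -> transpose
  dosage <- t(dosage)
  list(dosage = dosage, individual_ids = indiv, locus_ids = ids,
       allele1 = alt, allele2 = ref)    # dosage counts ALT
}

#' Quality-control configuration
#'
#' Thresholds of the SNP/individual filtering chain: minimum minor allele
#' frequency, maximum per-locus and per-individual missingness, and the LD
#' pruning r-squared ceiling.
#'
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param locus_missing_max Maximum fraction of missing calls per locus
#'   (default 0.10).
#' @param indiv_missing_max Maximum fraction of missing calls per individual
#'   (default 0.10).
#' @param ld_r2_max Squared dosage correlation above which the later locus of
#'   a pair is pruned (default 0.7).
#'
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, locus_missing_max = 0.10,
                      indiv_missing_max = 0.10, ld_r2_max = 0.7) {
  vals <- c(maf_min, locus_missing_max, indiv_missing_max, ld_r2_max)
  if (any(vals < 0 | vals > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, locus_missing_max = locus_missing_max,
                 indiv_missing_max = indiv_missing_max,
                 ld_r2_max = ld_r2_max),
            class = "qc_config")
}

#' Apply the QC filter chain
#'
#' Removes loci failing the missingness or minor-allele-frequency filter,
#' then individuals exceeding the missingness ceiling, then re-applies the
#' MAF filter once (individual removal can change allele frequencies). Every
#' removal is recorded in the report.
#'
#' @param G A [genotype_matrix].
#' @param cfg A [qc_config].
#'
#' @return A list with elements `genotypes` (filtered [genotype_matrix]) and
#'   `report` (class `qc_report`).
#' @export
apply_qc_filters <- function(G, cfg = qc_config()) {
  if (ncol(G$values) == 0 || nrow(G$values) == 0)
    stop("empty genotype matrix")
  in_dim <- dim(G$values)

  v <- gt_numeric(G)
  locus_miss <- colMeans(is.na(v))
  drop_miss <- locus_miss > cfg$locus_missing_max
  maf <- gt_maf(G)
  drop_maf <- !drop_miss & (is.na(maf) | maf < cfg$maf_min)
  keep_loci <- !(drop_miss | drop_maf)
  if (!any(keep_loci)) {
    binding <- if (sum(drop_miss) >= sum(drop_maf)) "locus missingness"
               else "minor allele frequency"
    stop("all loci removed by QC; binding filter: ", binding)
  }
  G1 <- gt_subset(G, loci = which(keep_loci))

  v1 <- gt_numeric(G1)
  ind_miss <- rowMeans(is.na(v1))
  keep_ind <- ind_miss <= cfg$indiv_missing_max
  if (!any(keep_ind))
    stop("all individuals removed by QC; binding filter: individual missingness")
  G2 <- gt_subset(G1, ind = which(keep_ind))

  maf2 <- gt_maf(G2)
  keep2 <- !is.na(maf2) & maf2 >= cfg$maf_min
  if (!any(keep2))
    stop("all loci removed by QC; binding filter: minor allele frequency (re-pass)")
  G3 <- gt_subset(G2, loci = which(keep2))

  report <- structure(
    list(input_dim = in_dim,
         loci_removed_missing = sum(drop_miss),
         loci_removed_maf = sum(drop_maf),
         individuals_removed = sum(!keep_ind),
         loci_removed_maf_repass = sum(!keep2),
         output_dim = dim(G3$values),
         config = cfg),
    class = "qc_report")
  list(genotypes = G3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input : %d individuals x %d loci\n",
              x$input_dim[1], x$input_dim[2]))
  cat(sprintf("  loci removed   : %d missingness, %d MAF, %d MAF re-pass\n",
              x$loci_removed_missing, x$loci_removed_maf,
              x$loci_removed_maf_repass))
  cat(sprintf("  individuals removed: %d\n", x$individuals_removed))
  cat(sprintf("  output: %d individuals x %d loci\n",
              x$output_dim[1], x$output_dim[2]))
  invisible(x)
}

#' Serialise a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report_json <- function(report, path = NULL) {
  x <- report[setdiff(names(report), "config")]
  x$config <- unclass(report$config)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window, while any retained pair of loci has squared
#' dosage correlation above `r2_max`, the later-indexed locus of the worst
#' offending pair is dropped. Correlations use pairwise-complete
#' observations.
#'
#' @param G A [genotype_matrix].
#' @param r2_max Squared-correlation ceiling (default 0.7).
#' @param window_loci Window width in loci (default 200).
#' @param step_loci Step between window starts (default 50).
#'
#' @return Integer vector of retained locus indices (increasing).
#' @export
ld_prune <- function(G, r2_max = 0.7, window_loci = 200, step_loci = 50) {
  if (window_loci < 2) stop("`window_loci` must be at least 2")
  v <- gt_numeric(G)
  L <- ncol(v)
  keep <- rep(TRUE, L)
  starts <- seq(1L, max(1L, L - 1L), by = step_loci)
  for (s in starts) {
    idx <- seq(s, min(s + window_loci - 1L, L))
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(
      stats::cor(v[, idx, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    diag(r2) <- 0
    r2[is.na(r2)] <- 0
    repeat {
      w <- which.max(r2)
      if (r2[w] <= r2_max) break
      pair <- arrayInd(w, dim(r2))
      drop_local <- max(pair)            # later-indexed locus of worst pair
      keep[idx[drop_local]] <- FALSE
      r2[drop_local, ] <- 0
      r2[, drop_local] <- 0
    }
  }
  which(keep)
}

#' Mean-impute missing dosages within populations
#'
#' Each missing cell is replaced by the mean dosage of the non-missing
#' members of the same population at that locus; a locus entirely missing
#' within a population falls back to the global locus mean.
#'
#' @param G A [genotype_matrix].
#' @return Numeric individuals x loci matrix with no missing values.
#' @export
impute_within_population <- function(G) {
  v <- gt_numeric(G)
  if (!anyNA(v)) return(v)
  global <- colMeans(v, na.rm = TRUE)
  if (anyNA(global))
    stop("locus entirely missing in every population: ",
         paste(utils::head(G$locus_ids[is.na(global)], 5), collapse = ", "))
  for (pop in unique(G$population_labels)) {
    rows <- G$population_labels == pop
    sub <- v[rows, , drop = FALSE]
    if (!anyNA(sub)) next
    mu <- colMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- global[is.nan(mu)]
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    sub[na_idx] <- mu[na_idx[, 2]]
    v[rows, ] <- sub
  }
  v
}

#' Population allele frequencies
#'
#' Frequency of the panel minor allele per population and locus, computed
#' over non-missing calls, with the number of observed allele copies
#' recorded per cell. A population with no non-missing call at a locus gets
#' `NA` (flagged unavailable).
#'
#' @param G A [genotype_matrix].
#' @return A list of class `pop_allele_freq` with matrices `freq` and
#'   `n_alleles` (populations x loci).
#' @export
population_allele_frequencies <- function(G) {
  v <- gt_numeric(G)
  pops <- sort(unique(G$population_labels))
  freq <- matrix(NA_real_, length(pops), ncol(v),
                 dimnames = list(pops, G$locus_ids))
  n_alleles <- matrix(0L, length(pops), ncol(v),
                      dimnames = list(pops, G$locus_ids))
  for (i in seq_along(pops)) {
    sub <- v[G$population_labels == pops[i], , drop = FALSE]
    n <- 2L * colSums(!is.na(sub))
    s <- colSums(sub, na.rm = TRUE)
    freq[i, ] <- ifelse(n > 0, s / n, NA_real_)
    n_alleles[i, ] <- n
  }
  structure(list(freq = freq, n_alleles = n_alleles,
                 populations = pops, locus_ids = G$locus_ids),
            class = "pop_allele_freq")
}

#' @export
print.pop_allele_freq <- function(x, ...) {
  cat(sprintf("pop_allele_freq: %d populations x %d loci\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}
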