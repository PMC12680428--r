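#' Run the full landscape-genomics pipeline
#'
#' Configuration-driven orchestration of every stage: QC, diversity and
#' F-statistics, Mantel IBD/IBE, PCA, the three outlier scans, the consensus
#' panel, RDA variance partitioning, genomic offsets per scenario, and the
#' selection-time grid. Intermediate tables are written as CSV/TSV/JSON
#' under the output directory together with a run log; a deterministic
#' `summary.json` carries the headline quantities.
#'
#' The configuration is a list (or the path of a YAML file) with either a
#' `synthetic` block (arguments of [landscape_panel_spec()]) or an `input`
#' block (`ped`, `pop_map`, `env`, `coords` paths), plus optional `qc`
#' (arguments of [qc_config()]), `scan` (`k`, `trim`, `q_threshold`,
#' `sd_mult`), `scenarios` (default the three SSP names), `selection`
#' (`p0_grid`, `s_grid`), and `seed`.
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp)
    stop("config must contain exactly one of `synthetic` or `input`")
  scenarios <- config$scenarios %||% c("ssp126", "ssp245", "ssp585")
  if (has_inp && length(scenarios) > 0 &&
      is.null(config$input$env_future) &&
      !isTRUE(config$builtin_scenarios))
    stop("offset stage requested but no future environment given: ",
         "supply `input$env_future` or set `builtin_scenarios: true`")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg)
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%H:%M:%S"), stage, msg),
        file = log_path, append = TRUE)
  stage <- function(name, expr) {
    logf(name, "start")
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    logf(name, "done")
    r
  }
  cat(sprintf("geaoffset pipeline, seed %d, R %s\n", seed,
              paste(R.version$major, R.version$minor, sep = ".")),
      file = log_path)

  panel <- stage("load", {
    if (has_syn) {
      spec <- do.call(landscape_panel_spec,
                      c(config$synthetic, list(seed = seed)))
      simulate_landscape_panel(spec)
    } else {
      inp <- config$input
      G <- load_genotypes(inp$ped, "ped", inp$pop_map)
      env <- utils::read.csv(inp$env, stringsAsFactors = FALSE)
      coords <- utils::read.csv(inp$coords, stringsAsFactors = FALSE)
      list(genotypes = G, env = env, coords = coords, loci_info = NULL)
    }
  })

  qc <- stage("qc", {
    cfg <- do.call(qc_config, config$qc %||% list())
    r <- apply_qc_filters(panel$genotypes, cfg)
    qc_report_json(r$report, file.path(out_dir, "qc_report.json"))
    r
  })
  G <- qc$genotypes

  div <- stage("diversity", {
    d <- heterozygosity_stats(G)
    utils::write.csv(d$per_population,
                     file.path(out_dir, "diversity.csv"), row.names = FALSE)
    d
  })
  fst <- stage("fst", {
    f <- wc_fst(G, mode = "pairwise")
    utils::write.csv(f$pairwise, file.path(out_dir, "fst_pairwise.csv"))
    f
  })
  mantel <- stage("mantel", {
    set.seed(seed)
    Dgeo <- geodesic_distances(panel$coords)
    Denv <- env_distances(panel$env)
    Dgen <- fst_linearize(fst$pairwise)
    list(ibd = mantel_test(Dgen, Dgeo), ibe = mantel_test(Dgen, Denv))
  })

  imputed <- impute_within_population(G)
  pca <- stage("pca", {
    p <- pca_genotypes(imputed)
    utils::write.csv(data.frame(axis = seq_along(p$eigenvalues),
                                eigenvalue = p$eigenvalues,
                                prop_var = p$prop_var),
                     file.path(out_dir, "pca_scree.csv"), row.names = FALSE)
    p
  })

  scan_cfg <- config$scan %||% list()
  q_thr <- scan_cfg$q_threshold %||% 0.05
  freqs <- population_allele_frequencies(G)
  of <- stage("outflank", outflank_scan(G, trim = scan_cfg$trim %||% 0.05,
                                        q_threshold = q_thr))
  pc <- stage("pcadapt", pcadapt_scan(G, K = scan_cfg$k,
                                      q_threshold = q_thr))
  rda_env <- stage("rda", {
    set.seed(seed)
    vp <- vif_prune(panel$env)
    X <- env_numeric(panel$env, vp$retained)
    m <- rda_fit(freqs$freq, X)
    axes_p <- anova_axes(m, n_perm = 199, max_axes = min(3, length(m$eigenvalues)))
    sig <- which(axes_p < 0.05)
    if (length(sig) == 0) sig <- 1L
    out <- rda_outliers(m, sd_mult = scan_cfg$sd_mult %||% 2.5, axes = sig)
    list(model = m, vif = vp, axes_p = axes_p, outliers = out, sig = sig)
  })
  cons <- stage("consensus", {
    cs <- consensus_outliers(
      of$per_locus$locus_id[which(of$per_locus$outlier)],
      pc$per_locus$locus_id[which(pc$per_locus$outlier)],
      rda_env$outliers$locus_id)
    writeLines(jsonlite::toJSON(cs$counts, auto_unbox = TRUE),
               file.path(out_dir, "venn_counts.json"))
    cs
  })
  write_scan_results(of, pc, rda_env$outliers$locus_id,
                     file.path(out_dir, "scan_results.tsv"))

  varpart <- stage("varpart", {
    set.seed(seed)
    mem <- dbmem_basis(panel$coords)
    fs <- forward_select(freqs$freq, mem$vectors, n_perm = 199)
    geo <- mem$vectors[, fs$selected, drop = FALSE]
    if (ncol(geo) == 0) geo <- mem$vectors[, 1, drop = FALSE]
    vp <- variance_partition(freqs$freq,
                             env_numeric(panel$env, rda_env$vif$retained),
                             geo)
    utils::write.csv(data.frame(fraction = c("a_env", "b_confounded",
                                             "c_geo", "unexplained"),
                                adj_r2 = c(vp$a, vp$b, vp$c,
                                           vp$unexplained)),
                     file.path(out_dir, "variance_partition.csv"),
                     row.names = FALSE)
    vp
  })

  offs <- stage("offset", {
    pav <- cons$pav
    if (length(pav) < 2) {
      ranked <- rda_env$outliers$locus_id
      pav <- utils::head(unique(c(pav, ranked)), 5)
    }
    if (length(pav) < 2)
      stop("fewer than two consensus loci; cannot calibrate offsets")
    fp <- freqs
    idx <- match(pav, fp$locus_ids)
    fp$freq <- fp$freq[, idx, drop = FALSE]
    fp$n_alleles <- fp$n_alleles[, idx, drop = FALSE]
    fp$locus_ids <- pav
    model <- fit_allele_env_model(fp, panel$env,
                                  variables = rda_env$vif$retained)
    rows <- list()
    for (sc in scenarios) {
      fut <- if (has_inp && !is.null(config$input$env_future[[sc]]))
        utils::read.csv(config$input$env_future[[sc]],
                        stringsAsFactors = FALSE)
      else
        shift_climate(panel$env,
                      climate_scenario_deltas(panel$coords, sc), sc)
      pred <- predict_future_frequencies(model, fut)
      rona <- rona_offset(fp, pred)
      ai <- adaptive_index_offset(model$stage1, panel$env, fut,
                                  axes = seq_along(rda_env$sig))
      rows[[paste0("rona_", sc)]] <-
        list(method = "rona_rda", scenario = sc, values = rona)
      rows[[paste0("ai_", sc)]] <-
        list(method = "rda_adaptive_index", scenario = sc, values = ai)
    }
    tab <- offset_table(rows)
    utils::write.csv(tab, file.path(out_dir, "offsets.csv"),
                     row.names = FALSE)
    list(table = tab, pav = pav)
  })

  sel <- stage("selection_time", {
    cfg <- config$selection %||% list()
    rng <- range(offs$table$offset[offs$table$method == "rona_rda" &
                                     offs$table$scenario ==
                                     scenarios[length(scenarios)]])
    sim <- simulate_selection_grid(
      p0_grid = cfg$p0_grid %||% seq(0.01, 0.9, by = 0.01),
      s_grid = cfg$s_grid %||% seq(0.1, 0.9, by = 0.1),
      targets = round(pmin(rng, 0.99), 4))
    utils::write.csv(sim$grid, file.path(out_dir, "selection_grid.csv"),
                     row.names = FALSE)
    sim
  })

  summary <- list(
    seed = seed,
    n_individuals = nrow(G$values),
    n_loci = ncol(G$values),
    n_populations = length(unique(G$population_labels)),
    global_fst = fst$global,
    overall_Ho = div$overall$Ho,
    overall_He = div$overall$He,
    mantel_ibd = list(r = mantel$ibd$r, p = mantel$ibd$p),
    mantel_ibe = list(r = mantel$ibe$r, p = mantel$ibe$p),
    outlier_counts = as.list(cons$counts),
    pav = cons$pav,
    variance_partition = list(a_env = varpart$a, b_confounded = varpart$b,
                              c_geo = varpart$c,
                              unexplained = varpart$unexplained),
    offsets = lapply(
      split(offs$table,
            paste(offs$table$method, offs$table$scenario, sep = ":")),
      function(d) as.list(stats::setNames(d$offset, d$population))),
    selection_summary = sel$summary)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE),
             file.path(out_dir, "summary.json"))
  logf("pipeline", "complete")
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
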