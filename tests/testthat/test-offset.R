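# Shared calibration objects for the offset tests.
offset_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    panel <- default_panel()
    fr <- population_allele_frequencies(panel$genotypes)
    clin <- panel$loci_info$locus_id[panel$loci_info$type == "adaptive"]
    clin <- intersect(clin, fr$locus_ids)
    fp <- freq_subset(fr, clin)
    model <- fit_allele_env_model(fp, panel$env)
    futs <- lapply(c(ssp126 = "ssp126", ssp245 = "ssp245",
                     ssp585 = "ssp585"), function(sc)
      shift_climate(panel$env, climate_scenario_deltas(panel$coords, sc), sc))
    cache <<- list(panel = panel, fp = fp, model = model, futs = futs)
    cache
  }
})

test_that("stage-2 calibration is monotone and flags uninformative loci", {
  fx <- offset_fixture()
  st2 <- fx$model$stage2
  expect_gte(sum(st2$slope[st2$ok] > 0), 19)

  # constant frequencies cannot be calibrated; predictions fall back
  P <- fx$fp$freq
  P[, 1] <- 0.4
  fp2 <- fx$fp; fp2$freq <- P
  m2 <- fit_allele_env_model(fp2, fx$panel$env)
  expect_false(m2$stage2$ok[1])
  pred <- predict_future_frequencies(m2, fx$futs$ssp585)
  expect_equal(unname(pred$freq[, 1]), rep(0.4, nrow(P)), tolerance = 1e-6)
})

test_that("predictions equal fitted values when the future equals the present", {
  fx <- offset_fixture()
  p_now <- predict_future_frequencies(fx$model, fx$panel$env)
  p_again <- predict_future_frequencies(fx$model, fx$panel$env)
  expect_lt(max(abs(p_now$freq - p_again$freq)), 1e-10)
  expect_equal(as.numeric(rona_offset(p_now, p_again)),
               rep(0, nrow(p_now$freq)))
})

test_that("recalibrating on fitted values approximately reproduces them", {
  fx <- offset_fixture()
  fitted_now <- predict_future_frequencies(fx$model, fx$panel$env)
  fp2 <- fx$fp
  fp2$freq <- fitted_now$freq
  m2 <- fit_allele_env_model(fp2, fx$panel$env)
  refit <- predict_future_frequencies(m2, fx$panel$env)
  expect_lt(max(abs(refit$freq - fitted_now$freq)), 0.05)
})

test_that("warming raises predicted frequencies of warm-adapted alleles", {
  fx <- offset_fixture()
  info <- fx$panel$loci_info
  pos <- info$locus_id[info$type == "adaptive" & info$effective_b > 0]
  pos <- intersect(pos, colnames(fx$fp$freq))
  plus3 <- fx$panel$env
  plus3$mean_temp <- plus3$mean_temp + 3
  p_now <- predict_future_frequencies(fx$model, fx$panel$env)
  p_fut <- predict_future_frequencies(fx$model, plus3)
  expect_true(all(p_fut$freq[, pos] > p_now$freq[, pos]))
})

test_that("predictions stay inside (0,1) under extreme climate stress", {
  fx <- offset_fixture()
  stress <- fx$panel$env
  stress$mean_temp <- stress$mean_temp + 50
  hi <- predict_future_frequencies(fx$model, stress)$freq
  stress$mean_temp <- stress$mean_temp - 100
  lo <- predict_future_frequencies(fx$model, stress)$freq
  expect_true(all(hi > 0 & hi < 1))
  expect_true(all(lo > 0 & lo < 1))
  bad <- fx$panel$env[, !(names(fx$panel$env) %in% "mean_temp")]
  expect_error(predict_future_frequencies(fx$model, bad), "mean_temp")
})

test_that("RONA is the mean absolute frequency shift", {
  cur <- rbind(p1 = c(0.2, 0.4))
  fut <- rbind(p1 = c(0.3, 0.1))
  expect_equal(as.numeric(rona_offset(cur, fut)), 0.2)
  expect_equal(as.numeric(rona_offset(cur, cur)), 0)
  expect_error(rona_offset(cur, fut[, 1, drop = FALSE]), "shape")
})

test_that("offsets grow with scenario severity and agree across methods", {
  fx <- offset_fixture()
  rona <- sapply(fx$futs, function(f)
    rona_offset(fx$fp, predict_future_frequencies(fx$model, f)))
  expect_true(all(rona[, "ssp126"] <= rona[, "ssp245"] + 1e-9))
  expect_true(all(rona[, "ssp245"] <= rona[, "ssp585"] + 1e-9))
  expect_true(all(rona >= 0 & rona <= 1))

  ai <- adaptive_index_offset(fx$model$stage1, fx$panel$env,
                              fx$futs$ssp585, axes = 1)
  expect_gt(cor(rona[, "ssp585"], ai, method = "spearman"), 0.7)
})

test_that("the adaptive index offset is a signed-axis-invariant distance", {
  fx <- offset_fixture()
  m <- fx$model$stage1
  expect_equal(unname(adaptive_index_offset(m, fx$panel$env,
                                            fx$panel$env, axes = 1)),
               rep(0, nrow(fx$panel$env)))
  one <- adaptive_index_offset(m, fx$panel$env, fx$futs$ssp585, axes = 1)
  B <- m$biplot_scores[, 1]
  std <- function(env) scale(as.matrix(env[, names(m$x_center)]),
                             m$x_center, m$x_scale)
  delta <- abs(drop((std(fx$panel$env) - std(fx$futs$ssp585)) %*% B))
  expect_equal(unname(one), unname(delta), tolerance = 1e-10)

  m2 <- m
  m2$biplot_scores[, 1] <- -m2$biplot_scores[, 1]
  expect_equal(adaptive_index_offset(m2, fx$panel$env, fx$futs$ssp585,
                                     axes = 1), one, tolerance = 1e-12)
  expect_error(adaptive_index_offset(m, fx$panel$env, fx$futs$ssp585,
                                     axes = 99L), "retained")
})

test_that("swapping the consensus panel for two-of-three keeps the ranking", {
  fx <- offset_fixture()
  fr <- population_allele_frequencies(fx$panel$genotypes)
  clin <- colnames(fx$fp$freq)
  extra <- setdiff(fr$locus_ids, clin)[1:4]
  two_of_three <- freq_subset(fr, c(clin, extra))
  m2 <- fit_allele_env_model(two_of_three, fx$panel$env)
  ai1 <- adaptive_index_offset(fx$model$stage1, fx$panel$env,
                               fx$futs$ssp585, axes = 1)
  ai2 <- adaptive_index_offset(m2$stage1, fx$panel$env,
                               fx$futs$ssp585, axes = 1)
  expect_gt(cor(ai1, ai2, method = "spearman"), 0.9)
})

test_that("IDW interpolation honours data points and weight normalization", {
  pts <- data.frame(lat = c(0, 0), lon = c(0, 2))
  grid <- data.frame(lat = c(0, 0, 0), lon = c(0, 1, 1.5))
  s <- idw_surface(pts, c(0, 1), grid)
  expect_equal(s$value[1], 0)                    # coincident node
  expect_equal(s$value[2], 0.5)                  # equidistant node
  expect_gt(s$value[3], 0.5)
  s2 <- idw_surface(pts, c(7, 7), grid)
  expect_equal(s2$value, rep(7, 3))              # constant field
  expect_error(idw_surface(pts[0, ], numeric(0), grid), "no data")

  cls <- offset_classes(seq(0, 1, length.out = 40), n = 10)
  expect_equal(range(cls), c(1L, 10L))
})
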