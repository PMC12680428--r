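test_that("rda_fit reduces to multiple regression for a single response", {
  set.seed(20)
  n <- 25
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -0.5, 0) + rnorm(n)
  m <- rda_fit(matrix(y, ncol = 1), X)
  lm_r2 <- summary(lm(y ~ X))$r.squared
  expect_equal(m$r_squared, lm_r2, tolerance = 1e-10)
  expect_equal(m$adj_r_squared, summary(lm(y ~ X))$adj.r.squared,
               tolerance = 1e-10)
})

test_that("conditioning on the predictors themselves removes all signal", {
  set.seed(21)
  Y <- matrix(rnorm(20 * 10), 20, 10)
  X <- matrix(rnorm(20 * 2), 20, 2)
  m <- rda_fit(Y, X, Z = X)
  expect_lt(abs(m$r_squared), 1e-10)
})

test_that("the Ezekiel adjustment matches its closed form", {
  # construct a single-predictor fit with R^2 exactly 0.5 at n = 11
  set.seed(22)
  x <- rnorm(11)
  e <- residuals(lm(rnorm(11) ~ x))
  xs <- scale(x)[, 1]
  ys <- xs / sqrt(sum(xs^2)) + e / sqrt(sum(e^2))   # equal SS components
  m <- rda_fit(matrix(ys, ncol = 1), matrix(x, ncol = 1))
  expect_equal(m$r_squared, 0.5, tolerance = 1e-10)
  expect_equal(m$adj_r_squared, 1 - 0.5 * 10 / 9, tolerance = 1e-10)
})

test_that("rda_fit agrees with vegan's constrained ordination", {
  panel <- default_panel()
  fr <- population_allele_frequencies(panel$genotypes)
  Y <- fr$freq[, colSums(is.na(fr$freq)) == 0][, 1:150]
  X <- scale(as.matrix(panel$env[, c("mean_temp", "ph", "wet")]))
  m <- rda_fit(Y, X)
  v <- vegan::rda(Y ~ X)
  expect_equal(unname(m$eigenvalues),
               unname(v$CCA$eig[seq_along(m$eigenvalues)]),
               tolerance = 1e-8)
  expect_equal(m$r_squared, unname(vegan::RsquareAdj(v)$r.squared),
               tolerance = 1e-10)
  expect_equal(m$adj_r_squared, unname(vegan::RsquareAdj(v)$adj.r.squared),
               tolerance = 1e-10)

  # partial RDA eigenvalues against vegan's Condition()
  Zg <- scale(panel$coords$lat)
  mp <- rda_fit(Y, X, Z = Zg)
  vp <- vegan::rda(Y ~ X + Condition(Zg))
  expect_equal(unname(mp$eigenvalues),
               unname(vp$CCA$eig[seq_along(mp$eigenvalues)]),
               tolerance = 1e-8)
})

test_that("orthonormal predictors reproduce the PCA of the fitted subspace", {
  set.seed(23)
  Y <- matrix(rnorm(30 * 40), 30, 40)
  X <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  m <- rda_fit(Y, X)
  fitted <- m$Xs %*% m$coefficients
  ev <- prcomp(fitted)$sdev^2
  expect_equal(m$eigenvalues, ev[seq_along(m$eigenvalues)],
               tolerance = 1e-10)
})

test_that("sequential axis tests detect planted structure and stay null otherwise", {
  # strong one-axis signal
  hits <- vapply(1:5, function(s) {
    set.seed(600 + s)
    n <- 20; grad <- scale(seq_len(n))[, 1]
    Y <- outer(grad, rnorm(30)) + matrix(rnorm(n * 30, sd = 0.5), n, 30)
    m <- rda_fit(Y, cbind(g = grad, n1 = rnorm(n)))
    anova_axes(m, n_perm = 99, max_axes = 1)[1] == 1 / 100
  }, logical(1))
  expect_gte(sum(hits), 4)

  # pure-noise response gives approximately uniform axis-1 p-values
  set.seed(24)
  ps <- vapply(1:200, function(i) {
    Y <- matrix(rnorm(12 * 25), 12, 25)
    X <- matrix(rnorm(12 * 2), 12, 2)
    anova_axes(rda_fit(Y, X), n_perm = 99, max_axes = 1)[1]
  }, numeric(1))
  # permutation p-values sit on a 1/100 grid; jitter within grid cells to
  # remove ties before the KS comparison
  set.seed(25)
  expect_gt(ks.test(ps - runif(length(ps)) / 100, "punif")$p.value, 0.01)
  expect_true(all(ps >= 1 / 100))
})

test_that("variance partitioning fractions are exact and well-behaved", {
  panel <- default_panel()
  fr <- population_allele_frequencies(panel$genotypes)
  Y <- fr$freq[, colSums(is.na(fr$freq)) == 0]
  Xe <- as.matrix(panel$env[, c("mean_temp", "ph")])
  mem <- dbmem_basis(panel$coords)
  Xg <- mem$vectors[, 1:5]
  vp <- variance_partition(Y, Xe, Xg)
  expect_equal(vp$a + vp$b + vp$c, unname(vp$adj_r2["combined"]),
               tolerance = 1e-10)
  expect_equal(vp$unexplained, 1 - unname(vp$adj_r2["combined"]),
               tolerance = 1e-10)

  # invariance to an invertible reparameterization of the env block
  A <- matrix(c(2, 1, 0.5, -1), 2, 2)
  vp2 <- variance_partition(Y, Xe %*% A, Xg)
  expect_equal(vp2$a, vp$a, tolerance = 1e-8)
  expect_equal(vp2$b, vp$b, tolerance = 1e-8)

  # cross-check [a] against the partial model
  mp <- rda_fit(Y, Xe, Z = Xg)
  expect_equal(vp$a, mp$adj_r_squared, tolerance = 1e-8)
})

test_that("orthogonal predictor blocks have no confounded fraction", {
  bs <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n <- 50
    Xe <- matrix(rnorm(n * 2), n, 2)
    Xg <- qr.resid(qr(cbind(1, Xe)), matrix(rnorm(n * 2), n, 2))
    Y <- 0.4 * Xe %*% matrix(rnorm(2 * 20), 2, 20) +
      0.4 * Xg %*% matrix(rnorm(2 * 20), 2, 20) +
      matrix(rnorm(n * 20), n, 20)
    variance_partition(Y, Xe, Xg)$b
  }, numeric(1))
  expect_lt(mean(abs(bs)), 0.02)
})

test_that("loading outliers follow the normal tail rate and ignore axis signs", {
  set.seed(25)
  m_loci <- 10000
  fake <- structure(list(
    loadings = matrix(rnorm(m_loci), m_loci, 1,
                      dimnames = list(paste0("L", 1:m_loci), NULL)),
    eigenvalues = 1,
    Y = matrix(rnorm(10 * m_loci), 10, m_loci,
               dimnames = list(NULL, paste0("L", 1:m_loci))),
    Xs = matrix(rnorm(10), 10, 1, dimnames = list(NULL, "v"))),
    class = "rda_model")
  out <- rda_outliers(fake, sd_mult = 2.5, axes = 1)
  expected <- 2 * pnorm(-2.5) * m_loci
  expect_lt(abs(nrow(out) - expected), 4 * sqrt(expected))

  fake2 <- fake
  fake2$loadings <- -fake2$loadings
  expect_setequal(rda_outliers(fake2, 2.5, 1)$locus_id, out$locus_id)
})

test_that("clinal loci are flagged by the RDA scan and annotated with temperature", {
  panel <- default_panel()
  fr <- population_allele_frequencies(panel$genotypes)
  ok <- colSums(is.na(fr$freq)) == 0
  m <- rda_fit(fr$freq[, ok], as.matrix(panel$env[, 2:9]))
  out <- rda_outliers(m, axes = 1)
  clin <- panel$loci_info$locus_id[panel$loci_info$type == "adaptive"]
  expect_gte(length(intersect(out$locus_id, clin)),
             0.7 * length(intersect(clin, colnames(fr$freq[, ok]))))
  expect_equal(names(sort(table(out$best_predictor), decreasing = TRUE))[1],
               "mean_temp")
  expect_warning(empty <- rda_outliers(m, axes = integer(0)), "no significant")
  expect_equal(nrow(empty), 0)
})

test_that("VIF pruning removes duplicated and derived variables", {
  set.seed(26)
  x1 <- rnorm(50); x2 <- rnorm(50)
  env <- data.frame(population = paste0("s", 1:50),
                    x1 = x1, x2 = x2, dup = x1)
  res <- vif_prune(env)
  expect_true("dup" %in% res$dropped$variable ||
                "x1" %in% res$dropped$variable)
  expect_equal(length(res$retained), 2)

  env2 <- data.frame(population = paste0("s", 1:50), x1 = x1, x2 = x2,
                     x3 = x1 + x2 + rnorm(50, sd = 0.05))
  res2 <- vif_prune(env2, r_max = 0.95)
  expect_equal(res2$dropped$variable[1], "x3")
  expect_equal(res2$dropped$reason[1], "vif")

  # mutually orthogonal variables are all retained
  Q <- qr.Q(qr(matrix(rnorm(50 * 4), 50, 4)))
  env3 <- data.frame(population = paste0("s", 1:50), Q)
  expect_equal(length(vif_prune(env3)$retained), 4)
})

test_that("the dbMEM basis matches the transect geometry", {
  panel <- default_panel()
  mem <- dbmem_basis(panel$coords)
  expect_equal(mem$n_candidate, 38)     # 39 sites -> 38 non-trivial axes
  expect_lte(ncol(mem$vectors), 38)
  G <- crossprod(mem$vectors)
  expect_equal(G, diag(ncol(mem$vectors)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(mem$values > 0))
  dup <- panel$coords; dup$lat[2] <- dup$lat[1]; dup$lon[2] <- dup$lon[1]
  expect_error(dbmem_basis(dup), "duplicate")
})

test_that("forward selection finds true predictors and rejects noise", {
  # pure noise: empty selection most of the time (the global-R^2 guard plus
  # the entry test keep spurious candidates out)
  empty <- vapply(1:20, function(s) {
    set.seed(800 + s)
    Y <- matrix(rnorm(25 * 15), 25, 15)
    C <- matrix(rnorm(25 * 6), 25, 6)
    length(forward_select(Y, C, n_perm = 99)$selected) == 0
  }, logical(1))
  expect_gte(sum(empty), 17)

  # the strongest true predictor enters first; a weaker second signal keeps
  # the global adjusted R^2 clearly above any single-variable model, so the
  # global guard cannot block the first entry
  first <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 100
    C <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("V", 1:6)))
    Y <- outer(C[, 3], rnorm(15)) + 0.5 * outer(C[, 5], rnorm(15)) +
      matrix(rnorm(n * 15, sd = 1.2), n, 15)
    fs <- forward_select(Y, C, n_perm = 99)
    length(fs$selected) > 0 && fs$selected[1] == "V3"
  }, logical(1))
  expect_gte(sum(first), 9)

  # cumulative adjusted R^2 never exceeds the global model's
  set.seed(27)
  C <- matrix(rnorm(30 * 5), 30, 5)
  Y <- C %*% matrix(rnorm(5 * 10), 5, 10) + matrix(rnorm(300), 30, 10)
  fs <- forward_select(Y, C, n_perm = 99)
  expect_lte(fs$adj_r_squared, fs$global_adj_r_squared + 1e-12)
})

test_that("the binomial GEA GLM estimates slopes and flags degeneracy", {
  set.seed(28)
  env <- rnorm(200)
  p <- plogis(-0.2 + 0.8 * env)
  d <- rbinom(200, 2, p)
  fit <- glm_binomial_gea(d, env)
  expect_true(fit$converged)
  expect_equal(fit$odds_ratio, exp(fit$beta1))
  expect_lt(abs(fit$beta1 - 0.8), 4 * fit$se)

  # null coverage: slope within 2 SE of zero in most replicates
  cover <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    fit0 <- glm_binomial_gea(rbinom(100, 2, 0.5), rnorm(100))
    abs(fit0$beta1) <= 2 * fit0$se
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # all-major-homozygote input runs to the boundary and is flagged
  fit2 <- glm_binomial_gea(rep(2L, 50), rnorm(50))
  expect_false(fit2$converged)
  expect_error(glm_binomial_gea(rep(1L, 50), rep(3, 50)), "constant")

  # homozygote coding drops heterozygotes but keeps the sign
  d2 <- rbinom(300, 2, plogis(0.9 * env[rep(1:200, length.out = 300)]))
  fit3 <- glm_binomial_gea(d2, env[rep(1:200, length.out = 300)],
                           coding = "homozygote")
  expect_gt(fit3$beta1, 0)
})

test_that("consensus intersects method panels and reports the Venn", {
  cs <- consensus_outliers(c("a", "b", "c"), c("b", "c"), "c")
  expect_equal(cs$pav, "c")
  expect_setequal(cs$two_of_three, c("b", "c"))
  expect_equal(unname(cs$counts["pav"]), 1L)
  expect_equal(consensus_outliers(character(0), c("a"), c("a"))$pav,
               character(0))
})
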