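test_that("gene filter keeps genes expressed in strictly more than the threshold", {
  expr <- matrix(0, 3, 24,
                 dimnames = list(c("g11", "g10", "g0"), paste0("s", 1:24)))
  expr["g11", 1:11] <- 5
  expr["g10", 1:10] <- 5
  out <- filter_genes(expr, 10)
  expect_equal(rownames(out), "g11")
  expect_error(filter_genes(expr["g0", , drop = FALSE], 10), "no genes")
})

test_that("bicor has correlation structure and a Pearson fallback", {
  set.seed(20)
  x <- rnorm(50)
  m <- rbind(a = x, b = -x, c = rnorm(50))
  bc <- bicor_matrix(m)
  expect_equal(diag(bc), c(a = 1, b = 1, c = 1))
  expect_equal(bc["a", "b"], -1, tolerance = 1e-9)
  expect_true(isSymmetric(bc))
  expect_error(bicor_matrix(m[, 1:3]), "4 samples")

  const <- rbind(m, d = rep(3, 50))
  w <- capture_warnings(bc2 <- bicor_matrix(const))
  expect_match(w, "MAD", all = FALSE)
  expect_match(w, "constant", all = FALSE)
  expect_equal(bc2["d", "a"], 0)
  expect_equal(bc2["d", "d"], 1)
})

test_that("bicor approximates Pearson for Gaussian data", {
  set.seed(21)
  diffs <- replicate(200, {
    z <- rnorm(200)
    x <- z + rnorm(200)
    y <- 0.5 * z + rnorm(200)  # population rho about 0.3-0.5
    m <- rbind(x, y)
    bicor_matrix(m)[1, 2] - cor(x, y)
  })
  expect_lt(mean(abs(diffs)), 0.05)
  expect_lt(max(abs(diffs)), 0.1)
})

test_that("signed adjacency maps correlation through the soft threshold", {
  cm <- matrix(c(1, -1, 0, -1, 1, 0.5, 0, 0.5, 1), 3)
  a <- signed_adjacency(cm, beta = 10)
  expect_equal(a[1, 2], 0)
  expect_equal(a[1, 3], 0.5^10)
  expect_equal(a[2, 3], 0.75^10)
  expect_equal(diag(a), rep(0, 3))
  expect_error(signed_adjacency(matrix(2, 2, 2)), "\\[-1, 1\\]")

  # monotone in correlation
  cors <- seq(-1, 1, by = 0.05)
  vals <- ((1 + cors) / 2)^10
  expect_true(all(diff(vals) >= 0))
})

test_that("scale-free fit is exact on a power-law degree fixture", {
  # frequencies proportional to k^-2 over well-separated k values
  k_vals <- 1:5
  counts <- round(3600 / k_vals^2)
  k <- rep(k_vals, counts)
  r2 <- scale_free_fit(k, n_bins = 5)
  expect_equal(r2, 1, tolerance = 1e-6)
  expect_error(scale_free_fit(rep(2, 30)), "degenerate")

  # agreement with a direct regression oracle on a random adjacency
  set.seed(22)
  cm <- cor(matrix(rnorm(40 * 60), 60, 40))
  adj <- signed_adjacency(cm, 6)
  kk <- rowSums(adj)
  breaks <- seq(min(kk), max(kk), length.out = 11)
  bin <- cut(kk, breaks, include.lowest = TRUE)
  fr <- tapply(kk, bin, length); mk <- tapply(kk, bin, mean)
  keep <- !is.na(fr)
  fit <- lm(log10(fr[keep] / length(kk)) ~ log10(mk[keep]))
  expected <- summary(fit)$r.squared * -sign(coef(fit)[2])
  expect_equal(scale_free_fit(adj), unname(expected), tolerance = 1e-12)
})

test_that("topological overlap matches the closed form and the triple-loop oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 0
  tom <- tom_matrix(a)
  expect_equal(tom$similarity[1, 2], 0.5, tolerance = 1e-12)

  zero <- matrix(0, 4, 4)
  expect_equal(tom_matrix(zero)$similarity, diag(4))

  set.seed(23)
  for (i in 1:5) {
    n <- sample(10:25, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_matrix(a)$similarity
    expect_equal(tom, tom_oracle(a), tolerance = 1e-9)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom_matrix(a)$dissimilarity, 1 - tom)
  }
  asym <- matrix(runif(9), 3)
  expect_error(tom_matrix(asym), "symmetric")
})

test_that("planted correlation blocks are recovered as two clean modules", {
  set.seed(24)
  n_samp <- 40
  f1 <- rnorm(n_samp); f2 <- rnorm(n_samp)
  expr <- rbind(
    t(replicate(50, f1 + rnorm(n_samp, sd = 0.35))),
    t(replicate(50, f2 + rnorm(n_samp, sd = 0.35)))
  )
  rownames(expr) <- paste0("g", 1:100)
  cfg <- network_config(log_transform = FALSE)
  adj <- signed_adjacency(correlation_matrix(expr, cfg), cfg$soft_power)
  asn <- detect_modules(tom_matrix(adj)$dissimilarity, cfg, expr = expr)
  truth <- rep(1:2, each = 50)
  expect_equal(mclust::adjustedRandIndex(asn$labels, truth), 1)
  expect_equal(sort(as.integer(table(asn$labels))), c(50L, 50L))
})

test_that("pure noise yields mostly unassigned genes", {
  cfg <- network_config(log_transform = FALSE)
  grey_frac <- vapply(1:10, function(s) {
    set.seed(100 + s)
    expr <- matrix(rnorm(100 * 30), 100, 30,
                   dimnames = list(paste0("g", 1:100), NULL))
    adj <- signed_adjacency(correlation_matrix(expr, cfg), cfg$soft_power)
    asn <- detect_modules(tom_matrix(adj)$dissimilarity, cfg, expr = expr)
    mean(asn$labels == "grey")
  }, numeric(1))
  expect_gte(mean(grey_frac), 0.9)
})

test_that("fewer genes than the minimum module size all go grey", {
  set.seed(25)
  d <- matrix(runif(100), 10); d <- (d + t(d)) / 2; diag(d) <- 0
  asn <- detect_modules(d, network_config(min_module_size = 30))
  expect_true(all(asn$labels == "grey"))
})

test_that("module eigengene matches the eigendecomposition oracle", {
  set.seed(26)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    got <- module_eigengene(x, 1:20)
    want <- eigengene_oracle(x)
    expect_equal(abs(cor(got$me, want$me)), 1, tolerance = 1e-9)
    expect_equal(got$var_explained, want$var_explained, tolerance = 1e-9)
    expect_equal(sum(got$me^2), 1, tolerance = 1e-9)
  }

  # identical genes: rank-1, ME proportional to the common profile
  common <- rnorm(12)
  x1 <- matrix(rep(common, each = 5), 5, 12)
  me1 <- module_eigengene(x1, 1:5)
  expect_equal(me1$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(me1$me, common)), 1, tolerance = 1e-12)

  # sign convention: the ME tracks the module average, so negating every
  # gene negates the ME (deterministically, no svd sign ambiguity)
  set.seed(27)
  x2 <- matrix(rnorm(8 * 10), 8, 10) + rep(rnorm(10), each = 8)
  expect_equal(module_eigengene(-x2, 1:8)$me,
               -module_eigengene(x2, 1:8)$me, tolerance = 1e-9)
})

test_that("module-trait correlation reports r, p and within-trait q", {
  set.seed(28)
  mes <- matrix(rnorm(30 * 3), 30, 3,
                dimnames = list(NULL, c("turquoise", "blue", "brown")))
  # trait equal to an eigengene
  mt <- module_trait_correlation(mes, data.frame(tr = mes[, "blue"]))
  row <- mt[mt$module == "blue", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_lt(row$p, 1e-20)
  expect_true(all(mt$q >= mt$p - 1e-15))
  expect_equal(mt$q, bh_stepup_oracle(mt$p), tolerance = 1e-12)

  # trait orthogonalized against all MEs
  y <- rnorm(30)
  ortho <- residuals(lm(y ~ mes))
  mt2 <- module_trait_correlation(mes, ortho)
  expect_true(all(abs(mt2$r) < 0.05))

  expect_error(module_trait_correlation(mes, rep(1, 30)), "zero variance")
  expect_error(module_trait_correlation(mes, rnorm(10)), "misaligned")
})

test_that("gene significance and module membership behave on planted data", {
  set.seed(29)
  n_samp <- 100
  f <- rnorm(n_samp)
  expr <- rbind(
    t(replicate(40, f + rnorm(n_samp, sd = 0.6))),
    matrix(rnorm(40 * n_samp), 40, n_samp)
  )
  rownames(expr) <- paste0("g", 1:80)
  me <- module_eigengene(expr, 1:40)$me
  trait <- 0.7 * scale(f)[, 1] + sqrt(1 - 0.49) * rnorm(n_samp)
  gsm <- gene_significance_membership(expr, cbind(turquoise = me), trait)

  # a gene equal to the common factor has high membership
  expect_gt(gsm$mm[1, "turquoise"], 0.6)
  # noise genes have low significance with high probability
  expect_lt(stats::quantile(gsm$gs[41:80], 0.9), 0.3)
  # within the planted module, GS tracks MM
  expect_gt(cor(gsm$gs[1:40], abs(gsm$mm[1:40, 1])), 0)
})

test_that("the end-to-end stage is deterministic for a fixed matrix", {
  p <- expression_sim_params(c(40, 40), 30, trait_correlations = c(0.5, 0),
                             noise_sd = 0.6, background_fraction = 0.3,
                             seed = 31)
  sim <- simulate_expression(p)
  cfg <- network_config(log_transform = FALSE)
  n1 <- coexpression_network(sim$expr, traits = sim$truth$trait, config = cfg)
  n2 <- coexpression_network(sim$expr, traits = sim$truth$trait, config = cfg)
  expect_identical(n1$assignment$labels, n2$assignment$labels)
  expect_identical(n1$module_trait, n2$module_trait)
})
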