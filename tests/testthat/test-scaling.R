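test_that("length normalization and the breakpoint scale are consistent", {
  expect_equal(normalize_length(46000, 2500000), 0.0184)
  expect_equal(normalize_length(5e6, 5e6), 1)
  # the log10 breakpoint -1.735 is the same quantity as 1.84% of a
  # chromosome
  expect_equal(10^-1.735, 0.0184, tolerance = 1e-3)
})

test_that("model scoring reduces to ordinary least squares", {
  set.seed(61)
  x <- runif(200, -3, 0)
  y <- 0.4 - 0.9 * x + rnorm(200, 0, 0.3)
  cm <- compare_models(x, y)
  lin <- cm[cm$model == "linear", ]
  ols <- lm(y ~ x)
  expect_equal(lin$rss, sum(residuals(ols)^2), tolerance = 1e-10)
  expect_equal(lin$adj_r2, summary(ols)$adj.r.squared, tolerance = 1e-10)
})

test_that("data on a single line collapse the segmented fit", {
  set.seed(62)
  x <- runif(300, -3, 0)
  y <- 0.2 - 0.9 * x
  fit <- fit_segmented(x, y)
  expect_equal(fit$slope1, -0.9, tolerance = 1e-6)
  expect_equal(fit$slope2, -0.9, tolerance = 1e-6)
  expect_true(fit$no_breakpoint_support)
  # parsimony: with noise added, the linear model wins the AIC ranking
  yn <- y + rnorm(300, 0, 0.3)
  cm <- compare_models(x, yn)
  expect_equal(cm$model[1], "linear")
})

test_that("slopes, breakpoint and ranking are invariant to shifting y", {
  set.seed(63)
  d <- simulate_scaling_data(n = 800, seed = 63)
  f1 <- fit_segmented(d$x, d$y)
  f2 <- fit_segmented(d$x, d$y + 7)
  expect_equal(f2$intercept, f1$intercept + 7, tolerance = 1e-6)
  expect_equal(f2$slope1, f1$slope1, tolerance = 1e-8)
  expect_equal(f2$slope2, f1$slope2, tolerance = 1e-8)
  expect_equal(f2$breakpoint, f1$breakpoint, tolerance = 1e-6)
  m1 <- compare_models(d$x, d$y)
  m2 <- compare_models(d$x, d$y + 7)
  expect_equal(m1$model, m2$model)
  expect_equal(diff(m1$aic), diff(m2$aic), tolerance = 1e-8)
})

test_that("the generator's parameters are recovered across replicates", {
  # per-replicate sampling noise at sigma = 0.4 puts individual
  # estimates within about +/- 3 SE; unbiasedness is the sharper claim
  est <- t(vapply(1:20, function(seed) {
    d <- simulate_scaling_data(n = 2000, seed = seed)
    fit <- fit_segmented(d$x, d$y)
    c(fit$slope1, fit$slope2, fit$breakpoint)
  }, numeric(3)))
  expect_true(all(abs(est[, 1] - (-0.88)) < 0.05))
  expect_gte(mean(abs(est[, 2] - (-0.125)) < 0.05), 0.8)
  expect_gte(mean(abs(est[, 3] - (-1.735)) < 0.1), 0.8)
  expect_lt(abs(mean(est[, 1]) - (-0.88)), 0.02)
  expect_lt(abs(mean(est[, 2]) - (-0.125)), 0.02)
  expect_lt(abs(mean(est[, 3]) - (-1.735)), 0.04)
})

test_that("AIC comparison identifies the generating model", {
  # sharp two-segment data: segmented wins decisively
  d <- simulate_scaling_data(n = 1500, slope1 = -1.2, slope2 = 0.1,
                             breakpoint = -1.5, sigma = 0.3, seed = 64)
  cm <- compare_models(d$x, d$y)
  expect_equal(cm$model[1], "segmented")
  expect_gt(cm$aic[cm$model == "linear"] -
              cm$aic[cm$model == "segmented"], 10)
  # quadratic-generated data: quadratic beats linear
  set.seed(65)
  x <- runif(1000, -3, 0)
  y <- 0.5 + 0.3 * x + 0.4 * x^2 + rnorm(1000, 0, 0.3)
  cm2 <- compare_models(x, y)
  expect_lt(cm2$aic[cm2$model == "quadratic"],
            cm2$aic[cm2$model == "linear"])
})

test_that("two-cluster K-means equals the exact 1-D optimum", {
  set.seed(66)
  for (i in 1:10) {
    lengths <- c(10^rnorm(60, 3.8, 0.25), 10^rnorm(60, 5.2, 0.35))
    rec <- tibble::tibble(length = lengths,
                          pcn = 10^rnorm(120, 0.5, 0.5))
    cs <- kmeans_two(rec, seed = i)
    exact <- kmeans1d_exact(log10(rec$length))
    expect_equal(attr(cs, "assignment"), exact$assignment)
    # well-separated modes: the boundary falls between them
    small_max <- cs$length_max[cs$cluster == "small"]
    large_min <- cs$length_min[cs$cluster == "large"]
    expect_lt(small_max, large_min)
  }
  # rerun with the same seed is identical
  rec <- tibble::tibble(length = c(10^rnorm(40, 4, 0.3),
                                   10^rnorm(40, 5.3, 0.3)),
                        pcn = runif(80, 1, 10))
  expect_identical(kmeans_two(rec, seed = 3), kmeans_two(rec, seed = 3))
  # a singleton cluster is permitted
  rec1 <- tibble::tibble(length = c(rep(5000, 9), 500000),
                         pcn = runif(10, 1, 5))
  cs1 <- kmeans_two(rec1, seed = 1)
  expect_equal(cs1$n[cs1$cluster == "large"], 1L)
})

test_that("the intragenomic census counts correlation signs per genome", {
  rec <- tibble::tibble(
    genome_id = c("g1", "g1", "g2", "g2", "g2", "g3", "g3"),
    length = c(5000, 100000, 2000, 9000, 30000, 7000, 7000),
    pcn = c(20, 1.5, 50, 10, 2, 3, 8)
  )
  cen <- intragenomic_correlations(rec)
  at2 <- cen[cen$threshold == 2, ]
  # g1: two points, perfectly inverse; g2: inverse; g3: undefined
  expect_equal(at2$n_genomes, 3L)
  expect_equal(at2$n_negative, 2L)
  expect_equal(at2$n_positive, 0L)
  expect_equal(at2$n_undefined, 1L)
  expect_equal(at2$mean_r_negative, mean(c(-1, cor(c(2000, 9000, 30000),
                                                   c(50, 10, 2)))))
  at3 <- cen[cen$threshold == 3, ]
  expect_equal(at3$n_genomes, 1L)
  expect_equal(at3$n_negative, 1L)
})

test_that("a simulated population recovers its inverse-correlation fraction", {
  set.seed(67)
  n_gen <- 400
  recs <- lapply(seq_len(n_gen), function(g) {
    k <- sample(2:4, 1)
    len <- 10^runif(k, 3.2, 5.5)
    pcn <- if (g <= 0.8 * n_gen) 10^(-0.9 * log10(len) + 5 + rnorm(k, 0, 0.2))
           else 10^(0.9 * log10(len) - 4 + rnorm(k, 0, 0.2))
    tibble::tibble(genome_id = paste0("g", g), length = len, pcn = pcn)
  })
  cen <- intragenomic_correlations(dplyr::bind_rows(recs))
  frac <- cen$n_negative[1] / cen$n_genomes[1]
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n_gen))
  expect_lt(cen$mean_r_negative[1], 0)
  expect_gt(cen$mean_r_positive[1], 0)
})

test_that("DNA content slopes follow the 1 + copy-number-slope identity", {
  # exact inverse scaling: content is flat
  set.seed(68)
  chrlen <- 4e6
  x <- runif(600, -3, -0.5)
  rec0 <- tibble::tibble(length = chrlen * 10^x,
                         chromosome_length = chrlen,
                         pcn = 10^(-x - 1))  # pcn = 0.1 / normalized length
  f0 <- dna_content_scaling(rec0)
  expect_equal(f0$slope1, 0, tolerance = 1e-6)
  expect_equal(f0$slope2, 0, tolerance = 1e-6)
  # simulated from the empirical law: content slopes = 1 + pcn slopes
  d <- simulate_scaling_data(n = 2000, sigma = 0.2, seed = 68)
  rec <- tibble::tibble(length = chrlen * 10^d$x,
                        chromosome_length = chrlen,
                        pcn = 10^d$y)
  f <- dna_content_scaling(rec)
  expect_lt(abs(f$slope1 - (1 - 0.88)), 0.05)
  expect_lt(abs(f$slope2 - (1 - 0.125)), 0.05)
})

test_that("degenerate predictors are fatal", {
  expect_error(fit_segmented(rep(1, 20), rnorm(20)), "degenerate")
  expect_error(fit_segmented(rep(c(1, 2), 10), rnorm(20)),
               "too few distinct")
})
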