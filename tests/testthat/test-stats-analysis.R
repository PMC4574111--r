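make_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    participant = seq_len(n),
    metronome_variability = exp(rnorm(n, log(0.045), 0.3)),
    adaptation_error_ms = exp(rnorm(n, log(20), 0.3)),
    drumalong_pct = 100 * plogis(rnorm(n, 1.5, 0.8)),
    memory_pct = 100 * plogis(rnorm(n, 1.0, 0.8)),
    awm = rnorm(n, 100, 15), digits_reversed = rnorm(n, 100, 15),
    mean_tempo_dev_ms = runif(n, 0, 2))
}

test_that("exclusion rules remove outliers and off-tempo drummers", {
  tab <- make_table(30)
  # everyone within range: no exclusions
  res <- apply_exclusions(tab)
  expect_equal(nrow(res$table), 30)
  expect_equal(nrow(res$exclusions), 0)
  # a 4-SD outlier on one rhythm measure is removed
  tab2 <- tab
  tab2$memory_pct[7] <- mean(tab$memory_pct) + 4 * sd(tab$memory_pct)
  res2 <- apply_exclusions(tab2)
  expect_false(7 %in% res2$table$participant)
  expect_equal(res2$exclusions$rule, "outlier_3sd")
  # the off-tempo drummer case: 38.7 ms against a 5-ms criterion
  tab3 <- tab[1:4, ]
  tab3$mean_tempo_dev_ms <- c(1, 2, 38.7, 3)
  res3 <- apply_exclusions(tab3)
  expect_equal(res3$exclusions$participant, 3)
  expect_equal(res3$exclusions$rule, "tempo_deviation")
  expect_equal(nrow(res3$table), 3)
  # the rule is applied once, not recursively
  tab4 <- tab
  tab4$memory_pct[1] <- 500  # huge outlier that inflates the SD
  n_excluded <- nrow(apply_exclusions(tab4)$exclusions)
  expect_equal(n_excluded, 1)
  expect_error(apply_exclusions(tab[1:3, ]), "at least 4")
})

test_that("jarque_bera matches its definition and an external oracle", {
  # null point: a sample with exact skewness 0 and kurtosis 3
  # (two-point symmetric mixture tuned to K = 3: not available in closed
  # form with small n, so check via a constructed vector through the formula)
  x <- c(-1.732051, 0, 1.732051, 0, 0, 0, -1.732051, 0, 1.732051, 0, 0, 0)
  jb <- jarque_bera(x)
  expect_equal(jb$skewness, 0, tolerance = 1e-6)
  expect_equal(jb$kurtosis, 3, tolerance = 1e-5)
  expect_equal(jb$statistic, 0, tolerance = 1e-9)
  expect_equal(jb$p_value, 1, tolerance = 1e-6)
  # frozen oracle value (statsmodels jarque_bera on the same vector)
  y <- c(2.1, 3.4, 1.9, 5.6, 2.2, 3.3, 4.8, 2.7, 3.1, 2.9, 6.4, 1.5)
  jb2 <- jarque_bera(y)
  expect_equal(jb2$statistic, 1.515653657546168, tolerance = 1e-10)
  expect_equal(jb2$p_value, 0.4686838513511201, tolerance = 1e-10)
  expect_error(jarque_bera(rep(1, 20)), "constant")
  expect_error(jarque_bera(c(1, 2, 3)), "at least 8")
})

test_that("jarque_bera holds its level and has power against skew", {
  # level: standard-normal samples rarely rejected
  rejections <- sapply(1:100, function(s) {
    set.seed(s); jarque_bera(rnorm(1000))$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.05 + 0.045)  # binomial slack on 100 draws
  # power: a log-normal sample of the study's size is detected
  power <- mean(sapply(1:50, function(s) {
    set.seed(s); jarque_bera(exp(rnorm(65, 0, 0.8)))$p_value < 0.05
  }))
  expect_gt(power, 0.9)
})

test_that("rau transform has the documented closed form", {
  expect_equal(rau_transform(0.5), 50)
  expect_equal(rau_transform(0), -23)
  expect_equal(rau_transform(1), 123)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(rau_transform(p)) > 0))
  expect_error(rau_transform(1.2), "\\[0, 1\\]")
  expect_error(rau_transform(-0.1), "\\[0, 1\\]")
})

test_that("transform pipeline normalizes the skewed measures once", {
  sc <- simulate_scores(65, seed = 1)
  tt <- transform_scores(sc)
  expect_true(isTRUE(attr(tt, "transformed")))
  expect_equal(unname(attr(tt, "transforms")[c("metronome_variability",
                                               "drumalong_pct")]),
               c("log", "rau"))
  expect_equal(tt$metronome_variability, log(sc$metronome_variability))
  expect_equal(tt$drumalong_pct, rau_transform(sc$drumalong_pct / 100))
  jb <- attr(tt, "jarque_bera")
  expect_equal(nrow(jb), 8)  # 4 measures x raw/transformed
  post <- jb[jb$stage == "transformed" &
             jb$measure %in% c("metronome_variability", "drumalong_pct"), ]
  expect_true(all(post$p_value > 0.05))
  # double transform refused; non-positive variability refused
  expect_error(transform_scores(tt), "already transformed")
  bad <- sc; bad$metronome_variability[1] <- 0
  expect_error(transform_scores(bad), "positive")
  # a monotone log leaves an all-equal column's correlations intact
  const <- make_table(20)
  r_raw <- cor(const$adaptation_error_ms, const$memory_pct)
  expect_equal(cor(transform_scores(const)$adaptation_error_ms,
                   transform_scores(const)$memory_pct), r_raw)
})

test_that("correlation matrix agrees with the Pearson formula and cor.test", {
  # hand-verifiable toy: r = 0.6 from the product-moment formula
  expect_equal(cor(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  tab <- make_table(35)
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  ct <- cor.test(tab$metronome_variability, tab$memory_pct)
  expect_equal(cm$r["metronome_variability", "memory_pct"],
               unname(ct$estimate))
  expect_equal(cm$p["metronome_variability", "memory_pct"], ct$p.value)
  # affine rescaling of a column changes nothing
  tab2 <- tab; tab2$memory_pct <- 3 - 0.2 * tab$memory_pct
  cm2 <- correlation_matrix(tab2)
  expect_equal(abs(cm2$r), abs(cm$r), tolerance = 1e-12)
  expect_equal(cm2$p, cm$p, tolerance = 1e-12)
  # degenerate inputs
  tab3 <- tab; tab3$memory_pct <- 50
  expect_error(correlation_matrix(tab3), "zero-variance")
  # perfect correlation endpoints
  x <- rnorm(10)
  d <- data.frame(metronome_variability = x, adaptation_error_ms = x,
                  drumalong_pct = -x, memory_pct = x + rnorm(10))
  cmx <- correlation_matrix(d)
  expect_equal(cmx$r[1, 2], 1)
  expect_equal(cmx$r[1, 3], -1)
})

test_that("GLS factor analysis recovers a known two-factor structure exactly", {
  # six measures, two factors: an identified configuration (df = 4)
  L_true <- cbind(c(0.85, 0.80, 0.75, 0.05, 0.00, 0.10),
                  c(0.05, -0.02, 0.10, 0.88, 0.82, 0.70))
  psi_true <- 1 - rowSums(L_true^2)
  S <- L_true %*% t(L_true) + diag(psi_true)
  rownames(S) <- colnames(S) <- letters[1:6]
  fit <- gls_factor_analysis(covmat = S, n_factors = 2)
  # uniquenesses and communalities recovered
  expect_equal(unname(fit$uniquenesses), psi_true, tolerance = 1e-4)
  # loadings equal the generator up to column order and sign
  ref <- stats::varimax(L_true, eps = 1e-10)$loadings[, , drop = FALSE]
  aligned <- align_loadings(fit$loadings, ref)
  expect_equal(unname(aligned), unname(ref), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_false(fit$heywood)
  expect_equal(fit$variance_explained, sum(L_true^2) / 6, tolerance = 1e-4)
  expect_error(gls_factor_analysis(covmat = S, n_factors = 6), "smaller")
})

test_that("varimax rotation preserves communalities to 1e-10", {
  sc <- simulate_scores(65, seed = 2)
  fit <- gls_factor_analysis(transform_scores(sc))
  # recompute the unrotated solution's communalities from uniquenesses:
  # rotation must not change row communalities
  expect_equal(fit$communalities, rowSums(fit$loadings^2), tolerance = 1e-12)
  # against an explicit unrotated fit: communality = 1 - psi at the optimum
  # only approximately (GLS does not force unit diagonals); check the
  # rotation-invariance directly instead on a random loading matrix
  set.seed(5)
  L <- matrix(rnorm(8, 0, 0.5), 4, 2)
  Lr <- stats::varimax(L)$loadings[, , drop = FALSE]
  expect_equal(rowSums(Lr^2), rowSums(L^2), tolerance = 1e-10)
})

test_that("ML factor analysis agrees with the GLS fit on sampled data", {
  # six measures from two orthogonal factors, sampled: maximum-likelihood
  # (factanal) is the independent route; the two discrepancies must agree
  # on the varimax pattern and approximately on the loadings
  set.seed(20)
  n <- 400
  L_true <- cbind(c(0.85, 0.80, 0.75, 0.05, 0.00, 0.10),
                  c(0.05, -0.02, 0.10, 0.88, 0.82, 0.70))
  z <- matrix(rnorm(n * 2), n, 2)
  e <- matrix(rnorm(n * 6), n, 6) %*% diag(sqrt(1 - rowSums(L_true^2)))
  x <- z %*% t(L_true) + e
  colnames(x) <- letters[1:6]
  gls <- gls_factor_analysis(as.data.frame(x), measures = letters[1:6])
  ml <- stats::factanal(x, factors = 2, rotation = "varimax")
  mlL <- ml$loadings[, , drop = FALSE]
  aligned <- align_loadings(gls$loadings, mlL)
  expect_equal(unname(aligned), unname(mlL), tolerance = 0.05,
               ignore_attr = TRUE)
  own_gls <- apply(abs(aligned), 1, which.max)
  own_ml <- apply(abs(mlL), 1, which.max)
  expect_equal(own_gls, own_ml, ignore_attr = TRUE)
})

test_that("hierarchical regression partitions variance correctly", {
  n <- 200
  set.seed(10)
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- residuals(lm(x2 ~ x1))  # exactly orthogonal
  x1 <- scale(x1)[, 1]; x2 <- scale(x2)[, 1]
  # y = x1 exactly: step 1 explains everything
  d1 <- data.frame(y = x1, x1 = x1, x2 = x2)
  h1 <- suppressWarnings(hierarchical_regression(d1, "y", "x1", "x2"))
  expect_equal(h1$r2_step1, 1)
  expect_equal(h1$delta_r2, 0, tolerance = 1e-12)
  # orthogonal useless step-2 predictor adds nothing
  set.seed(11)
  d2 <- data.frame(y = x1 + rnorm(n), x1 = x1, x2 = x2)
  d2$x2 <- residuals(lm(x2 ~ d2$y + x1))
  h2 <- hierarchical_regression(d2, "y", "x1", "x2")
  expect_equal(h2$delta_r2, 0, tolerance = 1e-10)
  # y = x1 + x2 with equal variances: R2 splits 0.5 / 0.5
  d3 <- data.frame(y = x1 + x2, x1 = x1, x2 = x2)
  h3 <- suppressWarnings(hierarchical_regression(d3, "y", "x1", "x2"))
  expect_equal(h3$r2_step1, 0.5, tolerance = 1e-10)
  expect_equal(h3$delta_r2, 0.5, tolerance = 1e-10)
  expect_gte(h3$delta_r2, 0)
  # F/p match anova's partial F test
  d4 <- data.frame(y = x1 + 0.4 * x2 + rnorm(n), x1 = x1, x2 = x2)
  h4 <- hierarchical_regression(d4, "y", "x1", "x2")
  an <- anova(lm(y ~ x1, d4), lm(y ~ x1 + x2, d4))
  expect_equal(h4$f, an$F[2])
  expect_equal(h4$p, an$`Pr(>F)`[2])
  # collinear step-2 predictors are a rank error
  d5 <- data.frame(y = x1, x1 = x1, x2 = x2, x3 = x2)
  expect_error(hierarchical_regression(d5, "y", "x1", c("x2", "x3")),
               "rank")
})

test_that("analyze_cohort assembles the full result object", {
  sc <- simulate_scores(65, seed = 1)
  res <- analyze_cohort(sc)
  expect_s3_class(res, "rhythm_analysis")
  expect_equal(dim(res$correlations$r), c(4, 4))
  expect_equal(dim(res$factors$loadings), c(4, 2))
  expect_true(res$factors$variance_explained > 0 &&
              res$factors$variance_explained <= 1)
  expect_true(all(res$factors$communalities <= 1 + 1e-8))
  expect_false(is.null(res$hierarchical))
  expect_gte(res$hierarchical$memory_on_verbal$delta_r2, 0)
  expect_output(print(res), "GLS factor loadings")
  # tiny cohorts run but are flagged as underpowered
  res4 <- analyze_cohort(simulate_scores(8, seed = 2))
  expect_true(res4$underpowered)
})
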