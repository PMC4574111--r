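# Cohort-level statistics: exclusions, normality checks and transforms,
# Pearson correlation matrix, GLS factor analysis with varimax rotation,
# and hierarchical regressions against verbal memory.

RHYTHM_MEASURES <- c("metronome_variability", "adaptation_error_ms",
                     "drumalong_pct", "memory_pct")

#' Apply the participant-exclusion rules
#'
#' Two rules, evaluated once on the input table (not re-iterated after
#' removal): (a) any participant more than `sd_limit` standard deviations
#' from the mean on any of the four rhythm measures; (b) any participant
#' whose produced metronome tempo deviated from the stimulus IOI by more
#' than `tempo_dev_limit_ms` on average (column `mean_tempo_dev_ms`, if
#' present) — a participant drumming at their own tempo is not measuring
#' synchronization.
#'
#' @param table Score table.
#' @param sd_limit Outlier cut in SD units (default 3).
#' @param tempo_dev_limit_ms Mean tempo-deviation cut in ms (default 5).
#' @return List with the filtered `table` and an `exclusions` data.frame of
#'   `(participant, rule, measure, value)`.
#' @export
apply_exclusions <- function(table, sd_limit = 3, tempo_dev_limit_ms = 5) {
  if (nrow(table) < 4) stop("need at least 4 participants")
  ids <- if ("participant" %in% names(table)) table$participant
         else seq_len(nrow(table))
  logs <- list()
  drop <- rep(FALSE, nrow(table))
  for (m in intersect(RHYTHM_MEASURES, names(table))) {
    x <- table[[m]]
    z <- abs(x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
    hit <- which(!is.na(z) & z > sd_limit)
    for (i in hit) {
      logs[[length(logs) + 1L]] <- data.frame(
        participant = ids[i], rule = "outlier_3sd", measure = m, value = x[i])
      drop[i] <- TRUE
    }
  }
  if ("mean_tempo_dev_ms" %in% names(table)) {
    hit <- which(!is.na(table$mean_tempo_dev_ms) &
                 table$mean_tempo_dev_ms > tempo_dev_limit_ms)
    for (i in hit) {
      logs[[length(logs) + 1L]] <- data.frame(
        participant = ids[i], rule = "tempo_deviation",
        measure = "mean_tempo_dev_ms", value = table$mean_tempo_dev_ms[i])
      drop[i] <- TRUE
    }
  }
  if (all(drop)) stop("exclusion rules removed every participant")
  list(table = table[!drop, , drop = FALSE],
       exclusions = if (length(logs)) do.call(rbind, logs)
                    else data.frame(participant = numeric(0), rule = character(0),
                                    measure = character(0), value = numeric(0)))
}

#' Jarque-Bera normality test
#'
#' `JB = (n/6) * (S^2 + (K - 3)^2 / 4)` with moment-based sample skewness
#' `S` and kurtosis `K`, referred to a chi-square distribution with 2
#' degrees of freedom.
#'
#' @param x Numeric vector (n >= 8; the moment estimates are meaningless
#'   below that).
#' @return List with `statistic`, `p_value`, `skewness`, `kurtosis`, `n`.
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("jarque_bera needs at least 8 observations")
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) stop("undefined moments: constant vector")
  S <- mean(d^3) / m2^1.5
  K <- mean(d^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K, n = n)
}

#' Rationalized arcsine transform (proportion form)
#'
#' `R = (146 / pi) * 2 * asin(sqrt(p)) - 23`: a variance-stabilizing
#' transform for proportion scores that is approximately linear in percent
#' mid-range (rau 50 at p = 0.5) and ranges from -23 at p = 0 to 123 at
#' p = 1.
#'
#' @param p Proportions in [0, 1].
#' @return rau units.
#' @export
rau_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("proportions must lie in [0, 1]")
  (146 / pi) * 2 * asin(sqrt(p)) - 23
}

#' Normality-driven transforms of the score table
#'
#' Log-transforms the metronome variability and rau-transforms the
#' drum-along proportion (the two measures whose raw distributions are
#' skewed), then re-runs the Jarque-Bera test on all four measures. A
#' transformed table is marked and refuses a second pass.
#'
#' @param table Score table.
#' @return Table with transformed columns and attributes `transforms` (map
#'   measure -> transform) and `jarque_bera` (data.frame of pre/post
#'   statistics).
#' @export
transform_scores <- function(table) {
  if (isTRUE(attr(table, "transformed")))
    stop("table is already transformed")
  if (any(table$metronome_variability <= 0, na.rm = TRUE))
    stop("metronome variability must be positive for the log transform")
  jb_row <- function(m, stage, x) {
    jb <- if (sum(!is.na(x)) >= 8) jarque_bera(x)
          else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(measure = m, stage = stage,
               statistic = jb$statistic, p_value = jb$p_value)
  }
  pre <- do.call(rbind, lapply(RHYTHM_MEASURES, function(m)
    jb_row(m, "raw", table[[m]])))
  table$metronome_variability <- log(table$metronome_variability)
  table$drumalong_pct <- rau_transform(table$drumalong_pct / 100)
  post <- do.call(rbind, lapply(RHYTHM_MEASURES, function(m)
    jb_row(m, "transformed", table[[m]])))
  attr(table, "transformed") <- TRUE
  attr(table, "transforms") <- c(metronome_variability = "log",
                                 adaptation_error_ms = "none",
                                 drumalong_pct = "rau", memory_pct = "none")
  attr(table, "jarque_bera") <- rbind(pre, post)
  table
}

#' Pearson correlation matrix of the four rhythm measures
#'
#' Pairwise Pearson r with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on complete cases.
#'
#' @param table Score table (raw or transformed).
#' @param measures Columns to correlate.
#' @return List with matrices `r` and `p` and the common `n`.
#' @export
correlation_matrix <- function(table, measures = RHYTHM_MEASURES) {
  x <- table[, measures, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 4) stop("need at least 4 complete cases")
  if (any(vapply(x, stats::sd, numeric(1)) == 0))
    stop("zero-variance column")
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  list(r = r, p = p, n = n)
}

# GLS discrepancy F(Psi) = (1/2) tr[(I - S^-1 Sigma)^2]: for fixed
# uniquenesses the conditional minimum over the loadings is attained at the
# top-m eigenpairs of S^(-1/2) (S - Psi) S^(-1/2), leaving half the sum of
# the squared residual eigenvalues.
.gls_objective <- function(psi, Si2, S, m) {
  M <- Si2 %*% (S - diag(psi)) %*% Si2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  resid <- ev[-seq_len(m)]
  neg <- pmin(ev[seq_len(m)], 0)    # clamped factors contribute residual too
  (sum(resid^2) + sum(neg^2)) / 2
}

#' Generalized least squares factor analysis with varimax rotation
#'
#' Fits the common factor model `Sigma = Lambda Lambda' + Psi` to the
#' correlation matrix by minimizing the GLS discrepancy
#' `F = (1/2) tr[(I - S^-1 Sigma)^2]` over the uniquenesses (L-BFGS-B,
#' started from 1 minus the squared multiple correlations), recovering the
#' loadings from the top eigenpairs of `S^(-1/2) (S - Psi) S^(-1/2)`. The
#' loadings are then varimax-rotated, columns ordered by explained variance
#' and signed so each factor's largest loading is positive. Uniquenesses
#' are floored at 0.005; a solution on the floor is flagged as a Heywood
#' case.
#'
#' @param table Score table, or `NULL` if `covmat` is given.
#' @param n_factors Number of factors (default 2).
#' @param measures Columns to analyze.
#' @param covmat Optional correlation/covariance matrix analyzed directly.
#' @param n_obs Number of observations behind `covmat`.
#' @return List with `loadings` (rotated), `uniquenesses`, `communalities`,
#'   `variance_explained` (total proportion), `per_factor_variance`,
#'   `heywood`, `objective`, `scree` (eigenvalues of the correlation
#'   matrix, as a retention diagnostic).
#' @export
gls_factor_analysis <- function(table = NULL, n_factors = 2,
                                measures = RHYTHM_MEASURES, covmat = NULL,
                                n_obs = NULL) {
  if (is.null(covmat)) {
    x <- table[, measures, drop = FALSE]
    x <- x[stats::complete.cases(x), , drop = FALSE]
    n_obs <- nrow(x)
    S <- stats::cor(x)
  } else {
    S <- stats::cov2cor(as.matrix(covmat))
  }
  p <- ncol(S)
  if (n_factors >= p) stop("n_factors must be smaller than the number of measures")
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 1e-10) stop("correlation matrix is not positive definite")
  Si2 <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  smc <- 1 - 1 / diag(solve(S))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  fit <- stats::optim(start, .gls_objective, Si2 = Si2, S = S, m = n_factors,
                      method = "L-BFGS-B", lower = 0.005, upper = 0.999,
                      control = list(factr = 10, pgtol = 1e-12, maxit = 1000))
  psi <- fit$par
  heywood <- any(psi <= 0.005 + 1e-8)
  M <- Si2 %*% (S - diag(psi)) %*% Si2
  em <- eigen(M, symmetric = TRUE)
  S12 <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  L <- S12 %*% em$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(pmax(em$values[seq_len(n_factors)], 0)), n_factors)
  rot <- stats::varimax(L, eps = 1e-10)
  Lr <- rot$loadings[, , drop = FALSE]
  class(Lr) <- "matrix"
  ssl <- colSums(Lr^2)
  Lr <- Lr[, order(ssl, decreasing = TRUE), drop = FALSE]
  for (j in seq_len(ncol(Lr)))
    if (Lr[which.max(abs(Lr[, j])), j] < 0) Lr[, j] <- -Lr[, j]
  rownames(Lr) <- rownames(S) <- colnames(S)
  colnames(Lr) <- paste0("Factor", seq_len(n_factors))
  names(psi) <- rownames(Lr)
  list(loadings = Lr, uniquenesses = psi, communalities = rowSums(Lr^2),
       variance_explained = sum(Lr^2) / p,
       per_factor_variance = colSums(Lr^2) / p,
       heywood = heywood, objective = fit$value, n_obs = n_obs,
       scree = ev$values)
}

#' Hierarchical regression
#'
#' Fits the step-1 OLS model `y ~ step1`, then the full model with the
#' step-2 block added, and tests the R-squared increment with the partial
#' F-test.
#'
#' @param table Data frame holding all variables.
#' @param response Response column name.
#' @param step1,step2 Character vectors of predictor column names.
#' @return List with `r2_step1`, `r2_full`, `delta_r2`, `f`, `df1`, `df2`,
#'   `p`, and the two fitted models.
#' @export
hierarchical_regression <- function(table, response, step1, step2) {
  dat <- table[, c(response, step1, step2)]
  dat <- dat[stats::complete.cases(dat), ]
  n <- nrow(dat)
  k_full <- length(step1) + length(step2)
  if (n <= k_full + 2) stop("too few observations for the full model")
  f1 <- stats::as.formula(paste(response, "~", paste(step1, collapse = "+")))
  f2 <- stats::as.formula(paste(response, "~",
                                paste(c(step1, step2), collapse = "+")))
  m1 <- stats::lm(f1, data = dat)
  m2 <- stats::lm(f2, data = dat)
  if (any(is.na(stats::coef(m2)))) stop("rank-deficient predictor set")
  r2_1 <- summary(m1)$r.squared
  r2_f <- summary(m2)$r.squared
  q <- length(step2)
  df2 <- n - k_full - 1
  f <- ((r2_f - r2_1) / q) / ((1 - r2_f) / df2)
  list(r2_step1 = r2_1, r2_full = r2_f, delta_r2 = r2_f - r2_1,
       f = f, df1 = q, df2 = df2,
       p = stats::pf(f, q, df2, lower.tail = FALSE),
       model_step1 = m1, model_full = m2)
}

#' Full dissociation analysis of a score table
#'
#' Runs the complete pipeline: exclusions, normality-driven transforms,
#' Pearson correlation matrix of the four rhythm measures, two-factor GLS
#' factor analysis with varimax rotation, and (when verbal scores are
#' present) the two hierarchical regressions relating rhythm memory to
#' verbal memory.
#'
#' @param scores Score table (one row per participant).
#' @param transform Apply the log/rau transforms before correlating and
#'   factoring (default TRUE, the headline pipeline).
#' @param n_factors Factors to extract (default 2).
#' @return A `rhythm_analysis` object: `exclusions`, `jarque_bera`,
#'   `transforms`, `correlations`, `factors`, `hierarchical`, `n`.
#' @export
analyze_cohort <- function(scores, transform = TRUE, n_factors = 2) {
  excl <- apply_exclusions(scores)
  tab <- excl$table
  underpowered <- nrow(tab) < 10
  if (transform) tab <- transform_scores(tab)
  cors <- correlation_matrix(tab)
  fa <- gls_factor_analysis(tab, n_factors = n_factors)
  hier <- NULL
  if (all(c("awm", "digits_reversed") %in% names(tab)) &&
      !all(is.na(tab$awm))) {
    hier <- list(
      memory_on_verbal = hierarchical_regression(
        tab, "memory_pct", c("awm", "digits_reversed"), "drumalong_pct"),
      digits_on_rhythm = hierarchical_regression(
        tab, "digits_reversed", c("drumalong_pct", "memory_pct"), "awm"))
  }
  structure(list(exclusions = excl$exclusions,
                 jarque_bera = attr(tab, "jarque_bera"),
                 transforms = attr(tab, "transforms"),
                 correlations = cors, factors = fa, hierarchical = hier,
                 n = cors$n, underpowered = underpowered,
                 table = tab),
            class = "rhythm_analysis")
}

#' @export
print.rhythm_analysis <- function(x, ...) {
  cat("Rhythm-skill dissociation analysis (n =", x$n, ")\n")
  if (x$underpowered)
    cat("WARNING: fewer than 10 participants; estimates are underpowered\n")
  if (nrow(x$exclusions))
    cat("Excluded", length(unique(x$exclusions$participant)),
        "participant(s):", paste(unique(x$exclusions$rule), collapse = ", "), "\n")
  cat("\nPearson correlations (r, lower triangle | p, upper triangle):\n")
  m <- x$correlations$r
  m[upper.tri(m)] <- x$correlations$p[upper.tri(m)]
  print(round(m, 3))
  cat("\nGLS factor loadings (varimax; |loading| > 0.3 marked *):\n")
  L <- x$factors$loadings
  disp <- matrix(sprintf("%6.3f%s", L, ifelse(abs(L) > 0.3, "*", " ")),
                 nrow = nrow(L), dimnames = dimnames(L))
  print(disp, quote = FALSE)
  cat(sprintf("Variance explained: %.1f%%\n", 100 * x$factors$variance_explained))
  if (!is.null(x$hierarchical)) {
    h1 <- x$hierarchical$memory_on_verbal
    h2 <- x$hierarchical$digits_on_rhythm
    cat(sprintf(
      "\nHierarchical regressions:\n  memory_pct ~ verbal: R2 = %.2f; + drumalong: dR2 = %.2f (p = %.2g)\n",
      h1$r2_step1, h1$delta_r2, h1$p))
    cat(sprintf(
      "  digits_reversed ~ rhythm memory: R2 = %.2f; + awm: dR2 = %.2f (p = %.2g)\n",
      h2$r2_step1, h2$delta_r2, h2$p))
  }
  invisible(x)
}

#' Scatter matrix of the four rhythm measures
#'
#' @param scores Score table (transformed or raw).
#' @param ... Passed to [graphics::pairs()].
#' @export
plot_score_pairs <- function(scores, ...) {
  graphics::pairs(scores[, RHYTHM_MEASURES],
                  labels = c("Metronome\nvariability", "Tempo adaptation\n(ms)",
                             "Drum-along", "Sequence memory"), ...)
}
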