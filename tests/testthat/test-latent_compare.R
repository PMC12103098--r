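# Joint-PCA latent-space comparison.

test_that("min-max normalization forces every column onto [0, 1] exactly", {
  pair <- preprocess_pair(fx_kap, degrade(fx_kap, degradation_spec(snr_db = 40,
                                                                   seed = 1)))
  nm <- normalize_combined(pair)
  expect_equal(unname(apply(nm, 2, min)), rep(0, 60))
  expect_equal(unname(apply(nm, 2, max)), rep(1, 60))
  # direct arithmetic example: a stacked column 2,4,6,8
  toy <- cbind(a = c(2, 4), b = c(1, 9))
  toy2 <- rbind(toy, cbind(a = c(6, 8), b = c(5, 3)))
  out <- normalize_combined(toy2)
  expect_equal(unname(out[, "a"]), c(0, 1/3, 2/3, 1))
  # oracle equivalence on a random matrix
  set.seed(5)
  x <- matrix(rnorm(120), 20, 6)
  expect_equal(unname(normalize_combined(x)), unname(oracle_minmax(x)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant column -> error naming the signal
  bad <- pair
  bad$ref[, "wrist_y"] <- 1; bad$cam[, "wrist_y"] <- 1
  expect_error(normalize_combined(bad), "wrist_y")
})

test_that("joint PCA projects identical halves identically with corr2d = 1", {
  pair <- preprocess_pair(fx_kap, fx_kap)
  lc <- latent_compare(pair)
  expect_equal(lc$ref_scores, lc$cam_scores, tolerance = 1e-12)
  expect_equal(lc$corr2d, 1, tolerance = 1e-12)
  expect_equal(unname(lc$offsets), c(0, 0), tolerance = 1e-12)
})

test_that("exact rank-2 data yields cumulative VAF of 1", {
  t <- seq(0, 4, length.out = 150)
  latent <- cbind(sin(2 * pi * t), cos(2 * pi * 1.7 * t))
  set.seed(3)
  mixing <- matrix(runif(120, -1, 1), 2, 60)
  x <- latent %*% mixing
  colnames(x) <- signal_names()
  x <- sweep(x, 2, seq(0.1, 6, length.out = 60), "+")  # arbitrary offsets
  lc <- joint_pca(rbind(x, x))
  expect_equal(lc$vaf_cum, 1, tolerance = 1e-9)
})

test_that("joint PCA matches a covariance-eigendecomposition oracle on small instances", {
  set.seed(9)
  for (rep in 1:5) {
    x <- matrix(rnorm(20 * 6), 20, 6)
    lc <- joint_pca(x, k = 2)
    ora <- oracle_pca(x, k = 2)
    for (j in 1:2) {
      # equality up to component sign
      same <- max(abs(lc$loadings[, j] - ora$loadings[, j]))
      flip <- max(abs(lc$loadings[, j] + ora$loadings[, j]))
      expect_lt(min(same, flip), 1e-9)
      s <- if (same < flip) 1 else -1
      expect_lt(max(abs(lc$ref_scores[, j] - s * ora$scores[1:10, j])), 1e-9)
    }
    expect_equal(unname(lc$vaf), ora$vaf[1:2], tolerance = 1e-9)
    # loadings orthonormal, full VAF spectrum sums to one and is sorted
    expect_equal(crossprod(lc$loadings), diag(2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sum(lc$vaf_all), 1, tolerance = 1e-12)
    expect_true(all(diff(lc$vaf_all) <= 1e-12))
  }
  expect_error(joint_pca(matrix(1, 10, 4)), "constant|rank")
})

test_that("latent mean alignment recovers shifts and leaves means matched", {
  pair <- preprocess_pair(fx_abd, degrade(fx_abd, degradation_spec(snr_db = 35,
                                                                   seed = 6)))
  lc <- offset_align_latent(joint_pca(normalize_combined(pair)))
  shifted <- lc
  shifted$cam_scores <- sweep(shifted$cam_scores, 2, c(5, -2), "+")
  back <- offset_align_latent(shifted)
  expect_equal(unname(back$offsets - lc$offsets), c(-5, 2), tolerance = 1e-9)
  expect_lt(max(abs(colMeans(back$cam_scores) - colMeans(back$ref_scores))),
            1e-12)
  # already mean-matched -> zero incremental offsets
  again <- offset_align_latent(back)
  expect_equal(again$offsets, back$offsets, tolerance = 1e-12)
})

test_that("corr2d is translation-invariant, matches its oracle, and is shape-sensitive", {
  pair <- preprocess_pair(fx_abd, degrade(fx_abd, degradation_spec(snr_db = 35,
                                                                   seed = 6)))
  lc <- joint_pca(normalize_combined(pair))
  before <- corr2d(lc)
  after <- corr2d(offset_align_latent(lc))
  expect_equal(before, after, tolerance = 1e-12)
  want <- mean(c(oracle_pearson(lc$ref_scores[, 1], lc$cam_scores[, 1]),
                 oracle_pearson(lc$ref_scores[, 2], lc$cam_scores[, 2])))
  expect_equal(before, want, tolerance = 1e-12)
  # a 90-degree latent rotation of orthogonal curves destroys the correlation
  t <- seq(0, 2 * pi, length.out = 200)
  rot <- lc
  rot$ref_scores <- cbind(cos(t), sin(2 * t))
  rot$cam_scores <- cbind(-sin(2 * t), cos(t))
  expect_lt(abs(corr2d(rot)), 0.2)
  # toy 5-sample projections against the oracle
  set.seed(12)
  toy <- lc
  toy$ref_scores <- matrix(rnorm(10), 5)
  toy$cam_scores <- matrix(rnorm(10), 5)
  expect_equal(corr2d(toy),
               mean(c(oracle_pearson(toy$ref_scores[, 1], toy$cam_scores[, 1]),
                      oracle_pearson(toy$ref_scores[, 2], toy$cam_scores[, 2]))),
               tolerance = 1e-12)
})

test_that("latent translation and simultaneous component sign flips leave corr2d unchanged", {
  pair <- preprocess_pair(fx_kap, degrade(fx_kap, degradation_spec(snr_db = 40,
                                                                   seed = 14)))
  lc <- latent_compare(pair)
  flip <- lc
  flip$ref_scores[, 1] <- -flip$ref_scores[, 1]
  flip$cam_scores[, 1] <- -flip$cam_scores[, 1]
  expect_equal(corr2d(flip), lc$corr2d, tolerance = 1e-12)
})

test_that("an amplitude offset translates the latent encoding almost rigidly", {
  lc <- perturbation_experiment(fx_kap, "offset", list(offset_mm = 10))
  spread <- mean(apply(lc$ref_scores, 2, sd))
  resid <- mean(sqrt(rowSums((lc$cam_scores - lc$ref_scores)^2)))
  expect_lt(resid, 0.05 * spread)
})

test_that("noise level orders corr2d and novel-task data scores lowest", {
  lc50 <- perturbation_experiment(fx_kap, "noise", list(snr_db = 50), seed = 3)
  lc30 <- perturbation_experiment(fx_kap, "noise", list(snr_db = 30), seed = 3)
  novel <- generate_trajectory(fx_spec, fx_abd_script)
  lcnov <- perturbation_experiment(fx_kap, "novel", list(novel = novel))
  expect_gte(lc50$corr2d, lc30$corr2d)
  expect_lt(lcnov$corr2d, lc50$corr2d)
  expect_error(perturbation_experiment(fx_kap, "novel"), "novel")
})

test_that("batch relationship matches the closed-form OLS oracle and filters by VAF", {
  mk_rep <- function(cs) structure(list(corr_signal = cs), class = "accuracy_report")
  mk_lc <- function(c2, vaf) structure(list(corr2d = c2, vaf_cum = vaf),
                                       class = "latent_comparison")
  cs <- c(0.70, 0.80, 0.88, 0.95)
  c2 <- c(0.60, 0.85, 0.90, 0.97)
  reports <- lapply(cs, mk_rep)
  lcs <- Map(mk_lc, c2, c(0.95, 0.92, 0.91, 0.96))
  fit <- batch_relationship(reports, lcs, 0.90)
  want <- oracle_ols(cs, c2)
  expect_equal(fit$slope, want$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, want$intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, want$r_squared, tolerance = 1e-12)
  # VAF filter drops low-VAF trials
  lcs2 <- Map(mk_lc, c2, c(0.95, 0.50, 0.91, 0.96))
  fit2 <- batch_relationship(reports, lcs2, 0.90)
  expect_equal(fit2$n_used, 3)
  expect_equal(fit2$slope, oracle_ols(cs[-2], c2[-2])$slope, tolerance = 1e-12)
  # identical trials form a degenerate cluster: rejected with a diagnostic
  same <- lapply(rep(0.9, 4), mk_rep)
  expect_error(batch_relationship(same, Map(mk_lc, rep(1, 4), rep(0.95, 4))),
               "degenerate")
  expect_error(batch_relationship(reports[1:2], lcs[1:2]), "one-to-one|fewer")
})

test_that("latent and high-dimensional agreement move together across degradations", {
  lags <- c(0, 0.15, 0.3, 0.45)
  cs <- c2 <- numeric(0)
  for (i in seq_along(lags)) {
    cam <- degrade(fx_abd, degradation_spec(snr_db = 45, lag_s = lags[i],
                                            seed = i))
    pair <- preprocess_pair(fx_abd, cam)
    cs <- c(cs, signal_correlations(pair)$corr_signal)
    c2 <- c(c2, latent_compare(pair)$corr2d)
  }
  expect_gt(cor(cs, c2, method = "spearman"), 0)
})

test_that("scatter export labels both systems over the same sample grid", {
  lc <- latent_compare(preprocess_pair(fx_abd, fx_abd))
  tab <- as_scatter_table(lc)
  expect_equal(sort(unique(tab$system)), c("camera", "reference"))
  expect_equal(nrow(tab), 2 * nrow(lc$ref_scores))
  expect_true(all(c("PC1", "PC2") %in% names(tab)))
})
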