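# Joint-PCA latent-space comparison: the two systems' matrices are stacked
# into one 2m x n matrix, min-max normalized per signal, passed through a
# single PCA so both systems share loadings, projected to 2D, aligned by
# latent means, and compared by the mean per-dimension Pearson correlation
# (corr2d). Variance accounted for (VAF) by the two retained components
# gates trial quality.

#' Min-max normalization of the stacked two-system matrix
#'
#' Row-stacks the reference and camera matrices (reference first) and rescales
#' each signal to `[0, 1]` over the combined 2m rows:
#' `(x - min(x)) / (max(x) - min(x))`. Normalizing jointly keeps the two
#' systems on a common scale per signal.
#'
#' @param pair A `trial_pair` (or a plain 2m x n matrix already stacked).
#' @return 2m x n matrix, every column spanning exactly `[0, 1]`, with
#'   attribute `m` (samples per system).
#' @export
normalize_combined <- function(pair) {
  x <- if (inherits(pair, "trial_pair")) rbind(pair$ref, pair$cam)
       else as.matrix(pair)
  rng_lo <- apply(x, 2, min)
  rng_hi <- apply(x, 2, max)
  flat <- rng_hi - rng_lo <= 0
  if (any(flat))
    stop("constant signal(s) cannot be min-max normalized: ",
         paste(colnames(x)[flat], collapse = ", "), call. = FALSE)
  out <- sweep(sweep(x, 2, rng_lo), 2, rng_hi - rng_lo, "/")
  attr(out, "m") <- nrow(x) %/% 2L
  out
}

# deterministic component sign convention: largest-|loading| entry positive
fix_component_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Joint PCA of a normalized trial pair
#'
#' Fits PCA on the mean-centered normalized 2m x n matrix and keeps the `k`
#' components explaining the most variance. Both systems are projected with
#' the same loadings; VAF per component is its variance over the total.
#' Component signs follow a fixed convention (largest-magnitude loading
#' positive) so projections are reproducible.
#'
#' @param normalized Output of [normalize_combined()] (attribute `m` set), or
#'   a `trial_pair` (normalized internally).
#' @param k Number of retained components (default 2).
#' @return Object of class `latent_comparison`: `loadings` (n x k,
#'   orthonormal columns), `vaf` (per retained component), `vaf_cum`
#'   (cumulative VAF of the `k` components), `vaf_all`, `ref_scores` and
#'   `cam_scores` (m x k), `offsets` (latent alignment offsets, zero until
#'   [offset_align_latent()]), `corr2d` (`NA` until computed).
#' @export
joint_pca <- function(normalized, k = 2) {
  if (inherits(normalized, "trial_pair")) normalized <- normalize_combined(normalized)
  m <- attr(normalized, "m")
  if (is.null(m)) {
    if (nrow(normalized) %% 2L != 0L)
      stop("stacked matrix must have an even number of rows", call. = FALSE)
    m <- nrow(normalized) %/% 2L
  }
  if (2 * m <= k || ncol(normalized) < k)
    stop("need more than k samples and at least k signals", call. = FALSE)
  fit <- stats::prcomp(normalized, center = TRUE, scale. = FALSE)
  if (length(fit$sdev) < k || fit$sdev[k] <= 0)
    stop("combined matrix has rank below k = ", k, call. = FALSE)
  vaf_all <- fit$sdev^2 / sum(fit$sdev^2)
  sf <- fix_component_signs(fit$rotation[, seq_len(k), drop = FALSE],
                            fit$x[, seq_len(k), drop = FALSE])
  structure(
    list(loadings = sf$loadings,
         vaf = vaf_all[seq_len(k)],
         vaf_cum = sum(vaf_all[seq_len(k)]),
         vaf_all = vaf_all,
         ref_scores = sf$scores[seq_len(m), , drop = FALSE],
         cam_scores = sf$scores[m + seq_len(m), , drop = FALSE],
         offsets = rep(0, k),
         corr2d = NA_real_),
    class = "latent_comparison")
}

#' Align latent projections by their means
#'
#' Shifts the camera projection so its per-dimension means equal the
#' reference's: the offset on each latent dimension is the reference mean
#' minus the camera mean. Used to compare projection shapes net of constant
#' latent displacement.
#'
#' @param lc A `latent_comparison`.
#' @return The `latent_comparison` with `cam_scores` shifted and `offsets`
#'   accumulated.
#' @export
offset_align_latent <- function(lc) {
  stopifnot(inherits(lc, "latent_comparison"))
  off <- colMeans(lc$ref_scores) - colMeans(lc$cam_scores)
  lc$cam_scores <- sweep(lc$cam_scores, 2, off, "+")
  lc$offsets <- lc$offsets + off
  lc
}

#' Latent-space correlation (corr2d)
#'
#' Pearson correlation between the camera and reference projections, computed
#' per latent dimension over matched samples and averaged (unweighted by
#' default; optionally VAF-weighted). Translation-invariant, so
#' [offset_align_latent()] does not change it. A constant latent dimension is
#' excluded and counted.
#'
#' @param lc A `latent_comparison`.
#' @param vaf_weighted Weight the per-dimension correlations by component VAF.
#' @return The mean latent correlation (scalar).
#' @export
corr2d <- function(lc, vaf_weighted = FALSE) {
  stopifnot(inherits(lc, "latent_comparison"))
  r <- paired_pearson(lc$ref_scores, lc$cam_scores)
  ok <- !is.na(r)
  if (!any(ok)) stop("all latent dimensions are constant", call. = FALSE)
  if (vaf_weighted) sum(r[ok] * lc$vaf[ok]) / sum(lc$vaf[ok]) else mean(r[ok])
}

#' Full latent comparison of a trial pair
#'
#' Convenience wrapper: [normalize_combined()] then [joint_pca()],
#' [offset_align_latent()], and [corr2d()].
#'
#' @param pair A `trial_pair`.
#' @param k Retained components.
#' @param vaf_weighted Passed to [corr2d()].
#' @return A `latent_comparison` with `corr2d` filled in.
#' @export
latent_compare <- function(pair, k = 2, vaf_weighted = FALSE) {
  lc <- joint_pca(normalize_combined(pair), k = k)
  lc <- offset_align_latent(lc)
  lc$corr2d <- corr2d(lc, vaf_weighted = vaf_weighted)
  lc
}

#' @export
print.latent_comparison <- function(x, ...) {
  cat(sprintf("<latent_comparison> %d samples/system, k = %d\n",
              nrow(x$ref_scores), ncol(x$ref_scores)))
  cat(sprintf("  VAF: %s (cumulative %.3f)\n",
              paste(sprintf("%.3f", x$vaf), collapse = " + "), x$vaf_cum))
  cat(sprintf("  latent offsets: %s; corr2d = %s\n",
              paste(sprintf("%.4f", x$offsets), collapse = ", "),
              ifelse(is.na(x$corr2d), "not computed", sprintf("%.4f", x$corr2d))))
  invisible(x)
}

#' Latent scatter table for plotting
#'
#' Long-format table of both systems' 2D projections (reference conventionally
#' plotted blue, camera red).
#'
#' @param lc A `latent_comparison`.
#' @return data.frame with columns `system`, `sample`, `PC1`, `PC2`, ...
#' @export
as_scatter_table <- function(lc) {
  stopifnot(inherits(lc, "latent_comparison"))
  k <- ncol(lc$ref_scores)
  mk <- function(scores, sys)
    data.frame(system = sys, sample = seq_len(nrow(scores)),
               stats::setNames(as.data.frame(scores), paste0("PC", seq_len(k))))
  rbind(mk(lc$ref_scores, "reference"), mk(lc$cam_scores, "camera"))
}

#' Perturbation experiments in latent space
#'
#' Reproduces the latent-space perturbation exploration on a single clean
#' trajectory: the trajectory is paired with a perturbed (or novel) copy and
#' run through the full preprocessing + latent pipeline.
#'
#' * `kind = "noise"`: Gaussian noise at `params$snr_db` (e.g. 50 = small,
#'   30 = large) — mildly distorted vs. heavily distorted encodings;
#' * `kind = "offset"`: amplitude offset of `params$offset_mm` (e.g. 10 mm) on
#'   all signals — a pure translation of the latent encoding;
#' * `kind = "novel"`: `params$novel` supplies a trajectory of a different
#'   task/origin — dissimilar encodings, low latent correlation. The novel
#'   trajectory is used unaligned (it is genuinely different data, not a
#'   miscalibrated copy).
#'
#' @param traj Clean reference trajectory.
#' @param kind `"noise"`, `"offset"` or `"novel"`.
#' @param params List of parameters (see above).
#' @param seed Seed for stochastic perturbations.
#' @return A `latent_comparison` with `corr2d` computed.
#' @export
perturbation_experiment <- function(traj, kind = c("noise", "offset", "novel"),
                                    params = list(), seed = 1L) {
  kind <- match.arg(kind)
  cam <- switch(kind,
    noise = degrade(traj, degradation_spec(snr_db = params$snr_db %||% 50,
                                           seed = seed)),
    offset = degrade(traj, degradation_spec(offset_mm = params$offset_mm %||% 10,
                                            seed = seed)),
    novel = {
      if (is.null(params$novel)) stop("kind = 'novel' needs params$novel",
                                      call. = FALSE)
      params$novel
    })
  pair <- preprocess_pair(traj, cam, align = kind != "novel")
  latent_compare(pair)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relationship between latent and high-dimensional agreement
#'
#' Ordinary least squares of `corr2d` on `corr_signal` across a batch of
#' trials, after discarding trials whose two-component cumulative VAF falls
#' below `vaf_threshold` (poorly compressed trials dilute the relationship).
#'
#' @param reports List of `accuracy_report`s.
#' @param lcs List of matching `latent_comparison`s.
#' @param vaf_threshold Minimum cumulative VAF of the two retained components
#'   (default 0.90); use 0 to keep every trial.
#' @return List: `slope`, `intercept`, `r_squared`, `n_used`, `n_total`, and
#'   the underlying `data` (corr_signal, corr2d, vaf_cum per trial).
#' @export
batch_relationship <- function(reports, lcs, vaf_threshold = 0.90) {
  if (length(reports) != length(lcs))
    stop("reports and latent comparisons must match one-to-one", call. = FALSE)
  df <- data.frame(
    corr_signal = vapply(reports, function(r) r$corr_signal, numeric(1)),
    corr2d = vapply(lcs, function(l) l$corr2d, numeric(1)),
    vaf_cum = vapply(lcs, function(l) l$vaf_cum, numeric(1)))
  keep <- df$vaf_cum >= vaf_threshold
  used <- df[keep, , drop = FALSE]
  if (nrow(used) < 3)
    stop("fewer than 3 trials survive the VAF filter", call. = FALSE)
  if (stats::sd(used$corr_signal) == 0)
    stop("degenerate batch: corr_signal has no variance across trials ",
         "(all trials identical); a linear fit is meaningless", call. = FALSE)
  fit <- stats::lm(corr2d ~ corr_signal, data = used)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_used = nrow(used), n_total = nrow(df), data = df)
}
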