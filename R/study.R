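# Batch orchestration: run preprocessing, conventional metrics and the latent
# comparison over a manifest of trial pairs, aggregate per task x hand x
# group, and fit the batch corr2d-vs-corr_signal relationship.

#' Study configuration
#'
#' @param manifest data.frame with one row per trial. Either file columns
#'   (`ref_file`, `cam_file`) or list-columns of in-memory trajectories
#'   (`ref`, `cam`), plus `task`, and optionally `hand`, `participant`,
#'   `group`, `drop_cmc`.
#' @param vaf_threshold Cumulative-VAF filter for the batch fit, in `(0, 1]`.
#' @param out_dir Optional directory for per-trial JSON reports.
#' @param seed Integer master seed (recorded; trials themselves are
#'   deterministic given their inputs).
#' @return Object of class `study_config`.
#' @export
study_config <- function(manifest, vaf_threshold = 0.90, out_dir = NULL,
                         seed = 1L) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0) stop("empty trial manifest", call. = FALSE)
  has_files <- all(c("ref_file", "cam_file") %in% names(manifest))
  has_objs <- all(c("ref", "cam") %in% names(manifest))
  if (!has_files && !has_objs)
    stop("manifest needs ref_file/cam_file columns or ref/cam list-columns",
         call. = FALSE)
  if (!"task" %in% names(manifest)) stop("manifest needs a task column", call. = FALSE)
  if (has_files) {
    missing <- !file.exists(c(manifest$ref_file, manifest$cam_file))
    if (any(missing))
      stop("manifest references missing file(s): ",
           paste(unique(c(manifest$ref_file, manifest$cam_file)[missing]),
                 collapse = ", "), call. = FALSE)
  }
  if (vaf_threshold <= 0 || vaf_threshold > 1)
    stop("vaf_threshold must lie in (0, 1]", call. = FALSE)
  for (col in c("hand", "participant", "group"))
    if (!col %in% names(manifest)) manifest[[col]] <- NA_character_
  if (!"drop_cmc" %in% names(manifest)) manifest$drop_cmc <- FALSE
  structure(list(manifest = manifest, vaf_threshold = vaf_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

run_one_trial <- function(row, has_files) {
  ref <- if (has_files) read_trajectory(row$ref_file) else row$ref[[1]]
  cam <- if (has_files) read_trajectory(row$cam_file) else row$cam[[1]]
  ref$task <- cam$task <- row$task
  ref$hand <- cam$hand <- row$hand
  ref$participant <- cam$participant <- row$participant
  pair <- preprocess_pair(ref, cam, drop_cmc = isTRUE(row$drop_cmc))
  list(report = accuracy_report(pair, task = row$task),
       latent = latent_compare(pair))
}

#' Run an accuracy study over a trial manifest
#'
#' Executes the full pipeline (preprocess, conventional metrics, latent
#' comparison) for every manifest row, aggregates means and standard errors
#' (sample SD / sqrt(N)) of the headline metrics by task x hand x group, and
#' fits the batch corr2d-vs-corr_signal regression at the configured VAF
#' threshold (falling back to the unfiltered fit, with a note, when too few
#' trials survive). Failing trials are logged and skipped.
#'
#' @param cfg A [study_config()].
#' @return Object of class `study_report`: `trials` (per-trial data.frame),
#'   `reports`, `latents` (per-trial objects), `aggregates` (data.frame),
#'   `fit` (batch regression, or NULL if < 3 usable trials), `skipped`
#'   (character log of failed trials).
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  man <- cfg$manifest
  has_files <- all(c("ref_file", "cam_file") %in% names(man))
  reports <- list(); latents <- list(); skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, , drop = FALSE]
    res <- tryCatch(run_one_trial(row, has_files), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped,
                   sprintf("trial %d (%s/%s/%s): %s", i, row$task, row$hand,
                           row$participant, conditionMessage(res)))
      next
    }
    reports[[length(reports) + 1L]] <- res$report
    latents[[length(latents) + 1L]] <- res$latent
    rep <- res$report; lc <- res$latent
    rows[[length(rows) + 1L]] <- data.frame(
      trial = i, task = row$task, hand = row$hand, group = row$group,
      participant = row$participant, n_signals = rep$n_signals,
      corr_signal = rep$corr_signal, mae_avg = rep$mae_avg,
      corr_fingertip_mean = mean(rep$corr_fingertip, na.rm = TRUE),
      segment_error_mean = mean(rep$segment_errors),
      proximal_error_mean = mean(rep$segment_errors[grep("proximal",
                                   names(rep$segment_errors))]),
      vaf_cum = lc$vaf_cum, corr2d = lc$corr2d,
      wrist_height_mm = rep$wrist_height_mm, speed_mm_s = rep$speed_mm_s)
    if (!is.null(cfg$out_dir)) {
      if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
      write_accuracy_report(rep, file.path(cfg$out_dir,
                                           sprintf("trial_%03d.json", i)))
    }
  }
  if (length(rows) == 0) stop("every trial failed; nothing to report", call. = FALSE)
  trials <- do.call(rbind, rows)
  fit <- if (nrow(trials) >= 3)
    tryCatch(batch_relationship(reports, latents, cfg$vaf_threshold),
             error = function(e) {
               tryCatch(batch_relationship(reports, latents, 0),
                        error = function(e2) NULL)
             })
  else NULL
  structure(list(trials = trials, reports = reports, latents = latents,
                 aggregates = aggregate_trials(trials), fit = fit,
                 skipped = skipped, seed = cfg$seed),
            class = "study_report")
}

# mean and standard error (sample SD / sqrt(N)) of the headline metrics,
# grouped by task x hand x group
aggregate_trials <- function(trials) {
  metrics <- c("corr_signal", "mae_avg", "corr_fingertip_mean",
               "segment_error_mean", "proximal_error_mean", "corr2d", "vaf_cum")
  key <- interaction(trials$task, trials$hand, trials$group, drop = TRUE)
  out <- lapply(split(trials, key), function(g) {
    stats_row <- data.frame(task = g$task[1], hand = g$hand[1],
                            group = g$group[1], n_trials = nrow(g))
    for (mcol in metrics) {
      stats_row[[paste0(mcol, "_mean")]] <- mean(g[[mcol]])
      stats_row[[paste0(mcol, "_se")]] <-
        if (nrow(g) > 1) stats::sd(g[[mcol]]) / sqrt(nrow(g)) else NA_real_
    }
    stats_row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d trials (%d skipped)\n",
              nrow(x$trials), length(x$skipped)))
  cat(sprintf("  mean corr_signal = %.4f, mean mae_avg = %.3f mm, mean corr2d = %.4f\n",
              mean(x$trials$corr_signal), mean(x$trials$mae_avg),
              mean(x$trials$corr2d)))
  if (!is.null(x$fit))
    cat(sprintf("  corr2d ~ corr_signal: slope %.3f, R^2 %.3f (%d/%d trials, VAF filter)\n",
                x$fit$slope, x$fit$r_squared, x$fit$n_used, x$fit$n_total))
  invisible(x)
}

#' Simulate a full synthetic accuracy study
#'
#' Generates a synthetic cohort — `n_rep` trial pairs per task per
#' degradation-grid point, alternating hands — and runs [run_study()] on it.
#' The default grid crosses noise levels with small lags and timestamp jitter,
#' emulating a camera system whose error level varies across trials.
#' Deterministic given `seed` (per-trial seeds are derived from it).
#'
#' @param tasks Tasks to simulate.
#' @param snr_db_grid Noise levels (dB) of the degradation grid.
#' @param lag_s_grid Temporal lags (s) crossed with the noise levels.
#' @param n_rep Replicates per grid point per task.
#' @param duration,rate Trial length (s) and sampling rate (Hz).
#' @param jitter_frac Timestamp jitter fraction for every camera stream.
#' @param vaf_threshold Passed to [study_config()].
#' @param spec A [hand_spec()].
#' @param seed Master seed.
#' @param out_dir Optional per-trial report directory.
#' @return A `study_report`.
#' @export
simulate_study <- function(tasks = c("kapandji", "abd_add"),
                           snr_db_grid = c(50, 40, 30),
                           lag_s_grid = c(0, 0.15, 0.3, 0.5),
                           n_rep = 3,
                           duration = 10, rate = 50,
                           jitter_frac = 0.2,
                           vaf_threshold = 0.90,
                           spec = hand_spec(),
                           seed = 1L, out_dir = NULL) {
  grid <- expand.grid(task = tasks, snr_db = snr_db_grid, lag_s = lag_s_grid,
                      rep = seq_len(n_rep), stringsAsFactors = FALSE)
  refs <- list(); cams <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    script <- task_script(g$task, duration = duration, rate = rate)
    hand <- if (i %% 2 == 0) "left" else "right"
    hspec <- hand_spec(hand = hand, palm_width = spec$palm_width,
                       hand_size = spec$hand_size, proximal = spec$proximal,
                       middle = spec$middle, distal = spec$distal,
                       thumb = spec$thumb)
    d <- degradation_spec(snr_db = g$snr_db, lag_s = g$lag_s,
                          jitter_frac = jitter_frac,
                          seed = as.integer((as.numeric(seed) * 1000 + i) %%
                                              2147483646 + 1))
    tp <- make_trial_pair(hspec, script, d,
                          participant = sprintf("S%03d", g$rep))
    refs[[i]] <- tp$reference
    cams[[i]] <- tp$camera
  }
  manifest <- data.frame(task = grid$task,
                         hand = ifelse(seq_len(nrow(grid)) %% 2 == 0,
                                       "left", "right"),
                         participant = sprintf("S%03d", grid$rep),
                         group = sprintf("snr%02d", grid$snr_db),
                         stringsAsFactors = FALSE)
  manifest$ref <- refs
  manifest$cam <- cams
  run_study(study_config(manifest, vaf_threshold = vaf_threshold,
                         out_dir = out_dir, seed = seed))
}

#' Serialize a study report
#'
#' Writes the per-trial table as CSV and the aggregates + batch fit as JSON.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aggregates, file.path(dir, "aggregates.csv"),
                   row.names = FALSE)
  fit <- report$fit
  if (!is.null(fit)) fit$data <- NULL
  jsonlite::write_json(list(fit = fit, skipped = report$skipped,
                            seed = report$seed),
                       file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
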