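# Conventional accuracy metrics.

pair_from_matrices <- function(ref, cam, time = seq_len(nrow(ref)) * 0.02,
                               task = "abd_add") {
  structure(list(time = time, ref = ref, cam = cam,
                 offset = c(x = 0, y = 0, z = 0), n_signals = ncol(ref),
                 task = task, hand = "right", participant = "toy"),
            class = "trial_pair")
}

test_that("identity pair attains the ideal of every metric exactly", {
  pair <- preprocess_pair(fx_kap, fx_kap)
  sc <- signal_correlations(pair)
  expect_true(all(abs(sc$corr_i - 1) < 1e-12))
  expect_equal(sc$corr_signal, 1, tolerance = 1e-12)
  expect_equal(sc$n_undefined, 0)
  expect_equal(signal_mae(pair)$mae_avg, 0)
  fc <- fingertip_correlations(pair)
  expect_true(all(fc$corr_fingertip == 1))
  se <- segment_length_errors(pair)
  expect_true(all(se$absolute == 0))
})

test_that("mirrored signals give correlation -1 and constant signals are excluded", {
  ref <- fx_jittered_matrix
  cam <- sweep(-sweep(ref, 2, colMeans(ref)), 2, colMeans(ref), "+")
  pair <- pair_from_matrices(ref, cam)
  sc <- signal_correlations(pair)
  expect_true(all(abs(sc$corr_i + 1) < 1e-12))
  # flatten one signal in the camera: flagged undefined, excluded, counted
  cam2 <- ref
  cam2[, "wrist_x"] <- 5
  sc2 <- signal_correlations(pair_from_matrices(ref, cam2))
  expect_true(is.na(sc2$corr_i["wrist_x"]))
  expect_equal(sc2$n_undefined, 1)
  expect_equal(sc2$corr_signal, mean(sc2$corr_i[-1]), tolerance = 1e-12)
})

test_that("per-signal Pearson matches the textbook oracle on toy pairs", {
  set.seed(17)
  ref <- fx_jittered_matrix[1:5, ]
  cam <- ref + matrix(rnorm(length(ref), sd = 4), 5)
  sc <- signal_correlations(pair_from_matrices(ref, cam))
  want <- sapply(seq_len(ncol(ref)), function(i) oracle_pearson(ref[, i], cam[, i]))
  expect_equal(unname(sc$corr_i), want, tolerance = 1e-12)
  expect_equal(sc$corr_signal, mean(want), tolerance = 1e-12)
})

test_that("MAE matches a constant offset and the elementwise oracle", {
  ref <- fx_jittered_matrix
  sm <- signal_mae(pair_from_matrices(ref, ref + 10))
  expect_true(all(sm$mae_i == 10))
  expect_equal(sm$mae_avg, 10)
  set.seed(23)
  a <- fx_jittered_matrix[1:4, ]
  b <- a + matrix(rnorm(length(a), sd = 6), 4)
  sm2 <- signal_mae(pair_from_matrices(a, b))
  want <- sapply(seq_len(ncol(a)), function(i) oracle_mae(a[, i], b[, i]))
  expect_equal(unname(sm2$mae_i), want, tolerance = 1e-12)
  expect_equal(sm2$mae_avg, mean(want), tolerance = 1e-12)
})

test_that("per-landmark 3D error complements the per-axis MAE", {
  ref <- fx_jittered_matrix
  # pure x-offset of 3 mm: per-landmark 3D error is exactly 3, per-axis MAE 1
  cam <- sweep(ref, 2, rep(c(3, 0, 0), 20), "+")
  pair <- pair_from_matrices(ref, cam)
  l3 <- landmark_mae_3d(pair)
  expect_length(l3$mae_landmark, 20)
  expect_true(all(abs(l3$mae_landmark - 3) < 1e-10))
  expect_equal(signal_mae(pair)$mae_avg, 1, tolerance = 1e-10)
  # general case: matches a hand-rolled norm average
  set.seed(8)
  cam2 <- ref + matrix(rnorm(length(ref)), nrow(ref))
  got <- landmark_mae_3d(pair_from_matrices(ref, cam2))$mae_landmark[["wrist"]]
  want <- mean(sqrt(rowSums((cam2[, 1:3] - ref[, 1:3])^2)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("fingertip distances are Euclidean and task-appropriate", {
  pos <- fx_flat$positions[rep(1, 2), ]
  # place thumb tip at origin-offset and index tip 3-4-5 away
  pos[, paste0("thumb_tip_", c("x", "y", "z"))] <- rep(c(10, 10, 10), each = 2)
  pos[, paste0("index_tip_", c("x", "y", "z"))] <- rep(c(13, 14, 10), each = 2)
  d <- fingertip_distances(pos, "kapandji")
  expect_equal(unname(d[1, "TI"]), 5)
  # coincident tips -> zero
  pos[, paste0("index_tip_", c("x", "y", "z"))] <- rep(c(10, 10, 10), each = 2)
  expect_equal(unname(fingertip_distances(pos, "kapandji")[1, "TI"]), 0)
  # task pairing differs between tasks
  expect_equal(colnames(fingertip_distances(fx_abd, "abd_add")),
               c("TI", "IM", "MR", "RP"))
  expect_equal(colnames(fingertip_distances(fx_kap, "kapandji")),
               c("TI", "TM", "TR", "TP"))
  expect_error(fingertip_distances(fx_kap, "fist"), "unknown task")
})

test_that("fingertip correlations compose Pearson with oracle distances", {
  ref <- generate_trajectory(fx_spec, fx_abd_script)
  cam <- degrade(ref, degradation_spec(snr_db = 30, seed = 2))
  pair <- preprocess_pair(ref, cam)
  fc <- fingertip_correlations(pair)
  dr <- fingertip_distances(pair$ref, "abd_add")
  dc <- fingertip_distances(pair$cam, "abd_add")
  want <- sapply(1:4, function(j) oracle_pearson(dr[, j], dc[, j]))
  expect_equal(unname(fc$corr_fingertip), want, tolerance = 1e-10)
  # adding a constant to the camera distances cannot change the correlation
  pair2 <- pair
  pair2$cam <- sweep(pair2$cam, 2, rep(c(4, 4, 4), 20), "+")
  # NB: a rigid translation of all landmarks leaves distances identical
  expect_equal(fingertip_correlations(pair2)$corr_fingertip,
               fc$corr_fingertip, tolerance = 1e-9)
})

test_that("segment lengths match hand-computed norms on a crafted finger", {
  pos <- fx_flat$positions[rep(1, 3), ]
  pos[, paste0("index_mcp_", c("x", "y", "z"))] <- rep(c(0, 0, 0), each = 3)
  pos[, paste0("index_pip_", c("x", "y", "z"))] <- rep(c(3, 4, 0), each = 3)
  pos[, paste0("index_dip_", c("x", "y", "z"))] <- rep(c(3, 4, 12), each = 3)
  pos[, paste0("index_tip_", c("x", "y", "z"))] <- rep(c(5, 4, 12), each = 3)
  lens <- segment_lengths(pos, 2)
  expect_equal(unname(lens["index_proximal"]), 5)
  expect_equal(unname(lens["index_middle"]), 12)
  expect_equal(unname(lens["index_distal"]), 2)
  expect_equal(length(lens), 12)
  expect_error(segment_lengths(pos, 9), "out of range")
})

test_that("segment-length errors recover an injected proximal bias", {
  for (b in c(5, 10, 18)) {
    cam <- degrade(fx_abd, degradation_spec(proximal_bias_mm = b))
    pair <- preprocess_pair(fx_abd, cam)
    se <- segment_length_errors(pair)
    prox <- grep("proximal", names(se$absolute))
    expect_equal(unname(se$absolute[prox]), rep(b, 4), tolerance = 0.5)
    expect_true(all(se$signed[prox] < 0))  # camera underestimates
    expect_lt(max(se$absolute[-prox]), 0.5)
  }
})

test_that("trial dynamics report wrist height and tip speed", {
  # static hand: zero speed, exact height
  expect_equal(trial_dynamics(fx_flat, "kapandji")$speed_mm_s, 0)
  expect_equal(trial_dynamics(fx_flat, "kapandji")$wrist_height_mm, 150)
  # tip moving at a constant 50 mm/s along x
  t <- seq(0, 2, by = 0.02)
  pos <- fx_flat$positions[rep(1, length(t)), ]
  pos[, "thumb_tip_x"] <- pos[, "thumb_tip_x"] + 50 * t
  tr <- trajectory(t, pos, task = "kapandji")
  expect_equal(trial_dynamics(tr, "kapandji")$speed_mm_s, 50, tolerance = 1e-9)
  # task selects the designated landmark
  expect_equal(trial_dynamics(fx_abd)$speed_landmark, "index_tip")
  expect_equal(trial_dynamics(fx_kap)$speed_landmark, "thumb_tip")
  # finite-difference speed matches a hand-rolled central estimate in scale
  dyn <- trial_dynamics(fx_kap)
  tip <- fx_kap$positions[, paste0("thumb_tip_", c("x", "y", "z"))]
  step <- sqrt(rowSums(diff(tip)^2))
  expect_equal(dyn$speed_mm_s, mean(step / diff(fx_kap$time)), tolerance = 1e-12)
})

test_that("accuracy_report bundles all metrics coherently", {
  cam <- degrade(fx_kap, degradation_spec(snr_db = 40, proximal_bias_mm = 10,
                                          seed = 44))
  pair <- preprocess_pair(fx_kap, cam)
  rep <- accuracy_report(pair)
  expect_s3_class(rep, "accuracy_report")
  expect_equal(length(rep$corr_i), 60)
  expect_equal(length(rep$corr_fingertip), 4)
  expect_equal(length(rep$segment_errors), 12)
  expect_true(rep$corr_signal > 0.9 && rep$corr_signal <= 1)
  expect_gt(rep$mae_avg, 0)
  # serialization round-trip (JSON)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_accuracy_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$corr_signal, rep$corr_signal, tolerance = 1e-12)
})
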