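# Shared fixtures: short trials keep the default suite fast. Anything that a
# test mutates is rebuilt locally; these are read-only.

fx_spec <- hand_spec()
fx_kap_script <- task_script("kapandji", duration = 6, rate = 50)
fx_abd_script <- task_script("abd_add", duration = 6, rate = 50)
fx_kap <- generate_trajectory(fx_spec, fx_kap_script)
fx_abd <- generate_trajectory(fx_spec, fx_abd_script)
fx_flat <- generate_trajectory(
  fx_spec, task_script("kapandji", duration = 2, amplitude_scale = 0, sway_mm = 0))

# true phalanx lengths in segment_lengths() order
fx_true_lengths <- local({
  v <- c(rbind(fx_spec$proximal, fx_spec$middle, fx_spec$distal))
  names(v) <- paste0(rep(finger_names(), each = 3),
                     "_", c("proximal", "middle", "distal"))
  v
})

# a small deterministic non-trajectory matrix with canonical columns is often
# handy; positions jittered around a flat pose so nothing is constant
fx_jittered_matrix <- local({
  set.seed(99)
  base <- fx_flat$positions[rep(1, 40), ]
  base + matrix(rnorm(length(base), sd = 3), nrow(base), ncol(base))
})
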