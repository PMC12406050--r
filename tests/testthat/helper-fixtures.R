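# Shared fixtures, built in code at test time.

# tiny two-region ROI set: one functional ("A"), one noise
tiny_roi_set <- function() {
  fus_roi_set(ids = c(0, 1), names = c("noise", "A"),
              roles = c("noise", "functional"))
}

# hand-built acquisition with deterministic content
tiny_acquisition <- function(n = 100, fs = 2.5, seed = 1) {
  set.seed(seed)
  sig <- matrix(rnorm(n * 6), n, 6)
  fus_acquisition(sig, fs = fs, pixel_labels = c(1, 1, 1, 0, 0, 0),
                  motion = abs(rnorm(n)), animal_id = "t1", group = "control")
}

# theoretical synchronicity vectors implied by a matrix of state offsets
theoretical_state_vectors <- function(offsets) {
  t(apply(offsets, 1, function(th) {
    M <- cos(outer(th, th, "-"))
    M[upper.tri(M)]
  }))
}

# small fast generator config for pipeline-level tests
fast_config <- function(...) {
  generator_config(duration = 300, pixels_per_roi = 3, noise_pixels = 9, ...)
}

# pooled per-sample accuracy of recovered labels against planted states,
# after matching model centroids to the theoretical state patterns
state_recovery_accuracy <- function(dfc, sim, cfg, trim_seconds = 30) {
  mt <- match_states(dfc$model$centroids,
                     theoretical_state_vectors(cfg$state_offsets))
  k <- floor(trim_seconds * cfg$fs)
  pred <- c(); truth <- c()
  for (id in names(dfc$labels)) {
    s <- sim$truth[[id]]$states
    truth <- c(truth, s[(k + 1):(length(s) - k)])
    pred <- c(pred, mt$perm[dfc$labels[[id]]])
  }
  mean(pred == truth)
}
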