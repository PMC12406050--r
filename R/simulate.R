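#' Default brain-state phase-offset patterns
#'
#' Each of the K = 4 latent states assigns one phase offset (radians) per
#' functional region; the cosine of pairwise offset differences is the
#' synchronicity pattern the state produces. The defaults emulate the four
#' recurring configurations seen in mouse fUS work: a globally synchronous
#' state, desynchronization of the sensorimotor cortices, desynchronization
#' of the insula/striatum ventral pathway, and a cortico-cortical state where
#' hippocampus, thalamus and cerebellum stay mutually synchronous but
#' oppose the cortex.
#'
#' @param roi_names character vector of functional region names (default the
#'   seven regions of [default_roi_set()]).
#' @return K x R numeric matrix of offsets in (-pi, pi], rownames = state ids.
#' @export
default_state_offsets <- function(roi_names = default_roi_set()$functional_order) {
  r <- length(roi_names)
  off <- matrix(0, 4, r, dimnames = list(paste0("state", 1:4), roi_names))
  pick <- function(nm) which(roi_names %in% nm)
  # state 1: global synchrony (all offsets 0)
  off[2, pick(c("S1", "M1"))] <- pi          # sensorimotor desynchronized
  off[3, pick(c("Ins", "Str"))] <- pi        # ventral pathway desynchronized
  off[4, pick(c("HPC", "TH", "CC"))] <- pi   # cortex vs HPC/TH/CC opposition
  off
}

#' Default per-group Markov transition matrices
#'
#' Built from target mean dwell times (seconds) and target occupancies:
#' the diagonal is `1 - 1/(fs * dwell)` and each row's off-diagonal mass is
#' distributed proportionally to the target occupancy of the destination
#' state. The control group dwells longer in the globally synchronous state;
#' the treated group shifts occupancy toward the partially desynchronized
#' states, the kind of mild global-connectivity reduction the pipeline is
#' meant to detect.
#'
#' @param group `"control"` or `"treated"`.
#' @param fs sampling frequency (Hz).
#' @return K x K row-stochastic matrix.
#' @export
default_transition_matrix <- function(group = c("control", "treated"),
                                      fs = 2.5) {
  group <- match.arg(group)
  if (group == "control") {
    dwell <- c(36, 24, 20, 20)      # seconds; state 1 = global synchrony
    target <- c(0.37, 0.26, 0.17, 0.20)
  } else {
    dwell <- c(26, 24, 20, 20)
    target <- c(0.21, 0.35, 0.25, 0.19)
  }
  transition_from_dwell(dwell, target, fs)
}

## build a transition matrix with prescribed mean dwell times (seconds) and
## stationary occupancies: diagonal from the dwells, off-diagonal jump
## weights solved by fixed-point iteration so the stationary distribution
## matches the target
transition_from_dwell <- function(dwell, target, fs) {
  k <- length(dwell)
  stopifnot(length(target) == k, abs(sum(target) - 1) < 1e-8)
  stay <- 1 - 1 / (fs * dwell)
  nu <- target / dwell
  nu <- nu / sum(nu)
  P <- matrix(0, k, k)
  for (it in 1:200) {
    for (i in seq_len(k)) {
      w <- nu[-i] / sum(nu[-i])
      P[i, i] <- stay[i]
      P[i, -i] <- (1 - stay[i]) * w
    }
    pi_hat <- stationary_distribution(P)
    if (max(abs(pi_hat - target)) < 1e-10) break
    nu <- nu * (target / pi_hat)
    nu <- nu / sum(nu)
  }
  P
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P row-stochastic matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

check_stochastic <- function(P, tol = 1e-8) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < -tol) ||
      any(abs(rowSums(P) - 1) > tol))
    stop("transition matrix must be square, non-negative, with rows summing to 1")
  invisible(P)
}

#' Simulator configuration
#'
#' Collects every tunable of the synthetic cohort generator. Defaults define
#' the reference study conditions: 15-minute acquisitions at 2.5 Hz, a
#' 0.05 Hz hemodynamic carrier phase-modulated by a K = 4 latent Markov
#' state sequence, shared physiological noise (respiration-like ~0.3 Hz and
#' slow anesthesia-like ~0.02 Hz components present in functional and noise
#' pixels alike), a shared very-slow drift, sparse motion-artifact bursts
#' co-varying with the tissue-motion trace, and per-pixel white noise.
#'
#' The tissue-motion magnitude trace couples to each noise source through
#' `motion_coupling`: fully to the bursts and weakly to the physiological
#' components, because respiration and slow positional drift are themselves
#' tissue motion.
#'
#' @param K number of latent states (>= 2).
#' @param transition named list of K x K row-stochastic matrices, one per
#'   group label.
#' @param state_offsets K x R matrix of per-state ROI phase offsets, radians.
#' @param roi_set a `fus_roi_set`.
#' @param carrier_freq carrier frequency, Hz; must lie in the 0.01-0.1 Hz
#'   hemodynamic band so state structure survives bandpass filtering.
#' @param carrier_amp carrier amplitude (arbitrary units).
#' @param pixels_per_roi pixels per functional region.
#' @param noise_pixels pixels in the noise region.
#' @param noise_sd per-pixel white-noise standard deviation.
#' @param shared_amp amplitude of each shared physiological component.
#' @param drift_amp amplitude of the shared slow drift.
#' @param burst_rate motion-artifact bursts per minute.
#' @param burst_amp burst amplitude in the pixel data.
#' @param motion_coupling named numeric: weight of each noise source in the
#'   motion trace (`burst`, `resp`, `slow`, `drift`).
#' @param motion_floor standard deviation of the motion-trace noise floor.
#' @param phase_jitter_sd per-pixel carrier phase jitter, radians.
#' @param blend_samples raised-cosine blending width (samples) applied to the
#'   state phase offsets at switches, avoiding phase discontinuities.
#' @param duration acquisition length, seconds.
#' @param fs sampling frequency, Hz.
#' @return A validated list of class `fus_generator_config`.
#' @export
generator_config <- function(K = 4,
                             transition = list(
                               control = default_transition_matrix("control", fs),
                               treated = default_transition_matrix("treated", fs)),
                             state_offsets = default_state_offsets(roi_set$functional_order),
                             roi_set = default_roi_set(),
                             carrier_freq = 0.05,
                             carrier_amp = 1,
                             pixels_per_roi = 8,
                             noise_pixels = 24,
                             noise_sd = 1,
                             shared_amp = 0.6,
                             drift_amp = 0.4,
                             burst_rate = 2,
                             burst_amp = 2,
                             motion_coupling = c(burst = 1, resp = 0.2,
                                                 slow = 0.15, drift = 0.1),
                             motion_floor = 0.02,
                             phase_jitter_sd = 0.1,
                             blend_samples = 12,
                             duration = 900,
                             fs = 2.5) {
  cfg <- list(K = K, transition = transition, state_offsets = state_offsets,
              roi_set = roi_set, carrier_freq = carrier_freq,
              carrier_amp = carrier_amp, pixels_per_roi = pixels_per_roi,
              noise_pixels = noise_pixels, noise_sd = noise_sd,
              shared_amp = shared_amp, drift_amp = drift_amp,
              burst_rate = burst_rate, burst_amp = burst_amp,
              motion_coupling = motion_coupling, motion_floor = motion_floor,
              phase_jitter_sd = phase_jitter_sd,
              blend_samples = blend_samples, duration = duration, fs = fs)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$K < 2) stop("K must be >= 2")
  if (!length(cfg$transition) || is.null(names(cfg$transition)))
    stop("`transition` must be a named list of matrices, one per group")
  for (g in names(cfg$transition)) {
    P <- cfg$transition[[g]]
    check_stochastic(P, tol = 1e-12)
    if (nrow(P) != cfg$K) stop("transition matrix for group '", g,
                               "' must be ", cfg$K, " x ", cfg$K)
  }
  r <- length(cfg$roi_set$functional_order)
  if (!is.matrix(cfg$state_offsets) ||
      nrow(cfg$state_offsets) != cfg$K || ncol(cfg$state_offsets) != r)
    stop("`state_offsets` must be a K x R matrix")
  if (any(cfg$state_offsets <= -pi) || any(cfg$state_offsets > pi))
    stop("state offsets must lie in (-pi, pi]")
  amps <- c(cfg$carrier_amp, cfg$noise_sd, cfg$shared_amp, cfg$drift_amp,
            cfg$burst_amp, cfg$motion_floor, cfg$motion_coupling)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (cfg$carrier_freq < 0.01 || cfg$carrier_freq > 0.1)
    stop("`carrier_freq` must lie within the 0.01-0.1 Hz band")
  if (cfg$duration * cfg$fs < 10) stop("duration * fs must be >= 10")
  structure(cfg, class = "fus_generator_config")
}

#' Simulate a latent Markov state sequence
#'
#' The first state is drawn from the stationary distribution, so the sequence
#' is stationary from the first sample.
#'
#' @param P K x K row-stochastic transition matrix.
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @return Integer vector of state labels in `1..K`.
#' @export
simulate_state_sequence <- function(P, n, seed = NULL) {
  P <- check_stochastic(P)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(P)
  s <- integer(n)
  s[1] <- sample.int(k, 1, prob = stationary_distribution(P))
  if (n > 1)
    for (t in 2:n) s[t] <- sample.int(k, 1, prob = P[s[t - 1], ])
  s
}

## band-limited unit-variance noise process
bandlimited_noise <- function(n, fs, low = NULL, high) {
  x <- stats::rnorm(n + 200)
  w <- c(low, high) / (fs / 2)
  flt <- if (is.null(low)) signal::butter(2, w, type = "low")
         else signal::butter(2, w, type = "pass")
  y <- signal::filtfilt(flt, x)[101:(n + 100)]
  as.numeric(scale(y))
}

## raised-cosine smoothing of per-ROI state phase offsets at switches.
## The offset sequence is first unwrapped into a continuous real path
## (each switch contributes its shortest-arc increment), then convolved
## with a raised-cosine kernel; cosines downstream absorb any 2*pi turns.
blend_offsets <- function(theta_t, blend_samples) {
  if (blend_samples <= 0) return(theta_t)
  half <- ceiling(blend_samples / 2)
  w <- 0.5 * (1 + cos(pi * seq(-half, half) / (half + 1)))
  w <- w / sum(w)
  wrap_pi <- function(x) {
    y <- (x + pi) %% (2 * pi) - pi
    y[y <= -pi] <- pi
    y
  }
  apply(theta_t, 2, function(th) {
    path <- th[1] + c(0, cumsum(wrap_pi(diff(th))))
    pp <- c(rep(path[1], half), path, rep(path[length(path)], half))
    sm <- stats::filter(pp, w, sides = 2)
    as.numeric(sm[(half + 1):(half + length(path))])
  })
}

seed_for_animal <- function(seed, animal_id) {
  h <- sum(utf8ToInt(animal_id) * seq_along(utf8ToInt(animal_id)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Simulate one acquisition with ground truth
#'
#' Functional pixels carry an in-band sinusoidal carrier whose per-region
#' phase offset follows the latent state sequence; noise-region pixels carry
#' the same shared physiological components, drift and motion bursts but no
#' state-driven carrier. The returned ground truth stores the state sequence
#' and every additive part separately; their sum reproduces the signal to
#' machine precision.
#'
#' @param config a `fus_generator_config`.
#' @param group group label (must name a transition matrix in the config).
#' @param animal_id animal identifier.
#' @param seed integer seed.
#' @return list with components `acquisition` (a `fus_acquisition`) and
#'   `truth` (states, per-part matrices, component traces, offsets).
#' @export
simulate_acquisition <- function(config, group = "control",
                                 animal_id = "a1", seed = 1) {
  cfg <- validate_generator_config(config)
  if (!group %in% names(cfg$transition))
    stop("no transition matrix for group '", group, "'")
  set.seed(seed)
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  roi <- cfg$roi_set
  fid <- functional_ids(roi)
  nid <- noise_ids(roi)
  r <- length(fid)
  npix_f <- r * cfg$pixels_per_roi
  npix_n <- length(nid) * max(1L, round(cfg$noise_pixels / length(nid)))
  p <- npix_f + npix_n
  labels <- c(rep(fid, each = cfg$pixels_per_roi),
              rep(nid, each = npix_n / length(nid)))
  func_idx <- seq_len(npix_f)

  states <- simulate_state_sequence(cfg$transition[[group]], n)
  theta_t <- cfg$state_offsets[states, , drop = FALSE]   # n x R
  theta_t <- blend_offsets(theta_t, cfg$blend_samples)

  ## state-driven carrier (functional pixels only)
  carrier <- matrix(0, n, p)
  base_phase <- 2 * pi * cfg$carrier_freq * tt
  for (k in seq_len(r)) {
    cols <- which(labels == fid[k])
    for (cpix in cols) {
      amp <- cfg$carrier_amp * stats::runif(1, 0.8, 1.2)
      jit <- stats::rnorm(1, 0, cfg$phase_jitter_sd)
      carrier[, cpix] <- amp * cos(base_phase + theta_t[, k] + jit)
    }
  }

  ## shared physiological components (both pixel populations)
  resp <- bandlimited_noise(n, fs, 0.25, 0.35)
  slow <- bandlimited_noise(n, fs, NULL, 0.03)
  shared <- cfg$shared_amp *
    (outer(resp, stats::rnorm(p, 0.5, 0.5)) +
     outer(slow, stats::rnorm(p, 0.5, 0.5)))

  ## shared very-slow drift
  driftc <- bandlimited_noise(n, fs, NULL, 0.008)
  drift <- cfg$drift_amp * outer(driftc, stats::rnorm(p, 0.5, 0.5))

  ## sparse motion-artifact bursts: one shared envelope, random pixel weights
  n_events <- stats::rpois(1, cfg$burst_rate * cfg$duration / 60)
  env <- numeric(n)
  if (n_events > 0) {
    centers <- sort(stats::runif(n_events, 0, cfg$duration))
    width <- 2                                  # seconds
    for (ctr in centers) {
      idx <- which(abs(tt - ctr) <= width / 2)
      env[idx] <- env[idx] +
        abs(stats::rnorm(1, 1, 0.3)) * 0.5 *
        (1 + cos(2 * pi * (tt[idx] - ctr) / width))
    }
  }
  bursts <- cfg$burst_amp * outer(env, stats::rnorm(p, 1, 0.5))

  white <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  baseline <- matrix(stats::runif(p, 50, 150), n, p, byrow = TRUE)

  sig <- carrier + shared + drift + bursts + white + baseline

  mc <- cfg$motion_coupling
  motion <- mc[["burst"]] * env +
    mc[["resp"]] * (resp - min(resp)) +
    mc[["slow"]] * (slow - min(slow)) +
    mc[["drift"]] * (driftc - min(driftc)) +
    abs(stats::rnorm(n, 0, cfg$motion_floor))

  acq <- fus_acquisition(sig, fs = fs, pixel_labels = labels, motion = motion,
                         animal_id = animal_id, group = group)
  truth <- list(states = states, offsets = theta_t,
                parts = list(carrier = carrier, shared = shared,
                             drift = drift, bursts = bursts, white = white,
                             baseline = baseline),
                components = list(resp = resp, slow = slow, drift = driftc,
                                  burst_env = env),
                functional_pixels = func_idx, seed = seed)
  list(acquisition = acq, truth = truth)
}

#' Simulate a cohort with known ground truth
#'
#' Per-animal seeds are derived deterministically from the cohort seed and
#' the animal id, so any animal can be regenerated in isolation.
#'
#' @param config a `fus_generator_config`.
#' @param n_per_group named integer vector, animals per group; names must
#'   match the config's transition matrices.
#' @param seed cohort-level integer seed.
#' @return list with `cohort` (a `fus_cohort`) and `truth` (one ground-truth
#'   record per animal, in cohort order).
#' @export
simulate_cohort <- function(config,
                            n_per_group = c(control = 18, treated = 17),
                            seed = 1) {
  cfg <- validate_generator_config(config)
  if (any(n_per_group < 1)) stop("need at least one animal per group")
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% names(cfg$transition)))
    stop("`n_per_group` names must match the config's transition matrices")
  acqs <- list(); truths <- list()
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      sim <- simulate_acquisition(cfg, group = g, animal_id = id,
                                  seed = seed_for_animal(seed, id))
      acqs[[id]] <- sim$acquisition
      truths[[id]] <- sim$truth
    }
  }
  list(cohort = fus_cohort(acqs, cfg$roi_set), truth = truths)
}
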