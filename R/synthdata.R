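#' Oscillator specification for synthetic EEG
#'
#' Parameters of the stochastic phase-oscillator (Kuramoto-style) generator.
#' Each channel carries a narrowband oscillation inside `carrier_band` whose
#' phase is pulled toward (neighbour phase + prescribed lag) with strength
#' proportional to the coupling matrix; instantaneous linear `mixing`
#' emulates volume conduction, and `noise_sd` adds white measurement noise.
#'
#' @param n_channels Number of channels.
#' @param sample_rate Sampling rate in Hz.
#' @param duration Length in seconds.
#' @param carrier_band Numeric length-2, (low, high) Hz of the oscillation band.
#' @param coupling Symmetric `n_channels` x `n_channels` matrix of coupling
#'   strengths in \[0, 1\], zero diagonal. Default: no coupling.
#' @param phase_lags Antisymmetric matrix of target phase offsets in radians
#'   (`phase_lags[i, j]` is the stationary phase of channel i minus channel j).
#' @param alpha_peak Alpha peak frequency in Hz (used by [generate_rest()]).
#' @param noise_sd Additive white measurement-noise SD, in signal units.
#' @param mixing Square instantaneous mixing matrix (rows: sensors, columns:
#'   sources). Identity by default, i.e. no volume-conduction leakage.
#' @param seed Integer seed; all randomness of one epoch flows from it.
#' @param coupling_gain Pull rate of the phase coupling, 1/s.
#' @param phase_noise_sd Phase diffusion intensity, rad/sqrt(s).
#' @param alpha_bump Height of the Gaussian alpha bump in rest spectra,
#'   relative power units.
#' @param alpha_width SD of the Gaussian alpha bump, Hz.
#' @param one_over_f_slope Spectral slope of the 1/f rest background.
#' @return An object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(n_channels = 24, sample_rate = 1000, duration = 60,
                            carrier_band = c(4, 8),
                            coupling = NULL, phase_lags = NULL,
                            alpha_peak = 10, noise_sd = 1,
                            mixing = NULL, seed = 1L,
                            coupling_gain = 4, phase_noise_sd = 2.5,
                            alpha_bump = 2, alpha_width = 1.5,
                            one_over_f_slope = 1) {
  n <- as.integer(n_channels)
  if (is.null(coupling)) coupling <- matrix(0, n, n)
  if (is.null(phase_lags)) phase_lags <- matrix(0, n, n)
  if (is.null(mixing)) mixing <- diag(n)
  if (!isTRUE(all.equal(coupling, t(coupling))) ||
      any(diag(coupling) != 0) ||
      any(coupling < 0) || any(coupling > 1)) {
    stop("`coupling` must be symmetric with zero diagonal and entries in [0, 1]")
  }
  if (!isTRUE(all.equal(phase_lags, -t(phase_lags)))) {
    stop("`phase_lags` must be antisymmetric")
  }
  if (!is.matrix(mixing) || any(dim(mixing) != n)) {
    stop("`mixing` must be a square n_channels matrix")
  }
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[2] <= carrier_band[1]) {
    stop("`carrier_band` must be (low, high) with 0 < low < high")
  }
  if (duration * sample_rate < 2 * sample_rate / carrier_band[1]) {
    stop("duration too short: need at least two carrier periods")
  }
  structure(
    list(n_channels = n, sample_rate = sample_rate, duration = duration,
         carrier_band = carrier_band, coupling = coupling,
         phase_lags = phase_lags, alpha_peak = alpha_peak,
         noise_sd = noise_sd, mixing = mixing, seed = as.integer(seed),
         coupling_gain = coupling_gain, phase_noise_sd = phase_noise_sd,
         alpha_bump = alpha_bump, alpha_width = alpha_width,
         one_over_f_slope = one_over_f_slope),
    class = "oscillator_spec"
  )
}

#' Generate one task epoch from coupled phase oscillators
#'
#' Integrates a stochastic Kuramoto-style phase model with Euler steps at the
#' sampling rate: each channel's phase advances at its carrier frequency and
#' is pulled toward the lagged phase of its coupled neighbours; cosine
#' projection gives the signal, which is premultiplied by the mixing matrix
#' and corrupted by white noise.
#'
#' @param spec An [oscillator_spec()].
#' @return A [recording()] with a single event spanning the epoch.
#' @export
generate_task_epoch <- function(spec) {
  stopifnot(inherits(spec, "oscillator_spec"))
  n <- spec$n_channels
  fs <- spec$sample_rate
  n_samp <- round(spec$duration * fs)
  dt <- 1 / fs
  withr_seed <- spec$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  # per-channel carrier frequencies drawn from the middle half of the band
  band <- spec$carrier_band
  w <- diff(band)
  freqs <- stats::runif(n, band[1] + 0.25 * w, band[2] - 0.25 * w)
  omega <- 2 * pi * freqs

  # complex coupling weights: W[i, j] = C[i, j] * exp(1i * lag[i, j]) so that
  # drift_i = gain * Im(conj(z_i) * (W %*% z)) pulls theta_i toward
  # theta_j + lag_ij
  W <- spec$coupling * exp(1i * spec$phase_lags)
  coupled <- any(spec$coupling != 0)

  theta <- stats::runif(n, 0, 2 * pi)
  sqdt_s <- sqrt(dt) * spec$phase_noise_sd
  X <- matrix(0, n, n_samp)
  for (t in seq_len(n_samp)) {
    z <- exp(1i * theta)
    drift <- omega
    if (coupled) drift <- drift + spec$coupling_gain * Im(Conj(z) * (W %*% z))
    theta <- theta + drift * dt + sqdt_s * stats::rnorm(n)
    X[, t] <- cos(theta)
  }
  X <- spec$mixing %*% X
  if (spec$noise_sd > 0) X <- X + spec$noise_sd * matrix(stats::rnorm(n * n_samp), n, n_samp)
  recording(X, fs,
            events = data.frame(label = "task", onset = 1L, offset = n_samp,
                                stringsAsFactors = FALSE))
}

#' Generate an eyes-closed rest recording
#'
#' Synthesizes channels whose power spectrum is a 1/f background plus a
#' Gaussian alpha bump centred at `spec$alpha_peak`, via inverse-FFT spectral
#' synthesis with random phases; white measurement noise is added on top.
#'
#' @param spec An [oscillator_spec()]; `alpha_peak`, `alpha_bump`,
#'   `alpha_width` and `one_over_f_slope` shape the spectrum.
#' @return A [recording()].
#' @export
generate_rest <- function(spec) {
  stopifnot(inherits(spec, "oscillator_spec"))
  fs <- spec$sample_rate
  if (spec$alpha_peak >= fs / 2) stop("alpha_peak must be below the Nyquist frequency")
  n <- spec$n_channels
  n_samp <- round(spec$duration * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n_half <- floor(n_samp / 2)
  f <- seq_len(n_half) * fs / n_samp
  psd <- (1 / f)^spec$one_over_f_slope +
    spec$alpha_bump * exp(-(f - spec$alpha_peak)^2 / (2 * spec$alpha_width^2))
  amp <- sqrt(psd)

  X <- matrix(0, n, n_samp)
  for (ch in seq_len(n)) {
    ph <- stats::runif(n_half, 0, 2 * pi)
    spec_half <- amp * exp(1i * ph)
    full <- complex(real = numeric(n_samp))
    full[2:(n_half + 1)] <- spec_half
    if (n_samp %% 2 == 0) {
      # real Nyquist bin
      full[n_half + 1] <- complex(real = amp[n_half], imaginary = 0)
      full[seq(n_samp, n_half + 2)] <- Conj(spec_half[seq_len(n_half - 1)])
    } else {
      full[seq(n_samp, n_half + 2)] <- Conj(spec_half[seq_len(n_half - 1)])
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n_samp
    x <- x / stats::sd(x)
    X[ch, ] <- x
  }
  if (spec$noise_sd > 0) X <- X + spec$noise_sd * 0.05 * matrix(stats::rnorm(n * n_samp), n, n_samp)
  recording(X, fs,
            events = data.frame(label = "rest", onset = 1L, offset = n_samp,
                                stringsAsFactors = FALSE))
}

#' Multi-subject study design
#'
#' Describes a within-subject crossed design of test sessions x task
#' scenarios with a per-cell effect map controlling the ground-truth coupling
#' of the generator. The default reproduces a 4-test x 4-scenario x 4-trial
#' protocol in which coupling density declines with scenario difficulty in
#' the later ("post-schema") sessions.
#'
#' @param n_subjects Number of subjects.
#' @param tests Ordered test-session labels.
#' @param scenarios Ordered scenario (difficulty) labels.
#' @param trials_per_scenario Trials per (test, scenario) cell.
#' @param effect_map data.frame with columns `test`, `scenario`, `density`,
#'   `strength` covering every cell: `density` is the fraction of channel
#'   pairs coupled, `strength` the coupling strength of coupled pairs.
#' @param n_channels,sample_rate,duration,noise_sd Passed to the per-trial
#'   [oscillator_spec()].
#' @param rest_duration Rest-recording length in seconds.
#' @param alpha_peak_mean,alpha_peak_sd Population distribution of subject
#'   alpha peaks, Hz.
#' @param seed Top-level seed; every recording derives its own seed from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 10,
                         tests = paste0("T", 1:4),
                         scenarios = paste0("L", 0:3),
                         trials_per_scenario = 4,
                         effect_map = NULL,
                         n_channels = 24, sample_rate = 1000, duration = 60,
                         noise_sd = 1, rest_duration = 120,
                         alpha_peak_mean = 10, alpha_peak_sd = 0.8,
                         seed = 1L) {
  if (is.null(effect_map)) {
    effect_map <- default_effect_map(tests, scenarios)
  }
  need <- expand.grid(test = tests, scenario = scenarios, stringsAsFactors = FALSE)
  key <- paste(effect_map$test, effect_map$scenario)
  missing <- !(paste(need$test, need$scenario) %in% key)
  if (any(missing)) {
    stop("effect_map is missing cells: ",
         paste(paste(need$test[missing], need$scenario[missing]), collapse = ", "))
  }
  structure(
    list(n_subjects = n_subjects, tests = tests, scenarios = scenarios,
         trials_per_scenario = trials_per_scenario, effect_map = effect_map,
         n_channels = n_channels, sample_rate = sample_rate,
         duration = duration, noise_sd = noise_sd,
         rest_duration = rest_duration,
         alpha_peak_mean = alpha_peak_mean, alpha_peak_sd = alpha_peak_sd,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Default effect map: density declines with difficulty after schema formation
#'
#' Early sessions get a flat coupling density (networks still reorganizing);
#' sessions from the midpoint on get density decreasing with scenario
#' difficulty, the qualitative pattern the pipeline is meant to recover.
#'
#' @param tests,scenarios Ordered labels.
#' @return data.frame with columns test, scenario, density, strength.
#' @export
default_effect_map <- function(tests = paste0("T", 1:4),
                               scenarios = paste0("L", 0:3)) {
  grid <- expand.grid(test = tests, scenario = scenarios,
                      stringsAsFactors = FALSE)
  n_sc <- length(scenarios)
  dens_late <- c(0.5, 0.3, 0.2, 0.15)[seq_len(n_sc)]
  post_schema <- match(grid$test, tests) > length(tests) / 2
  grid$density <- ifelse(post_schema, dens_late[match(grid$scenario, scenarios)], 0.35)
  grid$strength <- 0.8
  grid
}

# Deterministic per-recording seed from the design seed and indices.
# Multiplicative hash kept below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, subject, test_idx, scenario_idx = 0L, trial = 0L) {
  s <- (seed + 1e5 * subject + 1e4 * test_idx + 1e3 * scenario_idx + trial)
  as.integer((s * 48271) %% 2147483647)
}

# random symmetric coupling structure at a given density, with phase lags
# bounded away from 0 and pi so the imaginary cross-spectrum has mass
random_coupling <- function(n, density, strength, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  C <- matrix(0, n, n)
  L <- matrix(0, n, n)
  ut <- which(upper.tri(C))
  on_idx <- ut[stats::runif(length(ut)) < density]
  C[on_idx] <- strength
  L[on_idx] <- sample(c(-1, 1), length(on_idx), replace = TRUE) *
    stats::runif(length(on_idx), pi / 4, 3 * pi / 4)
  C <- C + t(C)
  L <- L - t(L)
  list(coupling = C, phase_lags = L)
}

#' Generate a full synthetic study
#'
#' Emits one task recording per (subject, test, scenario, trial) plus pre-
#' and post-session rest recordings, together with a tidy label table. The
#' per-cell coupling density and strength follow the design's effect map;
#' each subject draws an alpha peak from the population distribution, and
#' every recording is regenerable in isolation from its derived seed.
#'
#' @param design A [study_design()].
#' @param verbose Print a progress line per subject.
#' @return list with elements `task` (named list of recordings), `rest`
#'   (named list, two per subject x test), `labels` (data.frame subject,
#'   test, scenario, trial, id) and `alpha_peaks` (per-subject Hz).
#' @export
generate_study <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  em <- design$effect_map
  task <- list()
  rest <- list()
  labels <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)
  alpha_peaks <- stats::rnorm(design$n_subjects, design$alpha_peak_mean,
                              design$alpha_peak_sd)
  alpha_peaks <- pmin(pmax(alpha_peaks, 8), 12)

  for (s in seq_len(design$n_subjects)) {
    if (verbose) message(sprintf("subject %d/%d", s, design$n_subjects))
    for (ti in seq_along(design$tests)) {
      tlab <- design$tests[ti]
      for (which_rest in 1:2) {
        rseed <- derive_seed(design$seed, s, ti, 99L, which_rest)
        rspec <- oscillator_spec(
          n_channels = design$n_channels, sample_rate = design$sample_rate,
          duration = design$rest_duration, alpha_peak = alpha_peaks[s],
          noise_sd = design$noise_sd, seed = rseed)
        rid <- sprintf("S%02d_%s_rest%d", s, tlab, which_rest)
        rest[[rid]] <- generate_rest(rspec)
      }
      for (si in seq_along(design$scenarios)) {
        slab <- design$scenarios[si]
        cell <- em[em$test == tlab & em$scenario == slab, ]
        for (tr in seq_len(design$trials_per_scenario)) {
          tseed <- derive_seed(design$seed, s, ti, si, tr)
          cp <- random_coupling(design$n_channels, cell$density[1],
                                cell$strength[1], tseed)
          tspec <- oscillator_spec(
            n_channels = design$n_channels, sample_rate = design$sample_rate,
            duration = design$duration, carrier_band = c(4, 8),
            coupling = cp$coupling, phase_lags = cp$phase_lags,
            noise_sd = design$noise_sd, seed = tseed)
          id <- sprintf("S%02d_%s_%s_tr%d", s, tlab, slab, tr)
          rec <- generate_task_epoch(tspec)
          rec$events$label <- slab
          task[[id]] <- rec
          labels[[length(labels) + 1L]] <- data.frame(
            subject = sprintf("S%02d", s), test = tlab, scenario = slab,
            trial = tr, id = id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(task = task, rest = rest, labels = do.call(rbind, labels),
       alpha_peaks = alpha_peaks)
}

# save/restore the global RNG state so generator calls are referentially
# transparent with respect to the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
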