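test_that("oscillator_spec validates coupling, lags and mixing", {
  C <- matrix(0, 3, 3); C[1, 2] <- 0.5  # not symmetric
  expect_error(oscillator_spec(n_channels = 3, coupling = C), "symmetric")
  Cs <- C + t(C)
  L <- matrix(0, 3, 3); L[1, 2] <- 0.3; L[2, 1] <- 0.3  # not antisymmetric
  expect_error(oscillator_spec(n_channels = 3, coupling = Cs, phase_lags = L),
               "antisymmetric")
  expect_error(oscillator_spec(n_channels = 3, mixing = diag(2)), "square")
  bad <- Cs; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(oscillator_spec(n_channels = 3, coupling = bad), "\\[0, 1\\]")
  sp <- oscillator_spec(n_channels = 3, sample_rate = 250, duration = 10)
  expect_s3_class(sp, "oscillator_spec")
  expect_equal(sp$mixing, diag(3))
})

test_that("generation is deterministic in the seed and leaves the caller's RNG alone", {
  sp <- oscillator_spec(n_channels = 3, sample_rate = 250, duration = 5, seed = 42)
  set.seed(999)
  r1 <- generate_task_epoch(sp)
  after1 <- rnorm(1)
  set.seed(999)
  r2 <- generate_task_epoch(sp)
  after2 <- rnorm(1)
  expect_identical(r1$data, r2$data)
  expect_identical(after1, after2)
  r3 <- generate_task_epoch(oscillator_spec(n_channels = 3, sample_rate = 250,
                                            duration = 5, seed = 43))
  expect_false(identical(r1$data, r3$data))
  rest1 <- generate_rest(sp)
  rest2 <- generate_rest(sp)
  expect_identical(rest1$data, rest2$data)
})

test_that("a fully coupled noise-free pair locks at the prescribed quarter-cycle lag", {
  C <- matrix(c(0, 1, 1, 0), 2)
  L <- matrix(c(0, pi / 2, -pi / 2, 0), 2)
  sp <- oscillator_spec(n_channels = 2, sample_rate = 250, duration = 12,
                        coupling = C, phase_lags = L, noise_sd = 0,
                        phase_noise_sd = 0, coupling_gain = 25, seed = 3)
  z <- analytic_signals(generate_task_epoch(sp), c(4, 8))
  expect_equal(wpli(z[1, ], z[2, ]), 1)
})

test_that("uncoupled channels show chance-level wPLI at condition-level pooling", {
  vals <- sapply(1:8, function(s) {
    segs <- lapply(1:6, function(k) {
      sp <- oscillator_spec(n_channels = 3, sample_rate = 250, duration = 60,
                            seed = s * 100 + k)
      analytic_signals(generate_task_epoch(sp), c(4, 8))
    })
    cm <- connectivity_matrix(segs, band = c(4, 8))
    mean(cm$values[upper.tri(cm$values)])
  })
  expect_lt(mean(vals), 0.05)
})

test_that("pure zero-lag leakage of independent sources yields chance-level wPLI", {
  mix <- matrix(1 / 3, 3, 3)  # all-ones row-normalized: pure common-source leakage
  vals <- sapply(1:6, function(s) {
    segs <- lapply(1:6, function(k) {
      sp <- oscillator_spec(n_channels = 3, sample_rate = 250, duration = 60,
                            mixing = mix, seed = 5000 + s * 100 + k)
      analytic_signals(generate_task_epoch(sp), c(4, 8))
    })
    cm <- connectivity_matrix(segs, band = c(4, 8))
    mean(cm$values[upper.tri(cm$values)])
  })
  expect_lt(mean(vals), 0.05)
})

test_that("rest spectra peak at the requested alpha frequency and order correctly", {
  iapf_at <- function(peak, seed) {
    sp <- oscillator_spec(n_channels = 3, sample_rate = 250, duration = 40,
                          alpha_peak = peak, seed = seed)
    estimate_iapf_cog(generate_rest(sp))$iapf
  }
  expect_lt(abs(iapf_at(10, 1) - 10), 0.5)
  ord <- sapply(1:8, function(s) iapf_at(8, s) < iapf_at(12, s + 100))
  expect_true(all(ord))
  expect_error(generate_rest(oscillator_spec(n_channels = 2, sample_rate = 100,
                                             duration = 20, alpha_peak = 60)),
               "Nyquist")
})

test_that("study design enforces the crossed effect map and default trial counts", {
  expect_error(
    study_design(effect_map = data.frame(test = "T1", scenario = "L0",
                                         density = 0.3, strength = 0.8)),
    "missing cells")
  d <- study_design(n_subjects = 1)
  expect_equal(length(d$tests) * length(d$scenarios) * d$trials_per_scenario / 4,
               16)  # 16 trials per test session
})

test_that("generate_study emits 16 task recordings per session and tidy labels", {
  d <- study_design(n_subjects = 1, n_channels = 3, sample_rate = 250,
                    duration = 2, rest_duration = 11, seed = 5)
  st <- generate_study(d)
  per_session <- table(st$labels$test)
  expect_true(all(per_session == 16))
  expect_equal(nrow(st$labels), 64)
  expect_equal(length(st$rest), 2 * 4)  # pre+post per session
  expect_setequal(names(st$labels), c("subject", "test", "scenario", "trial", "id"))
  # minimal design: one task recording plus two rests
  d1 <- study_design(n_subjects = 1, tests = "T1", scenarios = "L0",
                     trials_per_scenario = 1, n_channels = 2, sample_rate = 250,
                     duration = 2, rest_duration = 11, seed = 6)
  st1 <- generate_study(d1)
  expect_equal(length(st1$task), 1L)
  expect_equal(length(st1$rest), 2L)
})

test_that("any single trial is regenerable in isolation from its derived seed", {
  d <- study_design(n_subjects = 2, tests = c("T1", "T2"), scenarios = c("L0", "L1"),
                    trials_per_scenario = 2, n_channels = 3, sample_rate = 250,
                    duration = 3, rest_duration = 11, seed = 11)
  st <- generate_study(d)
  cell <- d$effect_map[d$effect_map$test == "T2" & d$effect_map$scenario == "L1", ]
  tseed <- thetanet:::derive_seed(11L, 2, 2, 2, 1)
  cp <- thetanet:::random_coupling(3, cell$density, cell$strength, tseed)
  sp <- oscillator_spec(n_channels = 3, sample_rate = 250, duration = 3,
                        coupling = cp$coupling, phase_lags = cp$phase_lags,
                        noise_sd = d$noise_sd, seed = tseed)
  expect_identical(generate_task_epoch(sp)$data, st$task[["S02_T2_L1_tr1"]]$data)
})

test_that("channel amplitude rescaling leaves wPLI unchanged end to end", {
  sp <- oscillator_spec(n_channels = 3, sample_rate = 250, duration = 10,
                        seed = 21)
  rec <- generate_task_epoch(sp)
  scaled <- rec
  scaled$data[2, ] <- 40 * scaled$data[2, ]
  z1 <- analytic_signals(rec, c(4, 8))
  z2 <- analytic_signals(scaled, c(4, 8))
  # not bit-exact: sign(Im S) is discontinuous at 0, so rounding after the
  # linear filter chain can flip individual near-zero samples
  expect_equal(wpli(z1[1, ], z1[2, ]), wpli(z2[1, ], z2[2, ]), tolerance = 1e-6)
})

test_that("with no coupling, median thresholding forces half density with no pair preference", {
  n_ch <- 8
  n_pairs <- n_ch * (n_ch - 1) / 2
  counts <- numeric(n_pairs)
  densities <- numeric(30)
  for (s in 1:30) {
    segs <- lapply(1:2, function(k) {
      sp <- oscillator_spec(n_channels = n_ch, sample_rate = 250, duration = 12,
                            seed = 7000 + s * 10 + k)
      analytic_signals(generate_task_epoch(sp), c(4, 8))
    })
    cm <- connectivity_matrix(segs, band = c(4, 8))
    g <- binarize(cm, median(cm$values[upper.tri(cm$values)]))
    densities[s] <- g$density
    counts <- counts + g$adjacency[upper.tri(g$adjacency)]
  }
  expect_true(all(abs(densities - 0.5) < 0.05))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})
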