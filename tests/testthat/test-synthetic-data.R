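test_that("parameter constructors validate their domains", {
  expect_error(neuron_params(c_m = -1), "positive")
  expect_error(neuron_params(v_reset = 10, v_peak = 0), "below v_peak")
  expect_error(neuron_params(g_h = -0.1), ">= 0")
  expect_error(epsc_sim_params(rise_tau = 5, decay_tau = 2), "rise_tau")
  expect_error(epsc_sim_params(failure_prob = 1.5), "failure_prob")
  expect_error(epsc_sim_params(block_fraction = -0.1), "block_fraction")
  expect_error(qpcr_sim_params(true_relative_abundance = c(Pvalb = -1)),
               "cover every gene|positive")
  expect_error(qpcr_sim_params(reference_genes = "NotAGene"), "subset")
})

test_that("subthreshold simulation obeys the Ohmic steady-state limit", {
  p <- fs_preset_quiet(g_h = 0, a = 0, b = 0)
  rec <- simulate_current_clamp(p, step_protocol(c(-100, -50)), seed = 1)
  sw <- rec$sweeps[[1]]
  base <- baseline_window(sw, 100)$mean
  idx <- sweep_times(sw) >= 550 & sweep_times(sw) < 600   # last 10% of step
  defl <- mean(sw$samples[idx]) - base
  expect_equal(defl, -100 / 3, tolerance = 0.01)          # I * R, R = 1/g_L
  expect_equal(base, -66, tolerance = 1e-6)
})

test_that("subthreshold relaxation has time constant C/g_L", {
  # independent oracle: log-linear regression of the approach to steady state
  p <- fs_preset_quiet(g_h = 0, a = 0, b = 0, c_m = 60, g_l = 4)
  rec <- simulate_current_clamp(p, step_protocol(c(-100, -50)), seed = 1)
  sw <- rec$sweeps[[1]]
  t <- sweep_times(sw)
  base <- baseline_window(sw, 100)$mean
  idx <- which(t > 100 & t <= 160)
  v_ss <- mean(sw$samples[t >= 550 & t < 600])
  y <- log(abs(v_ss - sw$samples[idx]))
  tau_fit <- -1 / coef(lm(y ~ t[idx]))[[2]]
  expect_equal(tau_fit, 60 / 4, tolerance = 0.02)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  p <- neuron_params()                       # noise on
  proto <- step_protocol(c(-100, 300))
  a <- simulate_current_clamp(p, proto, seed = 99)
  b <- simulate_current_clamp(p, proto, seed = 99)
  expect_identical(lapply(a$sweeps, `[[`, "samples"),
                   lapply(b$sweeps, `[[`, "samples"))
  expect_identical(spike_log(a), spike_log(b))
  c2 <- simulate_cracm_sweeps(epsc_sim_params(), seed = 5)
  d2 <- simulate_cracm_sweeps(epsc_sim_params(), seed = 5)
  expect_identical(c2$control$sweeps[[3]]$samples,
                   d2$control$sweeps[[3]]$samples)
  expect_identical(simulate_qpcr_plate(qpcr_sim_params(), seed = 2)$ct,
                   simulate_qpcr_plate(qpcr_sim_params(), seed = 2)$ct)
})

test_that("H-conductance controls the hyperpolarization sag", {
  proto <- step_protocol(c(-100, -60, -20))
  rec0 <- simulate_current_clamp(fs_preset_quiet(g_h = 0), proto, seed = 3)
  expect_equal(suppressWarnings(sag_ratio(rec0)), 1, tolerance = 0.01)
  rec1 <- simulate_current_clamp(fs_preset_quiet(), proto, seed = 3)
  expect_lt(sag_ratio(rec1), 1)
})

test_that("spike count is non-decreasing in current without adaptation", {
  p <- fs_preset_quiet(a = 0, b = 0)
  rec <- simulate_current_clamp(p, step_protocol(seq(0, 1500, by = 100)),
                                seed = 4)
  counts <- lengths(spike_log(rec))
  expect_true(all(diff(counts) >= 0))
})

test_that("CRACM generator honors failure and block limits", {
  flat <- simulate_cracm_sweeps(
    epsc_sim_params(failure_prob = 1, noise_sd = 0), seed = 1)
  expect_true(all(vapply(flat$control$sweeps,
                         function(s) all(s$samples == 0), TRUE)))
  blk <- simulate_cracm_sweeps(
    epsc_sim_params(block_fraction = 0, noise_sd = 0), seed = 1)
  expect_true(all(vapply(blk$blocked$sweeps,
                         function(s) all(s$samples == 0), TRUE)))
  expect_equal(blk$control$sweeps[[1]]$mode, "voltage_clamp")
})

test_that("measured amplitude of generated EPSCs matches the ground truth", {
  # Monte-Carlo oracle: across seeds, the averaged-trace amplitude scatters
  # around 60 pA with sd ~ noise_sd/sqrt(n_sweeps)
  p <- epsc_sim_params(true_amplitude = 60, noise_sd = 2, n_sweeps = 10,
                       latency_jitter_sd = 0)
  amps <- vapply(1:10, function(s) {
    out <- simulate_cracm_sweeps(p, seed = s)
    measure_epsc(average_aligned_sweeps(out$control, 10))$mean_amplitude
  }, 0)
  expect_true(all(abs(amps - 60) < 3 * 2 / sqrt(10) + 1))
  expect_lt(abs(mean(amps) - 60), 2)
})

test_that("qPCR plate Ct differences encode log2 abundance ratios", {
  p <- qpcr_sim_params(genes = c("A", "B"),
                       true_relative_abundance = c(A = 2, B = 1),
                       reference_genes = "A", replicate_sd = 0, n_cells = 2)
  plate <- simulate_qpcr_plate(p, seed = 1)
  ct_a <- plate$ct[plate$gene == "A"][1]
  ct_b <- plate$ct[plate$gene == "B"][1]
  expect_equal(ct_b - ct_a, 1)               # abundance ratio 2 -> 1 cycle
  p_drop <- qpcr_sim_params(dropout_prob = 1)
  expect_true(all(is.na(simulate_qpcr_plate(p_drop, seed = 1)$ct)))
})

test_that("the qPCR pipeline recovers a known abundance vector", {
  p <- qpcr_sim_params(genes = c("G1", "G2", "G3", "R"),
                       true_relative_abundance = c(G1 = 1, G2 = 0.5,
                                                   G3 = 0.25, R = 4),
                       reference_genes = "R", replicate_sd = 0.1,
                       n_cells = 8)
  plate <- simulate_qpcr_plate(p, seed = 11)
  ra <- qpcr_pipeline(plate, targets = c("G1", "G2", "G3"),
                      references = "R", calibrator = "none")
  est <- vapply(c("G1", "G2", "G3"),
                function(g) mean(ra$value[ra$gene == g]), 0)
  truth <- c(1, 0.5, 0.25) / 4               # relative to the reference gene
  expect_true(all(abs(est - truth) / truth < 0.2))
})
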