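P <- laser_params()

test_that("rate equations evaluate exactly as written", {
  # spontaneous term alone: I = 0, G - Q - 1 arbitrary
  r <- yamada_rates(laser_state(I = 0, G = 1.25, Q = 2), mu1 = 1.25, P)
  expect_equal(unname(r["dI"]), 1e-4 * (1.25 + 1.4)^2)  # 7.0225e-4
  expect_equal(unname(r["dG"]), 0)
  expect_equal(unname(r["dQ"]), 0)

  # with a vanishing spontaneous source, (0, mu0, mu2) is the off state
  tiny <- laser_params(beta = 1e-12)
  r0 <- yamada_rates(laser_state(I = 0, G = 0.8, Q = 2), mu1 = 0.8, tiny)
  expect_equal(unname(r0[c("dG", "dQ")]), c(0, 0))
  expect_lt(abs(r0["dI"]), 1e-10)

  # dark state at zero pump
  rd <- yamada_rates(laser_state(I = 0, G = 0, Q = 1.5), mu1 = 0, tiny)
  expect_equal(unname(rd["dQ"]), tiny$gamma_Q * (tiny$mu2 - 1.5))

  expect_error(yamada_rates(laser_state(0, 1, 1), mu1 = NaN, P), "finite")
  expect_error(laser_state(I = Inf, G = 1, Q = 1), "finite")
})

test_that("the quiet steady state is a fixed point with tiny residuals", {
  for (mu0 in c(0.5, 1.25, 2.0, 2.65)) {
    st <- steady_state(P, mu0)
    r <- yamada_rates(st, mu0, P)
    expect_lt(max(abs(r)), 1e-10)
    expect_gte(st$I, 0)
  }
  # above the fold of the quiet branch there is no excitable rest state
  expect_error(steady_state(P, 2.9), "quiet state")
})

test_that("integration from the quiet state stays on the fixed point", {
  for (mu0 in c(1.25, 2.4)) {
    st <- steady_state(P, mu0)
    pr <- pump_program("0", mu0 = mu0, c = 0, tau_b = 1, tau_p = 1,
                       t_pad = 1e4 - 1)
    tr <- integrate_laser(P, pr, init = st)
    expect_lt(max(abs(tr$I - st$I)), 1e-6)
    expect_lt(max(abs(tr$G - st$G)), 1e-6)
    expect_lt(max(abs(tr$Q - st$Q)), 1e-6)
  }
})

test_that("trajectories keep non-negative intensity and exact net gain", {
  for (bits in c("00111", "10101", "11111")) {
    pr <- pump_program(bits, 1.25, 6, t_pad = 500)
    tr <- integrate_laser(P, pr)
    expect_true(all(tr$I >= 0))
    expect_equal(tr$R, tr$G - tr$Q - 1)
    expect_true(all(diff(tr$times) > 0))
  }
})

test_that("halving solver tolerances leaves the trajectory unchanged", {
  pr <- pump_program("00111", 1.25, 6, t_pad = 500)
  a <- integrate_laser(P, pr, rtol = 1e-8, atol = 1e-12)
  b <- integrate_laser(P, pr, rtol = 5e-9, atol = 5e-13)
  ia <- a$I[length(a$I)]
  ib <- b$I[length(b$I)]
  expect_lt(abs(ia - ib) / abs(ib), 1e-6)
})

test_that("adaptive solution matches a fixed-step RK4 oracle", {
  pr <- pump_program("00111", 1.25, 6, t_pad = 300)
  tr <- integrate_laser(P, pr)
  or <- rk4_integrate(P, pr, dt = 0.01)
  # compare the spike peak: height to 1e-5 relative, position to the
  # sampling resolution
  expect_equal(max(tr$I), max(or$I), tolerance = 1e-5)
  expect_lt(abs(tr$times[which.max(tr$I)] - or$times[which.max(or$I)]), 0.51)
  n <- length(tr$I)
  expect_equal(tr$I[n], or$final[1], tolerance = 1e-4)
})

test_that("three summed perturbations elicit exactly one spike", {
  # net gain crosses zero during the 3-run and a single pulse results
  pr <- pump_program("00111", 1.25, 6, t_pad = 1500)
  tr <- integrate_laser(P, pr)
  expect_gt(max(tr$R), 0)
  sp <- detect_spikes(tr)
  expect_length(sp$peak_times, 1)
  expect_gt(sp$peak_intensities[1], 1)
})

test_that("constant pump above laser threshold gives a pulse train", {
  pr <- pump_program("0", mu0 = 3.2, c = 0, tau_b = 1, tau_p = 1,
                     t_pad = 4999)
  init <- steady_state(P, 2.0)
  tr <- integrate_laser(P, pr, init = init)
  expect_gte(length(detect_spikes(tr)$peak_times), 2)
})

test_that("spike detection finds peaks above threshold, separated in time", {
  # constructed trajectories, no solver involved
  tt <- seq(0, 400, by = 0.5)
  bump <- function(t0) 5 * exp(-((tt - t0) / 4)^2)
  mk_traj <- function(I) structure(list(times = tt, I = I, G = I * 0,
                                        Q = I * 0, R = I * 0 - 1),
                                   class = "laser_trajectory")
  expect_length(detect_spikes(mk_traj(rep(1e-4, length(tt))))$peak_times, 0)

  one <- detect_spikes(mk_traj(1e-4 + bump(120)), threshold = 1)
  expect_equal(one$peak_times, 120)
  expect_equal(one$peak_intensities, max(1e-4 + bump(120)))

  # two peaks 30 apart violate min_separation: the earlier one is kept
  two <- detect_spikes(mk_traj(1e-4 + bump(120) + bump(150)), threshold = 1,
                       min_separation = 50)
  expect_equal(two$peak_times, 120)
  both <- detect_spikes(mk_traj(1e-4 + bump(120) + bump(300)), threshold = 1)
  expect_equal(both$peak_times, c(120, 300))
})

test_that("latency is measured from stimulus onset, Inf without a spike", {
  quiet <- neuron_response("00000", 1.25, 6)
  expect_equal(first_spike_latency(quiet), Inf)
  l3 <- first_spike_latency(neuron_response("11100", 1.25, 6))
  l4 <- first_spike_latency(neuron_response("11110", 1.25, 6))
  expect_true(is.finite(l3))
  expect_lte(l4, l3)  # saturated well above threshold: equal is allowed
  # near threshold the stronger stimulus is strictly earlier
  l3n <- first_spike_latency(neuron_response("11100", 2.6, 0.7))
  l4n <- first_spike_latency(neuron_response("11110", 2.6, 0.7))
  expect_lt(l4n, l3n)
})

test_that("latency is non-increasing in the pulse amplitude", {
  lats <- vapply(c(0.37, 0.5, 0.7, 1.0), function(cc)
    first_spike_latency(neuron_response("11100", 2.65, cc)), 0)
  expect_true(all(diff(lats) <= 0))
})

test_that("the spike outcome depends on pulse energy tau_p * c", {
  # same energy, twice the amplitude at half the duration
  fires <- function(tau_p, cc) is.finite(first_spike_latency(
    neuron_response("11100", 1.25, cc, tau_p = tau_p, t_pad = 2000)))
  expect_true(fires(10, 18))
  expect_true(fires(5, 36))
  expect_false(fires(10, 12))
  expect_false(fires(5, 24))
})

test_that("a second pulse within the refractory period is absorbed", {
  # c = 14 makes a single isolated pulse supra-threshold
  far <- neuron_response(c(1, rep(0, 19), 1, rep(0, 5)), 1.25, 14,
                         t_pad = 2000, use_cache = FALSE)
  expect_length(far$peak_times, 2)
  near <- neuron_response("11000", 1.25, 14, t_pad = 2000, use_cache = FALSE)
  expect_length(near$peak_times, 1)
})

test_that("delayed programs shift spikes by exactly the delay", {
  s0 <- neuron_response("00111", 1.25, 6)
  sd <- neuron_response("00111", 1.25, 6, tau_d = 123)
  expect_equal(sd$peak_times, s0$peak_times + 123)
  # equivariance holds for a genuinely re-integrated delayed program
  prog <- pump_program("00111", 1.25, 6, tau_d = 123, t_pad = 3000)
  tr <- integrate_laser(P, prog)
  re <- detect_spikes(tr)
  expect_equal(re$peak_times, s0$peak_times + 123, tolerance = 1e-6)
})
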