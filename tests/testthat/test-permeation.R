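test_that("single scripted traversals obey the hysteresis contract", {
  # resident ion: never leaves one side
  z_res <- rnorm(60, mean = -20, sd = 1)
  expect_equal(nrow(detect_crossings(scripted_trajectory(z_res))), 0)

  # monotone -20 -> +20 path with small jitter: exactly one event, +1
  z <- seq(-20, 20, length.out = 80) + sin(seq_len(80)) * 2
  ev <- detect_crossings(scripted_trajectory(z))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, 1L)

  # double-back inside the gate must not double count
  z_db <- c(seq(-20, 8, length.out = 30), seq(8, -8, length.out = 10),
            seq(-8, 20, length.out = 30))
  ev_db <- detect_crossings(scripted_trajectory(z_db))
  expect_equal(nrow(ev_db), 1)

  # periodic wrap resets state without an event
  z_wrap <- c(seq(-20, -25, length.out = 10), seq(28, 20, length.out = 10))
  ev_w <- detect_crossings(scripted_trajectory(z_wrap))
  expect_equal(nrow(ev_w), 0)

  # mid-plane passage outside the pore radius is rejected
  z_out <- seq(-20, 20, length.out = 40)
  x_out <- matrix(20, 40, 1)
  ev_o <- detect_crossings(scripted_trajectory(z_out, x = x_out))
  expect_equal(nrow(ev_o), 0)
})

test_that("the event detector agrees with a brute-force state machine", {
  set.seed(42)
  n_ions <- 50; n_frames <- 400
  z <- matrix(0, n_frames, n_ions)
  for (p in seq_len(n_ions)) {
    z[, p] <- cumsum(c(runif(1, -25, 25), rnorm(n_frames - 1, sd = 3)))
    z[, p] <- ((z[, p] + 30) %% 60) - 30   # periodic wraps included
  }
  traj <- scripted_trajectory(z, species = rep(c("K", "Cl"), 25))
  got <- detect_crossings(traj, gate_halfwidth = 10)
  want <- brute_force_crossings(traj, g = 10)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$time, want$time)
  expect_equal(got$direction, want$direction)
  expect_equal(got$id, want$id)
})

test_that("reversing time flips every event and negates the charge", {
  tr <- simulate_pore_bd(channel_spec(), duration = 30, dt = 0.005, seed = 13)
  ev <- detect_crossings(tr)
  rev_tr <- tr
  rev_tr$coords <- tr$coords[rev(seq_along(tr$times)), , , drop = FALSE]
  ev_r <- detect_crossings(rev_tr)
  expect_equal(nrow(ev_r), nrow(ev))
  q_fwd <- cumulative_charge(ev)
  q_rev <- cumulative_charge(ev_r)
  expect_equal(q_rev$q[length(q_rev$q)], -q_fwd$q[length(q_fwd$q)])
  # per-ion direction multiset is mirrored
  expect_equal(sort(ev_r$direction), sort(-ev$direction))
})

test_that("cumulative charge accumulates valence times direction", {
  # the open-state bookkeeping: 238 cation events down, 529 anion events up
  ev <- events_df(n_k = 238, n_cl = 529)
  qs <- cumulative_charge(ev)
  expect_equal(abs(qs$q[length(qs$q)]), 767)
  expect_equal(qs$q[1], 0)
  # every event moves the total by exactly one elementary charge
  expect_true(all(abs(qs$events$valence * qs$events$direction) == 1))

  # no events
  q0 <- cumulative_charge(events_df(), times = 0:10)
  expect_true(all(q0$q == 0))

  # one up then one down cancels
  ev2 <- data.frame(id = c(1, 1), species = "K", valence = 1L,
                    time = c(1, 2), direction = c(1L, -1L))
  q2 <- cumulative_charge(ev2, times = 0:3)
  expect_equal(q2$q[4], 0)

  # events outside the grid are an error
  expect_error(cumulative_charge(ev2, times = 0:1), "outside")
})

test_that("current estimation reproduces the printed arithmetic", {
  # renormalized slope of 1.534 e/ns with factor 0.586 is ~144 pA
  s1 <- synthetic_charge_series(1.534, duration = 500, noise_sd = 0)
  est1 <- estimate_current(s1, voltage = 40, renorm = 0.586)
  expect_equal(est1$current, 144.0, tolerance = 1e-3)

  # a current of 148.43 pA at 40 mV is a conductance of 3.71 nS
  slope <- 148.43 / 160.2176634
  est2 <- estimate_current(synthetic_charge_series(slope, noise_sd = 0),
                           voltage = 40)
  expect_equal(est2$current, 148.43, tolerance = 1e-6)
  expect_equal(round(est2$conductance, 2), 3.71)

  # flat series: zero current, undefined R2
  est3 <- estimate_current(synthetic_charge_series(0, noise_sd = 0),
                           voltage = 40)
  expect_equal(est3$current, 0)
  expect_equal(est3$conductance, 0)
  expect_true(is.na(est3$r_squared))

  expect_error(estimate_current(s1, voltage = 0), "voltage")
})

test_that("conductance is exactly linear in the renormalization factor", {
  s <- synthetic_charge_series(1.2, noise_sd = 0.3, seed = 4)
  g1 <- estimate_current(s, voltage = 40, renorm = 0.2)$conductance
  g2 <- estimate_current(s, voltage = 40, renorm = 0.6)$conductance
  expect_equal(g2 / g1, 3, tolerance = 1e-12)
})

test_that("renormalization factor is the plain diffusion ratio", {
  expect_equal(renormalization_factor(3.273e-5, 1.918e-5), 0.5860,
               tolerance = 1e-4)
  expect_equal(renormalization_factor(2e-5, 2e-5), 1)
  expect_equal(renormalization_factor(2e-5, 1e-5), 0.5)
  expect_error(renormalization_factor(0, 1e-5), "positive")
})

test_that("current ratio counts completed traversals irrespective of direction", {
  expect_equal(round(current_ratio(events_df(n_k = 238, n_cl = 529)), 1), 2.2)
  expect_equal(current_ratio(events_df(n_k = 100, n_cl = 100)), 1)
  expect_equal(round(current_ratio(events_df(n_k = 100, n_cl = 221)), 2), 2.21)
  expect_true(is.na(current_ratio(events_df(n_k = 0, n_cl = 10))))
  # direction-insensitive: flipping half the anion directions changes nothing
  ev <- events_df(n_k = 50, n_cl = 60)
  ev$direction[ev$species == "Cl"][1:30] <- -1L
  expect_equal(current_ratio(ev), 1.2)
})

test_that("field from voltage follows E = V / L with sign", {
  expect_equal(field_from_voltage(40, 90.2), 4.4346e6, tolerance = 1e-4)
  expect_equal(field_from_voltage(0, 90.2), 0)
  expect_equal(field_from_voltage(-40, 90.2), -field_from_voltage(40, 90.2))
  expect_error(field_from_voltage(40, 0), "positive")
})

test_that("MSD estimation flags non-diffusive signals", {
  # static particles
  coords <- array(0, c(120, 4, 3))
  tr0 <- ion_trajectory(seq(0, by = 0.1, length.out = 120), coords,
                        species = rep("K", 4), valence = rep(1L, 4),
                        box = c(100, 100, 100))
  expect_equal(estimate_diffusion_msd(tr0)$D_sim, 0)

  # pure drift: MSD grows like tau^2, log-log slope ~2, linearity flag off
  n <- 200
  coords <- array(0, c(n, 3, 3))
  for (k in 1:3) coords[, , k] <- matrix(seq(0, 19.9, by = 0.1), n, 3)
  trd <- ion_trajectory(seq(0, by = 0.1, length.out = n), coords,
                        species = rep("K", 3), valence = rep(1L, 3),
                        box = c(1000, 1000, 1000))
  de <- estimate_diffusion_msd(trd)
  expect_false(de$linear)
  expect_equal(de$loglog_slope, 2, tolerance = 0.01)
})

test_that("events export round-trips through CSV", {
  ev <- events_df(n_k = 5, n_cl = 3)
  path <- file.path(tempdir(), "events.csv")
  write_events_csv(ev, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 8)
  expect_named(back, c("id", "species", "valence", "time_ns", "direction"))
  unlink(path)
})
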