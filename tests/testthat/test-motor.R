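test_that("hand map is a unit-peak Gaussian inside the workspace", {
  h <- hand_map(c(22, 15), width = 1.5, size = 30)
  pk <- which(h == max(h), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(22, 15))
  expect_equal(max(h), 1)
  expect_equal(sum(h), 2 * pi * 1.5^2, tolerance = 0.01)
  expect_error(hand_map(c(0, 15), 1.5, 30))
})

test_that("displacement input encodes the hand-to-target offset", {
  n <- 30; c0 <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  centroid <- function(m) c(sum(m * rows), sum(m * cols)) / sum(m)
  # target blob exactly at the hand: peak at the map centre
  hand <- c(20, 15.5)
  fT <- gaussian_blob(hand, 1.5, n)
  d0 <- displacement_input(hand, fT, width = 1.5)
  expect_equal(centroid(d0), c(c0, c0), tolerance = 0.05)
  # target 5 px right of the hand: blob 5 px right of centre
  fT5 <- gaussian_blob(hand + c(0, 5), 1.5, n)
  d5 <- displacement_input(hand, fT5, width = 1.5)
  expect_equal(centroid(d5), c(c0, c0 + 5), tolerance = 0.05)
  # and 7 px up
  fTu <- gaussian_blob(hand + c(-7, 0), 1.5, n)
  du <- displacement_input(hand, fTu, width = 1.5)
  expect_equal(centroid(du), c(c0 - 7, c0), tolerance = 0.05)
  # zero target output -> zero map
  expect_equal(displacement_input(hand, matrix(0, n, n)),
               matrix(0, n, n))
})

test_that("displacement field rests at -5 and holds a driven blob", {
  cfg <- crt_config()
  n <- 30
  u <- matrix(cfg$disp$h, n, n)
  for (t in 1:100) u <- step_displacement_field(u, matrix(0, n, n),
                                                fp = cfg$disp)
  expect_lt(max(abs(u - cfg$disp$h)), 0.05)
  drive <- gaussian_blob(c(10, 10), 2, n) * 8
  for (t in 1:300) u <- step_displacement_field(u, drive, fp = cfg$disp)
  pk <- which(u == max(u), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(10, 10))
  expect_gt(max(u), 0)
  # doubling the drive never lowers the peak
  u2 <- matrix(cfg$disp$h, n, n)
  for (t in 1:300) u2 <- step_displacement_field(u2, 2 * drive,
                                                 fp = cfg$disp)
  expect_gte(max(u2), max(u))
})

test_that("the onset gate delays drive in proportion to s_prox", {
  expect_equal(onset_gate(0, 1), 1)
  expect_equal(onset_gate(0, 1000), 1)
  expect_equal(onset_gate(0.125, 1, steps_per_unit = 640), 0)
  expect_equal(onset_gate(0.125, 80, steps_per_unit = 640), 0)
  expect_equal(onset_gate(0.125, 81, steps_per_unit = 640), 1)
  expect_equal(onset_gate(0.35, 1e6), 1)    # always opens eventually
  # monotone non-decreasing in t
  g <- vapply(1:300, function(t) onset_gate(0.2, t, 640), 1)
  expect_true(all(diff(g) >= 0))
  expect_error(onset_gate(-0.1, 1))
})

test_that("velocity input is the gated displacement plus centre kick", {
  n <- 30
  zero_d <- matrix(0, n, n)
  iv <- velocity_input(zero_d, amp = 2, sigma = 3, gate = 1)
  pk <- which(iv == max(iv), arr.ind = TRUE)
  # unit-peak kick scaled by amp, sampled half a pixel off-centre
  expect_equal(max(iv), 2 * exp(-2 * 0.5^2 / (2 * 9)))
  expect_equal(mean(pk[, 1]), (n + 1) / 2)  # symmetric peak about centre
  expect_equal(velocity_input(zero_d, amp = 2, sigma = 3, gate = 0),
               zero_d)
  # a dominant displacement blob sets the input peak location
  d <- gaussian_blob(c(8, 20), 2, n) * 10 - 5
  iv2 <- velocity_input(d, amp = 2, sigma = 3, gate = 1)
  pk2 <- which(iv2 == max(iv2), arr.ind = TRUE)
  expect_equal(unname(pk2[1, ]), c(8, 20))
})

test_that("the two-layer velocity field stabilises and tracks a blob", {
  cfg <- crt_config()
  n <- 30
  v <- list(v1 = matrix(cfg$vel$h, n, n), v2 = matrix(cfg$vel$h, n, n))
  for (t in 1:150) v <- step_velocity_fields(v, matrix(0, n, n),
                                             fp = cfg$vel)
  expect_lt(max(field_sigmoid(v$v2, 4)), cfg$vel$move_threshold)
  drive <- gaussian_blob(c(10, 20), 2, n) * 8 - 5
  for (t in 1:300) v <- step_velocity_fields(v, drive, fp = cfg$vel)
  f2 <- field_sigmoid(v$v2, 4)
  expect_gt(max(f2), cfg$vel$move_threshold)
  pk <- which(f2 == max(f2), arr.ind = TRUE)
  expect_lt(sqrt(sum((pk[1, ] - c(10, 20))^2)), 1.01)  # tracks within 1 px
  # blob position follows the input when it moves
  drive2 <- gaussian_blob(c(14, 12), 2, n) * 8 - 5
  for (t in 1:300) v <- step_velocity_fields(v, drive2, fp = cfg$vel)
  f2b <- field_sigmoid(v$v2, 4)
  pkb <- which(f2b == max(f2b), arr.ind = TRUE)
  expect_lt(sqrt(sum((pkb[1, ] - c(14, 12))^2)), 1.01)
})

test_that("the readout moves the hand by the scaled blob offset", {
  cfg <- crt_config()
  n <- 30
  # subthreshold field: no movement
  sub <- matrix(cfg$vel$h, n, n)
  r <- readout_and_move(sub, c(22, 15.5), cfg$vel, gain = 0.1, dt = 1)
  expect_false(r$moved)
  expect_equal(r$position, c(22, 15.5))
  expect_equal(r$speed, 0)
  # a strong blob centred at the map centre commands a zero step
  centre_blob <- gaussian_blob(c(15.5, 15.5), 2, n) * 10 - 1
  r0 <- readout_and_move(centre_blob, c(22, 15.5), cfg$vel, gain = 0.1,
                         dt = 1, readout_sat = 0.1)
  expect_true(r0$moved)
  expect_equal(r0$speed, 0, tolerance = 1e-6)
  # blob 5 px left of centre, gain*dt = 0.1, saturated mass:
  # the hand moves exactly 0.5 px left
  left_blob <- gaussian_blob(c(15.5, 10.5), 2, n) * 10 - 1
  rl <- readout_and_move(left_blob, c(22, 15.5), cfg$vel, gain = 0.1,
                         dt = 1, readout_sat = 0.1)
  expect_equal(rl$position, c(22, 15.0), tolerance = 1e-6)
  expect_equal(rl$speed, 0.5, tolerance = 1e-6)
})
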