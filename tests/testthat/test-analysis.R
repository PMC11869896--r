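test_that("initiation latency matches the closed form on a linear ramp", {
  c_slope <- 0.002
  speeds <- c_slope * (1:100)
  gmax <- max(speeds)
  # threshold 0.1 * gmax = 0.02 -> crossing at t = 10 exactly
  il <- initiation_latency(speeds, gmax)
  expect_equal(il, 10, tolerance = 0.5)
  # different fraction
  il2 <- initiation_latency(speeds, gmax, frac = 0.5)
  expect_equal(il2, 50, tolerance = 0.5)
  # all-zero series: no movement
  expect_error(initiation_latency(rep(0, 50), gmax), "no movement")
})

test_that("initiation latency is stable under post-arrival padding", {
  t <- 1:120
  speeds <- 0.2 * exp(-(t - 50)^2 / (2 * 15^2))
  gmax <- max(speeds)
  il0 <- initiation_latency(speeds, gmax)
  il1 <- initiation_latency(c(speeds, rep(0, 60)), gmax)
  expect_equal(il0, il1, tolerance = 1)
})

test_that("maximum deviation equals the brute-force point-to-line oracle", {
  # oracle: projection-based point-to-line distance, checked point by point
  oracle <- function(pts, a, b) {
    u <- (b - a) / sqrt(sum((b - a)^2))
    max(vapply(seq_len(nrow(pts)), function(i) {
      v <- pts[i, ] - a
      sqrt(max(sum(v^2) - sum(v * u)^2, 0))
    }, 0))
  }
  set.seed(17)
  for (rep in 1:20) {
    pts <- matrix(cumsum(rnorm(40)), ncol = 2)
    a <- runif(2, -5, 5); b <- runif(2, 5, 15)
    expect_equal(max_deviation(pts, a, b), oracle(pts, a, b),
                 tolerance = 1e-10)
  }
  # geometry basics
  line_pts <- cbind(seq(0, 10, by = 0.5), seq(0, 20, by = 1))
  expect_equal(max_deviation(line_pts, c(0, 0), c(10, 20)), 0)
  expect_equal(max_deviation(rbind(c(0, 0), c(0, 1), c(10, 0)),
                             c(0, 0), c(10, 0)), 1)
  expect_error(max_deviation(line_pts, c(1, 1), c(1, 1)), "degenerate")
})

test_that("bell-shape scoring separates unimodal from bimodal profiles", {
  t <- 1:200
  bell <- exp(-(t - 100)^2 / (2 * 25^2))
  b1 <- bell_shape(bell)
  expect_true(b1$is_unimodal)
  expect_equal(b1$peak_time, 100, tolerance = 3)
  two <- exp(-(t - 60)^2 / (2 * 12^2)) + exp(-(t - 150)^2 / (2 * 12^2))
  expect_false(bell_shape(two)$is_unimodal)
  expect_false(bell_shape(rep(0.3, 50))$is_unimodal)
})

test_that("condition summaries aggregate and duplicate predictably", {
  ex <- run_experiment(crt_config(n_sets = 1, seed = 9, noise_sd = 0))
  s1 <- summarize_traces(ex$traces)
  doubled <- summarize_traces(c(ex$traces, ex$traces))
  expect_equal(doubled$mean_il, s1$mean_il)
  expect_equal(doubled$mean_md, s1$mean_md)
  expect_equal(doubled$n, 2 * s1$n)
})

test_that("normalised comparison behaves as a profile metric", {
  s <- data.frame(target_size = rep(c("small", "large"), each = 3),
                  distractor_config = rep(c("dd", "Dd", "DD"), 2),
                  target_position = "left",
                  mean_il = c(10, 8, 6, 9, 7, 5),
                  mean_md = c(1, 2, 1.5, 1.2, 2.2, 1.7))
  ref_same <- data.frame(s[1:3], il = s$mean_il, md = s$mean_md)
  cmp <- compare_reference(s, ref_same)
  expect_equal(cmp$sse_il, 0)
  expect_equal(cmp$sse_md, 0)
  expect_equal(cmp$sae_il, 0)
  # affine transformation of either side leaves the errors unchanged
  ref_aff <- transform(ref_same, il = 3 * il + 100, md = 0.5 * md - 2)
  cmp_aff <- compare_reference(s, ref_aff)
  expect_equal(cmp_aff$sse_il, 0, tolerance = 1e-12)
  expect_equal(cmp_aff$sse_md, 0, tolerance = 1e-12)
  # two-condition toy example: opposite normalised profiles
  s2 <- s[c(1, 2), ]
  s2$mean_il <- c(0, 1); s2$mean_md <- c(0, 1)
  ref2 <- data.frame(s2[1:3], il = c(1, 0), md = c(1, 0))
  cmp2 <- compare_reference(s2, ref2)
  expect_equal(cmp2$sse_il, 2)
  expect_equal(cmp2$sae_il, 2)
  # degenerate constant vectors are refused
  refc <- transform(ref_same, il = 1)
  expect_error(compare_reference(s, refc), "zero range")
  # key mismatches are named
  expect_error(compare_reference(s, ref_same[-1, ]), "missing conditions")
})
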