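test_that("sigmoid output is the increasing logistic", {
  expect_equal(field_sigmoid(0), 0.5)
  expect_equal(field_sigmoid(5, u0 = 5), 0.5)
  expect_equal(field_sigmoid(2, beta = 1), 1 / (1 + exp(-2)))
  expect_equal(field_sigmoid(1e3), 1)
  expect_equal(field_sigmoid(-1e3), 0)
  u <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(field_sigmoid(u, beta = 4)) > 0))
})

test_that("one competition step preserves symmetry and input order", {
  p <- crt_config()$competition
  u1 <- step_competition(c(0, 0, 0), c(0, 0, 0), p)
  expect_true(all(u1 == u1[1]))          # identical nodes move identically
  expect_true(u1[1] < 0)                 # pulled toward the resting level
  u2 <- step_competition(c(0, 0, 0), c(5.0, 4.6, 4.6), p)
  expect_gt(u2[1], u2[2])
  expect_equal(u2[2], u2[3])
  # with zero input and zero noise the nodes settle at a stable point
  u <- c(0, 0, 0)
  for (t in 1:2000) u <- step_competition(u, c(0, 0, 0), p)
  u_next <- step_competition(u, c(0, 0, 0), p)
  expect_equal(u, u_next, tolerance = 1e-6)
  expect_true(all(u < 0))
})

test_that("winner-takes-all selects the strongest input", {
  p <- crt_config()$competition
  expect_equal(run_wta(c(5.0, 4.6, 4.6), p)$winner, 1L)
  r <- run_wta(c(4.6, 4.6, 4.8), p)
  expect_equal(r$winner, 3L)
  expect_false(r$tie)
  expect_true(all(r$course >= 0 & r$course <= 1))
  # the time course ends with a dominant winner
  final <- r$course[nrow(r$course), ]
  expect_gt(final[3], 0.9)
  expect_lt(max(final[1:2]), 0.45)
  # exact ties are reported, never silently broken
  tie <- run_wta(c(4.6, 4.6, 4.6), p, max_steps = 500)
  expect_true(tie$tie)
  expect_true(is.na(tie$winner))
})

test_that("winner-takes-all is permutation equivariant", {
  p <- crt_config()$competition
  lv <- c(4.9, 4.5, 4.7)
  base <- run_wta(lv, p)$winner
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(1, 3, 2))) {
    w <- run_wta(lv[perm], p)$winner
    expect_equal(perm[w], base)
  }
})

test_that("coarse and dense Euler integration agree on the winner", {
  p <- crt_config()$competition
  set.seed(421)
  n_checked <- 0
  while (n_checked < 15) {
    lv <- runif(3, 4.4, 5.0)
    if (max(lv) - sort(lv, decreasing = TRUE)[2] < 0.1) next
    n_checked <- n_checked + 1
    expect_equal(run_wta(lv, p, 4000, dt = 1)$winner, which.max(lv))
    expect_equal(run_wta(lv, p, 4000, dt = 0.1)$winner, which.max(lv))
  }
})

test_that("location maps peak at the centroids with Gaussian mass", {
  items <- data.frame(centroid_row = c(15, 15), centroid_col = c(8, 23),
                      area = c(13, 13))
  maps <- location_maps(items, width = 1.5, size = 30)
  for (k in 1:2) {
    pk <- which(maps[[k]] == max(maps[[k]]), arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(items$centroid_row[k],
                                    items$centroid_col[k]))
    expect_equal(max(maps[[k]]), 1)
    expect_equal(sum(maps[[k]]), 2 * pi * 1.5^2, tolerance = 0.01)
  }
  # equidistant items give mirror-symmetric maps (col 8 vs col 23 about 15.5)
  expect_equal(maps[[1]], maps[[2]][, 30:1])
  # size scaling widens the blob of a larger item
  items2 <- data.frame(centroid_row = 15, centroid_col = 15,
                       area = c(26))
  wide <- location_maps(items2, width = 1.5, size = 30, size_exp = 1)[[1]]
  narrow <- location_maps(items2, width = 1.5, size = 30, size_exp = 0)[[1]]
  expect_gt(sum(wide), sum(narrow))
})

test_that("target field input combines node-weighted maps", {
  items <- data.frame(centroid_row = 10, centroid_col = c(8, 16, 24),
                      area = 13)
  maps <- location_maps(items, 1.5, 30)
  expect_equal(target_field_input(c(1, 0, 0), maps), maps[[1]])
  three <- target_field_input(c(0.5, 0.5, 0.5), maps)
  expect_equal(three[10, 8], three[10, 24])
  expect_equal(max(three), 0.5, tolerance = 1e-3)
})

test_that("target field holds a blob under sustained input", {
  cfg <- crt_config()
  n <- 30
  single <- gaussian_blob(c(15, 10), 1.5, n) * 3
  run_field <- function(input, steps = 300) {
    u <- matrix(cfg$tl$h, n, n)
    for (t in seq_len(steps)) u <- step_target_field(u, input, cfg$tl)
    u
  }
  # zero input: stays near the resting level
  rest <- run_field(matrix(0, n, n))
  expect_lt(max(abs(rest - cfg$tl$h)), 0.15)
  u1 <- run_field(single)
  pk <- which(u1 == max(u1), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(15, 10))
  expect_gt(field_sigmoid(max(u1), 4), 0.9)   # a formed blob
})

test_that("target field lateral interaction groups near blobs and
           suppresses far ones", {
  # point activation at the centre of a wide lattice: the interaction it
  # casts on its neighbourhood is excitatory at item spacing (8 px,
  # proximity grouping) and inhibitory beyond the kernel crossover
  # (~19 px for c_exc 3, s_exc 7.5 vs c_inh 1, s_inh 15)
  fp <- crt_config()$tl
  n <- 61
  ker <- reachfield:::make_kernel(fp$c_exc, fp$s_exc, fp$c_inh, fp$s_inh,
                                  fp$g_inh, n)
  f <- matrix(0, n, n); f[31, 31] <- 1
  inter <- reachfield:::field_interaction(f, ker)
  expect_gt(inter[31, 31 + 8], 0)
  expect_gt(inter[31, 31 + 14], 0)
  expect_lt(inter[31, 31 + 22], 0)
  expect_lt(inter[31, 31 + 28], 0)
})
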