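# Voting decoder: marginals, soft votes, full decode, and the Gaussian
# negative log-likelihood loss.

test_that("marginalize sums columns and rows and conserves mass", {
  h <- heatmap(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]] by row
  m <- marginalize(h)
  expect_equal(m$z_u, c(4, 6))
  expect_equal(m$z_v, c(3, 7))

  z <- marginalize(heatmap(matrix(0, 3, 3)))
  expect_equal(z$z_u, rep(0, 3))
  expect_equal(z$z_v, rep(0, 3))

  set.seed(11)
  g <- matrix(rnorm(35), 7, 5)  # w = 5, h = 7
  m <- marginalize(heatmap(g))
  brute <- 0
  for (r in 1:7) for (cl in 1:5) brute <- brute + g[r, cl]
  expect_equal(sum(m$z_u), brute)
  expect_equal(sum(m$z_v), brute)
  expect_length(m$z_u, 5)
  expect_length(m$z_v, 7)
})

test_that("heatmaps reject non-finite values and degenerate grids", {
  expect_error(heatmap(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
  expect_error(heatmap(matrix(c(1, Inf, 2, 3), 2, 2)), "non-finite")
  expect_error(heatmap(matrix(1:3, 1, 3)), "at least 2 x 2")
})

test_that("soft_vote matches the closed-form vote distribution", {
  sv <- soft_vote(c(0, 1, 0))
  expect_equal(sv$coord, 2)
  # softmax([0,1,0]) = (0.2119, 0.5761, 0.2119); sd = sqrt(2 * 0.2119)
  p <- ref_softmax(c(0, 1, 0))
  expect_equal(sv$uncertainty, sqrt(p[1] + p[3]), tolerance = 1e-12)
  expect_equal(sv$uncertainty, 0.65106, tolerance = 1e-4)

  for (const in c(-3, 0, 5.5)) {
    sv <- soft_vote(rep(const, 3))
    expect_equal(sv$coord, 2)
    expect_equal(sv$uncertainty, sqrt(2 / 3), tolerance = 1e-12)
  }
  expect_error(soft_vote(3), "length >= 2")
})

test_that("soft votes stay in bounds and softmax normalizes", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    z <- rnorm(n, sd = 3)
    sv <- soft_vote(z)
    p <- ref_softmax(z)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(sv$coord, sum(p * seq_len(n)), tolerance = 1e-12)
    expect_gte(sv$coord, 1)
    expect_lte(sv$coord, n)
    expect_gte(sv$uncertainty, 0)
    expect_lte(sv$uncertainty, (n - 1) / 2 + 1e-12)
  }
})

test_that("decode recovers rendered Gaussian centers to subpixel accuracy", {
  ctr <- rbind(c(10.5, 20.25), c(16, 16), c(22.3, 8.7))
  maps <- render_heatmaps(ctr, sigma = 1.5)
  dec <- decode_heatmaps(maps)
  expect_lt(max(abs(dec$u - ctr[, 1])), 0.1)
  expect_lt(max(abs(dec$v - ctr[, 2])), 0.1)
})

test_that("decode is invariant to additive offsets and equivariant to shifts", {
  set.seed(31)
  ctr <- rbind(c(12.4, 14.8), c(18.1, 20.6), c(9.9, 11.2))
  maps <- render_heatmaps(ctr, sigma = 1.5, noise_sigma = 0.05, seed = 5L)
  dec <- decode_heatmaps(maps)

  shifted <- lapply(maps, function(m) heatmap(m$values + 7.3, m$joint_id))
  dec2 <- decode_heatmaps(shifted)
  expect_equal(dec$u, dec2$u, tolerance = 1e-9)
  expect_equal(dec$v, dec2$v, tolerance = 1e-9)
  expect_equal(dec$c_u, dec2$c_u, tolerance = 1e-9)

  # an integer translation of a concentrated bump translates the decode;
  # the vote must be sharp enough that the softmax tail mass (which does
  # not travel with the bump) is negligible
  du <- 3; dv <- -2
  clean <- render_heatmaps(ctr, sigma = 1.5, gain = 25)
  moved <- render_heatmaps(sweep(ctr, 2, c(du, dv), "+"), sigma = 1.5,
                           gain = 25)
  d0 <- decode_heatmaps(clean)
  d1 <- decode_heatmaps(moved)
  expect_equal(d1$u, d0$u + du, tolerance = 1e-6)
  expect_equal(d1$v, d0$v + dv, tolerance = 1e-6)
})

test_that("decode rejects inconsistent grids and too-few joints", {
  m1 <- heatmap(matrix(rnorm(16), 4, 4))
  m2 <- heatmap(matrix(rnorm(20), 5, 4))
  expect_error(decode_heatmaps(list(m1, m1, m2)), "same \\(w, h\\)")
  expect_error(decode_heatmaps(list(m1, m1)), "at least 3")
})

test_that("sharper bumps decode with smaller uncertainty", {
  cs <- vapply(c(0.8, 1.2, 1.8, 2.5), function(s) {
    dec <- decode_heatmaps(render_heatmaps(
      rbind(c(16.2, 16.7), c(10, 10), c(20, 22)), sigma = s))
    dec$c_u[1]
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("kblock_loss matches the Gaussian NLL with regularizer", {
  # one joint, both axes exact, c = 1: each axis contributes
  # log(sqrt(2*pi)) + 0.2/2 = 1.01894
  est <- pose2d(data.frame(joint = 1:3, u = c(5, 6, 7), v = c(8, 9, 10),
                           c_u = 1, c_v = 1))
  truth <- cbind(c(5, 6, 7), c(8, 9, 10))
  expect_equal(kblock_loss(est, truth) / 6, log(sqrt(2 * pi)) + 0.1,
               tolerance = 1e-12)
  expect_equal(kblock_loss(est, truth) / 6, 1.01894, tolerance = 1e-5)

  # with all c = 1 the loss is 0.5 * sum(squared error) + constant
  est2 <- pose2d(data.frame(joint = 1:3, u = c(5.5, 6, 9), v = c(8, 7.2, 10),
                            c_u = 1, c_v = 1))
  err2 <- sum((est2$u - truth[, 1])^2 + (est2$v - truth[, 2])^2)
  expect_equal(kblock_loss(est2, truth) - kblock_loss(est, truth),
               0.5 * err2, tolerance = 1e-12)

  # doubling the error increases the loss
  est3 <- pose2d(data.frame(joint = 1:3, u = c(6, 6, 11), v = c(8, 5.4, 10),
                            c_u = 1, c_v = 1))
  expect_gt(kblock_loss(est3, truth), kblock_loss(est2, truth))
})

test_that("kblock_loss has an interior optimum in the uncertainty", {
  # 1-D scan oracle: at fixed nonzero error the loss first falls then rises
  d <- 0.8
  f <- function(cc) log(sqrt(2 * pi) * cc) + d^2 / (2 * cc^2) + 0.2 / (2 * cc^2)
  grid <- seq(0.05, 10, by = 0.005)
  vals <- f(grid)
  i <- which.min(vals)
  expect_gt(i, 1)
  expect_lt(i, length(grid))
  # scan minimum agrees with the stationary point sqrt(d^2 + omega_c)
  expect_equal(grid[i], sqrt(d^2 + 0.2), tolerance = 0.01)
})

test_that("kblock_loss validates shapes and clamps uncertainties", {
  est <- pose2d(data.frame(joint = 1:3, u = 1:3, v = 1:3, c_u = 0, c_v = 0))
  truth <- cbind(1:3, 1:3)
  expect_true(is.finite(kblock_loss(est, truth)))  # floor keeps it finite
  expect_error(kblock_loss(est, truth[1:2, ]), "joint count")
})
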