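# Weighted Kabsch alignment and the iterative 2D-3D correction.

test_that("aligning a set onto itself gives the identity transform", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0.5), c(0.2, 0.8, -1))
  fit <- kabsch(P, P)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-9)
})

test_that("kabsch recovers a constructed rotation and translation", {
  set.seed(41)
  P <- rand_points(6)
  Rz <- quaternion_to_rotation(axis_angle_to_quaternion(c(0, 0, 1), pi / 2))
  Q <- sweep(P %*% t(Rz), 2, c(0.3, -1, 2), "+")
  fit <- kabsch(P, Q)
  expect_equal(apply_transform(fit, P), Q, tolerance = 1e-9)
  expect_equal(fit$rotation, Rz, tolerance = 1e-9)
})

test_that("reflection-optimal inputs still yield a proper rotation", {
  set.seed(42)
  P <- rand_points(8)
  Q <- P %*% diag(c(1, 1, -1))          # mirrored copy
  fit <- kabsch(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
  # weighted variant exercises the same correction branch
  w <- runif(8, 0.5, 2)
  fitw <- kabsch(P, Q, w)
  expect_equal(det(fitw$rotation), 1, tolerance = 1e-9)
})

test_that("uniform weights reproduce the unweighted solution exactly", {
  set.seed(43)
  P <- rand_points(7)
  Q <- rand_points(7)
  f1 <- kabsch(P, Q)
  f2 <- kabsch(P, Q, rep(1, 7))
  expect_identical(f1$rotation, f2$rotation)
  # any other constant weight only rescales the objective
  f3 <- kabsch(P, Q, rep(2.5, 7))
  expect_equal(f1$rotation, f3$rotation, tolerance = 1e-12)
  expect_equal(f1$translation, f3$translation, tolerance = 1e-12)
})

test_that("the SVD solution beats sampled rotations on weighted instances", {
  set.seed(44)
  entries <- sampled_rotation_entries(20000L)
  for (i in 1:100) {
    k <- sample(3:10, 1)
    P <- rand_points(k)
    Q <- rand_points(k)
    w <- runif(k, 0.1, 3)
    fit <- kabsch(P, Q, w)
    expect_lte(alignment_residual(P, Q, w, fit),
               best_sampled_objective(P, Q, w, entries) + 1e-9)
  }
})

test_that("kabsch rejects degenerate and invalid input", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))  # collinear
  expect_error(kabsch(line, line + 1), "degenerate|rank")
  P <- rand_points(4)
  expect_error(kabsch(P, P, w = c(1, 1, -1, 1)), "positive")
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("alignment_residual equals the explicit loop and scales in w", {
  set.seed(45)
  P <- rand_points(5); Q <- rand_points(5); w <- runif(5, 0.2, 2)
  fit <- kabsch(P, Q, w)
  expect_equal(alignment_residual(P, Q, w, fit),
               loop_objective(P, Q, w, fit$rotation, fit$translation),
               tolerance = 1e-12)
  expect_equal(alignment_residual(P, Q, 2 * w, fit),
               2 * alignment_residual(P, Q, w, fit), tolerance = 1e-12)
  expect_equal(alignment_residual(Q, Q, w, euclidean_transform(diag(3),
                                                               rep(0, 3))), 0)
})

test_that("lifting keypoints is the orthographic inverse", {
  p <- cbind(c(1, 4, 2), c(3, 0, 5))
  expect_equal(lift_keypoints(p, rep(0, 3)), cbind(p, z = rep(0, 3)))
  set.seed(46)
  X <- rand_points(6)
  expect_equal(lift_keypoints(project_orthographic(X), X[, 3]),
               cbind(X[, 1:2], z = X[, 3]))
  # lifting the unit-scale projection at the true depths reproduces the
  # normalized 3D truth as a rigid (here: identity) transform
  sc <- sample_scene(seed = 21L)
  p2 <- project_orthographic(sc$truth3d)
  L <- lift_keypoints(p2, sc$truth3d$points[, 3])
  fit <- kabsch(sc$truth3d$points, L)
  expect_lt(alignment_residual(sc$truth3d$points, L, transform = fit), 1e-18)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
})

test_that("noise-free correction reproduces the observed 2D exactly", {
  for (i in 1:20) {
    sc <- sample_scene(seed = 500 + i)
    cr <- iterative_correction(sc$truth2d, sc$truth3d)
    expect_lt(max(abs(cr$corrected2d - sc$truth2d)), 1e-6)
    expect_lt(cr$residuals[cr$iterations], 1e-10)
    expect_true(all(diff(cr$residuals) <= 1e-9))
    # depths match the true normalized-frame depths up to a global sign
    s2 <- sqrt(mean(sweep(sc$truth2d, 2, colMeans(sc$truth2d))^2))
    ztrue <- sc$truth3d$points[, 3] * (sc$scale / s2)
    expect_lt(min(sqrt(mean((cr$depths - ztrue)^2)),
                  sqrt(mean((cr$depths + ztrue)^2))), 1e-6)
  }
})

test_that("a template equal to the lifted observation is a fixed point", {
  set.seed(47)
  Q <- normalize_points(rand_points(10))
  obs <- Q$points[, 1:2] * 4.2          # any similarity of the projection
  cr <- iterative_correction(obs, Q, n_iter = 3)
  expect_equal(cr$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(max(abs(cr$corrected2d - obs)), 0, tolerance = 1e-9)
  # depths sit at the template's z in the normalized-2D frame, unchanged
  # by the iterations
  a <- 1 / sqrt(mean(sweep(Q$points[, 1:2], 2,
                           colMeans(Q$points[, 1:2]))^2))
  expect_equal(cr$depths, a * Q$points[, 3], tolerance = 1e-9)
  expect_lt(max(abs(cr$residuals)), 1e-15)
})

test_that("uncertainty weighting beats uniform weights under corruption", {
  set.seed(48)
  med <- replicate(60, {
    sc <- sample_scene(seed = sample.int(1e6, 1))
    obs <- sc$truth2d
    bad <- sample(nrow(obs), 2)
    obs[bad, ] <- obs[bad, ] + matrix(rnorm(4, sd = 2), 2, 2)
    pose <- pose2d(data.frame(joint = seq_len(nrow(obs)),
                              u = obs[, 1], v = obs[, 2],
                              c_u = ifelse(seq_len(nrow(obs)) %in% bad, 3, 0.3),
                              c_v = ifelse(seq_len(nrow(obs)) %in% bad, 3, 0.3)))
    cw <- iterative_correction(pose, sc$truth3d, weighted = TRUE)
    cu <- iterative_correction(pose, sc$truth3d, weighted = FALSE)
    c(w = mpjpe(cw$corrected2d, sc$truth2d),
      u = mpjpe(cu$corrected2d, sc$truth2d))
  })
  expect_lt(median(med["w", ]), median(med["u", ]))
})

test_that("correction validates its inputs", {
  sc <- sample_scene(seed = 77L)
  expect_error(iterative_correction(sc$truth2d, sc$truth3d, n_iter = 0),
               "n_iter")
  raw <- skeleton3d(sc$truth3d$points * 3)       # not normalized
  expect_error(iterative_correction(sc$truth2d, raw), "normalized")
  expect_error(iterative_correction(sc$truth2d[1:5, ], sc$truth3d),
               "joint counts")
  same <- matrix(5, 17, 2)
  expect_error(iterative_correction(same, sc$truth3d), "degenerate")
})

test_that("blending pulls the output toward confident observations", {
  sc <- sample_scene(seed = 88L, noise_sigma = 0.05)
  dec <- decode_heatmaps(sc$heatmaps)
  pure <- iterative_correction(dec, sc$truth3d, blend = FALSE)
  mix <- iterative_correction(dec, sc$truth3d, blend = TRUE)
  obs <- as.matrix(dec[, c("u", "v")])
  d_pure <- mean(sqrt(rowSums((pure$corrected2d - obs)^2)))
  d_mix <- mean(sqrt(rowSums((mix$corrected2d - obs)^2)))
  expect_lt(d_mix, d_pure)
})
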