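# Synthetic kinematic body model: a parametric stand-in for a
# statistical body prior with the same interface (shape coefficients ->
# bone lengths, per-joint rotations -> articulated 3D joints), plus the
# orthographic camera, heatmap renderer and scene sampler used to build
# fully reproducible fixtures for the decoder, alignment and metrics
# modules.

#' Default 17-joint kinematic tree
#'
#' A COCO-like body: pelvis root, a spine/neck/head chain, two
#' three-joint arm chains and two three-joint leg chains. Bone lengths
#' are in arbitrary units (normalization removes scale downstream). The
#' shape basis mapping the 10 shape coefficients to per-bone length
#' offsets is a fixed, internally seeded sparse matrix scaled so that
#' offsets stay within 30% of the base length over the typical
#' coefficient range `[-1.5, 1.5]`.
#'
#' @return A list with class `"kinematic_tree"`: `joint_names`,
#'   `parent` (1-based, root = 0), `rest_dir` (`k x 3` unit rows, zero
#'   row at the root), `base_len` (length `k`, zero at the root) and
#'   `shape_basis` (`k x 10`, zero row at the root).
#' @export
default_skeleton_tree <- function() {
  joints <- c("pelvis", "spine", "thorax", "neck", "head",
              "left_shoulder", "left_elbow", "left_wrist",
              "right_shoulder", "right_elbow", "right_wrist",
              "left_hip", "left_knee", "left_ankle",
              "right_hip", "right_knee", "right_ankle")
  parent <- c(0, 1, 2, 3, 4,
              3, 6, 7,
              3, 9, 10,
              1, 12, 13,
              1, 15, 16)
  dirs <- rbind(
    c(0, 0, 0),            # pelvis (root)
    c(0, 1, 0),            # spine
    c(0, 1, 0),            # thorax
    c(0, 1, 0),            # neck
    c(0, 1, 0),            # head
    c(-1, 0.1, 0),         # left_shoulder
    c(-0.3, -1, 0.15),     # left_elbow
    c(-0.1, -1, 0),        # left_wrist
    c(1, 0.1, 0),          # right_shoulder
    c(0.3, -1, 0.15),      # right_elbow
    c(0.1, -1, 0),         # right_wrist
    c(-1, -0.3, 0),        # left_hip
    c(0, -1, 0),           # left_knee
    c(0, -1, 0.1),         # left_ankle
    c(1, -0.3, 0),         # right_hip
    c(0, -1, 0),           # right_knee
    c(0, -1, 0.1)          # right_ankle
  )
  nrm <- sqrt(rowSums(dirs^2)); nrm[1] <- 1
  dirs <- dirs / nrm
  base <- c(0, 0.15, 0.15, 0.10, 0.12,
            0.19, 0.28, 0.25,
            0.19, 0.28, 0.25,
            0.11, 0.40, 0.40,
            0.11, 0.40, 0.40)
  k <- length(joints)
  # fixed sparse shape basis: 3 active coefficients per bone, scaled so
  # |offset| <= 0.3 * base length at |beta| = 1.5
  basis <- with_seed(1724L, {
    b <- matrix(0, k, 10)
    for (j in 2:k) {
      idx <- sample.int(10, 3)
      b[j, idx] <- stats::rnorm(3)
      b[j, ] <- b[j, ] * (0.3 * base[j]) / (1.5 * sum(abs(b[j, ])))
    }
    b
  })
  structure(list(joint_names = joints, parent = parent, rest_dir = dirs,
                 base_len = base, shape_basis = basis),
            class = "kinematic_tree")
}

#' @export
print.kinematic_tree <- function(x, ...) {
  cat(sprintf("<kinematic_tree> %d joints, root '%s'\n",
              length(x$joint_names), x$joint_names[x$parent == 0]))
  invisible(x)
}

#' Construct a 3D skeleton point set
#'
#' @param points Numeric `k x 3` matrix of joint coordinates.
#' @param normalized Logical; `TRUE` when the set has zero centroid and
#'   unit pooled standard deviation (see [normalize_points()]).
#' @return A list with class `"skeleton3d"`.
#' @export
skeleton3d <- function(points, normalized = FALSE) {
  check_matrix(points, "skeleton points", ncol = 3)
  if (nrow(points) < 3) stop_posevote("a skeleton needs at least 3 joints")
  structure(list(points = points, normalized = isTRUE(normalized)),
            class = "skeleton3d")
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %d joints%s\n", nrow(x$points),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

bone_lengths <- function(tree, beta) {
  if (length(beta) != ncol(tree$shape_basis))
    stop_posevote("beta must have length ", ncol(tree$shape_basis))
  check_finite(beta, "shape parameters")
  drop(tree$base_len + tree$shape_basis %*% beta)
}

#' Pose the kinematic body
#'
#' Maps shape coefficients and per-joint rotations to 3D joint
#' positions. Rotations compose down the tree: each joint's accumulated
#' rotation is its parent's accumulated rotation times its own local
#' rotation, and each child sits at
#' `parent_position + R_accumulated %*% (length(beta) * rest_direction)`.
#' The first quaternion is the root (global) orientation. With zero
#' shape coefficients and all-identity rotations the rest pose is
#' reproduced exactly, and bone lengths are preserved under every pose.
#'
#' @param tree A [default_skeleton_tree()]-style kinematic tree.
#' @param beta Numeric vector of 10 shape coefficients (typical range
#'   `[-1.5, 1.5]`).
#' @param theta `k x 4` matrix (or list) of scalar-last unit
#'   quaternions, row 1 = root orientation, row `j` = local rotation of
#'   joint `j`'s bone.
#' @return A [skeleton3d()] (not normalized), with the root at the
#'   origin.
#' @export
forward_kinematics <- function(tree, beta, theta) {
  if (!inherits(tree, "kinematic_tree"))
    stop_posevote("tree must be a kinematic_tree")
  k <- length(tree$parent)
  theta <- as_quaternion_matrix(theta)
  if (nrow(theta) != k)
    stop_posevote("theta must supply ", k, " quaternions (root first)")
  len <- bone_lengths(tree, beta)
  if (any(len[-1] <= 0))
    stop_posevote("non-positive bone length after shape offset: ",
                  paste(tree$joint_names[-1][len[-1] <= 0], collapse = ", "))
  pos <- matrix(0, k, 3)
  rot <- vector("list", k)
  for (j in seq_len(k)) {
    Rj <- quaternion_to_rotation(theta[j, ])
    p <- tree$parent[j]
    if (p == 0) {
      rot[[j]] <- Rj
    } else {
      rot[[j]] <- rot[[p]] %*% Rj
      pos[j, ] <- pos[p, ] + drop(rot[[j]] %*% (len[j] * tree$rest_dir[j, ]))
    }
  }
  rownames(pos) <- tree$joint_names
  skeleton3d(pos)
}

#' Normalize a 3D point set to zero mean and unit pooled spread
#'
#' Removes the centroid and rescales by the reciprocal of the pooled
#' standard deviation (square root of the mean squared deviation over
#' all `3k` coordinates). Idempotent, invariant to input translation and
#' positive rescaling, equivariant to rotation.
#'
#' @param points Numeric `k x 3` matrix (`k >= 3`) or a [skeleton3d()].
#' @return A normalized [skeleton3d()].
#' @export
normalize_points <- function(points) {
  if (inherits(points, "skeleton3d")) points <- points$points
  check_matrix(points, "points", ncol = 3)
  if (nrow(points) < 3) stop_posevote("need at least 3 points")
  ctr <- colMeans(points)
  Xc <- sweep(points, 2, ctr)
  s <- pooled_sd(Xc)
  if (s < 1e-12)
    stop_posevote("degenerate point set: zero spread, cannot normalize")
  skeleton3d(Xc / s, normalized = TRUE)
}

#' Orthographic projection of a skeleton
#'
#' Drops the depth (`z`) axis, which is defined to be perpendicular to
#' the image plane, and maps into image units:
#' `(u, v) = scale * (x, y) + offset`.
#'
#' @param skeleton A [skeleton3d()] or `k x 3` matrix.
#' @param scale Positive scalar (grid units per skeleton unit).
#' @param offset Numeric 2-vector added after scaling.
#' @return Numeric `k x 2` matrix of `(u, v)` coordinates.
#' @export
project_orthographic <- function(skeleton, scale = 1, offset = c(0, 0)) {
  pts <- if (inherits(skeleton, "skeleton3d")) skeleton$points else skeleton
  check_matrix(pts, "skeleton points", ncol = 3)
  if (scale <= 0) stop_posevote("scale must be > 0")
  if (length(offset) != 2) stop_posevote("offset must be a 2-vector")
  sweep(pts[, 1:2, drop = FALSE] * scale, 2, offset, "+")
}

#' Render per-joint Gaussian heatmaps
#'
#' Emulates the output of a trained heatmap head: for each joint an
#' isotropic Gaussian bump centered at its (subpixel, 1-based) 2D
#' location, plus optional i.i.d. Gaussian pixel noise. The bump
#' amplitude is set so that each axis marginal peaks near `gain`, which
#' puts the accumulated votes on the logit scale a trained network
#' produces; decoding such maps is subpixel-accurate and decoded
#' uncertainty grows with `sigma`. Occluded joints are attenuated by
#' `attenuation`, so their votes are diffuse and their decoded
#' uncertainty is high — they are degraded, not deleted.
#'
#' @param points2d Numeric `k x 2` matrix of `(u, v)` centers in 1-based
#'   grid units.
#' @param grid Integer 2-vector `c(w, h)`; default `c(32, 32)`.
#' @param sigma Bump standard deviation in grid units, `> 0`.
#' @param noise_sigma Standard deviation of additive pixel noise.
#' @param occluded Logical vector, length `k`.
#' @param seed Optional integer; when given, rendering is bit-for-bit
#'   reproducible and the caller's RNG state is untouched.
#' @param gain Peak axis-marginal response of an unoccluded bump.
#' @param attenuation Amplitude factor applied to occluded joints.
#' @return A list of `k` [heatmap()] objects, with attribute
#'   `"out_of_bounds"`: logical, `TRUE` for joints whose center lies
#'   more than `2 * sigma` beyond the grid borders (a quality flag, not
#'   an error).
#' @export
render_heatmaps <- function(points2d, grid = c(32, 32), sigma = 1.5,
                            noise_sigma = 0, occluded = NULL, seed = NULL,
                            gain = 10, attenuation = 0.1) {
  check_matrix(points2d, "points2d", ncol = 2)
  if (sigma <= 0) stop_posevote("sigma must be > 0")
  if (noise_sigma < 0) stop_posevote("noise_sigma must be >= 0")
  k <- nrow(points2d)
  if (is.null(occluded)) occluded <- rep(FALSE, k)
  if (length(occluded) != k)
    stop_posevote("occluded must have one entry per joint")
  w <- grid[1]; h <- grid[2]
  render <- function() {
    cols <- matrix(rep(seq_len(w), each = h), nrow = h)
    rows <- matrix(rep(seq_len(h), times = w), nrow = h)
    amp0 <- gain / (sigma * sqrt(2 * pi))
    lapply(seq_len(k), function(i) {
      a <- amp0 * if (occluded[i]) attenuation else 1
      vals <- a * exp(-((cols - points2d[i, 1])^2 +
                        (rows - points2d[i, 2])^2) / (2 * sigma^2))
      if (noise_sigma > 0)
        vals <- vals + matrix(stats::rnorm(w * h, sd = noise_sigma), h, w)
      heatmap(vals, joint_id = i)
    })
  }
  maps <- if (is.null(seed)) render() else with_seed(seed, render())
  oob <- points2d[, 1] < 1 - 2 * sigma | points2d[, 1] > w + 2 * sigma |
         points2d[, 2] < 1 - 2 * sigma | points2d[, 2] > h + 2 * sigma
  attr(maps, "out_of_bounds") <- oob
  maps
}

#' Sample a complete synthetic scene
#'
#' Draws shape coefficients uniformly, bounded local joint rotations, a
#' uniform random global orientation, then builds the normalized 3D
#' truth, its orthographic 2D projection in grid units, and the rendered
#' (optionally noisy, optionally occlusion-corrupted) heatmaps. Fully
#' reproducible from `seed`.
#'
#' @param tree Kinematic tree; default [default_skeleton_tree()].
#' @param beta_range Half-width of the uniform shape coefficient draw.
#' @param pose_range Bound (radians) on local joint rotation angles.
#' @param noise_sigma Heatmap pixel noise standard deviation.
#' @param occlusion_rate Per-joint probability of occlusion, in `[0, 1]`.
#' @param seed Integer seed; required for reproducibility.
#' @param grid,sigma,gain,attenuation Passed to [render_heatmaps()].
#' @param scale,offset Camera mapping from normalized skeleton units to
#'   grid units; defaults place the body in the middle of a 32 x 32
#'   grid with ~5 grid units per skeleton unit.
#' @return A list with class `"scene"`: `truth3d` (normalized
#'   [skeleton3d()]), `truth2d` (`k x 2`, 1-based grid units),
#'   `heatmaps`, `occluded`, `noise_sigma`, `seed`, `scale`, `offset`,
#'   `grid`, `sigma`, and the drawn `beta` and `theta`.
#' @export
sample_scene <- function(tree = default_skeleton_tree(), beta_range = 1.5,
                         pose_range = 0.3, noise_sigma = 0,
                         occlusion_rate = 0, seed = 1L, grid = c(32, 32),
                         sigma = 1.5, scale = 5,
                         offset = grid / 2 + 0.5, gain = 10,
                         attenuation = 0.1) {
  if (occlusion_rate < 0 || occlusion_rate > 1)
    stop_posevote("occlusion_rate must be in [0, 1]")
  if (beta_range < 0 || beta_range > 1.5)
    stop_posevote("beta_range must be in [0, 1.5] (bone lengths stay positive)")
  if (pose_range < 0 || pose_range > pi)
    stop_posevote("pose_range must be in [0, pi]")
  k <- length(tree$parent)
  with_seed(as.integer(seed), {
    beta <- stats::runif(10, -beta_range, beta_range)
    theta <- matrix(0, k, 4)
    qroot <- stats::rnorm(4)
    theta[1, ] <- qroot / sqrt(sum(qroot^2))
    for (j in 2:k) {
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      theta[j, ] <- axis_angle_to_quaternion(
        ax, stats::runif(1, -pose_range, pose_range))
    }
    truth3d <- normalize_points(forward_kinematics(tree, beta, theta))
    truth2d <- project_orthographic(truth3d, scale = scale, offset = offset)
    occluded <- stats::runif(k) < occlusion_rate
    maps <- render_heatmaps(truth2d, grid = grid, sigma = sigma,
                            noise_sigma = noise_sigma, occluded = occluded,
                            gain = gain, attenuation = attenuation)
    structure(list(truth3d = truth3d, truth2d = truth2d, heatmaps = maps,
                   occluded = occluded, noise_sigma = noise_sigma,
                   seed = as.integer(seed), scale = scale, offset = offset,
                   grid = grid, sigma = sigma, beta = beta, theta = theta),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> %d joints, %d x %d grid, noise %.3g, %d occluded, seed %d\n",
    nrow(x$truth2d), x$grid[1], x$grid[2], x$noise_sigma,
    sum(x$occluded), x$seed))
  invisible(x)
}
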