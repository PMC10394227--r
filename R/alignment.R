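# Rigid alignment by SVD and the iterative uncertainty-weighted 2D-3D
# keypoint correction.
#
# The closed-form solver minimizes sum_i (1/2) w_i ||R p_i + t - q_i||^2
# over proper rotations R and translations t. After centering both sets
# at their weighted centroids the optimum rotation maximizes
# tr(R * sum_i w_i p_i q_i^T); with the SVD of the weighted
# cross-covariance C = sum_i w_i q_i p_i^T = U S V^T the maximizer is
# R = U D V^T, where D = diag(1, ..., 1, det(U V^T)) forces det(R) = +1
# (an unconstrained optimum that is a reflection is anatomically
# invalid for skeletons).

#' Construct a Euclidean transform
#'
#' @param rotation Proper orthogonal `d x d` matrix (orthogonality and
#'   `det = +1` checked to 1e-9).
#' @param translation Numeric `d`-vector.
#' @return A list with class `"euclidean_transform"`.
#' @export
euclidean_transform <- function(rotation, translation) {
  check_matrix(rotation, "rotation")
  d <- nrow(rotation)
  if (ncol(rotation) != d) stop_posevote("rotation must be square")
  if (max(abs(crossprod(rotation) - diag(d))) > 1e-9)
    stop_posevote("rotation is not orthogonal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop_posevote("rotation must be proper (det = +1)")
  if (length(translation) != d)
    stop_posevote("translation must have length ", d)
  check_finite(translation, "translation")
  structure(list(rotation = rotation, translation = translation),
            class = "euclidean_transform")
}

#' @export
print.euclidean_transform <- function(x, ...) {
  cat(sprintf("<euclidean_transform> %dD, |t| = %.4g\n",
              nrow(x$rotation), sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a Euclidean transform to points
#'
#' @param transform A [euclidean_transform()].
#' @param points Numeric `k x d` matrix.
#' @return `k x d` matrix of `R p + t` rows.
#' @export
apply_transform <- function(transform, points) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

# Optimal rotation taking centered P onto centered Q under weights w.
# Works in any dimension d >= 2; raises on (near-)degenerate inputs.
kabsch_rotation <- function(Pc, Qc, w) {
  C <- crossprod(Qc * w, Pc)             # sum_i w_i q_i p_i^T, d x d
  sv <- svd(C)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop_posevote("degenerate configuration: cross-covariance rank < 2 ",
                  "(points collinear?)")
  s <- sign(det(sv$u %*% t(sv$v)))
  D <- c(rep(1, ncol(Pc) - 1), s)
  sv$u %*% (t(sv$v) * D)
}

#' Weighted rigid alignment of two point sets (Kabsch/Procrustes)
#'
#' Finds the proper rotation and translation minimizing
#' `sum_i (1/2) w_i ||R p_i + t - q_i||^2`. Both sets are centered at
#' their weighted centroids; the rotation comes from the SVD of the
#' weighted cross-covariance with the reflection correction, and the
#' translation maps `P`'s weighted centroid onto `Q`'s. Uniform weights
#' reproduce the unweighted solution exactly.
#'
#' @param P,Q Numeric `k x 3` matrices (`k >= 3`), matched rows.
#' @param w Optional positive weight vector of length `k`; default
#'   uniform.
#' @return A [euclidean_transform()].
#' @examples
#' P <- matrix(rnorm(15), 5, 3)
#' Rz <- quaternion_to_rotation(axis_angle_to_quaternion(c(0, 0, 1), pi / 2))
#' fit <- kabsch(P, P %*% t(Rz))
#' max(abs(fit$rotation - Rz))
#' @export
kabsch <- function(P, Q, w = NULL) {
  check_matrix(P, "P", ncol = 3)
  check_matrix(Q, "Q", ncol = 3)
  if (nrow(P) != nrow(Q)) stop_posevote("P and Q must have matching rows")
  if (nrow(P) < 3) stop_posevote("need at least 3 point pairs")
  if (is.null(w)) w <- rep(1, nrow(P))
  check_finite(w, "weights")
  if (length(w) != nrow(P)) stop_posevote("one weight per point required")
  if (any(w <= 0)) stop_posevote("weights must be strictly positive")
  pbar <- weighted_centroid(P, w)
  qbar <- weighted_centroid(Q, w)
  R <- kabsch_rotation(sweep(P, 2, pbar), sweep(Q, 2, qbar), w)
  euclidean_transform(R, drop(qbar - R %*% pbar))
}

#' Weighted alignment residual
#'
#' Evaluates `sum_i (1/2) w_i ||R p_i + t - q_i||^2` for a given
#' transform — the objective that [kabsch()] minimizes.
#'
#' @param P,Q Matched `k x d` point matrices.
#' @param w Positive weights (default uniform).
#' @param transform A [euclidean_transform()].
#' @return Non-negative number.
#' @export
alignment_residual <- function(P, Q, w = NULL, transform) {
  check_matrix(P, "P"); check_matrix(Q, "Q")
  if (!all(dim(P) == dim(Q))) stop_posevote("P and Q must match in shape")
  if (is.null(w)) w <- rep(1, nrow(P))
  sum(0.5 * w * rowSums((apply_transform(transform, P) - Q)^2))
}

#' Lift 2D keypoints to 3D with per-joint depths
#'
#' Orthographic back-projection: row `i` becomes `(u_i, v_i, z_i)`, the
#' depth axis being perpendicular to the image plane.
#'
#' @param points2d Numeric `k x 2` matrix.
#' @param depths Numeric vector of length `k`.
#' @return Numeric `k x 3` matrix.
#' @export
lift_keypoints <- function(points2d, depths) {
  check_matrix(points2d, "points2d", ncol = 2)
  check_finite(depths, "depths")
  if (length(depths) != nrow(points2d))
    stop_posevote("one depth per keypoint required")
  cbind(points2d, z = depths)
}

# Scaled-orthographic initialization of the depths: unconstrained least
# squares for the 2 x 3 matrix M ~ s * R[1:2, ] mapping the (centered)
# template onto the normalized 2D observations, then row
# orthonormalization via SVD; the third rotation row is the cross
# product of the first two (proper completion) and yields the depths.
# Requires a template of full rank 3.
ortho_depth_init <- function(n2d, Qpts, w) {
  qc <- weighted_centroid(Qpts, w)
  Qc <- sweep(Qpts, 2, qc)
  G <- crossprod(Qc * w, Qc)
  if (rcond(G) < 1e-12)
    stop_posevote("degenerate 3D template: rank < 3, cannot initialize depths")
  M <- crossprod(n2d * w, Qc) %*% solve(G)
  sv <- svd(M)
  R2 <- sv$u %*% t(sv$v)
  s <- mean(sv$d)
  r3 <- c(R2[1, 2] * R2[2, 3] - R2[1, 3] * R2[2, 2],
          R2[1, 3] * R2[2, 1] - R2[1, 1] * R2[2, 3],
          R2[1, 1] * R2[2, 2] - R2[1, 2] * R2[2, 1])
  drop(s * (Qc %*% r3))
}

#' Iterative uncertainty-weighted 2D correction against a 3D prior
#'
#' Corrects decoded 2D keypoints using the body-structure prior carried
#' by a normalized 3D joint set. Per-joint weights are the reciprocal
#' uncertainties `w_i = 1 / c_i` (with `c_i` the mean of the two axis
#' uncertainties, floored), so diffuse, likely-occluded joints influence
#' the fit less. The procedure:
#'
#' 1. Normalize the 2D set (remove the weighted centroid, scale to unit
#'    pooled standard deviation).
#' 2. Initialize per-joint depths by a closed-form scaled-orthographic
#'    fit of the template to the normalized 2D observations.
#' 3. Repeat `n_iter` times: lift the 2D set with the current depths,
#'    re-normalize the lifted set, solve the weighted [kabsch()]
#'    alignment taking the template onto it (rotation only — scale is
#'    absorbed by the normalizations), update each depth to the aligned
#'    template's `z`, and record the weighted residual restricted to
#'    the `(u, v)` components.
#' 4. Replace the `(u, v)` of each joint by the aligned template's
#'    projection and map back to the input units.
#'
#' On noise-free input the corrected coordinates reproduce the
#' observations to machine precision and the recorded residuals are
#' non-increasing. Optionally the corrected and observed coordinates
#' are blended per joint with weight keyed by uncertainty
#' (`blend = TRUE`): confident joints keep more of the observation.
#'
#' @param p2d A [pose2d()] (decoded keypoints with uncertainties) or a
#'   plain `k x 2` matrix (uniform weights).
#' @param q3d A normalized [skeleton3d()] with the same joint count.
#' @param n_iter Number of alignment iterations, `>= 1`; default 3.
#' @param weighted Use the decoded uncertainties as weights (`TRUE`,
#'   default) or uniform weights (`FALSE`).
#' @param floor Lower clamp for uncertainties before inversion, in grid
#'   units; default 1e-3.
#' @param blend If `TRUE`, output a per-joint convex blend of corrected
#'   and observed coordinates with observation weight `1 / (1 + c_i)`;
#'   default `FALSE` (pure correction).
#' @return A list with class `"correction_result"`: `corrected2d`
#'   (`k x 2`, input units), `depths` (normalized-frame units),
#'   `transform` (the final [euclidean_transform()] taking the template
#'   onto the normalized lifted set), `residuals` (one weighted `(u,v)`
#'   objective value per iteration), `iterations`, `weights`.
#' @export
iterative_correction <- function(p2d, q3d, n_iter = 3, weighted = TRUE,
                                 floor = 1e-3, blend = FALSE) {
  if (n_iter < 1) stop_posevote("n_iter must be >= 1")
  if (inherits(p2d, "pose2d")) {
    obs <- as.matrix(p2d[, c("u", "v")])
    cc <- pmax((p2d$c_u + p2d$c_v) / 2, floor)
  } else {
    check_matrix(p2d, "p2d", ncol = 2)
    obs <- p2d
    cc <- rep(1, nrow(obs))
  }
  if (!inherits(q3d, "skeleton3d"))
    stop_posevote("q3d must be a skeleton3d")
  if (!q3d$normalized)
    stop_posevote("q3d must be normalized (see normalize_points)")
  Qpts <- q3d$points
  k <- nrow(obs)
  if (nrow(Qpts) != k)
    stop_posevote("2D and 3D joint counts differ: ", k, " vs ", nrow(Qpts))
  w <- if (weighted) 1 / cc else rep(1, k)

  ctr2 <- weighted_centroid(obs, w)
  obs_c <- sweep(obs, 2, ctr2)
  s2 <- pooled_sd(obs_c)
  if (s2 < 1e-12)
    stop_posevote("degenerate 2D configuration: zero spread")
  n2d <- obs_c / s2

  z <- ortho_depth_init(n2d, Qpts, w)
  residuals <- numeric(n_iter)
  aligned_lift <- NULL
  fit <- NULL
  for (it in seq_len(n_iter)) {
    L <- lift_keypoints(n2d, z)
    lctr <- weighted_centroid(L, w)
    Lc <- sweep(L, 2, lctr)
    ls <- pooled_sd(Lc)
    Lh <- Lc / ls
    fit <- kabsch(Qpts, Lh, w)
    A <- apply_transform(fit, Qpts)
    aligned_lift <- sweep(A * ls, 2, lctr, "+")    # back to lift frame
    z <- aligned_lift[, 3]
    residuals[it] <- sum(0.5 * w *
                           rowSums((aligned_lift[, 1:2] - L[, 1:2])^2))
  }
  corrected <- sweep(aligned_lift[, 1:2, drop = FALSE] * s2, 2, ctr2, "+")
  if (blend) {
    g <- 1 / (1 + cc)            # observation weight: confident joints keep more
    corrected <- corrected * (1 - g) + obs * g
  }
  dimnames(corrected) <- dimnames(obs)
  structure(list(corrected2d = corrected, depths = z, transform = fit,
                 residuals = residuals, iterations = n_iter, weights = w),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "<correction_result> %d joints, %d iterations, final (u,v) residual %.4g\n",
    nrow(x$corrected2d), x$iterations, x$residuals[x$iterations]))
  invisible(x)
}
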