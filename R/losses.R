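# Loss terms for SMPL-style body parameter regression and the combined
# training objective.

#' Loss weights of the combined objective
#'
#' Bundles the weighting constants of the full architecture's loss. The
#' defaults are the empirically chosen values of the reference
#' configuration: `lambda_shape = 0.2`, `lambda_pose = 0.25`,
#' `lambda_smpl = 0.15`, `lambda_det = 0.4`, `lambda_kb = 0.3`,
#' `omega_c = 0.2`, `omega_p = 1`.
#'
#' @param lambda_shape,lambda_pose,lambda_smpl,lambda_det,lambda_kb
#'   Non-negative weights of the shape, pose, 3D-keypoint, detector and
#'   k-block loss terms.
#' @param omega_c Regularizer weight inside [kblock_loss()].
#' @param omega_p Regularizer weight inside [pose_loss()].
#' @return A list with class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_shape = 0.2, lambda_pose = 0.25,
                         lambda_smpl = 0.15, lambda_det = 0.4,
                         lambda_kb = 0.3, omega_c = 0.2, omega_p = 1) {
  w <- list(lambda_shape = lambda_shape, lambda_pose = lambda_pose,
            lambda_smpl = lambda_smpl, lambda_det = lambda_det,
            lambda_kb = lambda_kb, omega_c = omega_c, omega_p = omega_p)
  vals <- unlist(w)
  check_finite(vals, "loss weights")
  if (any(vals < 0)) stop_posevote("loss weights must be >= 0")
  structure(w, class = "loss_weights")
}

#' Smooth-L1 shape parameter loss
#'
#' Scores predicted shape coefficients against ground truth with a
#' Smooth-L1 whose quadratic region is widened to `|delta| <= 1.5`,
#' matching the typical range of the 10 open shape coefficients:
#' `f(delta) = (2/9) delta^2` for `|delta| <= 1.5`, else
#' `(2/3) |delta| - 0.5`. The two branches agree (value 0.5, slope 2/3)
#' at the boundary, so the loss is continuously differentiable.
#'
#' @param beta,beta_hat Numeric vectors of equal length (predicted and
#'   true shape coefficients).
#' @return Non-negative number, zero iff `beta == beta_hat`.
#' @export
shape_loss <- function(beta, beta_hat) {
  if (length(beta) != length(beta_hat))
    stop_posevote("beta and beta_hat must have equal length")
  check_finite(c(beta, beta_hat), "shape parameters")
  d <- abs(beta - beta_hat)
  sum(ifelse(d <= 1.5, (2 / 9) * d^2, (2 / 3) * d - 0.5))
}

#' Quaternion pose parameter loss
#'
#' L1 distance between predicted and true per-joint quaternions plus a
#' unit-norm regularizer, summed over joints:
#' `sum_j [ ||theta_j - theta_hat_j||_1 + omega_p |1 - ||theta_j||_2^2| ]`.
#' Zero exactly when every predicted quaternion equals its target
#' elementwise and is unit-norm.
#'
#' @param theta,theta_hat Lists (or `n x 4` matrices) of scalar-last
#'   quaternions, one per joint with a rotational degree of freedom.
#' @param omega_p Weight of the norm regularizer; default 1.
#' @return Non-negative number.
#' @export
pose_loss <- function(theta, theta_hat, omega_p = 1) {
  theta <- as_quaternion_matrix(theta)
  theta_hat <- as_quaternion_matrix(theta_hat)
  if (nrow(theta) != nrow(theta_hat))
    stop_posevote("theta and theta_hat must have the same joint count")
  if (omega_p < 0) stop_posevote("omega_p must be >= 0")
  l1 <- rowSums(abs(theta - theta_hat))
  reg <- abs(1 - rowSums(theta^2))
  sum(l1 + omega_p * reg)
}

as_quaternion_matrix <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  check_matrix(x, "quaternions", ncol = 4)
  x
}

#' Squared-error 3D keypoint loss
#'
#' Sum of squared coordinate differences between predicted and true 3D
#' joint positions.
#'
#' @param pred,truth Numeric `k x 3` matrices.
#' @return Non-negative number.
#' @export
smpl_keypoint_loss <- function(pred, truth) {
  check_matrix(pred, "pred", ncol = 3)
  check_matrix(truth, "truth", ncol = 3)
  if (nrow(pred) != nrow(truth))
    stop_posevote("pred and truth must have the same joint count")
  sum((pred - truth)^2)
}

#' Weighted total training loss
#'
#' Combines the five loss components with their weights:
#' `lambda_shape L_shape + lambda_pose L_pose + lambda_smpl L_smpl +
#'  lambda_kb L_kb + lambda_det L_det`. The detector loss is accepted as
#' an externally computed number (its internals are outside this
#' toolkit's scope).
#'
#' @param l_shape,l_pose,l_smpl,l_kb,l_det Finite loss component values.
#' @param weights A [loss_weights()] object.
#' @return A single number.
#' @export
total_loss <- function(l_shape, l_pose, l_smpl, l_kb, l_det,
                       weights = loss_weights()) {
  if (!inherits(weights, "loss_weights"))
    stop_posevote("weights must be a loss_weights object")
  comps <- c(l_shape, l_pose, l_smpl, l_kb, l_det)
  check_finite(comps, "loss components")
  weights$lambda_shape * l_shape + weights$lambda_pose * l_pose +
    weights$lambda_smpl * l_smpl + weights$lambda_kb * l_kb +
    weights$lambda_det * l_det
}
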