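# Shared geometry fixtures, built in code.

rand_rotation <- function() {
  q <- rnorm(4)
  quaternion_to_rotation(q / sqrt(sum(q^2)))
}

rand_points <- function(k, d = 3) {
  matrix(rnorm(k * d), k, d)
}

# Reference softmax, kept separate from the decoder implementation.
ref_softmax <- function(z) {
  p <- exp(z - max(z))
  p / sum(p)
}

# Identity-pose quaternions for a k-joint tree.
identity_pose <- function(k) {
  matrix(rep(c(0, 0, 0, 1), each = k), k, 4)
}

# Weighted alignment objective by explicit loop (oracle for kabsch &
# alignment_residual).
loop_objective <- function(P, Q, w, R, t) {
  acc <- 0
  for (i in seq_len(nrow(P)))
    acc <- acc + 0.5 * w[i] * sum((R %*% P[i, ] + t - Q[i, ])^2)
  acc
}

# Rotation entries (row-major 9-vector per rotation) for n quaternion-
# sampled rotations; used by the rotation-sampling oracle.
sampled_rotation_entries <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  x <- q[, 1]; y <- q[, 2]; z <- q[, 3]; w <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
        2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
        2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2))
}

# Minimum weighted alignment objective over the sampled rotations
# (translation solved exactly by centering) -- the brute-force oracle.
best_sampled_objective <- function(P, Q, w, entries) {
  pb <- colSums(P * w) / sum(w); qb <- colSums(Q * w) / sum(w)
  Pc <- sweep(P, 2, pb); Qc <- sweep(Q, 2, qb)
  const <- 0.5 * sum(w * (rowSums(Pc^2) + rowSums(Qc^2)))
  B <- crossprod(Pc * w, Qc)              # sum w p q^T
  # tr(R %*% B) with R row-major entries: sum over R[i,j] * B[j,i]
  tr <- entries %*% as.vector(t(B))
  min(const - tr)
}
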