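# k-block decoder: whole-heatmap voting for subpixel keypoint coordinates
# and their uncertainties.
#
# A heatmap is a w x h grid of (possibly negative) responses for one joint.
# The decoder accumulates the grid along each axis, softmaxes the two
# marginal vectors, and reads the coordinate as the expectation of the
# position index under the vote distribution; the standard deviation of
# that distribution is the per-axis uncertainty. Coordinates use the
# 1-based enumeration e = (1, 2, ..., n) of rows/columns throughout the
# package; file I/O converts to 0-based pixel coordinates at the boundary.

#' Construct a heatmap
#'
#' Wraps one joint's response grid. Values are stored as an `h x w`
#' numeric matrix: rows index the vertical (`v`) axis, columns the
#' horizontal (`u`) axis. Raw network-style outputs are allowed, so
#' values may be negative; they must be finite.
#'
#' @param values Numeric matrix, `h` rows by `w` columns, all finite,
#'   with `w >= 2` and `h >= 2`.
#' @param joint_id Integer identifier of the joint this map scores.
#' @return An object of class `"heatmap"`.
#' @examples
#' h <- heatmap(matrix(c(1, 3, 2, 4), 2, 2), joint_id = 1L)
#' marginalize(h)
#' @export
heatmap <- function(values, joint_id = 1L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_posevote("heatmap values must be a numeric matrix")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop_posevote("heatmap must be at least 2 x 2, got ",
                  nrow(values), " x ", ncol(values))
  check_finite(values, "heatmap values")
  structure(list(values = values, joint_id = as.integer(joint_id)),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap> joint %d, %d x %d (w x h), range [%.3g, %.3g]\n",
              x$joint_id, ncol(x$values), nrow(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Marginalize a heatmap along both axes
#'
#' Accumulates the response grid in the `u` (column) and `v` (row)
#' directions. The two vectors are the coordinate voting weights of the
#' joint along each axis; both sum to the total mass of the map.
#'
#' @param h A [heatmap()].
#' @return A list with numeric vectors `z_u` (length `w`) and `z_v`
#'   (length `h`).
#' @export
marginalize <- function(h) {
  if (!inherits(h, "heatmap")) h <- heatmap(h)
  list(z_u = colSums(h$values), z_v = rowSums(h$values))
}

#' Soft voting along one axis
#'
#' Softmax-normalizes a marginal weight vector `z` into a vote
#' distribution over the enumeration `e = (1, 2, ..., n)`, and returns
#' the vote expectation as the coordinate together with the standard
#' deviation of the vote distribution as its uncertainty. The softmax is
#' invariant to adding a constant to `z`, so raw (even negative)
#' responses are usable without rectification.
#'
#' @param z Numeric vector of voting weights, length `n >= 2`, finite.
#' @return A list with `coord` in `[1, n]` and `uncertainty` in
#'   `[0, (n - 1) / 2]`.
#' @examples
#' soft_vote(c(0, 1, 0))
#' @export
soft_vote <- function(z) {
  if (length(z) < 2)
    stop_posevote("soft_vote needs a vector of length >= 2 (degenerate vote)")
  check_finite(z, "voting weights")
  p <- exp(z - max(z))
  p <- p / sum(p)
  e <- seq_along(z)
  coord <- sum(p * e)
  list(coord = coord, uncertainty = sqrt(sum(p * (e - coord)^2)))
}

#' Decode a stack of heatmaps into a 2D pose estimate
#'
#' Applies [marginalize()] and [soft_vote()] per joint and axis. All
#' heatmaps must share the same grid size.
#'
#' @param maps A list of `k >= 3` [heatmap()] objects (or plain
#'   matrices), one per joint, in skeleton order.
#' @return A `pose2d` data frame with one row per joint and columns
#'   `joint`, `u`, `v`, `c_u`, `c_v`; grid size is kept in
#'   `attr(, "grid")` as `c(w, h)`.
#' @export
decode_heatmaps <- function(maps) {
  if (!is.list(maps) || length(maps) < 3)
    stop_posevote("decode_heatmaps needs a list of at least 3 heatmaps")
  maps <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    if (inherits(m, "heatmap")) m else heatmap(m, joint_id = i)
  })
  dims <- vapply(maps, function(m) dim(m$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_posevote("all heatmaps must share the same (w, h) grid")
  rows <- lapply(maps, function(m) {
    mg <- marginalize(m)
    su <- soft_vote(mg$z_u)
    sv <- soft_vote(mg$z_v)
    data.frame(joint = m$joint_id, u = su$coord, v = sv$coord,
               c_u = su$uncertainty, c_v = sv$uncertainty)
  })
  out <- do.call(rbind, rows)
  pose2d(out, grid = c(dims[2, 1], dims[1, 1]))
}

#' Construct a 2D pose estimate table
#'
#' @param df Data frame with columns `joint`, `u`, `v`, `c_u`, `c_v`
#'   (uncertainties may be omitted; they default to 0, meaning
#'   "unknown/exact" and treated as uniform by consumers that weight).
#' @param grid Optional `c(w, h)` of the source heatmap grid.
#' @return The data frame with class `"pose2d"` prepended.
#' @export
pose2d <- function(df, grid = NULL) {
  need <- c("joint", "u", "v")
  if (!all(need %in% names(df)))
    stop_posevote("pose2d needs columns ", paste(need, collapse = ", "))
  if (is.null(df$c_u)) df$c_u <- 0
  if (is.null(df$c_v)) df$c_v <- 0
  if (nrow(df) < 3)
    stop_posevote("a pose needs at least 3 joints, got ", nrow(df))
  check_finite(as.matrix(df[c("u", "v", "c_u", "c_v")]), "pose2d coordinates")
  if (any(df$c_u < 0) || any(df$c_v < 0))
    stop_posevote("uncertainties c_u, c_v must be >= 0")
  rownames(df) <- NULL
  structure(df, class = c("pose2d", "data.frame"), grid = grid)
}

#' @export
print.pose2d <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<pose2d> %d joints%s\n", nrow(x),
              if (is.null(g)) "" else sprintf(" on %d x %d grid", g[1], g[2])))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Gaussian negative log-likelihood loss of the voting decoder
#'
#' Treats each decoded coordinate as a Gaussian with mean at the decoded
#' value and standard deviation equal to the decoded uncertainty, and
#' scores it against the ground truth:
#' \deqn{L = \sum_{i,a} \Big[\log(\sqrt{2\pi}\,c_{i,a}) +
#'   \frac{(x_{i,a} - \hat x_{i,a})^2}{2 c_{i,a}^2}\Big] +
#'   \omega_c \sum_{i,a} \frac{1}{2 c_{i,a}^2},}
#' summed over joints `i` and both axes `a`. The additive regularizer
#' keeps uncertainties from collapsing to zero. With all `c = 1` the
#' loss reduces to half the summed squared error plus a constant.
#'
#' @param estimates A [pose2d()] with strictly positive uncertainties
#'   (values below `floor` are clamped up to it).
#' @param truth Numeric `k x 2` matrix of true `(u, v)` coordinates in
#'   the same (1-based grid) units.
#' @param omega_c Weight of the `1 / (2 c^2)` regularizer; default 0.2.
#' @param floor Lower clamp for uncertainties, in grid units.
#' @return A single finite number.
#' @export
kblock_loss <- function(estimates, truth, omega_c = 0.2, floor = 1e-3) {
  if (!inherits(estimates, "pose2d"))
    stop_posevote("estimates must be a pose2d object")
  check_matrix(truth, "truth", ncol = 2)
  if (nrow(truth) != nrow(estimates))
    stop_posevote("estimates and truth disagree on joint count: ",
                  nrow(estimates), " vs ", nrow(truth))
  if (omega_c < 0) stop_posevote("omega_c must be >= 0")
  cc <- pmax(c(estimates$c_u, estimates$c_v), floor)
  if (any(cc <= 0)) stop_posevote("uncertainties must be positive after clamping")
  err <- c(estimates$u - truth[, 1], estimates$v - truth[, 2])
  sum(log(sqrt(2 * pi) * cc) + err^2 / (2 * cc^2)) + omega_c * sum(1 / (2 * cc^2))
}
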