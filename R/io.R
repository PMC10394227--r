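# File formats: COCO-style keypoint JSON (0-based pixel coordinates at
# the boundary, converted to/from the 1-based enumeration used
# internally), a JSON heatmap container with dataset metadata, and the
# YAML run configuration.

#' Write a 2D pose as COCO-style keypoint JSON
#'
#' Each joint becomes a record `{joint_id, u, v, c_u, c_v, score}` with
#' 0-based pixel coordinates and `score = 1 / (1 + c)` (mean axis
#' uncertainty), so downstream COCO-style tooling gets a confidence in
#' `(0, 1]`.
#'
#' @param pose A [pose2d()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(pose, path) {
  if (!inherits(pose, "pose2d")) stop_posevote("pose must be a pose2d")
  cbar <- (pose$c_u + pose$c_v) / 2
  records <- lapply(seq_len(nrow(pose)), function(i) {
    list(joint_id = pose$joint[i],
         u = pose$u[i] - 1, v = pose$v[i] - 1,
         c_u = pose$c_u[i], c_v = pose$c_v[i],
         score = 1 / (1 + cbar[i]))
  })
  g <- attr(pose, "grid")
  obj <- list(format = "posevote-keypoints", version = 1L,
              grid = if (is.null(g)) NULL else as.integer(g),
              keypoints = records)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read COCO-style keypoint JSON
#'
#' Strict counterpart of [write_keypoints()]: validates the schema,
#' converts 0-based file coordinates back to the package's 1-based
#' convention, and defaults missing uncertainties to 0 (uniform
#' weighting downstream).
#'
#' @param path Input file path.
#' @return A [pose2d()].
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) stop_posevote("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$keypoints))
    stop_posevote("keypoint file ", path, ": missing field 'keypoints'")
  kp <- as.data.frame(obj$keypoints)
  for (f in c("joint_id", "u", "v")) {
    if (is.null(kp[[f]]))
      stop_posevote("keypoint file ", path, ": record missing field '", f, "'")
    if (!is.numeric(kp[[f]]) || anyNA(kp[[f]]))
      stop_posevote("keypoint file ", path, ": field '", f,
                    "' must be numeric and complete")
  }
  if (is.null(kp$c_u)) kp$c_u <- 0
  if (is.null(kp$c_v)) kp$c_v <- 0
  if (any(kp$c_u < 0) || any(kp$c_v < 0))
    stop_posevote("keypoint file ", path,
                  ": field 'c_u'/'c_v' must be >= 0 (negative uncertainty)")
  kp <- kp[order(kp$joint_id), ]
  pose2d(data.frame(joint = kp$joint_id, u = kp$u + 1, v = kp$v + 1,
                    c_u = kp$c_u, c_v = kp$c_v),
         grid = if (is.null(obj$grid)) NULL else as.integer(obj$grid))
}

#' Write a heatmap stack to a JSON container
#'
#' Portable text container for a `(k, h, w)` heatmap tensor with
#' dataset-level metadata (grid size and any extra fields supplied).
#'
#' @param maps List of [heatmap()] objects sharing one grid.
#' @param path Output file path.
#' @param meta Named list of extra metadata (e.g. `sigma`, `seed`).
#' @return `path`, invisibly.
#' @export
write_heatmaps <- function(maps, path, meta = list()) {
  if (!length(maps)) stop_posevote("empty heatmap list")
  maps <- lapply(maps, function(m) if (inherits(m, "heatmap")) m else heatmap(m))
  h <- nrow(maps[[1]]$values); w <- ncol(maps[[1]]$values)
  obj <- c(list(format = "posevote-heatmaps", version = 1L,
                shape = c(length(maps), h, w),
                joint_ids = vapply(maps, function(m) m$joint_id, integer(1))),
           meta,
           list(values = lapply(maps, function(m) {
             # row-major (h x w): one vector of rows per map
             lapply(seq_len(nrow(m$values)), function(r) m$values[r, ])
           })))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a heatmap stack from a JSON container
#'
#' @param path Input file path.
#' @return List of [heatmap()] objects with the container's metadata in
#'   `attr(, "meta")`.
#' @export
read_heatmaps <- function(path) {
  if (!file.exists(path)) stop_posevote("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "posevote-heatmaps")
    stop_posevote("not a posevote heatmap container: ", path)
  shape <- as.integer(obj$shape)
  vals <- obj$values
  maps <- lapply(seq_len(shape[1]), function(i) {
    m <- if (is.array(vals) && length(dim(vals)) == 3) {
      matrix(vals[i, , ], shape[2], shape[3])
    } else {
      v <- vals[[i]]
      if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
      matrix(v, shape[2], shape[3])
    }
    heatmap(m, joint_id = obj$joint_ids[i])
  })
  meta <- obj[setdiff(names(obj), c("format", "version", "shape",
                                    "joint_ids", "values"))]
  attr(maps, "meta") <- meta
  maps
}

#' Default run configuration
#'
#' All tunables in one validated list: the loss weights, grid geometry,
#' renderer parameters, correction settings and seeds. Defaults match
#' the reference constants (`omega_c = 0.2`, `omega_p = 1`,
#' `n_iter = 3`, the lambda set of [loss_weights()], a 32 x 32 grid).
#'
#' @return A named list with class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    weights = loss_weights(),
    grid = c(32L, 32L),
    sigma = 1.5,
    gain = 10,
    noise_sigma = 0.05,
    occlusion_rate = 0.2,
    attenuation = 0.1,
    n_iter = 3L,
    uncertainty_floor = 1e-3,
    blend = FALSE,
    seed = 1L
  ), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Missing fields take their [default_config()] values; unknown fields
#' are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `"run_config"` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_posevote("no such config file: ", path)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), c(names(cfg), names(loss_weights())))
    if (length(bad))
      stop_posevote("unknown config field(s): ", paste(bad, collapse = ", "))
    wnames <- intersect(names(user), names(loss_weights()))
    if (length(wnames))
      cfg$weights <- do.call(loss_weights, utils::modifyList(
        unclass(cfg$weights), user[wnames]))
    for (f in intersect(names(user), setdiff(names(cfg), "weights")))
      cfg[[f]] <- user[[f]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (length(cfg$grid) != 2 || any(cfg$grid < 2))
    stop_posevote("config: grid must be two integers >= 2")
  if (cfg$sigma <= 0) stop_posevote("config: sigma must be > 0")
  if (cfg$noise_sigma < 0) stop_posevote("config: noise_sigma must be >= 0")
  if (cfg$occlusion_rate < 0 || cfg$occlusion_rate > 1)
    stop_posevote("config: occlusion_rate must be in [0, 1]")
  if (cfg$n_iter < 1) stop_posevote("config: n_iter must be >= 1")
  if (cfg$uncertainty_floor <= 0)
    stop_posevote("config: uncertainty_floor must be > 0")
  cfg$grid <- as.integer(cfg$grid)
  cfg$n_iter <- as.integer(cfg$n_iter)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; logged with every CLI run so
#' any report can be traced to its exact configuration.
#'
#' @param cfg A `"run_config"` list.
#' @return Lowercase hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
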