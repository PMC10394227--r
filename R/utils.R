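# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_posevote <- function(...) {
  stop(..., call. = FALSE)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop_posevote(what, " contains non-finite values (NaN/Inf/NA)")
  invisible(x)
}

check_matrix <- function(x, what, ncol = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_posevote(what, " must be a numeric matrix")
  if (!is.null(ncol) && ncol(x) != ncol)
    stop_posevote(what, " must have ", ncol, " columns, got ", ncol(x))
  check_finite(x, what)
}

# Weighted column means of a point matrix.
weighted_centroid <- function(X, w) {
  colSums(X * w) / sum(w)
}

# Pooled standard deviation over all coordinates of a centered point set:
# sqrt(mean of squared deviations over all n*d entries).
pooled_sd <- function(Xc) {
  sqrt(mean(Xc^2))
}

# Draw one rotation matrix uniformly on SO(3) (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quaternion_to_rotation(q)
}
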