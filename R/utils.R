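# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# k x 2 coordinate matrix from anything reasonable.
as_coord_matrix <- function(x, arg = "config") {
  if (inherits(x, "corolla_set")) {
    if (n_configs(x) != 1L)
      stop(sprintf("`%s` must be a single configuration", arg))
    x <- x$coords[, , 1L]
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop(sprintf("`%s` must have two coordinate columns", arg))
  if (!all(is.finite(x))) stop(sprintf("`%s` contains non-finite coordinates", arg))
  storage.mode(x) <- "double"
  x
}

# Flatten a p x 2 x n array to n x 2p (columns x1..xp, y1..yp) and back.
flatten_coords <- function(arr) {
  p <- dim(arr)[1L]
  n <- dim(arr)[3L]
  out <- matrix(0, n, 2L * p)
  out[, seq_len(p)] <- t(arr[, 1L, , drop = TRUE])
  out[, p + seq_len(p)] <- t(arr[, 2L, , drop = TRUE])
  out
}

unflatten_coords <- function(mat, p) {
  n <- nrow(mat)
  arr <- array(0, dim = c(p, 2L, n))
  arr[, 1L, ] <- t(mat[, seq_len(p), drop = FALSE])
  arr[, 2L, ] <- t(mat[, p + seq_len(p), drop = FALSE])
  arr
}

center_config <- function(x) sweep(x, 2L, colMeans(x))

rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Weighted between-group sum of squares of row vectors given per-row group
# sums and sizes: sum_g n_g ||mu_g - mu_parent(g)||^2.  `sums` is G x d,
# `sizes` length G, `parent` maps each group to its parent's row in
# `parent_sums`/`parent_sizes` (or NULL for the grand level).
between_ss <- function(sums, sizes, parent = NULL, parent_sums = NULL,
                       parent_sizes = NULL) {
  mu <- sums / sizes
  if (is.null(parent)) {
    grand <- colSums(sums) / sum(sizes)
    dev <- sweep(mu, 2L, grand)
  } else {
    dev <- mu - parent_sums[parent, , drop = FALSE] / parent_sizes[parent]
  }
  sum(sizes * rowSums(dev * dev))
}
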