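#' Collection of landmark configurations with nested-design metadata
#'
#' A `corolla_set` bundles an array of 2D landmark configurations with the
#' metadata of the nested sampling design used throughout the package:
#' sexual group / tree / flower / imaging replicate / digitisation replicate,
#' plus the symmetry-transform label of each configuration (raw digitised
#' data carry `"identity"`).
#'
#' @param coords a `p x 2 x n` array of landmark coordinates, or a list of
#'   `p x 2` matrices, or a single `p x 2` matrix.
#' @param meta optional `data.frame` with one row per configuration; missing
#'   columns among `object_id`, `flower`, `tree`, `sex`, `imaging`,
#'   `digitisation`, `transform` are filled with defaults.
#' @param n_petals number of repeated petal blocks the landmarks are divided
#'   into (landmark count must be divisible by it). The package is tested
#'   with tetrameric (4-petal) corollas.
#'
#' @return An object of class `corolla_set`: a list with elements `coords`
#'   (`p x 2 x n` array), `meta` (data frame) and `n_petals`.
#' @export
#' @examples
#' cfg <- matrix(rnorm(16), 8, 2)
#' cs <- corolla_set(cfg, n_petals = 4)
#' n_configs(cs)
corolla_set <- function(coords, meta = NULL, n_petals = 4L) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (is.list(coords) && !is.array(coords)) {
    p <- nrow(coords[[1L]])
    if (!all(vapply(coords, nrow, 0L) == p))
      stop("all configurations must have the same landmark count")
    coords <- array(unlist(coords), dim = c(p, 2L, length(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2L] != 2L)
    stop("`coords` must be a p x 2 x n array")
  if (!all(is.finite(coords))) stop("coordinates contain non-finite values")
  p <- dim(coords)[1L]
  n <- dim(coords)[3L]
  n_petals <- as.integer(n_petals)
  if (p %% n_petals != 0L)
    stop(sprintf("landmark count %d is not divisible by n_petals = %d", p, n_petals))
  defaults <- data.frame(
    object_id = sprintf("obj%04d", seq_len(n)),
    flower = NA_character_, tree = NA_character_, sex = NA_character_,
    imaging = 1L, digitisation = 1L, transform = "identity",
    stringsAsFactors = FALSE
  )
  if (is.null(meta)) {
    meta <- defaults
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (nrow(meta) != n) stop("`meta` must have one row per configuration")
    for (col in names(defaults))
      if (is.null(meta[[col]])) meta[[col]] <- defaults[[col]]
    meta <- meta[, union(names(defaults), names(meta)), drop = FALSE]
  }
  structure(list(coords = coords, meta = meta, n_petals = n_petals),
            class = "corolla_set")
}

#' Number of configurations in a corolla set
#' @param x a [corolla_set()].
#' @return integer count.
#' @export
n_configs <- function(x) {
  stopifnot(inherits(x, "corolla_set"))
  dim(x$coords)[3L]
}

#' @export
print.corolla_set <- function(x, ...) {
  p <- dim(x$coords)[1L]
  cat(sprintf("corolla_set: %d configurations, %d landmarks (%d petals x %d points)\n",
              n_configs(x), p, x$n_petals, p %/% x$n_petals))
  tr <- table(x$meta$transform)
  cat("  transforms:", paste(sprintf("%s=%d", names(tr), tr), collapse = ", "), "\n")
  if (!all(is.na(x$meta$sex))) {
    sx <- table(x$meta$sex)
    cat("  sex:", paste(sprintf("%s=%d", names(sx), sx), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.corolla_set` <- function(x, i, ...) {
  corolla_set(x$coords[, , i, drop = FALSE], x$meta[i, , drop = FALSE],
              n_petals = x$n_petals)
}

#' Summarise the nested design of a corolla set
#'
#' Counts the levels of the sampling design (sexes, trees, flowers, imaging
#' and digitisation replicates, symmetry transforms).
#'
#' @param object a [corolla_set()].
#' @param ... unused.
#' @return a named list of counts.
#' @export
summary.corolla_set <- function(object, ...) {
  m <- object$meta
  out <- list(
    configurations = n_configs(object),
    sexes = length(unique(stats::na.omit(m$sex))),
    trees = length(unique(stats::na.omit(m$tree))),
    flowers = length(unique(stats::na.omit(m$flower))),
    imaging = length(unique(m$imaging)),
    digitisation = length(unique(m$digitisation)),
    transforms = length(unique(m$transform))
  )
  class(out) <- "summary.corolla_set"
  out
}

#' @export
print.summary.corolla_set <- function(x, ...) {
  cat("design:", paste(sprintf("%s=%d", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}
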