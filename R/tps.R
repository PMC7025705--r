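#' Resample an open polyline to equidistant points
#'
#' Places `n_points` points at equal arc-length spacing along an ordered open
#' 2D polyline, preserving both endpoints exactly. This is the operation used
#' to turn digitised outline curves into the fixed number of semilandmarks
#' per petal.
#'
#' @param curve an `m x 2` matrix of ordered points (m >= 2, not all
#'   coincident).
#' @param n_points number of output points (>= 2).
#' @return an `n_points x 2` matrix.
#' @export
#' @examples
#' resample_outline(rbind(c(0, 0), c(1, 0)), 5)
resample_outline <- function(curve, n_points) {
  curve <- as_coord_matrix(curve, "curve")
  if (n_points < 2L) stop("`n_points` must be at least 2")
  if (nrow(curve) < 2L) stop("`curve` must have at least 2 points")
  seg <- sqrt(rowSums((curve[-1L, , drop = FALSE] -
                         curve[-nrow(curve), , drop = FALSE])^2))
  total <- sum(seg)
  if (total == 0) stop("degenerate input: zero-length curve")
  s <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = n_points)
  xi <- stats::approx(s, curve[, 1L], xout = target, ties = "ordered")$y
  yi <- stats::approx(s, curve[, 2L], xout = target, ties = "ordered")$y
  out <- cbind(xi, yi, deparse.level = 0)
  out[1L, ] <- curve[1L, ]
  out[n_points, ] <- curve[nrow(curve), ]
  out
}

#' Read a TPS landmark file
#'
#' Parses the loosely specified TPS format produced by the tps-series
#' digitising tools: records introduced by `LM=<count>`, followed by
#' whitespace-separated coordinate lines (y axis up) and optional `IMAGE=`,
#' `ID=` and `SCALE=` keys. `SCALE` multiplies the record's coordinates.
#' Three-dimensional records (`LM3=`) are rejected. Record order is
#' preserved.
#'
#' @param path path to the TPS file.
#' @param meta optional path to a sidecar metadata CSV with columns
#'   `object_id, flower, tree, sex, imaging, digitisation` (joined by
#'   `object_id` against the records' `ID=` values, or by order when the
#'   file has no IDs), or a data frame of the same shape.
#' @param n_petals passed to [corolla_set()].
#' @return a [corolla_set()].
#' @export
read_tps <- function(path, meta = NULL, n_petals = 4L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM3?=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= records found in TPS file")
  if (any(grepl("^LM3=", lines[starts], ignore.case = TRUE)))
    stop("LM3= (3D) records are not supported; this reader is 2D only")
  ends <- c(starts[-1L] - 1L, length(lines))
  coords <- vector("list", length(starts))
  ids <- character(length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    n_lm <- as.integer(sub("^LM=", "", block[1L], ignore.case = TRUE))
    body <- block[-1L]
    is_key <- grepl("^[A-Za-z]+=", body)
    coord_lines <- body[!is_key]
    if (length(coord_lines) != n_lm)
      stop(sprintf("record %d: LM=%d but %d coordinate lines found",
                   r, n_lm, length(coord_lines)))
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "[[:space:]]+"),
                                function(v) as.numeric(v[1:2])))
    if (anyNA(xy)) stop(sprintf("record %d: malformed coordinates", r))
    keys <- body[is_key]
    scale_key <- grep("^SCALE=", keys, ignore.case = TRUE, value = TRUE)
    if (length(scale_key)) xy <- xy * as.numeric(sub("^SCALE=", "", scale_key[1L],
                                                     ignore.case = TRUE))
    id_key <- grep("^ID=", keys, ignore.case = TRUE, value = TRUE)
    ids[r] <- if (length(id_key)) sub("^ID=", "", id_key[1L], ignore.case = TRUE)
              else sprintf("obj%04d", r)
    coords[[r]] <- xy
  }
  p <- vapply(coords, nrow, 0L)
  if (length(unique(p)) != 1L)
    stop(sprintf("mixed landmark counts in TPS file: %s",
                 paste(unique(p), collapse = ", ")))
  mdf <- data.frame(object_id = ids, stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    mt <- if (is.character(meta)) utils::read.csv(meta, stringsAsFactors = FALSE)
          else as.data.frame(meta)
    if (all(ids %in% mt$object_id)) {
      mdf <- mt[match(ids, mt$object_id), , drop = FALSE]
    } else if (nrow(mt) == length(ids)) {
      mdf <- mt
      mdf$object_id <- ids
    } else {
      stop("metadata cannot be joined: object_id mismatch and row count differs")
    }
    rownames(mdf) <- NULL
  }
  corolla_set(coords, mdf, n_petals = n_petals)
}

#' Write a TPS landmark file (and optional metadata sidecar)
#'
#' Writes one `LM=`/coordinates/`ID=` record per configuration, with enough
#' digits for a 1e-9 round trip. When `meta_path` is given, the nested-design
#' metadata is written as the sidecar CSV consumed by [read_tps()].
#'
#' @param x a [corolla_set()].
#' @param path output TPS path.
#' @param meta_path optional output CSV path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "corolla_set"))
  p <- dim(x$coords)[1L]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_configs(x))) {
    writeLines(sprintf("LM=%d", p), con)
    writeLines(sprintf("%.12g %.12g", x$coords[, 1L, i], x$coords[, 2L, i]), con)
    writeLines(sprintf("ID=%s", x$meta$object_id[i]), con)
  }
  if (!is.null(meta_path)) {
    cols <- c("object_id", "flower", "tree", "sex", "imaging", "digitisation")
    utils::write.csv(x$meta[, cols], meta_path, row.names = FALSE)
  }
  invisible(path)
}

#' Export configurations as a flat coordinate CSV
#'
#' One row per configuration with columns `object_id, x1, y1, ..., xp, yp`.
#'
#' @param x a [corolla_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coords_csv <- function(x, path) {
  stopifnot(inherits(x, "corolla_set"))
  p <- dim(x$coords)[1L]
  n <- n_configs(x)
  m <- matrix(0, n, 2L * p)
  m[, seq(1L, 2L * p, by = 2L)] <- t(x$coords[, 1L, , drop = TRUE])
  m[, seq(2L, 2L * p, by = 2L)] <- t(x$coords[, 2L, , drop = TRUE])
  df <- data.frame(object_id = x$meta$object_id, m)
  names(df) <- c("object_id", paste0(rep(c("x", "y"), p), rep(seq_len(p), each = 2L)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Re-label a configuration digitised in the opposite direction
#'
#' A corolla outline digitised counter-clockwise instead of clockwise visits
#' the same points in reverse sequence. This operation reverses the
#' within-petal point order (point i -> point k+1-i) and the petal block
#' order so the re-labelled configuration matches the canonical labels; it is
#' an involution (applying it twice returns the input exactly).
#'
#' @param config a `p x 2` coordinate matrix or single-configuration
#'   [corolla_set()].
#' @param n_petals number of petal blocks.
#' @return object of the same type as the input.
#' @export
reverse_digitisation <- function(config, n_petals = 4L) {
  if (inherits(config, "corolla_set")) {
    out <- config
    out$coords <- config$coords[rev(seq_len(dim(config$coords)[1L])), , ,
                                drop = FALSE]
    return(out)
  }
  config <- as_coord_matrix(config)
  if (nrow(config) %% n_petals != 0L)
    stop("landmark count not divisible by n_petals")
  config[rev(seq_len(nrow(config))), , drop = FALSE]
}
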