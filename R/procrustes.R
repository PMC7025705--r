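#' Centroid size of a configuration
#'
#' The square root of the sum of squared distances of all landmarks from
#' their centroid — the standard size measure of geometric morphometrics.
#' Scale-equivariant (`centroid_size(c * X) = c * centroid_size(X)`) and
#' invariant to rotation and translation.
#'
#' @param config a `p x 2` coordinate matrix (or single-configuration
#'   [corolla_set()]).
#' @return a positive scalar; 0 (with a warning) when all points coincide.
#' @export
#' @examples
#' centroid_size(rbind(c(-.5, -.5), c(.5, -.5), c(.5, .5), c(-.5, .5)))
centroid_size <- function(config) {
  m <- as_coord_matrix(config)
  if (nrow(m) < 2L) stop("need at least 2 points")
  cs <- sqrt(sum(center_config(m)^2))
  if (cs == 0) warning("degenerate configuration: all points coincident")
  cs
}

# Optimal rotation (determinant +1, reflections forbidden) of Y onto C,
# both assumed centered: returns the 2x2 rotation R minimizing ||Y R - C||.
optimal_rotation <- function(Y, C) {
  A <- crossprod(Y, C)
  s <- svd(A)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Pairwise partial Procrustes fit
#'
#' Centers and unit-scales both configurations, then rotates the source onto
#' the target minimizing the summed squared distance. Reflection is never
#' allowed (the rotation has determinant +1): reflected copies enter the
#' analysis as explicit data points, so allowing reflection here would
#' collapse the asymmetric subspaces.
#'
#' @param source,target `p x 2` coordinate matrices with equal landmark
#'   counts.
#' @return list with `aligned` (fitted source), `target` (centered,
#'   unit-scaled target), `rotation` (2x2 matrix) and `distance` (root
#'   summed squared difference).
#' @export
partial_procrustes_fit <- function(source, target) {
  S <- as_coord_matrix(source, "source")
  Tm <- as_coord_matrix(target, "target")
  if (nrow(S) != nrow(Tm)) stop("landmark counts differ")
  S <- center_config(S); Tm <- center_config(Tm)
  cs_s <- sqrt(sum(S^2)); cs_t <- sqrt(sum(Tm^2))
  if (cs_s == 0 || cs_t == 0) stop("degenerate (zero centroid size) input")
  S <- S / cs_s; Tm <- Tm / cs_t
  R <- optimal_rotation(S, Tm)
  A <- S %*% R
  list(aligned = A, target = Tm, rotation = R,
       distance = sqrt(sum((A - Tm)^2)))
}

#' Semilandmark slider specification
#'
#' Declares which landmarks are fixed and which slide along the outline. For
#' a corolla of `n_petals` blocks of `k` points, the first and last point of
#' each petal (the basal corners) are fixed landmarks and the `k - 2`
#' interior points are sliders; each slider's tangent is the chord between
#' its two within-petal neighbours.
#'
#' @param p total number of landmarks.
#' @param n_petals number of petal blocks.
#' @return an object of class `slider_spec`: list with `fixed` (indices),
#'   `sliders` (matrix with columns `before`, `point`, `after`).
#' @export
#' @examples
#' sp <- slider_spec(200, 4)
#' length(sp$fixed); nrow(sp$sliders)
slider_spec <- function(p, n_petals = 4L) {
  if (p %% n_petals != 0L) stop("p must be divisible by n_petals")
  k <- p %/% n_petals
  if (k < 3L) stop("petals need at least 3 points for sliding")
  fixed <- integer(0); sl <- list()
  for (b in seq_len(n_petals)) {
    off <- (b - 1L) * k
    fixed <- c(fixed, off + 1L, off + k)
    ii <- off + 2:(k - 1L)
    sl[[b]] <- cbind(before = ii - 1L, point = ii, after = ii + 1L)
  }
  structure(list(fixed = fixed, sliders = do.call(rbind, sl), p = p,
                 n_petals = n_petals),
            class = "slider_spec")
}

#' Thin-plate-spline bending energy matrix
#'
#' The standard 2D TPS construction with kernel `U(r) = r^2 log r`: the
#' bending energy matrix is the upper-left `p x p` block of the inverse of
#' `L = [[K, Q], [Q', 0]]` with `Q = [1, x, y]`. Its quadratic form measures
#' the non-affine part of a deformation from the reference; affine
#' deformations have exactly zero bending energy.
#'
#' @param reference `p x 2` reference configuration.
#' @return a symmetric `p x p` matrix.
#' @export
bending_energy_matrix <- function(reference) {
  X <- as_coord_matrix(reference, "reference")
  p <- nrow(X)
  r2 <- as.matrix(stats::dist(X))^2
  K <- matrix(0, p, p)
  pos <- r2 > 0
  K[pos] <- r2[pos] * log(r2[pos]) / 2   # r^2 log r = r^2 log(r^2)/2
  Q <- cbind(1, X)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Li <- tryCatch(solve(L), error = function(e) {
    warning("singular TPS system; using ridge-regularized solve")
    solve(L + diag(1e-8 * mean(abs(diag(L)) + 1), p + 3L))
  })
  B <- Li[seq_len(p), seq_len(p), drop = FALSE]
  (B + t(B)) / 2
}

#' Bending energy of a configuration relative to a reference
#'
#' @param reference `p x 2` reference (defines the TPS kernel).
#' @param config `p x 2` target configuration.
#' @param B optional precomputed [bending_energy_matrix()] of `reference`.
#' @return non-negative scalar (0 for affine deformations of the reference).
#' @export
bending_energy <- function(reference, config, B = NULL) {
  Y <- as_coord_matrix(config)
  if (is.null(B)) B <- bending_energy_matrix(reference)
  sum(Y[, 1L] * (B %*% Y[, 1L])) + sum(Y[, 2L] * (B %*% Y[, 2L]))
}

#' Slide semilandmarks to minimize bending energy
#'
#' For each superimposed configuration, every slider moves along its tangent
#' direction (the unit chord between its two outline neighbours) by the
#' amount minimizing the thin-plate-spline bending energy of the
#' configuration relative to the consensus; the sliders' joint optimum is the
#' solution of one linear system per configuration. Fixed landmarks never
#' move, and the bending energy never increases (the unslid position is a
#' feasible point of the minimized quadratic).
#'
#' @param aligned `p x 2 x n` array of superimposed configurations (or a
#'   single `p x 2` matrix).
#' @param consensus `p x 2` consensus configuration.
#' @param sliders a [slider_spec()].
#' @return object of the same shape as `aligned` with sliders displaced.
#' @export
slide_semilandmarks <- function(aligned, consensus, sliders) {
  stopifnot(inherits(sliders, "slider_spec"))
  single <- is.matrix(aligned)
  if (single) aligned <- array(aligned, dim = c(dim(aligned), 1L))
  X <- as_coord_matrix(consensus, "consensus")
  B <- bending_energy_matrix(X)
  si <- sliders$sliders[, "point"]
  Bss <- B[si, si, drop = FALSE]
  out <- aligned
  for (i in seq_len(dim(aligned)[3L])) {
    Y <- aligned[, , i]
    tang <- Y[sliders$sliders[, "after"], , drop = FALSE] -
      Y[sliders$sliders[, "before"], , drop = FALSE]
    len <- sqrt(rowSums(tang^2))
    len[len == 0] <- 1
    ux <- tang[, 1L] / len; uy <- tang[, 2L] / len
    Rx <- B %*% (Y[, 1L] - X[, 1L])
    Ry <- B %*% (Y[, 2L] - X[, 2L])
    A <- Bss * (outer(ux, ux) + outer(uy, uy))
    b <- -(ux * Rx[si] + uy * Ry[si])
    t_opt <- tryCatch(solve(A, b), error = function(e) {
      warning("singular sliding system; using ridge-regularized solve")
      solve(A + diag(1e-10 * (mean(diag(A)) + 1), nrow(A)), b)
    })
    Y[si, 1L] <- Y[si, 1L] + ux * t_opt
    Y[si, 2L] <- Y[si, 2L] + uy * t_opt
    out[, , i] <- Y
  }
  if (single) out[, , 1L] else out
}

#' Generalized Procrustes analysis with optional sliding semilandmarks
#'
#' Iteratively centers, scales to unit centroid size and rotates all
#' configurations onto their consensus (full Procrustes, reflections
#' forbidden), recomputing the consensus until its root-mean-square change
#' falls below `tol`. When a [slider_spec()] is given, converged alignment
#' rounds alternate with bending-energy sliding of the semilandmarks against
#' the grand consensus (`slide_iter` outer rounds). Centroid sizes are
#' recorded from the raw input coordinates before any scaling. The final
#' orientation is canonicalized by rotating the consensus so that its first
#' petal block's centroid sits on the 45-degree bisector, which makes the
#' result invariant to the input's ordering, orientation, position and
#' scale.
#'
#' @param data a [corolla_set()] or `p x 2 x n` array (n >= 2).
#' @param sliders optional [slider_spec()]; `NULL` disables sliding.
#' @param max_iter maximum alignment iterations per round.
#' @param tol convergence tolerance on the consensus RMS change.
#' @param slide_iter number of outer align-slide rounds when `sliders` is
#'   given.
#' @return an object of class `gpa_result`: list with `aligned`
#'   (`p x 2 x n`, each centered with unit centroid size), `consensus`
#'   (`p x 2`, the coordinate-wise mean of `aligned`), `centroid_size`
#'   (length-n, raw units), `iterations`, `deltas` (consensus changes),
#'   `objective` (summed squared deviation from the consensus after each
#'   alignment iteration) and `sliders`.
#' @export
gpa <- function(data, sliders = NULL, max_iter = 100L, tol = 1e-6,
                slide_iter = 5L) {
  n_petals <- 4L
  if (inherits(data, "corolla_set")) {
    n_petals <- data$n_petals
    arr <- data$coords
  } else arr <- data
  stopifnot(length(dim(arr)) == 3L, dim(arr)[2L] == 2L)
  p <- dim(arr)[1L]; n <- dim(arr)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  cs <- numeric(n)
  Xc <- arr
  for (i in seq_len(n)) {
    m <- center_config(arr[, , i])
    cs[i] <- sqrt(sum(m^2))
    if (cs[i] == 0) stop(sprintf("configuration %d has zero centroid size", i))
    Xc[, , i] <- m / cs[i]
  }

  align_round <- function(Xc, consensus) {
    deltas <- objective <- numeric(0)
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n))
        Xc[, , i] <- Xc[, , i] %*% optimal_rotation(Xc[, , i], consensus)
      raw_mean <- apply(Xc, c(1L, 2L), mean)
      objective <- c(objective, sum(sweep(Xc, c(1L, 2L), raw_mean)^2))
      newc <- center_config(raw_mean)
      newc <- newc / sqrt(sum(newc^2))
      delta <- sqrt(mean((newc - consensus)^2))
      deltas <- c(deltas, delta)
      consensus <- newc
      if (delta < tol) break
    }
    list(Xc = Xc, consensus = consensus, deltas = deltas, objective = objective)
  }

  consensus <- Xc[, , 1L]
  rd <- align_round(Xc, consensus)
  deltas <- rd$deltas
  objective <- rd$objective
  if (!is.null(sliders)) {
    stopifnot(inherits(sliders, "slider_spec"), sliders$p == p)
    for (s in seq_len(slide_iter)) {
      slid <- slide_semilandmarks(rd$Xc, rd$consensus, sliders)
      for (i in seq_len(n)) {
        m <- center_config(slid[, , i])
        slid[, , i] <- m / sqrt(sum(m^2))
      }
      rd <- align_round(slid, rd$consensus)
      deltas <- c(deltas, rd$deltas)
      objective <- c(objective, rd$objective)
    }
  }
  if (utils::tail(deltas, 1L) >= tol)
    warning(sprintf("GPA did not converge below tol = %g (final delta %.3g)",
                    tol, utils::tail(deltas, 1L)))

  # canonical orientation: first petal block centroid at the 45-degree bisector
  Xc <- rd$Xc
  consensus <- apply(Xc, c(1L, 2L), mean)
  k <- p %/% n_petals
  dir <- colMeans(consensus[seq_len(k), , drop = FALSE]) - colMeans(consensus)
  ang <- atan2(dir[2L], dir[1L])
  # row-vector convention: Y %*% rotation_matrix(theta) rotates by -theta
  R <- rotation_matrix(ang - pi / 4)
  for (i in seq_len(n)) Xc[, , i] <- Xc[, , i] %*% R
  consensus <- consensus %*% R

  structure(list(aligned = Xc, consensus = consensus, centroid_size = cs,
                 iterations = length(deltas), deltas = deltas,
                 objective = objective, sliders = sliders,
                 n_petals = n_petals),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("gpa_result: %d configurations, %d landmarks, %d iterations (final delta %.3g)%s\n",
              dim(x$aligned)[3L], dim(x$aligned)[1L], x$iterations,
              utils::tail(x$deltas, 1L),
              if (is.null(x$sliders)) "" else ", with sliding semilandmarks"))
  invisible(x)
}
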