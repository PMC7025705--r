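# Independent oracles used to cross-check the package's implementations.
# They deliberately use different algorithms than the code under test.

# Brute-force pairwise Procrustes distance: minimize over a fine rotation
# grid instead of the SVD solution.
grid_procrustes_distance <- function(source, target, step = 1e-4) {
  S <- scale(source, scale = FALSE); S <- S / sqrt(sum(S^2))
  Tm <- scale(target, scale = FALSE); Tm <- Tm / sqrt(sum(Tm^2))
  A <- crossprod(S, Tm)
  theta <- seq(0, 2 * pi, by = step)
  # ||S R(theta) - T||^2 = 2 - 2 * (a cos + b sin) for unit-size S, T
  a <- A[1, 1] + A[2, 2]
  b <- A[1, 2] - A[2, 1]
  sqrt(max(0, min(2 - 2 * (a * cos(theta) + b * sin(theta)))))
}

# Plain GPA implemented independently via the closed-form 2D rotation fit
# (complex/atan2 algebra, no SVD), full Procrustes, no sliding.
oracle_gpa <- function(arr, max_iter = 200, tol = 1e-12) {
  n <- dim(arr)[3]
  X <- arr
  for (i in seq_len(n)) {
    m <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
    X[, , i] <- m / sqrt(sum(m^2))
  }
  cons <- X[, , 1]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      A <- crossprod(X[, , i], cons)
      th <- atan2(A[2, 1] - A[1, 2], A[1, 1] + A[2, 2])
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      X[, , i] <- X[, , i] %*% R
    }
    newc <- apply(X, c(1, 2), mean)
    newc <- sweep(newc, 2, colMeans(newc))
    newc <- newc / sqrt(sum(newc^2))
    if (sqrt(mean((newc - cons)^2)) < tol) { cons <- newc; break }
    cons <- newc
  }
  list(aligned = X, consensus = apply(X, c(1, 2), mean))
}

# Copy-projection classification oracle: label each PC from the score
# pattern of the four symmetry copies of every object (equal scores =>
# symmetric; mirror-pair patterns identify the asymmetric subspaces).
copy_projection_labels <- function(dec, meta, ev_floor = 1e-9) {
  stopifnot(!is.null(meta$object_id), !is.null(meta$transform))
  n_pc <- ncol(dec$scores)
  labels <- rep("negligible", n_pc)
  ids <- meta$object_id
  trs <- c("identity", "reflectV", "reflectH", "reflectHV")
  ord <- order(ids, match(meta$transform, trs))
  sc <- dec$scores[ord, , drop = FALSE]
  n_obj <- length(unique(ids))
  for (j in seq_len(n_pc)) {
    if (dec$eigenvalues[j] <= ev_floor * dec$eigenvalues[1]) next
    m <- matrix(sc[, j], nrow = 4L)  # rows: identity, V, H, HV per object
    denom <- mean(m[1, ]^2)
    if (denom == 0) next
    r <- rowMeans(m * rep(m[1, ], each = 4L)) / denom  # correlation pattern
    pat <- round(r)
    if (all(pat == c(1, 1, 1, 1))) labels[j] <- "symmetric"
    else if (all(pat == c(1, -1, -1, 1))) labels[j] <- "transversal"
    else if (all(pat == c(1, 1, -1, -1)) || all(pat == c(1, -1, 1, -1)))
      labels[j] <- "lateral"
    else labels[j] <- "ambiguous"
  }
  labels
}

# arc-length position of a point along a polyline (the point is assumed to
# lie on it): cumulative length up to the nearest segment projection
arc_position <- function(poly, pt) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- pmin(pmax(((pt[1] - a[, 1]) * ab[, 1] + (pt[2] - a[, 2]) * ab[, 2]) /
                   pmax(len2, 1e-300), 0), 1)
  proj <- a + ab * t
  d2 <- (proj[, 1] - pt[1])^2 + (proj[, 2] - pt[2])^2
  i <- which.min(d2)
  seg <- sqrt(len2)
  sum(seg[seq_len(i - 1)]) + t[i] * seg[i]
}

# direct covariance eigendecomposition (PCA oracle)
oracle_pca <- function(X) {
  e <- eigen(stats::cov(X), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors,
       scores = sweep(X, 2, colMeans(X)) %*% e$vectors)
}
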