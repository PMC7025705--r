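#' Principal component analysis of aligned shape coordinates
#'
#' PCA of the Procrustes-aligned coordinates of the symmetry-expanded
#' dataset about the grand mean, using the covariance of the flattened
#' coordinates with divisor `n - 1`. Because the expanded dataset is closed
#' under the symmetry group, the sample covariance commutes with every
#' symmetry transform and the principal components fall into character-pure
#' subspaces (up to eigenvalue degeneracy, handled by
#' [classify_components()]).
#'
#' @param alignment a [gpa_result][gpa()] on the expanded dataset.
#' @param meta optional metadata data frame (one row per configuration),
#'   carried along for score tables.
#' @return an object of class `shape_decomposition`: list with
#'   `eigenvectors` (`2p x m`, columns orthonormal), `eigenvalues` (length
#'   m, decreasing), `scores` (`n x m`), `center` (flattened grand mean),
#'   `total_variance`, `labels` (all `"unlabelled"` until classification),
#'   `characters`, `p`, `n_petals`, `meta`.
#' @export
shape_pca <- function(alignment, meta = NULL) {
  stopifnot(inherits(alignment, "gpa_result"))
  n <- dim(alignment$aligned)[3L]
  if (n < 2L) stop("PCA needs at least 2 configurations")
  p <- dim(alignment$aligned)[1L]
  X <- flatten_coords(alignment$aligned)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0)
  keep <- seq_len(min(n - 1L, ncol(Xc)))
  eig <- sv$d[keep]^2 / (n - 1L)
  vec <- sv$v[, keep, drop = FALSE]
  scores <- Xc %*% vec
  structure(list(eigenvectors = vec, eigenvalues = eig, scores = scores,
                 center = ctr, total_variance = sum(Xc^2) / (n - 1L),
                 labels = rep("unlabelled", length(eig)),
                 characters = matrix(NA_real_, length(eig), 2L,
                                     dimnames = list(NULL, c("s_V", "s_H"))),
                 p = p, n_petals = alignment$n_petals, meta = meta),
            class = "shape_decomposition")
}

#' Classify principal components into symmetry subspaces
#'
#' Computes each unit eigenvector's character under the two reflection
#' transforms, `s_T = v . T(v)`. Each transform is an orthogonal map of
#' shape space that fixes the (symmetric) consensus, so it preserves the
#' space the aligned deviations live in and the character of a pure
#' component is exactly +1 or -1. Components with both
#' characters above `threshold` are fully `symmetric` (the four symmetry
#' copies of an object have identical scores); both below `-threshold` is
#' `transversal` asymmetry (opposite petal pairs contrast); opposite signs
#' are `lateral` asymmetry (adjacent pairs contrast; the two lateral
#' subspaces cannot be told apart because the two symmetry axes are
#' anatomically ambiguous, so they are pooled). Components that mix
#' characters — possible only within (near-)degenerate eigenvalue blocks —
#' are re-rotated inside each such block to diagonalize the transforms;
#' anything still mixed is labelled `ambiguous`. Components with eigenvalues
#' below `ev_tol` (relative to the leading eigenvalue) are numerical noise
#' and labelled `negligible`.
#'
#' @param dec a [shape_pca()] result.
#' @param threshold character magnitude required for a pure label.
#' @param ev_tol relative eigenvalue floor for classification.
#' @return `dec` with `labels` and `characters` filled in (eigenvectors and
#'   scores are updated where degenerate blocks were re-rotated).
#' @export
classify_components <- function(dec, threshold = 0.9, ev_tol = 1e-12) {
  stopifnot(inherits(dec, "shape_decomposition"))
  trs <- symmetry_transforms()
  p <- dec$p
  tv <- function(v, tr) transform_shape_vector(v, tr, p, dec$n_petals)
  m <- length(dec$eigenvalues)
  active <- which(dec$eigenvalues > ev_tol * dec$eigenvalues[1L])
  sV <- sH <- rep(NA_real_, m)
  for (j in active) {
    v <- dec$eigenvectors[, j]
    sV[j] <- sum(v * tv(v, trs$reflectV))
    sH[j] <- sum(v * tv(v, trs$reflectH))
  }
  label_of <- function(a, b) {
    if (is.na(a) || is.na(b)) return("negligible")
    if (a > threshold && b > threshold) return("symmetric")
    if (a < -threshold && b < -threshold) return("transversal")
    if (abs(a) > threshold && abs(b) > threshold && a * b < 0) return("lateral")
    "ambiguous"
  }
  labels <- mapply(label_of, sV, sH)

  # re-rotate within contiguous ambiguous blocks (near-degenerate spectra)
  amb <- which(labels == "ambiguous")
  if (length(amb) > 1L) {
    blocks <- split(amb, cumsum(c(1L, diff(amb) != 1L)))
    for (blk in blocks) {
      if (length(blk) < 2L) next
      V <- dec$eigenvectors[, blk, drop = FALSE]
      MV <- crossprod(V, apply(V, 2L, tv, tr = trs$reflectV))
      eV <- eigen((MV + t(MV)) / 2, symmetric = TRUE)
      Rot <- eV$vectors
      # within each eigenvalue cluster of T_V, diagonalize T_H too
      cl <- cumsum(c(1L, abs(diff(eV$values)) > 0.5))
      for (g in unique(cl)) {
        sub <- which(cl == g)
        if (length(sub) < 2L) next
        W <- V %*% Rot[, sub, drop = FALSE]
        MH <- crossprod(W, apply(W, 2L, tv, tr = trs$reflectH))
        eH <- eigen((MH + t(MH)) / 2, symmetric = TRUE)
        Rot[, sub] <- Rot[, sub, drop = FALSE] %*% eH$vectors
      }
      Vnew <- V %*% Rot
      dec$eigenvectors[, blk] <- Vnew
      dec$scores[, blk] <- dec$scores[, blk, drop = FALSE] %*% Rot
      lam <- colSums(Rot^2 * dec$eigenvalues[blk])
      dec$eigenvalues[blk] <- lam
      for (idx in seq_along(blk)) {
        j <- blk[idx]
        v <- Vnew[, idx]
        sV[j] <- sum(v * tv(v, trs$reflectV))
        sH[j] <- sum(v * tv(v, trs$reflectH))
        labels[j] <- label_of(sV[j], sH[j])
      }
    }
  }
  dec$characters <- cbind(s_V = sV, s_H = sH)
  dec$labels <- labels
  dec
}

#' Variance fractions of the symmetry subspaces
#'
#' Sums the eigenvalues of the components carrying each label and expresses
#' them as percentages of the total shape variance.
#'
#' @param dec a classified [shape_pca()] result.
#' @return named numeric vector with elements `symmetric`, `lateral`,
#'   `transversal` (percent), plus `unassigned` when ambiguous components
#'   are present (with a warning).
#' @export
variance_fractions <- function(dec) {
  stopifnot(inherits(dec, "shape_decomposition"))
  if (all(dec$labels == "unlabelled"))
    stop("run classify_components() first")
  tot <- sum(dec$eigenvalues)
  frac <- function(lab) 100 * sum(dec$eigenvalues[dec$labels == lab]) / tot
  out <- c(symmetric = frac("symmetric"), lateral = frac("lateral"),
           transversal = frac("transversal"))
  amb <- frac("ambiguous")
  if (amb > 0) {
    warning(sprintf("%.3g%% of variance on ambiguous components reported as unassigned", amb))
    out <- c(out, unassigned = amb)
  }
  out
}

#' Per-object asymmetry scores
#'
#' For each configuration, the Euclidean distance of its scores on the PCs
#' of an asymmetric subspace from the subspace origin (the ideally symmetric
#' consensus): the magnitude of that type of asymmetry in shape units. The
#' four symmetry copies of an object sit in mirror positions and share the
#' same distance. `mode = "per_flower"` averages the scores over symmetry
#' copies and imaging/digitisation replicates of each flower.
#'
#' @param dec a classified [shape_pca()] result whose `meta` rows describe
#'   the configurations.
#' @param mode `"per_configuration"` or `"per_flower"`.
#' @param method `"norm"` (Euclidean distance in the subspace, default) or
#'   `"abs_sum"` (sum of per-PC absolute distances).
#' @return a data frame with the identifying metadata columns plus
#'   `lateral_score` and `transversal_score`.
#' @export
asymmetry_scores <- function(dec, mode = c("per_configuration", "per_flower"),
                             method = c("norm", "abs_sum")) {
  stopifnot(inherits(dec, "shape_decomposition"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (all(dec$labels == "unlabelled"))
    stop("run classify_components() first")
  if (is.null(dec$meta)) stop("decomposition carries no metadata")
  score_of <- function(lab) {
    S <- dec$scores[, dec$labels == lab, drop = FALSE]
    if (method == "norm") sqrt(rowSums(S^2)) else rowSums(abs(S))
  }
  df <- data.frame(dec$meta,
                   lateral_score = score_of("lateral"),
                   transversal_score = score_of("transversal"),
                   stringsAsFactors = FALSE)
  if (mode == "per_configuration") return(df)
  agg <- stats::aggregate(df[, c("lateral_score", "transversal_score")],
                          by = list(flower = df$flower), FUN = mean)
  key <- df[!duplicated(df$flower), c("flower", "tree", "sex")]
  merge(key, agg, by = "flower", sort = TRUE)
}

#' Stacked histogram of subspace variance fractions
#'
#' @param x a classified [shape_pca()] result.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the fractions.
#' @export
plot_variance_fractions <- function(x, ...) {
  fr <- variance_fractions(x)
  graphics::barplot(matrix(fr, ncol = 1L), names.arg = "shape variance",
                    legend.text = names(fr), ylab = "% of total variance", ...)
  invisible(fr)
}
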