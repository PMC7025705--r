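#' The Klein four-group of biradial symmetry transformations
#'
#' A corolla with two perpendicular axes of symmetry admits four symmetry
#' transformations: the identity, the reflection across each axis, and the
#' reflection across both (a half-turn). Each reflection must be accompanied
#' by a re-labelling of the landmarks so that homologous points keep their
#' labels: for the canonical petal layout (P1..P4 counterclockwise from the
#' (+x, +y) quadrant, axes along x and y) the vertical-axis reflection swaps
#' P1/P2 and P3/P4, the horizontal one swaps P1/P4 and P2/P3 — both reverse
#' the within-petal point order — and the double reflection swaps P1/P3 and
#' P2/P4 keeping point order. Reflections act in the configuration's own
#' centroid-centered coordinates; the subsequent Procrustes alignment removes
#' any residual orientation, so no symmetry axis is ever estimated from the
#' data.
#'
#' @return a named list of four transform objects (class
#'   `symmetry_transform`), each with fields `id`, `sign` (coordinate
#'   multipliers), `petal_perm` (new petal j takes old petal `petal_perm[j]`)
#'   and `reverse` (within-petal order reversal flag).
#' @export
#' @examples
#' names(symmetry_transforms())
symmetry_transforms <- function() {
  mk <- function(id, sign, perm, rev)
    structure(list(id = id, sign = sign, petal_perm = perm, reverse = rev),
              class = "symmetry_transform")
  list(
    identity  = mk("identity",  c(1, 1),   1:4,          FALSE),
    reflectV  = mk("reflectV",  c(-1, 1),  c(2, 1, 4, 3), TRUE),
    reflectH  = mk("reflectH",  c(1, -1),  c(4, 3, 2, 1), TRUE),
    reflectHV = mk("reflectHV", c(-1, -1), c(3, 4, 1, 2), FALSE)
  )
}

# landmark index permutation realising a transform's re-labelling
transform_indices <- function(tr, n_petals, k) {
  idx <- integer(n_petals * k)
  for (j in seq_len(n_petals)) {
    src <- (tr$petal_perm[j] - 1L) * k + seq_len(k)
    if (tr$reverse) src <- rev(src)
    idx[(j - 1L) * k + seq_len(k)] <- src
  }
  idx
}

#' Apply a symmetry transformation to a configuration
#'
#' Reflects the coordinates about the configuration's centroid according to
#' the transform's sign pattern and re-labels the landmarks (petal
#' permutation plus within-petal reversal). Each transform is an involution.
#'
#' @param config a `p x 2` coordinate matrix or a [corolla_set()] (all
#'   configurations are transformed; their `transform` metadata is updated).
#' @param t one of the four [symmetry_transforms()], or its name.
#' @param n_petals number of petal blocks (for matrix input).
#' @return object of the same type as `config`.
#' @export
#' @examples
#' cfg <- generate_corolla(petal_template(), rep(list(list()), 4))
#' v <- apply_transform(cfg, "reflectV")
#' max(abs(apply_transform(v, "reflectV") - cfg))
apply_transform <- function(config, t, n_petals = 4L) {
  if (is.character(t)) {
    trs <- symmetry_transforms()
    if (!t %in% names(trs)) stop(sprintf("unknown transform id '%s'", t))
    t <- trs[[t]]
  }
  stopifnot(inherits(t, "symmetry_transform"))
  if (inherits(config, "corolla_set")) {
    p <- dim(config$coords)[1L]
    idx <- transform_indices(t, config$n_petals, p %/% config$n_petals)
    out <- config
    for (i in seq_len(n_configs(config)))
      out$coords[, , i] <- reflect_relabel(config$coords[, , i], t, idx)
    out$meta$transform <- compose_transform_id(config$meta$transform, t$id)
    return(out)
  }
  config <- as_coord_matrix(config)
  idx <- transform_indices(t, n_petals, nrow(config) %/% n_petals)
  reflect_relabel(config, t, idx)
}

reflect_relabel <- function(m, tr, idx) {
  ctr <- colMeans(m)
  out <- sweep(m, 2L, ctr)[idx, , drop = FALSE]
  out[, 1L] <- out[, 1L] * tr$sign[1L]
  out[, 2L] <- out[, 2L] * tr$sign[2L]
  sweep(out, 2L, ctr, "+")
}

# Klein four-group composition on transform ids
compose_transform_id <- function(a, b) {
  tab <- c(identity = 0L, reflectV = 1L, reflectH = 2L, reflectHV = 3L)
  inv <- names(tab)
  inv[bitwXor(tab[a], tab[b]) + 1L]
}

# a transform as a linear operator on flattened shape vectors (x1..xp,y1..yp)
transform_shape_vector <- function(v, tr, p, n_petals = 4L) {
  idx <- transform_indices(tr, n_petals, p %/% n_petals)
  c(v[idx] * tr$sign[1L], v[p + idx] * tr$sign[2L])
}

#' Expand a dataset into its full symmetry group
#'
#' Joins every raw configuration with its three reflected-and-relabelled
#' copies, quadrupling the dataset (the study's 676 configurations become
#' 2,704). All copies share their object's metadata except the `transform`
#' label.
#'
#' @param data a [corolla_set()] whose configurations all have
#'   `transform == "identity"`.
#' @return a [corolla_set()] with `4 * n` configurations, grouped in blocks
#'   by transform (identity first).
#' @export
expand_symmetry_group <- function(data) {
  stopifnot(inherits(data, "corolla_set"))
  if (!all(data$meta$transform == "identity"))
    stop("input already contains non-identity transforms; expansion must start from raw data")
  trs <- symmetry_transforms()
  parts <- lapply(trs, function(tr) apply_transform(data, tr))
  coords <- array(0, dim = c(dim(data$coords)[1:2], 4L * n_configs(data)))
  meta <- vector("list", 4L)
  for (j in seq_along(parts)) {
    coords[, , (j - 1L) * n_configs(data) + seq_len(n_configs(data))] <-
      parts[[j]]$coords
    meta[[j]] <- parts[[j]]$meta
  }
  corolla_set(coords, do.call(rbind, meta), n_petals = data$n_petals)
}

#' Average the aligned symmetry copies of each object
#'
#' After expansion and Procrustes alignment, the four aligned copies of each
#' object (flower x imaging x digitisation) are averaged coordinate-wise.
#' The averages — the "symmetrised" configurations — carry no asymmetric
#' variation and are the responses used by the size/shape ANOVA and the sex
#' regression.
#'
#' @param expanded the expanded [corolla_set()] (metadata source).
#' @param alignment the [gpa()] result on `expanded` (aligned coordinates).
#' @return a [corolla_set()] with one configuration per original object,
#'   `transform = "symmetrised"`, metadata from the identity copies.
#' @export
symmetrise <- function(expanded, alignment) {
  stopifnot(inherits(expanded, "corolla_set"), inherits(alignment, "gpa_result"))
  n <- n_configs(expanded)
  if (dim(alignment$aligned)[3L] != n)
    stop("alignment does not match the expanded dataset")
  ids <- expanded$meta$object_id
  groups <- split(seq_len(n), ids)
  full <- sort(names(symmetry_transforms()))
  ok <- vapply(groups, function(ix)
    identical(sort(expanded$meta$transform[ix]), full), TRUE)
  if (any(!ok)) {
    stop(sprintf("incomplete symmetry groups for objects: %s",
                 paste(utils::head(names(groups)[!ok], 5L), collapse = ", ")))
  }
  keep <- which(expanded$meta$transform == "identity")
  keep <- keep[order(expanded$meta$object_id[keep])]
  p <- dim(alignment$aligned)[1L]
  out <- array(0, dim = c(p, 2L, length(groups)))
  for (g in seq_along(groups))
    out[, , g] <- apply(alignment$aligned[, , groups[[g]], drop = FALSE],
                        c(1L, 2L), mean)
  meta <- expanded$meta[keep, , drop = FALSE]
  meta$transform <- "symmetrised"
  rownames(meta) <- NULL
  corolla_set(out, meta, n_petals = expanded$n_petals)
}

#' Cyclically re-label petal blocks and point directions
#'
#' Utility for mapping between labelling conventions of digitised data:
#' shifts which block is called petal 1 (`offset`), reverses the petal block
#' order (`direction = -1`), and/or reverses the within-petal point order.
#'
#' @param config `p x 2` matrix or [corolla_set()].
#' @param offset petal offset 0..3 (new petal j takes old petal
#'   `j + offset`, cyclically).
#' @param direction +1 keeps the petal block order, -1 reverses it.
#' @param reverse_within reverse each petal's point order.
#' @param n_petals number of petal blocks (matrix input).
#' @return re-labelled object of the same type.
#' @export
apply_remap <- function(config, offset = 0L, direction = 1L,
                        reverse_within = FALSE, n_petals = 4L) {
  if (inherits(config, "corolla_set")) {
    out <- config
    idx <- remap_indices(dim(config$coords)[1L], config$n_petals, offset,
                         direction, reverse_within)
    out$coords <- config$coords[idx, , , drop = FALSE]
    return(out)
  }
  config <- as_coord_matrix(config)
  config[remap_indices(nrow(config), n_petals, offset, direction,
                       reverse_within), , drop = FALSE]
}

remap_indices <- function(p, n_petals, offset, direction, reverse_within) {
  k <- p %/% n_petals
  idx <- integer(p)
  for (j in seq_len(n_petals)) {
    src_pet <- ((j - 1L) * direction + offset) %% n_petals + 1L
    src <- (src_pet - 1L) * k + seq_len(k)
    if (reverse_within) src <- rev(src)
    idx[(j - 1L) * k + seq_len(k)] <- src
  }
  idx
}

#' Diagnose the labelling convention of a dataset
#'
#' Checks that all configurations follow one consistent labelling
#' convention. A *uniform* re-labelling of the whole dataset (any petal
#' offset, petal direction or within-petal reversal applied to every
#' configuration alike) is a pure gauge: it conjugates the Klein four-group
#' onto itself, so the symmetry-expanded orbit, the Procrustes alignment and
#' every downstream statistic (variance fractions, asymmetry scores, tests)
#' are provably unchanged. What *does* matter — and what this diagnostic
#' detects — is labelling that is inconsistent *between* configurations,
#' e.g. a digitisation traced in the opposite direction and not re-labelled.
#'
#' Each configuration is compared against a reference configuration (the
#' first one) under all 16 candidate remaps (petal offset x direction x
#' within-petal reversal): parity errors (wrong direction or within-petal
#' reversal relative to the reference) cannot be absorbed by the rotation-
#' only Procrustes fit and stand out sharply, while the four petal offsets
#' tie for near-rotationally-symmetric flowers. The per-configuration best
#' parity class flags the inconsistent records.
#'
#' @param data a [corolla_set()] of identity-transform configurations
#'   (>= 2 configurations).
#' @param max_configs diagnostic sample size (taken from the head of the
#'   dataset; the reference is the first configuration).
#' @return list with `scores` (data frame over the 16 remaps: mean
#'   Procrustes distance to the reference across the sampled
#'   configurations), `recommended` (row of `scores` with the minimal
#'   score; ties broken towards the identity remap), `ties` (logical vector
#'   over remaps: within 1e-8 of the recommended score) and `per_config`
#'   (data frame: each sampled configuration's best direction /
#'   within-petal reversal relative to the reference — rows deviating from
#'   the majority indicate inconsistently labelled records).
#' @export
validate_labeling <- function(data, max_configs = 20L) {
  stopifnot(inherits(data, "corolla_set"), n_configs(data) >= 1L)
  sub <- data[seq_len(min(max_configs, n_configs(data)))]
  n <- n_configs(sub)
  ref <- sub$coords[, , 1L]
  grid <- expand.grid(offset = 0:3, direction = c(1L, -1L),
                      reverse_within = c(FALSE, TRUE))
  d <- matrix(NA_real_, n, nrow(grid))
  for (r in seq_len(nrow(grid))) {
    for (i in seq_len(n)) {
      cfg <- apply_remap(sub$coords[, , i], grid$offset[r], grid$direction[r],
                         grid$reverse_within[r], n_petals = sub$n_petals)
      d[i, r] <- partial_procrustes_fit(cfg, ref)$distance
    }
  }
  grid$score <- colMeans(d)
  best <- min(grid$score)
  cand <- which(grid$score <= best + 1e-8)
  rec <- cand[order(grid$reverse_within[cand], grid$direction[cand] != 1L,
                    grid$offset[cand])][1L]
  per_config <- data.frame(
    object_id = sub$meta$object_id,
    direction = grid$direction[apply(d, 1L, which.min)],
    reverse_within = grid$reverse_within[apply(d, 1L, which.min)],
    distance = apply(d, 1L, min))
  list(scores = grid, recommended = grid[rec, , drop = FALSE],
       ties = grid$score <= grid$score[rec] + 1e-8,
       per_config = per_config)
}
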