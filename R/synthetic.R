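#' Petal outline template
#'
#' Parameterizes a single petal outline as two mirrored cubic arcs running
#' from one basal corner over the tip to the other basal corner. All
#' quantities are in the (arbitrary, typically pixel-scale) digitising units.
#'
#' @param length petal length from base midpoint to tip (> 0).
#' @param width maximal petal width (> 0).
#' @param tip_shape pointedness of the tip in `[0, 1]` (0 = obtuse/rounded,
#'   1 = sharply pointed).
#' @param base_width basal width as a fraction of `width`, in `(0, 1]`.
#' @param skew left-right skew of the outline; 0 gives a petal that is
#'   mirror-symmetric about its long axis. The tip is displaced laterally by
#'   `skew * width / 2`.
#' @param attach_radius distance of the petal base midpoint from the corolla
#'   center.
#'
#' @return an object of class `petal_template`.
#' @export
#' @examples
#' tpl <- petal_template(length = 200, width = 110)
#' curve <- render_petal(tpl, 50)
petal_template <- function(length = 330, width = 180, tip_shape = 0.4,
                           base_width = 0.5, skew = 0, attach_radius = 95) {
  tpl <- list(length = length, width = width, tip_shape = tip_shape,
              base_width = base_width, skew = skew,
              attach_radius = attach_radius)
  validate_template(tpl)
  class(tpl) <- "petal_template"
  tpl
}

validate_template <- function(tpl) {
  if (!is.finite(tpl$length) || tpl$length <= 0)
    stop("invalid petal template: `length` must be > 0")
  if (!is.finite(tpl$width) || tpl$width <= 0)
    stop("invalid petal template: `width` must be > 0")
  if (tpl$base_width <= 0 || tpl$base_width > 1)
    stop("invalid petal template: `base_width` must be in (0, 1]")
  if (tpl$tip_shape < 0 || tpl$tip_shape > 1)
    stop("invalid petal template: `tip_shape` must be in [0, 1]")
  invisible(tpl)
}

bezier_points <- function(P, t) {
  # cubic Bezier; P is 4 x 2, t a vector in [0, 1]
  b0 <- (1 - t)^3; b1 <- 3 * t * (1 - t)^2; b2 <- 3 * t^2 * (1 - t); b3 <- t^3
  cbind(b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1] + b3 * P[4, 1],
        b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2] + b3 * P[4, 2])
}

#' Render a petal outline as equidistant points
#'
#' Evaluates the template's outline (basal corner A, over the tip, to basal
#' corner B) as a dense polyline and resamples it to `n_points` points at
#' equal arc-length spacing. The first and last points are the basal corners
#' and lie on the petal base; these are the landmarks treated as fixed during
#' sliding. Coordinates are local: the base midpoint at the origin, the long
#' axis along +y.
#'
#' @param template a [petal_template()].
#' @param n_points number of outline points (>= 4); the study digitised 50
#'   per petal.
#' @param dense number of dense samples per arc used for the arc-length
#'   parameterization.
#' @return an `n_points x 2` coordinate matrix, ordered from corner A
#'   (negative local x) to corner B.
#' @export
render_petal <- function(template, n_points = 50L, dense = 600L) {
  validate_template(template)
  if (n_points < 4L) stop("`n_points` must be at least 4")
  L <- template$length; w <- template$width
  tip <- template$tip_shape; bh <- w * template$base_width / 2
  tipx <- template$skew * w / 2
  tip_pt <- c(tipx, L)
  shoulder <- (0.80 + 0.15 * tip) * L
  flare <- (1 - tip) * 0.45 * w
  left <- rbind(c(-bh, 0), c(-w / 2, 0.40 * L),
                c(tipx - flare, shoulder), tip_pt)
  right <- rbind(tip_pt, c(tipx + flare, shoulder),
                 c(w / 2, 0.40 * L), c(bh, 0))
  t <- seq(0, 1, length.out = dense)
  poly <- rbind(bezier_points(left, t), bezier_points(right, t)[-1L, , drop = FALSE])
  resample_outline(poly, n_points)
}

#' Assemble a four-petal corolla configuration
#'
#' Places four (possibly perturbed) copies of a base petal template at the
#' bisector angles 45, 135, 225 and 315 degrees, so that the two nominal
#' axes of symmetry lie along the x and y axes before `rotation` is applied.
#' Petals are indexed P1..P4 counterclockwise starting in the (+x, +y)
#' quadrant and each petal's points run counterclockwise (corner A first).
#' The four 50-point curves are concatenated in petal order into a single
#' configuration.
#'
#' @param base a [petal_template()].
#' @param perturbations list of exactly 4 named numeric vectors/lists of
#'   additive offsets to template fields (e.g. `list(length = 5)`); use
#'   `list()` for an unperturbed petal.
#' @param rotation whole-corolla rotation angle in radians.
#' @param translation length-2 numeric offset added to all points.
#' @param n_points points per petal.
#' @return a `(4 * n_points) x 2` coordinate matrix.
#' @export
#' @examples
#' cfg <- generate_corolla(petal_template(), rep(list(list()), 4))
#' nrow(cfg)
generate_corolla <- function(base, perturbations = rep(list(list()), 4),
                             rotation = 0, translation = c(0, 0),
                             n_points = 50L) {
  if (length(perturbations) != 4L)
    stop("`perturbations` must have exactly 4 entries (one per petal)")
  blocks <- vector("list", 4L)
  for (k in 1:4) {
    tpl <- perturb_template(base, perturbations[[k]])
    local <- render_petal(tpl, n_points)
    theta <- pi / 4 + (k - 1L) * pi / 2 + rotation
    er <- c(cos(theta), sin(theta))
    et <- c(-sin(theta), cos(theta))
    u <- local[, 1L]; v <- local[, 2L] + tpl$attach_radius
    blocks[[k]] <- cbind(v * er[1L] + u * et[1L] + translation[1L],
                         v * er[2L] + u * et[2L] + translation[2L])
  }
  do.call(rbind, blocks)
}

perturb_template <- function(base, offsets) {
  tpl <- unclass(base)
  for (f in names(offsets)) {
    if (!f %in% names(tpl)) stop(sprintf("unknown template field '%s'", f))
    tpl[[f]] <- tpl[[f]] + offsets[[f]]
  }
  tpl$tip_shape <- min(max(tpl$tip_shape, 0), 1)
  tpl$base_width <- min(max(tpl$base_width, 1e-3), 1)
  class(tpl) <- "petal_template"
  tpl
}

#' Parameters of the synthetic corolla population generator
#'
#' Defines the nested sampling design and the variance components of the
#' synthetic population. The defaults reproduce the study conditions this
#' package was validated against: 8 trees per sexual group with the reported
#' unbalanced per-tree flower counts (169 flowers in total), two imaging
#' events and two digitisations per flower (676 configurations), female
#' corollas 15.5% smaller on average, and female within-flower asymmetry
#' elevated so that mean asymmetric dispersion exceeds the hermaphrodite
#' level by roughly a quarter.
#'
#' The coordinated (tree- and flower-level symmetric) shape perturbations are
#' drawn as near size-neutral elongation contrasts — petal length `+d` goes
#' with width `-0.55 d` plus independent width noise (`0.3` of the SD) and a
#' tip-pointedness component (`0.0025` of the SD) — so that symmetric shape
#' variance and centroid-size variance can be controlled independently (size
#' variability is generated by the pure `size_cv_*` scale factors). The
#' asymmetric SDs (`sigma_lat`, `sigma_trans`) and `sigma_petal` act on
#' per-petal length (and, scaled by 0.6, width) in digitising units.
#' `sigma_imaging` is the SD of per-photograph point jitter (with a rigid
#' rotation of SD `0.002 * sigma_imaging` rad and translation of SD
#' `2 * sigma_imaging` that GPA later removes); `sigma_digit` is the SD of
#' per-digitisation jitter along the local outline tangent (which the
#' sliding semilandmarks largely absorb, making digitising the smallest
#' error term, as it should be).
#'
#' @param n_trees_per_sex trees per sexual group.
#' @param flowers_per_tree named list with numeric vectors `female` and
#'   `hermaphrodite` (recycled to `n_trees_per_sex`), or a single count.
#' @param n_imaging,n_digitisation replicate counts (study design: 2 and 2).
#' @param sigma_sym SD of coordinated (all-petal) template perturbations.
#' @param sigma_lat SD of each of the two adjacent-petal-pair contrast
#'   perturbations (lateral asymmetry).
#' @param sigma_trans SD of the opposite-petal-pair contrast perturbation
#'   (transversal asymmetry).
#' @param sigma_petal SD of independent per-petal template noise.
#' @param sigma_imaging SD of per-photograph jitter (see Details).
#' @param sigma_digit SD of per-digitisation tangential point jitter.
#' @param size_cv_tree,size_cv_flower,size_cv_imaging coefficients of
#'   variation of log-normal size factors drawn per tree, per flower and per
#'   photograph: corolla size varies among trees and flowers (and slightly
#'   with camera distance) far more than shape does, so size variability is
#'   generated as pure scaling, carrying no shape-space variance.
#' @param female_size_factor multiplicative centroid-size factor applied to
#'   female flowers (0.845 = 15.5% smaller).
#' @param female_asym_factor multiplier on `sigma_lat` and `sigma_trans` for
#'   female flowers.
#' @param female_base_factor multiplicative factor on the female petals'
#'   `base_width` (the sexes' mean shapes differ by slightly thicker petal
#'   bases in females; 1 disables the effect).
#' @param tree_effect_sd SD of tree-level template shifts.
#' @param base the common [petal_template()].
#' @param n_points points per petal.
#' @param seed RNG seed for [generate_population()]; `NULL` leaves the RNG
#'   stream alone.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_trees_per_sex = 8L,
                             flowers_per_tree = list(
                               female = c(13, 12, 11, 11, 9, 13, 10, 10),
                               hermaphrodite = c(11, 9, 10, 10, 10, 10, 10, 10)),
                             n_imaging = 2L, n_digitisation = 2L,
                             sigma_sym = 44, sigma_lat = 18,
                             sigma_trans = 10.2, sigma_petal = 3,
                             sigma_imaging = 0.9, sigma_digit = 0.65,
                             size_cv_tree = 0.047, size_cv_flower = 0.038,
                             size_cv_imaging = 0.0084,
                             female_size_factor = 0.845,
                             female_asym_factor = 1.22,
                             female_base_factor = 1.19,
                             tree_effect_sd = 23,
                             base = petal_template(), n_points = 50L,
                             seed = NULL) {
  if (is.numeric(flowers_per_tree) && length(flowers_per_tree) == 1L)
    flowers_per_tree <- list(female = rep(flowers_per_tree, n_trees_per_sex),
                             hermaphrodite = rep(flowers_per_tree, n_trees_per_sex))
  p <- list(n_trees_per_sex = as.integer(n_trees_per_sex),
            flowers_per_tree = lapply(flowers_per_tree, function(v)
              as.integer(rep_len(v, n_trees_per_sex))),
            n_imaging = as.integer(n_imaging),
            n_digitisation = as.integer(n_digitisation),
            sigma_sym = sigma_sym, sigma_lat = sigma_lat,
            sigma_trans = sigma_trans, sigma_petal = sigma_petal,
            sigma_imaging = sigma_imaging, sigma_digit = sigma_digit,
            size_cv_tree = size_cv_tree, size_cv_flower = size_cv_flower,
            size_cv_imaging = size_cv_imaging,
            female_size_factor = female_size_factor,
            female_asym_factor = female_asym_factor,
            female_base_factor = female_base_factor,
            tree_effect_sd = tree_effect_sd, base = base,
            n_points = as.integer(n_points), seed = seed)
  sds <- c(p$sigma_sym, p$sigma_lat, p$sigma_trans, p$sigma_petal,
           p$sigma_imaging, p$sigma_digit, p$tree_effect_sd,
           p$size_cv_tree, p$size_cv_flower, p$size_cv_imaging)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (p$n_trees_per_sex < 1L || p$n_imaging < 1L || p$n_digitisation < 1L ||
      any(unlist(p$flowers_per_tree) < 1L))
    stop("all design counts must be >= 1")
  if (p$female_size_factor <= 0) stop("`female_size_factor` must be > 0")
  class(p) <- "generator_params"
  p
}

# contrast patterns over petals P1..P4
.pat_lat1 <- c(1, 1, -1, -1)   # adjacent pair contrast, axis 1
.pat_lat2 <- c(1, -1, -1, 1)   # adjacent pair contrast, axis 2
.pat_trans <- c(1, -1, 1, -1)  # opposite pair contrast

#' Generate a synthetic corolla population
#'
#' Draws a full nested dataset of tetrameric corolla configurations: sexual
#' group / tree / flower / imaging replicate / digitisation replicate, with
#' latent shape effects split into a coordinated symmetric component, two
#' orthogonal lateral (adjacent-pair) asymmetry contrasts, a transversal
#' (opposite-pair) contrast, independent petal noise, and imaging plus
#' digitisation measurement error. Identical `seed` gives identical output.
#'
#' @param params a [generator_params()].
#' @return a list with elements `set` (a [corolla_set()] of
#'   `identity`-transform configurations) and `truth` (data frames of every
#'   drawn tree-, flower- and photograph-level latent effect, for
#'   parameter-recovery tests).
#' @export
#' @examples
#' pop <- generate_population(generator_params(
#'   n_trees_per_sex = 2, flowers_per_tree = 2, seed = 1))
#' n_configs(pop$set)
generate_population <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, generate_population_impl(params))
}

generate_population_impl <- function(p) {
  k <- p$n_points
  # template perturbations are pure shape: every flower is rescaled to the
  # base corolla's centroid size before the explicit size-factor chain
  cs_base <- centroid_size(generate_corolla(p$base, rep(list(list()), 4L),
                                            n_points = k))
  coords <- list(); meta <- list(); obj <- 0L
  tree_truth <- list(); flower_truth <- list(); photo_truth <- list()
  flower_no <- 0L
  for (sex in c("female", "hermaphrodite")) {
    fem <- sex == "female"
    af <- if (fem) p$female_asym_factor else 1
    counts <- p$flowers_per_tree[[sex]]
    for (t in seq_len(p$n_trees_per_sex)) {
      tree_id <- sprintf("%s%d", sex, t)
      tl <- stats::rnorm(1, 0, p$tree_effect_sd)
      tw <- -0.55 * tl + stats::rnorm(1, 0, 0.3 * p$tree_effect_sd)
      tsize <- exp(stats::rnorm(1, 0, p$size_cv_tree))
      tree_truth[[tree_id]] <- data.frame(tree = tree_id, sex = sex,
                                          d_length = tl, d_width = tw,
                                          size_factor = tsize)
      for (f in seq_len(counts[t])) {
        flower_no <- flower_no + 1L
        flower_id <- sprintf("fl%03d", flower_no)
        sym_len <- stats::rnorm(1, 0, p$sigma_sym)
        sym <- c(len = sym_len,
                 wid = -0.55 * sym_len + stats::rnorm(1, 0, 0.3 * p$sigma_sym),
                 tip = stats::rnorm(1, 0, 0.0025 * p$sigma_sym))
        lat1 <- stats::rnorm(2, 0, af * p$sigma_lat * c(1, 0.6))
        lat2 <- stats::rnorm(2, 0, af * p$sigma_lat * c(1, 0.6))
        trn <- stats::rnorm(2, 0, af * p$sigma_trans * c(1, 0.6))
        pet_l <- stats::rnorm(4, 0, p$sigma_petal)
        pet_w <- stats::rnorm(4, 0, 0.6 * p$sigma_petal)
        rot <- stats::runif(1, 0, 2 * pi)
        trans <- stats::rnorm(2, 0, 30)
        perts <- lapply(1:4, function(j) list(
          length = tl + sym["len"] + lat1[1] * .pat_lat1[j] +
            lat2[1] * .pat_lat2[j] + trn[1] * .pat_trans[j] + pet_l[j],
          width = tw + sym["wid"] + lat1[2] * .pat_lat1[j] +
            lat2[2] * .pat_lat2[j] + trn[2] * .pat_trans[j] + pet_w[j],
          tip_shape = sym["tip"],
          base_width = if (fem) (p$female_base_factor - 1) * p$base$base_width else 0
        ))
        fsize <- tsize * exp(stats::rnorm(1, 0, p$size_cv_flower)) *
          (if (fem) p$female_size_factor else 1)
        flower <- generate_corolla(p$base, perts, rotation = rot,
                                   translation = c(0, 0), n_points = k)
        flower <- flower * (cs_base / centroid_size(flower)) * fsize
        flower_truth[[flower_id]] <- data.frame(
          flower = flower_id, tree = tree_id, sex = sex,
          sym_len = sym[["len"]], sym_wid = sym[["wid"]], sym_tip = sym[["tip"]],
          lat1_len = lat1[1], lat1_wid = lat1[2],
          lat2_len = lat2[1], lat2_wid = lat2[2],
          trans_len = trn[1], trans_wid = trn[2],
          rotation = rot, size_factor = fsize)
        for (img in seq_len(p$n_imaging)) {
          irot <- stats::rnorm(1, 0, 0.002 * p$sigma_imaging)
          itr <- stats::rnorm(2, 0, 2 * p$sigma_imaging)
          iscale <- exp(stats::rnorm(1, 0, p$size_cv_imaging))
          photo <- (flower * iscale) %*% rotation_matrix(irot)
          photo <- photo + matrix(stats::rnorm(length(photo), 0, p$sigma_imaging),
                                  ncol = 2L)
          photo <- sweep(photo, 2L, trans + itr, "+")
          photo_truth[[length(photo_truth) + 1L]] <- data.frame(
            flower = flower_id, imaging = img, rot = irot, scale = iscale,
            tx = trans[1] + itr[1], ty = trans[2] + itr[2])
          for (d in seq_len(p$n_digitisation)) {
            obj <- obj + 1L
            pts <- photo + tangential_jitter(photo, k, p$sigma_digit)
            coords[[obj]] <- pts
            meta[[obj]] <- data.frame(
              object_id = sprintf("obj%04d", obj), flower = flower_id,
              tree = tree_id, sex = sex, imaging = img, digitisation = d,
              transform = "identity", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  set <- corolla_set(coords, do.call(rbind, meta), n_petals = 4L)
  list(set = set,
       truth = list(params = p,
                    trees = do.call(rbind, tree_truth),
                    flowers = do.call(rbind, flower_truth),
                    photos = do.call(rbind, photo_truth)))
}

# jitter each point along its within-petal outline tangent
tangential_jitter <- function(pts, k, sd) {
  if (sd == 0) return(matrix(0, nrow(pts), 2L))
  out <- matrix(0, nrow(pts), 2L)
  n_pet <- nrow(pts) %/% k
  for (b in seq_len(n_pet)) {
    idx <- (b - 1L) * k + seq_len(k)
    blk <- pts[idx, , drop = FALSE]
    prev <- blk[c(1L, seq_len(k - 1L)), ]
    nxt <- blk[c(2:k, k), ]
    tang <- nxt - prev
    len <- sqrt(rowSums(tang^2))
    len[len == 0] <- 1
    tang <- tang / len
    out[idx, ] <- tang * stats::rnorm(k, 0, sd)
  }
  out
}

#' Simulate a study-shaped dataset
#'
#' Convenience wrapper: [generate_population()] with the default
#' [generator_params()] (the validated study conditions), returning 676
#' configurations (169 flowers x 2 photographs x 2 digitisations).
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [generator_params()].
#' @return see [generate_population()].
#' @export
simulate_study_dataset <- function(seed = NULL, ...) {
  generate_population(generator_params(seed = seed, ...))
}
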