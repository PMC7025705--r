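#' Nested permutation (Procrustes) ANOVA
#'
#' Type-I sequential decomposition of a univariate (centroid size) or
#' multivariate (symmetrised Procrustes shape coordinates) response over the
#' fully nested design sex / tree(sex) / flower(tree) / imaging /
#' digitisation. Each effect's sum of squares is the summed squared
#' deviation (summed over coordinates for shape) of the group means at that
#' level from the means one level up; the digitisation level is the
#' residual. Each F ratio uses the mean square of the immediately nested
#' effect as its denominator, and its permutation p-value is obtained by
#' restricted permutation of the exchangeable units of that nested level:
#' whole trees across sexes, whole flowers across trees within sex, whole
#' photographs across flowers within tree, and digitisations across
#' photographs within flower.
#'
#' @param response numeric vector (length n) or matrix (`n x d`).
#' @param design data frame with columns `sex`, `tree`, `flower`, `imaging`,
#'   `digitisation` (n rows).
#' @param n_perm number of permutations (999 in the validated analyses).
#' @param seed RNG seed for the permutations.
#' @return an object of class `anova_table`: data frame with columns
#'   `effect`, `Df`, `SS`, `MS`, `eta2`, `F`, `p` (rows Sex, Tree(sex),
#'   Flower(tree), Imaging error, Digitising error, Total). F and p are `NA`
#'   where a level has no replication.
#' @export
nested_anova <- function(response, design, n_perm = 999L, seed = NULL) {
  Y <- if (is.matrix(response)) response else matrix(response, ncol = 1L)
  n <- nrow(Y)
  stopifnot(nrow(design) == n)
  for (col in c("sex", "tree", "flower", "imaging", "digitisation"))
    if (is.null(design[[col]])) stop(sprintf("design lacks column '%s'", col))

  sex <- as.character(design$sex)
  tree <- as.character(design$tree)
  flower <- as.character(design$flower)
  photo <- paste(flower, design$imaging, sep = "/")

  grand <- colMeans(Y)
  ss_total <- sum(sweep(Y, 2L, grand)^2)

  level_stats <- function(fac) {
    sums <- rowsum(Y, fac)
    sizes <- as.vector(rowsum(rep(1, n), fac))
    list(sums = sums, sizes = sizes, keys = rownames(sums))
  }
  Lsex <- level_stats(sex); Ltree <- level_stats(tree)
  Lflow <- level_stats(flower); Lphoto <- level_stats(photo)

  parent_of <- function(child_keys, child_fac, parent_fac) {
    map <- parent_fac[match(child_keys, child_fac)]
    map
  }
  # SS at one level given its parent level
  nested_ss <- function(L, parent_keys, Lp) {
    pa <- match(parent_keys, Lp$keys)
    between_ss(L$sums, L$sizes, pa, Lp$sums, Lp$sizes)
  }

  ss_sex <- between_ss(Lsex$sums, Lsex$sizes)
  ss_tree <- nested_ss(Ltree, parent_of(Ltree$keys, tree, sex), Lsex)
  ss_flow <- nested_ss(Lflow, parent_of(Lflow$keys, flower, tree), Ltree)
  ss_img <- nested_ss(Lphoto, parent_of(Lphoto$keys, photo, flower), Lflow)
  ss_dig <- ss_total - ss_sex - ss_tree - ss_flow - ss_img

  n_sex <- length(Lsex$keys); n_tree <- length(Ltree$keys)
  n_flow <- length(Lflow$keys); n_photo <- length(Lphoto$keys)
  df <- c(sex = n_sex - 1L, tree = n_tree - n_sex, flower = n_flow - n_tree,
          imaging = n_photo - n_flow, digit = n - n_photo)
  ss <- c(ss_sex, ss_tree, ss_flow, ss_img, ss_dig)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  f <- c(ms[1L] / ms[2L], ms[2L] / ms[3L], ms[3L] / ms[4L], ms[4L] / ms[5L], NA)
  f[!is.finite(f)] <- NA_real_

  p <- rep(NA_real_, 5L)
  if (n_perm > 0L && ss_total > 0) {
    p[seq_len(4L)] <- with_seed(seed, perm_nested_p(
      Y, sex, tree, flower, photo, Lsex, Ltree, Lflow, Lphoto, df, f, n_perm))
  }

  out <- data.frame(
    effect = c("Sex", "Tree (sex)", "Flower (tree)", "Imaging error",
               "Digitising error", "Total"),
    Df = c(df, n - 1L),
    SS = c(ss, ss_total),
    MS = c(ms, NA_real_),
    eta2 = c(ss / ss_total, NA_real_),
    F = c(f, NA_real_),
    p = c(p, NA_real_))
  class(out) <- c("anova_table", "data.frame")
  out
}

# permutation p-values for the four testable effects of the nested design
perm_nested_p <- function(Y, sex, tree, flower, photo,
                          Lsex, Ltree, Lflow, Lphoto, df, f_obs, n_perm) {
  n <- nrow(Y)
  # aggregated means and sizes at each level
  tree_sex <- sex[match(Ltree$keys, tree)]
  flow_tree <- tree[match(Lflow$keys, flower)]
  flow_sex <- sex[match(Lflow$keys, flower)]
  photo_flow <- flower[match(Lphoto$keys, photo)]
  photo_tree <- tree[match(Lphoto$keys, photo)]
  row_photo <- match(photo, Lphoto$keys)

  f_stat_12 <- function(tree_sex_lab) {
    # F_sex from tree-level aggregates under a tree->sex assignment
    sums_sex <- rowsum(Ltree$sums, tree_sex_lab)
    sizes_sex <- as.vector(rowsum(Ltree$sizes, tree_sex_lab))
    ss1 <- between_ss(sums_sex, sizes_sex)
    pa <- match(tree_sex_lab, rownames(sums_sex))
    ss2 <- between_ss(Ltree$sums, Ltree$sizes, pa, sums_sex, sizes_sex)
    (ss1 / df["sex"]) / (ss2 / df["tree"])
  }
  f_stat_23 <- function(flow_tree_lab) {
    sums_tree <- rowsum(Lflow$sums, flow_tree_lab)
    sizes_tree <- as.vector(rowsum(Lflow$sizes, flow_tree_lab))
    sums_sex <- rowsum(sums_tree, tree_sex)
    sizes_sex <- as.vector(rowsum(sizes_tree, tree_sex))
    pa_t <- match(tree_sex, rownames(sums_sex))
    ss2 <- between_ss(sums_tree, sizes_tree, pa_t, sums_sex, sizes_sex)
    pa_f <- match(flow_tree_lab, rownames(sums_tree))
    ss3 <- between_ss(Lflow$sums, Lflow$sizes, pa_f, sums_tree, sizes_tree)
    (ss2 / df["tree"]) / (ss3 / df["flower"])
  }
  f_stat_34 <- function(photo_flow_lab) {
    sums_flow <- rowsum(Lphoto$sums, photo_flow_lab)
    sizes_flow <- as.vector(rowsum(Lphoto$sizes, photo_flow_lab))
    sums_tree <- rowsum(sums_flow, flow_tree[match(rownames(sums_flow), Lflow$keys)])
    sizes_tree <- as.vector(rowsum(sizes_flow,
                                   flow_tree[match(rownames(sums_flow), Lflow$keys)]))
    pa_f <- match(flow_tree[match(rownames(sums_flow), Lflow$keys)],
                  rownames(sums_tree))
    ss3 <- between_ss(sums_flow, sizes_flow, pa_f, sums_tree, sizes_tree)
    pa_p <- match(photo_flow_lab, rownames(sums_flow))
    ss4 <- between_ss(Lphoto$sums, Lphoto$sizes, pa_p, sums_flow, sizes_flow)
    (ss3 / df["flower"]) / (ss4 / df["imaging"])
  }
  f_stat_45 <- function(row_photo_lab) {
    sums_photo <- rowsum(Y, row_photo_lab)
    sizes_photo <- as.vector(rowsum(rep(1, n), row_photo_lab))
    keyp <- rownames(sums_photo)
    pf <- photo_flow[match(keyp, Lphoto$keys)]
    sums_flow <- rowsum(sums_photo, pf)
    sizes_flow <- as.vector(rowsum(sizes_photo, pf))
    pa_p <- match(pf, rownames(sums_flow))
    ss4 <- between_ss(sums_photo, sizes_photo, pa_p, sums_flow, sizes_flow)
    mu_photo <- sums_photo / sizes_photo
    ss5 <- sum((Y - mu_photo[match(row_photo_lab, keyp), , drop = FALSE])^2)
    (ss4 / df["imaging"]) / (ss5 / df["digit"])
  }

  count <- numeric(4L)
  valid <- !is.na(f_obs[1:4])
  for (b in seq_len(n_perm)) {
    if (valid[1L]) {
      perm <- sample(tree_sex)
      count[1L] <- count[1L] + (f_stat_12(perm) >= f_obs[1L])
    }
    if (valid[2L]) {
      perm <- stats::ave(flow_tree, flow_sex, FUN = sample)
      count[2L] <- count[2L] + (f_stat_23(perm) >= f_obs[2L])
    }
    if (valid[3L]) {
      perm <- stats::ave(photo_flow, photo_tree, FUN = sample)
      count[3L] <- count[3L] + (f_stat_34(perm) >= f_obs[3L])
    }
    if (valid[4L]) {
      perm <- stats::ave(Lphoto$keys[row_photo],
                         flower, FUN = sample)
      count[4L] <- count[4L] + (f_stat_45(perm) >= f_obs[4L])
    }
  }
  p <- (count + 1) / (n_perm + 1)
  p[!valid] <- NA_real_
  p
}

#' @export
print.anova_table <- function(x, digits = 4L, ...) {
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, digits); df$MS <- signif(df$MS, digits)
  df$eta2 <- signif(df$eta2, 3L); df$F <- signif(df$F, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Multivariate regression on a binary group with Goodall's F
#'
#' Regresses shape coordinates onto a single binary factor and assesses
#' significance with Goodall's F — the ratio of between-group to
#' within-group Procrustes variance with df 1 and n - 2 — under permutation
#' of the group labels (the observed statistic is included in the reference
#' distribution).
#'
#' @param shapes `n x d` matrix of (symmetrised) shape coordinates.
#' @param group factor or vector with exactly two non-empty levels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return an object of class `goodall_regression`: list with `F`, `p`,
#'   `percent_variance` (SS_model / SS_total x 100), `df` (c(1, n - 2)),
#'   `group_means` (2 x d) and `n`.
#' @export
goodall_regression <- function(shapes, group, n_perm = 999L, seed = NULL) {
  Y <- as.matrix(shapes)
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("`group` must have exactly two non-empty levels")
  n <- nrow(Y)
  f_of <- function(g) {
    sums <- rowsum(Y, g)
    sizes <- as.vector(rowsum(rep(1, n), g))
    ssb <- between_ss(sums, sizes)
    mu <- sums / sizes
    ssw <- sum((Y - mu[match(as.character(g), rownames(sums)), , drop = FALSE])^2)
    c(ssb, ssw)
  }
  obs <- f_of(g)
  f_obs <- (obs[1L] / 1) / (obs[2L] / (n - 2L))
  p <- NA_real_
  if (n_perm > 0L) {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        ssp <- f_of(sample(g))
        (ssp[1L] / 1) / (ssp[2L] / (n - 2L)) >= f_obs
      }, TRUE))
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  sums <- rowsum(Y, g); sizes <- as.vector(rowsum(rep(1, n), g))
  structure(list(F = f_obs, p = p,
                 percent_variance = 100 * obs[1L] / (obs[1L] + obs[2L]),
                 df = c(1L, n - 2L), group_means = sums / sizes, n = n),
            class = "goodall_regression")
}

#' @export
print.goodall_regression <- function(x, ...) {
  cat(sprintf("Goodall's F = %.3f (df %d, %d), p = %.4g; %.2f%% of variance explained\n",
              x$F, x$df[1L], x$df[2L], x$p, x$percent_variance))
  invisible(x)
}

#' Levene-analogue test of multivariate dispersion
#'
#' Compares the dispersion of two (or more) groups in a score subspace:
#' each point's Euclidean distance to its group centroid is computed, the
#' one-way ANOVA F on these distances is the test statistic, and its
#' p-value comes from permuting the group assignments of the chosen
#' exchangeable unit (whole flowers by default, keeping symmetry copies and
#' replicate digitisations together; `"configuration"` permutes rows, the
#' classical row-level analysis). The confidence interval of the difference
#' in mean distances (first group minus second) is a two-sample Welch t
#' interval on the distances.
#'
#' @param scores `n x d` matrix of subspace scores (or a vector).
#' @param group factor with >= 2 levels, each with >= 2 members.
#' @param permute_unit `"flower"` or `"configuration"`.
#' @param unit unit identifiers (length n), required for flower-level
#'   permutation.
#' @param n_perm number of permutations (9,999 in the validated analyses).
#' @param seed RNG seed.
#' @param conf_level confidence level of the t interval.
#' @return an object of class `dispersion_result`: list with `mean_dist`
#'   (named per-group mean distance to centroid), `difference`, `conf_int`,
#'   `F`, `p`, `n_perm`, `permute_unit`.
#' @export
dispersion_test <- function(scores, group,
                            permute_unit = c("flower", "configuration"),
                            unit = NULL, n_perm = 9999L, seed = NULL,
                            conf_level = 0.95) {
  S <- as.matrix(scores)
  g <- factor(group)
  permute_unit <- match.arg(permute_unit)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need >= 2 groups with >= 2 members each")
  if (permute_unit == "flower" && is.null(unit))
    stop("flower-level permutation requires `unit` identifiers")
  n <- nrow(S)

  dists_for <- function(g) {
    sums <- rowsum(S, g)
    sizes <- as.vector(rowsum(rep(1, n), g))
    mu <- sums / sizes
    sqrt(rowSums((S - mu[match(as.character(g), rownames(sums)), ,
                          drop = FALSE])^2))
  }
  # one-way ANOVA F on the distances, computed from group sums
  anova_f <- function(d, g) {
    sums <- rowsum(d, g)
    sizes <- as.vector(rowsum(rep(1, length(d)), g))
    k <- length(sizes)
    ssb <- sum(sums^2 / sizes) - sum(d)^2 / length(d)
    ssw <- sum(d^2) - sum(sums^2 / sizes)
    (ssb / (k - 1)) / (ssw / (length(d) - k))
  }
  f_of <- function(g) anova_f(dists_for(g), g)
  d_obs <- dists_for(g)
  f_obs <- anova_f(d_obs, g)

  p <- NA_real_
  if (n_perm > 0L) {
    p <- with_seed(seed, {
      if (permute_unit == "configuration") {
        exceed <- sum(vapply(seq_len(n_perm),
                             function(b) f_of(sample(g)) >= f_obs, TRUE))
      } else {
        u <- as.character(unit)
        uk <- unique(u)
        ug <- g[match(uk, u)]
        exceed <- sum(vapply(seq_len(n_perm), function(b) {
          gp <- sample(ug)[match(u, uk)]
          f_of(gp) >= f_obs
        }, TRUE))
      }
      (exceed + 1) / (n_perm + 1)
    })
  }

  means <- tapply(d_obs, g, mean)
  diff <- ci <- NA
  if (nlevels(g) == 2L) {
    tt <- stats::t.test(d_obs[g == levels(g)[1L]], d_obs[g == levels(g)[2L]],
                        conf.level = conf_level)
    diff <- unname(means[1L] - means[2L])
    ci <- unname(tt$conf.int)
  }
  structure(list(mean_dist = means, difference = diff, conf_int = ci,
                 F = f_obs, p = p, n_perm = n_perm,
                 permute_unit = permute_unit, distances = d_obs, group = g),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion (distance to group centroid)\n")
  for (lv in names(x$mean_dist))
    cat(sprintf("  %s: mean distance %.4f\n", lv, x$mean_dist[lv]))
  if (!all(is.na(x$difference)))
    cat(sprintf("  difference %.4f, 95%% CI [%.4f, %.4f]\n",
                x$difference, x$conf_int[1L], x$conf_int[2L]))
  cat(sprintf("  F = %.3f, permutation p = %.4g (%d perms, unit = %s)\n",
              x$F, x$p, x$n_perm, x$permute_unit))
  invisible(x)
}

#' Non-metric multidimensional scaling of subspace scores
#'
#' Two-dimensional NMDS (Kruskal stress-1, via \code{vegan::monoMDS}) of
#' the Euclidean distances between score rows. Runs a metric (principal
#' coordinates) start plus `n_starts - 1` random starts and keeps the
#' lowest-stress solution; deterministic given `seed`.
#'
#' @param scores `n x d` score matrix (n >= 3).
#' @param k embedding dimension.
#' @param n_starts number of starts (including the metric one).
#' @param seed RNG seed.
#' @param maxit maximum iterations per start.
#' @return an object of class `nmds_result`: list with `points` (`n x k`),
#'   `stress` (Kruskal stress-1 in [0, 1]) and `n_starts`.
#' @export
nmds <- function(scores, k = 2L, n_starts = 4L, seed = NULL, maxit = 200L) {
  S <- as.matrix(scores)
  if (nrow(S) < 3L) stop("NMDS needs at least 3 points")
  d <- stats::dist(S)
  with_seed(seed, {
    init <- tryCatch(stats::cmdscale(d, k = k), error = function(e) NULL)
    best <- NULL
    for (s in seq_len(max(1L, n_starts))) {
      y0 <- if (s == 1L && !is.null(init) && ncol(init) == k) init
            else matrix(stats::rnorm(nrow(S) * k), ncol = k)
      fit <- vegan::monoMDS(d, y = y0, k = k, model = "global", maxit = maxit)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    structure(list(points = best$points, stress = best$stress,
                   n_starts = n_starts),
              class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (%d points, 2D): Kruskal stress-1 = %.4f\n",
              nrow(x$points), x$stress))
  invisible(x)
}
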