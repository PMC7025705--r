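toy_design <- function() {
  data.frame(
    sex = rep(c("F", "H"), each = 4),
    tree = rep(c("t1", "t2", "t3", "t4"), each = 2),
    flower = paste0("fl", 1:8),
    imaging = 1L, digitisation = 1L)
}

test_that("nested ANOVA reproduces hand-computed sums of squares", {
  y <- c(1, 3, 5, 7, 11, 13, 15, 17)
  an <- nested_anova(y, toy_design(), n_perm = 0)
  expect_equal(an$SS[1:3], c(200, 32, 8))      # sex, tree, flower (by hand)
  expect_equal(an$SS[6], 240)                  # total
  expect_equal(an$Df[1:3], c(1L, 2L, 4L))
  expect_equal(an$Df[6], 7L)
  expect_equal(sum(an$SS[1:5]), an$SS[6], tolerance = 1e-10)
  expect_equal(sum(an$eta2[1:5]), 1, tolerance = 1e-10)
  # no replication below flower: imaging/digitising SS 0, F undefined there
  expect_equal(an$SS[4:5], c(0, 0))
  expect_true(is.na(an$F[3]))
  expect_equal(an$F[1], (200 / 1) / (32 / 2))
  expect_equal(an$F[2], (32 / 2) / (8 / 4))
})

test_that("nested ANOVA handles multivariate responses and constant input", {
  Y <- cbind(c(1, 3, 5, 7, 11, 13, 15, 17), c(2, 2, 4, 4, 6, 6, 8, 8))
  an <- nested_anova(Y, toy_design(), n_perm = 0)
  # multivariate SS are sums of the univariate SS per column
  a1 <- nested_anova(Y[, 1], toy_design(), n_perm = 0)
  a2 <- nested_anova(Y[, 2], toy_design(), n_perm = 0)
  expect_equal(an$SS, a1$SS + a2$SS, tolerance = 1e-10)

  cn <- nested_anova(rep(4, 8), toy_design(), n_perm = 99, seed = 1)
  expect_equal(cn$SS[6], 0)
  expect_true(all(is.na(cn$p)))
})

test_that("nested ANOVA on the study design yields the study df column", {
  pop <- study_raw()
  cs <- apply(pop$set$coords, 3, centroid_size)
  an <- nested_anova(cs, pop$set$meta, n_perm = 0)
  expect_equal(an$Df, c(1L, 14L, 153L, 169L, 338L, 675L))
  # F consistency: every F equals MS_effect / MS_nested-effect
  for (i in 1:4)
    expect_equal(an$F[i], an$MS[i] / an$MS[i + 1], tolerance = 1e-3)
  # sequential decomposition is exact
  expect_equal(sum(an$SS[1:5]), an$SS[6], tolerance = 1e-6 * an$SS[6])
})

test_that("nested ANOVA permutation p-values are valid and reproducible", {
  pop <- small_population()
  cs <- apply(pop$set$coords, 3, centroid_size)
  a1 <- nested_anova(cs, pop$set$meta, n_perm = 99, seed = 7)
  a2 <- nested_anova(cs, pop$set$meta, n_perm = 99, seed = 7)
  expect_identical(a1$p, a2$p)
  expect_true(all(a1$p[1:4] >= 1 / 100 & a1$p[1:4] <= 1, na.rm = TRUE))
  # strong size signal at flower level must be detected
  expect_lt(a1$p[3], 0.05)
})

test_that("Goodall's F equals the sex row of a two-level Procrustes ANOVA", {
  an <- small_analysis()
  symm <- symmetrise(an$expanded, an$alignment)
  Y <- florasym:::flatten_coords(symm$coords)
  g <- symm$meta$sex
  gr <- goodall_regression(Y, g, n_perm = 0)

  # independent two-level route via lm(): between/within SS per column
  fit <- stats::lm(Y ~ g)
  ssb <- sum((fitted(fit) - matrix(colMeans(Y), nrow(Y), ncol(Y),
                                   byrow = TRUE))^2)
  ssw <- sum(residuals(fit)^2)
  f_oracle <- (ssb / 1) / (ssw / (nrow(Y) - 2))
  expect_equal(gr$F, f_oracle, tolerance = 1e-8)
  expect_equal(gr$percent_variance, 100 * ssb / (ssb + ssw), tolerance = 1e-8)

  # determinism of the permutation p under a fixed seed
  p1 <- goodall_regression(Y, g, n_perm = 199, seed = 3)$p
  p2 <- goodall_regression(Y, g, n_perm = 199, seed = 3)$p
  expect_identical(p1, p2)
  expect_error(goodall_regression(Y, rep("a", nrow(Y))), "two non-empty")
})

test_that("Goodall regression is near-null when group means coincide", {
  set.seed(9)
  Y <- matrix(rnorm(120 * 6), 120, 6)
  g <- rep(c("a", "b"), each = 60)
  gr <- goodall_regression(Y, g, n_perm = 199, seed = 2)
  expect_lt(gr$percent_variance, 5)
  expect_gt(gr$p, 0.01)
})

test_that("dispersion test matches vegan::betadisper and basic contracts", {
  set.seed(31)
  S <- rbind(matrix(rnorm(40 * 3), 40, 3), matrix(rnorm(40 * 3, sd = 2), 40, 3))
  g <- rep(c("a", "b"), each = 40)
  dt <- dispersion_test(S, g, permute_unit = "configuration",
                        n_perm = 999, seed = 5)
  bd <- vegan::betadisper(dist(S), g, type = "centroid")
  f_veg <- anova(bd)$`F value`[1]
  expect_equal(dt$F, f_veg, tolerance = 1e-8)
  expect_equal(unname(dt$mean_dist),
               unname(tapply(bd$distances, g, mean)), tolerance = 1e-8)
  expect_lt(dt$p, 0.01)
  # CI brackets the observed difference
  expect_lte(dt$conf_int[1], dt$difference)
  expect_gte(dt$conf_int[2], dt$difference)

  # a group of coincident points has zero mean distance
  S0 <- rbind(matrix(0, 10, 2), matrix(rnorm(20), 10, 2))
  d0 <- dispersion_test(S0, rep(c("z", "w"), each = 10),
                        permute_unit = "configuration", n_perm = 0)
  expect_equal(unname(d0$mean_dist["z"]), 0)

  expect_error(dispersion_test(S, g, permute_unit = "flower"), "unit")
  expect_error(dispersion_test(S, rep("a", 80),
                               permute_unit = "configuration"), "2 groups")
})

test_that("flower-level permutation keeps symmetry copies together", {
  an <- small_analysis()
  dec <- an$dec
  lat <- dec$scores[, dec$labels == "lateral", drop = FALSE]
  d1 <- dispersion_test(lat, an$expanded$meta$sex, permute_unit = "flower",
                        unit = an$expanded$meta$flower, n_perm = 199, seed = 4)
  d2 <- dispersion_test(lat, an$expanded$meta$sex, permute_unit = "flower",
                        unit = an$expanded$meta$flower, n_perm = 199, seed = 4)
  expect_identical(d1$p, d2$p)
  expect_true(d1$p >= 1 / 200 && d1$p <= 1)
})

test_that("NMDS embeds 2D data perfectly and preserves embeddable structure", {
  set.seed(13)
  pts <- matrix(rnorm(30), 15, 2)
  nm <- nmds(pts, seed = 1)
  expect_lt(nm$stress, 1e-4)

  # square in 4D with preserved pairwise distances
  sq <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 1, 0, 0))
  nm2 <- nmds(sq, seed = 2)
  expect_lt(nm2$stress, 0.01)

  n1 <- nmds(pts, seed = 7); n2 <- nmds(pts, seed = 7)
  expect_identical(n1$points, n2$points)
  expect_true(nm$stress >= 0 && nm$stress <= 1)
  expect_error(nmds(pts[1:2, ]), "at least 3")
})
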