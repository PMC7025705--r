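test_that("centroid size matches closed forms and a direct-summation oracle", {
  expect_equal(centroid_size(rbind(c(-.5, -.5), c(.5, -.5), c(.5, .5), c(-.5, .5))),
               sqrt(2))
  cfg <- random_config(200, seed = 4)
  expect_equal(centroid_size(2 * cfg), 2 * centroid_size(cfg))
  # brute-force sum over squared centroid distances
  ctr <- colMeans(cfg)
  oracle <- sqrt(sum(apply(cfg, 1, function(r) sum((r - ctr)^2))))
  expect_equal(centroid_size(cfg), oracle, tolerance = 1e-12)
  # rigid-motion invariance
  R <- cbind(c(cos(2), sin(2)), c(-sin(2), cos(2)))
  expect_equal(centroid_size(cfg %*% R + 7), centroid_size(cfg))
  expect_warning(centroid_size(matrix(1, 4, 2)), "coincident")
})

test_that("pairwise fit recovers similarity transforms and forbids reflection", {
  X <- random_config(10, seed = 5)
  R <- cbind(c(cos(0.8), sin(0.8)), c(-sin(0.8), cos(0.8)))
  Y <- 2.5 * X %*% R + 3
  expect_lt(partial_procrustes_fit(Y, X)$distance, 1e-10)
  expect_equal(det(partial_procrustes_fit(Y, X)$rotation), 1, tolerance = 1e-12)

  Xr <- X; Xr[, 1] <- -Xr[, 1]
  expect_gt(partial_procrustes_fit(Xr, X)$distance, 0.1)
  expect_equal(det(partial_procrustes_fit(Xr, X)$rotation), 1, tolerance = 1e-12)

  expect_error(partial_procrustes_fit(matrix(1, 4, 2), X[1:4, ]), "degenerate")
})

test_that("pairwise fit agrees with the rotation-grid oracle", {
  for (s in 1:5) {
    A <- random_config(10, seed = s)
    B <- random_config(10, seed = s + 50)
    expect_equal(partial_procrustes_fit(A, B)$distance,
                 grid_procrustes_distance(A, B), tolerance = 1e-6)
  }
})

test_that("GPA aligns identical configurations exactly and is invariant", {
  base <- perfect_corolla()
  n <- 6
  arr <- array(0, c(200, 2, n))
  set.seed(11)
  for (i in 1:n) {
    th <- runif(1, 0, 2 * pi)
    R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    arr[, , i] <- sweep(runif(1, 0.5, 2) * base %*% R, 2, rnorm(2), "+")
  }
  al <- gpa(arr, tol = 1e-10)
  for (i in 2:n) expect_lt(max(abs(al$aligned[, , i] - al$aligned[, , 1])), 1e-8)
  expect_lt(partial_procrustes_fit(al$consensus, base)$distance, 1e-8)

  # aligned configurations are centered with unit centroid size; consensus
  # is their coordinate-wise mean
  expect_lt(max(abs(apply(al$aligned, 3, colMeans))), 1e-9)
  expect_lt(max(abs(apply(al$aligned, 3, centroid_size) - 1)), 1e-9)
  expect_lt(max(abs(al$consensus - apply(al$aligned, c(1, 2), mean))), 1e-9)

  # objective is non-increasing across GPA iterations
  pop <- small_population()
  al2 <- gpa(pop$set$coords, tol = 1e-12)
  expect_true(all(diff(al2$objective) <= 1e-12))

  # invariance to input ordering and global rigid motion/scale
  perm <- rev(seq_len(n_configs(pop$set)))
  al3 <- gpa(pop$set$coords[, , perm], tol = 1e-12)
  expect_lt(max(abs(al3$aligned[, , perm] - al2$aligned)), 1e-8)
  moved <- pop$set$coords * 0.25
  for (i in seq_len(dim(moved)[3]))
    moved[, , i] <- moved[, , i] %*% cbind(c(cos(1), sin(1)), c(-sin(1), cos(1))) + 40
  al4 <- gpa(moved, tol = 1e-12)
  expect_lt(max(abs(al4$aligned - al2$aligned)), 1e-8)
})

test_that("GPA without sliders matches an independent closed-form oracle", {
  pop <- small_population()
  arr <- pop$set$coords[, , 1:10]
  al <- gpa(arr, tol = 1e-12)
  or <- oracle_gpa(arr)
  # same consensus shape and same total Procrustes spread
  expect_lt(partial_procrustes_fit(or$consensus, al$consensus)$distance, 1e-8)
  ss_pkg <- sum(sweep(al$aligned, c(1, 2), al$consensus)^2)
  ss_or <- sum(sweep(or$aligned, c(1, 2), or$consensus)^2)
  expect_equal(ss_pkg, ss_or, tolerance = 1e-8)
})

test_that("GPA consensus of an expanded symmetry group is biradially symmetric", {
  an <- small_analysis()
  cons <- an$alignment$consensus
  for (id in c("reflectV", "reflectH"))
    expect_lt(partial_procrustes_fit(apply_transform(cons, id), cons)$distance,
              1e-8)
})

test_that("bending energy: affine null space and slider structure", {
  ref <- perfect_corolla()
  B <- bending_energy_matrix(ref)
  # affine deformation of the reference has zero bending energy
  aff <- ref %*% matrix(c(1.3, 0.2, -0.4, 0.9), 2, 2) + 11
  expect_lt(bending_energy(ref, aff, B), 1e-8 * sum(diag(B)))
  expect_gt(bending_energy(ref, ref + matrix(rnorm(400, 0, 5), 200, 2), B), 0)

  sp <- slider_spec(200, 4)
  expect_equal(length(sp$fixed), 8L)
  expect_equal(nrow(sp$sliders), 192L)
  # slider neighbours stay within the petal block
  blk <- (sp$sliders[, "point"] - 1) %/% 50
  expect_true(all((sp$sliders[, "before"] - 1) %/% 50 == blk))
  expect_true(all((sp$sliders[, "after"] - 1) %/% 50 == blk))
})

test_that("sliding never increases bending energy and fixes the fixed points", {
  an <- small_analysis()
  al0 <- gpa(an$expanded, sliders = NULL, tol = 1e-8)
  sp <- slider_spec(200, 4)
  cons <- al0$consensus / centroid_size(al0$consensus)
  B <- bending_energy_matrix(cons)
  sub <- al0$aligned[, , 1:12]
  slid <- slide_semilandmarks(sub, cons, sp)
  for (i in 1:12) {
    expect_lte(bending_energy(cons, slid[, , i], B),
               bending_energy(cons, sub[, , i], B) + 1e-12)
    expect_equal(slid[sp$fixed, , i], sub[sp$fixed, , i])
  }
  # a configuration equal to the consensus does not move
  expect_lt(max(abs(slide_semilandmarks(cons, cons, sp) - cons)), 1e-12)
})

test_that("single-slider slide matches the scalar closed-form optimum", {
  ref <- rbind(c(0, 0), c(1, 0.2), c(2, -0.1), c(3, 0.3), c(4, 0))
  cfg <- ref + rbind(0, c(0.02, -0.01), c(-0.4, 0.15), c(0.01, 0.03), 0)
  sp <- structure(list(fixed = c(1L, 2L, 4L, 5L),
                       sliders = cbind(before = 2L, point = 3L, after = 4L),
                       p = 5L, n_petals = 1L), class = "slider_spec")
  slid <- slide_semilandmarks(cfg, ref, sp)
  # independent scalar-calculus oracle: minimize bending energy along the
  # tangent with optimize()
  u <- cfg[4, ] - cfg[2, ]; u <- u / sqrt(sum(u^2))
  B <- bending_energy_matrix(ref)
  be_of <- function(t) {
    y <- cfg; y[3, ] <- y[3, ] + t * u
    bending_energy(ref, y, B)
  }
  # bending energy is quadratic in t: exact vertex from three evaluations
  t_star <- (be_of(-1) - be_of(1)) / (2 * (be_of(-1) - 2 * be_of(0) + be_of(1)))
  expect_equal(unname(slid[3, ] - cfg[3, ]), unname(t_star * u),
               tolerance = 1e-8)
})

test_that("full GPA with sliding reduces total bending energy against the consensus", {
  an <- small_analysis()
  al_plain <- gpa(an$expanded, sliders = NULL, tol = 1e-8)
  al_slid <- an$alignment
  be_total <- function(al) {
    cons <- al$consensus / centroid_size(al$consensus)
    B <- bending_energy_matrix(cons)
    sum(vapply(seq_len(dim(al$aligned)[3]), function(i)
      bending_energy(cons, al$aligned[, , i], B), 0))
  }
  expect_lt(be_total(al_slid), be_total(al_plain))
})
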