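test_that("shape PCA matches a direct eigendecomposition oracle", {
  pop <- small_population()
  ex <- expand_symmetry_group(pop$set[1:10])
  al <- gpa(ex, tol = 1e-10)
  dec <- shape_pca(al, meta = ex$meta)

  X <- florasym:::flatten_coords(al$aligned)
  or <- oracle_pca(X)
  m <- length(dec$eigenvalues)
  expect_equal(dec$eigenvalues, or$values[1:m], tolerance = 1e-8)
  for (j in 1:5)  # leading components agree up to sign
    expect_lt(min(sum(abs(dec$scores[, j] - or$scores[, j])),
                  sum(abs(dec$scores[, j] + or$scores[, j]))), 1e-6)

  # trace identity: eigenvalues sum to total Procrustes variance
  expect_equal(sum(dec$eigenvalues), dec$total_variance, tolerance = 1e-8)
  expect_equal(dec$total_variance,
               sum(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1),
               tolerance = 1e-10)

  # identical configurations: all eigenvalues 0
  same <- array(rep(perfect_corolla(), 4), c(200, 2, 4))
  al0 <- gpa(same)
  expect_lt(max(shape_pca(al0)$eigenvalues), 1e-16)
})

test_that("eigenvector characters agree with the copy-projection oracle", {
  an <- small_analysis()
  dec <- an$dec
  oracle <- copy_projection_labels(dec, an$expanded$meta)
  live <- dec$eigenvalues > 1e-9 * dec$eigenvalues[1]
  agree <- dec$labels[live] == oracle[live]
  # exact label agreement on the non-degenerate spectrum
  expect_true(all(agree[oracle[live] != "ambiguous"]))
})

test_that("single-subspace generators give pure labels and fractions", {
  # only coordinated all-petal variation -> every live PC symmetric
  p_sym <- generator_params(n_trees_per_sex = 1, flowers_per_tree = 8,
                            n_imaging = 1, n_digitisation = 1,
                            sigma_lat = 0, sigma_trans = 0, sigma_petal = 0,
                            sigma_imaging = 0, sigma_digit = 0,
                            tree_effect_sd = 0, size_cv_tree = 0,
                            size_cv_flower = 0, size_cv_imaging = 0,
                            female_size_factor = 1, female_asym_factor = 1,
                            female_base_factor = 1, seed = 21)
  pop <- generate_population(p_sym)
  ex <- expand_symmetry_group(pop$set)
  dec <- classify_components(shape_pca(gpa(ex, tol = 1e-9), meta = ex$meta))
  live <- dec$eigenvalues > 1e-12 * dec$eigenvalues[1]
  expect_true(all(dec$labels[live] == "symmetric"))
  fr <- variance_fractions(dec)
  expect_equal(unname(fr["symmetric"]), 100, tolerance = 0.1)
  expect_equal(sum(fr[c("symmetric", "lateral", "transversal")]), 100,
               tolerance = 1e-6)

  # only opposite-pair contrasts -> dominant PCs transversal
  p_trn <- generator_params(n_trees_per_sex = 1, flowers_per_tree = 8,
                            n_imaging = 1, n_digitisation = 1,
                            sigma_sym = 0, sigma_lat = 0, sigma_petal = 0,
                            sigma_imaging = 0, sigma_digit = 0,
                            tree_effect_sd = 0, size_cv_tree = 0,
                            size_cv_flower = 0, size_cv_imaging = 0,
                            female_size_factor = 1, female_asym_factor = 1,
                            female_base_factor = 1, seed = 22)
  pop2 <- generate_population(p_trn)
  ex2 <- expand_symmetry_group(pop2$set)
  dec2 <- classify_components(shape_pca(gpa(ex2, tol = 1e-9), meta = ex2$meta))
  fr2 <- variance_fractions(dec2)
  expect_gte(unname(fr2["transversal"]), 95)
})

test_that("asymmetry scores: mirror copies tie, rigid motion is irrelevant", {
  an <- small_analysis()
  sc <- asymmetry_scores(an$dec, mode = "per_configuration")
  expect_true(all(sc$lateral_score >= 0 & sc$transversal_score >= 0))
  for (v in c("lateral_score", "transversal_score")) {
    spread <- tapply(sc[[v]], sc$object_id, function(x) diff(range(x)))
    expect_lt(max(spread), 1e-8)   # the 4 symmetry copies share their norm
  }
  # per-flower aggregation
  pf <- asymmetry_scores(an$dec, mode = "per_flower")
  expect_equal(nrow(pf), length(unique(an$expanded$meta$flower)))
  expect_true(all(c("tree", "sex") %in% names(pf)))

  # abs-sum variant is an upper bound on the norm
  ab <- asymmetry_scores(an$dec, mode = "per_configuration", method = "abs_sum")
  expect_true(all(ab$lateral_score >= sc$lateral_score - 1e-12))

  # scores are invariant to rigid motion + scaling of the raw input
  set <- an$pop$set[1:8]
  R <- cbind(c(cos(0.7), sin(0.7)), c(-sin(0.7), cos(0.7)))
  moved <- set
  for (i in 1:8) moved$coords[, , i] <- 3 * set$coords[, , i] %*% R + 100
  run <- function(s) {
    ex <- expand_symmetry_group(s)
    dec <- classify_components(shape_pca(gpa(ex, tol = 1e-11), meta = ex$meta))
    asymmetry_scores(dec, mode = "per_configuration")
  }
  s1 <- run(set); s2 <- run(moved)
  expect_equal(s1$lateral_score, s2$lateral_score, tolerance = 1e-6)
  expect_equal(s1$transversal_score, s2$transversal_score, tolerance = 1e-6)
})

test_that("perfectly symmetric flowers have zero asymmetry scores", {
  p0 <- generator_params(n_trees_per_sex = 1, flowers_per_tree = 4,
                         n_imaging = 1, n_digitisation = 1,
                         sigma_lat = 0, sigma_trans = 0, sigma_petal = 0,
                         sigma_imaging = 0, sigma_digit = 0,
                         female_asym_factor = 1, seed = 23)
  pop <- generate_population(p0)
  ex <- expand_symmetry_group(pop$set)
  dec <- classify_components(shape_pca(gpa(ex, tol = 1e-10), meta = ex$meta))
  sc <- asymmetry_scores(dec, mode = "per_configuration")
  expect_lt(max(sc$lateral_score, sc$transversal_score), 1e-9)
})

test_that("variance fractions are invariant to pre-transforming the raw data", {
  pop <- small_population()
  set <- pop$set[1:12]
  run_frac <- function(s) {
    ex <- expand_symmetry_group(s)
    suppressWarnings(variance_fractions(classify_components(
      shape_pca(gpa(ex, tol = 1e-12), meta = ex$meta))))
  }
  f1 <- run_frac(set)
  hv <- set
  for (i in 1:12)
    hv$coords[, , i] <- apply_transform(set$coords[, , i], "reflectHV")
  f2 <- run_frac(hv)
  expect_equal(f1[c("symmetric", "lateral", "transversal")],
               f2[c("symmetric", "lateral", "transversal")], tolerance = 1e-10)
})
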