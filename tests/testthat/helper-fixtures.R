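# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

perfect_corolla <- function(rotation = 0, translation = c(0, 0)) {
  generate_corolla(petal_template(), rep(list(list()), 4),
                   rotation = rotation, translation = translation)
}

# small nested population with all variance components active
small_population <- function() memo("small_pop", {
  generate_population(generator_params(
    n_trees_per_sex = 2, flowers_per_tree = 3,
    n_imaging = 2, n_digitisation = 2, seed = 101))
})

# its expanded + slid-GPA + classified decomposition, shared across tests
small_analysis <- function() memo("small_analysis", {
  pop <- small_population()
  ex <- expand_symmetry_group(pop$set)
  al <- gpa(ex, sliders = slider_spec(dim(ex$coords)[1], ex$n_petals))
  dec <- classify_components(shape_pca(al, meta = ex$meta))
  list(pop = pop, expanded = ex, alignment = al, dec = dec)
})

# full study-shaped raw dataset (no alignment; design/count checks)
study_raw <- function() memo("study_raw", simulate_study_dataset(seed = 42))

random_config <- function(p = 12, seed = 1) {
  set.seed(seed)
  matrix(rnorm(2 * p), p, 2)
}
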