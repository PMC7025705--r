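#' Configuration of a full study run
#'
#' Collects every setting of [run_study_pipeline()] in one list that is
#' serialized verbatim (JSON) into the output directory, so a run can be
#' reproduced bit-for-bit from its saved configuration. The single `seed` is
#' expanded into per-stage seeds by a fixed splitter (`seed + stage index`),
#' so individual stages can be re-run in isolation.
#'
#' @param tps,meta input TPS landmark file and metadata CSV paths (leave
#'   `NULL` to simulate instead).
#' @param generator a [generator_params()] used when no input files are
#'   given.
#' @param slide_iter,gpa_tol GPA settings (see [gpa()]).
#' @param n_perm_anova,n_perm_disp,n_perm_regr permutation counts.
#' @param permute_unit dispersion-test exchangeable unit (see
#'   [dispersion_test()]).
#' @param score_mode asymmetry score method (see [asymmetry_scores()]).
#' @param regression_unit `"flower"` (per-flower mean symmetrised shapes)
#'   or `"configuration"` (all symmetrised rows) for the sex regression.
#' @param nmds_starts NMDS starts per subspace.
#' @param run_nmds set `FALSE` to skip the (slow) ordinations.
#' @param seed base seed of the run.
#' @param out output directory.
#' @return a list of class `florasym_config`.
#' @export
study_config <- function(tps = NULL, meta = NULL,
                         generator = generator_params(),
                         slide_iter = 5L, gpa_tol = 1e-6,
                         n_perm_anova = 999L, n_perm_disp = 9999L,
                         n_perm_regr = 999L,
                         permute_unit = "flower", score_mode = "norm",
                         regression_unit = "flower",
                         nmds_starts = 2L, run_nmds = TRUE,
                         seed = 1L, out = tempfile("florasym_run_")) {
  cfg <- list(tps = tps, meta = meta, generator = generator,
              slide_iter = slide_iter, gpa_tol = gpa_tol,
              n_perm_anova = n_perm_anova, n_perm_disp = n_perm_disp,
              n_perm_regr = n_perm_regr, permute_unit = permute_unit,
              score_mode = score_mode, regression_unit = regression_unit,
              nmds_starts = nmds_starts, run_nmds = run_nmds,
              seed = as.integer(seed), out = out)
  class(cfg) <- "florasym_config"
  cfg
}

stage_seed <- function(cfg, stage) {
  stages <- c(simulate = 1L, anova_size = 2L, anova_shape = 3L,
              regression = 4L, dispersion = 5L, nmds = 6L)
  cfg$seed + stages[[stage]]
}

#' Run the full corolla-symmetry study workflow
#'
#' One-command orchestration: read (or simulate) the raw configurations,
#' check the labelling convention, expand the symmetry group, run GPA with
#' bending-energy sliding, symmetrise, test size and shape over the nested
#' design, regress shape on sex (Goodall's F), decompose the shape space
#' into symmetry subspaces, score per-object asymmetry, test multivariate
#' dispersion per subspace and (optionally) ordinate each subspace by NMDS.
#' All tables and reports named in the individual functions' documentation
#' are written to `config$out`; a re-run from the saved `config.json` with
#' the same seed reproduces them bit-for-bit.
#'
#' @param config a [study_config()].
#' @return invisibly, a list with every intermediate result (`set`,
#'   `expanded`, `alignment`, `symmetrised`, `anova_size`, `anova_shape`,
#'   `regression`, `decomposition`, `fractions`, `scores`, `dispersion`,
#'   `nmds`, `report`).
#' @export
run_study_pipeline <- function(config = study_config()) {
  stopifnot(inherits(config, "florasym_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$tps)) {
      set <- read_tps(config$tps, meta = config$meta)
    } else {
      gp <- config$generator
      gp$seed <- gp$seed %||% stage_seed(config, "simulate")
      set <- generate_population(gp)$set
    }
    if (n_configs(set) == 0L) stop("empty input dataset")

    stage <- "labelling check"
    lab <- validate_labeling(set, max_configs = min(12L, n_configs(set)))

    stage <- "symmetry expansion"
    expanded <- expand_symmetry_group(set)

    stage <- "GPA"
    sl <- slider_spec(dim(set$coords)[1L], set$n_petals)
    alignment <- gpa(expanded, sliders = sl, tol = config$gpa_tol,
                     slide_iter = config$slide_iter)

    stage <- "symmetrisation"
    symm <- symmetrise(expanded, alignment)

    stage <- "size ANOVA"
    id_rows <- which(expanded$meta$transform == "identity")
    cs_meta <- expanded$meta[id_rows, , drop = FALSE]
    anova_size <- nested_anova(alignment$centroid_size[id_rows], cs_meta,
                               n_perm = config$n_perm_anova,
                               seed = stage_seed(config, "anova_size"))

    stage <- "shape ANOVA"
    symm_flat <- flatten_coords(symm$coords)
    anova_shape <- nested_anova(symm_flat, symm$meta,
                                n_perm = config$n_perm_anova,
                                seed = stage_seed(config, "anova_shape"))

    stage <- "sex regression"
    if (config$regression_unit == "flower") {
      fl <- factor(symm$meta$flower)
      Yr <- rowsum(symm_flat, fl) / as.vector(table(fl))
      gr <- symm$meta$sex[match(levels(fl), symm$meta$flower)]
    } else {
      Yr <- symm_flat
      gr <- symm$meta$sex
    }
    regression <- goodall_regression(Yr, gr, n_perm = config$n_perm_regr,
                                     seed = stage_seed(config, "regression"))

    stage <- "symmetry decomposition"
    dec <- classify_components(shape_pca(alignment, meta = expanded$meta))
    fractions <- variance_fractions(dec)
    scores <- asymmetry_scores(dec, mode = "per_flower",
                               method = config$score_mode)

    stage <- "dispersion tests"
    subspaces <- c("symmetric", "lateral", "transversal")
    disp <- lapply(subspaces, function(lab2) {
      dispersion_test(dec$scores[, dec$labels == lab2, drop = FALSE],
                      group = expanded$meta$sex,
                      permute_unit = config$permute_unit,
                      unit = expanded$meta$flower,
                      n_perm = config$n_perm_disp,
                      seed = stage_seed(config, "dispersion"))
    })
    names(disp) <- subspaces

    stage <- "NMDS"
    nm <- NULL
    if (isTRUE(config$run_nmds)) {
      nm <- lapply(subspaces, function(lab2)
        nmds(dec$scores[, dec$labels == lab2, drop = FALSE],
             n_starts = config$nmds_starts,
             seed = stage_seed(config, "nmds")))
      names(nm) <- subspaces
    }

    list(set = set, labelling = lab, expanded = expanded,
         alignment = alignment, symmetrised = symm,
         anova_size = anova_size, anova_shape = anova_shape,
         regression = regression, decomposition = dec,
         fractions = fractions, scores = scores, dispersion = disp,
         nmds = nm)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  write_pipeline_outputs(res, config)
  invisible(res)
}

write_pipeline_outputs <- function(res, config) {
  out <- config$out
  w <- function(df, f) utils::write.csv(df, file.path(out, f), row.names = FALSE)
  w(as.data.frame(res$anova_size), "anova_size.csv")
  w(as.data.frame(res$anova_shape), "anova_shape.csv")
  jsonlite::write_json(
    list(F = res$regression$F, p = res$regression$p,
         percent_variance = res$regression$percent_variance,
         df = res$regression$df, n = res$regression$n),
    file.path(out, "regression.json"), auto_unbox = TRUE, digits = NA)
  dec_tab <- data.frame(pc = seq_along(res$decomposition$eigenvalues),
                        eigenvalue = res$decomposition$eigenvalues,
                        label = res$decomposition$labels,
                        s_V = res$decomposition$characters[, "s_V"],
                        s_H = res$decomposition$characters[, "s_H"])
  w(dec_tab, "decomposition.csv")
  w(res$scores, "scores.csv")
  for (lab in names(res$dispersion)) {
    d <- res$dispersion[[lab]]
    jsonlite::write_json(
      list(mean_dist = as.list(d$mean_dist), difference = d$difference,
           conf_int = d$conf_int, F = d$F, p = d$p,
           permute_unit = d$permute_unit, n_perm = d$n_perm),
      file.path(out, sprintf("dispersion_%s.json", lab)),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$nmds)) {
    for (lab in names(res$nmds)) {
      nm <- res$nmds[[lab]]
      df <- data.frame(object_id = res$expanded$meta$object_id,
                       transform = res$expanded$meta$transform,
                       sex = res$expanded$meta$sex,
                       x = nm$points[, 1L], y = nm$points[, 2L])
      attr(df, "stress") <- nm$stress
      w(df, sprintf("nmds_%s.csv", lab))
    }
  }
  cfg_out <- config
  cfg_out$generator$base <- unclass(cfg_out$generator$base)
  cfg_out$generator <- unclass(cfg_out$generator)
  jsonlite::write_json(unclass(cfg_out), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  rpt <- c(
    sprintf("florasym run (seed %d)", config$seed),
    sprintf("configurations (raw): %d", n_configs(res$set)),
    sprintf("configurations (symmetry-expanded): %d", n_configs(res$expanded)),
    sprintf("recommended labelling remap: offset %d, direction %d, reverse_within %s",
            res$labelling$recommended$offset,
            res$labelling$recommended$direction,
            res$labelling$recommended$reverse_within),
    sprintf("GPA iterations: %d (final delta %.3g)",
            res$alignment$iterations, utils::tail(res$alignment$deltas, 1L)),
    "nested ANOVA Df (size): " ,
    paste(capture_df(res$anova_size), collapse = "\n"),
    sprintf("variance fractions (%%): %s",
            paste(sprintf("%s %.2f", names(res$fractions), res$fractions),
                  collapse = ", ")),
    sprintf("NMDS stress: %s",
            if (is.null(res$nmds)) "skipped"
            else paste(sprintf("%s %.3f", names(res$nmds),
                               vapply(res$nmds, `[[`, 0, "stress")),
                       collapse = ", ")))
  writeLines(rpt, file.path(out, "summary.txt"))
  invisible(out)
}

capture_df <- function(df) utils::capture.output(print(df))
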