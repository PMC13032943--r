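# End-to-end pipeline orchestration -------------------------------------

#' Pipeline configuration
#'
#' Collects all parameters of the end-to-end synthetic run: cohort
#' specification, splitting, model, signature and enrichment settings,
#' plus the per-stage seeds. Can also be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param out_dir Output directory (created if absent).
#' @param spec A [cohort_spec()] describing the synthetic cohort.
#' @param label,secondary Class and treatment column names.
#' @param ml_fraction Holdout split fraction.
#' @param n_folds Requested fold count.
#' @param n_trees Trees per forest.
#' @param step Elimination-curve grid spacing.
#' @param max_k Largest permuted count on the curve (default: all).
#' @param span Elbow smoothing span.
#' @param tolerance_ppm Enrichment matching tolerance.
#' @param n_taxa,n_compounds,frac_significant Synthetic association-table
#'   settings.
#' @param plant_taxon Place the planted features at adduct m/z of one
#'   taxon's compounds so that enrichment has a recoverable truth.
#' @param seed Master seed; per-stage seeds are derived as small offsets.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, spec = cohort_spec(),
                            label = "class_label", secondary = "treatment",
                            ml_fraction = 0.8, n_folds = 5, n_trees = 500,
                            step = 50, max_k = NULL, span = 0.75,
                            tolerance_ppm = 5, n_taxa = 30,
                            n_compounds = 60, frac_significant = 0.6,
                            plant_taxon = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  structure(list(out_dir = out_dir, spec = spec, label = label,
                 secondary = secondary, ml_fraction = ml_fraction,
                 n_folds = n_folds, n_trees = n_trees, step = step,
                 max_k = max_k, span = span, tolerance_ppm = tolerance_ppm,
                 n_taxa = n_taxa, n_compounds = n_compounds,
                 frac_significant = frac_significant,
                 plant_taxon = plant_taxon, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the `pipeline_config`
#'   arguments (cohort settings under a `spec:` mapping).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(cohort_spec, y$spec %||% list())
  y$spec <- spec
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(fmt, ...) message(sprintf(paste0("[metabosig] ", fmt), ...))

#' Run the full synthetic-cohort pipeline
#'
#' Executes, in order: simulate -> preprocess -> split -> train (with
#' permuted-label control) -> rank -> signature -> holdout rank ->
#' enrich (all / V > 0 / V < 0), writing every intermediate as plain
#' text plus a JSON manifest of parameters, seeds, package versions and
#' per-file checksums into `config$out_dir`. A failing stage aborts with
#' the stage name; already-written outputs are preserved.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stages <- character(0)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
    path
  }
  run_stage <- function(name, expr) {
    stage_log("stage %s ...", name)
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  sim <- run_stage("simulate", {
    assoc <- generate_association_table(config$n_taxa, config$n_compounds,
                                        config$frac_significant,
                                        seed = seed + 11L)
    db <- build_microbe_db(assoc)
    planted_mz <- NULL
    anchor_mz <- NULL
    target_taxon <- NA_character_
    if (config$plant_taxon && length(db$sets)) {
      sizes <- lengths(db$sets)
      target_taxon <- names(sizes)[which.max(sizes)]
      proton <- default_adducts()$mass_shift[1]
      in_range <- function(v) v[v >= 70 & v <= 1000]
      masses <- db$compounds$mass[db$compounds$compound_id %in%
                                    db$sets[[target_taxon]]]
      planted_mz <- head(in_range(unique(masses + proton)),  # [M+H]+
                         config$spec$n_planted)
      # every other database compound enters the grid as a
      # non-differential feature, populating the enrichment universe
      anchor_mz <- in_range(unique(db$compounds$mass + proton))
    }
    meta <- generate_cohort(config$spec)
    pt <- generate_peak_table(meta, config$spec, planted_mz = planted_mz,
                              anchor_mz = anchor_mz)
    write.csv(meta, file.path(out, "metadata.csv"), row.names = FALSE)
    write_peak_table(pt$peaks, file.path(out, "peaks.tsv"))
    writeLines(as.character(pt$planted), file.path(out, "planted_features.txt"))
    emit(assoc, "associations.csv")
    files <<- c(files, "metadata.csv", "peaks.tsv", "planted_features.txt")
    list(meta = meta, peaks = pt$peaks, planted = pt$planted, assoc = assoc,
         db = db, target_taxon = target_taxon)
  })

  prep <- run_stage("preprocess", {
    pp <- preprocess_peaks(sim$peaks, sim$meta)
    write.table(data.frame(sample_id = rownames(pp$scaled), pp$scaled,
                           check.names = FALSE),
                file.path(out, "matrix_scaled.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <<- c(files, "matrix_scaled.tsv")
    pp
  })

  smeta <- sim$meta[!duplicated(sim$meta$sample_id), ]
  smeta <- smeta[match(rownames(prep$scaled), smeta$sample_id), ]
  labels <- smeta[[config$label]]

  split <- run_stage("split", {
    hs <- holdout_split(sim$meta, config$label,
                        ml_fraction = config$ml_fraction,
                        secondary = config$secondary, seed = seed + 1L)
    folds <- dual_variable_folds(sim$meta[sim$meta$sample_id %in%
                                            hs$ml$sample_id, ],
                                 config$label, config$secondary,
                                 n_folds = config$n_folds, seed = seed + 2L)
    assert_grouped(hs$plan); assert_grouped(folds)
    emit(hs$plan, "holdout_plan.csv"); emit(folds, "fold_plan.csv")
    list(holdout = hs, folds = folds)
  })

  ml_rows <- match(split$folds$sample_id, rownames(prep$scaled))
  x_ml <- prep$scaled[ml_rows, , drop = FALSE]
  fc_ml <- prep$intensity[ml_rows, , drop = FALSE]
  lab_ml <- labels[ml_rows]
  sub_ml <- smeta$subject_id[ml_rows]
  fold_ml <- split$folds$fold

  train <- run_stage("train", {
    ev <- train_rf_cv(x_ml, lab_ml, fold_ml, n_trees = config$n_trees,
                      seed = seed + 3L)
    ctrl <- permuted_label_control(x_ml, lab_ml, fold_ml, sub_ml,
                                   n_trees = config$n_trees, seed = seed + 4L)
    cmp <- delong_compare(ev$scores$score, ctrl$scores$score,
                          ev$scores$label)
    emit(ev$scores, "pooled_scores.csv")
    emit(ctrl$scores, "control_scores.csv")
    summary <- list(auroc = ev$auroc, auprc = ev$auprc,
                    control_auroc = ctrl$auroc, control_auprc = ctrl$auprc,
                    delong_p = cmp$p_value, stars = star_code(cmp$p_value))
    jsonlite::write_json(summary, file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    files <<- c(files, "evaluation.json")
    list(eval = ev, control = ctrl, comparison = cmp)
  })

  rankings <- run_stage("rank", {
    rks <- per_fold_rankings(fc_ml, x_ml, lab_ml, fold_ml, method = "v")
    for (nm in names(rks))
      emit(rks[[nm]], sprintf("ranking_fold%s.csv", nm))
    rks
  })

  sig <- run_stage("signature", {
    curve <- build_elimination_curves(x_ml, lab_ml, fold_ml, rankings,
                                      subjects = sub_ml, step = config$step,
                                      n_trees = config$n_trees,
                                      seed = seed + 5L, max_k = config$max_k)
    thr <- elbow_threshold(curve, span = config$span)
    emit(as.data.frame(curve), "elimination_curve.csv")
    jsonlite::write_json(list(n_signature = thr$n_signature,
                              no_signal = thr$no_signal),
                         file.path(out, "signature.json"),
                         auto_unbox = TRUE, digits = NA)
    files <<- c(files, "signature.json")
    list(curve = curve, threshold = thr)
  })

  hold_rank <- run_stage("holdout_rank", {
    hrows <- match(split$holdout$holdout$sample_id, rownames(prep$scaled))
    hr <- rank_by_v(prep$intensity[hrows, , drop = FALSE],
                    prep$scaled[hrows, , drop = FALSE], labels[hrows])
    emit(hr, "holdout_ranking.csv")
    hr
  })

  enrich <- run_stage("enrich", {
    n_sig <- max(sig$threshold$n_signature, 1L)
    res <- lapply(c("all", "pos", "neg"), function(d) {
      r <- run_enrichment(hold_rank, n_sig, sim$db,
                          tolerance_ppm = config$tolerance_ppm,
                          direction = d)
      emit(r, sprintf("enrichment_%s.csv", d))
      r
    })
    names(res) <- c("all", "pos", "neg")
    res
  })

  manifest <- list(
    package = as.character(utils::packageVersion("metabosig")),
    r_version = R.version.string,
    seed = seed,
    parameters = config[setdiff(names(config), "spec")],
    spec = unclass(config$spec),
    stages = stages,
    target_taxon = sim$target_taxon,
    checksums = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_log("done: %d stages complete", length(stages))
  invisible(list(sim = sim, preprocess = prep, split = split, train = train,
                 rankings = rankings, signature = sig,
                 holdout_rank = hold_rank, enrich = enrich,
                 manifest = manifest))
}
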