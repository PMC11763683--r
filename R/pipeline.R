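# End-to-end orchestration: simulate -> segment -> extract -> resample ->
# benchmark, with every intermediate persisted as plain text/PNG so any stage
# can be re-run from the upstream artefacts. One master seed is expanded
# deterministically into per-stage seeds.

#' Build a pipeline run configuration
#'
#' @param n_patients cohort size
#' @param degraded_fraction fraction of degraded images
#' @param image_height,image_width image dimensions
#' @param texture_separation class-separation control
#' @param n_levels grey levels for feature discretisation
#' @param train_fraction train share of the stratified split
#' @param k_smote SMOTE/ADASYN neighbour count
#' @param grids `"reduced"`, `"full"`, or a named grid list
#' @param folds CV folds
#' @param seed master seed; expanded per stage via [derive_seed()]
#' @param out_dir artefact directory
#' @return a named list (class `pipeline_config`)
#' @export
pipeline_config <- function(n_patients = 60L, degraded_fraction = 0.2,
                            image_height = 160L, image_width = 150L,
                            texture_separation = 1.5, n_levels = 32L,
                            train_fraction = 0.7, k_smote = 5L,
                            grids = "reduced", folds = 5L, seed = 1L,
                            out_dir = tempfile("osteotex_run_")) {
  structure(list(
    n_patients = n_patients, degraded_fraction = degraded_fraction,
    image_height = image_height, image_width = image_width,
    texture_separation = texture_separation, n_levels = n_levels,
    train_fraction = train_fraction, k_smote = k_smote, grids = grids,
    folds = folds, seed = seed, out_dir = out_dir
  ), class = "pipeline_config")
}

resolve_grids <- function(grids) {
  if (is.character(grids))
    default_grids(reduced = match.arg(grids, c("reduced", "full")) == "reduced")
  else grids
}

#' Run the full synthetic DXA classification pipeline
#'
#' Executes the five stages in order: (1) cohort simulation, (2) mask
#' generation, (3) feature extraction into the nine datasets, (4) stratified
#' split plus resampling into the 45 training sets, (5) cross-validated
#' benchmark of the three classifiers. Artefacts are written under
#' `config$out_dir`: `images/`, `masks_truth/`, `masks/`, `features/`,
#' `resampled/`, `report/`. Identical configs produce identical reports.
#'
#' @param config a [pipeline_config()]
#' @param verbose print stage progress
#' @return list: `report` (the 45 x 3 benchmark data.frame), `summary`
#'   (Table-style best-classifier rows), `datasets`, `matrix` (split +
#'   resampled tables), `out_dir`
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: simulate
  spec <- cohort_spec(config$n_patients, config$degraded_fraction,
                      config$image_height, config$image_width,
                      config$texture_separation,
                      seed = derive_seed(config$seed, 1L))
  cohort <- tryCatch(generate_cohort(spec),
                     error = function(e) stop("stage simulate failed: ",
                                              conditionMessage(e), call. = FALSE))
  write_cohort(cohort, config$out_dir)
  say("stage 1 simulate: %d images (%d degraded)", length(cohort),
      sum(vapply(cohort, function(x) x$label == "degraded", logical(1))))

  # stage 2: segment
  msk_dir <- file.path(config$out_dir, "masks")
  dir.create(msk_dir, showWarnings = FALSE)
  masks <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    masks[[i]] <- tryCatch(build_mask(cohort[[i]]),
                           error = function(e)
                             stop(sprintf("stage segment failed on image %d: %s",
                                          i, conditionMessage(e)), call. = FALSE))
    write_grey_png(masks[[i]], file.path(msk_dir, sprintf("img%04d.png", i)))
  }
  say("stage 2 segment: %d masks", length(masks))

  # stage 3: extract features, assemble the nine datasets
  features <- extract_cohort(cohort, masks, n_levels = config$n_levels)
  datasets <- assemble_datasets(features)
  feat_dir <- file.path(config$out_dir, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  for (dn in names(datasets))
    write.csv(datasets[[dn]], file.path(feat_dir, paste0(dn, ".csv")),
              row.names = FALSE)
  say("stage 3 extract: %d features x %d samples, %d datasets",
      ncol(features) - 1L, nrow(features), length(datasets))

  # stage 4: split + resample
  mat <- build_resampled_matrix(datasets, seed = derive_seed(config$seed, 4L),
                                train_fraction = config$train_fraction,
                                k = config$k_smote)
  res_dir <- file.path(config$out_dir, "resampled")
  dir.create(res_dir, showWarnings = FALSE)
  for (key in names(mat$resampled)) {
    r <- mat$resampled[[key]]
    out <- r$table
    out$origin <- r$origin
    write.csv(out, file.path(res_dir, paste0(gsub("\\|", "__", key), ".csv")),
              row.names = FALSE)
  }
  say("stage 4 resample: %d resampled training sets (train %d / test %d)",
      length(mat$resampled), nrow(mat$train[[1]]), nrow(mat$test[[1]]))

  # stage 5: benchmark
  report <- run_benchmark(mat, resolve_grids(config$grids), config$folds,
                          seed = derive_seed(config$seed, 5L))
  rep_dir <- file.path(config$out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  write.csv(report, file.path(rep_dir, "benchmark.csv"), row.names = FALSE)
  summary <- summarise_benchmark(report)
  write.csv(summary, file.path(rep_dir, "summary.csv"), row.names = FALSE)
  say("stage 5 benchmark: %d cells; best F-score %.3f (%s, %s, %s)",
      nrow(report), max(summary$f_score),
      summary$feature_set[which.max(summary$f_score)],
      summary$resampling[which.max(summary$f_score)],
      summary$best_classifier[which.max(summary$f_score)])

  list(report = report, summary = summary, datasets = datasets,
       matrix = mat, out_dir = config$out_dir)
}
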