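#' Default pipeline configuration
#'
#' A self-contained configuration running the whole chain on the packaged
#' fixture CNN at desk scale: synthesis of `n_seeds` images per fixture
#' layer, feature extraction, rating simulation, and the layer-level
#' analyses. A single master seed fans out to fixed per-stage offsets so
#' stages are independently re-runnable.
#'
#' @param out_dir output directory.
#' @param master_seed integer master seed.
#' @param inventory layer names to synthesize (default: the fixture CNN's
#'   own layers).
#' @param image_size synthesized image side (default 32 at fixture scale).
#' @param n_seeds images per layer.
#' @param max_iterations synthesis iteration cap.
#' @param n_participants,n_incomplete study roster sizes.
#' @param n_groups layer groups; must divide the inventory size.
#' @param target_r2 population R-squared of the arousal/valence feature
#'   effect used by the simulator (length 2).
#' @return a named list (class `run_config`).
#' @export
pipeline_config <- function(out_dir, master_seed = 1L, inventory = NULL,
                            image_size = 32L, n_seeds = 2L,
                            max_iterations = 25L,
                            n_participants = 24L, n_incomplete = 0L,
                            n_groups = 3L, target_r2 = c(0.37, 0.033)) {
  structure(list(out_dir = out_dir, master_seed = as.integer(master_seed),
                 inventory = inventory, image_size = as.integer(image_size),
                 n_seeds = as.integer(n_seeds),
                 max_iterations = as.integer(max_iterations),
                 n_participants = as.integer(n_participants),
                 n_incomplete = as.integer(n_incomplete),
                 n_groups = as.integer(n_groups),
                 target_r2 = target_r2), class = "run_config")
}

stage_seeds <- function(master_seed) {
  list(synthesis = master_seed, study = master_seed + 1000L,
       ratings = master_seed + 2000L)
}

#' Run the full pipeline
#'
#' Executes synthesis -> features -> simulation -> analysis in order,
#' writing every artifact under `config$out_dir` and returning a run
#' manifest with per-stage seeds and MD5 checksums of the emitted files.
#' Identical configurations produce identical checksums. Any stage failure
#' halts the run with the error and leaves the completed stages' outputs in
#' place. The six-predictor regression stage requires more layers than
#' predictors and is skipped (with a note in the report) at fixture scale.
#'
#' @param config a [pipeline_config()] list.
#' @param model a [model_adapter()]; default [tiny_cnn_adapter()] seeded
#'   from the master seed.
#' @return list (class `run_manifest`): `stages`, `seeds`, `checksums`,
#'   `version`.
#' @export
run_pipeline <- function(config, model = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(model)) model <- tiny_cnn_adapter(seed = config$master_seed)
  inventory <- config$inventory %||% model$layer_names
  bad <- setdiff(inventory, model$layer_names)
  if (length(bad))
    stop("inventory layers absent from model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(inventory) %% config$n_groups != 0L)
    stop(sprintf("inventory size %d not divisible by n_groups = %d",
                 length(inventory), config$n_groups), call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$master_seed)
  stages <- c(synthesis = FALSE, features = FALSE, simulate = FALSE,
              analyze = FALSE)

  scfg <- synthesis_config(image_size = config$image_size,
                           max_iterations = config$max_iterations,
                           seed = seeds$synthesis)
  stim_dir <- file.path(config$out_dir, "stimuli")
  set <- suppressWarnings(
    generate_stimulus_set(model, inventory, scfg, n_seeds = config$n_seeds,
                          out_dir = stim_dir, keep_images = TRUE))
  stages["synthesis"] <- TRUE

  features <- compute_feature_table(set, out_csv = file.path(config$out_dir,
                                                             "features.csv"))
  stages["features"] <- TRUE

  roster <- make_roster(config$n_participants, config$n_incomplete,
                        rng_seed = seeds$study)
  assignment <- assign_groups(inventory, roster, n_groups = config$n_groups,
                              n_images = config$n_seeds, rng_seed = seeds$study)
  feats <- c("hue", "saturation", "brightness", "jpeg_pct", "cfc", "cse")
  sds <- vapply(features[feats], stats::sd, 0)
  beta <- stats::setNames(ifelse(sds > 0, 1 / pmax(sds, 1e-8), 0), feats)
  beta_a <- beta * c(-1, 0, 1, 0, 1, -1)      # arousal loads on hue/clutter
  beta_v <- beta * c(1, 0, 0, 0, 0, 0) * 0.3
  eff <- effect_spec(
    arousal_beta = beta_a, valence_beta = beta_v, intercept = 50,
    participant_sd = 3,
    residual_sd = c(
      if (any(beta_a != 0))
        rsq_to_noise_sd(beta_a, features, config$target_r2[1]) else 10,
      if (any(beta_v != 0))
        rsq_to_noise_sd(beta_v, features, config$target_r2[2]) else 10))
  ratings <- simulate_ratings(assignment, features, eff,
                              rng_seed = seeds$ratings, roster = roster)
  utils::write.csv(roster, file.path(config$out_dir, "roster.csv"),
                   row.names = FALSE)
  utils::write.csv(ratings, file.path(config$out_dir, "ratings.csv"),
                   row.names = FALSE)
  stages["simulate"] <- TRUE

  summaries <- layer_summaries(ratings, inventory)
  utils::write.csv(summaries, file.path(config$out_dir, "layer_summaries.csv"),
                   row.names = FALSE)
  neut <- suppressWarnings(neutrality_test(ratings))
  utils::write.csv(neut, file.path(config$out_dir, "neutrality.csv"),
                   row.names = FALSE)
  grids <- lapply(stats::setNames(summaries$layer, summaries$layer),
                  function(lay) {
                    d <- ratings[ratings$layer_name == lay, ]
                    joint_density(d$arousal, d$valence)
                  })
  ranking <- rank_layers_by_entropy(grids, summaries)
  anchors <- nearest_to_anchors(summaries)
  report <- list(master_seed = config$master_seed,
                 entropy_ranking = ranking$scores,
                 lowest_entropy = ranking$lowest,
                 highest_entropy = ranking$highest,
                 balanced = ranking$balanced,
                 anchors = anchors)
  lay_feat <- stats::aggregate(features[feats],
                               by = list(layer = features$layer), mean)
  if (nrow(lay_feat) > length(feats) + 1L) {
    lay_out <- summaries[match(lay_feat$layer, summaries$layer), ]
    fit <- ols_fit(lay_out$arousal_mean, lay_feat[feats])
    report$arousal_regression <- unclass(fit)
  } else {
    report$regression_note <- sprintf(
      "regression skipped: %d layers <= %d predictors + 1",
      nrow(lay_feat), length(feats))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages["analyze"] <- TRUE

  files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                        "run_manifest.json"))
  checksums <- tools::md5sum(file.path(config$out_dir, files))
  names(checksums) <- files
  manifest <- structure(list(stages = as.list(stages), seeds = seeds,
                             checksums = as.list(checksums),
                             version = as.character(utils::packageVersion("dreamaffect"))),
                        class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Validate pipeline artifacts
#'
#' Schema checks for the CSV artifacts and PNG stimuli of a pipeline run:
#' required columns, value ranges (ratings and seed indices), uniqueness of
#' the (participant, layer) key, and PNG readability. Returns a data.frame
#' of violations (empty when everything is well-formed).
#'
#' @param dir a pipeline output directory, or a named list with any of
#'   `manifest`, `features`, `ratings` (data.frames) and `png` (paths).
#' @return data.frame with columns `file`, `row`, `issue`.
#' @export
validate_io <- function(dir) {
  viol <- list()
  note <- function(file, row, issue)
    viol[[length(viol) + 1L]] <<- data.frame(file = file, row = row,
                                             issue = issue,
                                             stringsAsFactors = FALSE)
  get_tab <- function(what, csv) {
    if (is.list(dir) && !is.null(dir[[what]])) return(dir[[what]])
    if (is.character(dir) && file.exists(file.path(dir, csv)))
      return(utils::read.csv(file.path(dir, csv), stringsAsFactors = FALSE))
    NULL
  }
  man <- get_tab("manifest", "stimuli/manifest.csv")
  if (!is.null(man)) {
    need <- c("file", "layer", "seed", "iterations", "converged")
    for (m in setdiff(need, names(man)))
      note("manifest.csv", NA, paste("missing column", m))
    if (all(c("layer", "seed") %in% names(man)) &&
        anyDuplicated(man[c("layer", "seed")]))
      note("manifest.csv", NA, "duplicate (layer, seed) keys")
  }
  feat <- get_tab("features", "features.csv")
  if (!is.null(feat)) {
    need <- c("layer", "seed", "hue", "saturation", "brightness",
              "jpeg_pct", "cfc", "cse")
    for (m in setdiff(need, names(feat)))
      note("features.csv", NA, paste("missing column", m))
    if (!is.null(feat$jpeg_pct))
      for (r in which(!is.na(feat$jpeg_pct) & feat$jpeg_pct <= 0))
        note("features.csv", r, "jpeg_pct must be positive")
  }
  rat <- get_tab("ratings", "ratings.csv")
  if (!is.null(rat)) {
    need <- c("participant_id", "layer_name", "seed_index", "arousal",
              "valence", "presentation_order")
    for (m in setdiff(need, names(rat)))
      note("ratings.csv", NA, paste("missing column", m))
    for (sc in intersect(c("arousal", "valence"), names(rat)))
      for (r in which(rat[[sc]] < 0 | rat[[sc]] > 100))
        note("ratings.csv", r, paste(sc, "outside [0, 100]"))
    if (!is.null(rat$seed_index))
      for (r in which(rat$seed_index < 0 | rat$seed_index > 4))
        note("ratings.csv", r, "seed_index outside 0..4")
    if (all(c("participant_id", "layer_name") %in% names(rat))) {
      dup <- which(duplicated(rat[c("participant_id", "layer_name")]))
      for (r in dup) note("ratings.csv", r, "duplicate (participant, layer) key")
    }
  }
  pngs <- if (is.list(dir)) dir$png
          else if (is.character(dir))
            list.files(file.path(dir, "stimuli"), "\\.png$", full.names = TRUE)
  for (f in pngs %||% character()) {
    ok <- tryCatch({ png::readPNG(f); TRUE }, error = function(e) FALSE)
    if (!ok) note(basename(f), NA, "unreadable PNG")
  }
  if (!length(viol))
    return(data.frame(file = character(), row = integer(),
                      issue = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}
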