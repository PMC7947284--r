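# Pipeline runner: chains generate -> extract -> train -> predict ->
# project -> select -> morphset -> stats from a single validated
# config, with per-stage artifacts and provenance sidecars.

#' Default run configuration
#'
#' All defaults mirror the pipeline's printed constants: the circumplex
#' coefficient table, quadrant windows with the 0.15 distance rule,
#' k = 20 prototype pools, 10,000 mediation bootstraps, and the
#' SD < 0.4 / 50 ms / 10,000 ms trial filters.
#'
#' @param seed global seed.
#' @param outdir output directory.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, outdir = "facetriad_out") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    generator = list(n_per_cell = 8, image_size = 128,
                     idiosyncrasy_sd = 1.0, pixel_noise_sd = 0.01,
                     confound = list(male = c(anger = 0.5),
                                     female = c(fear = 0.5))),
    learner = list(learner = "multinom", decay = 0.01,
                   test_fraction = 0.25),
    facespace = list(min_distance = 0.15, k = 20, n_bases_per_gender = 4),
    morph = list(reps_per_category = 4, alpha = 0.5),
    stats = list(n_boot = 10000, alpha = 0.05,
                 sd_min = 0.4, rt_min_ms = 50, rt_max_ms = 10000),
    trials = list(n_participants = 20, n_faces_each = 10)
  ), class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys and invalid values are reported together; missing keys
#' fall back to [default_run_config()].
#'
#' @param path YAML file path (NULL = pure defaults).
#' @param seed optional seed override.
#' @param outdir optional output-directory override.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path = NULL, seed = NULL, outdir = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  errs <- character(0)
  if (is.null(cfg$seed) || is.na(cfg$seed)) errs <- c(errs, "seed")
  if (cfg$generator$n_per_cell < 1) errs <- c(errs, "generator.n_per_cell")
  if (cfg$generator$image_size < 64) errs <- c(errs, "generator.image_size")
  if (cfg$stats$n_boot < 1) errs <- c(errs, "stats.n_boot")
  if (cfg$facespace$k < 1) errs <- c(errs, "facespace.k")
  if (length(errs))
    stop("invalid config values for keys: ", paste(errs, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_provenance <- function(cfg, stage, outdir) {
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("facetriad")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(outdir, paste0(stage, ".provenance.json")),
    auto_unbox = TRUE)
}

#' Run the pipeline
#'
#' Executes one stage (or `"all"`) against the artifacts in
#' `cfg$outdir`; each stage reads its predecessors' CSV/PNG outputs, so
#' stages are individually re-runnable.
#'
#' @param stage one of generate, extract, train, predict, project,
#'   select, morphset, stats, all.
#' @param cfg a `run_config`.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(stage = c("all", "generate", "extract", "train",
                                   "predict", "project", "select",
                                   "morphset", "stats"),
                         cfg = default_run_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("generate", "extract", "train", "predict", "project", "select",
      "morphset", "stats") else stage
  for (s in stages) {
    message("[facetriad] stage: ", s)
    switch(s,
      generate = stage_generate(cfg),
      extract = stage_extract(cfg),
      train = stage_train(cfg),
      predict = stage_predict(cfg),
      project = stage_project(cfg),
      select = stage_select(cfg),
      morphset = stage_morphset(cfg),
      stats = stage_stats(cfg))
    write_provenance(cfg, s, out)
  }
  invisible(out)
}

gen_params_from_config <- function(cfg) {
  g <- cfg$generator
  face_gen_params(image_size = g$image_size,
                  idiosyncrasy_sd = g$idiosyncrasy_sd,
                  pixel_noise_sd = g$pixel_noise_sd, seed = cfg$seed)
}

confound_from_config <- function(cfg) {
  cf <- cfg$generator$confound
  if (is.null(cf)) return(NULL)
  lapply(cf, function(v) {
    v <- unlist(v)
    stats::setNames(as.numeric(v), names(v))
  })
}

stage_generate <- function(cfg) {
  params <- gen_params_from_config(cfg)
  cohort <- make_cohort(params, cfg$generator$n_per_cell,
                        confound_spec = confound_from_config(cfg),
                        seed = cfg$seed)
  write_cohort(cohort, file.path(cfg$outdir, "faces"))
  ratings <- make_ratings(cohort$metadata, seed = cfg$seed + 1L)
  utils::write.csv(ratings, file.path(cfg$outdir, "ratings.csv"),
                   row.names = FALSE)
  trials <- make_trials(ratings, cfg$trials$n_participants,
                        cfg$trials$n_faces_each,
                        contamination = list(n_low_sd = 2, n_fast = 10,
                                             n_slow = 5),
                        seed = cfg$seed + 2L)
  utils::write.csv(trials, file.path(cfg$outdir, "trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(trial_manifest(trials),
                       file.path(cfg$outdir, "trials_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

load_cohort_records <- function(cfg) {
  dir <- file.path(cfg$outdir, "faces")
  md <- utils::read.csv(file.path(dir, "metadata.csv"),
                        stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(md)), function(i)
    read_face_record(dir, md$face_id[i], md$gender[i], md$emotion[i]))
  names(records) <- md$face_id
  list(records = records, metadata = md)
}

stage_extract <- function(cfg) {
  ch <- load_cohort_records(cfg)
  feats <- cohort_features(ch$records)
  write_features(feats, cfg$outdir)
  invisible(NULL)
}

stage_train <- function(cfg) {
  ch <- load_cohort_records(cfg)
  feats <- read_features(cfg$outdir)
  model <- train_combined_model(feats, ch$metadata,
                                config = cfg$learner,
                                test_fraction = cfg$learner$test_fraction,
                                seed = cfg$seed)
  saveRDS(model, file.path(cfg$outdir, "combined_model.rds"))
  utils::write.csv(
    data.frame(metric = names(model$weights),
               test_accuracy = unname(model$weights)),
    file.path(cfg$outdir, "accuracies.csv"), row.names = FALSE)
  invisible(NULL)
}

stage_predict <- function(cfg) {
  model <- readRDS(file.path(cfg$outdir, "combined_model.rds"))
  feats <- read_features(cfg$outdir)
  pr <- stats::predict(model, feats)
  utils::write.csv(data.frame(face_id = rownames(pr), pr,
                              check.names = FALSE),
                   file.path(cfg$outdir, "emotion_output.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

read_emotion_output <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "face_id"), drop = FALSE])
  rownames(m) <- df$face_id
  m
}

stage_project <- function(cfg) {
  pr <- read_emotion_output(file.path(cfg$outdir, "emotion_output.csv"))
  md <- utils::read.csv(file.path(cfg$outdir, "faces", "metadata.csv"),
                        stringsAsFactors = FALSE)
  win <- quadrant_windows(min_distance = cfg$facespace$min_distance)
  pos <- face_space_positions(pr, windows = win, metadata = md)
  utils::write.csv(pos, file.path(cfg$outdir, "positions.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

stage_select <- function(cfg) {
  pos <- utils::read.csv(file.path(cfg$outdir, "positions.csv"),
                         stringsAsFactors = FALSE)
  md <- utils::read.csv(file.path(cfg$outdir, "faces", "metadata.csv"),
                        stringsAsFactors = FALSE)
  pr <- read_emotion_output(file.path(cfg$outdir, "emotion_output.csv"))
  neutral <- pos[pos$face_id %in% md$face_id[md$emotion == "neutral"], ]
  win <- quadrant_windows(min_distance = cfg$facespace$min_distance)
  pools <- select_prototypes(neutral, k = cfg$facespace$k,
                             mode = "quadrant", windows = win)
  for (e in c("anger", "happy")) {
    ep <- select_prototypes(neutral, k = cfg$facespace$k, mode = "emotion",
                            emotion_output = pr, emotion = e)
    pools[names(ep)] <- ep
  }
  bases <- select_origin_bases(neutral, cfg$facespace$n_bases_per_gender)
  jsonlite::write_json(list(pools = pools, bases = bases),
                       file.path(cfg$outdir, "selection.json"),
                       auto_unbox = FALSE)
  invisible(NULL)
}

stage_morphset <- function(cfg) {
  sel <- jsonlite::read_json(file.path(cfg$outdir, "selection.json"),
                             simplifyVector = TRUE)
  ch <- load_cohort_records(cfg)
  pools <- sel$pools[vapply(sel$pools, length, 0L) > 0]
  # keep only categories whose pool is populated for every base gender
  cats <- unique(sub("\\.[^.]+$", "", names(pools)))
  ok <- vapply(cats, function(cat)
    all(paste0(cat, ".", names(sel$bases)) %in% names(pools)), TRUE)
  if (!any(ok)) stop("no morph category has donors for every gender")
  dropped <- cats[!ok]
  if (length(dropped))
    message("[facetriad] skipping donor-less categories: ",
            paste(dropped, collapse = ", "))
  pools <- pools[sub("\\.[^.]+$", "", names(pools)) %in% cats[ok]]
  set <- build_stimulus_set(ch$records, sel$bases, pools,
                            reps_per_category = cfg$morph$reps_per_category,
                            alpha = cfg$morph$alpha, seed = cfg$seed)
  mdir <- file.path(cfg$outdir, "morphs")
  for (r in set$records) write_face_record(r, mdir)
  utils::write.csv(set$manifest, file.path(cfg$outdir, "morph_manifest.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

stage_stats <- function(cfg) {
  pr <- read_emotion_output(file.path(cfg$outdir, "emotion_output.csv"))
  ratings <- utils::read.csv(file.path(cfg$outdir, "ratings.csv"),
                             stringsAsFactors = FALSE)
  md <- utils::read.csv(file.path(cfg$outdir, "faces", "metadata.csv"),
                        stringsAsFactors = FALSE)
  neutral_ids <- md$face_id[md$emotion == "neutral"]
  rr <- ratings[match(neutral_ids, ratings$face_id), ]
  prn <- pr[neutral_ids, , drop = FALSE]
  trait_cols <- intersect(c(TRAITS, "masculinity", "femininity"),
                          names(rr))
  cors <- correlate_traits(prn, rr[, trait_cols], alpha = cfg$stats$alpha)
  utils::write.csv(data.frame(output = rownames(cors$r), cors$r,
                              check.names = FALSE),
                   file.path(cfg$outdir, "correlations.csv"),
                   row.names = FALSE)
  gender01 <- as.integer(md$gender[match(neutral_ids, md$face_id)] == "male")
  mf <- masculinity_composite(rr$masculinity, rr$femininity)
  med <- list(
    gender_anger_dominant = mediate(gender01, prn[, "anger"], rr$dominant,
                                    n_boot = cfg$stats$n_boot,
                                    seed = cfg$seed),
    anger_mf_dominant = mediate(prn[, "anger"], mf, rr$dominant,
                                n_boot = cfg$stats$n_boot,
                                seed = cfg$seed + 1L))
  utils::write.csv(mediation_table(med),
                   file.path(cfg$outdir, "mediation.csv"),
                   row.names = FALSE)
  trials <- utils::read.csv(file.path(cfg$outdir, "trials.csv"),
                            stringsAsFactors = FALSE)
  pp <- preprocess_trials(trials, cfg$stats$sd_min, cfg$stats$rt_min_ms,
                          cfg$stats$rt_max_ms)
  utils::write.csv(pp$trials, file.path(cfg$outdir, "trials_clean.csv"),
                   row.names = FALSE)
  jsonlite::write_json(pp$report[1:4],
                       file.path(cfg$outdir, "preprocess_report.json"),
                       auto_unbox = TRUE)
  invisible(NULL)
}
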