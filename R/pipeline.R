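#' @name pipeline
#' @title Reproducible file-based pipeline
#'
#' @description
#' The pipeline functions tie the package's stages into reproducible runs
#' over plain-CSV datasets: [pipeline_simulate()] writes a synthetic cohort
#' to disk, [pipeline_fit()] fits the happiness models to a dataset (on disk
#' or in memory) and writes per-subject fits plus the model-comparison
#' table, [pipeline_describe()] writes the model-free descriptives and the
#' generosity linkage, and [pipeline_recover()] runs a full
#' simulate-then-fit parameter-recovery study. Every function is
#' deterministic given its inputs and seed; identical reruns produce
#' byte-identical files.
#'
#' Observed tables (`subjects.csv`, `trials.csv`, `ratings.csv`) never
#' contain generative parameters; ground truth lives in `ground_truth.csv`
#' and `ratings_model.csv`, and the full configuration in
#' `provenance.yaml`. Money is serialised as GBP with 2 decimal places
#' (4 for derived event terms, which can sit on a half-penny),
#' model-scale values with 6 significant digits.
NULL

fmt_money <- function(x, digits = 2L) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- ""
  out
}
fmt_model <- function(x) {
  out <- as.character(signif(x, 6))
  out[is.na(x)] <- ""
  out
}

write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

session_task_kind <- function(session) session$schedule$task_kind

empty_trials_table <- function() {
  cols <- c("subject_id", "session_id", "task_kind", "trial_index",
            "is_social", "trial_type", "safe_amount", "gamble_high",
            "gamble_low", "gamble_prob", "rating_after", "chooser", "choice",
            "outcome_subject", "outcome_partner", "CR", "EV", "RPE", "R", "O")
  stats::setNames(data.frame(matrix(nrow = 0L, ncol = length(cols))), cols)
}

cohort_trials_table <- function(cohort) {
  if (!length(cohort$subjects)) return(empty_trials_table())
  rows <- lapply(cohort$subjects, function(subj) {
    do.call(rbind, lapply(names(subj$sessions), function(sid) {
      s <- subj$sessions[[sid]]
      tr <- s$schedule$trials
      ev <- s$events
      data.frame(subject_id = subj$subject_id, session_id = sid,
                 task_kind = s$schedule$task_kind,
                 trial_index = tr$trial_index,
                 is_social = as.integer(tr$is_social),
                 trial_type = tr$trial_type,
                 safe_amount = fmt_money(tr$safe_amount),
                 gamble_high = fmt_money(tr$gamble_high),
                 gamble_low = fmt_money(tr$gamble_low),
                 gamble_prob = tr$gamble_prob,
                 rating_after = tr$rating_after,
                 chooser = s$outcomes$chooser,
                 choice = s$outcomes$choice,
                 outcome_subject = fmt_money(s$outcomes$outcome_subject),
                 outcome_partner = fmt_money(s$outcomes$outcome_partner),
                 CR = fmt_money(ev$CR, 4L), EV = fmt_money(ev$EV, 4L),
                 RPE = fmt_money(ev$RPE, 4L),
                 R = fmt_money(ev$R, 4L), O = fmt_money(ev$O, 4L))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cohort_ratings_table <- function(cohort, scale = c("raw", "model")) {
  scale <- match.arg(scale)
  if (!length(cohort$subjects)) {
    cols <- c("subject_id", "session_id", "rating_index", "position",
              if (scale == "raw") "rating_raw" else "rating_model")
    return(stats::setNames(data.frame(matrix(nrow = 0L, ncol = 5L)), cols))
  }
  rows <- lapply(cohort$subjects, function(subj) {
    do.call(rbind, lapply(names(subj$sessions), function(sid) {
      s <- subj$sessions[[sid]]
      base <- data.frame(subject_id = subj$subject_id, session_id = sid,
                         rating_index = seq_along(s$positions),
                         position = s$positions)
      if (scale == "raw") base$rating_raw <- sprintf("%.1f", s$ratings_raw)
      else base$rating_model <- fmt_model(s$ratings_model)
      base
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to a dataset directory
#'
#' Simulates a cohort (or takes one already simulated) and writes the full
#' file set: observed `subjects.csv`, `trials.csv`, `ratings.csv`;
#' ground-truth `ground_truth.csv`, `ratings_model.csv`; and
#' `provenance.yaml` recording the configuration and master seed.
#'
#' @param config a [cohort_config()], ignored if `cohort` is supplied.
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param cohort optional pre-built `mswb_cohort`.
#' @return (invisibly) the cohort.
#' @export
pipeline_simulate <- function(config = cohort_config(), out_dir, seed = 1L,
                              cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- cohort$population
  subjects <- data.frame(
    subject_id = pop$subject_id, procedure = pop$procedure,
    endowment_gbp = fmt_money(ifelse(pop$procedure == "P1", 3, 2)),
    generosity = pop$generosity)
  write_table(subjects, file.path(out_dir, "subjects.csv"))
  write_table(cohort_trials_table(cohort), file.path(out_dir, "trials.csv"))
  write_table(cohort_ratings_table(cohort, "raw"),
              file.path(out_dir, "ratings.csv"))
  gt <- pop
  gt[c("CR", "EV", "RPE", "guilt", "envy", "gamma", "raw_mean", "raw_sd")] <-
    lapply(gt[c("CR", "EV", "RPE", "guilt", "envy", "gamma", "raw_mean",
                "raw_sd")], fmt_model)
  gt$noise_sd <- fmt_model(rep(cohort$config$noise_sd, nrow(gt)))
  write_table(gt, file.path(out_dir, "ground_truth.csv"))
  write_table(cohort_ratings_table(cohort, "model"),
              file.path(out_dir, "ratings_model.csv"))
  prov <- list(seed = cohort$seed,
               config = unclass_config(cohort$config))
  writeLines(yaml::as.yaml(prov), file.path(out_dir, "provenance.yaml"))
  invisible(cohort)
}

#' Read a cohort configuration from a provenance YAML file
#'
#' Reconstructs the [cohort_config()] (and master seed) recorded by
#' [pipeline_simulate()], so a dataset can be regenerated or varied from its
#' own provenance. Unknown keys are rejected.
#'
#' @param path path to a `provenance.yaml`.
#' @return list with `config` (a `cohort_config`) and `seed`.
#' @export
read_provenance <- function(path) {
  y <- yaml::read_yaml(path)
  if (!all(c("seed", "config") %in% names(y)))
    stop_mswb("provenance file lacks seed/config", class = "mswb_validation_error")
  cfg <- y$config
  known <- c("n_subjects", "procedure", "weight_means", "weight_sds",
             "gamma_mean", "gamma_sd", "noise_sd", "raw_mean_range",
             "raw_sd_range", "generosity", "subject_agent", "partner_agent",
             "battery", "include_nonsocial_task")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop_mswb("unknown config key(s): ", paste(extra, collapse = ", "),
              class = "mswb_validation_error")
  agent <- function(a) pt_params(a$lambda, a$rho,
                                 if (is.null(a$mu) || a$mu == ".inf" ||
                                       is.character(a$mu)) Inf else a$mu)
  list(config = cohort_config(
         n_subjects = cfg$n_subjects, procedure = cfg$procedure,
         weight_means = unlist(cfg$weight_means),
         weight_sds = unlist(cfg$weight_sds),
         gamma_mean = cfg$gamma_mean, gamma_sd = cfg$gamma_sd,
         noise_sd = cfg$noise_sd,
         raw_mean_range = unlist(cfg$raw_mean_range),
         raw_sd_range = unlist(cfg$raw_sd_range),
         generosity = cfg$generosity,
         subject_agent = agent(cfg$subject_agent),
         partner_agent = agent(cfg$partner_agent),
         battery = do.call(battery_config,
                           lapply(cfg$battery, function(v)
                             if (is.list(v)) unlist(v) else v)),
         include_nonsocial_task = cfg$include_nonsocial_task),
       seed = y$seed)
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$subject_agent <- unclass(cfg$subject_agent)
  cfg$partner_agent <- unclass(cfg$partner_agent)
  cfg$battery <- unclass(cfg$battery)
  cfg$weight_means <- as.list(cfg$weight_means)
  cfg$weight_sds <- as.list(cfg$weight_sds)
  cfg
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_mswb(file, " lacks required column(s): ",
              paste(missing, collapse = ", "), class = "mswb_validation_error")
  invisible(df)
}

#' Read a dataset directory back into a cohort object
#'
#' Reconstructs an `mswb_cohort`-shaped object from the CSVs written by
#' [pipeline_simulate()]. Ground-truth files are attached only when present
#' (`population`, model-scale ratings); observed files are mandatory.
#'
#' @param dir dataset directory.
#' @return an object of class `mswb_cohort`.
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("subjects.csv", "trials.csv", "ratings.csv"))
    if (!file.exists(path(f)))
      stop_mswb("dataset file missing: ", f, class = "mswb_validation_error")
  subjects <- require_columns(read.csv(path("subjects.csv")),
                              c("subject_id", "procedure", "generosity"),
                              "subjects.csv")
  trials <- require_columns(
    read.csv(path("trials.csv")),
    c("subject_id", "session_id", "task_kind", "trial_index", "is_social",
      "trial_type", "safe_amount", "gamble_high", "gamble_low", "gamble_prob",
      "rating_after", "chooser", "choice", "outcome_subject",
      "outcome_partner", "CR", "EV", "RPE", "R", "O"), "trials.csv")
  ratings <- require_columns(read.csv(path("ratings.csv")),
                             c("subject_id", "session_id", "rating_index",
                               "position", "rating_raw"), "ratings.csv")
  rat_model <- if (file.exists(path("ratings_model.csv")))
    read.csv(path("ratings_model.csv"))
  population <- if (file.exists(path("ground_truth.csv")))
    read.csv(path("ground_truth.csv"))
  subj_list <- lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    straits <- trials[trials$subject_id == sid, ]
    srat <- ratings[ratings$subject_id == sid, ]
    sessions <- lapply(split(straits, straits$session_id), function(st) {
      st <- st[order(st$trial_index), ]
      kind <- st$task_kind[1]
      schedule <- structure(list(
        task_kind = kind,
        procedure = if (kind == "social")
          if (nrow(st) == 210L) "P1" else "P2" else NA_character_,
        rating_at_start = kind == "nonsocial",
        trials = data.frame(trial_index = st$trial_index,
                            is_social = st$is_social == 1L,
                            trial_type = st$trial_type,
                            safe_amount = st$safe_amount,
                            gamble_high = st$gamble_high,
                            gamble_low = st$gamble_low,
                            gamble_prob = st$gamble_prob,
                            rating_after = st$rating_after)),
        class = "mswb_schedule")
      r <- srat[srat$session_id == st$session_id[1], ]
      r <- r[order(r$rating_index), ]
      rm_ses <- if (!is.null(rat_model)) {
        rms <- rat_model[rat_model$subject_id == sid &
                           rat_model$session_id == st$session_id[1], ]
        rms$rating_model[order(rms$rating_index)]
      }
      list(schedule = schedule,
           outcomes = data.frame(trial_index = st$trial_index,
                                 is_social = st$is_social == 1L,
                                 chooser = st$chooser, choice = st$choice,
                                 outcome_subject = st$outcome_subject,
                                 outcome_partner = st$outcome_partner),
           events = data.frame(trial_index = st$trial_index,
                               is_social = st$is_social == 1L,
                               CR = st$CR, EV = st$EV, RPE = st$RPE,
                               R = st$R, O = st$O),
           positions = r$position,
           ratings_raw = r$rating_raw,
           ratings_model = rm_ses)
    })
    list(subject_id = sid, procedure = subjects$procedure[i],
         generosity = subjects$generosity[i], sessions = sessions)
  })
  structure(list(config = NULL, seed = NA_integer_, population = population,
                 subjects = subj_list),
            class = "mswb_cohort")
}

#' Fit happiness models to a dataset and write the results
#'
#' @param dataset an `mswb_cohort` or a dataset directory path.
#' @param out_dir optional output directory for `fits.csv` and
#'   `comparison.csv`.
#' @param models list of [model_spec()]s.
#' @param ratings_scale passed to [fit_cohort()].
#' @return list with `fits` and `comparison` data frames.
#' @export
pipeline_fit <- function(dataset, out_dir = NULL, models = all_models(),
                         ratings_scale = "raw") {
  cohort <- if (inherits(dataset, "mswb_cohort")) dataset
            else read_cohort(dataset)
  fits <- fit_cohort(cohort, models, ratings_scale)
  comparison <- compare_models(fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ff <- fits
    num <- vapply(ff, is.numeric, TRUE) & names(ff) != "n_ratings"
    ff[num] <- lapply(ff[num], fmt_model)
    write_table(ff, file.path(out_dir, "fits.csv"))
    cc <- comparison
    cc[c("mean_r2", "median_r2", "bic_sum", "bic_rel")] <-
      lapply(cc[c("mean_r2", "median_r2", "bic_sum", "bic_rel")], fmt_model)
    write_table(cc, file.path(out_dir, "comparison.csv"))
  }
  list(fits = fits, comparison = comparison)
}

#' Compute descriptives and the generosity linkage, optionally to disk
#'
#' @param dataset an `mswb_cohort` or dataset directory.
#' @param fits optional fits data frame (from [pipeline_fit()]) enabling the
#'   parameter-based linkage.
#' @param out_dir optional output directory for `descriptives.csv` and
#'   `linkage.yaml`.
#' @return list with `descriptives` and `linkage`.
#' @export
pipeline_describe <- function(dataset, fits = NULL, out_dir = NULL) {
  cohort <- if (inherits(dataset, "mswb_cohort")) dataset
            else read_cohort(dataset)
  descriptives <- cohort_descriptives(cohort)
  linkage <- generosity_linkage(descriptives, fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dd <- descriptives
    num <- vapply(dd, is.numeric, TRUE) &
      !grepl("^n_", names(dd)) & names(dd) != "generosity"
    dd[num] <- lapply(dd[num], fmt_model)
    write_table(dd, file.path(out_dir, "descriptives.csv"))
    writeLines(yaml::as.yaml(linkage), file.path(out_dir, "linkage.yaml"))
  }
  list(descriptives = descriptives, linkage = linkage)
}

#' Parameter-recovery study
#'
#' Simulates a cohort, fits the guilt-envy model to each subject's
#' model-scale ratings, and summarises recovery of every generative
#' parameter: correlation between true and recovered values, mean bias
#' (recovered - true) and RMSE.
#'
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @param ratings_scale `"model"` (default; exact generative scale) or
#'   `"raw"` (through the display-scale mapping and z-scoring).
#' @return list with `report` (per-parameter data frame), `fits`,
#'   `comparison` and the `cohort`.
#' @export
pipeline_recover <- function(config = cohort_config(), seed = 1L,
                             ratings_scale = "model") {
  cohort <- simulate_cohort(config, seed)
  res <- pipeline_fit(cohort, models = all_models()["guilt_envy"],
                      ratings_scale = ratings_scale)
  fits <- res$fits
  pars <- c("CR", "EV", "RPE", "guilt", "envy", "gamma")
  truth <- cohort$population[order(cohort$population$subject_id), ]
  est <- fits[order(fits$subject_id), ]
  report <- do.call(rbind, lapply(pars, function(p) {
    tv <- truth[[p]]; ev <- est[[p]]
    data.frame(parameter = p,
               correlation = if (sd(tv) > 0 && sd(ev) > 0) cor(tv, ev)
                             else NA_real_,
               bias = mean(ev - tv),
               rmse = sqrt(mean((ev - tv)^2)))
  }))
  list(report = report, fits = fits, comparison = res$comparison,
       cohort = cohort)
}
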