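#' z-score happiness ratings
#'
#' Standardises ratings to mean 0 and sample standard deviation 1 so that
#' subjects with more variable ratings do not contribute disproportionately
#' to group analyses, and so the model needs no constant term.
#'
#' @param ratings numeric vector, at least two values with nonzero variance.
#' @return z-scored ratings.
#' @export
zscore_ratings <- function(ratings) {
  if (length(ratings) < 2L)
    stop_mswb("need at least 2 ratings to z-score", class = "mswb_degenerate_error")
  s <- sd(ratings)
  if (!is.finite(s) || s == 0)
    stop_mswb("ratings have zero variance; cannot z-score",
              class = "mswb_degenerate_error")
  (ratings - mean(ratings)) / s
}

#' Bayesian Information Criterion for a least-squares fit
#'
#' Gaussian least-squares form: `BIC = n * log(rss / n) + k * log(n)`.
#' Lower is better; the `k log n` penalty allows comparison of models with
#' different numbers of parameters.
#'
#' @param rss residual sum of squares (> 0; `rss = 0` returns `-Inf` with a
#'   warning, flagging a degenerate/noiseless fit).
#' @param n number of ratings fitted (must exceed `k`).
#' @param k number of free parameters (weights plus gamma).
#' @return BIC value.
#' @export
bic <- function(rss, n, k) {
  stopifnot(n > k, rss >= 0)
  if (rss == 0) {
    warning("rss = 0: BIC is degenerate (-Inf)")
    return(-Inf)
  }
  n * log(rss / n) + k * log(n)
}

# Normalise (events, positions) to per-session lists.
as_session_list <- function(x) if (is.data.frame(x) || !is.list(x)) list(x) else x

# Stack per-session design matrices for one gamma.
stacked_design <- function(events, positions, gamma, model) {
  do.call(rbind, Map(function(e, p) build_design_matrix(e, p, gamma, model),
                     as_session_list(events), as_session_list(positions)))
}

#' Fit one subject's ratings under one happiness model
#'
#' Nonlinear least squares over (weights, gamma). For fixed gamma the model
#' is linear in the weights, so the fit profiles gamma: an exact linear
#' solve at each point of a gamma grid, followed by local refinement of the
#' best grid point with [stats::optimize()]. This avoids the multi-start
#' fragility of joint nonlinear optimisation and guarantees
#' `0 <= gamma <= 1`.
#'
#' For multi-session subjects pass `events` and `positions` as lists (one
#' element per session); decayed sums reset at session boundaries and the
#' sessions share one parameter set.
#'
#' @param ratings numeric vector of (z-scored) ratings, sessions
#'   concatenated in order.
#' @param events per-session event data frame(s) from [derive_events()].
#' @param positions per-session rating reference indices.
#' @param model a [model_spec()].
#' @param gamma_step grid step for the gamma profile (default 0.01).
#' @param refine logical; locally refine gamma around the best grid point.
#' @return object of class `mswb_fit`: list with `model`, `params` (named
#'   weights + `gamma`), `gamma_boundary`, `rss`, `r2`, `n_ratings`, `bic`.
#' @export
fit_subject <- function(ratings, events, positions,
                        model = model_spec("guilt_envy"),
                        gamma_step = 0.01, refine = TRUE) {
  stopifnot(inherits(model, "model_spec"))
  ev <- as_session_list(events)
  pos <- as_session_list(positions)
  n <- length(ratings)
  if (n != sum(lengths(pos)))
    stop_mswb("ratings (", n, ") do not match rating positions (",
              sum(lengths(pos)), ")", class = "mswb_alignment_error")
  if (n <= model$n_params)
    stop_mswb("underdetermined fit: ", n, " ratings for ", model$n_params,
              " parameters", class = "mswb_underdetermined_error")

  solve_at <- function(gamma) {
    X <- stacked_design(ev, pos, gamma, model)
    fit <- stats::lm.fit(X, ratings)
    w <- coef(fit)
    w[is.na(w)] <- 0  # rank-deficient columns (e.g. all-zero social terms)
    list(rss = sum(fit$residuals^2), weights = w)
  }
  grid <- seq(0, 1, by = gamma_step)
  rss_grid <- vapply(grid, function(g) solve_at(g)$rss, 0)
  g_best <- grid[which.min(rss_grid)]
  if (refine) {
    lo <- max(0, g_best - gamma_step)
    hi <- min(1, g_best + gamma_step)
    opt <- optimize(function(g) solve_at(g)$rss, c(lo, hi), tol = 1e-8)
    if (opt$objective < min(rss_grid)) g_best <- opt$minimum
  }
  best <- solve_at(g_best)
  tss <- sum((ratings - mean(ratings))^2)
  params <- c(as.list(best$weights), gamma = g_best)
  structure(list(model = model,
                 params = params,
                 gamma_boundary = g_best <= 1e-9 || g_best >= 1 - 1e-9,
                 rss = best$rss,
                 r2 = 1 - best$rss / tss,
                 n_ratings = n,
                 bic = suppressWarnings(bic(best$rss, n, model$n_params))),
            class = "mswb_fit")
}

#' @export
print.mswb_fit <- function(x, ...) {
  cat(sprintf("<mswb_fit> model=%s  n=%d  r2=%.3f  BIC=%.1f\n",
              x$model$name, x$n_ratings, x$r2, x$bic))
  print(round(unlist(x$params), 4))
  invisible(x)
}

#' Fit every subject of a cohort under one or more models
#'
#' z-scores each subject's social-task ratings and fits the requested models
#' to the decayed-regressor design, pooling a subject's social sessions
#' (decay resets at session boundaries).
#'
#' @param cohort an `mswb_cohort` from [simulate_cohort()].
#' @param models list of [model_spec()]s (default: all three).
#' @param ratings_scale `"raw"` (default) z-scores the observed 0-100
#'   ratings — the realistic observational path; `"model"` fits the
#'   generator's model-scale series directly, the path used for exact
#'   parameter-recovery studies.
#' @return data frame with one row per subject x model: `subject_id`,
#'   `model`, one column per weight (absent terms `NA`), `gamma`,
#'   `gamma_boundary`, `rss`, `r2`, `n_ratings`, `bic`, `low_r2_flag`
#'   (non-social model explaining < 10% of variance).
#' @export
fit_cohort <- function(cohort, models = all_models(),
                       ratings_scale = c("raw", "model")) {
  ratings_scale <- match.arg(ratings_scale)
  stopifnot(inherits(cohort, "mswb_cohort"))
  all_terms <- c("CR", "EV", "RPE", "inequality", "guilt", "envy")
  rows <- list()
  for (subj in cohort$subjects) {
    soc <- subj$sessions[vapply(subj$sessions, function(s)
      s$schedule$task_kind == "social", TRUE)]
    ev <- lapply(soc, `[[`, "events")
    pos <- lapply(soc, `[[`, "positions")
    y <- unlist(lapply(soc, function(s)
      if (ratings_scale == "raw") s$ratings_raw else s$ratings_model),
      use.names = FALSE)
    if (ratings_scale == "raw") y <- zscore_ratings(y)
    for (m in models) {
      f <- fit_subject(y, ev, pos, m)
      w <- setNames(rep(NA_real_, length(all_terms)), all_terms)
      w[m$terms] <- unlist(f$params[m$terms])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, model = m$name, t(w),
        gamma = f$params$gamma, gamma_boundary = f$gamma_boundary,
        rss = f$rss, r2 = f$r2, n_ratings = f$n_ratings, bic = f$bic)
    }
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  ns <- fits[fits$model == "nonsocial", c("subject_id", "r2")]
  fits$low_r2_flag <- fits$subject_id %in% ns$subject_id[ns$r2 < 0.10]
  fits
}

#' Compare fitted models across a cohort
#'
#' Sums BIC across subjects per model and reports each model's BIC relative
#' to the winning (lowest-BIC) model, alongside mean and median r2 — the
#' cohort-level model-comparison table.
#'
#' @param fits data frame from [fit_cohort()] (needs `subject_id`, `model`,
#'   `r2`, `bic`).
#' @return data frame with one row per model: `model`, `n_params`,
#'   `mean_r2`, `median_r2`, `bic_sum`, `bic_rel`.
#' @export
compare_models <- function(fits) {
  mods <- unique(fits$model)
  subj <- unique(fits$subject_id)
  counts <- table(fits$subject_id, fits$model)
  if (any(counts != 1L))
    stop_mswb("every subject must be fitted exactly once under every model",
              class = "mswb_completeness_error")
  if (any(!is.finite(fits$bic)))
    stop_mswb("non-finite BIC (degenerate fit); comparison undefined",
              class = "mswb_completeness_error")
  tab <- do.call(rbind, lapply(mods, function(m) {
    f <- fits[fits$model == m, ]
    data.frame(model = m, n_params = model_spec(m)$n_params,
               mean_r2 = mean(f$r2), median_r2 = median(f$r2),
               bic_sum = sum(f$bic))
  }))
  tab$bic_rel <- tab$bic_sum - min(tab$bic_sum)
  rownames(tab) <- NULL
  tab
}
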