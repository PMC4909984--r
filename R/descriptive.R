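#' Mean happiness by social outcome context
#'
#' Model-free analysis of social trials on which the partner gambled: both
#' gambles resolve independently, so the subject and partner each "win" (get
#' the better of the two equiprobable outcomes) or "lose". Each qualifying
#' trial contributes the *next* happiness rating's z-value to one of four
#' contexts: both win, both lose, subject wins / partner loses (advantageous
#' inequality), subject loses / partner wins (disadvantageous inequality).
#' A rating may serve several qualifying trials since the previous rating;
#' trials after the last rating contribute nothing.
#'
#' @param z_ratings z-scored ratings for one session.
#' @param positions rating reference trial indices (see
#'   [rating_positions()]).
#' @param outcomes data frame from [simulate_session()].
#' @param schedule the session's `mswb_schedule` (for gamble outcomes).
#' @return list with `means` (named numeric, NA where a context is empty),
#'   `counts` (trials per context) and `values` (per-context rating values,
#'   for pooling across sessions).
#' @export
context_means <- function(z_ratings, positions, outcomes, schedule) {
  stopifnot(length(z_ratings) == length(positions))
  tr <- schedule$trials
  ctx_names <- c("both_win", "both_lose",
                 "subject_win_partner_lose", "subject_lose_partner_win")
  qual <- which(outcomes$is_social & outcomes$choice == "gamble")
  values <- setNames(vector("list", 4L), ctx_names)
  for (t in qual) {
    ridx <- match(TRUE, positions >= t)  # next rating at/after this trial
    if (is.na(ridx)) next
    best <- max(tr$gamble_high[t], tr$gamble_low[t])
    swin <- outcomes$outcome_subject[t] == best
    pwin <- outcomes$outcome_partner[t] == best
    ctx <- if (swin && pwin) "both_win"
           else if (!swin && !pwin) "both_lose"
           else if (swin) "subject_win_partner_lose"
           else "subject_lose_partner_win"
    values[[ctx]] <- c(values[[ctx]], z_ratings[ridx])
  }
  counts <- vapply(values, length, 0L)
  means <- vapply(values, function(v) if (length(v)) mean(v) else NA_real_, 0)
  list(means = means, counts = counts, values = values)
}

#' Descriptive guilt and envy measures
#'
#' Model-free sensitivity to inequality, from context means: guilt is the
#' happiness change from "both win" to "subject wins, partner loses";
#' envy is the change from "both lose" to "subject loses, partner wins".
#' Negative values mean the unequal context lowers happiness. The
#' difference (guilt - envy) equals the happiness difference between
#' partner-loses and partner-wins contexts and is the measure linked to
#' dictator-game generosity.
#'
#' @param cm output of [context_means()] (or any list with a `means`
#'   element carrying the four context means).
#' @return list `guilt`, `envy`, `difference` (z-units; NA, flagged, if a
#'   required context is missing).
#' @export
guilt_envy_measures <- function(cm) {
  m <- cm$means
  guilt <- m[["subject_win_partner_lose"]] - m[["both_win"]]
  envy <- m[["subject_lose_partner_win"]] - m[["both_lose"]]
  list(guilt = guilt, envy = envy, difference = guilt - envy,
       complete = !anyNA(m))
}

#' Wilcoxon signed-rank test (one-sample or paired)
#'
#' Thin wrapper around [stats::wilcox.test()] using the large-sample normal
#' approximation with continuity correction; reports an approximate z
#' statistic (signed by the median shift) alongside the exact-rank statistic.
#'
#' @param x numeric sample (or first member of the pair).
#' @param y optional second paired sample.
#' @param mu null location (one-sample case).
#' @return list `statistic` (V), `z`, `p.value`, `n`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x - mu else x - y
  d <- d[!is.na(d)]
  if (all(d == 0))
    stop_mswb("all differences zero: signed-rank test degenerate",
              class = "mswb_degenerate_error")
  ht <- suppressWarnings(
    wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE))
  z <- sign(median(d)) * abs(qnorm(ht$p.value / 2))
  list(statistic = unname(ht$statistic), z = z, p.value = ht$p.value,
       n = length(d))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @param x,y the two independent samples.
#' @return list `statistic` (W), `z` (signed by the difference in medians),
#'   `p.value`, `n` (c(nx, ny)).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  z <- sign(median(x) - median(y)) * abs(qnorm(ht$p.value / 2))
  list(statistic = unname(ht$statistic), z = z, p.value = ht$p.value,
       n = c(length(x), length(y)))
}

#' Spearman rank correlation
#'
#' Rank-based, monotone-invariant correlation with tie handling; p-value
#' from the large-sample approximation. Zero variance in either input is
#' flagged rather than an error.
#'
#' @param x,y paired numeric vectors.
#' @return list `rho`, `p.value`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p.value = NA_real_, n = length(x),
                degenerate = TRUE))
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p.value = ht$p.value, n = length(x),
       degenerate = FALSE)
}

#' Per-subject descriptive measures for a cohort
#'
#' Pools each subject's social sessions: z-scores the subject's raw social
#' ratings, assigns post-gamble ratings to the four outcome contexts, and
#' derives guilt/envy measures and the subject's dictator-game generosity.
#'
#' @param cohort an `mswb_cohort`.
#' @param ratings_scale `"raw"` (z-score observed ratings; default) or
#'   `"model"`.
#' @return data frame, one row per subject: context means, context counts,
#'   `guilt`, `envy`, `difference`, `generosity`.
#' @export
cohort_descriptives <- function(cohort, ratings_scale = c("raw", "model")) {
  ratings_scale <- match.arg(ratings_scale)
  rows <- lapply(cohort$subjects, function(subj) {
    soc <- subj$sessions[vapply(subj$sessions, function(s)
      s$schedule$task_kind == "social", TRUE)]
    y <- unlist(lapply(soc, function(s)
      if (ratings_scale == "raw") s$ratings_raw else s$ratings_model),
      use.names = FALSE)
    if (ratings_scale == "raw") y <- zscore_ratings(y)
    split_y <- split(y, rep(seq_along(soc), vapply(soc, function(s)
      length(s$positions), 0L)))
    pooled <- setNames(vector("list", 4L),
                       c("both_win", "both_lose",
                         "subject_win_partner_lose", "subject_lose_partner_win"))
    for (i in seq_along(soc)) {
      cm <- context_means(split_y[[i]], soc[[i]]$positions,
                          soc[[i]]$outcomes, soc[[i]]$schedule)
      for (ctx in names(pooled))
        pooled[[ctx]] <- c(pooled[[ctx]], cm$values[[ctx]])
    }
    means <- vapply(pooled, function(v) if (length(v)) mean(v) else NA_real_, 0)
    ge <- guilt_envy_measures(list(means = means))
    data.frame(subject_id = subj$subject_id, t(means),
               n_both_win = length(pooled$both_win),
               n_both_lose = length(pooled$both_lose),
               n_swpl = length(pooled$subject_win_partner_lose),
               n_slpw = length(pooled$subject_lose_partner_win),
               guilt = ge$guilt, envy = ge$envy, difference = ge$difference,
               generosity = subj$generosity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Link inequality reactivity to dictator-game generosity
#'
#' The headline individual-differences analysis: Spearman correlation
#' between each subject's guilt-minus-envy happiness difference and the
#' percentage of the endowment given away in the dictator game; a rank-sum
#' comparison of generosity between subjects happier when the partner loses
#' (difference > 0) versus wins (difference < 0); and, when fitted
#' parameters are supplied, the same correlation for the model's guilt and
#' envy weights plus signed-rank tests of those weights within generosity
#' classes (gave nothing / some / half).
#'
#' @param descriptives data frame from [cohort_descriptives()].
#' @param fits optional data frame from [fit_cohort()]; its `guilt_envy`
#'   rows supply w4 (guilt) and w5 (envy) weights.
#' @return list with `descriptive` (spearman + rank-sum) and, if `fits`
#'   given, `parameter` (spearman on w4 - w5, subgroup signed-rank tests).
#' @export
generosity_linkage <- function(descriptives, fits = NULL) {
  d <- descriptives
  dropped <- sum(is.na(d$difference) | is.na(d$generosity))
  if (dropped)
    warning(dropped, " subject(s) dropped from linkage (missing context or generosity)")
  ok <- complete.cases(d$difference, d$generosity)
  d <- d[ok, ]
  pos <- d$generosity[d$difference > 0]
  neg <- d$generosity[d$difference < 0]
  out <- list(descriptive = list(
    spearman = spearman_cor(d$difference, d$generosity),
    ranksum = if (length(pos) >= 2L && length(neg) >= 2L)
      c(wilcoxon_rank_sum(neg, pos),
        list(mean_generosity = c(partner_loses_happier = mean(pos),
                                 partner_wins_happier = mean(neg))))
      else NULL,
    n = nrow(d), n_dropped = dropped))
  if (!is.null(fits)) {
    ge <- fits[fits$model == "guilt_envy", c("subject_id", "guilt", "envy")]
    m <- merge(ge, descriptives[, c("subject_id", "generosity")],
               by = "subject_id")
    cls <- ifelse(m$generosity == 0, "nothing",
                  ifelse(m$generosity >= 50, "half", "some"))
    subgroup <- lapply(split(m, cls), function(g) {
      if (nrow(g) < 4L) return(NULL)
      list(n = nrow(g),
           guilt = wilcoxon_signed_rank(g$guilt),
           envy = wilcoxon_signed_rank(g$envy))
    })
    out$parameter <- list(
      spearman = spearman_cor(m$guilt - m$envy, m$generosity),
      subgroup = subgroup)
  }
  out
}
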