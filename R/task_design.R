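#' Configure a battery of choice problems
#'
#' A battery is a pool of trial specifications from which session schedules
#' draw. Each trial offers a safe amount against a two-outcome gamble with
#' equal (0.5) probabilities. Three trial types are used: Gain (certain gain
#' vs. a gamble for a larger gain or zero), Mixed (zero vs. a gamble to gain
#' or lose), and Loss (certain loss vs. a gamble for a larger loss or zero).
#'
#' Default amount ranges are chosen so that an agent with typical prospect
#' theory preferences (loss aversion 1.35, curvature 0.9) gambles on roughly
#' 55% of trials, matching observed gamble rates in tasks of this design.
#' Amounts are in GBP, rounded to 5p.
#'
#' @param n_gain,n_mixed,n_loss number of trials of each type.
#' @param gain_safe range (length 2) of Gain safe amounts in GBP.
#' @param gain_mult range of the ratio gamble-high / safe on Gain trials.
#' @param mixed_gain,mixed_loss ranges of the Mixed gamble's gain and loss
#'   magnitudes in GBP.
#' @param loss_safe range of Loss safe amount magnitudes (stored negative).
#' @param loss_mult range of the ratio |gamble-low| / |safe| on Loss trials.
#' @param round_to granularity of amounts in GBP (default 0.05 = 5p).
#' @return an object of class `battery_config`.
#' @export
battery_config <- function(n_gain = 70L, n_mixed = 70L, n_loss = 70L,
                           gain_safe = c(0.30, 0.60),
                           gain_mult = c(1.6, 2.8),
                           mixed_gain = c(0.40, 1.50),
                           mixed_loss = c(0.30, 1.00),
                           loss_safe = c(0.30, 0.60),
                           loss_mult = c(1.6, 2.8),
                           round_to = 0.05) {
  cfg <- list(n_gain = as.integer(n_gain), n_mixed = as.integer(n_mixed),
              n_loss = as.integer(n_loss),
              gain_safe = gain_safe, gain_mult = gain_mult,
              mixed_gain = mixed_gain, mixed_loss = mixed_loss,
              loss_safe = loss_safe, loss_mult = loss_mult,
              round_to = round_to)
  for (nm in c("n_gain", "n_mixed", "n_loss"))
    if (cfg[[nm]] < 0L)
      stop_mswb("battery_config: ", nm, " must be >= 0", class = "mswb_config_error")
  for (nm in c("gain_safe", "gain_mult", "mixed_gain", "mixed_loss",
               "loss_safe", "loss_mult")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2])
      stop_mswb("battery_config: ", nm, " must be an increasing positive range",
                class = "mswb_config_error")
  }
  # a Gain/Loss gamble must strictly dominate its safe amount in magnitude
  if (cfg$gain_mult[1] <= 1 || cfg$loss_mult[1] <= 1)
    stop_mswb("battery_config: gamble multipliers must exceed 1",
              class = "mswb_config_error")
  structure(cfg, class = "battery_config")
}

round_money <- function(x, to) round(x / to) * to

#' Generate a battery of trial specifications
#'
#' Draws trial amounts uniformly within the configured ranges and returns a
#' data frame of trial specifications, one row per choice problem.
#'
#' @param config a [battery_config()].
#' @param seed integer seed; the battery is deterministic given
#'   `(config, seed)`.
#' @return data frame with columns `trial_type` ("Gain"/"Mixed"/"Loss"),
#'   `safe_amount`, `gamble_high`, `gamble_low`, `gamble_prob` (always 0.5).
#' @export
make_option_battery <- function(config = battery_config(), seed = 1L) {
  stopifnot(inherits(config, "battery_config"))
  with_seed(seed, {
    to <- config$round_to
    gain <- if (config$n_gain > 0L) {
      safe <- round_money(runif(config$n_gain, config$gain_safe[1],
                                config$gain_safe[2]), to)
      high <- round_money(safe * runif(config$n_gain, config$gain_mult[1],
                                       config$gain_mult[2]), to)
      high <- pmax(high, safe + to)  # rounding must not collapse dominance
      data.frame(trial_type = "Gain", safe_amount = safe,
                 gamble_high = high, gamble_low = 0)
    }
    mixed <- if (config$n_mixed > 0L) {
      data.frame(
        trial_type = "Mixed", safe_amount = 0,
        gamble_high = pmax(round_money(runif(config$n_mixed,
                                             config$mixed_gain[1],
                                             config$mixed_gain[2]), to), to),
        gamble_low = -pmax(round_money(runif(config$n_mixed,
                                             config$mixed_loss[1],
                                             config$mixed_loss[2]), to), to))
    }
    loss <- if (config$n_loss > 0L) {
      safe <- -round_money(runif(config$n_loss, config$loss_safe[1],
                                 config$loss_safe[2]), to)
      low <- round_money(safe * runif(config$n_loss, config$loss_mult[1],
                                      config$loss_mult[2]), to)
      low <- pmin(low, safe - to)
      data.frame(trial_type = "Loss", safe_amount = safe,
                 gamble_high = 0, gamble_low = low)
    }
    battery <- do.call(rbind, Filter(Negate(is.null), list(gain, mixed, loss)))
    if (is.null(battery))
      battery <- data.frame(trial_type = character(), safe_amount = numeric(),
                            gamble_high = numeric(), gamble_low = numeric())
    battery$gamble_prob <- rep(0.5, nrow(battery))
    rownames(battery) <- NULL
    battery
  })
}

#' Validate trial specifications
#'
#' Checks every row of a battery (or the trial columns of a schedule)
#' against the trial-type invariants.
#'
#' @param trials data frame with trial-spec columns.
#' @return character vector of violation messages; empty if all rows valid.
#' @export
validate_trials <- function(trials) {
  msgs <- character()
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) c(msgs, sprintf("%s (rows %s)", msg,
                                     paste(utils::head(idx, 5L), collapse = ",")))
    else msgs
  }
  if (!nrow(trials)) return(msgs)
  msgs <- bad(!trials$trial_type %in% c("Gain", "Mixed", "Loss"),
              "unknown trial_type")
  msgs <- bad(trials$gamble_prob != 0.5, "gamble_prob must be 0.5")
  g <- trials$trial_type == "Gain"
  msgs <- bad(g & !(trials$safe_amount > 0 & trials$gamble_low == 0 &
                      trials$gamble_high > trials$safe_amount),
              "Gain invariant violated (need gamble_high > safe > 0, low = 0)")
  m <- trials$trial_type == "Mixed"
  msgs <- bad(m & !(trials$safe_amount == 0 & trials$gamble_high > 0 &
                      trials$gamble_low < 0),
              "Mixed invariant violated (need high > 0 > low, safe = 0)")
  l <- trials$trial_type == "Loss"
  msgs <- bad(l & !(trials$safe_amount < 0 & trials$gamble_high == 0 &
                      trials$gamble_low < trials$safe_amount),
              "Loss invariant violated (need gamble_low < safe < 0, high = 0)")
  msgs
}

# Arrange n_social TRUE and n_nonsocial FALSE flags so that runs never
# exceed max_social (4) consecutive social or max_nonsocial (2) consecutive
# non-social trials. Greedy randomized construction with a feasibility
# look-ahead, so it never needs restarts.
arrange_social_flags <- function(n_social, n_nonsocial,
                                 max_social = 4L, max_nonsocial = 2L) {
  feasible <- function(s, n, last, run) {
    cap_s <- if (identical(last, TRUE)) (max_social - run) + max_social * n
             else max_social * (n + 1L)
    cap_n <- if (identical(last, FALSE)) (max_nonsocial - run) + max_nonsocial * s
             else max_nonsocial * (s + 1L)
    s <= cap_s && n <= cap_n
  }
  total <- n_social + n_nonsocial
  out <- logical(total)
  s <- n_social; n <- n_nonsocial
  last <- NA; run <- 0L
  for (i in seq_len(total)) {
    cand <- c(
      if (s > 0L && !(identical(last, TRUE) && run >= max_social) &&
            feasible(s - 1L, n, TRUE, if (identical(last, TRUE)) run + 1L else 1L))
        TRUE,
      if (n > 0L && !(identical(last, FALSE) && run >= max_nonsocial) &&
            feasible(s, n - 1L, FALSE, if (identical(last, FALSE)) run + 1L else 1L))
        FALSE)
    if (!length(cand))
      stop_mswb("arrange_social_flags: infeasible trial composition",
                class = "mswb_schedule_error")
    pick <- if (length(cand) == 1L) cand else {
      # weight by remaining counts for well-mixed sequences
      w <- ifelse(cand, s, n)
      cand[sample.int(length(cand), 1L, prob = w)]
    }
    out[i] <- pick
    if (pick) s <- s - 1L else n <- n - 1L
    run <- if (identical(last, pick)) run + 1L else 1L
    last <- pick
  }
  out
}

# Rating positions for a social session: gaps of 2 or 3 trials whose counts
# are solved exactly from the printed totals (n_trials, n_ratings).
social_rating_positions <- function(n_trials, n_ratings) {
  n3 <- n_trials - 2L * n_ratings
  n2 <- 3L * n_ratings - n_trials
  if (n3 < 0L || n2 < 0L)
    stop_mswb("no {2,3} gap sequence yields ", n_ratings, " ratings in ",
              n_trials, " trials", class = "mswb_schedule_error")
  gaps <- sample(rep(c(2L, 3L), times = c(n2, n3)))
  cumsum(gaps)
}

schedule_sizes <- list(
  social = list(P1 = list(n_trials = 210L, n_social = 140L, n_ratings = 85L),
                P2 = list(n_trials = 150L, n_social = 100L, n_ratings = 61L)),
  nonsocial = list(n_trials = 140L, n_ratings = 15L, gap = 10L))

#' Generate a session schedule
#'
#' Builds an ordered trial list for one session of either the non-social
#' decision task (140 trials; happiness rated at the start and after every
#' tenth trial, 15 ratings) or the social decision task. The social task
#' interleaves non-social and social trials, pseudo-randomised so that there
#' are never more than two non-social or four social trials in a row, with a
#' happiness rating after every 2-3 trials. Procedure 1 sessions have 210
#' trials (70 non-social + 140 social) and 85 ratings; procedure 2 sessions
#' have 150 trials (50 non-social + 100 social) and 61 ratings.
#'
#' @param task_kind `"social"` or `"nonsocial"`.
#' @param procedure `"P1"` or `"P2"` (social task only).
#' @param battery trial battery from [make_option_battery()]; must contain at
#'   least as many trials as the session needs.
#' @param seed integer seed; schedules are deterministic given all arguments.
#' @return an object of class `mswb_schedule`: a list with `task_kind`,
#'   `procedure`, `rating_at_start`, and `trials`, a data frame with columns
#'   `trial_index` (1-based), `is_social`, trial-spec columns, and
#'   `rating_after` (0/1).
#' @export
make_session_schedule <- function(task_kind = c("social", "nonsocial"),
                                  procedure = c("P1", "P2"),
                                  battery = make_option_battery(seed = seed),
                                  seed = 1L) {
  task_kind <- match.arg(task_kind)
  procedure <- match.arg(procedure)
  with_seed(as.numeric(seed) + 1000003, {
    if (task_kind == "social") {
      sz <- schedule_sizes$social[[procedure]]
      n_trials <- sz$n_trials
      is_social <- arrange_social_flags(sz$n_social, n_trials - sz$n_social)
      ratings <- social_rating_positions(n_trials, sz$n_ratings)
      rating_at_start <- FALSE
    } else {
      sz <- schedule_sizes$nonsocial
      n_trials <- sz$n_trials
      is_social <- rep(FALSE, n_trials)
      ratings <- seq(sz$gap, n_trials, by = sz$gap)  # plus one at the start
      rating_at_start <- TRUE
    }
    if (nrow(battery) < n_trials)
      stop_mswb("battery has ", nrow(battery), " trials; session needs ",
                n_trials, class = "mswb_schedule_error")
    rows <- sample.int(nrow(battery), n_trials)
    trials <- battery[rows, , drop = FALSE]
    rownames(trials) <- NULL
    trials <- cbind(trial_index = seq_len(n_trials), is_social = is_social,
                    trials,
                    rating_after = as.integer(seq_len(n_trials) %in% ratings))
    structure(list(task_kind = task_kind,
                   procedure = if (task_kind == "social") procedure else NA_character_,
                   rating_at_start = rating_at_start,
                   trials = trials),
              class = "mswb_schedule")
  })
}

#' Validate a session schedule
#'
#' Checks a schedule against all session invariants: trial and rating counts,
#' social/non-social run lengths, rating cadence, and per-trial specification
#' invariants. Validation never raises on content; it reports.
#'
#' @param schedule an `mswb_schedule`.
#' @return character vector of violation messages; empty iff valid.
#' @export
validate_schedule <- function(schedule) {
  msgs <- validate_trials(schedule$trials)
  tr <- schedule$trials
  n <- nrow(tr)
  ratings <- tr$trial_index[tr$rating_after == 1L]
  if (schedule$task_kind == "social") {
    sz <- schedule_sizes$social[[schedule$procedure]]
    if (n != sz$n_trials)
      msgs <- c(msgs, sprintf("expected %d trials, found %d", sz$n_trials, n))
    if (sum(tr$is_social) != sz$n_social)
      msgs <- c(msgs, sprintf("expected %d social trials, found %d",
                              sz$n_social, sum(tr$is_social)))
    n_rat <- length(ratings) + as.integer(isTRUE(schedule$rating_at_start))
    if (n_rat != sz$n_ratings)
      msgs <- c(msgs, sprintf("expected %d ratings, found %d",
                              sz$n_ratings, n_rat))
    runs <- rle(tr$is_social)
    if (any(runs$lengths[runs$values] > 4L))
      msgs <- c(msgs, sprintf("social run of %d trials exceeds 4",
                              max(runs$lengths[runs$values])))
    if (any(runs$lengths[!runs$values] > 2L))
      msgs <- c(msgs, sprintf("non-social run of %d trials exceeds 2",
                              max(runs$lengths[!runs$values])))
    gaps <- diff(c(0L, ratings))
    if (length(ratings) && !all(gaps %in% c(2L, 3L)))
      msgs <- c(msgs, sprintf("rating gap(s) outside {2,3}: %s",
                              paste(unique(gaps[!gaps %in% c(2L, 3L)]),
                                    collapse = ",")))
  } else {
    sz <- schedule_sizes$nonsocial
    if (n != sz$n_trials)
      msgs <- c(msgs, sprintf("expected %d trials, found %d", sz$n_trials, n))
    if (any(tr$is_social))
      msgs <- c(msgs, "non-social session contains social trials")
    if (!isTRUE(schedule$rating_at_start))
      msgs <- c(msgs, "non-social session must have a rating at the start")
    expected <- seq(sz$gap, sz$n_trials, by = sz$gap)
    if (!identical(as.integer(ratings), expected))
      msgs <- c(msgs, "ratings must follow every tenth trial")
  }
  msgs
}

#' Rating positions of a schedule
#'
#' Reference trial indices for each happiness rating: a rating taken after
#' trial `t` has position `t`; a rating at the start of the session has
#' position 0 (no completed trials yet).
#'
#' @param schedule an `mswb_schedule`.
#' @return integer vector of reference trial indices, in rating order.
#' @export
rating_positions <- function(schedule) {
  pos <- schedule$trials$trial_index[schedule$trials$rating_after == 1L]
  if (isTRUE(schedule$rating_at_start)) pos <- c(0L, pos)
  as.integer(pos)
}
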