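# Shared fixtures: hand-built micro-sessions and independent oracles.

# A minimal schedule object (bypassing the generator) from explicit trial
# rows; used to construct sessions with known structure.
tiny_schedule <- function(trials, task_kind = "social", procedure = "P1",
                          rating_at_start = FALSE) {
  trials$trial_index <- seq_len(nrow(trials))
  if (is.null(trials$gamble_prob)) trials$gamble_prob <- 0.5
  if (is.null(trials$rating_after)) trials$rating_after <- 0L
  structure(list(task_kind = task_kind, procedure = procedure,
                 rating_at_start = rating_at_start, trials = trials),
            class = "mswb_schedule")
}

# Random small event table (n trials, mix of social safe/gamble outcomes).
random_events <- function(n, seed) {
  set.seed(seed)
  soc <- runif(n) < 0.6
  gam <- runif(n) < 0.5
  high <- round(runif(n, 0.2, 1.5), 2)
  low <- -round(runif(n, 0, 1), 2)
  ev <- (high + low) / 2
  out_s <- ifelse(runif(n) < 0.5, high, low)
  out_p <- ifelse(runif(n) < 0.5, high, low)
  data.frame(
    trial_index = seq_len(n), is_social = soc,
    CR = ifelse(gam, 0, round(runif(n, -0.5, 0.5), 2)),
    EV = ifelse(gam, ev, 0),
    RPE = ifelse(gam, out_s - ev, 0),
    R = out_s, O = ifelse(soc, out_p, NA_real_))
}

# O(n^2) reference implementation of the decayed-regressor design matrix.
naive_design_matrix <- function(events, positions, gamma, model) {
  soc <- events$is_social & !is.na(events$O)
  d <- ifelse(soc, events$R - events$O, 0)
  vals <- list(CR = events$CR, EV = events$EV, RPE = events$RPE,
               inequality = abs(d), guilt = pmax(d, 0), envy = pmax(-d, 0))
  X <- matrix(0, length(positions), length(model$terms),
              dimnames = list(NULL, model$terms))
  for (r in seq_along(positions)) {
    t <- positions[r]
    if (t == 0L) next
    for (k in seq_along(model$terms)) {
      v <- vals[[model$terms[k]]]
      X[r, k] <- sum(gamma^(t - seq_len(t)) * v[seq_len(t)])
    }
  }
  X
}

# Simulated subject on the model scale: events, positions, ratings, truth.
synthetic_subject <- function(seed, n = 60, noise_sd = 0,
                              truth = list(CR = 0.8, EV = 0.6, RPE = 1.1,
                                           guilt = -0.5, envy = -0.35,
                                           gamma = 0.6)) {
  events <- random_events(n, seed)
  positions <- seq(3, n, by = 3)
  y <- predict_ratings(truth, events, positions, model_spec("guilt_envy"))
  if (noise_sd > 0) {
    set.seed(seed + 1)
    y <- y + rnorm(length(y), 0, noise_sd)
  }
  list(events = events, positions = positions, ratings = y, truth = truth)
}
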