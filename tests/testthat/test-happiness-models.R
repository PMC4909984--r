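test_that("derive_events zeroes terms for unchosen options", {
  tr <- data.frame(trial_type = c("Gain", "Gain", "Mixed"),
                   is_social = c(FALSE, TRUE, TRUE),
                   safe_amount = c(0.40, 0.40, 0),
                   gamble_high = c(0.95, 0.95, 0.95),
                   gamble_low = c(0, 0, -0.45),
                   gamble_prob = 0.5)
  sch <- tiny_schedule(tr)
  out <- data.frame(trial_index = 1:3, is_social = tr$is_social,
                    chooser = c("subject", "partner", "partner"),
                    choice = c("safe", "gamble", "safe"),
                    outcome_subject = c(0.40, 0.95, 0),
                    outcome_partner = c(NA, 0, 0))
  ev <- derive_events(out, sch)
  # safe chosen: CR = safe, EV = RPE = 0
  expect_equal(unlist(ev[1, c("CR", "EV", "RPE")]),
               c(CR = 0.40, EV = 0, RPE = 0))
  # gamble {0.95, 0} won: EV = 0.475, RPE = +0.475
  expect_equal(unlist(ev[2, c("CR", "EV", "RPE")]),
               c(CR = 0, EV = 0.475, RPE = 0.475))
  expect_equal(ev$R[2], 0.95)
  expect_equal(ev$O[2], 0)
  # misaligned inputs
  expect_error(derive_events(out[1:2, ], sch), class = "mswb_alignment_error")
})

test_that("social safe trials carry zero inequality", {
  tr <- data.frame(trial_type = "Gain", is_social = TRUE, safe_amount = 0.40,
                   gamble_high = 0.60, gamble_low = 0, gamble_prob = 0.5)
  sch <- tiny_schedule(tr)
  out <- simulate_session(sch, partner_params = pt_params(100, 0.9), seed = 1)
  ev <- derive_events(out, sch)
  X <- build_design_matrix(ev, 1L, 0.5, model_spec("guilt_envy"))
  expect_equal(unname(X[, "guilt"]), 0)
  expect_equal(unname(X[, "envy"]), 0)
})

test_that("decayed_sum implements geometric forgetting", {
  v <- c(1, 2, 3, 4)
  expect_equal(decayed_sum(v, 1, 4), sum(v))        # no forgetting
  expect_equal(decayed_sum(v, 0, 4), 4)             # total forgetting, 0^0 = 1
  expect_equal(decayed_sum(c(1, 1), 0.5, 2), 1.5)
  expect_equal(decayed_sum(v, 0.5, 3), 3 + 0.5 * 2 + 0.25 * 1)
  expect_equal(decayed_sum(v, 0.7, 0), 0)           # rating before any trial
  expect_error(decayed_sum(v, 1.2, 2), class = "mswb_param_error")
  expect_error(decayed_sum(v, -0.1, 2), class = "mswb_param_error")
})

test_that("design matrix matches the naive double-loop oracle", {
  for (seed in 1:20) {
    ev <- random_events(12, seed)
    pos <- sort(sample(0:12, 5))
    gamma <- runif(1)
    for (m in all_models()) {
      expect_equal(build_design_matrix(ev, pos, gamma, m),
                   naive_design_matrix(ev, pos, gamma, m),
                   tolerance = 1e-10)
    }
  }
})

test_that("design matrix handles edge cases", {
  ev <- random_events(6, 1)
  m <- model_spec("guilt_envy")
  # no ratings -> empty matrix with model columns
  X0 <- build_design_matrix(ev, integer(0), 0.5, m)
  expect_equal(dim(X0), c(0L, 5L))
  # all-zero events -> all-zero matrix
  ev0 <- ev
  ev0[c("CR", "EV", "RPE")] <- 0
  ev0$R <- ev0$O <- 0
  expect_true(all(build_design_matrix(ev0, 1:6, 0.8, m) == 0))
  # single trial, rating straight after: row equals raw term values (gamma^0)
  ev1 <- random_events(1, 3)
  X1 <- build_design_matrix(ev1, 1L, 0.3, m)
  d <- ev1$R - ev1$O
  expect_equal(unname(X1[1, ]),
               c(ev1$CR, ev1$EV, ev1$RPE, max(d, 0), max(-d, 0)))
})

test_that("guilt/envy terms decompose the inequality terms", {
  ev <- random_events(40, 9)
  ge <- build_design_matrix(ev, 1:40, 0.6, model_spec("guilt_envy"))
  si <- build_design_matrix(ev, 1:40, 0.6, model_spec("simple_inequality"))
  expect_equal(ge[, "guilt"] + ge[, "envy"], si[, "inequality"])
  soc <- ev$is_social & !is.na(ev$O)
  d <- ifelse(soc, ev$R - ev$O, 0)
  expect_equal(pmax(d, 0) - pmax(-d, 0), d)
  expect_equal(pmax(d, 0) + pmax(-d, 0), abs(d))
})

test_that("predictions are linear in weights and nest the non-social model", {
  subj <- synthetic_subject(5)
  expect_equal(predict_ratings(list(CR = 0, EV = 0, RPE = 0, guilt = 0,
                                    envy = 0, gamma = 0.5),
                               subj$events, subj$positions),
               rep(0, length(subj$positions)))
  # zero social weights: guilt-envy collapses onto the non-social model
  p <- list(CR = 0.8, EV = 0.6, RPE = 1.1, guilt = 0, envy = 0, gamma = 0.6)
  expect_equal(predict_ratings(p, subj$events, subj$positions,
                               model_spec("guilt_envy")),
               predict_ratings(p, subj$events, subj$positions,
                               model_spec("nonsocial")))
  # sign propagation: only a negative guilt weight, advantageous event
  ev <- data.frame(trial_index = 1L, is_social = TRUE, CR = 0, EV = 0.5,
                   RPE = 0.5, R = 1, O = 0)
  pr <- predict_ratings(list(CR = 0, EV = 0, RPE = 0, guilt = -0.5, envy = 0,
                             gamma = 0.5), ev, 1L)
  expect_lt(pr, 0)
  expect_error(predict_ratings(list(CR = 1, gamma = 0.5), ev, 1L),
               class = "mswb_param_error")
})

test_that("generative round-trip: noiseless ratings are reproduced exactly", {
  subj <- synthetic_subject(11)
  again <- predict_ratings(subj$truth, subj$events, subj$positions,
                           model_spec("guilt_envy"))
  expect_identical(again, subj$ratings)
})
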