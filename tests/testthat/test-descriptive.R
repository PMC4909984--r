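# Hand-built social session: all trials are partner-chosen gambles over
# {+1, -1} so win/lose contexts are fully controlled.
context_fixture <- function(sub_out, part_out, positions, ratings) {
  n <- length(sub_out)
  tr <- data.frame(trial_type = "Mixed", is_social = TRUE, safe_amount = 0,
                   gamble_high = 1, gamble_low = -1, gamble_prob = 0.5)
  tr <- tr[rep(1, n), ]
  sch <- tiny_schedule(tr)
  out <- data.frame(trial_index = seq_len(n), is_social = TRUE,
                    chooser = "partner", choice = "gamble",
                    outcome_subject = sub_out, outcome_partner = part_out)
  context_means(ratings, positions, out, sch)
}

test_that("context means pick the next rating for each outcome context", {
  cm <- context_fixture(sub_out = c(1, -1), part_out = c(1, -1),
                        positions = c(1, 2), ratings = c(1, -1))
  expect_equal(cm$means[["both_win"]], 1)
  expect_equal(cm$means[["both_lose"]], -1)
  expect_true(is.na(cm$means[["subject_win_partner_lose"]]))
  expect_equal(unname(cm$counts),
               c(1L, 1L, 0L, 0L))
})

test_that("one rating serves every qualifying trial since the last rating", {
  cm <- context_fixture(sub_out = c(1, -1), part_out = c(-1, 1),
                        positions = 2, ratings = 0.3)
  expect_equal(cm$means[["subject_win_partner_lose"]], 0.3)
  expect_equal(cm$means[["subject_lose_partner_win"]], 0.3)
  # trials after the final rating contribute nothing
  cm2 <- context_fixture(sub_out = c(1, 1), part_out = c(1, -1),
                         positions = 1, ratings = 0.5)
  expect_equal(unname(cm2$counts), c(1L, 0L, 0L, 0L))
})

test_that("ratings preceded only by non-social trials join no context", {
  s <- make_session_schedule("nonsocial", seed = 2)
  out <- simulate_session(s, seed = 2)
  cm <- context_means(rnorm(15), rating_positions(s), out, s)
  expect_true(all(cm$counts == 0L))
  expect_true(all(is.na(cm$means)))
})

test_that("guilt and envy measures are the documented contrasts", {
  cm <- list(means = c(both_win = 0.5, both_lose = -0.5,
                       subject_win_partner_lose = 0.2,
                       subject_lose_partner_win = -0.9))
  ge <- guilt_envy_measures(cm)
  expect_equal(ge$guilt, -0.3)
  expect_equal(ge$envy, -0.4)
  expect_equal(ge$difference, 0.1)
  # equal means in all contexts: no inequality reactivity
  ge0 <- guilt_envy_measures(list(means = c(both_win = 0.2, both_lose = 0.2,
                                            subject_win_partner_lose = 0.2,
                                            subject_lose_partner_win = 0.2)))
  expect_equal(ge0$guilt, 0)
  expect_equal(ge0$envy, 0)
  # happier when partner loses than wins => positive difference
  ge1 <- guilt_envy_measures(list(means = c(both_win = 0, both_lose = 0,
                                            subject_win_partner_lose = 0.4,
                                            subject_lose_partner_win = -0.4)))
  expect_gt(ge1$difference, 0)
})

test_that("rank statistics behave as rank statistics", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_cor(x, x^3)$rho, 1)        # monotone invariance
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  expect_true(spearman_cor(x, rep(2, 5))$degenerate)
  # signed-rank statistic equals the brute-force sum of positive ranks
  d <- c(0.8, -0.4, 1.2, -0.1, 0.3, -2.0, 0.6)
  manual <- sum(rank(abs(d))[d > 0])
  expect_equal(wilcoxon_signed_rank(d)$statistic, manual)
  expect_error(wilcoxon_signed_rank(rep(0, 5)), class = "mswb_degenerate_error")
  # rank-sum z sign follows the first sample
  rs <- wilcoxon_rank_sum(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_gt(rs$z, 0)
  expect_lt(rs$p.value, 0.05)
})

test_that("signed-rank p-value agrees with exact enumeration at small n", {
  d <- c(0.8, -0.4, 1.2, -0.1, 0.3, -2.0, 0.6, 1.5)
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  # enumerate all 2^n sign assignments for the exact two-sided null
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  ev <- n * (n + 1) / 4
  p_exact <- mean(abs(v_all - ev) >= abs(v_obs - ev))
  p_pkg <- wilcoxon_signed_rank(d)$p.value
  expect_equal(p_pkg, p_exact, tolerance = 0.05)  # normal approx vs exact
})

test_that("generosity linkage recovers the built-in association", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 24,
                                          include_nonsocial_task = FALSE),
                            seed = 5)
  d <- cohort_descriptives(cohort)
  link <- generosity_linkage(d)
  expect_lt(link$descriptive$spearman$rho, 0)
  # identical generosity across subjects: flagged degenerate, not an error
  d2 <- d
  d2$generosity <- 20
  expect_true(generosity_linkage(d2)$descriptive$spearman$degenerate)
})

test_that("parameter-based linkage reports subgroup tests", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 24,
                                          include_nonsocial_task = FALSE),
                            seed = 6)
  d <- cohort_descriptives(cohort)
  fits <- fit_cohort(cohort, all_models()["guilt_envy"], "model")
  link <- generosity_linkage(d, fits)
  expect_lt(link$parameter$spearman$rho, 0)
  expect_true(length(link$parameter$subgroup) >= 1)
})
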