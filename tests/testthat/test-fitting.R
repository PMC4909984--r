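test_that("z-scoring follows the sample-sd convention", {
  expect_equal(zscore_ratings(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- runif(30, 0, 100)
  z <- zscore_ratings(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(zscore_ratings(z), z)  # idempotent
  expect_error(zscore_ratings(rep(5, 10)), class = "mswb_degenerate_error")
  expect_error(zscore_ratings(3), class = "mswb_degenerate_error")
})

test_that("BIC has the Gaussian least-squares form", {
  expect_equal(bic(61, 61, 6), 6 * log(61))     # rss/n = 1 kills the fit term
  expect_equal(bic(61, 61, 6), 24.666, tolerance = 1e-4)
  expect_equal(bic(10, 20, 4), 20 * log(10 / 20) + 4 * log(20))
  # monotone penalty in k at fixed rss
  expect_true(all(diff(vapply(3:8, function(k) bic(10, 20, k), 0)) > 0))
  expect_warning(b0 <- bic(0, 20, 4), "degenerate")
  expect_identical(b0, -Inf)
})

test_that("noiseless subjects are recovered exactly by the profile fit", {
  subj <- synthetic_subject(21)
  f <- fit_subject(subj$ratings, subj$events, subj$positions,
                   model_spec("guilt_envy"))
  expect_equal(unlist(f$params[names(subj$truth)]), unlist(subj$truth),
               tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_false(f$gamma_boundary)
})

test_that("profile fit matches an independent joint optimiser", {
  for (seed in c(2, 8)) {
    subj <- synthetic_subject(seed, n = 36, noise_sd = 0.4)
    m <- model_spec("nonsocial")
    f <- fit_subject(subj$ratings, subj$events, subj$positions, m)
    # oracle 1: dense gamma grid, step 1e-3
    rss_at <- function(g) {
      X <- build_design_matrix(subj$events, subj$positions, g, m)
      sum(stats::lm.fit(X, subj$ratings)$residuals^2)
    }
    dense <- min(vapply(seq(0, 1, by = 1e-3), rss_at, 0))
    expect_lte(f$rss, dense + 1e-8)
    # oracle 2: joint L-BFGS-B over (weights, gamma), multi-start
    obj <- function(p) {
      X <- build_design_matrix(subj$events, subj$positions, p[4], m)
      sum((subj$ratings - X %*% p[1:3])^2)
    }
    joint <- min(vapply(list(c(0, 0, 0, 0.3), c(1, 1, 1, 0.6), c(0.5, 0.5, 1, 0.9)),
                        function(st)
                          stats::optim(st, obj, method = "L-BFGS-B",
                                       lower = c(-5, -5, -5, 0),
                                       upper = c(5, 5, 5, 1))$value, 0))
    expect_lte(f$rss, joint + 1e-6)
  }
})

test_that("underdetermined and misaligned fits are rejected", {
  subj <- synthetic_subject(3, n = 12)
  short <- seq(3, 12, by = 3)  # 4 ratings < 6 parameters
  y <- predict_ratings(subj$truth, subj$events, short)
  expect_error(fit_subject(y, subj$events, short, model_spec("guilt_envy")),
               class = "mswb_underdetermined_error")
  expect_error(fit_subject(subj$ratings[-1], subj$events, subj$positions),
               class = "mswb_alignment_error")
})

test_that("multi-session fits reset decay at session boundaries", {
  a <- synthetic_subject(31, n = 45)
  b <- synthetic_subject(32, n = 45)
  y <- c(a$ratings, b$ratings)  # same truth generated both sessions
  f <- fit_subject(y, list(a$events, b$events),
                   list(a$positions, b$positions), model_spec("guilt_envy"))
  expect_equal(unlist(f$params[names(a$truth)]), unlist(a$truth),
               tolerance = 1e-6)
  expect_equal(f$n_ratings, length(y))
})

test_that("fitted models respect nesting (rss ordering)", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 4,
                                          include_nonsocial_task = FALSE),
                            seed = 17)
  fits <- fit_cohort(cohort, ratings_scale = "raw")
  w <- reshape(fits[, c("subject_id", "model", "rss")],
               direction = "wide", idvar = "subject_id", timevar = "model")
  expect_true(all(w$rss.guilt_envy <= w$rss.simple_inequality + 1e-8))
  expect_true(all(w$rss.simple_inequality <= w$rss.nonsocial + 1e-8))
  # gamma estimates never leave [0, 1]
  expect_true(all(fits$gamma >= 0 & fits$gamma <= 1))
})

test_that("model comparison table identifies the winner", {
  fits <- data.frame(subject_id = rep(c("S1", "S2"), each = 3),
                     model = c("nonsocial", "simple_inequality", "guilt_envy"),
                     r2 = c(0.3, 0.35, 0.4, 0.2, 0.3, 0.32),
                     bic = c(-10, -12, -15, -8, -9, -11))
  tab <- compare_models(fits)
  expect_equal(tab$bic_rel[tab$model == "guilt_envy"], 0)
  expect_true(all(tab$bic_rel[tab$model != "guilt_envy"] > 0))
  expect_equal(sum(tab$bic_rel == 0), 1L)
  expect_error(compare_models(fits[-1, ]), class = "mswb_completeness_error")
})
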