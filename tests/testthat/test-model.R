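make_panel <- function(n_id = 12, n_day = 8, seed = 1, sd_id = 2,
                       beta_w = 0, beta_b = 0) {
  set.seed(seed)
  id <- rep(sprintf("P%02d", seq_len(n_id)), each = n_day)
  mu <- rep(rnorm(n_id, 2, 1), each = n_day)
  pain <- pmax(0, pmin(10, mu + rnorm(n_id * n_day)))
  u <- rep(rnorm(n_id, 0, sd_id), each = n_day)
  pm <- ave(pain, id)
  y <- 10 + u + beta_b * (pm - mean(tapply(pain, id, mean))) +
    beta_w * (pain - pm) + rnorm(n_id * n_day)
  tibble::tibble(participant_id = id, mean_pain = pain, excursion_size = y,
                 age = rep(round(rnorm(n_id, 73, 5)), each = n_day),
                 female = rep(rbinom(n_id, 1, 0.7), each = n_day),
                 lives_alone = rep(rbinom(n_id, 1, 0.3), each = n_day))
}

test_that("centering reproduces the worked two-person example", {
  cen <- center_within_between(c(1, 2, 3, 3, 4, 5), rep(c("a", "b"), each = 3))
  expect_equal(attr(cen, "grand_mean"), 3)
  expect_equal(cen$between, rep(c(-1, 1), each = 3))
  expect_equal(cen$within, rep(c(-1, 0, 1), times = 2))
})

test_that("centering identities hold on random panels", {
  set.seed(31)
  for (r in 1:20) {
    n_id <- sample(3:10, 1)
    id <- rep(seq_len(n_id), times = sample(2:9, n_id, replace = TRUE))
    x <- runif(length(id), 0, 10)
    cen <- center_within_between(x, id)
    # within-person means are zero
    expect_true(all(abs(tapply(cen$within, id, mean)) < 1e-10))
    # between constant within person
    expect_true(all(tapply(cen$between, id, function(v) max(v) - min(v)) == 0))
    # reconstruction identity
    expect_true(all(abs(attr(cen, "grand_mean") + cen$between + cen$within - x)
                    < 1e-10))
  }
})

test_that("constant pain within persons gives zero within components", {
  cen <- center_within_between(rep(c(2, 5), each = 4), rep(c("a", "b"), each = 4))
  expect_equal(cen$within, rep(0, 8))
})

test_that("grand-mean conventions differ only under unbalanced panels", {
  x <- c(1, 1, 1, 5)
  id <- c("a", "a", "a", "b")
  p <- center_within_between(x, id, grand = "person")
  q <- center_within_between(x, id, grand = "pooled")
  expect_equal(attr(p, "grand_mean"), 3)
  expect_equal(attr(q, "grand_mean"), 2)
})

test_that("single-participant panels are rejected", {
  expect_error(center_within_between(1:5, rep("a", 5)), "at least 2")
  panel <- make_panel(n_id = 1, n_day = 20)
  expect_error(fit_feature_model(panel, "excursion_size"), "at least 2")
})

test_that("the mixed model recovers strong within effects with correct sign", {
  panel <- make_panel(n_id = 30, n_day = 12, seed = 5, beta_w = -3, beta_b = -1)
  fit <- fit_feature_model(panel, "excursion_size")
  cw <- fit$coefficients[fit$coefficients$term == "pain_within", ]
  expect_lt(cw$estimate, 0)
  expect_equal(cw$estimate, -3, tolerance = 0.15)
  # normal-reference inference invariants
  expect_equal(cw$conf.low, cw$estimate - 1.96 * cw$se)
  expect_equal(cw$conf.high, cw$estimate + 1.96 * cw$se)
  expect_equal(cw$p, 2 * pnorm(-abs(cw$estimate / cw$se)))
  expect_equal(fit$n_obs, 360)
  expect_true(fit$converged)
})

test_that("adding a constant to the outcome moves only the intercept", {
  panel <- make_panel(n_id = 15, n_day = 6, seed = 9, beta_w = -2)
  f1 <- fit_feature_model(panel, "excursion_size")
  panel2 <- panel
  panel2$excursion_size <- panel2$excursion_size + 57
  f2 <- fit_feature_model(panel2, "excursion_size")
  c1 <- f1$coefficients
  c2 <- f2$coefficients
  for (term in c("pain_within", "pain_between", "age", "female")) {
    expect_equal(c1$estimate[c1$term == term], c2$estimate[c2$term == term],
                 tolerance = 1e-8)
  }
  expect_equal(c2$estimate[c2$term == "(Intercept)"],
               c1$estimate[c1$term == "(Intercept)"] + 57, tolerance = 1e-6)
})

test_that("with no between-person variance the fit collapses to OLS", {
  panel <- make_panel(n_id = 40, n_day = 6, seed = 14, sd_id = 0, beta_w = -2)
  fit <- fit_feature_model(panel, "excursion_size", reml = FALSE)
  expect_true(fit$singular)
  cen <- center_within_between(panel$mean_pain, panel$participant_id)
  ols <- lm(panel$excursion_size ~ cen$within + cen$between + panel$age +
              panel$female + panel$lives_alone)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "pain_within"],
               unname(coef(ols)[["cen$within"]]), tolerance = 1e-6)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "pain_between"],
               unname(coef(ols)[["cen$between"]]), tolerance = 1e-6)
})

test_that("fit_all_features mirrors the ten-feature report layout", {
  pool <- get_day_pool()
  feats <- get_pool_features()
  pd <- aggregate_daily_pain(pool$cohort$prompts)
  panel <- build_panel(feats, pd, pool$cohort$demographics)
  res <- fit_all_features(panel)
  expect_equal(unique(res$feature), lifespace_feature_names())
  expect_equal(nrow(res), 20)
  expect_equal(res$effect, rep(c("between", "within"), 10))
  expect_true(all(is.na(res$error)))
  # deterministic given a fixed panel
  res2 <- fit_all_features(panel)
  expect_equal(res$estimate, res2$estimate)
  # report renders one block per feature
  lines <- format_results_table(res)
  expect_length(lines, 1 + 30)
})
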