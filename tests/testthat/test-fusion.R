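test_that("tool log factors realize the score-indicator marginalization", {
  m <- reference_model()
  # missing score: only the non-reporting term survives
  expect_equal(tool_log_factor(m, 1, NA, y = 1), log(0.5918),
               tolerance = 1e-12)
  expect_equal(tool_log_factor(m, 1, NA, y = 0), log(0.9123),
               tolerance = 1e-12)
  # present score: density times reporting rate
  x <- -0.4
  expect_equal(tool_log_factor(m, 1, x, y = 1),
               log(dcond(m$tools[[1]]$pos, x)) + log(0.4082),
               tolerance = 1e-12)
  # unit density and unit rate give a zero log factor
  flat <- fusion_model(0.5, list(list(
    name = "t", tpr = 1, fpr = 0.5,
    pos = mirfuse:::new_cond_density("exponential_shifted", list(rate = 1),
                                     transform = list(shift = 0)),
    neg = mirfuse:::new_cond_density("gaussian", list(mean = 0, sd = 1)))))
  expect_equal(tool_log_factor(flat, 1, 0, y = 1),
               log(1) + log(1 - flat$rate_floor), tolerance = 1e-9)
})

test_that("log-space posterior matches direct Bayes rule on random models", {
  set.seed(42)
  for (i in 1:200) {
    model <- random_model()
    scores <- random_record(model)
    got <- posterior_detail(model, scores)
    want <- oracle_posterior(model, scores)
    expect_equal(got$posterior, want, tolerance = 1e-10)
    # normalization and the expit identity
    lo <- log(model$prior) - log1p(-model$prior) +
      got$loglik_pos - got$loglik_neg
    expect_equal(got$posterior, 1 / (1 + exp(-lo)), tolerance = 1e-12)
  }
})

test_that("posterior is symmetric under identical classes and prior 1/2", {
  pos <- mirfuse:::new_cond_density("gaussian", list(mean = 1, sd = 2))
  tools <- lapply(1:4, function(j) {
    list(name = paste0("t", j), pos = pos, neg = pos, tpr = 0.3, fpr = 0.3)
  })
  m <- fusion_model(0.5, tools)
  for (scores in list(rep(NA_real_, 4), c(0, NA, 2, -1), rnorm(4))) {
    expect_equal(posterior_detail(m, scores)$posterior, 0.5,
                 tolerance = 1e-12)
  }
})

test_that("posterior approaches the prior limits", {
  set.seed(19)
  m1 <- random_model(4)
  # all-missing record: the likelihood ratio is bounded by the rate ratios
  # (at most (0.95/0.05)^4 here), so a vanishing prior forces the limit
  scores <- rep(NA_real_, 4)
  p_lo <- posterior_detail(fusion_model(1e-12, m1$tools), scores)$posterior
  p_hi <- posterior_detail(fusion_model(1 - 1e-12, m1$tools),
                           scores)$posterior
  expect_lt(p_lo, 1e-4)
  expect_gt(p_hi, 1 - 1e-4)
})

test_that("an uninformative tool leaves every posterior unchanged", {
  set.seed(24)
  base <- random_model(3)
  flatdens <- mirfuse:::new_cond_density("gaussian", list(mean = 0, sd = 1))
  extended <- fusion_model(base$prior, c(base$tools, list(
    list(name = "flat", pos = flatdens, neg = flatdens,
         tpr = 0.4, fpr = 0.4))))
  for (i in 1:20) {
    scores <- random_record(base)
    x4 <- if (runif(1) < 0.5) NA_real_ else rnorm(1)
    expect_equal(posterior_detail(extended, c(scores, x4))$posterior,
                 posterior_detail(base, scores)$posterior,
                 tolerance = 1e-12)
  }
})

test_that("batch prediction equals looped single-record posteriors", {
  model <- reference_model()
  tab <- generate_score_table(model, n = 500, seed = 9)
  batch <- predict(model, tab)
  m <- score_matrix(tab)
  looped <- vapply(seq_len(nrow(m)), function(i) {
    posterior_detail(model, m[i, ])$posterior
  }, numeric(1))
  expect_equal(batch, looped, tolerance = 1e-12)
  # determinism: identical records give identical posteriors
  expect_equal(predict(model, tab), batch, tolerance = 0)
})

test_that("prediction rejects mismatched tool sets", {
  model <- reference_model()
  tab <- toy_table()  # 3 tools only: strict subset must be rejected
  expect_error(predict(model, tab), "do not match")
  expect_error(posterior_detail(model, c(NA, NA, NA)), "per model tool")
})

test_that("degenerate reporting rates are clamped, never -Inf", {
  dens <- mirfuse:::new_cond_density("gaussian", list(mean = 0, sd = 1))
  m <- fusion_model(0.2, list(list(name = "t", pos = dens, neg = dens,
                                   tpr = 1, fpr = 0)))
  d <- posterior_detail(m, NA_real_)
  expect_true(is.finite(d$loglik_pos) && is.finite(d$loglik_neg))
  expect_true(d$posterior >= 0 && d$posterior <= 1)
})

test_that("model serialization round-trips through YAML", {
  set.seed(77)
  model <- random_model(4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$prior, model$prior, tolerance = 1e-12)
  for (i in 1:30) {
    scores <- random_record(model)
    expect_equal(posterior_detail(back, scores)$posterior,
                 posterior_detail(model, scores)$posterior,
                 tolerance = 1e-10)
  }
})
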