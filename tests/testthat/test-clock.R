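test_that("mappable-probe subsetting uses intersection semantics", {
  beta <- tiny_beta(matrix(0.5, 3, 4))
  ann <- tiny_annotation(rownames(beta),
                         mappable = list("opossum", "mouse",
                                         c("opossum", "mouse")))
  expect_equal(rownames(subset_mappable_probes(beta, ann,
                                               c("opossum", "mouse"))),
               "cg003")
  expect_equal(nrow(subset_mappable_probes(beta, ann, "opossum")), 2L)
  expect_error(subset_mappable_probes(beta, ann, c("human", "opossum")),
               "no probes mappable")
})

test_that("a clock recovers a constructed exact-signal probe", {
  set.seed(21)
  n <- 60
  ss <- tiny_samples(n, ages = runif(n, 0, 4.2))
  beta <- matrix(runif(100 * n), 100, n)
  beta[1, ] <- 0.1 + 0.8 * ss$age_years / 4.2  # exact affine image of age
  beta <- tiny_beta(beta, samples = ss$sample_id)
  fit <- fit_clock(beta, ss, age_transform("identity"), seed = 1)
  expect_true("cg001" %in% names(fit$coefficients))
  expect_gt(abs(fit$coefficients["cg001"]), max(0.5 * abs(fit$coefficients)))
  pred <- predict_age(fit, beta, ss)
  expect_gt(cor(pred, ss$age_years), 0.99)
  # unpenalized least-squares oracle on the selected support does no worse
  dat <- data.frame(y = ss$age_years, t(beta[names(fit$coefficients), ,
                                             drop = FALSE]))
  ols <- lm(y ~ ., dat)
  expect_gt(cor(fitted(ols), ss$age_years), 0.99)
})

test_that("fitting is deterministic under a fixed seed", {
  ds <- default_sim(seed = 22, n_probes = 300)
  f1 <- fit_clock(ds$beta, ds$samples, seed = 5)
  f2 <- fit_clock(ds$beta, ds$samples, seed = 5)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$lambda, f2$lambda)
})

test_that("prediction is affine in betas and inverse-transformed per sample", {
  ss <- tiny_samples(2, ages = c(1, 2))
  beta <- tiny_beta(matrix(c(0.25, 0.75), 1, 2), probes = "cg001",
                    samples = ss$sample_id)
  model <- structure(list(intercept = 1, coefficients = c(cg001 = 2),
                          transform = age_transform("identity"), alpha = 0.5,
                          lambda = 0.1, training = list()),
                     class = "clock_model")
  expect_equal(as.numeric(predict_age(model, beta, ss)), c(1.5, 2.5))
  # zero-coefficient model predicts the inverse-transformed intercept
  model0 <- model
  model0$coefficients <- c(cg001 = 0)
  model0$transform <- age_transform("relative")
  expect_equal(as.numeric(predict_age(model0, beta, ss)), c(4.2, 4.2))
})

test_that("predictions are invariant to probe and sample order", {
  ds <- default_sim(seed = 23, n_probes = 300)
  fit <- fit_clock(ds$beta, ds$samples, seed = 2)
  p1 <- predict_age(fit, ds$beta, ds$samples)
  set.seed(1)
  rp <- sample(nrow(ds$beta)); cp <- sample(ncol(ds$beta))
  p2 <- predict_age(fit, ds$beta[rp, cp], ds$samples)
  expect_equal(as.numeric(p1[names(p2)]), as.numeric(p2), tolerance = 1e-12)
})

test_that("evaluation reports Pearson r and median absolute error", {
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$median_abs_error, 0)
  ev <- evaluate_predictions(c(1, 2, 3) + 0.5, c(1, 2, 3))
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$median_abs_error, 0.5)
  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev$pearson_r, 0.9819805, tolerance = 1e-6)
  # degenerate predictor flagged, never an exception
  ev <- evaluate_predictions(c(1, 1, 1), c(1, 2, 4))
  expect_equal(ev$pearson_r, 0)
  expect_true(ev$degenerate)
  expect_error(evaluate_predictions(1, 1), "fewer than 2")
})

test_that("LOOCV recovers a strong synthetic age signal", {
  ds <- default_sim(seed = 24, n_probes = 500)
  loo <- loocv_evaluate(ds$beta, ds$samples, seed = 3)
  expect_gt(loo$evaluation$pearson_r, 0.9)
  # summary equals recomputation from the per-sample predictions
  ev <- evaluate_predictions(loo$predictions$predicted,
                             loo$predictions$actual)
  expect_equal(ev$pearson_r, loo$evaluation$pearson_r)
})

test_that("dual-species fit reduces to fit_clock in degenerate settings", {
  ds <- default_sim(seed = 25, n_probes = 200)
  ann <- ds$annotation
  single <- fit_dual_species_clock(list(list(beta = ds$beta,
                                             samples = ds$samples)),
                                   ann, mode = "relative", seed = 4)
  direct <- fit_clock(ds$beta, ds$samples, age_transform("relative"),
                      seed = 4)
  expect_identical(single$coefficients, direct$coefficients)

  # chronological mode on pooled identical-constants data equals a pooled
  # loglinear fit
  half <- seq_len(ncol(ds$beta) / 2)
  ds$samples$maturity_years <- 1
  datasets <- list(list(beta = ds$beta[, half], samples = ds$samples[half, ]),
                   list(beta = ds$beta[, -half], samples = ds$samples[-half, ]))
  dual <- fit_dual_species_clock(datasets, ann, mode = "chronological",
                                 k = 1, seed = 4)
  pooled <- fit_clock(ds$beta, ds$samples, age_transform("loglinear", k = 1),
                      seed = 4)
  expect_identical(dual$coefficients, pooled$coefficients)
})

test_that("clock models serialize to JSON and back", {
  ds <- default_sim(seed = 26, n_probes = 200)
  fit <- fit_clock(ds$beta, ds$samples, age_transform("loglinear", k = 2),
                   seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_model(fit, path)
  back <- read_clock_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$transform$kind, "loglinear")
  expect_equal(back$transform$k, 2)
  p1 <- predict_age(fit, ds$beta, ds$samples)
  p2 <- predict_age(back, ds$beta, ds$samples)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("missing betas follow the drop/flag policy", {
  ds <- default_sim(seed = 27, n_probes = 200)
  beta <- ds$beta
  beta[3, 5] <- NA
  expect_message(fit <- fit_clock(beta, ds$samples, seed = 1),
                 "1 probe")
  expect_false("cg000003" %in% fit$training$probe_universe)
  # prediction-time missing model probe value flags the sample
  fit2 <- fit_clock(ds$beta, ds$samples, seed = 1)
  beta2 <- ds$beta
  beta2[names(fit2$coefficients)[1], 2] <- NA
  pr <- predict_age(fit2, beta2, ds$samples)
  expect_true(is.na(pr[2]))
  expect_false(anyNA(pr[-2]))
})
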