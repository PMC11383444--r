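test_that("splits hit the 70/10/20 proportions and are reproducible", {
  ids <- sprintf("s%03d", 1:100)
  sp <- make_splits(ids, seed = 5)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 70, val = 10, test = 20))
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), sort(ids))
  expect_identical(make_splits(ids, seed = 5), sp)
  expect_false(identical(make_splits(ids, seed = 6), sp))
  expect_error(make_splits(ids[1:5]), "at least 10")
})

test_that("classification splits are stratified by label", {
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(c(1L, 2L), c(80, 20))   # 20% positives
  sp <- make_splits(ids, seed = 7, labels = labels)
  for (part in c("train", "val", "test")) {
    rate <- mean(labels[match(sp[[part]], ids)] == 2L)
    n_part <- length(sp[[part]])
    expect_lt(abs(rate - 0.2), 1 / n_part + 1e-9)
  }
})

test_that("evaluation metrics match closed forms", {
  y <- matrix(c(1, 2, 3, 4), 4)
  expect_equal(maskgnn:::compute_metrics(y, y, "regression"),
               list(rmse = 0, mae = 0, rmse_per_target = 0, mae_per_target = 0))
  # constant predictor: RMSE is the root mean squared deviation from c
  cpred <- matrix(2.5, 4, 1)
  m <- maskgnn:::compute_metrics(cpred, y, "regression")
  expect_equal(m$rmse, sqrt(mean((y - 2.5)^2)))
  expect_equal(m$mae, mean(abs(y - 2.5)))
  expect_gte(m$rmse, m$mae)

  # classification: perfect and anti-ranked scores
  labels <- matrix(c(1L, 1L, 2L, 2L), 4)
  logits <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  mc <- maskgnn:::compute_metrics(logits, labels, "classification")
  expect_equal(mc, list(accuracy = 1, f1 = 1, auc = 1))
  mc2 <- maskgnn:::compute_metrics(logits[4:1, ], labels, "classification")
  expect_equal(mc2$auc, 0)
  expect_error(maskgnn:::compute_metrics(matrix(0, 0, 1), matrix(0, 0, 1),
                                         "regression"), "empty")
})

test_that("RMSE is never below MAE on random evaluations", {
  set.seed(50)
  for (i in 1:20) {
    pred <- matrix(rnorm(30), 30)
    y <- matrix(rnorm(30), 30)
    m <- maskgnn:::compute_metrics(pred, y, "regression")
    expect_gte(m$rmse, m$mae)
  }
})

test_that("training descends, beats the constant predictor, and reproduces", {
  co <- small_cohort()
  fit <- small_fit()
  h <- fit$history
  expect_lt(h$train_e[nrow(h)], h$train_e[1])

  # validation RMSE below the best constant predictor's RMSE
  y_all <- sapply(co$subjects, `[[`, "y")
  expect_lt(fit$metrics$rmse, sd(y_all))

  # mask stays symmetric and inside (0,1) after training
  expect_equal(fit$mask, t(fit$mask))
  expect_true(all(fit$mask > 0 & fit$mask < 1))

  # identical config + seed reproduces the metrics exactly
  fit2 <- maskgnn(co, small_config())
  expect_identical(fit2$metrics, fit$metrics)
  expect_identical(fit2$mask, fit$mask)
})

test_that("with all regularizers off the objective reduces to the error term", {
  co <- small_cohort()
  cfg <- small_config(alpha = 0, lambda1 = 0, lambda2 = 0, lambda3 = 0,
                      max_epochs = 5)
  fit <- maskgnn(co, cfg)
  expect_equal(fit$history$mask_penalty, rep(0, 5))
  expect_equal(fit$history$val_total, fit$history$val_e)
})

test_that("fit methods expose predictions, residuals and coefficients", {
  co <- small_cohort()
  fit <- small_fit()
  expect_output(print(fit), "test RMSE")
  preds <- predict(fit, co, ids = fit$splits$test)
  expect_equal(dim(preds), c(length(fit$splits$test), 1))
  expect_equal(unname(preds), unname(fit$predictions))
  res <- residuals(fit, co)
  expect_equal(dim(res), dim(preds))
  expect_equal(coef(fit), fit$mask)
  expect_named(coef(fit, "all"), c("V", "Theta1", "Theta2", "W1", "b1",
                                   "W2", "b2"))
})

test_that("repeated runs report spread and the t-test utility works", {
  co <- small_cohort()
  cfg <- small_config(max_epochs = 6)
  rep2 <- bootstrap_runs(co, cfg, n_reps = 2)
  expect_equal(nrow(rep2$per_rep), 2)
  expect_true(all(c("rmse", "mae") %in% names(rep2$mean)))
  expect_error(bootstrap_runs(co, cfg, n_reps = 1), "n_reps")

  # Welch t of a sample against itself: statistic 0, p = 1
  fake <- structure(list(per_rep = data.frame(rep = 1:4, rmse = c(1, 2, 3, 4)),
                         mean = c(rmse = 2.5), sd = c(rmse = sd(1:4))),
                    class = "metrics_report")
  tt <- compare_runs(fake, fake)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)

  # a hand-computed Welch statistic on two small samples
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  fa <- structure(list(per_rep = data.frame(rep = 1:3, rmse = a),
                       mean = c(rmse = mean(a)), sd = c(rmse = sd(a))),
                  class = "metrics_report")
  fb <- structure(list(per_rep = data.frame(rep = 1:3, rmse = b),
                       mean = c(rmse = mean(b)), sd = c(rmse = sd(b))),
                  class = "metrics_report")
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(unname(compare_runs(fa, fb)$statistic), t_hand)
})

test_that("the ablation grid covers modality subsets without cross-needs", {
  co <- small_cohort()
  cfg <- small_config(max_epochs = 4)
  tab <- ablate(co, cfg, modality_subsets = list("FC", c("FC", "SC")),
                n_reps = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$modalities, c("FC", "FC+SC"))

  # an FC-only configuration trains on a cohort with no SC data at all
  co_fc <- co
  co_fc$subjects <- lapply(co_fc$subjects, function(su) {
    su$sc_raw <- NULL; su$gm_volumes <- NULL; su$morphology <- NULL; su
  })
  co_fc$features <- NULL
  fit_fc <- maskgnn(co_fc, small_config(modalities = "FC", max_epochs = 3))
  expect_s3_class(fit_fc, "maskgnn")
})

test_that("classification training yields the full metric set", {
  co <- small_cohort()
  cfg <- small_config(task = "classification", max_epochs = 8)
  fit <- maskgnn(co, cfg)
  m <- fit$metrics
  expect_true(all(c("accuracy", "f1", "auc") %in% names(m)))
  expect_gte(m$auc, 0); expect_lte(m$auc, 1)
  lab <- predict(fit, co, ids = fit$splits$test)
  expect_true(all(lab %in% c(1L, 2L)))
})
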