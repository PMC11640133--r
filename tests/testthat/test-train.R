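# Fold plans, two-stage training bookkeeping, determinism, leakage guards,
# and the experiment driver.

small_model <- function(seed = 1) {
  build_model(encoder_config(input_dim = 90, widths = c(32, 24, 16),
                             bottleneck = 16),
              head_config(widths = c(8, 6)),
              seed = seed, check_parameter_count = FALSE)
}

small_pixels <- function(co) {
  pixels_from_cohort(co, median_window = 1, snr_threshold = 0,
                     per_channel_length = 30)
}

test_that("fold plans stratify, rotate, and are deterministic", {
  pats <- data.frame(patient_id = 1:20,
                     diagnosis = rep(c("benign", "malignant"), each = 10))
  plan <- make_fold_plan(pats, 10, seed = 4)
  tab <- table(plan$assignment$fold, plan$assignment$diagnosis)
  expect_true(all(tab == 1)) # each fold: 1 benign + 1 malignant
  # rotation covers every fold as test exactly once
  tests <- vapply(plan$runs, `[[`, integer(1), "test")
  expect_equal(sort(tests), 1:10)
  for (run in plan$runs) {
    expect_length(intersect(run$test, run$dev), 0)
    expect_length(intersect(run$test, run$train), 0)
    expect_length(intersect(run$dev, run$train), 0)
    expect_equal(sort(c(run$test, run$dev, run$train)), 1:10)
    expect_length(run$dev, 2)
    expect_length(run$train, 7)
  }
  expect_identical(make_fold_plan(pats, 10, seed = 4), plan)
  expect_error(make_fold_plan(pats[1:5, ], 10), "at least")
})

test_that("fold sizes differ by at most one patient per class", {
  pats <- data.frame(patient_id = 1:23,
                     diagnosis = rep(c("benign", "malignant"),
                                     c(13, 10)))
  plan <- make_fold_plan(pats, 10, seed = 1)
  tab <- table(plan$assignment$fold, plan$assignment$diagnosis)
  for (cl in colnames(tab)) {
    expect_lte(max(tab[, cl]) - min(tab[, cl]), 1)
  }
})

test_that("no patient spans split boundaries within a run", {
  co <- tiny_cohort(n_benign = 6, n_malignant = 6, hw = 3, n_samples = 15)
  plan <- make_fold_plan(co, 10, seed = 2)
  for (run in plan$runs) {
    tr <- flimcontrast:::plan_patients(plan, run$train)
    dv <- flimcontrast:::plan_patients(plan, run$dev)
    te <- flimcontrast:::plan_patients(plan, run$test)
    expect_length(intersect(tr, dv), 0)
    expect_length(intersect(tr, te), 0)
    expect_length(intersect(dv, te), 0)
  }
})

test_that("contrastive pre-training logs, selects, clips, and reproduces", {
  co <- tiny_cohort(n_benign = 2, n_malignant = 2, hw = 5, n_samples = 20)
  px <- small_pixels(co)
  cfg <- train_config(pre_lr = 1e-3, pre_batch = 64, pre_epochs = 3,
                      mt_epochs = 1, monitor_n = 120)
  r1 <- pretrain_contrastive(px, cfg, model = small_model(), seed = 5)
  expect_equal(nrow(r1$history), 4) # epoch 0 (init) + 3 epochs
  expect_true(all(r1$history$grad_norm[-1] <= cfg$clip + 1e-12))
  r2 <- pretrain_contrastive(px, cfg, model = small_model(), seed = 5)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$history, r2$history)
  expect_equal(r1$best_epoch,
               r1$history$epoch[which.max(r1$history$sil_dev)])
  # a dataset missing one class is rejected
  sub <- flimcontrast:::subset_pixels(px, px$contrastive != 2L)
  expect_error(pretrain_contrastive(sub, cfg, model = small_model()),
               "three contrastive classes")
})

test_that("stratified batches hold all classes and two patients per class", {
  co <- tiny_cohort(n_benign = 3, n_malignant = 3, hw = 4, n_samples = 15)
  px <- small_pixels(co)
  class_idx <- lapply(1:3, function(c) which(px$contrastive == c))
  group_idx <- lapply(1:3, function(c) {
    split(class_idx[[c]], px$patient_id[class_idx[[c]]])
  })
  set.seed(1)
  for (i in 1:20) {
    idx <- flimcontrast:::sample_contrastive_batch(class_idx, group_idx, 48)
    expect_length(idx, 48)
    expect_setequal(unique(px$contrastive[idx]), 1:3)
    for (c in 1:3) {
      expect_gte(length(unique(px$patient_id[idx][px$contrastive[idx] == c])),
                 2)
    }
  }
})

test_that("multitask training selects by dev balanced accuracy and reproduces", {
  co <- tiny_cohort(n_benign = 2, n_malignant = 2, hw = 5, n_samples = 20)
  px <- small_pixels(co)
  cfg <- train_config(pre_lr = 1e-3, mt_lr = 1e-2, mt_batch = 64,
                      mt_epochs = 3, monitor_n = 120)
  r1 <- train_multitask(small_model(), px, cfg, dev = px, seed = 9)
  expect_equal(nrow(r1$history), 4)
  expect_true(all(diff(r1$history$epoch) == 1))
  r2 <- train_multitask(small_model(), px, cfg, dev = px, seed = 9)
  expect_identical(r1$history, r2$history)
  # the additive identity holds in every logged epoch
  h <- r1$history[-1, ]
  expect_equal(h$L_MT, h$CE_diag + h$CE_delin + h$L_reg, tolerance = 1e-9)
})

test_that("single-task ablation leaves the delineation head untouched", {
  co <- tiny_cohort(n_benign = 2, n_malignant = 2, hw = 4, n_samples = 15)
  px <- small_pixels(co)
  m0 <- small_model(seed = 3)
  cfg <- train_config(mt_lr = 1e-2, mt_batch = 64, mt_epochs = 2,
                      monitor_n = 100)
  r <- train_multitask(m0, px, cfg, single_task = TRUE, seed = 1)
  expect_identical(r$model$params[["hl1.W"]], m0$params[["hl1.W"]])
  expect_false(identical(r$model$params[["hd1.W"]], m0$params[["hd1.W"]]))
})

test_that("the experiment driver orchestrates trials, runs, and ablations", {
  co <- tiny_cohort(n_benign = 4, n_malignant = 4, hw = 4, n_samples = 15)
  cfg <- train_config(pre_lr = 1e-3, pre_batch = 64, pre_epochs = 1,
                      mt_lr = 1e-2, mt_batch = 64, mt_epochs = 1,
                      monitor_n = 100)
  rep <- run_experiment(co, cfg, n_trials = 2, n_folds = 4, runs = 1:2,
                        median_window = 1, snr_threshold = 0,
                        per_channel_length = 30,
                        encoder = encoder_config(input_dim = 90,
                                                 widths = c(32, 24, 16)),
                        head = head_config(widths = c(8, 6)), seed = 3)
  expect_length(rep$trials, 2)
  expect_length(rep$trials[[1]], 2)
  # aggregate = arithmetic mean of run metrics
  runs <- unlist(rep$trials, recursive = FALSE)
  lh <- vapply(runs, function(r) r$metrics$delineation_lh$accuracy,
               numeric(1))
  expect_equal(unname(rep$aggregate$delineation_lh["accuracy"]), mean(lh),
               tolerance = 1e-9)
  # every test image appears exactly once per trial over executed runs
  tab <- rep$pooled_images
  expect_false(any(duplicated(tab[, c("trial", "image_id")])))
})

test_that("all-ablations-off reduces to a plain single-task classifier", {
  co <- tiny_cohort(n_benign = 4, n_malignant = 4, hw = 4, n_samples = 15)
  cfg <- train_config(mt_lr = 1e-2, mt_batch = 64, mt_epochs = 1,
                      monitor_n = 100)
  rep <- run_experiment(co, cfg, n_trials = 1, n_folds = 4, runs = 1,
                        ablation = list(pretrain = FALSE, multitask = FALSE,
                                        consistency = FALSE),
                        median_window = 1, snr_threshold = 0,
                        per_channel_length = 30,
                        encoder = encoder_config(input_dim = 90,
                                                 widths = c(32, 24, 16)),
                        head = head_config(widths = c(8, 6)), seed = 3)
  r <- rep$trials[[1]][[1]]
  expect_null(r$history_pre) # no pre-training stage ran
  expect_true(all(r$history_mt$CE_delin[-1] == 0))
  expect_true(all(r$history_mt$L_reg[-1] == 0))
})
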