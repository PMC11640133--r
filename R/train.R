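# Two-stage training protocol: contrastive pre-training with adaptive loss
# weighting (stage 1), then joint multitask fine-tuning of encoder + task
# heads (stage 2); patient-level stratified cross-validation plans; the
# experiment driver with ablation switches.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-5,
#' batch size 512, gradient clipping at 0.25 and 10 epochs for contrastive
#' pre-training; Adam, learning rate 1e-5, batch size 256, 5 epochs for the
#' multitask phase. Smaller datasets provide proportionally fewer optimizer
#' steps per epoch, so desk-scale experiments typically raise the learning
#' rates (see the package vignette).
#'
#' @param pre_lr,pre_batch,pre_epochs,clip Pre-training optimizer settings.
#' @param mt_lr,mt_batch,mt_epochs Multitask-phase optimizer settings.
#' @param alpha0 Base clustering weight for [adaptive_alpha()].
#' @param epsilon Distance guard for [adaptive_beta()].
#' @param monitor_n Pixel subsample size for per-epoch silhouette monitoring.
#' @param freeze_encoder Freeze encoder weights during the multitask phase
#'   (default `FALSE`: joint fine-tuning).
#' @return An object of class `train_config`.
#' @export
train_config <- function(pre_lr = 1e-5, pre_batch = 512L, pre_epochs = 10L,
                         clip = 0.25, mt_lr = 1e-5, mt_batch = 256L,
                         mt_epochs = 5L, alpha0 = 1, epsilon = 1e-8,
                         monitor_n = 10000L, freeze_encoder = FALSE) {
  stopifnot(pre_lr > 0, pre_batch >= 2, pre_epochs >= 1, clip > 0,
            mt_lr > 0, mt_batch >= 1, mt_epochs >= 1, alpha0 >= 0,
            epsilon > 0, monitor_n >= 10)
  structure(list(pre_lr = pre_lr, pre_batch = as.integer(pre_batch),
                 pre_epochs = as.integer(pre_epochs), clip = clip,
                 mt_lr = mt_lr, mt_batch = as.integer(mt_batch),
                 mt_epochs = as.integer(mt_epochs), alpha0 = alpha0,
                 epsilon = epsilon, monitor_n = as.integer(monitor_n),
                 freeze_encoder = freeze_encoder),
            class = "train_config")
}

#' Patient-level stratified cross-validation plan (one trial)
#'
#' Assigns patients (and therefore both of each patient's images) to
#' `n_folds` folds, stratified by diagnosis so folds differ by at most one
#' patient per class, then generates `n_folds` runs by rotating the test fold
#' with the next two folds as the development set and the rest as training.
#' Keeping a patient's lesion and healthy images in the same fold prevents
#' patient-identity leakage across split boundaries.
#'
#' @param patients A `maflim_cohort` or a data.frame with `patient_id` and
#'   `diagnosis` columns.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: `assignment` (data.frame
#'   patient_id, diagnosis, fold) and `runs` (list of
#'   `list(test, dev, train)` fold-id vectors).
#' @export
make_fold_plan <- function(patients, n_folds = 10L, seed = 1L) {
  if (inherits(patients, "maflim_cohort")) {
    patients <- data.frame(
      patient_id = vapply(patients, `[[`, numeric(1), "patient_id"),
      diagnosis = vapply(patients, `[[`, character(1), "diagnosis"))
  }
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "diagnosis") %in% names(patients)))
  n_folds <- as.integer(n_folds)
  if (nrow(patients) < n_folds) {
    stop("need at least ", n_folds, " patients for ", n_folds, " folds")
  }
  set.seed(seed)
  fold <- integer(nrow(patients))
  offset <- 0L
  for (dx in sort(unique(patients$diagnosis))) {
    idx <- which(patients$diagnosis == dx)
    idx <- idx[sample.int(length(idx))]
    # deal round-robin, rotating the start so extras spread across folds
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    offset <- (offset + length(idx)) %% n_folds
  }
  runs <- lapply(seq_len(n_folds), function(r) {
    dev <- (c(r, r + 1L) %% n_folds) + 1L
    list(test = r, dev = dev, train = setdiff(seq_len(n_folds), c(r, dev)))
  })
  structure(list(assignment = data.frame(patient_id = patients$patient_id,
                                         diagnosis = patients$diagnosis,
                                         fold = fold),
                 n_folds = n_folds, runs = runs),
            class = "fold_plan")
}

# patient ids belonging to a fold-id set
#' @keywords internal
plan_patients <- function(plan, folds) {
  plan$assignment$patient_id[plan$assignment$fold %in% folds]
}

# stratified contrastive batch: quota per class, guaranteeing >= 2 patients
# per class when available
#' @keywords internal
sample_contrastive_batch <- function(class_idx, group_idx, batch_size) {
  K <- length(class_idx)
  quota <- rep(batch_size %/% K, K)
  extra <- batch_size - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  unlist(lapply(seq_len(K), function(c) {
    groups <- group_idx[[c]]
    picked <- integer(0)
    if (length(groups) >= 2) {
      gs <- sample.int(length(groups), 2)
      picked <- vapply(gs, function(g) {
        ii <- groups[[g]]
        ii[sample.int(length(ii), 1)]
      }, integer(1))
    }
    remaining <- quota[c] - length(picked)
    if (remaining > 0) {
      pool <- class_idx[[c]]
      picked <- c(picked, pool[sample.int(length(pool),
                                          min(remaining, length(pool)),
                                          replace = remaining > length(pool))])
    }
    picked
  }), use.names = FALSE)
}

# silhouette of the contrastive tap on a fixed monitoring subsample
#' @keywords internal
monitor_silhouette <- function(model, pixels, idx) {
  emb <- encoder_forward(model, pixels$x[idx, , drop = FALSE],
                         mode = "embedding", train = FALSE)
  silhouette_score(emb, pixels$contrastive[idx])$S
}

#' Contrastive pre-training of the encoder
#'
#' Runs the configured number of epochs of stratified batches (every batch
#' contains all classes present and at least two patients per class when
#' available), optimizing `L_contr = L_clust - L_sep` applied to the
#' fourth-layer post-batch-norm embedding with Adam and global gradient-norm
#' clipping. Once per epoch the silhouette of a fixed training subsample is
#' recomputed to update the adaptive clustering weight, and the development
#' silhouette selects the returned checkpoint.
#'
#' @param train A `pixel_dataset` carrying 3-class contrastive labels and
#'   patient ids (all three classes must be present).
#' @param config A [train_config()].
#' @param dev Optional development `pixel_dataset` for model selection
#'   (training subsample silhouette is used when absent).
#' @param model Optional pre-built `flim_model` (default architecture built
#'   otherwise).
#' @param use_clustering,use_separation Ablation switches for the two loss
#'   terms.
#' @param use_adaptive_alpha Silhouette-driven clustering-weight schedule
#'   (static `alpha0` when `FALSE`).
#' @param use_adaptive_beta Inverse-distance separation weights (static
#'   uniform weights when `FALSE`).
#' @param seed Integer seed (initialization, batch sampling, subsamples).
#' @return List with `model` (the selected checkpoint), `history` (one row
#'   per epoch; epoch 0 is the initialization), and `best_epoch`.
#' @export
pretrain_contrastive <- function(train, config = train_config(), dev = NULL,
                                 model = NULL, use_clustering = TRUE,
                                 use_separation = TRUE,
                                 use_adaptive_alpha = TRUE,
                                 use_adaptive_beta = TRUE, seed = 1L) {
  stopifnot(inherits(train, "pixel_dataset"), inherits(config, "train_config"))
  present <- sort(unique(train$contrastive))
  if (!all(1:3 %in% present)) {
    stop("training data must contain all three contrastive classes; found: ",
         paste(present, collapse = ", "))
  }
  if (is.null(model)) model <- build_model(seed = seed)
  set.seed(seed + 1L)
  n <- nrow(train$x)
  class_idx <- lapply(1:3, function(c) which(train$contrastive == c))
  group_idx <- lapply(1:3, function(c) {
    split(class_idx[[c]], train$patient_id[class_idx[[c]]])
  })
  mon_idx <- sample.int(n, min(config$monitor_n, n))
  dev_idx <- if (!is.null(dev)) {
    sample.int(nrow(dev$x), min(config$monitor_n, nrow(dev$x)))
  }
  opt <- adam_init(model$params)
  steps <- max(1L, n %/% config$pre_batch)
  sil_train <- monitor_silhouette(model, train, mon_idx)
  sil_dev0 <- if (!is.null(dev)) monitor_silhouette(model, dev, dev_idx) else
    sil_train
  alpha <- if (use_adaptive_alpha) {
    adaptive_alpha(sil_train, config$alpha0)
  } else {
    config$alpha0
  }
  hist <- data.frame(epoch = 0L, L_clust = NA, L_sep = NA, L_contr = NA,
                     alpha = alpha, sil_train = sil_train, sil_dev = sil_dev0,
                     grad_norm = NA)
  best <- list(params = model$params, stats = model$stats,
               sil = sil_dev0, epoch = 0L)
  for (ep in seq_len(config$pre_epochs)) {
    acc <- c(L_clust = 0, L_sep = 0, L_contr = 0, gnorm = 0)
    for (s in seq_len(steps)) {
      idx <- sample_contrastive_batch(class_idx, group_idx, config$pre_batch)
      fw <- encoder_forward(model, train$x[idx, , drop = FALSE],
                            mode = "embedding", train = TRUE,
                            keep_cache = TRUE)
      cg <- contrastive_grad(fw$out, train$contrastive[idx],
                             train$patient_id[idx], alpha = alpha,
                             beta = if (use_adaptive_beta) NULL else
                               uniform_beta(train$contrastive[idx]),
                             epsilon = config$epsilon,
                             use_clustering = use_clustering,
                             use_separation = use_separation)
      grads <- encoder_backward(model, cg$d_emb, fw$caches,
                                d_at = "embedding")
      st <- adam_step(model$params, grads, opt, config$pre_lr,
                      clip = config$clip)
      model$params <- st$params
      opt <- st$state
      model <- update_bn_stats(model, fw$caches)
      acc <- acc + c(cg$report$L_clust, cg$report$L_sep, cg$report$L_contr,
                     min(st$grad_norm, config$clip))
    }
    acc <- acc / steps
    sil_train <- monitor_silhouette(model, train, mon_idx)
    if (use_adaptive_alpha) {
      alpha <- adaptive_alpha(sil_train, config$alpha0)
    }
    sil_dev <- if (!is.null(dev)) monitor_silhouette(model, dev, dev_idx) else
      sil_train
    hist <- rbind(hist, data.frame(epoch = ep, L_clust = acc[1],
                                   L_sep = acc[2], L_contr = acc[3],
                                   alpha = alpha, sil_train = sil_train,
                                   sil_dev = sil_dev, grad_norm = acc[4]))
    if (sil_dev > best$sil) {
      best <- list(params = model$params, stats = model$stats, sil = sil_dev,
                   epoch = ep)
    }
  }
  model$params <- best$params
  model$stats <- best$stats
  rownames(hist) <- NULL
  list(model = model, history = hist, best_epoch = best$epoch)
}

# static uniform per-pair separation weights for the classes present
#' @keywords internal
uniform_beta <- function(class_labels) {
  K <- length(unique(class_labels))
  if (K < 2) return(matrix(0, K, K))
  b <- matrix(1 / (K - 1), K, K)
  diag(b) <- 0
  b
}

# pixel-level predictions from both heads, chunked to bound memory
#' @keywords internal
predict_pixels <- function(model, x, chunk = 8192L) {
  n <- nrow(x)
  diag_lab <- integer(n)
  delin_lab <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    feats <- encoder_forward(model, x[ii, , drop = FALSE], mode = "features",
                             train = FALSE)
    hs <- heads_forward(model, feats, train = FALSE)
    diag_lab[ii] <- max.col(hs$diagnosis, ties.method = "first")
    delin_lab[ii] <- max.col(hs$delineation, ties.method = "first")
  }
  list(diagnosis = diag_lab, delineation = delin_lab)
}

#' @keywords internal
balanced_accuracy <- function(predictions, truths) {
  pos <- truths == 2L
  neg <- truths == 1L
  sens <- if (any(pos)) mean(predictions[pos] == 2L) else NA_real_
  spec <- if (any(neg)) mean(predictions[neg] == 1L) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

#' Multitask training of encoder + task heads
#'
#' Optimizes `L_MT = CE_diag + CE_delin + L_reg` (sample-weighted
#' cross-entropies plus the consistency regularizer) with Adam. By default the
#' encoder keeps updating (joint fine-tuning). The checkpoint with the highest
#' development-set mean of the two tasks' pixel-level balanced accuracies is
#' returned.
#'
#' @param model A `flim_model`, typically the [pretrain_contrastive()] output
#'   (a freshly initialized model reproduces the multitask-only baseline).
#' @param train Training `pixel_dataset` (both task labels present).
#' @param config A [train_config()].
#' @param dev Optional development `pixel_dataset` for checkpoint selection.
#' @param use_consistency Include the consistency loss (`L_reg`).
#' @param single_task Train the diagnosis head only (single-task ablation).
#' @param seed Integer seed.
#' @return List with `model`, `history`, `best_epoch`.
#' @export
train_multitask <- function(model, train, config = train_config(), dev = NULL,
                            use_consistency = TRUE, single_task = FALSE,
                            seed = 1L) {
  stopifnot(inherits(model, "flim_model"), inherits(train, "pixel_dataset"))
  set.seed(seed + 2L)
  n <- nrow(train$x)
  w_diag_cls <- balanced_class_weights(train$diagnosis)
  w_delin_cls <- balanced_class_weights(train$delineation)
  w_diag <- unname(w_diag_cls[as.character(train$diagnosis)])
  w_delin <- unname(w_delin_cls[as.character(train$delineation)])
  opt <- adam_init(model$params)
  steps <- max(1L, n %/% config$mt_batch)
  dev_score <- function(m) {
    if (is.null(dev)) return(NA_real_)
    pr <- predict_pixels(m, dev$x)
    ba_d <- balanced_accuracy(pr$diagnosis, dev$diagnosis)
    if (single_task) return(ba_d)
    mean(c(ba_d, balanced_accuracy(pr$delineation, dev$delineation)))
  }
  best <- list(params = model$params, stats = model$stats,
               score = dev_score(model), epoch = 0L)
  hist <- data.frame(epoch = 0L, CE_diag = NA, CE_delin = NA, L_reg = NA,
                     L_MT = NA, dev_score = best$score)
  for (ep in seq_len(config$mt_epochs)) {
    perm <- sample.int(n)
    acc <- c(0, 0, 0, 0)
    for (s in seq_len(steps)) {
      ii <- perm[((s - 1L) * config$mt_batch + 1L):
                   min(s * config$mt_batch, n)]
      fw <- encoder_forward(model, train$x[ii, , drop = FALSE],
                            mode = "features", train = TRUE,
                            keep_cache = TRUE)
      hs <- heads_forward(model, fw$out, train = TRUE, keep_cache = TRUE)
      p_diag <- nn_softmax(hs$diagnosis)
      ce_d <- nn_ce_loss(p_diag, train$diagnosis[ii], w_diag[ii])
      d_diag <- nn_ce_grad(p_diag, train$diagnosis[ii], w_diag[ii])
      if (single_task) {
        ce_l <- 0
        lreg <- 0
        d_delin <- NULL
      } else {
        p_delin <- nn_softmax(hs$delineation)
        ce_l <- nn_ce_loss(p_delin, train$delineation[ii], w_delin[ii])
        d_delin <- nn_ce_grad(p_delin, train$delineation[ii], w_delin[ii])
        if (use_consistency) {
          cl <- consistency_loss(hs$diagnosis, hs$delineation,
                                 train$contrastive[ii], grad = TRUE)
          lreg <- cl$loss
          d_diag <- d_diag + cl$d_diag
          d_delin <- d_delin + cl$d_delin
        } else {
          lreg <- 0
        }
      }
      bd <- head_backward(model, "d", d_diag, hs$caches$d)
      grads <- bd$grads
      dfeat <- bd$dfeatures
      if (!single_task) {
        bl <- head_backward(model, "l", d_delin, hs$caches$l)
        grads <- c(grads, bl$grads)
        dfeat <- dfeat + bl$dfeatures
      }
      if (!config$freeze_encoder) {
        grads <- c(grads,
                   encoder_backward(model, dfeat, fw$caches,
                                    d_at = "features"))
      }
      st <- adam_step(model$params, grads, opt, config$mt_lr)
      model$params <- st$params
      opt <- st$state
      model <- update_bn_stats(model, fw$caches)
      acc <- acc + c(ce_d, ce_l, lreg, ce_d + ce_l + lreg)
    }
    acc <- acc / steps
    score <- dev_score(model)
    hist <- rbind(hist, data.frame(epoch = ep, CE_diag = acc[1],
                                   CE_delin = acc[2], L_reg = acc[3],
                                   L_MT = acc[4], dev_score = score))
    if (is.na(best$score) || (!is.na(score) && score > best$score)) {
      best <- list(params = model$params, stats = model$stats, score = score,
                   epoch = ep)
    }
  }
  model$params <- best$params
  model$stats <- best$stats
  rownames(hist) <- NULL
  list(model = model, history = hist, best_epoch = best$epoch)
}

# image-level truth table from a pixel dataset
#' @keywords internal
image_table <- function(pixels) {
  first <- match(unique(pixels$image_id), pixels$image_id)
  data.frame(image_id = pixels$image_id[first],
             patient_id = pixels$patient_id[first],
             tissue = c("healthy", "lesion")[pixels$delineation[first]],
             diag_truth = pixels$diagnosis[first],
             delin_truth = pixels$delineation[first])
}

# evaluate a trained model on a test pixel dataset at image level
#' @keywords internal
evaluate_images <- function(model, test) {
  pr <- predict_pixels(model, test$x)
  tab <- image_table(test)
  tab$diag_pred <- NA_integer_
  tab$delin_pred <- NA_integer_
  for (i in seq_len(nrow(tab))) {
    sel <- test$image_id == tab$image_id[i]
    tab$diag_pred[i] <- aggregate_image(pr$diagnosis[sel])$label
    tab$delin_pred[i] <- aggregate_image(pr$delineation[sel])$label
  }
  tab
}

# metrics for the three evaluation universes from an image prediction table
#' @keywords internal
universe_metrics <- function(tab) {
  lesion <- tab[tab$tissue == "lesion", ]
  mh <- tab[tab$tissue == "healthy" |
              (tab$tissue == "lesion" & tab$diag_truth == 2L), ]
  list(
    diagnosis = if (nrow(lesion)) {
      compute_metrics(lesion$diag_pred, lesion$diag_truth)
    },
    delineation_mh = if (nrow(mh)) {
      compute_metrics(mh$delin_pred, mh$delin_truth)
    },
    delineation_lh = compute_metrics(tab$delin_pred, tab$delin_truth)
  )
}

#' Run the full cross-validated experiment
#'
#' For each trial a fresh patient-level fold plan is drawn; for each run the
#' pipeline pre-trains the encoder (unless ablated), trains the task heads,
#' and evaluates on the held-out test fold at image level. Diagnosis metrics
#' are computed on lesion images only; margin delineation is evaluated both
#' for malignant-vs-healthy and lesion-vs-healthy universes.
#'
#' @param cohort A `maflim_cohort`.
#' @param config A [train_config()].
#' @param n_trials Number of independent fold plans.
#' @param n_folds Folds per trial (default 10).
#' @param runs Which fold rotations to execute per trial (default all).
#' @param ablation Named list of switches, all defaulting to `TRUE`:
#'   `pretrain`, `clustering`, `separation`, `adaptive_alpha`,
#'   `adaptive_beta`, `consistency`, `multitask`.
#' @param median_window,snr_threshold,per_channel_length Preprocessing
#'   settings.
#' @param encoder Optional [encoder_config()]; defaults to the full
#'   architecture with `input_dim = 3 * per_channel_length`.
#' @param head Optional [head_config()].
#' @param seed Integer master seed.
#' @param verbose Print per-run progress.
#' @return An object of class `experiment_report`: per-trial run reports,
#'   `aggregate` (arithmetic mean of run metrics), and `pooled` (metrics over
#'   all test-fold image predictions pooled across runs).
#' @export
run_experiment <- function(cohort, config = train_config(), n_trials = 1L,
                           n_folds = 10L, runs = NULL, ablation = list(),
                           median_window = 3L, snr_threshold = 2,
                           per_channel_length = 300L, encoder = NULL,
                           head = head_config(), seed = 1L,
                           verbose = FALSE) {
  if (is.null(encoder)) {
    encoder <- encoder_config(input_dim = 3L * per_channel_length)
  }
  ab <- utils::modifyList(
    list(pretrain = TRUE, clustering = TRUE, separation = TRUE,
         adaptive_alpha = TRUE, adaptive_beta = TRUE, consistency = TRUE,
         multitask = TRUE),
    ablation)
  pixels <- pixels_from_cohort(cohort, median_window, snr_threshold,
                               per_channel_length)
  if (is.null(runs)) runs <- seq_len(n_folds)
  trials <- vector("list", n_trials)
  all_tabs <- list()
  for (tr in seq_len(n_trials)) {
    plan <- make_fold_plan(cohort, n_folds, seed = seed + 17L * tr)
    run_reports <- vector("list", length(runs))
    for (ri in seq_along(runs)) {
      r <- runs[ri]
      rs <- seed + 1000L * tr + 10L * r
      split <- plan$runs[[r]]
      tr_px <- subset_pixels(pixels,
                             pixels$patient_id %in%
                               plan_patients(plan, split$train))
      dv_px <- subset_pixels(pixels,
                             pixels$patient_id %in%
                               plan_patients(plan, split$dev))
      te_px <- subset_pixels(pixels,
                             pixels$patient_id %in%
                               plan_patients(plan, split$test))
      model <- build_model(encoder, head, seed = rs,
                           check_parameter_count = FALSE)
      hist_pre <- NULL
      if (ab$pretrain && (ab$clustering || ab$separation)) {
        pt <- pretrain_contrastive(tr_px, config, dev = dv_px, model = model,
                                   use_clustering = ab$clustering,
                                   use_separation = ab$separation,
                                   use_adaptive_alpha = ab$adaptive_alpha,
                                   use_adaptive_beta = ab$adaptive_beta,
                                   seed = rs)
        model <- pt$model
        hist_pre <- pt$history
      }
      mt <- train_multitask(model, tr_px, config, dev = dv_px,
                            use_consistency = ab$consistency,
                            single_task = !ab$multitask, seed = rs)
      tab <- evaluate_images(mt$model, te_px)
      tab$trial <- tr
      tab$run <- r
      all_tabs[[length(all_tabs) + 1L]] <- tab
      run_reports[[ri]] <- list(trial = tr, run = r, images = tab,
                                metrics = universe_metrics(tab),
                                history_pre = hist_pre,
                                history_mt = mt$history)
      if (verbose) {
        message(sprintf("trial %d run %d done (%d test images)", tr, r,
                        nrow(tab)))
      }
    }
    trials[[tr]] <- run_reports
  }
  pooled_tab <- do.call(rbind, all_tabs)
  structure(list(trials = trials,
                 aggregate = aggregate_run_metrics(trials),
                 pooled = universe_metrics(pooled_tab),
                 pooled_images = pooled_tab,
                 ablation = ab),
            class = "experiment_report")
}

# arithmetic mean of run-level metrics across all trials/runs
#' @keywords internal
aggregate_run_metrics <- function(trials) {
  runs <- unlist(trials, recursive = FALSE)
  out <- list()
  for (u in c("diagnosis", "delineation_mh", "delineation_lh")) {
    ms <- Filter(Negate(is.null), lapply(runs, function(r) r$metrics[[u]]))
    if (!length(ms)) next
    fields <- c("sensitivity", "specificity", "average", "precision", "F1",
                "accuracy")
    out[[u]] <- vapply(fields, function(f) {
      mean(vapply(ms, function(m) m[[f]], numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  out
}
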