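# Silhouette scoring, pixel-to-image aggregation, confusion-matrix metrics,
# paired significance testing, and the 2D embedding snapshot payload.

#' Silhouette score
#'
#' Per-sample `s = (B - A) / max(A, B)` with Euclidean distances, where `A` is
#' the mean distance to all other points of the same class and `B` the mean
#' distance to the points of the next nearest cluster (the other cluster
#' minimizing that mean). Samples in singleton clusters score 0. The report's
#' `S` is the mean over samples; range `[-1, 1]`, negative values indicating
#' wrong assignments.
#'
#' @param embeddings Numeric `n x d` matrix (n >= 2).
#' @param labels Class label per row (>= 2 distinct classes).
#' @return An object of class `silhouette_report`: `S`, per-sample `s`, `A`,
#'   `B`.
#' @export
silhouette_score <- function(embeddings, labels) {
  if (!is.matrix(embeddings)) embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  stopifnot(n >= 2, length(labels) == n)
  cls <- factor(labels)
  if (nlevels(cls) < 2) stop("silhouette needs at least two classes")
  D <- as.matrix(stats::dist(embeddings))
  counts <- as.vector(table(cls))
  # n x K matrix of summed distances to each class
  sums <- t(rowsum(D, cls)) # transpose: rows = samples, cols = classes
  ci <- as.integer(cls)
  idx <- cbind(seq_len(n), ci)
  A <- ifelse(counts[ci] > 1, sums[idx] / (counts[ci] - 1), NA_real_)
  means_other <- sweep(sums, 2, counts, `/`)
  means_other[idx] <- Inf
  B <- apply(means_other, 1, min)
  s <- ifelse(counts[ci] == 1, 0, (B - A) / pmax(A, B))
  s[counts[ci] > 1 & A == 0 & B == 0] <- 0
  structure(list(S = mean(s), s = s, A = A, B = B, metric = "euclidean"),
            class = "silhouette_report")
}

#' Aggregate pixel predictions to an image-level label
#'
#' Majority vote with a 50% threshold; an exact tie is assigned to the
#' positive (lesion / malignant) class, the clinically conservative choice.
#'
#' @param pixel_labels Integer predicted labels in {1, 2} (2 = positive) for
#'   the unmasked pixels of one image.
#' @param image_id Optional identifier.
#' @return An object of class `image_prediction`: `label` (1 or 2),
#'   `positive_fraction`, `n_pixels`.
#' @export
aggregate_image <- function(pixel_labels, image_id = NULL) {
  if (length(pixel_labels) == 0) {
    stop("degenerate image: no unmasked pixels to aggregate")
  }
  frac <- mean(pixel_labels == 2L)
  structure(list(image_id = image_id,
                 label = if (frac >= 0.5) 2L else 1L,
                 positive_fraction = frac,
                 n_pixels = length(pixel_labels)),
            class = "image_prediction")
}

#' Classification metrics from image-level predictions
#'
#' Sensitivity, specificity, their average, precision, F1, and accuracy, all
#' as percentages, from the confusion counts. Ratios with a zero denominator
#' are reported as `NA` (absent), not 0.
#'
#' @param predictions Integer predicted labels (2 = positive).
#' @param truths Integer true labels (2 = positive).
#' @return An object of class `metrics_report` with the metrics and the
#'   confusion counts `TP`, `FP`, `TN`, `FN`.
#' @export
compute_metrics <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  if (length(predictions) == 0) stop("empty evaluation set")
  tp <- sum(predictions == 2L & truths == 2L)
  fp <- sum(predictions == 2L & truths == 1L)
  tn <- sum(predictions == 1L & truths == 1L)
  fn <- sum(predictions == 1L & truths == 2L)
  rat <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  prec <- rat(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  acc <- rat(tp + tn, tp + fp + tn + fn)
  avg <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  structure(list(sensitivity = sens, specificity = spec, average = avg,
                 precision = prec, F1 = f1, accuracy = acc,
                 TP = tp, FP = fp, TN = tn, FN = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sens. %.2f  Spec. %.2f  Avg. %.2f  Prec. %.2f  F1 %.2f  Acc. %.2f\n",
              x$sensitivity, x$specificity, x$average, x$precision, x$F1,
              x$accuracy))
  cat(sprintf("  (TP %d  FP %d  TN %d  FN %d)\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Paired one-tailed t-test
#'
#' Tests whether `mean(x - y) > 0` with `n - 1` degrees of freedom.
#'
#' @param x,y Equal-length metric vectors (one entry per run), length >= 2.
#' @return List with `t` and one-tailed `p`.
#' @export
paired_one_tailed_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate test: differences have zero variance")
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Per-image 2D embedding snapshot
#'
#' For a visualization-configured encoder (2-unit bottleneck), computes the
#' mean contrastive-tap embedding of each image's unmasked pixels plus the
#' silhouette score of a pixel subsample -- the payload used to watch class
#' clustering emerge during pre-training.
#'
#' @param model A `flim_model` with `bottleneck = 2`.
#' @param pixels A `pixel_dataset`.
#' @param monitor_n Pixel subsample size for the silhouette.
#' @param seed Seed for the subsample.
#' @return List with `payload` (data.frame: image_id, patient_id, class,
#'   tissue, x, y) and `silhouette`.
#' @export
embed_2d_snapshot <- function(model, pixels, monitor_n = 2000L, seed = 1L) {
  stopifnot(inherits(model, "flim_model"), model$encoder$bottleneck == 2L)
  emb <- encoder_forward(model, pixels$x, mode = "embedding", train = FALSE)
  img <- factor(pixels$image_id)
  means <- rowsum(emb, img) / as.vector(table(img))
  first <- match(levels(img), pixels$image_id)
  payload <- data.frame(
    image_id = levels(img),
    patient_id = pixels$patient_id[first],
    class = c("healthy", "benign", "malignant")[pixels$contrastive[first]],
    tissue = c("healthy", "lesion")[pixels$delineation[first]],
    x = means[, 1], y = means[, 2], row.names = NULL)
  set.seed(seed)
  idx <- sample.int(nrow(emb), min(monitor_n, nrow(emb)))
  sil <- silhouette_score(emb[idx, , drop = FALSE], pixels$contrastive[idx])
  list(payload = payload, silhouette = sil$S)
}
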