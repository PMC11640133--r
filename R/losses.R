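# Contrastive clustering/separation losses over class anchors and patient-mean
# embeddings, adaptive loss weights, balanced class weights, the multitask
# cross-entropies, and the inter-head consistency regularizer.
#
# The total contrastive objective is L_contr = L_clust - L_sep: the clustering
# term pulls each same-class patient-mean embedding toward its class anchor
# (the mean embedding of the class within the batch); the separation term,
# subtracted so that minimizing L_contr maximizes it, pushes anchors away from
# other-class patient means. "Squared difference" is read as the squared
# Euclidean norm of the embedding difference.

#' Build class anchors and patient-mean embeddings for one batch
#'
#' The anchor of class `c` is the mean embedding over all batch pixels of that
#' class (pixel-weighted). Each (class, patient) group's mean embedding serves
#' as a positive for its own class and as a negative for every other class.
#'
#' @param embeddings Numeric `n x d` matrix.
#' @param class_labels Integer/character class label per row.
#' @param patient_ids Patient identifier per row.
#' @return An object of class `class_anchors`: `anchors` (`K x d`),
#'   `patient_means` (`P x d`), `pm_class` (class of each patient mean),
#'   `classes`, per-group pixel counts, and index maps back to rows.
#' @export
build_anchors <- function(embeddings, class_labels, patient_ids) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) >= 1,
            length(class_labels) == nrow(embeddings),
            length(patient_ids) == nrow(embeddings))
  cls <- factor(class_labels)
  grp <- factor(paste(as.character(cls), patient_ids, sep = "\r"))
  n_c <- as.vector(table(cls))
  n_g <- as.vector(table(grp))
  anchors <- rowsum(embeddings, cls) / n_c
  pms <- rowsum(embeddings, grp) / n_g
  pm_class <- vapply(strsplit(levels(grp), "\r", fixed = TRUE),
                     `[[`, character(1), 1)
  structure(list(anchors = anchors, classes = levels(cls),
                 n_class = n_c, class_of_row = as.integer(cls),
                 patient_means = pms, pm_class = pm_class,
                 n_group = n_g, group_of_row = as.integer(grp)),
            class = "class_anchors")
}

#' Clustering loss
#'
#' `sum_c alpha_c * sum_{patients p of class c} ||anchor_c - pm_{c,p}||^2`.
#'
#' @param anchors A [build_anchors()] result.
#' @param alpha Per-class clustering weights (scalar recycled across classes),
#'   named by class or in `anchors$classes` order.
#' @return Scalar loss.
#' @export
clustering_loss <- function(anchors, alpha = 1) {
  stopifnot(inherits(anchors, "class_anchors"))
  alpha <- expand_class_weights(alpha, anchors$classes)
  ci <- match(anchors$pm_class, anchors$classes)
  diff <- anchors$patient_means - anchors$anchors[ci, , drop = FALSE]
  sum(alpha[ci] * rowSums(diff * diff))
}

#' Separation loss
#'
#' `sum_c sum_{patients p of other classes} beta[c, class(p)] *
#' ||anchor_c - pm_p||^2`. Returns 0 with a warning when only one class is
#' present (no negatives exist).
#'
#' @param anchors A [build_anchors()] result.
#' @param beta Per-(anchor class, negative class) weight matrix `K x K`
#'   (diagonal ignored), or a scalar recycled over all pairs.
#' @return Scalar loss.
#' @export
separation_loss <- function(anchors, beta = 1) {
  stopifnot(inherits(anchors, "class_anchors"))
  K <- length(anchors$classes)
  if (K < 2) {
    warning("single-class batch: separation loss is 0 (no negatives)")
    return(0)
  }
  beta <- expand_pair_weights(beta, K)
  ci <- match(anchors$pm_class, anchors$classes)
  total <- 0
  for (c in seq_len(K)) {
    neg <- which(ci != c)
    if (!length(neg)) next
    diff <- anchors$patient_means[neg, , drop = FALSE] -
      matrix(anchors$anchors[c, ], length(neg), ncol(anchors$anchors),
             byrow = TRUE)
    total <- total + sum(beta[c, ci[neg]] * rowSums(diff * diff))
  }
  total
}

#' @keywords internal
expand_class_weights <- function(alpha, classes) {
  K <- length(classes)
  if (length(alpha) == 1) return(rep(alpha, K))
  if (!is.null(names(alpha))) return(alpha[classes])
  stopifnot(length(alpha) == K)
  alpha
}

#' @keywords internal
expand_pair_weights <- function(beta, K) {
  if (is.matrix(beta)) {
    stopifnot(nrow(beta) == K, ncol(beta) == K)
    return(beta)
  }
  stopifnot(length(beta) == 1)
  matrix(beta, K, K)
}

#' Adaptive separation weights (inverse squared class-mean distance)
#'
#' `beta[c, c'] = 1 / max(dist^2(anchor_c, anchor_c'), epsilon)`, normalized
#' to sum to one over the negative classes of each anchor class, so the
#' weight is larger when two classes are poorly separated.
#'
#' @param anchors A [build_anchors()] result with >= 2 classes.
#' @param epsilon Guard against coincident class means.
#' @return `K x K` weight matrix with zero diagonal; rows sum to 1.
#' @export
adaptive_beta <- function(anchors, epsilon = 1e-8) {
  stopifnot(inherits(anchors, "class_anchors"))
  A <- anchors$anchors
  K <- nrow(A)
  if (K < 2) stop("adaptive_beta needs at least two classes")
  sq <- rowSums(A * A)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(A)
  d2 <- pmax(d2, 0)
  raw <- 1 / pmax(d2, epsilon)
  diag(raw) <- 0
  raw / rowSums(raw)
}

#' Adaptive clustering weight schedule
#'
#' Linear decay of the clustering weight as the silhouette score improves:
#' `alpha = alpha0 * (1 - clamp(S, 0, 1))`, so the representation clusters
#' quickly at first but the clustering term releases its pressure (avoiding
#' collapse) once the classes are well grouped.
#'
#' @param silhouette Silhouette score `S` in `[-1, 1]`.
#' @param alpha0 Base clustering weight.
#' @return Scalar alpha in `[0, alpha0]`.
#' @export
adaptive_alpha <- function(silhouette, alpha0 = 1) {
  stopifnot(is.finite(silhouette))
  alpha0 * (1 - min(max(silhouette, 0), 1))
}

#' Total contrastive loss report
#'
#' @param anchors A [build_anchors()] result.
#' @param alpha Per-class clustering weights.
#' @param beta Pair weight matrix or scalar (see [separation_loss()]).
#' @return An object of class `contrastive_report` with `L_clust`, `L_sep`,
#'   and `L_contr = L_clust - L_sep`.
#' @export
contrastive_total <- function(anchors, alpha = 1, beta = 1) {
  lc <- clustering_loss(anchors, alpha)
  ls <- if (length(anchors$classes) >= 2) separation_loss(anchors, beta) else 0
  structure(list(L_clust = lc, L_sep = ls, L_contr = lc - ls),
            class = "contrastive_report")
}

#' Balanced class weights
#'
#' `weight(c) = n_total / (n_classes_present * n_c)`, so the weighted mean of
#' per-sample weights under the empirical distribution is 1.
#'
#' @param labels Vector of class labels (>= 1 entry).
#' @return Named numeric vector of per-class weights.
#' @export
balanced_class_weights <- function(labels) {
  if (length(labels) == 0) stop("empty label vector")
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.vector(tab))
  names(w) <- names(tab)
  w
}

#' Consistency (regularization) loss between the two heads
#'
#' Penalizes mutually contradictory predictions: for ground-truth malignant
#' samples on which the diagnosis head predicts malignant, a cross-entropy
#' pushes the delineation head toward "lesion"; for ground-truth healthy
#' samples on which the delineation head predicts healthy, a cross-entropy
#' pushes the diagnosis head toward its benign side. The selection by
#' predicted class is treated as fixed (no gradient flows through the
#' selecting head). The loss is averaged over contributing samples and is 0
#' when none contribute.
#'
#' @param diag_logits,delin_logits `n x 2` logit matrices (column 2 =
#'   malignant / lesion).
#' @param contrastive_labels Integer ground-truth 3-class labels
#'   (1 = healthy, 2 = benign, 3 = malignant).
#' @param grad Also return gradients w.r.t. both logit matrices.
#' @return Scalar loss, or list(`loss`, `d_diag`, `d_delin`) when
#'   `grad = TRUE`.
#' @export
consistency_loss <- function(diag_logits, delin_logits, contrastive_labels,
                             grad = FALSE) {
  n <- nrow(diag_logits)
  stopifnot(nrow(delin_logits) == n, length(contrastive_labels) == n)
  p_diag <- nn_softmax(diag_logits)
  p_delin <- nn_softmax(delin_logits)
  pred_diag <- max.col(p_diag, ties.method = "first")
  pred_delin <- max.col(p_delin, ties.method = "first")
  # rule 1: malignant truth + diagnosis says malignant => delineation: lesion
  r1 <- which(contrastive_labels == 3L & pred_diag == 2L)
  # rule 2: healthy truth + delineation says healthy => diagnosis: benign side
  r2 <- which(contrastive_labels == 1L & pred_delin == 1L)
  m <- length(r1) + length(r2)
  if (m == 0) {
    if (grad) {
      return(list(loss = 0, d_diag = diag_logits * 0,
                  d_delin = delin_logits * 0))
    }
    return(0)
  }
  loss <- 0
  d_diag <- diag_logits * 0
  d_delin <- delin_logits * 0
  if (length(r1)) {
    p <- pmax(p_delin[r1, 2], 1e-12)
    loss <- loss + sum(-log(p))
    g <- p_delin[r1, , drop = FALSE]
    g[, 2] <- g[, 2] - 1
    d_delin[r1, ] <- d_delin[r1, ] + g
  }
  if (length(r2)) {
    p <- pmax(p_diag[r2, 1], 1e-12)
    loss <- loss + sum(-log(p))
    g <- p_diag[r2, , drop = FALSE]
    g[, 1] <- g[, 1] - 1
    d_diag[r2, ] <- d_diag[r2, ] + g
  }
  if (grad) {
    list(loss = loss / m, d_diag = d_diag / m, d_delin = d_delin / m)
  } else {
    loss / m
  }
}

#' Multitask loss report
#'
#' `L_MT = CE_diag + CE_delin + L_reg`, where the cross-entropies are
#' sample-weighted over the two binary tasks and `L_reg` is the
#' [consistency_loss()] (0 when disabled).
#'
#' @param diag_logits,delin_logits `n x 2` logit matrices.
#' @param diag_labels,delin_labels Integer labels in {1, 2} (2 = positive:
#'   malignant / lesion).
#' @param contrastive_labels 3-class ground truth for the consistency term.
#' @param diag_weights,delin_weights Per-sample weights (default 1).
#' @param use_consistency Include the consistency regularizer.
#' @return An object of class `multitask_report` with `CE_diag`, `CE_delin`,
#'   `L_reg`, and `L_MT` (their exact sum).
#' @export
multitask_loss <- function(diag_logits, delin_logits, diag_labels,
                           delin_labels, contrastive_labels = NULL,
                           diag_weights = NULL, delin_weights = NULL,
                           use_consistency = TRUE) {
  p_diag <- nn_softmax(diag_logits)
  p_delin <- nn_softmax(delin_logits)
  ce_d <- nn_ce_loss(p_diag, diag_labels, diag_weights)
  ce_l <- nn_ce_loss(p_delin, delin_labels, delin_weights)
  lreg <- if (use_consistency && !is.null(contrastive_labels)) {
    consistency_loss(diag_logits, delin_logits, contrastive_labels)
  } else {
    0
  }
  structure(list(CE_diag = ce_d, CE_delin = ce_l, L_reg = lreg,
                 L_MT = ce_d + ce_l + lreg),
            class = "multitask_report")
}

# ---- gradient of the contrastive loss w.r.t. the embedding batch ------------
# Anchors and patient means are linear in the embeddings, so the chain rule
# distributes anchor/patient-mean gradients back to rows by group size.
# Returns list(report, d_emb).
#' @keywords internal
contrastive_grad <- function(embeddings, class_labels, patient_ids,
                             alpha = 1, beta = NULL, epsilon = 1e-8,
                             use_clustering = TRUE, use_separation = TRUE) {
  an <- build_anchors(embeddings, class_labels, patient_ids)
  K <- length(an$classes)
  d <- ncol(embeddings)
  alpha_v <- expand_class_weights(alpha, an$classes)
  if (is.null(beta)) {
    beta_m <- if (K >= 2) adaptive_beta(an, epsilon) else matrix(0, K, K)
  } else {
    beta_m <- expand_pair_weights(beta, K)
  }
  ci <- match(an$pm_class, an$classes)
  gA <- matrix(0, K, d)
  gP <- matrix(0, nrow(an$patient_means), d)
  lc <- 0
  ls <- 0
  if (use_clustering) {
    diff <- an$patient_means - an$anchors[ci, , drop = FALSE] # pm - anchor
    w <- alpha_v[ci]
    lc <- sum(w * rowSums(diff * diff))
    gP <- gP + 2 * w * diff
    gA <- gA - rowsum(2 * w * diff, ci)
  }
  if (use_separation && K >= 2) {
    for (c in seq_len(K)) {
      neg <- which(ci != c)
      if (!length(neg)) next
      diff <- an$patient_means[neg, , drop = FALSE] -
        matrix(an$anchors[c, ], length(neg), d, byrow = TRUE)
      w <- beta_m[c, ci[neg]]
      ls <- ls + sum(w * rowSums(diff * diff))
      # L_contr subtracts the separation term
      gP[neg, ] <- gP[neg, ] - 2 * w * diff
      gA[c, ] <- gA[c, ] + colSums(2 * w * diff)
    }
  }
  d_emb <- gA[an$class_of_row, , drop = FALSE] / an$n_class[an$class_of_row] +
    gP[an$group_of_row, , drop = FALSE] / an$n_group[an$group_of_row]
  list(report = structure(list(L_clust = lc, L_sep = ls, L_contr = lc - ls),
                          class = "contrastive_report"),
       d_emb = d_emb, anchors = an, beta = beta_m, alpha = alpha_v)
}
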