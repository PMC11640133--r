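# Loss-function validation on 2D interleaved arcs: a small dense network maps
# the 2D points to a 2D embedding on which the contrastive loss operates,
# replicating the behaviors the loss design rests on -- batch normalization
# keeping the separation term from diverging, and adaptive separation weights
# yielding nearly equidistant class clusters in the 3-class case.

#' Contrastive-loss validation experiment on 2D arcs
#'
#' Trains a small fully connected network (2 -> hidden -> hidden -> 2, ReLU,
#' optional batch normalization on the embedding layer) with full-batch Adam
#' on the contrastive loss over an interleaved-arc dataset from
#' [make_arcs()].
#'
#' @param n_classes 2 or 3.
#' @param n_per_class Points per class.
#' @param noise_sd Arc noise.
#' @param steps Optimizer steps (full batch).
#' @param lr Adam learning rate.
#' @param hidden Hidden-layer widths (length 2).
#' @param batchnorm Apply batch normalization to the embedding layer.
#' @param use_clustering,use_separation Loss-term switches (separation-only
#'   training without batch normalization reproduces the divergence failure
#'   mode).
#' @param adaptive_beta_weights Adaptive inverse-distance separation weights;
#'   `FALSE` uses static uniform weights.
#' @param adaptive_alpha_weights Silhouette-driven clustering weight schedule.
#' @param alpha0 Base clustering weight.
#' @param seed Integer seed.
#' @return List with `history` (per-step L_clust, L_sep, L_contr, and the
#'   silhouette sampled every 10 steps), `embeddings` (final), `data`,
#'   `silhouette_init`, `silhouette_final`, `centroids`, and
#'   `centroid_distance_ratio` (max/min pairwise centroid distance).
#' @export
moons_demo <- function(n_classes = 2L, n_per_class = 150L, noise_sd = 0.1,
                       steps = 400L, lr = 0.01, hidden = c(32L, 32L),
                       batchnorm = TRUE, use_clustering = TRUE,
                       use_separation = TRUE, adaptive_beta_weights = TRUE,
                       adaptive_alpha_weights = TRUE, alpha0 = 1,
                       seed = 7L) {
  data <- make_arcs(n_per_class, n_classes, noise_sd, seed = seed)
  x <- as.matrix(data[, c("x", "y")])
  labels <- data$class_label + 1L
  pats <- data$patient_id
  set.seed(seed + 1L)
  p <- c(nn_init_dense(2L, hidden[1]),
         nn_init_dense(hidden[1], hidden[2]),
         nn_init_dense(hidden[2], 2L))
  names(p) <- c("W1", "b1", "W2", "b2", "W3", "b3")
  if (batchnorm) {
    bn <- nn_init_batchnorm(2L)
    p$g <- bn$gamma
    p$be <- bn$beta
  }
  forward <- function(p, train = TRUE) {
    z1 <- nn_dense_forward(x, p$W1, p$b1)
    a1 <- nn_relu(z1)
    z2 <- nn_dense_forward(a1, p$W2, p$b2)
    a2 <- nn_relu(z2)
    z3 <- nn_dense_forward(a2, p$W3, p$b3)
    if (batchnorm) {
      bn <- nn_bn_forward_train(z3, p$g, p$be)
      list(emb = bn$out, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3,
           bn = bn$cache)
    } else {
      list(emb = z3, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3)
    }
  }
  backward <- function(p, fw, d_emb) {
    g <- list()
    if (batchnorm) {
      bnb <- nn_bn_backward(d_emb, fw$bn, p$g)
      g$g <- bnb$dgamma
      g$be <- bnb$dbeta
      dz3 <- bnb$dx
    } else {
      dz3 <- d_emb
    }
    b3 <- nn_dense_backward(dz3, fw$a2, p$W3)
    g$W3 <- b3$dW
    g$b3 <- b3$db
    da2 <- nn_relu_backward(b3$dx, fw$z2)
    b2 <- nn_dense_backward(da2, fw$a1, p$W2)
    g$W2 <- b2$dW
    g$b2 <- b2$db
    da1 <- nn_relu_backward(b2$dx, fw$z1)
    b1 <- nn_dense_backward(da1, x, p$W1)
    g$W1 <- b1$dW
    g$b1 <- b1$db
    g
  }
  opt <- adam_init(p)
  emb0 <- forward(p)$emb
  sil_init <- silhouette_score(emb0, labels)$S
  alpha <- if (adaptive_alpha_weights) {
    adaptive_alpha(sil_init, alpha0)
  } else {
    alpha0
  }
  static_beta <- uniform_beta(labels)
  hist <- data.frame(step = integer(0), L_clust = numeric(0),
                     L_sep = numeric(0), L_contr = numeric(0),
                     silhouette = numeric(0))
  emb <- emb0
  for (s in seq_len(steps)) {
    fw <- forward(p)
    emb <- fw$emb
    cg <- contrastive_grad(emb, labels, pats, alpha = alpha,
                           beta = if (adaptive_beta_weights) NULL else
                             static_beta,
                           use_clustering = use_clustering,
                           use_separation = use_separation)
    grads <- backward(p, fw, cg$d_emb)
    st <- adam_step(p, grads, opt, lr)
    p <- st$params
    opt <- st$state
    sil <- if (s %% 10L == 0L || s == steps) {
      silhouette_score(emb, labels)$S
    } else {
      NA_real_
    }
    if (adaptive_alpha_weights && !is.na(sil)) {
      alpha <- adaptive_alpha(sil, alpha0)
    }
    hist <- rbind(hist, data.frame(step = s, L_clust = cg$report$L_clust,
                                   L_sep = cg$report$L_sep,
                                   L_contr = cg$report$L_contr,
                                   silhouette = sil))
  }
  emb_final <- forward(p)$emb
  sil_final <- silhouette_score(emb_final, labels)$S
  cents <- rowsum(emb_final, labels) / as.vector(table(labels))
  ratio <- if (nrow(cents) >= 2) {
    dd <- stats::dist(cents)
    max(dd) / min(dd)
  } else {
    NA_real_
  }
  list(history = hist, embeddings = emb_final, data = data,
       silhouette_init = sil_init, silhouette_final = sil_final,
       centroids = cents, centroid_distance_ratio = ratio)
}
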