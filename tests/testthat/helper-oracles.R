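# Shared fixtures and independent brute-force references used by the unit and
# acceptance suites. All fixtures are generated in code.

# small raw cohort for pipeline tests (fast: 20 samples/channel)
tiny_cohort <- function(n_benign = 2, n_malignant = 2, hw = 6,
                        class_effect = 0.4, patient_effect = 0.05,
                        noise_sd = 0.02, gain_sd = 0.05, seed = 42,
                        n_samples = 20) {
  simulate_cohort(cohort_spec(
    n_benign = n_benign, n_malignant = n_malignant, height = hw, width = hw,
    class_effect = class_effect, patient_effect = patient_effect,
    noise_sd = noise_sd, gain_sd = gain_sd,
    base_params = decay_params(n_samples = n_samples), seed = seed))
}

# naive triple-loop references for the contrastive losses and adaptive beta
naive_losses <- function(emb, labels, patients, alpha, beta_mat,
                         epsilon = 1e-8) {
  classes <- sort(unique(labels))
  K <- length(classes)
  anchors <- lapply(classes, function(c) colMeans(emb[labels == c, ,
                                                      drop = FALSE]))
  l_clust <- 0
  l_sep <- 0
  for (ci in seq_len(K)) {
    c <- classes[ci]
    for (p in unique(patients[labels == c])) {
      pm <- colMeans(emb[labels == c & patients == p, , drop = FALSE])
      l_clust <- l_clust + alpha[ci] * sum((anchors[[ci]] - pm)^2)
    }
    for (cj in seq_len(K)) {
      if (cj == ci) next
      cn <- classes[cj]
      for (p in unique(patients[labels == cn])) {
        pm <- colMeans(emb[labels == cn & patients == p, , drop = FALSE])
        l_sep <- l_sep + beta_mat[ci, cj] * sum((anchors[[ci]] - pm)^2)
      }
    }
  }
  # naive adaptive beta
  raw <- matrix(0, K, K)
  for (ci in seq_len(K)) {
    for (cj in seq_len(K)) {
      if (ci == cj) next
      raw[ci, cj] <- 1 / max(sum((anchors[[ci]] - anchors[[cj]])^2), epsilon)
    }
  }
  list(L_clust = l_clust, L_sep = l_sep,
       beta = raw / rowSums(raw))
}

# random small contrastive batch with varying class/patient structure
random_batch <- function(seed) {
  set.seed(seed)
  K <- sample(2:3, 1)
  d <- sample(2:4, 1)
  rows <- list()
  labels <- integer(0)
  patients <- integer(0)
  pid <- 0L
  for (c in seq_len(K)) {
    for (p in seq_len(sample(1:3, 1))) {
      pid <- pid + 1L
      npx <- sample(1:4, 1)
      rows[[length(rows) + 1L]] <- matrix(rnorm(npx * d, mean = c), npx, d)
      labels <- c(labels, rep(c, npx))
      patients <- c(patients, rep(pid, npx))
    }
  }
  list(emb = do.call(rbind, rows), labels = labels, patients = patients,
       K = K)
}

# brute-force silhouette from its definition
naive_silhouette <- function(emb, labels) {
  n <- nrow(emb)
  D <- as.matrix(stats::dist(emb))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- setdiff(same, i)
    if (!length(same)) {
      s[i] <- 0
      next
    }
    A <- mean(D[i, same])
    B <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- if (max(A, B) > 0) (B - A) / max(A, B) else 0
  }
  list(S = mean(s), s = s)
}
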