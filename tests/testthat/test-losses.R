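# Contrastive losses, adaptive weights, class weights, consistency and
# multitask losses -- hand examples, algebraic identities, and brute-force
# oracle equivalence.

test_that("anchors and patient means follow their definitions", {
  # one class, one patient
  an <- build_anchors(matrix(c(0, 2, 0, 0), 2, 2), c(1, 1), c("P", "P"))
  expect_equal(unname(an$anchors[1, ]), c(1, 0))
  expect_equal(unname(an$patient_means[1, ]), c(1, 0))
  # one class, two patients
  an2 <- build_anchors(matrix(c(0, 2, 0, 0), 2, 2), c(1, 1), c("P1", "P2"))
  expect_equal(unname(an2$anchors[1, ]), c(1, 0))
  expect_equal(unname(sort(an2$patient_means[, 1])), c(0, 2))
  expect_equal(sum(an2$pm_class == "1"), 2)
  # anchor equals the pixel-count-weighted mean of patient means
  set.seed(1)
  emb <- matrix(rnorm(20), 10, 2)
  labs <- rep(1, 10)
  pats <- c(rep("a", 7), rep("b", 3))
  an3 <- build_anchors(emb, labs, pats)
  expect_equal(unname(an3$anchors[1, ]),
               unname((7 * an3$patient_means["1\ra", ] +
                         3 * an3$patient_means["1\rb", ]) / 10))
  # two classes: every patient mean is positive for its class, negative for
  # the other
  an4 <- build_anchors(matrix(rnorm(8), 4, 2), c(1, 1, 2, 2),
                       c("p", "q", "p", "q"))
  expect_equal(an4$pm_class, c("1", "1", "2", "2"))
})

test_that("clustering loss evaluates its definition", {
  an <- build_anchors(matrix(c(0, 2, 0, 0), 2, 2), c(1, 1), c("P1", "P2"))
  expect_equal(clustering_loss(an, 1), 2) # 1 + 1
  expect_equal(clustering_loss(an, 3), 6) # linear in alpha
  same <- build_anchors(matrix(1, 4, 2), c(1, 1, 2, 2), c("a", "b", "a", "b"))
  expect_equal(clustering_loss(same, 1), 0)
})

test_that("separation loss evaluates its definition", {
  an <- build_anchors(matrix(c(0, 3, 0, 0), 2, 2), c(1, 2), c("P1", "P2"))
  expect_equal(separation_loss(an, 1), 18) # 9 + 9
  # doubling all coordinates quadruples the loss
  an2 <- build_anchors(matrix(c(0, 6, 0, 0), 2, 2), c(1, 2), c("P1", "P2"))
  expect_equal(separation_loss(an2, 1), 72)
  co <- build_anchors(matrix(1, 4, 2), c(1, 1, 2, 2), c("a", "b", "a", "b"))
  expect_equal(separation_loss(co, 1), 0)
  single <- build_anchors(matrix(rnorm(4), 2, 2), c(1, 1), c("a", "b"))
  expect_warning(expect_equal(separation_loss(single, 1), 0), "single-class")
})

test_that("adaptive beta inverts squared distances and normalizes per anchor", {
  an <- build_anchors(matrix(c(0, 1, 3, 0, 0, 0), 3, 2), 1:3, c("a", "b", "c"))
  b <- adaptive_beta(an)
  expect_equal(unname(b[1, 2:3]), c(0.9, 0.1)) # raw (1, 1/9) normalized
  expect_equal(unname(rowSums(b)), rep(1, 3), tolerance = 1e-9)
  two <- build_anchors(matrix(c(0, 5, 0, 0), 2, 2), 1:2, c("a", "b"))
  expect_equal(unname(adaptive_beta(two)[1, 2]), 1) # singleton normalization
  # equilateral triangle: equal weights within each anchor class
  tri <- build_anchors(matrix(c(0, 1, 0.5, 0, 0, sqrt(3) / 2), 3, 2), 1:3,
                       c("a", "b", "c"))
  expect_equal(unname(adaptive_beta(tri)[1, 2:3]), c(0.5, 0.5),
               tolerance = 1e-9)
  # coincident means are guarded by epsilon, not infinite
  coin <- build_anchors(matrix(0, 3, 2), 1:3, c("a", "b", "c"))
  expect_true(all(is.finite(adaptive_beta(coin))))
})

test_that("adaptive alpha follows the linear silhouette schedule", {
  expect_equal(adaptive_alpha(0, 1), 1)
  expect_equal(adaptive_alpha(1, 1), 0)
  expect_equal(adaptive_alpha(0.5, 1), 0.5)
  expect_equal(adaptive_alpha(-0.4, 2), 2) # clamped below 0
  expect_equal(adaptive_alpha(1.5, 2), 0) # clamped above 1
  s <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(vapply(s, adaptive_alpha, numeric(1), alpha0 = 1))
                  <= 1e-12))
})

test_that("total contrastive loss keeps the additive identity", {
  an <- build_anchors(matrix(c(0, 2, 10, 13, 0, 0, 0, 0), 4, 2),
                      c(1, 1, 2, 2), c("P1", "P2", "P3", "P4"))
  r <- contrastive_total(an, alpha = 1, beta = 1)
  expect_equal(r$L_contr, r$L_clust - r$L_sep)
  same <- build_anchors(matrix(2, 4, 2), c(1, 1, 2, 2), c("a", "b", "a", "b"))
  r0 <- contrastive_total(same)
  expect_equal(r0$L_contr, 0)
  # L_sep = 0 => L_contr = L_clust
  r1 <- contrastive_total(an, alpha = 1, beta = 0)
  expect_equal(r1$L_contr, r1$L_clust)
})

test_that("balanced class weights follow n/(K*n_c)", {
  w <- balanced_class_weights(c(0, 0, 0, 1))
  expect_equal(unname(w), c(4 / 6, 2), tolerance = 1e-12)
  wb <- balanced_class_weights(rep(c("a", "b", "c"), 5))
  expect_equal(unname(wb), rep(1, 3))
  # weighted mean of per-sample weights under the empirical distribution is 1
  labs <- sample(c(1, 1, 1, 2, 3), 60, replace = TRUE)
  w3 <- balanced_class_weights(labs)
  expect_equal(mean(w3[as.character(labs)]), 1, tolerance = 1e-12)
  expect_error(balanced_class_weights(integer(0)), "empty")
})

test_that("consistency loss penalizes exactly the contradiction patterns", {
  big <- 40
  # confidently consistent: malignant predicted malignant + lesion
  diag_l <- matrix(c(-big, big), 1)
  delin_l <- matrix(c(-big, big), 1)
  expect_lt(consistency_loss(diag_l, delin_l, 3L), 1e-3)
  # malignant, diagnosis says malignant w.p. ~1, delineation healthy with
  # lesion probability p => contribution -log(p)
  p <- 0.3
  delin_p <- matrix(log(c(1 - p, p)), 1)
  expect_equal(consistency_loss(diag_l, delin_p, 3L), -log(p),
               tolerance = 1e-9)
  # healthy, delineation says healthy, diagnosis malignant w.p. q =>
  # contribution -log(1 - q)
  q <- 0.8
  diag_q <- matrix(log(c(1 - q, q)), 1)
  delin_h <- matrix(c(big, -big), 1)
  expect_equal(consistency_loss(diag_q, delin_h, 1L), -log(1 - q),
               tolerance = 1e-9)
  # benign samples and non-triggering predictions contribute nothing
  expect_equal(consistency_loss(diag_q, delin_p, 2L), 0)
  # averaging over contributing samples
  dl <- rbind(diag_l, diag_l)
  dp <- rbind(delin_p, delin_p)
  expect_equal(consistency_loss(dl, dp, c(3L, 2L)), -log(p), tolerance = 1e-9)
})

test_that("multitask loss keeps the additive identity and known values", {
  n <- 4
  zero <- matrix(0, n, 2) # uniform predictions
  r <- multitask_loss(zero, zero, rep(1:2, 2), rep(1:2, 2),
                      contrastive_labels = rep(2L, n))
  expect_equal(r$CE_diag, log(2), tolerance = 1e-9)
  expect_equal(r$CE_delin, log(2), tolerance = 1e-9)
  expect_equal(r$L_MT, r$CE_diag + r$CE_delin + r$L_reg)
  expect_equal(r$L_MT, 2 * log(2), tolerance = 1e-9)
  # perfect confident consistent predictions
  big <- 40
  dl <- rbind(c(big, -big), c(-big, big))
  r2 <- multitask_loss(dl, dl, c(1L, 2L), c(1L, 2L),
                       contrastive_labels = c(1L, 3L))
  expect_lt(r2$L_MT, 1e-3)
  # sample weights shift the weighted mean
  r3 <- multitask_loss(zero, zero, c(1L, 1L, 1L, 2L), rep(1:2, 2),
                       diag_weights = c(1, 1, 1, 9))
  expect_equal(r3$CE_diag, log(2), tolerance = 1e-9) # uniform: same nll
})

test_that("vectorized losses and beta match brute-force references", {
  for (i in 1:50) {
    b <- random_batch(i)
    alpha <- runif(b$K, 0.2, 2)
    beta_m <- matrix(runif(b$K * b$K), b$K, b$K)
    diag(beta_m) <- 0
    ref <- naive_losses(b$emb, b$labels, b$patients, alpha, beta_m)
    an <- build_anchors(b$emb, b$labels, b$patients)
    expect_equal(clustering_loss(an, alpha), ref$L_clust, tolerance = 1e-6)
    expect_equal(separation_loss(an, beta_m), ref$L_sep, tolerance = 1e-6)
    expect_equal(unname(adaptive_beta(an)), unname(ref$beta),
                 tolerance = 1e-6)
    expect_equal(unname(rowSums(adaptive_beta(an))), rep(1, b$K),
                 tolerance = 1e-9)
    # the internal gradient path reports identical loss values
    cg <- flimcontrast:::contrastive_grad(b$emb, b$labels, b$patients,
                                          alpha = alpha, beta = beta_m)
    expect_equal(cg$report$L_clust, ref$L_clust, tolerance = 1e-6)
    expect_equal(cg$report$L_sep, ref$L_sep, tolerance = 1e-6)
  }
})

test_that("one gradient step tightens clusters and separates classes", {
  # two classes, two patients each, one pixel per patient
  emb <- rbind(c(-0.5, 0), c(0.5, 0), c(3.5, 0), c(4.5, 0))
  labels <- c(1, 1, 2, 2)
  pats <- c("a", "b", "c", "d")
  # beta < alpha so the clustering pull dominates the (distance-independent)
  # within-class differential of the separation term
  cg <- flimcontrast:::contrastive_grad(emb, labels, pats, alpha = 1,
                                        beta = 0.3)
  emb2 <- emb - 0.01 * cg$d_emb
  gap <- function(e) {
    an <- build_anchors(e, labels, pats)
    ci <- match(an$pm_class, an$classes)
    within <- sum((an$patient_means - an$anchors[ci, ])^2)
    between <- sum((an$anchors[1, ] - an$anchors[2, ])^2)
    c(within, between)
  }
  g1 <- gap(emb)
  g2 <- gap(emb2)
  expect_lt(g2[1], g1[1]) # within-class anchor-patient distance shrinks
  expect_gt(g2[2], g1[2]) # between-class anchor distance grows
})
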