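# Preprocessing chain: spatial median filtering, SNR masking, and per-pixel
# transformation of raw decays into 900-dimensional network inputs
# (inversion -> zero-padding to 300 samples/channel -> channel calibration ->
# concatenation -> sum-to-100 normalization).

# row-wise median of a small-column matrix via a vectorized bubble network
#' @keywords internal
row_median_small <- function(v) {
  kk <- ncol(v)
  for (pass in seq_len(kk - 1L)) {
    for (j in seq_len(kk - pass)) {
      a <- v[, j]
      b <- v[, j + 1L]
      v[, j] <- pmin(a, b)
      v[, j + 1L] <- pmax(a, b)
    }
  }
  if (kk %% 2L == 1L) v[, (kk + 1L) %/% 2L] else
    (v[, kk %/% 2L] + v[, kk %/% 2L + 1L]) / 2
}

# clipped-window 2D median of one matrix; window is odd
#' @keywords internal
median_filter_2d <- function(m, window) {
  if (window == 1L) return(m)
  k <- (window - 1L) %/% 2L
  H <- nrow(m)
  W <- ncol(m)
  if (window == 3L && H >= 3 && W >= 3) {
    # fully vectorized: interior (9 neighbors), edges (6), corners (4)
    out <- m
    ri <- 2:(H - 1)
    ci <- 2:(W - 1)
    v <- do.call(cbind, lapply(-1:1, function(dx) {
      cbind(as.vector(m[ri - 1, ci + dx]), as.vector(m[ri, ci + dx]),
            as.vector(m[ri + 1, ci + dx]))
    }))
    out[ri, ci] <- matrix(row_median_small(v), length(ri), length(ci))
    for (r in c(1L, H)) { # top/bottom edges
      rr <- max(1, r - 1):min(H, r + 1)
      v <- do.call(cbind, lapply(-1:1, function(dx) t(m[rr, ci + dx])))
      out[r, ci] <- row_median_small(v)
    }
    for (cc in c(1L, W)) { # left/right edges
      ccr <- max(1, cc - 1):min(W, cc + 1)
      v <- do.call(cbind, lapply(ccr, function(j) {
        cbind(m[ri - 1, j], m[ri, j], m[ri + 1, j])
      }))
      out[ri, cc] <- row_median_small(v)
    }
    for (r in c(1L, H)) { # corners
      for (cc in c(1L, W)) {
        out[r, cc] <- stats::median(m[max(1, r - k):min(H, r + k),
                                      max(1, cc - k):min(W, cc + k)])
      }
    }
    return(out)
  }
  out <- m
  for (j in seq_len(W)) {
    cj <- max(1, j - k):min(W, j + k)
    for (i in seq_len(H)) {
      out[i, j] <- stats::median(m[max(1, i - k):min(H, i + k), cj])
    }
  }
  out
}

#' Median filter a maFLIM image
#'
#' Applies, for every (channel, time) slice independently, a spatial median
#' over a `window x window` neighborhood clipped at the image borders, so the
#' image plane size is unchanged.
#'
#' @param image A `maflim_image`.
#' @param window Odd window size (>= 1); 1 is the identity.
#' @return The filtered `maflim_image`.
#' @export
median_filter <- function(image, window = 3L) {
  stopifnot(inherits(image, "maflim_image"))
  window <- as.integer(window)
  if (window < 1 || window %% 2L == 0L) {
    stop("window must be an odd integer >= 1")
  }
  if (window == 1L) return(image)
  d <- dim(image$data)
  for (k in seq_len(d[3])) {
    for (ti in seq_len(d[4])) {
      image$data[, , k, ti] <- median_filter_2d(image$data[, , k, ti], window)
    }
  }
  image
}

#' Compute a per-pixel SNR mask
#'
#' SNR is defined per pixel as the peak absolute amplitude over all channels
#' divided by the standard deviation of the final 10% of samples of the
#' weakest channel (the channel with the smallest peak), floored at machine
#' epsilon and capped at `snr_cap`. The mask is `TRUE` (keep) where
#' `SNR >= threshold`.
#'
#' @param image A `maflim_image`.
#' @param threshold Non-negative SNR threshold.
#' @param snr_cap Upper cap guarding noiseless tails.
#' @return Logical `height x width` matrix.
#' @export
compute_snr_mask <- function(image, threshold = 2, snr_cap = 1e12) {
  stopifnot(inherits(image, "maflim_image"), threshold >= 0)
  d <- dim(image$data)
  n_px <- d[1] * d[2]
  L <- d[4]
  tail_idx <- seq.int(max(1L, L - ceiling(L / 10) + 1L), L)
  # per pixel per channel: peak |amplitude|
  row_max <- function(m) {
    out <- m[, 1]
    for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
    out
  }
  row_sd <- function(m) {
    nc <- ncol(m)
    if (nc < 2) return(rep(0, nrow(m)))
    rs <- rowSums(m)
    sqrt(pmax(rowSums(m * m) - rs * rs / nc, 0) / (nc - 1))
  }
  peaks <- vapply(seq_len(d[3]), function(k) {
    row_max(matrix(abs(image$data[, , k, ]), n_px, L))
  }, numeric(n_px))
  peak_all <- row_max(peaks)
  weakest <- max.col(-peaks, ties.method = "first")
  tail_sd <- numeric(n_px)
  for (k in seq_len(d[3])) {
    sel <- weakest == k
    if (!any(sel)) next
    flat <- matrix(image$data[, , k, ], n_px, L)[sel, tail_idx, drop = FALSE]
    tail_sd[sel] <- row_sd(flat)
  }
  snr <- pmin(peak_all / pmax(tail_sd, .Machine$double.eps), snr_cap)
  matrix(snr >= threshold, d[1], d[2])
}

#' Preprocess one raw pixel decay
#'
#' Applies, in order: (1) inversion (negation) of each channel decay;
#' (2) zero-padding each channel at its end to `per_channel_length` samples;
#' (3) multiplication of each channel by its calibration factor;
#' (4) concatenation of the three channels; (5) scaling so the concatenated
#' vector sums to exactly 100.
#'
#' @param raw A raw `decay_pixel` (three channel segments).
#' @param calibration Positive 3-vector of per-channel calibration factors.
#' @param per_channel_length Padded channel length (default 300, so the
#'   network input is 3 x 300 = 900-dimensional).
#' @return A preprocessed `decay_pixel` whose `values` vector has length
#'   `3 * per_channel_length` and sums to 100.
#' @export
preprocess_pixel <- function(raw, calibration = c(1, 1, 1),
                             per_channel_length = 300L) {
  stopifnot(inherits(raw, "decay_pixel"), identical(raw$stage, "raw"),
            length(raw$channels) == 3, length(calibration) == 3,
            all(calibration > 0))
  L <- as.integer(per_channel_length)
  segs <- lapply(seq_len(3), function(k) {
    ch <- -raw$channels[[k]] # inversion
    if (length(ch) > L) {
      stop("channel ", k, " has ", length(ch),
           " samples; cannot pad to ", L)
    }
    c(ch, rep(0, L - length(ch))) * calibration[k]
  })
  v <- unlist(segs, use.names = FALSE)
  s <- sum(v)
  if (abs(s) < .Machine$double.eps * length(v)) {
    stop("degenerate pixel: zero total signal, cannot normalize")
  }
  structure(list(values = v * (100 / s), per_channel_length = L,
                 stage = "preprocessed"),
            class = "decay_pixel")
}

#' Run the image-level preprocessing stages
#'
#' Median filtering followed by SNR masking; the stored decays themselves are
#' left raw (per-pixel preprocessing happens in
#' [image_to_training_pixels()]).
#'
#' @param image A `maflim_image`.
#' @param median_window Odd spatial window for [median_filter()].
#' @param snr_threshold Threshold for [compute_snr_mask()].
#' @return The image with filtered data and `snr_mask` set.
#' @export
preprocess_image <- function(image, median_window = 3L, snr_threshold = 2) {
  image <- median_filter(image, median_window)
  image$snr_mask <- compute_snr_mask(image, snr_threshold)
  image
}

# label mapping: pure function of (tissue type, diagnosis)
# contrastive: 1 = healthy, 2 = benign, 3 = malignant (dysplasia and SCC both
# map to malignant); delineation: 2 = lesion, 1 = healthy;
# diagnosis: 2 = malignant, 1 = benign-or-healthy
#' @keywords internal
map_labels <- function(tissue_type, diagnosis) {
  if (tissue_type == "healthy") {
    return(list(contrastive = 1L, delineation = 1L, diagnosis = 1L))
  }
  if (tissue_type != "lesion") stop("unknown tissue type: ", tissue_type)
  if (is.null(diagnosis) || diagnosis %in% c("none", NA)) {
    stop("lesion image lacks a diagnosis")
  }
  if (diagnosis == "benign") {
    list(contrastive = 2L, delineation = 2L, diagnosis = 1L)
  } else if (diagnosis %in% c("malignant", "dysplasia", "SCC")) {
    list(contrastive = 3L, delineation = 2L, diagnosis = 2L)
  } else {
    stop("unknown diagnosis: ", diagnosis)
  }
}

#' Convert a masked image into per-pixel training records
#'
#' Preprocesses every unmasked pixel (vectorized equivalent of
#' [preprocess_pixel()]) and attaches the three task labelings derived from
#' the image metadata: the 3-class contrastive label (healthy / benign /
#' malignant, dysplasia and SCC grouped as malignant), the delineation label
#' (lesion vs healthy), and the diagnosis label (malignant vs
#' benign-or-healthy).
#'
#' @param image A `maflim_image` that has been through [preprocess_image()]
#'   (it must carry an `snr_mask`).
#' @param per_channel_length Padded channel length (default 300).
#' @param image_id Optional identifier stored with each record.
#' @return An object of class `pixel_dataset`: list with matrix `x`
#'   (`n x 3*per_channel_length`), integer vectors `contrastive`,
#'   `delineation`, `diagnosis`, `patient_id`, and character `image_id`.
#' @export
image_to_training_pixels <- function(image, per_channel_length = 300L,
                                     image_id = NULL) {
  stopifnot(inherits(image, "maflim_image"))
  if (is.null(image$snr_mask)) {
    stop("image has no SNR mask; run preprocess_image() first")
  }
  labs <- map_labels(image$tissue_type, image$diagnosis)
  if (is.null(image_id)) {
    image_id <- paste0("p", image$patient_id, "_", image$tissue_type)
  }
  d <- dim(image$data)
  keep <- which(as.vector(image$snr_mask))
  L <- as.integer(per_channel_length)
  if (length(keep) == 0) {
    return(new_pixel_dataset(matrix(0, 0, 3L * L), integer(0), integer(0),
                             integer(0), integer(0), character(0)))
  }
  n_px <- d[1] * d[2]
  x <- matrix(0, length(keep), 3L * L)
  for (k in 1:3) {
    flat <- matrix(image$data[, , k, ], n_px, d[4])[keep, , drop = FALSE]
    x[, (k - 1L) * L + seq_len(d[4])] <- -flat * image$calibration[k]
  }
  s <- rowSums(x)
  degen <- abs(s) < .Machine$double.eps * ncol(x)
  if (any(degen)) {
    stop(sum(degen), " degenerate pixel(s) with zero total signal")
  }
  x <- x * (100 / s)
  n <- length(keep)
  new_pixel_dataset(x,
                    contrastive = rep(labs$contrastive, n),
                    delineation = rep(labs$delineation, n),
                    diagnosis = rep(labs$diagnosis, n),
                    patient_id = rep(image$patient_id, n),
                    image_id = rep(image_id, n))
}

#' @keywords internal
new_pixel_dataset <- function(x, contrastive, delineation, diagnosis,
                              patient_id, image_id) {
  structure(list(x = x, contrastive = as.integer(contrastive),
                 delineation = as.integer(delineation),
                 diagnosis = as.integer(diagnosis),
                 patient_id = patient_id, image_id = image_id),
            class = "pixel_dataset")
}

#' Combine pixel datasets
#'
#' @param ... `pixel_dataset` objects.
#' @return A single concatenated `pixel_dataset`.
#' @export
bind_pixel_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && is.list(ds[[1]]) &&
      !inherits(ds[[1]], "pixel_dataset")) {
    ds <- ds[[1]]
  }
  stopifnot(all(vapply(ds, inherits, logical(1), "pixel_dataset")))
  new_pixel_dataset(do.call(rbind, lapply(ds, `[[`, "x")),
                    unlist(lapply(ds, `[[`, "contrastive")),
                    unlist(lapply(ds, `[[`, "delineation")),
                    unlist(lapply(ds, `[[`, "diagnosis")),
                    unlist(lapply(ds, `[[`, "patient_id")),
                    unlist(lapply(ds, `[[`, "image_id")))
}

#' Preprocess a whole cohort into one pixel dataset
#'
#' @param cohort A `maflim_cohort`.
#' @param median_window,snr_threshold See [preprocess_image()].
#' @param per_channel_length Padded channel length.
#' @return A `pixel_dataset` covering every unmasked pixel of every image.
#' @export
pixels_from_cohort <- function(cohort, median_window = 3L, snr_threshold = 2,
                               per_channel_length = 300L) {
  stopifnot(inherits(cohort, "maflim_cohort"))
  parts <- list()
  for (ps in cohort) {
    for (tt in c("lesion", "healthy")) {
      img <- preprocess_image(ps[[tt]], median_window, snr_threshold)
      parts[[length(parts) + 1L]] <-
        image_to_training_pixels(img, per_channel_length)
    }
  }
  bind_pixel_datasets(parts)
}

# subset rows of a pixel dataset
#' @keywords internal
subset_pixels <- function(ds, idx) {
  new_pixel_dataset(ds$x[idx, , drop = FALSE], ds$contrastive[idx],
                    ds$delineation[idx], ds$diagnosis[idx],
                    ds$patient_id[idx], ds$image_id[idx])
}
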