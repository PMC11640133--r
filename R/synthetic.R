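# Synthetic data generators: 2D interleaved-arc ("moons") datasets for loss
# validation, and maFLIM cohorts with biexponential channel decays,
# class-dependent lifetime shifts, and patient-level nuisance variability.

#' Generate interleaved 2D arcs with synthetic patient grouping
#'
#' Two classes reproduce the classic two-moons construction: an upper arc
#' `(cos t, sin t)` and a lower arc `(1 - cos t, 0.5 - sin t)`, `t` in
#' `[0, pi]`. The three-class variant adds a copy of the upper arc translated
#' by `(2, 0)` so it interleaves with the lower arc from the other side,
#' preserving the nonlinearly separable difficulty. Points are assigned
#' synthetic patient ids in contiguous blocks so patient-mean machinery can be
#' exercised on 2D data.
#'
#' @param n_per_class Points per class (may be 0).
#' @param n_classes 2 or 3.
#' @param noise_sd Gaussian noise added to both coordinates.
#' @param seed Integer seed; identical seeds give identical output.
#' @param patients_per_class Number of contiguous patient blocks per class.
#' @return A data.frame with columns `x`, `y`, `class_label` (0-based
#'   integer), `patient_id` (integer, unique across classes).
#' @export
make_arcs <- function(n_per_class, n_classes = 2L, noise_sd = 0.1, seed = 1L,
                      patients_per_class = 4L) {
  if (!n_classes %in% c(2L, 3L)) {
    stop("n_classes must be 2 or 3")
  }
  stopifnot(n_per_class >= 0, noise_sd >= 0, patients_per_class >= 1)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      class_label = integer(0), patient_id = integer(0))
  if (n_per_class == 0) return(empty)
  set.seed(seed)
  t <- seq(0, pi, length.out = n_per_class)
  arcs <- list(
    cbind(cos(t), sin(t)),
    cbind(1 - cos(t), 0.5 - sin(t)),
    cbind(2 + cos(t), sin(t))
  )[seq_len(n_classes)]
  out <- do.call(rbind, lapply(seq_along(arcs), function(ci) {
    xy <- arcs[[ci]] + matrix(stats::rnorm(2 * n_per_class, 0, noise_sd),
                              ncol = 2)
    blocks <- rep(seq_len(patients_per_class), length.out = n_per_class)
    blocks <- sort(blocks) # contiguous
    data.frame(x = xy[, 1], y = xy[, 2],
               class_label = ci - 1L,
               patient_id = (ci - 1L) * patients_per_class + blocks - 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Biexponential decay model parameters
#'
#' One parameter set per emission channel. Each channel's noiseless decay is
#' `gain * (A1 * exp(-t / tau1) + A2 * exp(-t / tau2))` sampled at
#' `t = 0, dt, ..., (n_samples - 1) * dt` nanoseconds. Defaults loosely follow
#' the three maFLIM emission bands (collagen, NADH, FAD): a long and a short
#' lifetime component per channel, 0.25 ns resolution.
#'
#' @param A1,A2 Amplitude vectors (one entry per channel, arbitrary photon
#'   units, >= 0).
#' @param tau1,tau2 Lifetime vectors in ns (> 0).
#' @param n_samples Samples recorded per channel.
#' @param dt Time step in ns.
#' @param noise_sd Standard deviation of additive Gaussian noise per sample.
#' @param gain Detector gain (> 0), removed later by sum normalization.
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(A1 = c(6, 7, 5), A2 = c(4, 3, 5),
                         tau1 = c(5.0, 2.5, 2.8), tau2 = c(1.2, 0.5, 0.4),
                         n_samples = 250L, dt = 0.25, noise_sd = 0,
                         gain = 1) {
  k <- length(A1)
  stopifnot(length(A2) == k, length(tau1) == k, length(tau2) == k)
  if (any(tau1 <= 0) || any(tau2 <= 0)) stop("lifetimes must be positive")
  if (any(A1 < 0) || any(A2 < 0)) stop("amplitudes must be non-negative")
  if (dt <= 0) stop("time step must be positive")
  if (gain <= 0) stop("gain must be positive")
  stopifnot(n_samples >= 1, noise_sd >= 0)
  structure(list(A1 = A1, A2 = A2, tau1 = tau1, tau2 = tau2,
                 n_samples = as.integer(n_samples), dt = dt,
                 noise_sd = noise_sd, gain = gain),
            class = "decay_params")
}

# noiseless decay curves, one column per channel (positive-going)
#' @keywords internal
clean_decays <- function(params) {
  t <- (seq_len(params$n_samples) - 1) * params$dt
  vapply(seq_along(params$A1), function(k) {
    params$gain * (params$A1[k] * exp(-t / params$tau1[k]) +
                     params$A2[k] * exp(-t / params$tau2[k]))
  }, numeric(params$n_samples))
}

#' Simulate one raw pixel decay
#'
#' Samples the biexponential model per channel, adds Gaussian noise, and
#' stores the result negated (negative-going), matching the acquisition
#' convention that the preprocessing inversion step undoes.
#'
#' @param params A [decay_params()] object.
#' @param seed Integer seed for the noise.
#' @return An object of class `decay_pixel` with `channels` (list of numeric
#'   vectors) and `stage = "raw"`.
#' @export
simulate_pixel_decay <- function(params, seed = 1L) {
  stopifnot(inherits(params, "decay_params"))
  set.seed(seed)
  y <- clean_decays(params)
  if (params$noise_sd > 0) {
    y <- y + matrix(stats::rnorm(length(y), 0, params$noise_sd), nrow(y))
  }
  structure(list(channels = lapply(seq_len(ncol(y)), function(k) -y[, k]),
                 stage = "raw"),
            class = "decay_pixel")
}

#' Synthetic maFLIM cohort specification
#'
#' Defines a cohort in which every patient contributes exactly two images
#' (one lesion, one healthy). Malignant lesions differ from benign/healthy
#' tissue by shortened NADH/FAD-channel lifetimes (`class_effect`); every
#' patient carries a multiplicative lognormal lifetime perturbation shared by
#' both of their images (`patient_effect`), emulating inter-patient nuisance
#' variability.
#'
#' @param n_benign,n_malignant Patients per diagnosis class.
#' @param height,width Image size in pixels.
#' @param class_effect Relative shortening of channel-2/3 lifetimes on
#'   malignant lesion images (0 = no class signal).
#' @param benign_effect Relative shortening of channel-1 (collagen) lifetimes
#'   on benign lesion images, so benign tissue is distinguishable from
#'   healthy tissue on a different channel than the malignant effect.
#'   Defaults to `class_effect / 2` (hence 0 whenever the class effect is 0).
#' @param patient_effect Standard deviation of the per-patient log-lifetime
#'   perturbation (0 = no nuisance variation).
#' @param noise_sd Per-sample Gaussian noise.
#' @param gain_sd Standard deviation of the per-image log-gain nuisance.
#' @param base_params A [decay_params()] giving the healthy-tissue decay model.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_benign, n_malignant, height = 160L, width = 160L,
                        class_effect = 0.3, benign_effect = class_effect / 2,
                        patient_effect = 0.1, noise_sd = 0.05, gain_sd = 0.1,
                        base_params = decay_params(), seed = 1L) {
  if (n_benign + n_malignant == 0) {
    stop("at least one patient is required")
  }
  stopifnot(n_benign >= 0, n_malignant >= 0, height >= 1, width >= 1,
            class_effect >= 0, benign_effect >= 0, patient_effect >= 0,
            noise_sd >= 0, gain_sd >= 0,
            inherits(base_params, "decay_params"))
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 height = as.integer(height), width = as.integer(width),
                 class_effect = class_effect, benign_effect = benign_effect,
                 patient_effect = patient_effect,
                 noise_sd = noise_sd, gain_sd = gain_sd,
                 base_params = base_params, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @keywords internal
new_maflim_image <- function(data, patient_id, tissue_type, diagnosis,
                             calibration = c(1, 1, 1), snr_mask = NULL) {
  stopifnot(length(dim(data)) == 4, dim(data)[3] == 3,
            all(calibration > 0))
  structure(list(data = data, patient_id = patient_id,
                 tissue_type = tissue_type, diagnosis = diagnosis,
                 calibration = calibration, snr_mask = snr_mask),
            class = "maflim_image")
}

#' Simulate a synthetic maFLIM cohort
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `maflim_cohort`: a list of `patient_sample`
#'   objects, each holding `patient_id`, `diagnosis`, and `lesion` / `healthy`
#'   `maflim_image`s (arrays of shape height x width x 3 x n_samples, raw
#'   negative-going decays).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  bp <- spec$base_params
  n_px <- spec$height * spec$width
  L <- bp$n_samples
  diagnoses <- c(rep("benign", spec$n_benign),
                 rep("malignant", spec$n_malignant))
  samples <- vector("list", length(diagnoses))
  for (i in seq_along(diagnoses)) {
    dx <- diagnoses[i]
    # patient nuisance: one lognormal lifetime factor per channel, shared
    # across both of this patient's images
    pfac <- exp(stats::rnorm(3, 0, spec$patient_effect))
    make_image <- function(tissue) {
      p <- bp
      p$tau1 <- p$tau1 * pfac
      p$tau2 <- p$tau2 * pfac
      if (tissue == "lesion" && dx == "malignant" && spec$class_effect > 0) {
        sh <- 1 - spec$class_effect
        p$tau1[2:3] <- p$tau1[2:3] * sh
        p$tau2[2:3] <- p$tau2[2:3] * sh
      }
      if (tissue == "lesion" && dx == "benign" && spec$benign_effect > 0) {
        sh <- 1 - spec$benign_effect
        p$tau1[1] <- p$tau1[1] * sh
        p$tau2[1] <- p$tau2[1] * sh
      }
      gain <- if (spec$gain_sd > 0) exp(stats::rnorm(1, 0, spec$gain_sd)) else 1
      y <- clean_decays(p) * gain # L x 3
      arr <- array(0, dim = c(spec$height, spec$width, 3L, L))
      for (k in 1:3) {
        plane <- matrix(rep(y[, k], each = n_px), nrow = n_px)
        if (spec$noise_sd > 0) {
          plane <- plane + matrix(stats::rnorm(n_px * L, 0, spec$noise_sd),
                                  nrow = n_px)
        }
        arr[, , k, ] <- array(plane, dim = c(spec$height, spec$width, L))
      }
      new_maflim_image(-arr, patient_id = i, tissue_type = tissue,
                       diagnosis = if (tissue == "lesion") dx else "none")
    }
    samples[[i]] <- structure(
      list(patient_id = i, diagnosis = dx,
           lesion = make_image("lesion"), healthy = make_image("healthy")),
      class = "patient_sample")
  }
  structure(samples, class = "maflim_cohort", spec = spec)
}

#' @export
print.maflim_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("maFLIM cohort:", length(x), "patients (",
      spec$n_benign, "benign,", spec$n_malignant, "malignant ),",
      spec$height, "x", spec$width, "px,",
      spec$base_params$n_samples, "samples/channel\n")
  invisible(x)
}
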