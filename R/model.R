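# Encoder + task-head architecture.
#
# Encoder: four fully connected layers (900 -> 512 -> 256 -> 128 -> 16 by
# default), each followed by batch normalization and ReLU. The contrastive
# loss attaches to the fourth layer's output AFTER batch normalization and
# BEFORE the ReLU (the "embedding tap"); the ReLU-activated bottleneck feeds
# the heads. Heads: three fully connected layers (16 -> 21 -> 14 -> 2) with
# dropout inside the first two, ending in a 2-node classification layer.
# The default configuration carries 630,814 trainable parameters (weights,
# biases, and batch-norm scale/shift), which build_model() validates.

#' Encoder configuration
#'
#' @param input_dim Length of a preprocessed pixel vector (3 channels x 300
#'   samples = 900 by default).
#' @param widths Widths of the first three fully connected layers.
#' @param bottleneck Width of the fourth (bottleneck) layer on which the
#'   contrastive loss operates; 16 for the full model, 2 for the
#'   visualization variant.
#' @param bn_eps,bn_momentum Batch-normalization numerical constants.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(input_dim = 900L, widths = c(512L, 256L, 128L),
                           bottleneck = 16L, bn_eps = 1e-5,
                           bn_momentum = 0.1) {
  stopifnot(length(widths) == 3, all(widths >= 1), input_dim >= 1,
            bottleneck %in% c(2L, 16L) || bottleneck >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 widths = as.integer(widths),
                 bottleneck = as.integer(bottleneck),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "encoder_config")
}

#' Task-head configuration
#'
#' Both heads (diagnosis, margin delineation) share this shape: three fully
#' connected layers ending in a 2-node classification layer, with dropout
#' regularization in the hidden layers.
#'
#' @param widths Widths of the two hidden layers.
#' @param dropout Drop probability used during training.
#' @return An object of class `head_config`.
#' @export
head_config <- function(widths = c(21L, 14L), dropout = 0.5) {
  stopifnot(length(widths) == 2, all(widths >= 1),
            dropout >= 0, dropout < 1)
  structure(list(widths = as.integer(widths), dropout = dropout),
            class = "head_config")
}

#' Build the full model (encoder plus two task heads)
#'
#' @param encoder An [encoder_config()].
#' @param head A [head_config()].
#' @param seed Integer seed for weight initialization.
#' @param check_parameter_count If `TRUE` (default when both configs are at
#'   their defaults), fail unless the trainable-parameter total equals
#'   630,814, the architecture's reference size.
#' @return An object of class `flim_model`: flat parameter list, batch-norm
#'   running statistics, and the configuration.
#' @export
build_model <- function(encoder = encoder_config(), head = head_config(),
                        seed = 1L, check_parameter_count = NULL) {
  set.seed(seed)
  dims <- c(encoder$input_dim, encoder$widths, encoder$bottleneck)
  params <- list()
  stats <- list()
  for (i in 1:4) {
    d <- nn_init_dense(dims[i], dims[i + 1])
    bn <- nn_init_batchnorm(dims[i + 1])
    params[[paste0("e", i, ".W")]] <- d$W
    params[[paste0("e", i, ".b")]] <- d$b
    params[[paste0("e", i, ".g")]] <- bn$gamma
    params[[paste0("e", i, ".be")]] <- bn$beta
    stats[[paste0("e", i, ".rm")]] <- rep(0, dims[i + 1])
    stats[[paste0("e", i, ".rv")]] <- rep(1, dims[i + 1])
  }
  hdims <- c(encoder$bottleneck, head$widths, 2L)
  for (h in c("d", "l")) { # d = diagnosis head, l = delineation head
    for (i in 1:3) {
      d <- nn_init_dense(hdims[i], hdims[i + 1])
      params[[paste0("h", h, i, ".W")]] <- d$W
      params[[paste0("h", h, i, ".b")]] <- d$b
    }
  }
  model <- structure(list(params = params, stats = stats,
                          encoder = encoder, head = head),
                     class = "flim_model")
  default_cfg <- identical(unclass(encoder)[1:3],
                           unclass(encoder_config())[1:3]) &&
    identical(head$widths, head_config()$widths)
  if (is.null(check_parameter_count)) check_parameter_count <- default_cfg
  if (check_parameter_count && count_parameters(model) != 630814L) {
    stop("architecture mismatch: expected 630,814 trainable parameters, got ",
         count_parameters(model))
  }
  model
}

#' Count trainable parameters
#'
#' Counts all weights, biases, and batch-normalization scale/shift parameters
#' of the encoder and both heads. The default configuration totals 630,814.
#'
#' @param model A `flim_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "flim_model"))
  as.integer(sum(vapply(model$params, length, numeric(1))))
}

#' Encoder forward pass
#'
#' @param model A `flim_model`.
#' @param x Numeric matrix, one preprocessed pixel per row.
#' @param mode `"embedding"` returns the contrastive tap (fourth layer after
#'   batch normalization, before ReLU); `"features"` returns the activated
#'   bottleneck fed to the heads.
#' @param train Use batch statistics (`TRUE`) or running statistics (`FALSE`).
#' @param keep_cache Internal: also return layer caches for backprop.
#' @return Matrix `n x bottleneck` (or a list when `keep_cache = TRUE`).
#' @export
encoder_forward <- function(model, x, mode = c("features", "embedding"),
                            train = FALSE, keep_cache = FALSE) {
  mode <- match.arg(mode)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$encoder$input_dim) {
    stop("input has ", ncol(x), " columns; encoder expects ",
         model$encoder$input_dim)
  }
  p <- model$params
  st <- model$stats
  eps <- model$encoder$bn_eps
  caches <- if (keep_cache) vector("list", 4) else NULL
  h <- x
  for (i in 1:4) {
    z <- nn_dense_forward(h, p[[paste0("e", i, ".W")]],
                          p[[paste0("e", i, ".b")]])
    if (train) {
      bn <- nn_bn_forward_train(z, p[[paste0("e", i, ".g")]],
                                p[[paste0("e", i, ".be")]], eps)
      a <- bn$out
      if (keep_cache) {
        caches[[i]] <- list(x_in = h, z = z, bn = bn$cache, pre_relu = a)
      }
    } else {
      a <- nn_bn_forward_eval(z, p[[paste0("e", i, ".g")]],
                              p[[paste0("e", i, ".be")]],
                              st[[paste0("e", i, ".rm")]],
                              st[[paste0("e", i, ".rv")]], eps)
      if (keep_cache) caches[[i]] <- list(x_in = h, z = z, pre_relu = a)
    }
    h <- if (i < 4 || mode == "features") nn_relu(a) else a
  }
  if (keep_cache) list(out = h, caches = caches) else h
}

#' Task-head forward pass
#'
#' @param model A `flim_model`.
#' @param features Activated bottleneck features from
#'   `encoder_forward(mode = "features")`.
#' @param train Apply dropout (`TRUE`) or run deterministically (`FALSE`).
#' @param keep_cache Internal: also return caches for backprop.
#' @return List with `diagnosis` and `delineation` `n x 2` logit matrices.
#' @export
heads_forward <- function(model, features, train = FALSE, keep_cache = FALSE) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$encoder$bottleneck) {
    stop("features have ", ncol(features), " columns; heads expect ",
         model$encoder$bottleneck)
  }
  p <- model$params
  drop_p <- model$head$dropout
  run_head <- function(tag) {
    h <- features
    cache <- vector("list", 3)
    for (i in 1:3) {
      z <- nn_dense_forward(h, p[[paste0("h", tag, i, ".W")]],
                            p[[paste0("h", tag, i, ".b")]])
      if (i < 3) {
        if (train && drop_p > 0) {
          dp <- nn_dropout_forward(z, drop_p)
          zd <- dp$out
          mask <- dp$mask
        } else {
          zd <- z
          mask <- NULL
        }
        a <- nn_relu(zd)
        cache[[i]] <- list(x_in = h, z = z, zd = zd, mask = mask)
        h <- a
      } else {
        cache[[i]] <- list(x_in = h)
        h <- z
      }
    }
    list(logits = h, cache = cache)
  }
  d <- run_head("d")
  l <- run_head("l")
  out <- list(diagnosis = d$logits, delineation = l$logits)
  if (keep_cache) {
    out$caches <- list(d = d$cache, l = l$cache)
  }
  out
}

# Backward through one head; returns grads (named, model keys) and dfeatures.
#' @keywords internal
head_backward <- function(model, tag, dlogits, cache) {
  p <- model$params
  grads <- list()
  dout <- dlogits
  for (i in 3:1) {
    cc <- cache[[i]]
    if (i < 3) {
      # back through ReLU then dropout
      dout <- nn_relu_backward(dout, cc$zd)
      if (!is.null(cc$mask)) dout <- dout * cc$mask
    }
    bw <- nn_dense_backward(dout, cc$x_in, p[[paste0("h", tag, i, ".W")]])
    grads[[paste0("h", tag, i, ".W")]] <- bw$dW
    grads[[paste0("h", tag, i, ".b")]] <- bw$db
    dout <- bw$dx
  }
  list(grads = grads, dfeatures = dout)
}

# Backward through the encoder from a gradient at either tap.
# d_at = "embedding": gradient w.r.t. post-BN pre-ReLU layer-4 output.
# d_at = "features":  gradient w.r.t. ReLU(layer-4) output.
#' @keywords internal
encoder_backward <- function(model, dout, caches,
                             d_at = c("embedding", "features")) {
  d_at <- match.arg(d_at)
  p <- model$params
  grads <- list()
  for (i in 4:1) {
    cc <- caches[[i]]
    if (i < 4 || d_at == "features") {
      dout <- nn_relu_backward(dout, cc$pre_relu)
    }
    bn <- nn_bn_backward(dout, cc$bn, p[[paste0("e", i, ".g")]])
    grads[[paste0("e", i, ".g")]] <- bn$dgamma
    grads[[paste0("e", i, ".be")]] <- bn$dbeta
    bw <- nn_dense_backward(bn$dx, cc$x_in, p[[paste0("e", i, ".W")]])
    grads[[paste0("e", i, ".W")]] <- bw$dW
    grads[[paste0("e", i, ".b")]] <- bw$db
    dout <- bw$dx
  }
  grads
}

# Update batch-norm running statistics from a training-mode forward cache.
#' @keywords internal
update_bn_stats <- function(model, caches) {
  mom <- model$encoder$bn_momentum
  for (i in 1:4) {
    mu <- caches[[i]]$bn$mu
    v <- caches[[i]]$bn$v
    krm <- paste0("e", i, ".rm")
    krv <- paste0("e", i, ".rv")
    model$stats[[krm]] <- (1 - mom) * model$stats[[krm]] + mom * mu
    model$stats[[krv]] <- (1 - mom) * model$stats[[krv]] + mom * v
  }
  model
}
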