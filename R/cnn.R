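# 1D convolutional beat/non-beat classifier, implemented directly on BLAS
# matrix products (im2col). Four conv(+ReLU)+maxpool stages, two dense
# hidden layers, dropout, and a 2-way softmax head; trained with SGD +
# momentum under a staged learning-rate schedule.

#' Model architecture specification
#'
#' Four convolution/pooling stages with valid (zero) padding and stride-1
#' convolutions followed by width-2/stride-2 max pooling, then two
#' fully-connected hidden layers, dropout, and a final two-neuron softmax
#' layer. With the default kernels `(49, 25, 9, 9)` an input of 300 samples
#' shrinks through temporal lengths 252/126, 102/51, 43/21 and 13/6. Channel
#' counts and dense widths are configurable; the defaults (32, 32, 64, 64
#' channels; 512- and 128-unit dense layers) keep the network trainable on a
#' CPU in minutes. ReLU activations follow every convolution and hidden
#' dense layer.
#'
#' @param input_len input window length in samples.
#' @param kernels convolution kernel widths per stage.
#' @param channels output channels per stage.
#' @param dense hidden fully-connected layer widths.
#' @param dropout dropout fraction applied before the final layer.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_len = 300L, kernels = c(49L, 25L, 9L, 9L),
                     channels = c(32L, 32L, 64L, 64L), dense = c(512L, 128L),
                     dropout = 0.5) {
  if (length(kernels) != length(channels)) {
    stop("`kernels` and `channels` must have one entry per conv stage")
  }
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  spec <- structure(list(input_len = as.integer(input_len),
                         kernels = as.integer(kernels),
                         channels = as.integer(channels),
                         dense = as.integer(dense),
                         dropout = dropout, n_class = 2L),
                    class = "cnn_spec")
  cnn_shape(spec)  # validates that no stage collapses
  spec
}

#' Per-stage temporal lengths of the conv/pool cascade
#'
#' A valid convolution maps length `L` to `L - k + 1`; width-2/stride-2 max
#' pooling then maps to `floor(L / 2)`. Errors name the first stage at which
#' the length collapses below 1.
#'
#' @param spec a [cnn_spec()].
#' @param input_len input length (defaults to the spec's).
#' @return A `data.frame` with columns `stage`, `conv_len`, `pool_len`.
#' @export
cnn_shape <- function(spec, input_len = spec$input_len) {
  L <- as.integer(input_len)
  out <- data.frame(stage = seq_along(spec$kernels), conv_len = NA_integer_,
                    pool_len = NA_integer_)
  for (i in seq_along(spec$kernels)) {
    Lc <- L - spec$kernels[i] + 1L
    if (Lc < 1L) {
      stop(sprintf("input length collapses at conv stage %d (length %d < kernel %d)",
                   i, L, spec$kernels[i]))
    }
    Lp <- Lc %/% 2L
    if (Lp < 1L) {
      stop(sprintf("input length collapses at pool stage %d (conv length %d)", i, Lc))
    }
    out$conv_len[i] <- Lc
    out$pool_len[i] <- Lp
    L <- Lp
  }
  out
}

#' Initialise a model from a specification
#'
#' He-scaled Gaussian initialisation for all weights, zero biases; the seed
#' makes initialisation reproducible.
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `cnn_model` (untrained).
#' @export
cnn_build <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "cnn_spec"))
  shp <- cnn_shape(spec)
  with_seed(seed, {
    params <- list()
    cin <- 1L
    for (i in seq_along(spec$kernels)) {
      fan_in <- spec$kernels[i] * cin
      params[[paste0("conv", i, ".W")]] <-
        matrix(stats::rnorm(fan_in * spec$channels[i], sd = sqrt(2 / fan_in)),
               fan_in, spec$channels[i])
      params[[paste0("conv", i, ".b")]] <- numeric(spec$channels[i])
      cin <- spec$channels[i]
    }
    fin <- shp$pool_len[nrow(shp)] * cin
    widths <- c(fin, spec$dense)
    for (j in seq_along(spec$dense)) {
      params[[paste0("dense", j, ".W")]] <-
        matrix(stats::rnorm(widths[j] * widths[j + 1L], sd = sqrt(2 / widths[j])),
               widths[j], widths[j + 1L])
      params[[paste0("dense", j, ".b")]] <- numeric(widths[j + 1L])
    }
    hl <- widths[length(widths)]
    params[["out.W"]] <- matrix(stats::rnorm(hl * spec$n_class, sd = sqrt(1 / hl)),
                                hl, spec$n_class)
    params[["out.b"]] <- numeric(spec$n_class)
    structure(list(spec = spec, params = params, trained = FALSE),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<cnn_model: input %d, %d conv stages, %s params%s>\n",
              x$spec$input_len, length(x$spec$kernels),
              format(np, big.mark = ","),
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

im2col_idx <- function(L, k) as.vector(outer(seq_len(L - k + 1L), 0:(k - 1L), `+`))

# Forward pass. X: B x input_len matrix. Returns p (B x n_class softmax
# probabilities) and, when training = TRUE, the caches needed for backprop.
cnn_forward <- function(model, X, training = FALSE, drop_mask = NULL) {
  spec <- model$spec
  p <- model$params
  B <- nrow(X)
  cache <- if (training) list() else NULL
  A <- array(as.numeric(X), c(B, ncol(X), 1L))
  for (i in seq_along(spec$kernels)) {
    k <- spec$kernels[i]
    d <- dim(A); L <- d[2]; Cin <- d[3]; Lout <- L - k + 1L
    M <- A[, im2col_idx(L, k), , drop = FALSE]
    dim(M) <- c(B * Lout, k * Cin)               # rows: batch fastest, then t
    Z <- M %*% p[[paste0("conv", i, ".W")]]
    Z <- Z + rep(p[[paste0("conv", i, ".b")]], each = nrow(Z))
    H <- Z * (Z > 0)
    dim(H) <- c(B, Lout, spec$channels[i])
    Lp <- Lout %/% 2L
    i1 <- seq.int(1L, 2L * Lp, 2L)
    A1 <- H[, i1, , drop = FALSE]
    A2 <- H[, i1 + 1L, , drop = FALSE]
    mask <- A1 >= A2
    if (training) {
      cache[[paste0("conv", i)]] <- list(M = M, relu = Z > 0, pool_mask = mask,
                                         Lin = L, Lout = Lout, Cin = Cin)
    }
    A <- pmax(A1, A2)
  }
  d <- dim(A)
  F0 <- A
  dim(F0) <- c(B, d[2] * d[3])
  if (training) cache$flat_dim <- d
  H <- F0
  for (j in seq_along(spec$dense)) {
    Z <- H %*% p[[paste0("dense", j, ".W")]]
    Z <- Z + rep(p[[paste0("dense", j, ".b")]], each = B)
    if (training) cache[[paste0("dense", j)]] <- list(input = H, relu = Z > 0)
    H <- Z * (Z > 0)
  }
  if (training && spec$dropout > 0) {
    if (is.null(drop_mask)) {
      keep <- 1 - spec$dropout
      drop_mask <- matrix((stats::runif(length(H)) < keep) / keep, nrow(H), ncol(H))
    }
    cache$drop_mask <- drop_mask
    H <- H * drop_mask
  }
  if (training) cache$head_input <- H
  logits <- H %*% p[["out.W"]]
  logits <- logits + rep(p[["out.b"]], each = B)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(p = probs, cache = cache)
}

# Backward pass; y is an integer class vector (1 = beat, 2 = non_beat).
cnn_backward <- function(model, probs, y, cache) {
  spec <- model$spec
  p <- model$params
  B <- nrow(probs)
  grads <- list()
  dlogit <- probs
  dlogit[cbind(seq_len(B), y)] <- dlogit[cbind(seq_len(B), y)] - 1
  dlogit <- dlogit / B
  grads[["out.W"]] <- crossprod(cache$head_input, dlogit)
  grads[["out.b"]] <- colSums(dlogit)
  dH <- tcrossprod(dlogit, p[["out.W"]])
  if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
  for (j in rev(seq_along(spec$dense))) {
    cc <- cache[[paste0("dense", j)]]
    dZ <- dH * cc$relu
    grads[[paste0("dense", j, ".W")]] <- crossprod(cc$input, dZ)
    grads[[paste0("dense", j, ".b")]] <- colSums(dZ)
    dH <- tcrossprod(dZ, p[[paste0("dense", j, ".W")]])
  }
  d <- cache$flat_dim
  dA <- dH
  dim(dA) <- d                                   # (B, Lp, C)
  for (i in rev(seq_along(spec$kernels))) {
    cc <- cache[[paste0("conv", i)]]
    k <- spec$kernels[i]
    Lp <- dim(dA)[2]
    i1 <- seq.int(1L, 2L * Lp, 2L)
    dHc <- array(0, c(B, cc$Lout, spec$channels[i]))
    dHc[, i1, ] <- dA * cc$pool_mask
    dHc[, i1 + 1L, ] <- dA * !cc$pool_mask
    dim(dHc) <- c(B * cc$Lout, spec$channels[i])
    dZ <- dHc * cc$relu
    grads[[paste0("conv", i, ".W")]] <- crossprod(cc$M, dZ)
    grads[[paste0("conv", i, ".b")]] <- colSums(dZ)
    if (i > 1L) {
      dM <- tcrossprod(dZ, p[[paste0("conv", i, ".W")]])
      dim(dM) <- c(B, cc$Lout, k, cc$Cin)
      dAin <- array(0, c(B, cc$Lin, cc$Cin))
      for (jj in seq_len(k)) {
        sl <- dM[, , jj, , drop = FALSE]
        dim(sl) <- c(B, cc$Lout, cc$Cin)
        dAin[, jj:(jj + cc$Lout - 1L), ] <- dAin[, jj:(jj + cc$Lout - 1L), ] + sl
      }
      dA <- dAin
    }
  }
  grads
}

#' Training configuration
#'
#' Defaults follow the reference schedule: 30 epochs of SGD with momentum
#' 0.9 and cross-entropy loss, with the learning rate stepping through 0.01
#' (epochs 1-3), 0.005 (4-10), 0.001 (11-20) and 0.0001 (21-30); 30% of the
#' training segments (stratified per source record) are held out as a
#' within-training validation partition.
#'
#' @param epochs number of training epochs.
#' @param lr_schedule `data.frame` with columns `epochs` (segment lengths)
#'   and `lr`; segments are consumed in order and the last rate persists if
#'   `epochs` exceeds the schedule.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param batch_size minibatch size.
#' @param val_frac fraction of segments held out for validation.
#' @param seed integer seed covering the split, shuffling and dropout.
#' @return An object of class `cnn_train_config`.
#' @export
cnn_train_config <- function(epochs = 30L,
                             lr_schedule = data.frame(
                               epochs = c(3L, 7L, 10L, 10L),
                               lr = c(0.01, 0.005, 0.001, 0.0001)),
                             momentum = 0.9, batch_size = 256L,
                             val_frac = 0.30, seed = 0L) {
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0, 1)")
  if (val_frac < 0 || val_frac >= 1) stop("`val_frac` must be in [0, 1)")
  structure(list(epochs = as.integer(epochs), lr_schedule = lr_schedule,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "cnn_train_config")
}

#' Learning rate in force at a given epoch
#'
#' @param epoch 1-based epoch number.
#' @param cfg a [cnn_train_config()].
#' @return The scheduled learning rate (epoch 3 -> 0.01, 4 -> 0.005,
#'   11 -> 0.001, 21 -> 0.0001 with the defaults).
#' @export
cnn_learning_rate <- function(epoch, cfg = cnn_train_config()) {
  bounds <- cumsum(cfg$lr_schedule$epochs)
  seg <- findInterval(epoch - 1L, c(0L, bounds), rightmost.closed = FALSE)
  seg <- min(seg, nrow(cfg$lr_schedule))
  cfg$lr_schedule$lr[seg]
}

label_to_class <- function(label) {
  y <- match(label, c("beat", "non_beat"))
  if (anyNA(y)) stop("labels must be 'beat' or 'non_beat'")
  y
}

#' Train the beat validator
#'
#' Stochastic gradient descent with momentum under the staged learning-rate
#' schedule, minimising cross-entropy on the softmax outputs. The segments
#' are split 70/30 into train/validation partitions, stratified within each
#' source record when `strata` is given, and per-epoch train/validation loss
#' and error rates are recorded. A fixed seed reproduces the whole history.
#'
#' @param model a [cnn_build()] result.
#' @param x matrix of segments (one per row, `input_len` columns).
#' @param label character vector, `"beat"` / `"non_beat"`; both classes must
#'   be present.
#' @param cfg a [cnn_train_config()].
#' @param strata optional vector (e.g. source record ids) used to stratify
#'   the train/validation split.
#' @param verbose print per-epoch progress.
#' @return The trained model, with a `history` data.frame (`epoch`, `lr`,
#'   `train_loss`, `train_err`, `val_loss`, `val_err`) attached.
#' @export
cnn_train <- function(model, x, label, cfg = cnn_train_config(), strata = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), is.matrix(x))
  if (ncol(x) != model$spec$input_len) {
    stop(sprintf("segments have %d samples but the model expects %d",
                 ncol(x), model$spec$input_len))
  }
  y <- label_to_class(label)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both beat and non_beat segments")
  }
  n <- nrow(x)
  if (is.null(strata)) strata <- rep("all", n)
  with_seed(cfg$seed, {
    val_idx <- unlist(lapply(split(seq_len(n), strata), function(idx) {
      if (length(idx) < 2L) return(integer(0))
      sample(idx, max(1L, round(cfg$val_frac * length(idx))))
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(n), val_idx)
    vel <- lapply(model$params, function(p) p * 0)
    history <- data.frame(epoch = seq_len(cfg$epochs), lr = NA_real_,
                          train_loss = NA_real_, train_err = NA_real_,
                          val_loss = NA_real_, val_err = NA_real_)
    eval_split <- function(idx) {
      loss <- 0; err <- 0
      for (s in split(idx, ceiling(seq_along(idx) / 512))) {
        fw <- cnn_forward(model, x[s, , drop = FALSE], training = FALSE)
        pr <- pmax(fw$p[cbind(seq_along(s), y[s])], 1e-12)
        loss <- loss + sum(-log(pr))
        err <- err + sum(max.col(fw$p) != y[s])
      }
      c(loss / length(idx), err / length(idx))
    }
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cnn_learning_rate(epoch, cfg)
      ord <- sample(tr_idx)
      tot_loss <- 0; tot_err <- 0
      for (batch in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        xb <- x[batch, , drop = FALSE]
        yb <- y[batch]
        fw <- cnn_forward(model, xb, training = TRUE)
        pr <- pmax(fw$p[cbind(seq_along(batch), yb)], 1e-12)
        bloss <- mean(-log(pr))
        if (!is.finite(bloss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d (lr %g)",
                       epoch, lr))
        }
        tot_loss <- tot_loss + bloss * length(batch)
        tot_err <- tot_err + sum(max.col(fw$p) != yb)
        grads <- cnn_backward(model, fw$p, yb, fw$cache)
        for (nm in names(model$params)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] - lr * grads[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      vl <- eval_split(val_idx)
      history$lr[epoch] <- lr
      history$train_loss[epoch] <- tot_loss / length(tr_idx)
      history$train_err[epoch] <- tot_err / length(tr_idx)
      history$val_loss[epoch] <- vl[1]
      history$val_err[epoch] <- vl[2]
      if (verbose) {
        message(sprintf("epoch %2d lr %.4g  train loss %.4f err %.4f | val loss %.4f err %.4f",
                        epoch, lr, history$train_loss[epoch], history$train_err[epoch],
                        vl[1], vl[2]))
      }
    }
    model$trained <- TRUE
    model$history <- history
    model
  })
}

#' Probability that a window holds a centred beat
#'
#' Feed-forward inference (no dropout). Accepts a single window or a matrix
#' of windows, which must already be at the model input length (resample
#' native-rate windows with [resample_to_length()] first).
#'
#' @param model a trained [cnn_build()] model.
#' @param x numeric vector of length `input_len`, or a matrix with
#'   `input_len` columns.
#' @return Numeric vector of beat probabilities in `[0, 1]`.
#' @export
cnn_predict <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$spec$input_len) {
    stop(sprintf("input has %d samples but the model expects %d",
                 ncol(x), model$spec$input_len))
  }
  out <- numeric(nrow(x))
  for (s in split(seq_len(nrow(x)), ceiling(seq_len(nrow(x)) / 1024))) {
    out[s] <- cnn_forward(model, x[s, , drop = FALSE], training = FALSE)$p[, 1L]
  }
  out
}

#' Save / load a trained model
#'
#' The artifact stores a format tag, a format version, the architecture
#' specification and the raw weights; loading verifies each field and
#' reproduces predictions bit-for-bit.
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @return `cnn_load()` returns the model; `cnn_save()` the path, invisibly.
#' @export
cnn_save <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  obj <- list(format = "qrsvalid_cnn", version = 1L, spec = unclass(model$spec),
              params = model$params, trained = isTRUE(model$trained))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname cnn_save
#' @export
cnn_load <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "qrsvalid_cnn")) {
    stop("not a qrsvalid CNN artifact: missing or wrong `format` field")
  }
  if (!identical(obj$version, 1L)) {
    stop(sprintf("unsupported model artifact `version` field: %s", obj$version))
  }
  for (f in c("spec", "params")) {
    if (is.null(obj[[f]])) stop(sprintf("model artifact missing `%s` field", f))
  }
  spec <- do.call(cnn_spec, obj$spec[c("input_len", "kernels", "channels",
                                       "dense", "dropout")])
  structure(list(spec = spec, params = obj$params, trained = obj$trained),
            class = "cnn_model")
}
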