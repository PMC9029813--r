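#' Define an autoencoder architecture
#'
#' An architecture is the chain of encoder layer widths, starting at the
#' input width and ending at the code layer. With tied weights (the
#' default) every decoder weight matrix is the transpose of the mirrored
#' encoder matrix, so the decoder widths are the encoder widths reversed.
#'
#' @param encoder_sizes Integer vector of layer widths, input first,
#'   code layer last (e.g. `c(1024, 900, 700, 500)`).
#' @param name Optional display name.
#' @param tied Logical; tie decoder weights to encoder transposes.
#' @param decoder_sizes Optional explicit decoder widths for untied
#'   models; must start at the code width and end at the input width.
#' @return An `ae_architecture` object.
#' @export
ae_architecture <- function(encoder_sizes, name = "custom", tied = TRUE,
                            decoder_sizes = NULL) {
  encoder_sizes <- as.integer(encoder_sizes)
  stopifnot(length(encoder_sizes) >= 2, all(encoder_sizes > 0))
  if (tied) {
    if (!is.null(decoder_sizes) &&
        !identical(as.integer(decoder_sizes), rev(encoder_sizes))) {
      stop("tied architectures force decoder_sizes == rev(encoder_sizes)")
    }
    decoder_sizes <- rev(encoder_sizes)
  } else {
    if (is.null(decoder_sizes)) decoder_sizes <- rev(encoder_sizes)
    decoder_sizes <- as.integer(decoder_sizes)
    stopifnot(decoder_sizes[1] == encoder_sizes[length(encoder_sizes)],
              decoder_sizes[length(decoder_sizes)] == encoder_sizes[1])
  }
  structure(
    list(name = name, encoder_sizes = encoder_sizes,
         code_size = encoder_sizes[length(encoder_sizes)],
         tied = isTRUE(tied), decoder_sizes = decoder_sizes),
    class = "ae_architecture"
  )
}

#' @export
print.ae_architecture <- function(x, ...) {
  cat(sprintf("<ae_architecture> %s: %s -> code %d%s\n", x$name,
              paste(x$encoder_sizes, collapse = "-"), x$code_size,
              if (x$tied) " (tied)" else ""))
  invisible(x)
}

#' Preset dimensionality-reduction architectures
#'
#' The three published reduction networks for 1024-feature count
#' fingerprints:
#' * `AE1-DR`: encoder 1024-900-700-500, 500-dimensional code;
#' * `AE2-DR`: encoder 1024-800-600-400-300, 300-dimensional code;
#' * `AE3-DR`: encoder 1024-900-800-600-400, 400-dimensional code.
#'
#' All are tied by default, so the decoder mirrors the encoder exactly.
#' (Untied decoders with other widths can be built via
#' [ae_architecture()].)
#'
#' @param name One of `"AE1-DR"`, `"AE2-DR"`, `"AE3-DR"`.
#' @param tied Logical; tie decoder weights (default `TRUE`).
#' @return An [ae_architecture()].
#' @export
#' @examples
#' preset_architecture("AE2-DR")$code_size  # 300
preset_architecture <- function(name = c("AE1-DR", "AE2-DR", "AE3-DR"),
                                tied = TRUE) {
  name <- match.arg(name)
  sizes <- switch(name,
    "AE1-DR" = c(1024L, 900L, 700L, 500L),
    "AE2-DR" = c(1024L, 800L, 600L, 400L, 300L),
    "AE3-DR" = c(1024L, 900L, 800L, 600L, 400L))
  ae_architecture(sizes, name = name, tied = tied)
}

#' Training configuration for the autoencoder
#'
#' @param tolerance Stopping threshold on the epoch-mean reconstruction
#'   MSE (default 0.01): training stops once the mean loss drops below
#'   it.
#' @param max_epochs Maximum number of passes over the data (default
#'   100).
#' @param step_size Gradient-descent step (default 0.05).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param init `"glorot"` (default; scaled symmetric uniform weights,
#'   zero biases) or `"uniform01"` (all weights and biases uniform on
#'   (0,1) — prone to saturating the sigmoids, kept for fidelity
#'   experiments).
#' @param per_molecule Logical; train one molecule at a time to
#'   tolerance instead of dataset-level epochs (fidelity mode, default
#'   `FALSE`).
#' @return A `train_config` list.
#' @export
train_config <- function(tolerance = 0.01, max_epochs = 100,
                         step_size = 0.05, batch_size = 32, seed = 1,
                         init = c("glorot", "uniform01"),
                         per_molecule = FALSE) {
  init <- match.arg(init)
  stopifnot(tolerance > 0, max_epochs >= 1, step_size > 0, batch_size >= 1)
  structure(list(tolerance = tolerance, max_epochs = as.integer(max_epochs),
                 step_size = step_size, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), init = init,
                 per_molecule = isTRUE(per_molecule)),
            class = "train_config")
}

#' Initialize an autoencoder model
#'
#' Encoder weight `i` has dimensions `encoder_sizes[i] x
#' encoder_sizes[i+1]`. Tied models carry no decoder weights — the
#' decoder always reads the encoder transposes — but decoder biases are
#' free parameters (initialized to zero under glorot).
#'
#' @param arch An [ae_architecture()].
#' @param cfg A [train_config()]; supplies the seed and init mode.
#' @return An `ae_model` object.
#' @export
init_model <- function(arch, cfg = train_config()) {
  stopifnot(inherits(arch, "ae_architecture"))
  set.seed(derive_seed(cfg$seed, "init"))
  enc <- arch$encoder_sizes
  n_enc <- length(enc) - 1
  draw <- function(nr, nc) {
    if (cfg$init == "uniform01") {
      matrix(runif(nr * nc), nr, nc)
    } else {
      lim <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
  }
  draw_bias <- function(n) {
    if (cfg$init == "uniform01") runif(n) else rep(0, n)
  }
  W <- lapply(seq_len(n_enc), function(i) draw(enc[i], enc[i + 1]))
  b <- lapply(seq_len(n_enc), function(i) draw_bias(enc[i + 1]))
  dec <- arch$decoder_sizes
  n_dec <- length(dec) - 1
  b_dec <- lapply(seq_len(n_dec), function(j) draw_bias(dec[j + 1]))
  W_dec <- NULL
  if (!arch$tied) {
    W_dec <- lapply(seq_len(n_dec), function(j) draw(dec[j], dec[j + 1]))
  }
  structure(list(architecture = arch, W = W, b = b,
                 W_dec = W_dec, b_dec = b_dec),
            class = "ae_model")
}

# Decoder weight for layer j: transpose of the mirrored encoder weight
# when tied, the free matrix otherwise.
decoder_weight <- function(model, j) {
  if (model$architecture$tied) {
    t(model$W[[length(model$W) - j + 1]])
  } else {
    model$W_dec[[j]]
  }
}

as_row_matrix <- function(x, width) {
  if (is.matrix(x)) {
    if (ncol(x) != width) stop("input width ", ncol(x),
                               " does not match expected ", width)
    x
  } else {
    if (length(x) != width) stop("input length ", length(x),
                                 " does not match expected ", width)
    matrix(x, nrow = 1)
  }
}

#' Encode inputs to the code layer
#'
#' Applies `sigmoid(x W_i + b_i)` through every encoder layer. Entries of
#' the code always lie in the open interval (0, 1).
#'
#' @param model An [init_model()] (usually trained) model.
#' @param x Numeric vector of the input width, or a matrix with one
#'   input per row.
#' @return Code vector (or matrix, one code per row) of width
#'   `code_size`.
#' @export
ae_encode <- function(model, x) {
  vec <- !is.matrix(x)
  a <- as_row_matrix(x, model$architecture$encoder_sizes[1])
  for (i in seq_along(model$W)) {
    a <- sigmoid(sweep(a %*% model$W[[i]], 2, model$b[[i]], "+"))
  }
  if (vec) drop(a) else a
}

#' Decode a code back to the input space
#'
#' @param model An `ae_model`.
#' @param h Code vector of width `code_size`, or a matrix of codes.
#' @return Reconstruction in the input space, entries in (0, 1).
#' @export
ae_decode <- function(model, h) {
  vec <- !is.matrix(h)
  a <- as_row_matrix(h, model$architecture$code_size)
  for (j in seq_along(model$b_dec)) {
    a <- sigmoid(sweep(a %*% decoder_weight(model, j), 2,
                       model$b_dec[[j]], "+"))
  }
  if (vec) drop(a) else a
}

#' Mean squared reconstruction error
#'
#' The training objective: the mean of squared componentwise differences
#' between an input and its reconstruction.
#'
#' @param x,z Numeric vectors (or matrices) of equal shape.
#' @return Non-negative scalar.
#' @export
#' @examples
#' reconstruction_error(c(1, 0), c(0, 1))  # 1
reconstruction_error <- function(x, z) {
  if (length(x) != length(z)) stop("x and z differ in length")
  mean((x - z)^2)
}

# Forward pass keeping activations; X is batch x input.
ae_forward <- function(model, X) {
  a_enc <- vector("list", length(model$W) + 1)
  a_enc[[1]] <- X
  for (i in seq_along(model$W)) {
    a_enc[[i + 1]] <- sigmoid(sweep(a_enc[[i]] %*% model$W[[i]], 2,
                                    model$b[[i]], "+"))
  }
  n_dec <- length(model$b_dec)
  a_dec <- vector("list", n_dec + 1)
  a_dec[[1]] <- a_enc[[length(a_enc)]]
  for (j in seq_len(n_dec)) {
    a_dec[[j + 1]] <- sigmoid(sweep(a_dec[[j]] %*% decoder_weight(model, j),
                                    2, model$b_dec[[j]], "+"))
  }
  list(a_enc = a_enc, a_dec = a_dec,
       loss = mean((X - a_dec[[n_dec + 1]])^2))
}

#' Analytic gradients of the reconstruction loss
#'
#' Backpropagates the mean-squared reconstruction error through the
#' decoder and encoder sigmoids. For tied models the gradient of each
#' encoder weight accumulates both its encoder-side use and its
#' transposed decoder-side use.
#'
#' @param model An `ae_model`.
#' @param X Input matrix (batch x input width), entries in \[0, 1\].
#' @return List with `gW`, `gb`, `gb_dec`, `gW_dec` (untied models
#'   only) and the batch `loss`.
#' @export
ae_gradients <- function(model, X) {
  X <- as_row_matrix(X, model$architecture$encoder_sizes[1])
  fw <- ae_forward(model, X)
  n_enc <- length(model$W)
  n_dec <- length(model$b_dec)
  scale <- 2 / length(X)  # d/dz of mean((X - z)^2)
  gW <- lapply(model$W, function(w) array(0, dim(w)))
  gW_dec <- if (!model$architecture$tied) {
    lapply(model$W_dec, function(w) array(0, dim(w)))
  }
  gb <- vector("list", n_enc)
  gb_dec <- vector("list", n_dec)

  zhat <- fw$a_dec[[n_dec + 1]]
  d_act <- -scale * (X - zhat)          # dL/d(output activation)
  for (j in rev(seq_len(n_dec))) {
    a_out <- fw$a_dec[[j + 1]]
    delta <- d_act * a_out * (1 - a_out)
    V <- decoder_weight(model, j)
    gV <- crossprod(fw$a_dec[[j]], delta)
    gb_dec[[j]] <- colSums(delta)
    if (model$architecture$tied) {
      k <- n_enc - j + 1
      gW[[k]] <- gW[[k]] + t(gV)
    } else {
      gW_dec[[j]] <- gV
    }
    d_act <- delta %*% t(V)
  }
  for (i in rev(seq_len(n_enc))) {
    a_out <- fw$a_enc[[i + 1]]
    delta <- d_act * a_out * (1 - a_out)
    gW[[i]] <- gW[[i]] + crossprod(fw$a_enc[[i]], delta)
    gb[[i]] <- colSums(delta)
    d_act <- delta %*% t(model$W[[i]])
  }
  list(gW = gW, gb = gb, gW_dec = gW_dec, gb_dec = gb_dec, loss = fw$loss)
}

apply_step <- function(model, g, step) {
  for (i in seq_along(model$W)) {
    model$W[[i]] <- model$W[[i]] - step * g$gW[[i]]
    model$b[[i]] <- model$b[[i]] - step * g$gb[[i]]
  }
  for (j in seq_along(model$b_dec)) {
    model$b_dec[[j]] <- model$b_dec[[j]] - step * g$gb_dec[[j]]
    if (!model$architecture$tied) {
      model$W_dec[[j]] <- model$W_dec[[j]] - step * g$gW_dec[[j]]
    }
  }
  model
}

#' Train an autoencoder on a scaled fingerprint dataset
#'
#' Minibatch gradient descent on the mean squared reconstruction error.
#' Each epoch shuffles the molecules (seeded), sweeps the minibatches,
#' and records the epoch-mean loss; training stops as soon as that mean
#' drops below `cfg$tolerance`, or after `cfg$max_epochs` epochs.
#'
#' @param ds A scaled [fingerprint_dataset()] (entries in \[0, 1\]) whose
#'   width matches the architecture's input width.
#' @param arch An [ae_architecture()].
#' @param cfg A [train_config()].
#' @return List with `model` (the trained `ae_model`) and `report` (per-
#'   epoch loss trace, epochs run, and `stopped_by` =
#'   `"tolerance"`/`"max_epochs"`).
#' @export
train_autoencoder <- function(ds, arch, cfg = train_config()) {
  stopifnot(inherits(ds, "fingerprint_dataset"),
            inherits(arch, "ae_architecture"))
  if (length(ds$ids) == 0) stop("cannot train on an empty dataset")
  X <- ds$counts
  if (min(X) < 0 || max(X) > 1) {
    stop("training data must be scaled to [0, 1]; see minmax_scale()")
  }
  if (ncol(X) != arch$encoder_sizes[1]) {
    stop("dataset width ", ncol(X), " does not match architecture input ",
         arch$encoder_sizes[1])
  }
  model <- init_model(arch, cfg)
  if (cfg$per_molecule) {
    return(train_per_molecule(model, X, cfg))
  }
  set.seed(derive_seed(cfg$seed, "epochs"))
  m <- nrow(X)
  trace <- numeric(0)
  stopped_by <- "max_epochs"
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(m)
    starts <- seq(1, m, by = cfg$batch_size)
    loss_sum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1, m)]
      g <- ae_gradients(model, X[idx, , drop = FALSE])
      model <- apply_step(model, g, cfg$step_size)
      loss_sum <- loss_sum + g$loss * length(idx)
    }
    trace <- c(trace, loss_sum / m)
    if (trace[epoch] < cfg$tolerance) {
      stopped_by <- "tolerance"
      break
    }
  }
  list(model = model,
       report = list(loss = trace, epochs = length(trace),
                     stopped_by = stopped_by))
}

# Fidelity mode: each molecule is trained to tolerance in turn.
train_per_molecule <- function(model, X, cfg) {
  trace <- numeric(0)
  for (k in seq_len(nrow(X))) {
    xk <- X[k, , drop = FALSE]
    for (it in seq_len(cfg$max_epochs)) {
      g <- ae_gradients(model, xk)
      if (g$loss < cfg$tolerance) break
      model <- apply_step(model, g, cfg$step_size)
    }
    trace <- c(trace, g$loss)
  }
  list(model = model,
       report = list(loss = trace, epochs = length(trace),
                     stopped_by = "per_molecule"))
}

#' Encode a whole dataset into the reduced descriptor
#'
#' Runs every molecule through the encoder; the resulting codes are the
#' new low-dimensional descriptor used for similarity searching.
#'
#' @param model A trained `ae_model`.
#' @param ds A scaled [fingerprint_dataset()] of matching width.
#' @return A [fingerprint_dataset()] with `code_size` columns; ids and
#'   labels carried over, marked scaled.
#' @export
encode_dataset <- function(model, ds) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  codes <- ae_encode(model, ds$counts)
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = length(ds$ids))
  colnames(codes) <- sprintf("c%04d", seq_len(ncol(codes)) - 1)
  fingerprint_dataset(ds$ids, ds$labels, codes, scaled = TRUE)
}

#' Save / load a trained model
#'
#' Serialized with `saveRDS`; `load_ae_model(save_ae_model(m, p))`
#' round-trips bit-exactly.
#'
#' @param model An `ae_model`.
#' @param path Destination file.
#' @return `path` invisibly (`save_ae_model`); the model
#'   (`load_ae_model`).
#' @export
save_ae_model <- function(model, path) {
  stopifnot(inherits(model, "ae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ae_model
#' @export
load_ae_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ae_model"))
  model
}
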