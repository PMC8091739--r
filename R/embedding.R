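#' Encoder layer pyramid
#'
#' Returns the encoder layer sizes from the input width down to the latent
#' width. The full-scale reference architecture for a 6338-gene adjacency
#' matrix with a 100-dimensional latent space and 7 encoder layers is the
#' fixed pyramid 6338-3000-1500-500-250-150-100; any other shape is
#' interpolated geometrically between \code{n_input} and \code{d_latent},
#' rounded, and forced strictly decreasing.
#'
#' @param n_input input width (number of genes).
#' @param d_latent latent width, default 100.
#' @param n_layers number of encoder layers including input and latent,
#'   default 7.
#' @return integer vector of length \code{n_layers}, strictly decreasing from
#'   \code{n_input} to \code{d_latent}.
#' @export
make_layer_pyramid <- function(n_input, d_latent = 100L, n_layers = 7L) {
  n_input <- as.integer(n_input); d_latent <- as.integer(d_latent)
  n_layers <- as.integer(n_layers)
  if (d_latent >= n_input)
    stop("latent width must be smaller than the input width")
  if (n_layers < 2L) stop("need at least 2 encoder layers")
  if (n_input == 6338L && d_latent == 100L && n_layers == 7L)
    return(c(6338L, 3000L, 1500L, 500L, 250L, 150L, 100L))
  sizes <- round(exp(seq(log(n_input), log(d_latent), length.out = n_layers)))
  # enforce strict decrease after rounding
  for (i in seq.int(2L, n_layers))
    if (sizes[i] >= sizes[i - 1L]) sizes[i] <- sizes[i - 1L] - 1L
  if (sizes[n_layers] < 1L)
    stop("cannot build a strictly decreasing pyramid with these arguments")
  sizes[1L] <- n_input; sizes[n_layers] <- d_latent
  as.integer(sizes)
}

#' Autoencoder training configuration
#'
#' Two profiles are provided. \code{"paper"} is the full-scale fidelity
#' reference: Adam with learning rate 1e-6, 10000 epochs, batch size 10.
#' \code{"desk"} is the single-CPU reduced-scale profile: learning rate 1e-3,
#' 200 epochs, batch size 32. Hidden layers (including the latent layer) use
#' ReLU; the output layer is sigmoid; the loss is mean binary cross-entropy
#' against the binary adjacency input.
#'
#' @param layer_sizes encoder sizes ending at the latent width (see
#'   \code{\link{make_layer_pyramid}}).
#' @param profile \code{"desk"} or \code{"paper"}; sets defaults for the
#'   optimizer parameters below, each individually overridable.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return list of class \code{autoencoder_config}.
#' @export
autoencoder_config <- function(layer_sizes, profile = c("desk", "paper"),
                               learning_rate = NULL, epochs = NULL,
                               batch_size = NULL, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    paper = list(learning_rate = 1e-6, epochs = 10000L, batch_size = 10L),
    desk = list(learning_rate = 1e-3, epochs = 200L, batch_size = 32L))
  cfg <- list(
    layer_sizes = as.integer(layer_sizes),
    profile = profile,
    learning_rate = if (is.null(learning_rate)) defaults$learning_rate
                    else learning_rate,
    epochs = if (is.null(epochs)) defaults$epochs else as.integer(epochs),
    batch_size = if (is.null(batch_size)) defaults$batch_size
                 else as.integer(batch_size),
    seed = as.integer(seed))
  if (length(cfg$layer_sizes) < 2L || any(diff(cfg$layer_sizes) >= 0))
    stop("layer_sizes must be strictly decreasing through the encoder")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  class(cfg) <- "autoencoder_config"
  cfg
}

# internal: Glorot-uniform weight init for one layer
glorot_init <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.BCE_EPS <- 1e-7

# internal: forward pass; returns activations per layer
ae_forward <- function(model, x) {
  L <- length(model$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    z <- acts[[l]] %*% model$W[[l]]
    z <- sweep(z, 2L, model$b[[l]], `+`)
    acts[[l + 1L]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, .BCE_EPS), 1 - .BCE_EPS)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a symmetric deep autoencoder on adjacency rows
#'
#' The decoder mirrors the encoder (reversed layer sizes, independent
#' weights). Hidden activations are ReLU, the output is sigmoid, and the
#' objective is mean binary cross-entropy between input and reconstruction,
#' minimized with Adam (beta1 0.9, beta2 0.999, eps 1e-8). Rows are shuffled
#' every epoch with the run seed; the per-epoch mean minibatch loss is
#' recorded. Deterministic given the config seed (single-threaded BLAS).
#'
#' @param adjacency binary N x N matrix (rows are gene features).
#' @param config an \code{autoencoder_config} whose first layer size equals
#'   \code{ncol(adjacency)}.
#' @return list of class \code{pin_autoencoder}: weight/bias lists (encoder
#'   then decoder), \code{latent_index} (index of the latent activation),
#'   \code{loss_trace} (per-epoch), and the config.
#' @export
train_autoencoder <- function(adjacency, config) {
  stopifnot(inherits(config, "autoencoder_config"))
  adjacency <- as.matrix(adjacency)
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency input must be binary (0/1)")
  if (ncol(adjacency) != config$layer_sizes[1L])
    stop("config layer_sizes[1] must equal ncol(adjacency)")
  sizes <- c(config$layer_sizes, rev(config$layer_sizes)[-1L])
  L <- length(sizes) - 1L
  with_seed(config$seed, {
    model <- list(W = vector("list", L), b = vector("list", L),
                  latent_index = length(config$layer_sizes),
                  layer_sizes = sizes, config = config)
    for (l in seq_len(L)) {
      model$W[[l]] <- glorot_init(sizes[l], sizes[l + 1L])
      model$b[[l]] <- numeric(sizes[l + 1L])
    }
    mW <- lapply(model$W, function(w) w * 0); vW <- mW
    mb <- lapply(model$b, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
    t_step <- 0L
    n <- nrow(adjacency)
    loss_trace <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq.int(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[seq.int(starts[bi], min(starts[bi] + config$batch_size - 1L, n))]
        x <- adjacency[idx, , drop = FALSE]
        acts <- ae_forward(model, x)
        p <- acts[[L + 1L]]
        batch_losses[bi] <- bce_loss(p, x)
        # backprop: sigmoid + BCE gives delta = (p - y) / n_entries
        delta <- (p - x) / length(x)
        t_step <- t_step + 1L
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        gW <- vector("list", L); gb <- vector("list", L)
        for (l in seq.int(L, 1L)) {
          gW[[l]] <- crossprod(acts[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1L) {
            delta <- tcrossprod(delta, model$W[[l]])
            delta <- delta * (acts[[l]] > 0)
          }
        }
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
          model$W[[l]] <- model$W[[l]] -
            lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
          model$b[[l]] <- model$b[[l]] -
            lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      loss_trace[epoch] <- mean(batch_losses)
      if (!is.finite(loss_trace[epoch]))
        stop("non-finite training loss at epoch ", epoch,
             "; reduce the learning rate")
    }
    model$loss_trace <- loss_trace
    class(model) <- "pin_autoencoder"
    model
  })
}

#' @export
print.pin_autoencoder <- function(x, ...) {
  cat(sprintf("pin_autoencoder: layers %s; final loss %.6f after %d epochs\n",
              paste(x$layer_sizes, collapse = "-"),
              x$loss_trace[length(x$loss_trace)], length(x$loss_trace)))
  invisible(x)
}

#' Extract middle-layer latent features
#'
#' Forward-propagates adjacency rows to the narrowest (latent) encoder layer.
#' Latent values are nonnegative (rectified); dimensions that are zero for
#' every gene are flagged in \code{attr(, "na_dims")} — they correspond to
#' dead rectifier units and are retained so the feature count stays fixed.
#'
#' @param model a trained \code{pin_autoencoder}.
#' @param adjacency matrix whose width matches the model input width.
#' @return N x d matrix with gene rownames and \code{dim_1..dim_d} colnames.
#' @export
encode <- function(model, adjacency) {
  stopifnot(inherits(model, "pin_autoencoder"))
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != model$layer_sizes[1L])
    stop("adjacency width does not match the model input width")
  a <- adjacency
  for (l in seq_len(model$latent_index - 1L)) {
    a <- a %*% model$W[[l]]
    a <- sweep(a, 2L, model$b[[l]], `+`)
    a <- pmax(a, 0)
  }
  colnames(a) <- paste0("dim_", seq_len(ncol(a)))
  rownames(a) <- rownames(adjacency)
  attr(a, "na_dims") <- apply(a, 2L, function(x) all(x == 0))
  a
}

#' Mean binary cross-entropy reconstruction error
#'
#' Diagnostic: mean BCE over all matrix entries between the input and the
#' model's reconstruction (probabilities clipped at 1e-7). A constant-0.5
#' reconstruction scores ln 2 per entry; useful as an untrained baseline.
#'
#' @param model a trained \code{pin_autoencoder}.
#' @param adjacency matrix whose width matches the model input width.
#' @return scalar mean BCE.
#' @export
reconstruction_error <- function(model, adjacency) {
  stopifnot(inherits(model, "pin_autoencoder"))
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != model$layer_sizes[1L])
    stop("adjacency width does not match the model input width")
  acts <- ae_forward(model, adjacency)
  bce_loss(acts[[length(acts)]], adjacency)
}

#' Write a latent feature matrix as TSV
#' @param latent matrix from \code{\link{encode}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_latent_matrix <- function(latent, path) {
  df <- data.frame(gene = rownames(latent), latent, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a latent feature matrix written by \code{write_latent_matrix}
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_latent_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  attr(m, "na_dims") <- apply(m, 2L, function(x) all(x == 0))
  m
}
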