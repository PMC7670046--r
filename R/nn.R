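## Small feed-forward network for binary classification, trained with Adam
## on binary cross-entropy. The default architecture is the five-layer
## stack 8 -> 16 -> 32 -> 64 -> 1: ReLU on the inputs and on every hidden
## layer, sigmoid on the single output. The input "layer" carries no
## weights — it is ReLU applied to the raw features, which for the
## non-negative strip counts is the identity.

sigmoid <- function(z) 1 / (1 + exp(-z))

nnInit <- function(sizes) {
  # Glorot-uniform weights, zero biases
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fanIn <- sizes[l]; fanOut <- sizes[l + 1L]
    lim <- sqrt(6 / (fanIn + fanOut))
    list(W = matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut),
         b = rep(0, fanOut))
  })
}

nnForwardFull <- function(layers, x) {
  a <- pmax(x, 0)                      # input-layer ReLU
  acts <- list(a)
  L <- length(layers)
  for (l in seq_len(L)) {
    z <- a %*% layers[[l]]$W + matrix(layers[[l]]$b, nrow(a),
                                      length(layers[[l]]$b), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else sigmoid(z)
    acts[[l + 1L]] <- a
  }
  acts
}

#' Train the feed-forward apathy network
#'
#' Fits the small fully connected network (default hidden widths 16, 32,
#' 64, single sigmoid output) by full-batch Adam on binary cross-entropy.
#' Training is deterministic given the seed: weight initialization (and
#' mini-batch shuffling, when a batch size is set) are the only sources of
#' randomness.
#'
#' @param x numeric matrix (n x d) of feature vectors; negative entries
#'   are clipped by the input ReLU.
#' @param y numeric 0/1 vector (1 = apathy) of length n.
#' @param hidden integer vector of hidden-layer widths.
#' @param epochs number of training epochs.
#' @param lr Adam learning rate.
#' @param seed integer RNG seed.
#' @param batchSize mini-batch size; `NULL` (default) trains full-batch.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return An object of class `apathyNN` holding the fitted layers.
#' @seealso [nnPredictProb()], [nnParameterCount()]
#' @export
nnFit <- function(x, y, hidden = c(16L, 32L, 64L), epochs = 50L, lr = 1e-3,
                  seed = 1L, batchSize = NULL,
                  beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(hidden) < 1L || any(hidden < 1L) || ncol(x) < 1L)
    stop("invalid architecture")
  sizes <- c(ncol(x), as.integer(hidden), 1L)
  set.seed(as.integer(seed))
  layers <- nnInit(sizes)
  L <- length(layers)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  t <- 0L
  n <- nrow(x)
  bs <- if (is.null(batchSize)) n else min(as.integer(batchSize), n)
  for (epoch in seq_len(epochs)) {
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    starts <- seq(1L, n, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      acts <- nnForwardFull(layers, xb)
      p <- acts[[L + 1L]][, 1]
      # d(BCE)/d(logit) for the sigmoid output
      delta <- matrix((p - yb) / length(yb), ncol = 1L)
      grads <- vector("list", L)
      for (l in rev(seq_len(L))) {
        grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                           b = colSums(delta))
        if (l > 1L) {
          delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
        }
      }
      t <- t + 1L
      for (l in seq_len(L)) {
        for (slot in c("W", "b")) {
          g <- grads[[l]][[slot]]
          m[[l]][[slot]] <- beta1 * m[[l]][[slot]] + (1 - beta1) * g
          v[[l]][[slot]] <- beta2 * v[[l]][[slot]] + (1 - beta2) * g^2
          mhat <- m[[l]][[slot]] / (1 - beta1^t)
          vhat <- v[[l]][[slot]] / (1 - beta2^t)
          layers[[l]][[slot]] <- layers[[l]][[slot]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
  }
  structure(list(layers = layers, sizes = sizes, epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed),
                 batchSize = if (is.null(batchSize)) NA_integer_ else bs),
            class = "apathyNN")
}

#' Predicted apathy probability from a fitted network
#'
#' @param object an `apathyNN` fit from [nnFit()].
#' @param x numeric matrix (n x d) or a single feature vector.
#' @return Numeric vector of sigmoid outputs in `(0, 1)`.
#' @export
nnPredictProb <- function(object, x) {
  stopifnot(inherits(object, "apathyNN"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != object$sizes[1])
    stop(sprintf("expected %d features, got %d", object$sizes[1], ncol(x)))
  acts <- nnForwardFull(object$layers, x)
  acts[[length(acts)]][, 1]
}

#' Number of trainable parameters of the network
#'
#' Counts weights and biases of a fully connected stack. The default
#' 8 -> 16 -> 32 -> 64 -> 1 architecture has
#' (8*16+16) + (16*32+32) + (32*64+64) + (64*1+1) = 2865 parameters.
#'
#' @param inputSize number of input features.
#' @param hidden integer vector of hidden-layer widths (may be empty for a
#'   direct input-to-output map).
#' @param outputSize number of outputs.
#' @return Integer parameter count.
#' @examples
#' nnParameterCount()          # 2865
#' nnParameterCount(8, integer(0), 1)  # 9
#' @export
nnParameterCount <- function(inputSize = 8L, hidden = c(16L, 32L, 64L),
                             outputSize = 1L) {
  sizes <- c(as.integer(inputSize), as.integer(hidden), as.integer(outputSize))
  if (any(is.na(sizes)) || any(sizes < 1L) || length(sizes) < 2L)
    stop("invalid architecture: all layer sizes must be >= 1")
  sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
}
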