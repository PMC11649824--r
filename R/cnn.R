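#' Specification of a 1D convolutional sequence classifier
#'
#' Architecture contract: `length(conv_filters)` blocks of 1D convolution
#' (valid cross-correlation) with ReLU activation, optional dropout,
#' batch normalization and max pooling; the output is flattened and, per
#' task, passed through that task's own fully connected hidden layer into
#' a sigmoid scalar output, trained with binary cross-entropy (summed
#' over tasks) under Adam. Training is deterministic given `seed` (single-threaded
#' numeric ops, seeded initialization, shuffling and dropout).
#'
#' @param input_len input sequence length (odd: site at the center)
#' @param n_outputs number of sigmoid output heads
#' @param conv_filters filters per conv block
#' @param kernel_sizes kernel length per block
#' @param pool_sizes max-pool size per block (1 = no pooling)
#' @param dense_units hidden fully connected layer width
#' @param dropout dropout rate applied after each conv ReLU
#' @param batchnorm use batch normalization in each block
#' @param epochs,batch_size,lr training hyperparameters
#' @param seed RNG seed for initialization/shuffling/dropout
#' @return list of class `cnn_spec`
#' @export
cnn_spec <- function(input_len, n_outputs = 1L,
                     conv_filters = c(64L, 64L, 64L, 64L),
                     kernel_sizes = c(8L, 6L, 6L, 6L),
                     pool_sizes = rep(2L, length(conv_filters)),
                     dense_units = 32L, dropout = 0, batchnorm = TRUE,
                     epochs = 20L, batch_size = 64L, lr = 1e-3,
                     seed = 1L) {
  .stop_if(input_len %% 2L == 0L, "input_len must be odd")
  .stop_if(length(conv_filters) < 1L, "need at least one conv block")
  .stop_if(length(kernel_sizes) != length(conv_filters) ||
             length(pool_sizes) != length(conv_filters),
           "conv_filters, kernel_sizes, pool_sizes must align")
  structure(list(input_len = input_len, n_channels = 4L,
                 n_outputs = n_outputs, conv_filters = conv_filters,
                 kernel_sizes = kernel_sizes, pool_sizes = pool_sizes,
                 dense_units = dense_units, dropout = dropout,
                 batchnorm = batchnorm, epochs = epochs,
                 batch_size = batch_size, lr = lr, seed = seed),
            class = c("cnn_spec", "list"))
}

# Feature maps live in one matrix layout throughout the network:
# a length-P map over N samples and C channels is the (P*N) x C matrix
# whose row (n-1)*P + p holds position p of sample n. All layout
# conversions are cached gather indices; no aperm copies.
.idx_cache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  idx <- .idx_cache[[key]]
  if (is.null(idx)) {
    if (length(.idx_cache) > 30L)
      rm(list = ls(.idx_cache), envir = .idx_cache)
    idx <- build()
    .idx_cache[[key]] <- idx
  }
  idx
}

# windows of width k over the matrix layout: (P_out*N) x (k*C)
.idx_conv <- function(P, N, C, k) .cached(paste("c", P, N, C, k), function() {
  Po <- P - k + 1L
  base <- rep((seq_len(N) - 1L) * P, each = Po) + seq_len(Po)
  off <- rep((seq_len(C) - 1L) * P * N, each = k) + (seq_len(k) - 1L)
  outer(base, off, `+`)
})

# flatten: (P*N) x C matrix -> N x (P*C) features (p fastest within c)
.idx_flat <- function(P, N, C) .cached(paste("f", P, N, C), function() {
  j <- seq_len(P * C)                       # (c-1)*P + p
  cc <- as.numeric((j - 1L) %/% P); pp <- (j - 1L) %% P + 1L
  t(vapply(seq_len(N), function(n) cc * P * N + (n - 1L) * P + pp,
           numeric(P * C)))
})

# array (L, C, N) -> matrix layout (L*N) x C
.idx_in <- function(L, C, N) .cached(paste("i", L, C, N), function() {
  r <- seq_len(L * N)                       # (n-1)*L + l
  l <- (r - 1L) %% L + 1L; n <- (r - 1L) %/% L
  vapply(seq_len(C), function(c) l + (c - 1L) * L + n * L * C,
         integer(L * N))
})

.to_mat <- function(X) {
  d <- dim(X)
  idx <- .idx_in(d[1], d[2], d[3])
  v <- X[idx]
  dim(v) <- dim(idx)
  v
}

# im2col over the matrix layout
.im2col_mat <- function(M, P, N, k) {
  idx <- .idx_conv(P, N, ncol(M), k)
  v <- M[idx]
  dim(v) <- dim(idx)
  v
}

# scatter-add of dZ back onto the matrix layout (reverse of .im2col_mat)
.col2im_mat <- function(dZ, P, N, C, k) {
  idx <- .idx_conv(P, N, C, k)
  dM <- matrix(0, P * N, C)
  for (j in seq_len(ncol(idx))) {   # indices within a column are unique
    dM[idx[, j]] <- dM[idx[, j]] + dZ[, j]
  }
  dM
}

# legacy array interface used by one-shot filter scans
.im2col <- function(X, k) {
  d <- dim(X)
  .im2col_mat(.to_mat(X), d[1], d[3], k)
}

.col_add <- function(M, v) M + rep(v, each = nrow(M))
.col_mul <- function(M, v) M * rep(v, each = nrow(M))

.cnn_init <- function(spec) {
  set.seed(spec$seed)
  params <- list()
  Cin <- spec$n_channels; L <- spec$input_len
  for (l in seq_along(spec$conv_filters)) {
    k <- spec$kernel_sizes[l]; Cout <- spec$conv_filters[l]
    params[[paste0("convW", l)]] <-
      matrix(stats::rnorm(k * Cin * Cout, 0, sqrt(2 / (k * Cin))),
             k * Cin, Cout)
    params[[paste0("convb", l)]] <- numeric(Cout)
    if (spec$batchnorm) {
      params[[paste0("bng", l)]] <- rep(1, Cout)
      params[[paste0("bnb", l)]] <- numeric(Cout)
    }
    L <- L - k + 1L
    if (spec$pool_sizes[l] > 1L) L <- L %/% spec$pool_sizes[l]
    Cin <- Cout
  }
  flat <- L * Cin
  # a separate fully connected layer per output head
  for (h in seq_len(spec$n_outputs)) {
    params[[paste0("headDW", h)]] <-
      matrix(stats::rnorm(flat * spec$dense_units, 0, sqrt(2 / flat)),
             flat, spec$dense_units)
    params[[paste0("headDb", h)]] <- numeric(spec$dense_units)
    params[[paste0("headW", h)]] <-
      matrix(stats::rnorm(spec$dense_units, 0, sqrt(1 / spec$dense_units)),
             spec$dense_units, 1L)
    params[[paste0("headb", h)]] <- 0
  }
  bn_stats <- list()
  if (spec$batchnorm)
    for (l in seq_along(spec$conv_filters))
      bn_stats[[l]] <- list(mean = numeric(spec$conv_filters[l]),
                            var = rep(1, spec$conv_filters[l]))
  list(params = params, bn_stats = bn_stats, flat_dims = c(L, Cin))
}

# forward pass; X: array (L, 4, N) or a matrix-layout list; returns
# probs and (optionally) the cache needed for backprop
.cnn_forward <- function(net, spec, X, train = FALSE, keep = FALSE) {
  if (is.array(X)) {
    N <- dim(X)[3]
    M <- .to_mat(X)
  } else {
    N <- X$N
    M <- X$M
  }
  P <- spec$input_len
  pr <- net$params
  cache <- list(layers = list())
  for (l in seq_along(spec$conv_filters)) {
    k <- spec$kernel_sizes[l]
    Pin <- P; Cin <- ncol(M)
    Z <- .im2col_mat(M, Pin, N, k)
    P <- Pin - k + 1L
    M <- .col_add(Z %*% pr[[paste0("convW", l)]], pr[[paste0("convb", l)]])
    lay <- list(Pin = Pin, Cin = Cin, Z = if (keep) Z else NULL)
    # ReLU
    relu_mask <- M > 0
    M <- M * relu_mask
    if (keep) lay$relu_mask <- relu_mask
    # dropout (inverted)
    if (train && spec$dropout > 0) {
      dm <- matrix(stats::runif(length(M)) >= spec$dropout, nrow(M))
      M <- M * dm / (1 - spec$dropout)
      if (keep) lay$drop_mask <- dm
    }
    # batchnorm over (positions x samples) per channel
    if (spec$batchnorm) {
      if (train) {
        mu <- colMeans(M)
        vr <- colMeans(M^2) - mu^2
        net$bn_stats[[l]]$mean <- 0.9 * net$bn_stats[[l]]$mean + 0.1 * mu
        net$bn_stats[[l]]$var <- 0.9 * net$bn_stats[[l]]$var + 0.1 * vr
      } else {
        mu <- net$bn_stats[[l]]$mean
        vr <- net$bn_stats[[l]]$var
      }
      sdv <- sqrt(vr + 1e-5)
      Mn <- .col_mul(.col_add(M, -mu), 1 / sdv)
      M <- .col_add(.col_mul(Mn, pr[[paste0("bng", l)]]),
                    pr[[paste0("bnb", l)]])
      if (keep) { lay$Mn <- Mn; lay$sdv <- sdv }
    }
    # max pool along positions
    ps <- spec$pool_sizes[l]
    if (ps > 1L) {
      P2 <- P %/% ps
      sel <- function(r) {
        prow <- (rep(seq_len(P2), N) - 1L) * ps + r
        prow + rep((seq_len(N) - 1L) * P, each = P2)
      }
      rows <- lapply(seq_len(ps), sel)
      Mp <- M[rows[[1]], , drop = FALSE]
      which_max <- matrix(1L, nrow(Mp), ncol(Mp))
      for (r in 2:ps) {
        Mr <- M[rows[[r]], , drop = FALSE]
        upd <- Mr > Mp
        Mp[upd] <- Mr[upd]
        which_max[upd] <- r
      }
      if (keep) { lay$rows <- rows; lay$which_max <- which_max
                  lay$dimM <- dim(M) }
      M <- Mp
      P <- P2
    }
    cache$layers[[l]] <- lay
  }
  C <- ncol(M)
  idxf <- .idx_flat(P, N, C)
  Fm <- M[idxf]
  dim(Fm) <- c(N, P * C)
  logits <- matrix(0, N, spec$n_outputs)
  hmask <- H <- vector("list", spec$n_outputs)
  for (h in seq_len(spec$n_outputs)) {
    H0 <- .col_add(Fm %*% pr[[paste0("headDW", h)]],
                   pr[[paste0("headDb", h)]])
    hmask[[h]] <- H0 > 0
    H[[h]] <- H0 * hmask[[h]]
    logits[, h] <- H[[h]] %*% pr[[paste0("headW", h)]] +
      pr[[paste0("headb", h)]]
  }
  probs <- stats::plogis(logits)
  if (keep) {
    cache$Fm <- Fm; cache$hmask <- hmask; cache$H <- H
    cache$P_final <- P; cache$C_final <- C; cache$N <- N
  }
  list(probs = probs, logits = logits, cache = cache, bn_stats = net$bn_stats)
}

.cnn_backward <- function(net, spec, fw, Y) {
  pr <- net$params
  cache <- fw$cache
  N <- nrow(fw$probs)
  grads <- list()
  dFm <- matrix(0, N, ncol(cache$Fm))
  for (h in seq_len(spec$n_outputs)) {
    dlogit <- (fw$probs[, h] - Y[, h]) / N
    grads[[paste0("headW", h)]] <- crossprod(cache$H[[h]], dlogit)
    grads[[paste0("headb", h)]] <- sum(dlogit)
    dH0 <- (dlogit %*% t(pr[[paste0("headW", h)]])) * cache$hmask[[h]]
    grads[[paste0("headDW", h)]] <- crossprod(cache$Fm, dH0)
    grads[[paste0("headDb", h)]] <- colSums(dH0)
    dFm <- dFm + dH0 %*% t(pr[[paste0("headDW", h)]])
  }
  # unflatten: bijective scatter back to the matrix layout
  P <- cache$P_final; C <- cache$C_final
  dM <- matrix(0, P * N, C)
  dM[.idx_flat(P, N, C)] <- dFm
  for (l in rev(seq_along(spec$conv_filters))) {
    lay <- cache$layers[[l]]
    if (spec$pool_sizes[l] > 1L) {
      dMfull <- matrix(0, lay$dimM[1], lay$dimM[2])
      for (r in seq_len(spec$pool_sizes[l])) {
        dMfull[lay$rows[[r]], ] <- dMfull[lay$rows[[r]], ] +
          dM * (lay$which_max == r)
      }
      dM <- dMfull
    }
    if (spec$batchnorm) {
      g <- pr[[paste0("bng", l)]]
      grads[[paste0("bng", l)]] <- colSums(dM * lay$Mn)
      grads[[paste0("bnb", l)]] <- colSums(dM)
      dMn <- .col_mul(dM, g)
      # batch-statistics backward
      t1 <- .col_add(dMn, -colMeans(dMn))
      t2 <- .col_mul(lay$Mn, colMeans(dMn * lay$Mn))
      dM <- .col_mul(t1 - t2, 1 / lay$sdv)
    }
    if (!is.null(lay$drop_mask))
      dM <- dM * lay$drop_mask / (1 - spec$dropout)
    dM <- dM * lay$relu_mask
    grads[[paste0("convW", l)]] <- crossprod(lay$Z, dM)
    grads[[paste0("convb", l)]] <- colSums(dM)
    if (l > 1L)
      dM <- .col2im_mat(dM %*% t(pr[[paste0("convW", l)]]), lay$Pin, N,
                        lay$Cin, spec$kernel_sizes[l])
  }
  grads
}

#' Train a convolutional sequence classifier
#'
#' @param X one-hot input array `(input_len, 4, N)` (see
#'   [onehot_encode()]) or a character vector of equal-length sequences
#' @param Y numeric matrix `N x n_outputs` of 0/1 labels (a vector for a
#'   single output)
#' @param spec a [cnn_spec()]
#' @param verbose print per-epoch loss
#' @return an object of class `cnn_model`
#' @export
cnn_train <- function(X, Y, spec, verbose = FALSE) {
  if (is.character(X)) X <- .onehot_batch(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  .stop_if(dim(X)[1] != spec$input_len, "input length mismatch")
  .stop_if(ncol(Y) != spec$n_outputs, "label columns must match n_outputs")
  N <- dim(X)[3]
  .stop_if(nrow(Y) != N, "labels must match samples")
  for (h in seq_len(ncol(Y)))
    .stop_if(length(unique(Y[, h])) < 2L,
             "output ", h, " has a single class in the training data")
  net <- .cnn_init(spec)
  Xm <- .to_mat(X)
  L <- spec$input_len
  adam <- list(m = lapply(net$params, function(p) p * 0),
               v = lapply(net$params, function(p) p * 0), t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample(N)
    nb <- ceiling(N / spec$batch_size)
    tot <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * spec$batch_size + 1L):min(b * spec$batch_size, N)]
      rows <- rep((idx - 1L) * L, each = L) + seq_len(L)
      Xb <- list(M = Xm[rows, , drop = FALSE], N = length(idx))
      Yb <- Y[idx, , drop = FALSE]
      fw <- .cnn_forward(net, spec, Xb, train = TRUE, keep = TRUE)
      net$bn_stats <- fw$bn_stats
      # stable BCE summed over heads
      tot <- tot + sum(log1p(exp(-abs(fw$logits))) +
                         pmax(fw$logits, 0) - Yb * fw$logits)
      gr <- .cnn_backward(net, spec, fw, Yb)
      adam$t <- adam$t + 1L
      corr1 <- 1 - b1^adam$t; corr2 <- 1 - b2^adam$t
      for (nm in names(gr)) {
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * gr[[nm]]
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * gr[[nm]]^2
        net$params[[nm]] <- net$params[[nm]] -
          spec$lr * (adam$m[[nm]] / corr1) /
          (sqrt(adam$v[[nm]] / corr2) + eps)
      }
    }
    if (verbose)
      message(sprintf("epoch %d: loss %.4f", epoch, tot / N))
  }
  structure(list(spec = spec, params = net$params,
                 bn_stats = net$bn_stats), class = "cnn_model")
}

#' Predict with a trained classifier
#' @param object a `cnn_model`
#' @param X one-hot array or character sequences
#' @param chunk prediction batch size
#' @param ... unused
#' @return matrix `N x n_outputs` of probabilities
#' @export
predict.cnn_model <- function(object, X, chunk = 256L, ...) {
  if (is.character(X)) X <- .onehot_batch(X)
  N <- dim(X)[3]
  L <- object$spec$input_len
  Xm <- .to_mat(X)
  out <- matrix(NA_real_, N, object$spec$n_outputs)
  i <- 1L
  while (i <= N) {
    j <- min(i + chunk - 1L, N)
    rows <- rep((i:j - 1L) * L, each = L) + seq_len(L)
    fw <- .cnn_forward(object, object$spec,
                       list(M = Xm[rows, , drop = FALSE], N = j - i + 1L),
                       train = FALSE, keep = FALSE)
    out[i:j, ] <- fw$probs
    i <- j + 1L
  }
  out
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("CNN sequence classifier: input %d nt, %d block(s) [%s filters], %d output(s)\n",
              s$input_len, length(s$conv_filters),
              paste(s$conv_filters, collapse = ","), s$n_outputs))
  invisible(x)
}

# first-layer filters as an array (k, 4, n_filters)
.first_layer_filters <- function(model) {
  W <- model$params$convW1
  k <- model$spec$kernel_sizes[1]
  array(W, c(k, 4L, ncol(W)))
}

# pre-activation cross-correlation scores of one filter over sequences:
# returns matrix (positions x N)
.scan_filter <- function(filter_w, X) {
  k <- dim(filter_w)[1]
  Z <- .im2col(X, k)
  sc <- Z %*% matrix(filter_w, ncol = 1L)
  matrix(sc, nrow = dim(X)[1] - k + 1L)
}
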