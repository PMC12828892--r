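## Minimal feed-forward network engine: 1-D valid convolutions, max pooling,
## global average pooling, dense layers, ReLU/sigmoid, inverted dropout,
## binary cross-entropy and Adam, with early stopping on validation
## accuracy. Activations are stored as (batch*time) x channels matrices so
## convolutions reduce to one matrix product per kernel offset.

nn_conv1d <- function(in_ch, out_ch, kernel) {
  w <- matrix(rnorm(kernel * in_ch * out_ch, sd = sqrt(2 / (kernel * in_ch))),
              nrow = kernel * in_ch, ncol = out_ch)
  list(type = "conv", W = w, b = numeric(out_ch), kernel = kernel,
       in_ch = in_ch, out_ch = out_ch)
}
nn_maxpool <- function(size) list(type = "maxpool", size = size)
nn_gap <- function() list(type = "gap")
nn_dense <- function(in_d, out_d, act = c("relu", "sigmoid", "linear")) {
  act <- match.arg(act)
  sdv <- if (act == "relu") sqrt(2 / in_d) else sqrt(1 / in_d)
  list(type = "dense", W = matrix(rnorm(in_d * out_d, sd = sdv), in_d, out_d),
       b = numeric(out_d), act = act)
}
nn_relu <- function() list(type = "relu")
nn_dropout <- function(rate) list(type = "dropout", rate = rate)

## rows of the (batch*time) layout touched by kernel offset k
conv_rows <- function(B, L, L_out, k) {
  rep((0:(B - 1)) * L, each = L_out) + rep(seq_len(L_out), B) + (k - 1L)
}

nn_forward <- function(layers, X, B, L, training = FALSE) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    cache <- list(B = B, L = L)
    if (lay$type == "conv") {
      L_out <- L - lay$kernel + 1L
      Y <- matrix(rep(lay$b, each = B * L_out), B * L_out, lay$out_ch)
      rows <- vector("list", lay$kernel)
      for (k in seq_len(lay$kernel)) {
        rows[[k]] <- conv_rows(B, L, L_out, k)
        wk <- lay$W[((k - 1) * lay$in_ch + 1):(k * lay$in_ch), , drop = FALSE]
        Y <- Y + X[rows[[k]], , drop = FALSE] %*% wk
      }
      cache$X <- X; cache$rows <- rows; cache$L_out <- L_out
      X <- Y; L <- L_out
    } else if (lay$type == "relu") {
      cache$mask <- X > 0
      X <- X * cache$mask
    } else if (lay$type == "maxpool") {
      P <- lay$size
      L_out <- L %/% P
      parts <- lapply(seq_len(P), function(p) {
        X[rep((0:(B - 1)) * L, each = L_out) + (seq_len(L_out) - 1L) * P + p, ,
          drop = FALSE]
      })
      M <- parts[[1]]
      for (p in 2:P) M <- pmax(M, parts[[p]])
      cache$parts <- parts; cache$M <- M; cache$L_out <- L_out
      X <- M; L <- L_out
    } else if (lay$type == "gap") {
      grp <- rep(seq_len(B), each = L)
      Y <- rowsum(X, grp) / L
      cache$L_in <- L
      X <- Y; L <- 1L
    } else if (lay$type == "dense") {
      Z <- sweep(X %*% lay$W, 2, lay$b, "+")
      cache$X <- X; cache$Z <- Z
      X <- switch(lay$act,
                  relu = Z * (Z > 0),
                  sigmoid = 1 / (1 + exp(-Z)),
                  linear = Z)
      cache$Y <- X
    } else if (lay$type == "dropout") {
      if (training && lay$rate > 0) {
        cache$mask <- (matrix(runif(length(X)), nrow(X), ncol(X)) >= lay$rate) /
          (1 - lay$rate)
        X <- X * cache$mask
      }
    }
    caches[[li]] <- cache
  }
  list(out = X, caches = caches)
}

nn_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    cache <- caches[[li]]
    if (lay$type == "conv") {
      dW <- matrix(0, nrow(lay$W), ncol(lay$W))
      dX <- matrix(0, cache$B * cache$L, lay$in_ch)
      for (k in seq_len(lay$kernel)) {
        rows <- cache$rows[[k]]
        sl <- ((k - 1) * lay$in_ch + 1):(k * lay$in_ch)
        dW[sl, ] <- crossprod(cache$X[rows, , drop = FALSE], dY)
        dX[rows, ] <- dX[rows, , drop = FALSE] +
          dY %*% t(lay$W[sl, , drop = FALSE])
      }
      grads[[li]] <- list(W = dW, b = colSums(dY))
      dY <- dX
    } else if (lay$type == "relu") {
      dY <- dY * cache$mask
    } else if (lay$type == "maxpool") {
      P <- lay$size
      B <- cache$B; L <- cache$L; L_out <- cache$L_out
      dX <- matrix(0, B * L, ncol(dY))
      remaining <- matrix(TRUE, nrow(dY), ncol(dY))
      for (p in seq_len(P)) {
        hit <- (cache$parts[[p]] == cache$M) & remaining
        remaining <- remaining & !hit
        rows <- rep((0:(B - 1)) * L, each = L_out) + (seq_len(L_out) - 1L) * P + p
        dX[rows, ] <- dY * hit
      }
      dY <- dX
    } else if (lay$type == "gap") {
      B <- cache$B; L <- cache$L_in
      dY <- dY[rep(seq_len(B), each = L), , drop = FALSE] / L
    } else if (lay$type == "dense") {
      dZ <- switch(lay$act,
                   relu = dY * (cache$Z > 0),
                   sigmoid = dY * cache$Y * (1 - cache$Y),
                   linear = dY)
      grads[[li]] <- list(W = crossprod(cache$X, dZ), b = colSums(dZ))
      dY <- dZ %*% t(lay$W)
    } else if (lay$type == "dropout") {
      if (!is.null(cache$mask)) dY <- dY * cache$mask
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(lay) {
    if (!is.null(lay$W)) {
      list(mW = lay$W * 0, vW = lay$W * 0, mb = lay$b * 0, vb = lay$b * 0)
    } else NULL
  })
}

adam_step <- function(layers, grads, state, t, lr = 1e-3, b1 = 0.9,
                      b2 = 0.999, eps = 1e-8) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    st <- state[[li]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    corr1 <- 1 - b1^t
    corr2 <- 1 - b2^t
    layers[[li]]$W <- layers[[li]]$W -
      lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    layers[[li]]$b <- layers[[li]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[li]] <- st
  }
  list(layers = layers, state = state)
}

## Forward pass for a feature matrix (n x p). Conv stacks view each row as a
## length-p single-channel series.
nn_predict_prob <- function(layers, X, conv_input) {
  n <- nrow(X)
  if (conv_input) {
    inp <- matrix(as.numeric(t(X)), ncol = 1) # (n*p) x 1, sample-major
    nn_forward(layers, inp, B = n, L = ncol(X), training = FALSE)$out[, 1]
  } else {
    nn_forward(layers, X, B = n, L = 1L, training = FALSE)$out[, 1]
  }
}

## Train with BCE + Adam, early stopping on validation accuracy (best epoch
## restored). X: n x p features, y: 0/1 labels. A stratified `val_frac`
## slice of the supplied training data is held out for early stopping.
nn_train <- function(layers, X, y, conv_input, seed,
                     epochs = 100, batch_size = 32, lr = 1e-3,
                     val_frac = 0.2, patience = 10) {
  n <- nrow(X)
  withr::with_seed(seed, {
    val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      sample(ix, max(1L, round(length(ix) * val_frac)))
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]
    ntr <- length(tr_idx)
    state <- adam_init(layers)
    best <- list(acc = -Inf, layers = layers, epoch = 0L)
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ntr)
      for (s in seq(1L, ntr, by = batch_size)) {
        take <- ord[s:min(s + batch_size - 1L, ntr)]
        xb <- Xtr[take, , drop = FALSE]
        yb <- ytr[take]
        B <- nrow(xb)
        if (conv_input) {
          inp <- matrix(as.numeric(t(xb)), ncol = 1)
          fw <- nn_forward(layers, inp, B = B, L = ncol(xb), training = TRUE)
        } else {
          fw <- nn_forward(layers, xb, B = B, L = 1L, training = TRUE)
        }
        p <- fw$out[, 1]
        # BCE gradient wrt pre-sigmoid z is (p - y)/B; the last layer is a
        # sigmoid dense, so feed dY = dL/dp and let backward apply p(1-p).
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        dY <- matrix((pc - yb) / (pc * (1 - pc)) / B, ncol = 1)
        grads <- nn_backward(layers, fw$caches, dY)
        t_step <- t_step + 1L
        upd <- adam_step(layers, grads, state, t_step, lr = lr)
        layers <- upd$layers
        state <- upd$state
      }
      pv <- nn_predict_prob(layers, Xva, conv_input)
      acc <- mean((pv > 0.5) == (yva == 1))
      if (acc > best$acc) {
        best <- list(acc = acc, layers = layers, epoch = ep)
      } else if (ep - best$epoch >= patience) {
        break
      }
    }
    best
  })
}
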