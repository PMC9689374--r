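# Minimal convolutional-network engine used by the SR architectures.
# Tensors are 4D arrays (H, W, C, N), double precision. Convolutions are
# 'same' padded, stride 1, realised as im2col + BLAS matrix multiply; the
# backward pass recomputes the im2col matrix from the cached input to keep
# memory proportional to activations.

.im2col <- function(x, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(H + 2 * p, W + 2 * p, C, N))
  Xp[p + seq_len(H), p + seq_len(W), , ] <- x
  M <- matrix(0, H * W * N, k * k * C)
  col <- 0L
  for (cc in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    col <- col + 1L
    M[, col] <- Xp[dy:(dy + H - 1L), dx:(dx + W - 1L), cc, ]
  }
  M
}

.col2im <- function(dM, k, H, W, C, N) {
  p <- (k - 1L) %/% 2L
  dXp <- array(0, c(H + 2 * p, W + 2 * p, C, N))
  col <- 0L
  for (cc in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    col <- col + 1L
    dXp[dy:(dy + H - 1L), dx:(dx + W - 1L), cc, ] <-
      dXp[dy:(dy + H - 1L), dx:(dx + W - 1L), cc, ] + array(dM[, col], c(H, W, N))
  }
  dXp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
}

.conv_layer <- function(k, cin, cout, init = c("he", "zero", "small"),
                        init_sd = NULL) {
  init <- match.arg(init)
  sd <- switch(init, he = sqrt(2 / (k * k * cin)), zero = 0,
               small = init_sd %||% 0.01)
  W <- matrix(stats::rnorm(k * k * cin * cout, 0, sd), k * k * cin, cout)
  list(type = "conv", W = W, b = numeric(cout), k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout))
}

# set W so that output channel `oc` passes input channel `ic` through unchanged
.conv_set_delta <- function(layer, ic = 1L, oc = 1L, weight = 1) {
  k <- layer$k
  centre <- (k + 1L) %/% 2L
  row <- centre + k * (centre - 1L) + k * k * (ic - 1L)
  layer$W[row, oc] <- weight
  layer
}

.relu_layer <- function() list(type = "relu")
.prelu_layer <- function(c) list(type = "prelu", a = rep(0.25, c))
.bn_layer <- function(c) list(type = "bn", gamma = rep(1, c), beta = rep(0, c),
                              rmean = rep(0, c), rvar = rep(1, c),
                              momentum = 0.9, eps = 1e-5)

.forward_layer <- function(layer, x, training) {
  d <- dim(x)
  switch(layer$type,
    conv = {
      M <- .im2col(x, layer$k)
      Y <- M %*% layer$W
      Y <- Y + rep(layer$b, each = nrow(Y))
      y <- aperm(array(Y, c(d[1], d[2], d[4], layer$cout)), c(1, 2, 4, 3))
      list(y = y, cache = list(x = x))
    },
    relu = {
      y <- pmax(x, 0)
      list(y = y, cache = list(pos = x > 0))
    },
    prelu = {
      a <- rep(layer$a, each = d[1] * d[2])
      neg <- pmin(x, 0)
      y <- pmax(x, 0) + a * neg
      list(y = y, cache = list(neg = neg, pos = x > 0))
    },
    bn = {
      m <- d[1] * d[2] * d[4]
      xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(m, d[3])
      if (training) {
        mu <- colMeans(xp)
        xc <- xp - rep(mu, each = m)
        var <- colMeans(xc^2)
        layer$rmean <- layer$momentum * layer$rmean + (1 - layer$momentum) * mu
        layer$rvar <- layer$momentum * layer$rvar + (1 - layer$momentum) * var
      } else {
        mu <- layer$rmean; var <- layer$rvar
        xc <- xp - rep(mu, each = m)
      }
      isd <- 1 / sqrt(var + layer$eps)
      xhat <- xc * rep(isd, each = m)
      yp <- xhat * rep(layer$gamma, each = m) + rep(layer$beta, each = m)
      y <- aperm(array(yp, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(y = y, cache = list(xhat = xhat, isd = isd, dims = d, m = m),
           layer = if (training) layer else NULL)
    },
    stop("unknown layer type"))
}

.backward_layer <- function(layer, dy, cache) {
  d <- dim(dy)
  switch(layer$type,
    conv = {
      x <- cache$x; dx_dims <- dim(x)
      dYm <- matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], layer$cout)
      M <- .im2col(x, layer$k)
      dW <- crossprod(M, dYm)
      db <- colSums(dYm)
      dM <- tcrossprod(dYm, layer$W)
      dx <- .col2im(dM, layer$k, dx_dims[1], dx_dims[2], dx_dims[3], dx_dims[4])
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dy * cache$pos, grads = NULL),
    prelu = {
      a <- rep(layer$a, each = d[1] * d[2])
      dx <- dy * cache$pos + a * dy * (!cache$pos)
      prod <- dy * cache$neg
      dim(prod) <- c(d[1] * d[2], d[3], d[4])
      da <- rowSums(colSums(prod))
      list(dx = dx, grads = list(a = da))
    },
    bn = {
      m <- cache$m
      dyp <- aperm(dy, c(1, 2, 4, 3)); dim(dyp) <- c(m, d[3])
      xhat <- cache$xhat
      dgamma <- colSums(dyp * xhat)
      dbeta <- colSums(dyp)
      g <- rep(layer$gamma * cache$isd, each = m)
      dxhat_terms <- dyp - rep(dbeta / m, each = m) -
        xhat * rep(dgamma / m, each = m)
      dxp <- g * dxhat_terms
      dx <- aperm(array(dxp, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    stop("unknown layer type"))
}

.forward_seq <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- .forward_layer(layers[[i]], x, training)
    x <- r$y
    caches[i] <- list(r$cache)              # [i] <- list(): keep NULL slots
    if (!is.null(r$layer)) layers[[i]] <- r$layer  # updated BN running stats
  }
  list(y = x, caches = caches, layers = layers)
}

.backward_seq <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- .backward_layer(layers[[i]], dy, caches[[i]])
    dy <- r$dx
    grads[i] <- list(r$grads)               # [i] <- list(): keep NULL slots
  }
  list(dx = dy, grads = grads)
}

# --- parameter bookkeeping ----------------------------------------------

.layer_param_names <- function(layer) {
  switch(layer$type, conv = c("W", "b"), prelu = "a",
         bn = c("gamma", "beta"), character(0))
}

.segments <- function(model) {
  segs <- list(stem = model$stem, mid = model$mid, tail = model$tail)
  for (i in seq_along(model$blocks)) segs[[paste0("block", i)]] <- model$blocks[[i]]
  segs
}

.collect_params <- function(model) {
  out <- list()
  for (sn in names(.segments(model))) {
    layers <- .segments(model)[[sn]]
    for (i in seq_along(layers)) {
      for (pn in .layer_param_names(layers[[i]])) {
        out[[paste(sn, i, pn, sep = ".")]] <- layers[[i]][[pn]]
      }
    }
  }
  out
}

.assign_params <- function(model, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sn <- parts[1]; i <- as.integer(parts[2]); pn <- parts[3]
    if (sn %in% c("stem", "mid", "tail")) {
      model[[sn]][[i]][[pn]] <- params[[key]]
    } else {
      bi <- as.integer(sub("block", "", sn))
      model$blocks[[bi]][[i]][[pn]] <- params[[key]]
    }
  }
  model
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (key in names(params)) {
    g <- grads[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    params[[key]] <- params[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2), 0)))
}
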