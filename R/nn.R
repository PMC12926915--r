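## Minimal feed-forward / 1-D convolutional network engine.
##
## Supports exactly the layer types the compartment classifiers need:
## dense, batch normalization, ReLU, dropout (inverted), 1-D same-padding
## convolution, max pooling (pool 2, floor), global average pooling, and a
## weighted softmax cross-entropy head, trained with Adam. Written against
## base R matrix algebra; intended for the small problem sizes of this
## package, not as a general deep-learning framework.

nn_new <- function(layers) structure(list(layers = layers), class = "prox_nn")

## He-normal init for ReLU fan-ins, seeded
nn_init_dense <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

nn_init_batchnorm <- function(d) {
  list(type = "batchnorm", gamma = rep(1, d), beta = numeric(d),
       running_mean = numeric(d), running_var = rep(1, d),
       eps = 1e-5, momentum = 0.9)
}

nn_init_conv <- function(c_in, n_filters, kernel) {
  list(type = "conv", kernel = kernel,
       W = matrix(rnorm(kernel * c_in * n_filters, 0,
                        sqrt(2 / (kernel * c_in))),
                  kernel * c_in, n_filters),
       b = numeric(n_filters))
}

## im2col for (N, L, C) input with same padding; rows ordered sample-fastest
conv_im2col <- function(x, kernel) {
  d <- dim(x); n <- d[1]; l <- d[2]; cc <- d[3]
  pl <- (kernel - 1) %/% 2
  xp <- array(0, c(n, l + kernel - 1, cc))
  xp[, pl + seq_len(l), ] <- x
  m <- matrix(0, n * l, kernel * cc)
  for (j in seq_len(kernel)) {
    sl <- xp[, j + 0:(l - 1), , drop = FALSE]
    m[, (j - 1) * cc + seq_len(cc)] <- matrix(sl, n * l, cc)
  }
  m
}

nn_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    cache <- list(x = x)
    x <- switch(ly$type,
      dense = sweep(x %*% ly$W, 2, ly$b, "+"),
      batchnorm = {
        if (training) {
          mu <- colMeans(x)
          va <- colMeans(sweep(x, 2, mu)^2)
          cache$mu <- mu; cache$va <- va
        } else {
          mu <- ly$running_mean; va <- ly$running_var
        }
        xhat <- sweep(sweep(x, 2, mu), 2, sqrt(va + ly$eps), "/")
        cache$xhat <- xhat
        sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      },
      relu = pmax(x, 0),
      dropout = {
        if (training && ly$rate > 0) {
          mask <- matrix(rbinom(length(x), 1, 1 - ly$rate), nrow(x)) /
            (1 - ly$rate)
          cache$mask <- mask
          x * mask
        } else x
      },
      conv = {
        d <- dim(x)
        m <- conv_im2col(x, ly$kernel)
        cache$m <- m; cache$dims <- d
        y <- sweep(m %*% ly$W, 2, ly$b, "+")
        array(y, c(d[1], d[2], ncol(ly$W)))
      },
      maxpool = {
        d <- dim(x); lout <- d[2] %/% 2
        a <- x[, seq(1, 2 * lout, by = 2), , drop = FALSE]
        b <- x[, seq(2, 2 * lout, by = 2), , drop = FALSE]
        cache$take_a <- a >= b
        cache$dims <- d
        pmax(a, b)
      },
      gap = {
        d <- dim(x); cache$dims <- d
        colMeans(aperm(x, c(2, 1, 3)), dims = 1)
      },
      stop("unknown layer type: ", ly$type))
    cache$out <- if (keep_cache) x else NULL
    caches[[i]] <- cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- caches[[i]]
    g <- list()
    dout <- switch(ly$type,
      dense = {
        g$W <- crossprod(ca$x, dout)
        g$b <- colSums(dout)
        dout %*% t(ly$W)
      },
      batchnorm = {
        xhat <- ca$xhat
        g$gamma <- colSums(dout * xhat)
        g$beta <- colSums(dout)
        dxhat <- sweep(dout, 2, ly$gamma, "*")
        if (!is.null(ca$mu)) {           # training-mode statistics
          nb <- nrow(xhat)
          inv <- 1 / sqrt(ca$va + ly$eps)
          t1 <- nb * dxhat
          t2 <- matrix(colSums(dxhat), nb, ncol(xhat), byrow = TRUE)
          t3 <- xhat * matrix(colSums(dxhat * xhat), nb, ncol(xhat),
                              byrow = TRUE)
          sweep(t1 - t2 - t3, 2, inv / nb, "*")
        } else {                          # inference: affine transform
          sweep(dxhat, 2, 1 / sqrt(ly$running_var + ly$eps), "*")
        }
      },
      relu = dout * (ca$x > 0),
      dropout = if (!is.null(ca$mask)) dout * ca$mask else dout,
      conv = {
        d <- ca$dims
        dy <- matrix(dout, d[1] * d[2], ncol(ly$W))
        g$W <- crossprod(ca$m, dy)
        g$b <- colSums(dy)
        dm <- dy %*% t(ly$W)
        kernel <- ly$kernel; cc <- d[3]
        pl <- (kernel - 1) %/% 2
        dxp <- array(0, c(d[1], d[2] + kernel - 1, cc))
        for (j in seq_len(kernel)) {
          dxp[, j + 0:(d[2] - 1), ] <- dxp[, j + 0:(d[2] - 1), ] +
            array(dm[, (j - 1) * cc + seq_len(cc)], c(d[1], d[2], cc))
        }
        dxp[, pl + seq_len(d[2]), , drop = FALSE]
      },
      maxpool = {
        d <- ca$dims; lout <- d[2] %/% 2
        dx <- array(0, d)
        dx[, seq(1, 2 * lout, by = 2), ] <- dout * ca$take_a
        dx[, seq(2, 2 * lout, by = 2), ] <- dout * !ca$take_a
        dx
      },
      gap = {
        d <- ca$dims
        dx <- array(0, d)
        for (t in seq_len(d[2])) dx[, t, ] <- dout / d[2]
        dx
      })
    grads[[i]] <- g
  }
  list(grads = grads, dx = dout)
}

## update running batch-norm statistics after a training forward pass
nn_update_running <- function(net, caches) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "batchnorm" && !is.null(caches[[i]]$mu)) {
      mom <- ly$momentum
      net$layers[[i]]$running_mean <- mom * ly$running_mean +
        (1 - mom) * caches[[i]]$mu
      net$layers[[i]]$running_var <- mom * ly$running_var +
        (1 - mom) * caches[[i]]$va
    }
  }
  net
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## weighted categorical cross-entropy; returns loss and gradient wrt logits
softmax_ce <- function(logits, y_idx, w) {
  p <- softmax(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), y_idx)]
  loss <- -sum(w * log(pmax(picked, 1e-12))) / sum(w)
  dl <- p
  dl[cbind(seq_len(n), y_idx)] <- dl[cbind(seq_len(n), y_idx)] - 1
  dl <- dl * (w / sum(w))
  list(loss = loss, dlogits = dl)
}

nn_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    for (nm in intersect(names(net$layers[[i]]),
                         c("W", "b", "gamma", "beta"))) {
      out[[paste0(i, ".", nm)]] <- net$layers[[i]][[nm]]
    }
  }
  out
}

adam_init <- function(net) {
  p <- nn_params(net)
  list(m = lapply(p, function(v) v * 0), v = lapply(p, function(v) v * 0),
       t = 0)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(net$layers)) {
    for (nm in intersect(names(grads[[i]] %||% list()),
                         c("W", "b", "gamma", "beta"))) {
      key <- paste0(i, ".", nm)
      g <- grads[[i]][[nm]]
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / (1 - beta1^state$t)
      vhat <- state$v[[key]] / (1 - beta2^state$t)
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

## subset rows of a 2-D matrix or 3-D array
take_rows <- function(x, idx) {
  if (length(dim(x)) == 3) x[idx, , , drop = FALSE]
  else x[idx, , drop = FALSE]
}

nn_predict <- function(net, x) {
  softmax(nn_forward(net, x, training = FALSE)$out)
}

## core Adam training loop with early stopping on validation loss
nn_train <- function(net, x, y_idx, w, x_val, y_val_idx, w_val,
                     lr = 1e-4, batch_size = 32, max_epochs = 1000,
                     patience = 25) {
  state <- adam_init(net)
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  best <- list(loss = Inf, net = net, epoch = 0)
  wait <- 0
  history <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      if (length(idx) < 2) next  # batch statistics need >= 2 rows
      fw <- nn_forward(net, take_rows(x, idx), training = TRUE)
      ce <- softmax_ce(fw$out, y_idx[idx], w[idx])
      bw <- nn_backward(net, fw$caches, ce$dlogits)
      net <- nn_update_running(net, fw$caches)
      upd <- adam_step(net, bw$grads, state, lr)
      net <- upd$net; state <- upd$state
    }
    val_logits <- nn_forward(net, x_val, training = FALSE)$out
    val_loss <- softmax_ce(val_logits, y_val_idx, w_val)$loss
    history <- c(history, val_loss)
    if (val_loss < best$loss - 1e-8) {
      best <- list(loss = val_loss, net = net, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(net = best$net, best_epoch = best$epoch, epochs_run = length(history),
       val_loss = best$loss, history = history)
}
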