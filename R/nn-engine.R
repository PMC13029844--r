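# Minimal neural-network engine for 1D time-series classification.
#
# Activations are arrays of dim (L, C, B): time x channels x batch; dense
# layers operate on (F, B) matrices. Every layer is a plain list with a
# $type; composite nodes (seq / res / parallel) recurse. Backward passes are
# hand-derived and verified against numerical gradients in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- constructors -----------------------------------------------------

nn_conv1d <- function(in_ch, out_ch, kernel) {
  sd <- sqrt(2 / (kernel * in_ch))
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       params = list(W = matrix(stats::rnorm(kernel * in_ch * out_ch, 0, sd),
                                kernel * in_ch, out_ch),
                     b = numeric(out_ch)))
}

nn_dwconv1d <- function(ch, kernel) {
  sd <- sqrt(2 / kernel)
  list(type = "dwconv1d", ch = ch, kernel = kernel,
       params = list(W = matrix(stats::rnorm(kernel * ch, 0, sd), kernel, ch),
                     b = numeric(ch)))
}

nn_dense <- function(in_f, out_f) {
  sd <- sqrt(2 / in_f)
  list(type = "dense", in_f = in_f, out_f = out_f,
       params = list(W = matrix(stats::rnorm(out_f * in_f, 0, sd), out_f, in_f),
                     b = numeric(out_f)))
}

nn_lstm <- function(in_ch, hidden) {
  s <- 1 / sqrt(hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
  list(type = "lstm", in_ch = in_ch, hidden = hidden,
       params = list(
         Wx = matrix(stats::runif(in_ch * 4 * hidden, -s, s), in_ch, 4 * hidden),
         Wh = matrix(stats::runif(hidden * 4 * hidden, -s, s), hidden, 4 * hidden),
         b = b))
}

nn_relu <- function() list(type = "relu")
nn_gelu <- function() list(type = "gelu")
nn_maxpool <- function(size) list(type = "maxpool", size = as.integer(size))
nn_gap <- function() list(type = "gap")
nn_flatten <- function() list(type = "flatten")
nn_dropout <- function(p) list(type = "dropout", p = p)
nn_rev <- function() list(type = "rev")

nn_seq <- function(...) list(type = "seq", layers = list(...))
# y = act(body(x) + proj(x)); proj NULL means identity skip
nn_res <- function(body, proj = NULL, act = "relu")
  list(type = "res", body = body, proj = proj, act = act)
nn_parallel <- function(...) list(type = "parallel", branches = list(...))

## ---- forward ----------------------------------------------------------

im2col <- function(xp, L, k, cin, B) {
  M <- matrix(0, L * B, k * cin)
  for (o in seq_len(k)) {
    slab <- xp[o:(o + L - 1), , , drop = FALSE]
    M[, ((o - 1) * cin + 1):(o * cin)] <-
      matrix(aperm(slab, c(1, 3, 2)), L * B, cin)
  }
  M
}

pad_time <- function(x, k) {
  L <- dim(x)[1]; cin <- dim(x)[2]; B <- dim(x)[3]
  p_l <- (k - 1) %/% 2
  xp <- array(0, c(L + k - 1, cin, B))
  xp[p_l + seq_len(L), , ] <- x
  list(xp = xp, p_l = p_l)
}

nn_forward <- function(node, x, train = FALSE) {
  switch(node$type,
    seq = {
      caches <- vector("list", length(node$layers))
      for (i in seq_along(node$layers)) {
        fw <- nn_forward(node$layers[[i]], x, train)
        x <- fw$y
        caches[[i]] <- fw$cache
      }
      list(y = x, cache = caches)
    },
    res = {
      body <- nn_forward(node$body, x, train)
      if (is.null(node$proj)) {
        skip <- list(y = x, cache = NULL)
      } else {
        skip <- nn_forward(node$proj, x, train)
      }
      pre <- body$y + skip$y
      y <- if (node$act == "relu") pmax(pre, 0) * 1 else pre
      dim(y) <- dim(pre)
      list(y = y, cache = list(body = body$cache, skip = skip$cache,
                               pre = pre))
    },
    parallel = {
      outs <- lapply(node$branches, nn_forward, x = x, train = train)
      chans <- vapply(outs, function(o) dim(o$y)[2], numeric(1))
      L <- dim(outs[[1]]$y)[1]; B <- dim(outs[[1]]$y)[3]
      y <- array(0, c(L, sum(chans), B))
      at <- 0
      for (o in outs) {
        cc <- dim(o$y)[2]
        y[, at + seq_len(cc), ] <- o$y
        at <- at + cc
      }
      list(y = y, cache = list(caches = lapply(outs, `[[`, "cache"),
                               chans = chans))
    },
    conv1d = {
      L <- dim(x)[1]; B <- dim(x)[3]
      pd <- pad_time(x, node$kernel)
      M <- im2col(pd$xp, L, node$kernel, node$in_ch, B)
      Ymat <- M %*% node$params$W
      Ymat <- sweep(Ymat, 2, node$params$b, "+")
      y <- aperm(array(Ymat, c(L, B, node$out_ch)), c(1, 3, 2))
      list(y = y, cache = list(M = M, L = L, B = B, p_l = pd$p_l))
    },
    dwconv1d = {
      L <- dim(x)[1]; ch <- dim(x)[2]; B <- dim(x)[3]
      pd <- pad_time(x, node$kernel)
      y <- array(rep(node$params$b, each = L), c(L, ch, B))
      for (o in seq_len(node$kernel)) {
        y <- y + pd$xp[o:(o + L - 1), , , drop = FALSE] *
          rep(node$params$W[o, ], each = L)
      }
      list(y = y, cache = list(xp = pd$xp, L = L, B = B, p_l = pd$p_l))
    },
    dense = {
      y <- node$params$W %*% x + node$params$b
      list(y = y, cache = list(x = x))
    },
    lstm = nn_forward_lstm(node, x),
    relu = {
      y <- pmax(x, 0)
      dim(y) <- dim(x)
      list(y = y, cache = list(mask = x > 0))
    },
    gelu = {
      c0 <- sqrt(2 / pi)
      u <- c0 * (x + 0.044715 * x^3)
      t <- tanh(u)
      list(y = 0.5 * x * (1 + t), cache = list(x = x, t = t))
    },
    maxpool = {
      s <- node$size
      L <- dim(x)[1]; ch <- dim(x)[2]; B <- dim(x)[3]
      Lp <- L %/% s
      if (Lp < 1) stop("sequence too short for pooling", call. = FALSE)
      y <- array(-Inf, c(Lp, ch, B))
      amax <- array(1L, c(Lp, ch, B))
      for (o in seq_len(s)) {
        cand <- x[o + s * (seq_len(Lp) - 1L), , , drop = FALSE]
        upd <- cand > y
        y[upd] <- cand[upd]
        amax[upd] <- o
      }
      list(y = y, cache = list(amax = amax, L = L, s = s))
    },
    gap = {
      L <- dim(x)[1]; ch <- dim(x)[2]; B <- dim(x)[3]
      y <- matrix(colMeans(matrix(x, L, ch * B)), ch, B)
      list(y = y, cache = list(L = L, ch = ch, B = B))
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, d[1] * d[2], d[3]), cache = list(d = d))
    },
    dropout = {
      if (!train || node$p <= 0) return(list(y = x, cache = list(mask = NULL)))
      mask <- (array(stats::runif(length(x)), dim(x)) >= node$p) / (1 - node$p)
      list(y = x * mask, cache = list(mask = mask))
    },
    rev = {
      L <- dim(x)[1]
      list(y = x[L:1, , , drop = FALSE], cache = NULL)
    },
    stop("unknown layer type: ", node$type)
  )
}

nn_forward_lstm <- function(node, x) {
  L <- dim(x)[1]; B <- dim(x)[3]
  H <- node$hidden
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  y <- array(0, c(L, H, B))
  steps <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- t(matrix(x[t, , ], dim(x)[2], B))           # (B, Cin)
    z <- xt %*% node$params$Wx + h %*% node$params$Wh
    z <- sweep(z, 2, node$params$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc,
                       i = i, f = f, g = g, o = o, tc = tc)
    h <- h_new; cc <- c_new
    y[t, , ] <- t(h)
  }
  list(y = y, cache = list(steps = steps, L = L, B = B))
}

## ---- backward ---------------------------------------------------------
# returns list(dx = ..., grads = tree mirroring the node structure)

col2im <- function(dM, L, k, cin, B, p_l) {
  dxp <- array(0, c(L + k - 1, cin, B))
  for (o in seq_len(k)) {
    dslab <- aperm(array(dM[, ((o - 1) * cin + 1):(o * cin)], c(L, B, cin)),
                   c(1, 3, 2))
    dxp[o:(o + L - 1), , ] <- dxp[o:(o + L - 1), , , drop = FALSE] + dslab
  }
  dxp[p_l + seq_len(L), , , drop = FALSE]
}

nn_backward <- function(node, cache, dy) {
  switch(node$type,
    seq = {
      grads <- vector("list", length(node$layers))
      for (i in rev(seq_along(node$layers))) {
        bw <- nn_backward(node$layers[[i]], cache[[i]], dy)
        dy <- bw$dx
        grads[i] <- list(bw$grads)  # keep NULL slots for parameterless layers
      }
      list(dx = dy, grads = grads)
    },
    res = {
      if (node$act == "relu") {
        dy <- dy * (cache$pre > 0)
      }
      body_bw <- nn_backward(node$body, cache$body, dy)
      if (is.null(node$proj)) {
        dx <- body_bw$dx + dy
        proj_grads <- NULL
      } else {
        proj_bw <- nn_backward(node$proj, cache$skip, dy)
        dx <- body_bw$dx + proj_bw$dx
        proj_grads <- proj_bw$grads
      }
      list(dx = dx, grads = list(body = body_bw$grads, proj = proj_grads))
    },
    parallel = {
      at <- 0
      dx <- NULL
      grads <- vector("list", length(node$branches))
      for (bi in seq_along(node$branches)) {
        cc <- cache$chans[bi]
        dpart <- dy[, at + seq_len(cc), , drop = FALSE]
        at <- at + cc
        bw <- nn_backward(node$branches[[bi]], cache$caches[[bi]], dpart)
        dx <- if (is.null(dx)) bw$dx else dx + bw$dx
        grads[bi] <- list(bw$grads)
      }
      list(dx = dx, grads = grads)
    },
    conv1d = {
      L <- cache$L; B <- cache$B
      dYmat <- matrix(aperm(dy, c(1, 3, 2)), L * B, node$out_ch)
      dW <- crossprod(cache$M, dYmat)
      db <- colSums(dYmat)
      dM <- dYmat %*% t(node$params$W)
      dx <- col2im(dM, L, node$kernel, node$in_ch, B, cache$p_l)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    dwconv1d = {
      L <- cache$L; B <- cache$B
      ch <- node$ch; k <- node$kernel
      dW <- matrix(0, k, ch)
      dxp <- array(0, dim(cache$xp))
      for (o in seq_len(k)) {
        slab <- cache$xp[o:(o + L - 1), , , drop = FALSE]
        dW[o, ] <- colSums(matrix(aperm(dy * slab, c(1, 3, 2)), ncol = ch))
        dxp[o:(o + L - 1), , ] <- dxp[o:(o + L - 1), , , drop = FALSE] +
          dy * rep(node$params$W[o, ], each = L)
      }
      db <- colSums(matrix(aperm(dy, c(1, 3, 2)), ncol = ch))
      dx <- dxp[cache$p_l + seq_len(L), , , drop = FALSE]
      list(dx = dx, grads = list(W = dW, b = db))
    },
    dense = {
      list(dx = t(node$params$W) %*% dy,
           grads = list(W = dy %*% t(cache$x), b = rowSums(dy)))
    },
    lstm = nn_backward_lstm(node, cache, dy),
    relu = list(dx = dy * cache$mask, grads = NULL),
    gelu = {
      c0 <- sqrt(2 / pi)
      x <- cache$x; t <- cache$t
      du <- c0 * (1 + 3 * 0.044715 * x^2)
      list(dx = dy * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * du), grads = NULL)
    },
    maxpool = {
      s <- cache$s
      Lp <- dim(dy)[1]
      dx <- array(0, c(cache$L, dim(dy)[2], dim(dy)[3]))
      for (o in seq_len(s)) {
        dx[o + s * (seq_len(Lp) - 1L), , ] <- dy * (cache$amax == o)
      }
      list(dx = dx, grads = NULL)
    },
    gap = {
      dx <- array(rep(as.numeric(dy) / cache$L, each = cache$L),
                  c(cache$L, cache$ch, cache$B))
      list(dx = dx, grads = NULL)
    },
    flatten = list(dx = array(dy, cache$d), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache$mask, grads = NULL)
    },
    rev = {
      L <- dim(dy)[1]
      list(dx = dy[L:1, , , drop = FALSE], grads = NULL)
    },
    stop("unknown layer type: ", node$type)
  )
}

nn_backward_lstm <- function(node, cache, dy) {
  H <- node$hidden
  L <- cache$L; B <- cache$B
  dWx <- matrix(0, nrow(node$params$Wx), 4 * H)
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  dx <- array(0, c(L, node$in_ch, B))
  for (t in rev(seq_len(L))) {
    st <- cache$steps[[t]]
    dh <- t(matrix(dy[t, , ], H, B)) + dh_next
    do_ <- dh * st$tc
    dc <- dh * st$o * (1 - st$tc^2) + dc_next
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dz)
    dWh <- dWh + crossprod(st$h_prev, dz)
    db <- db + colSums(dz)
    dx[t, , ] <- t(dz %*% t(node$params$Wx))
    dh_next <- dz %*% t(node$params$Wh)
    dc_next <- dc * st$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- loss, optimizer, training loop -----------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# logits (C, B), labels integer in 1..C; returns loss and dlogits
softmax_xent <- function(logits, labels) {
  B <- ncol(logits)
  p <- softmax_cols(logits)
  idx <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B)
}

# Adam over the nested parameter tree. The state mirrors the net structure.
adam_update <- function(node, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, t = 1) {
  if (node$type %in% c("seq", "parallel")) {
    kids <- if (node$type == "seq") "layers" else "branches"
    if (is.null(state)) state <- vector("list", length(node[[kids]]))
    for (i in seq_along(node[[kids]])) {
      up <- adam_update(node[[kids]][[i]], grads[[i]], state[[i]],
                        lr, beta1, beta2, eps, t)
      node[[kids]][[i]] <- up$node
      state[i] <- list(up$state)  # keep NULL slots for stateless layers
    }
    return(list(node = node, state = state))
  }
  if (node$type == "res") {
    if (is.null(state)) state <- list(body = NULL, proj = NULL)
    up <- adam_update(node$body, grads$body, state$body, lr, beta1, beta2, eps, t)
    node$body <- up$node; state$body <- up$state
    if (!is.null(node$proj)) {
      up <- adam_update(node$proj, grads$proj, state$proj, lr, beta1, beta2, eps, t)
      node$proj <- up$node; state$proj <- up$state
    }
    return(list(node = node, state = state))
  }
  if (is.null(node$params)) return(list(node = node, state = state))
  if (is.null(state)) {
    state <- lapply(node$params, function(p) list(m = p * 0, v = p * 0))
  }
  for (nm in names(node$params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    node$params[[nm]] <- node$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(node = node, state = state)
}

# x: (L, C, M) array; y: integer labels 1..C. Trains with minibatch Adam and
# early stopping on validation loss; returns the best-validation snapshot.
nn_fit <- function(net, x, y, x_val = NULL, y_val = NULL,
                   epochs = 100, batch_size = 16, lr = 1e-3,
                   patience = 10, verbose = FALSE) {
  M <- dim(x)[3]
  state <- NULL
  step <- 0
  best <- list(net = net, val_loss = Inf, epoch = 0)
  wait <- 0
  has_val <- !is.null(x_val) && dim(x_val)[3] > 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(M)
    for (start in seq(1, M, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, M)]
      xb <- x[, , idx, drop = FALSE]
      fw <- nn_forward(net, xb, train = TRUE)
      ls <- softmax_xent(fw$y, y[idx])
      if (!is.finite(ls$loss)) stop("non-finite training loss", call. = FALSE)
      bw <- nn_backward(net, fw$cache, ls$dlogits)
      step <- step + 1
      up <- adam_update(net, bw$grads, state, lr, t = step)
      net <- up$node
      state <- up$state
    }
    if (has_val) {
      vl <- nn_eval_loss(net, x_val, y_val, batch_size)
      if (verbose) {
        message(sprintf("epoch %d: val loss %.4f", ep, vl))
      }
      if (vl < best$val_loss - 1e-6) {
        best <- list(net = net, val_loss = vl, epoch = ep)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    } else {
      best <- list(net = net, val_loss = NA_real_, epoch = ep)
    }
  }
  best
}

nn_eval_loss <- function(net, x, y, batch_size = 64) {
  M <- dim(x)[3]
  tot <- 0
  for (start in seq(1, M, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, M)
    fw <- nn_forward(net, x[, , idx, drop = FALSE], train = FALSE)
    tot <- tot + softmax_xent(fw$y, y[idx])$loss * length(idx)
  }
  tot / M
}

nn_predict_probs <- function(net, x, batch_size = 64) {
  M <- dim(x)[3]
  out <- NULL
  for (start in seq(1, M, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, M)
    fw <- nn_forward(net, x[, , idx, drop = FALSE], train = FALSE)
    p <- t(softmax_cols(fw$y))
    out <- rbind(out, p)
  }
  out
}
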