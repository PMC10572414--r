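# Compact reverse-mode automatic differentiation on a tape.
#
# Values are plain R numerics: matrices for the recurrent controller,
# 3-D arrays (H, W, C) for the convolutional segmentation models. Each tape
# node stores its value, its parent node ids, and a backward closure mapping
# the node's output gradient to parent gradients. Convolutions are computed
# as im2col patch-matrix products so the heavy lifting stays in BLAS.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- list()
  tp$parents <- list()
  tp$back <- list()
  tp$pname <- character(0)
  tp
}

ad_push <- function(tp, val, parents = integer(0), back = NULL,
                    pname = NA_character_) {
  # force args before claiming an id: evaluating `val`/`parents` may push
  # parent nodes, and parents must precede children on the tape
  force(val); force(parents); force(back)
  tp$n <- tp$n + 1L
  id <- tp$n
  tp$vals[[id]] <- val
  tp$parents[[id]] <- parents
  tp$back[[id]] <- back
  tp$pname[id] <- pname
  id
}

ad_val <- function(tp, id) {
  force(id)  # id may be an unevaluated call that pushes onto the tape
  tp$vals[[id]]
}

ad_const <- function(tp, val) ad_push(tp, val)

# Leaf node bound to a named parameter in store `ps` (an environment with a
# list `W` of arrays). Gradients accumulate under the same name.
ad_param <- function(tp, ps, name) ad_push(tp, ps$W[[name]], pname = name)

# Backpropagate from scalar node `loss_id`; accumulates parameter gradients
# into environment `gr` (a list `G` keyed by parameter name). Returns the
# per-node gradient list (used by tests).
ad_backward <- function(tp, loss_id, gr) {
  g <- vector("list", tp$n)
  g[[loss_id]] <- 1
  for (id in seq.int(tp$n, 1L)) {
    gi <- g[[id]]
    if (is.null(gi)) next
    nm <- tp$pname[id]
    if (!is.na(nm)) {
      gr$G[[nm]] <- if (is.null(gr$G[[nm]])) gi else gr$G[[nm]] + gi
    }
    bf <- tp$back[[id]]
    if (is.null(bf)) next
    pg <- bf(gi)
    ps <- tp$parents[[id]]
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      p <- ps[k]
      g[[p]] <- if (is.null(g[[p]])) pg[[k]] else g[[p]] + pg[[k]]
    }
  }
  invisible(g)
}

grad_store <- function() {
  gr <- new.env(parent = emptyenv())
  gr$G <- list()
  gr
}

## ---- elementwise ------------------------------------------------------

ad_relu <- function(tp, a) {
  x <- ad_val(tp, a)
  y <- x * (x > 0)
  ad_push(tp, y, a, function(g) list(g * (x > 0)))
}

ad_sigmoid <- function(tp, a) {
  s <- 1 / (1 + exp(-ad_val(tp, a)))
  ad_push(tp, s, a, function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tp, a) {
  t <- tanh(ad_val(tp, a))
  ad_push(tp, t, a, function(g) list(g * (1 - t * t)))
}

ad_exp <- function(tp, a) {
  y <- exp(ad_val(tp, a))
  ad_push(tp, y, a, function(g) list(g * y))
}

ad_add <- function(tp, a, b) {
  ad_push(tp, ad_val(tp, a) + ad_val(tp, b), c(a, b), function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  ad_push(tp, ad_val(tp, a) - ad_val(tp, b), c(a, b), function(g) list(g, -g))
}

ad_mul <- function(tp, a, b) {
  va <- ad_val(tp, a); vb <- ad_val(tp, b)
  ad_push(tp, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

ad_scale <- function(tp, a, k) {
  ad_push(tp, ad_val(tp, a) * k, a, function(g) list(g * k))
}

ad_sum <- function(tp, a) {
  x <- ad_val(tp, a)
  ad_push(tp, sum(x), a, function(g) list(array(g, dim(x) %||% length(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- matrix ops (controller) ------------------------------------------

ad_matmul <- function(tp, a, b) {
  va <- ad_val(tp, a); vb <- ad_val(tp, b)
  ad_push(tp, va %*% vb, c(a, b),
          function(g) list(g %*% t(vb), t(va) %*% g))
}

# A (n x d) + row vector b (length d), broadcast over rows
ad_bias_row <- function(tp, a, b) {
  va <- ad_val(tp, a); vb <- ad_val(tp, b)
  ad_push(tp, sweep(va, 2, vb, "+"), c(a, b),
          function(g) list(g, colSums(g)))
}

ad_slice_cols <- function(tp, a, cols) {
  va <- ad_val(tp, a)
  ad_push(tp, va[, cols, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    out[, cols] <- g
    list(out)
  })
}

ad_cbind2 <- function(tp, a, b) {
  va <- ad_val(tp, a); vb <- ad_val(tp, b)
  na <- ncol(va)
  ad_push(tp, cbind(va, vb), c(a, b),
          function(g) list(g[, seq_len(na), drop = FALSE],
                           g[, -seq_len(na), drop = FALSE]))
}

# Select row i of a parameter matrix (embedding lookup)
ad_row <- function(tp, a, i) {
  va <- ad_val(tp, a)
  ad_push(tp, va[i, , drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(va), ncol(va))
    out[i, ] <- g
    list(out)
  })
}

# log-probability of token k under softmax(logits); logits is 1 x V
ad_logsoftmax_pick <- function(tp, a, k) {
  z <- ad_val(tp, a)
  z <- z - max(z)
  q <- exp(z) / sum(exp(z))
  ad_push(tp, log(q[k]), a, function(g) {
    d <- -q
    d[k] <- d[k] + 1
    list(g * matrix(d, 1))
  })
}

# entropy of softmax(logits)
ad_entropy <- function(tp, a) {
  z <- ad_val(tp, a)
  z <- z - max(z)
  q <- exp(z) / sum(exp(z))
  lq <- log(pmax(q, 1e-12))
  H <- -sum(q * lq)
  ad_push(tp, H, a, function(g) list(g * matrix(-q * (lq + H), 1)))
}

## ---- convolutional ops (H, W, C arrays) --------------------------------

.conv_cache <- new.env(parent = emptyenv())

# Index matrix mapping each of the H*W 3x3 patches of a zero-padded
# (H+2, W+2, Cin) array to its 9*Cin linear positions.
im2col_idx <- function(h, w, cin) {
  key <- paste(h, w, cin, sep = "_")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  hp <- h + 2L
  # top-left corner (0-based, padded coords) of each patch
  ci <- rep(0:(h - 1), times = w)
  cj <- rep(0:(w - 1), each = h)
  corner <- ci + cj * hp  # 0-based linear index within one padded channel
  off <- as.vector(outer(0:2, 0:2, function(di, dj) di + dj * hp))
  base <- outer(corner, off, "+")  # (h*w) x 9
  plane <- hp * (w + 2L)
  idx <- matrix(0L, h * w, 9L * cin)
  for (c in seq_len(cin)) {
    idx[, (c - 1L) * 9L + 1:9] <- base + (c - 1L) * plane
  }
  idx <- idx + 1L
  .conv_cache[[key]] <- idx
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

# 3x3 convolution, stride 1, zero padding 1.
# x: (H, W, Cin); w: (9*Cin, Cout); b: length Cout
ad_conv3 <- function(tp, a, wid, bid) {
  x <- ad_val(tp, a); w <- ad_val(tp, wid); b <- ad_val(tp, bid)
  d <- dim(x)
  h <- d[1]; wd <- d[2]; cin <- d[3]
  cout <- ncol(w)
  idx <- im2col_idx(h, wd, cin)
  xp <- pad1(x)
  P <- matrix(xp[idx], h * wd, 9L * cin)
  out <- sweep(P %*% w, 2, b, "+")
  ad_push(tp, array(out, c(h, wd, cout)), c(a, wid, bid), function(g) {
    gm <- matrix(g, h * wd, cout)
    dW <- crossprod(P, gm)
    db <- colSums(gm)
    dP <- gm %*% t(w)
    # scatter-add the 9 patch offsets back onto the padded input
    dxp <- array(0, dim(xp))
    for (k in 1:9) {
      di <- (k - 1L) %% 3L
      dj <- (k - 1L) %/% 3L
      blk <- array(dP[, seq.int(k, 9L * cin, by = 9L)], c(h, wd, cin))
      dxp[(1:h) + di, (1:wd) + dj, ] <-
        dxp[(1:h) + di, (1:wd) + dj, , drop = FALSE] + blk
    }
    list(dxp[2:(h + 1L), 2:(wd + 1L), , drop = FALSE], dW, db)
  })
}

# 1x1 convolution. x: (H, W, Cin); w: (Cin, Cout); b: length Cout
ad_conv1 <- function(tp, a, wid, bid) {
  x <- ad_val(tp, a); w <- ad_val(tp, wid); b <- ad_val(tp, bid)
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3])
  out <- sweep(X %*% w, 2, b, "+")
  ad_push(tp, array(out, c(d[1], d[2], ncol(w))), c(a, wid, bid), function(g) {
    gm <- matrix(g, d[1] * d[2], ncol(w))
    list(array(gm %*% t(w), d), crossprod(X, gm), colSums(gm))
  })
}

# 2x2 max pooling (H, W even)
ad_maxpool2 <- function(tp, a) {
  x <- ad_val(tp, a)
  d <- dim(x)
  h <- d[1]; w <- d[2]; ch <- d[3]
  io <- seq(1L, h, 2L); jo <- seq(1L, w, 2L)
  s <- list(x[io, jo, , drop = FALSE], x[io + 1L, jo, , drop = FALSE],
            x[io, jo + 1L, , drop = FALSE], x[io + 1L, jo + 1L, , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  ad_push(tp, out, a, function(g) {
    dx <- array(0, d)
    left <- out  # running "still unclaimed max" marker
    for (k in 1:4) {
      hit <- (s[[k]] == left) & !is.na(left)
      gk <- g * hit
      left[hit] <- NA  # ties route gradient to the first position only
      if (k == 1L) dx[io, jo, ] <- gk
      else if (k == 2L) dx[io + 1L, jo, ] <- gk
      else if (k == 3L) dx[io, jo + 1L, ] <- gk
      else dx[io + 1L, jo + 1L, ] <- gk
    }
    list(dx)
  })
}

# 2x2 stride-2 transposed convolution (upsampling by 2).
# x: (h, w, Cin); w: (Cin, 4*Cout) with the 4 block positions ordered
# (dy=0,dx=0), (1,0), (0,1), (1,1); b: length Cout
ad_convT2 <- function(tp, a, wid, bid) {
  x <- ad_val(tp, a); w <- ad_val(tp, wid); b <- ad_val(tp, bid)
  d <- dim(x)
  h <- d[1]; wd <- d[2]; cin <- d[3]
  cout <- ncol(w) %/% 4L
  X <- matrix(x, h * wd, cin)
  Y <- X %*% w  # (h*w, 4*cout)
  out <- array(0, c(2L * h, 2L * wd, cout))
  io <- seq(1L, 2L * h, 2L); jo <- seq(1L, 2L * wd, 2L)
  for (k in 1:4) {
    blk <- array(Y[, (k - 1L) * cout + seq_len(cout)], c(h, wd, cout))
    if (k == 1L) out[io, jo, ] <- blk
    else if (k == 2L) out[io + 1L, jo, ] <- blk
    else if (k == 3L) out[io, jo + 1L, ] <- blk
    else out[io + 1L, jo + 1L, ] <- blk
  }
  out <- sweep(out, 3, b, "+")
  ad_push(tp, out, c(a, wid, bid), function(g) {
    gY <- matrix(0, h * wd, 4L * cout)
    for (k in 1:4) {
      blk <- if (k == 1L) g[io, jo, , drop = FALSE]
      else if (k == 2L) g[io + 1L, jo, , drop = FALSE]
      else if (k == 3L) g[io, jo + 1L, , drop = FALSE]
      else g[io + 1L, jo + 1L, , drop = FALSE]
      gY[, (k - 1L) * cout + seq_len(cout)] <- matrix(blk, h * wd, cout)
    }
    db <- rowSums(matrix(aperm(g, c(3, 1, 2)), cout))
    list(array(gY %*% t(w), d), crossprod(X, gY), db)
  })
}

ad_concat_c <- function(tp, a, b) {
  va <- ad_val(tp, a); vb <- ad_val(tp, b)
  da <- dim(va); db_ <- dim(vb)
  out <- array(0, c(da[1], da[2], da[3] + db_[3]))
  out[, , seq_len(da[3])] <- va
  out[, , da[3] + seq_len(db_[3])] <- vb
  ad_push(tp, out, c(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db_[3]), drop = FALSE])
  })
}

# Instance normalization: per-channel standardization over H x W, then
# affine (gamma, beta). gamma/beta: length-C parameters.
ad_instnorm <- function(tp, a, gid, bid, eps = 1e-5) {
  x <- ad_val(tp, a); gamma <- ad_val(tp, gid); beta <- ad_val(tp, bid)
  d <- dim(x)
  n <- d[1] * d[2]
  X <- matrix(x, n, d[3])
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colSums(xc * xc) / n
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  ad_push(tp, array(out, d), c(a, gid, bid), function(g) {
    gm <- matrix(g, n, d[3])
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gx <- sweep(gm, 2, gamma, "*")
    # standard instance/batch-norm backward per channel
    t1 <- sweep(gx, 2, colMeans(gx))
    t2 <- sweep(xhat, 2, colMeans(gx * xhat) , "*")
    dX <- sweep(t1 - t2, 2, istd, "*")
    list(array(dX, d), dgamma, dbeta)
  })
}

# x (H, W, C) scaled by single-channel attention map a (H, W, 1)
ad_mul_att <- function(tp, a, att) {
  x <- ad_val(tp, a); m <- ad_val(tp, att)
  d <- dim(x)
  mv <- as.vector(m)
  out <- x * array(mv, d)
  ad_push(tp, out, c(a, att), function(g) {
    dx <- g * array(mv, d)
    dm <- array(rowSums(matrix(g * x, d[1] * d[2], d[3])), c(d[1], d[2], 1L))
    list(dx, dm)
  })
}

## ---- fused segmentation loss node --------------------------------------

# scores: (H, W, 2) raw class scores; target: (H, W, 2) one-hot constant.
# Value: 0.5 * CE + 0.5 * DiceLoss (foreground channel), exactly the
# hybrid_loss() definition. Gradient is analytic through the softmax.
ad_hybrid_loss_node <- function(tp, a, target, alpha = 1, w_ce = 0.5,
                                w_dice = 0.5) {
  s <- ad_val(tp, a)
  d <- dim(s)
  n <- d[1] * d[2]
  m <- pmax(s[, , 1], s[, , 2])
  e1 <- exp(s[, , 1] - m); e2 <- exp(s[, , 2] - m)
  z <- e1 + e2
  q1 <- e1 / z; q2 <- e2 / z
  p1 <- target[, , 1]; p2 <- target[, , 2]
  qc1 <- pmin(pmax(q1, 1e-7), 1 - 1e-7)
  qc2 <- pmin(pmax(q2, 1e-7), 1 - 1e-7)
  ce <- -sum(p1 * log(qc1) + p2 * log(qc2)) / n
  y <- p2; qf <- q2
  num <- 2 * sum(y * qf) + alpha
  den <- sum(y) + sum(qf) + alpha
  dice_loss <- 1 - num / den
  val <- w_ce * ce + w_dice * dice_loss
  id <- ad_push(tp, val, a, function(g) {
    dce1 <- (q1 - p1) / n
    dce2 <- (q2 - p2) / n
    # d dice_loss / d qf
    gqf <- -(2 * y * den - num) / (den * den)
    dd1 <- gqf * qf * (0 - q1)
    dd2 <- gqf * qf * (1 - q2)
    ds <- array(0, d)
    ds[, , 1] <- w_ce * dce1 + w_dice * dd1
    ds[, , 2] <- w_ce * dce2 + w_dice * dd2
    list(g * ds)
  })
  attr(tp$vals[[id]], "components") <- c(ce = ce, dice = dice_loss)
  id
}

## ---- Adam optimizer -----------------------------------------------------

adam_new <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- list(); opt$v <- list()
  opt
}

adam_step <- function(opt, ps, gr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(gr$G)) {
    g <- gr$G[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mh <- opt$m[[nm]] / bc1
    vh <- opt$v[[nm]] / bc2
    ps$W[[nm]] <- ps$W[[nm]] - opt$lr * mh / (sqrt(vh) + opt$eps)
  }
  invisible(opt)
}
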