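# Self-contained residual convolutional network engine.
#
# Activations are 4D arrays (H, W, C, N). Convolutions are evaluated as
# im2col matrix products against BLAS; the im2col / col2im passes are
# expressed as k^2 strided slice copies, so no per-pixel R loops occur.
# Layers are environments (parameters update in place during SGD);
# residual blocks hold nested layer lists for the main and shortcut
# branches. Only what the two classifiers need is implemented:
# convolution, batch normalization, ReLU, max pooling, global average
# pooling, a linear head, and softmax cross-entropy.

nnConv <- function(k, cin, cout, stride = 1L, pad = 0L, needDx = TRUE) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- k; e$cin <- cin; e$cout <- cout
  e$stride <- stride; e$pad <- pad; e$needDx <- needDx
  sdv <- sqrt(2 / (k * k * cin))           # He initialization
  e$W <- matrix(rnorm(k * k * cin * cout, sd = sdv), k * k * cin, cout)
  e$b <- numeric(cout)
  e$vW <- 0 * e$W; e$vb <- numeric(cout)
  e
}

nnBatchNorm <- function(c) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"; e$c <- c
  e$gamma <- rep(1, c); e$beta <- numeric(c)
  e$runMean <- numeric(c); e$runVar <- rep(1, c)
  e$momentum <- 0.1; e$eps <- 1e-5
  e$vgamma <- numeric(c); e$vbeta <- numeric(c)
  e
}

nnRelu <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "relu"; e
}

nnMaxPool <- function(k = 3L, stride = 2L, pad = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool"; e$k <- k; e$stride <- stride; e$pad <- pad
  e
}

nnGap <- function() {
  e <- new.env(parent = emptyenv()); e$type <- "gap"; e
}

nnFc <- function(cin, cout) {
  e <- new.env(parent = emptyenv())
  e$type <- "fc"; e$cin <- cin; e$cout <- cout
  e$W <- matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  e$b <- numeric(cout)
  e$vW <- 0 * e$W; e$vb <- numeric(cout)
  e
}

nnResBlock <- function(main, shortcut = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- "res"; e$main <- main; e$shortcut <- shortcut
  e
}

padArray <- function(x, p, fill = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  xp
}

convForward <- function(L, x, train) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  k <- L$k; s <- L$stride; p <- L$pad
  xp <- padArray(x, p)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  Xc <- matrix(0, Ho * Wo * N, k * k * C)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    sl <- xp[seq.int(di, by = s, length.out = Ho),
             seq.int(dj, by = s, length.out = Wo), , , drop = FALSE]
    sl <- aperm(sl, c(1L, 2L, 4L, 3L))
    dim(sl) <- c(Ho * Wo * N, C)
    Xc[, di + (dj - 1L) * k + (seq_len(C) - 1L) * k * k] <- sl
  }
  y <- Xc %*% L$W
  y <- y + rep(L$b, each = nrow(y))
  if (train) {
    L$Xc <- Xc; L$dims <- c(H, W, C, N, Ho, Wo)
  }
  dim(y) <- c(Ho, Wo, N, L$cout)
  aperm(y, c(1L, 2L, 4L, 3L))
}

convBackward <- function(L, dy) {
  d <- L$dims; H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  Ho <- d[5L]; Wo <- d[6L]
  k <- L$k; s <- L$stride; p <- L$pad
  dY <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dY) <- c(Ho * Wo * N, L$cout)
  L$dW <- crossprod(L$Xc, dY)
  L$db <- colSums(dY)
  L$Xc <- NULL
  if (!L$needDx) return(NULL)
  dXc <- dY %*% t(L$W)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  dxp <- array(0, c(Hp, Wp, C, N))
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    sl <- dXc[, di + (dj - 1L) * k + (seq_len(C) - 1L) * k * k,
              drop = FALSE]
    dim(sl) <- c(Ho, Wo, N, C)
    sl <- aperm(sl, c(1L, 2L, 4L, 3L))
    si <- seq.int(di, by = s, length.out = Ho)
    sj <- seq.int(dj, by = s, length.out = Wo)
    dxp[si, sj, , ] <- dxp[si, sj, , ] + sl
  }
  if (p > 0L)
    dxp <- dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
  dxp
}

bnForward <- function(L, x, train) {
  d <- dim(x); C <- d[3L]
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(d[1L] * d[2L] * d[4L], C)
  m <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + L$eps)
    xhat <- xc * rep(invstd, each = m)
    if (isTRUE(L$calibrating)) {
      L$accMean <- L$accMean + mu
      L$accVar <- L$accVar + v
      L$accN <- L$accN + 1L
    } else {
      L$runMean <- (1 - L$momentum) * L$runMean + L$momentum * mu
      L$runVar <- (1 - L$momentum) * L$runVar + L$momentum * v
    }
    L$xhat <- xhat; L$invstd <- invstd; L$dims <- d
  } else {
    invstd <- 1 / sqrt(L$runVar + L$eps)
    xhat <- (xm - rep(L$runMean, each = m)) * rep(invstd, each = m)
  }
  y <- xhat * rep(L$gamma, each = m) + rep(L$beta, each = m)
  dim(y) <- c(d[1L], d[2L], d[4L], C)
  aperm(y, c(1L, 2L, 4L, 3L))
}

bnBackward <- function(L, dy) {
  d <- L$dims; C <- d[3L]
  dym <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dym) <- c(d[1L] * d[2L] * d[4L], C)
  m <- nrow(dym)
  xhat <- L$xhat
  L$dgamma <- colSums(dym * xhat)
  L$dbeta <- colSums(dym)
  dxhat <- dym * rep(L$gamma, each = m)
  sum1 <- colSums(dxhat)
  sum2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(sum1 / m, each = m) -
         xhat * rep(sum2 / m, each = m)) * rep(L$invstd, each = m)
  L$xhat <- NULL
  dim(dx) <- c(d[1L], d[2L], d[4L], C)
  aperm(dx, c(1L, 2L, 4L, 3L))
}

reluForward <- function(L, x, train) {
  y <- x
  y[y < 0] <- 0
  if (train) L$mask <- y > 0
  y
}

reluBackward <- function(L, dy) {
  dx <- dy
  dx[!L$mask] <- 0
  L$mask <- NULL
  dx
}

maxpoolForward <- function(L, x, train) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  k <- L$k; s <- L$stride; p <- L$pad
  xp <- padArray(x, p, fill = -Inf)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  out <- array(-Inf, c(Ho, Wo, C, N))
  arg <- array(0L, c(Ho, Wo, C, N))
  q <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    q <- q + 1L
    sl <- xp[seq.int(di, by = s, length.out = Ho),
             seq.int(dj, by = s, length.out = Wo), , , drop = FALSE]
    upd <- sl > out
    out[upd] <- sl[upd]
    arg[upd] <- q
  }
  if (train) { L$arg <- arg; L$dims <- d; L$out <- c(Ho, Wo) }
  out
}

maxpoolBackward <- function(L, dy) {
  d <- L$dims; H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  k <- L$k; s <- L$stride; p <- L$pad
  Ho <- L$out[1L]; Wo <- L$out[2L]
  dxp <- array(0, c(H + 2L * p, W + 2L * p, C, N))
  q <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    q <- q + 1L
    contrib <- dy * (L$arg == q)
    si <- seq.int(di, by = s, length.out = Ho)
    sj <- seq.int(dj, by = s, length.out = Wo)
    dxp[si, sj, , ] <- dxp[si, sj, , ] + contrib
  }
  L$arg <- NULL
  if (p > 0L)
    dxp <- dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
  dxp
}

gapForward <- function(L, x, train) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L], d[3L] * d[4L])
  y <- colMeans(x)
  dim(y) <- c(d[3L], d[4L])
  if (train) L$dims <- d
  t(y)                                     # (N, C)
}

gapBackward <- function(L, dy) {
  d <- L$dims
  hw <- d[1L] * d[2L]
  array(rep(as.vector(t(dy)) / hw, each = hw), d)
}

fcForward <- function(L, x, train) {
  if (train) L$x <- x
  y <- x %*% L$W
  y + rep(L$b, each = nrow(y))
}

fcBackward <- function(L, dy) {
  L$dW <- crossprod(L$x, dy)
  L$db <- colSums(dy)
  L$x <- NULL
  dy %*% t(L$W)
}

forwardLayer <- function(L, x, train) {
  switch(L$type,
    conv = convForward(L, x, train),
    bn = bnForward(L, x, train),
    relu = reluForward(L, x, train),
    maxpool = maxpoolForward(L, x, train),
    gap = gapForward(L, x, train),
    fc = fcForward(L, x, train),
    res = resForward(L, x, train),
    stop("unknown layer type ", L$type))
}

backwardLayer <- function(L, dy) {
  switch(L$type,
    conv = convBackward(L, dy),
    bn = bnBackward(L, dy),
    relu = reluBackward(L, dy),
    maxpool = maxpoolBackward(L, dy),
    gap = gapBackward(L, dy),
    fc = fcBackward(L, dy),
    res = resBackward(L, dy),
    stop("unknown layer type ", L$type))
}

forwardSeq <- function(layers, x, train) {
  for (L in layers) x <- forwardLayer(L, x, train)
  x
}

backwardSeq <- function(layers, dy) {
  for (L in rev(layers)) dy <- backwardLayer(L, dy)
  dy
}

resForward <- function(L, x, train) {
  h <- forwardSeq(L$main, x, train)
  sc <- if (is.null(L$shortcut)) x else forwardSeq(L$shortcut, x, train)
  y <- h + sc
  y[y < 0] <- 0
  if (train) L$mask <- y > 0
  y
}

resBackward <- function(L, dy) {
  dy <- dy * L$mask
  L$mask <- NULL
  dm <- backwardSeq(L$main, dy)
  ds <- if (is.null(L$shortcut)) dy else backwardSeq(L$shortcut, dy)
  dm + ds
}

basicBlock <- function(cin, cout, stride) {
  main <- list(nnConv(3L, cin, cout, stride, 1L),
               nnBatchNorm(cout), nnRelu(),
               nnConv(3L, cout, cout, 1L, 1L),
               nnBatchNorm(cout))
  shortcut <- if (cin != cout || stride != 1L)
    list(nnConv(1L, cin, cout, stride, 0L), nnBatchNorm(cout))
  nnResBlock(main, shortcut)
}

bottleneckBlock <- function(cin, cmid, stride) {
  cout <- 4L * cmid
  main <- list(nnConv(1L, cin, cmid, 1L, 0L),
               nnBatchNorm(cmid), nnRelu(),
               nnConv(3L, cmid, cmid, stride, 1L),
               nnBatchNorm(cmid), nnRelu(),
               nnConv(1L, cmid, cout, 1L, 0L),
               nnBatchNorm(cout))
  shortcut <- if (cin != cout || stride != 1L)
    list(nnConv(1L, cin, cout, stride, 0L), nnBatchNorm(cout))
  nnResBlock(main, shortcut)
}

# standard residual arrangement: 7x7/2 stem + 3x3/2 max pool, four
# stages of residual blocks doubling the width and halving resolution,
# global average pooling and a linear softmax head.
buildResnet <- function(depth, width, inChannels, nClasses) {
  depth <- as.integer(depth)
  if (!depth %in% c(18L, 50L))
    stop("unsupported backbone depth: ", depth,
         " (supported: 18, 50)")
  w <- as.integer(width)
  layers <- list(nnConv(7L, inChannels, w, 2L, 3L, needDx = FALSE),
                 nnBatchNorm(w), nnRelu(), nnMaxPool(3L, 2L, 1L))
  widths <- w * c(1L, 2L, 4L, 8L)
  if (depth == 18L) {
    nblocks <- c(2L, 2L, 2L, 2L); expansion <- 1L
    makeBlock <- basicBlock
  } else {
    nblocks <- c(3L, 4L, 6L, 3L); expansion <- 4L
    makeBlock <- bottleneckBlock
  }
  cur <- w
  for (s in 1:4) {
    for (b in seq_len(nblocks[s])) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      layers <- c(layers, list(makeBlock(cur, widths[s], stride)))
      cur <- widths[s] * expansion
    }
  }
  c(layers, list(nnGap(), nnFc(cur, nClasses)))
}

collectParamLayers <- function(layers) {
  out <- list()
  for (L in layers) {
    if (L$type == "res") {
      out <- c(out, collectParamLayers(L$main))
      if (!is.null(L$shortcut))
        out <- c(out, collectParamLayers(L$shortcut))
    } else if (L$type %in% c("conv", "fc", "bn")) {
      out <- c(out, list(L))
    }
  }
  out
}

sgdStep <- function(paramLayers, lr, momentum = 0.9, weightDecay = 1e-4) {
  for (L in paramLayers) {
    if (L$type == "bn") {
      L$vgamma <- momentum * L$vgamma - lr * L$dgamma
      L$vbeta <- momentum * L$vbeta - lr * L$dbeta
      L$gamma <- L$gamma + L$vgamma
      L$beta <- L$beta + L$vbeta
    } else {
      L$vW <- momentum * L$vW - lr * (L$dW + weightDecay * L$W)
      L$vb <- momentum * L$vb - lr * L$db
      L$W <- L$W + L$vW
      L$b <- L$b + L$vb
    }
  }
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# After short training runs the exponential running estimates used at
# inference lag behind the final weights; recompute them exactly by
# averaging batch statistics over a sweep of the training data.
calibrateBatchNorm <- function(layers, x, batchSize = 64L) {
  bns <- Filter(function(L) L$type == "bn", collectParamLayers(layers))
  for (L in bns) {
    L$calibrating <- TRUE
    L$accMean <- 0 * L$runMean; L$accVar <- 0 * L$runVar
    L$accN <- 0L
  }
  n <- dim(x)[4L]
  for (start in seq.int(1L, n, by = batchSize)) {
    ix <- start:min(start + batchSize - 1L, n)
    if (length(ix) < 2L) next          # batch stats need >= 2 samples
    forwardSeq(layers, x[, , , ix, drop = FALSE], train = TRUE)
  }
  for (L in bns) {
    if (L$accN > 0L) {
      L$runMean <- L$accMean / L$accN
      L$runVar <- L$accVar / L$accN
    }
    L$calibrating <- FALSE
    L$xhat <- NULL
  }
  invisible(layers)
}

# weight transport for model persistence ----------------------------------

exportWeights <- function(layers) {
  lapply(layers, function(L) {
    switch(L$type,
      res = list(type = "res", main = exportWeights(L$main),
                 shortcut = if (!is.null(L$shortcut))
                   exportWeights(L$shortcut)),
      conv = , fc = list(type = L$type, W = L$W, b = L$b),
      bn = list(type = "bn", gamma = L$gamma, beta = L$beta,
                runMean = L$runMean, runVar = L$runVar),
      list(type = L$type))
  })
}

importWeights <- function(layers, weights) {
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) {
    L <- layers[[i]]; wt <- weights[[i]]
    stopifnot(identical(L$type, wt$type))
    if (L$type == "res") {
      importWeights(L$main, wt$main)
      if (!is.null(L$shortcut)) importWeights(L$shortcut, wt$shortcut)
    } else if (L$type %in% c("conv", "fc")) {
      L$W <- wt$W; L$b <- wt$b
    } else if (L$type == "bn") {
      L$gamma <- wt$gamma; L$beta <- wt$beta
      L$runMean <- wt$runMean; L$runVar <- wt$runVar
    }
  }
  invisible(layers)
}

# simple per-sample augmentation: axis flips and 90-degree rotations
augmentBatch <- function(xb) {
  N <- dim(xb)[4L]
  for (n in seq_len(N)) {
    s <- xb[, , , n, drop = FALSE]
    if (runif(1L) < 0.5) s <- s[rev(seq_len(dim(s)[1L])), , , , drop = FALSE]
    if (runif(1L) < 0.5) s <- s[, rev(seq_len(dim(s)[2L])), , , drop = FALSE]
    k <- sample(0:3, 1L)
    if (k > 0L && dim(s)[1L] == dim(s)[2L]) {
      for (j in seq_len(k)) {
        s <- aperm(s, c(2L, 1L, 3L, 4L))
        s <- s[rev(seq_len(dim(s)[1L])), , , , drop = FALSE]
      }
    }
    xb[, , , n] <- s
  }
  xb
}
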