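# Network forward/backward. Activations are (H, W, C, N) double arrays; the
# heavy conv work is done by the im2col GEMM kernels in src/.

LRELU_SLOPE <- 0.01
INORM_EPS <- 1e-5

conv_pad <- function(k) (k - 1L) %/% 2L

# instance norm forward: per (channel, sample) standardization + affine
inorm_fw <- function(x, g, b) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  X <- matrix(x, HW, C * N)
  m <- colMeans(X)
  Xm <- sweep(X, 2, m)
  v <- colMeans(Xm^2)
  istd <- 1 / sqrt(v + INORM_EPS)
  xhat <- sweep(Xm, 2, istd, `*`)
  gc <- rep(g, N); bc <- rep(b, N)
  y <- array(sweep(sweep(xhat, 2, gc, `*`), 2, bc, `+`), d)
  list(y = y, xhat = xhat, istd = istd, dims = d)
}

inorm_bw <- function(cache, g, dy) {
  d <- cache$dims
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  DY <- matrix(dy, HW, C * N)
  xhat <- cache$xhat
  dg_cols <- colSums(DY * xhat)
  db_cols <- colSums(DY)
  dg <- rowSums(matrix(dg_cols, C, N))
  db <- rowSums(matrix(db_cols, C, N))
  dxhat <- sweep(DY, 2, rep(g, N), `*`)
  mu1 <- colMeans(dxhat)
  mu2 <- colMeans(dxhat * xhat)
  dX <- sweep(dxhat - sweep(xhat, 2, mu2, `*`), 2, mu1) # dxhat - mean - xhat*mean(dxhat*xhat)
  dX <- sweep(dX, 2, cache$istd, `*`)
  list(dx = array(dX, d), dg = dg, db = db)
}

lrelu_fw <- function(x) ifelse(x > 0, x, LRELU_SLOPE * x)
lrelu_bw <- function(x, dy) dy * ifelse(x > 0, 1, LRELU_SLOPE)

# structural metadata shared by forward and backward
arch_topology <- function(arch) {
  ns <- arch$n_stages
  pool <- arch$n_poolings_per_axis
  stride <- function(i) ifelse(i <= pool & i >= 1L, 2L, 1L)
  list(ns = ns,
       enc_stride = lapply(seq_len(ns) - 1L, stride),
       dec_stride = lapply(seq_len(ns - 1L) - 1L, function(d) stride(ns - 1L - d)))
}

# one conv->inorm->lrelu block; returns output and cache
block_fw <- function(p, pre, j, x, stride) {
  w <- p[[sprintf("%s.convs.%d.weight", pre, j)]]
  b <- p[[sprintf("%s.convs.%d.bias", pre, j)]]
  k <- dim(w)[1]; pd <- conv_pad(k)
  z <- .conv2d_fw(x, w, b, stride[1], stride[2], pd, pd)
  nm <- inorm_fw(z, p[[sprintf("%s.norms.%d.weight", pre, j)]],
                 p[[sprintf("%s.norms.%d.bias", pre, j)]])
  list(y = lrelu_fw(nm$y), x = x, z = z, nm = nm, stride = stride, pre = pre, j = j)
}

block_bw <- function(p, cache, dy, grads) {
  pre <- cache$pre; j <- cache$j
  dz_act <- lrelu_bw(cache$nm$y, dy)
  nb <- inorm_bw(cache$nm, p[[sprintf("%s.norms.%d.weight", pre, j)]], dz_act)
  grads[[sprintf("%s.norms.%d.weight", pre, j)]] <- nb$dg
  grads[[sprintf("%s.norms.%d.bias", pre, j)]] <- nb$db
  w <- p[[sprintf("%s.convs.%d.weight", pre, j)]]
  k <- dim(w)[1]; pd <- conv_pad(k)
  cb <- .conv2d_bw(cache$x, w, nb$dx, cache$stride[1], cache$stride[2], pd, pd)
  grads[[sprintf("%s.convs.%d.weight", pre, j)]] <- cb$gw
  grads[[sprintf("%s.convs.%d.bias", pre, j)]] <- cb$gb
  list(dx = cb$gx, grads = grads)
}

# full forward; returns logits and (optionally) caches for backward
net_fw <- function(state, arch, x, keep_cache = FALSE) {
  p <- state$params
  topo <- arch_topology(arch)
  ns <- topo$ns
  skips <- vector("list", ns)
  caches <- list(enc = vector("list", ns), dec = vector("list", ns - 1L))
  h <- x
  for (i in seq_len(ns) - 1L) {
    pre <- sprintf("encoder.stages.%d", i)
    c0 <- block_fw(p, pre, 0L, h, if (i == 0L) c(1L, 1L) else topo$enc_stride[[i + 1L]])
    c1 <- block_fw(p, pre, 1L, c0$y, c(1L, 1L))
    h <- c1$y
    skips[[i + 1L]] <- h
    if (keep_cache) caches$enc[[i + 1L]] <- list(c0 = c0, c1 = c1)
  }
  z <- h
  for (d in seq_len(ns - 1L) - 1L) {
    pre <- sprintf("decoder.stages.%d", d)
    st <- topo$dec_stride[[d + 1L]]
    w <- p[[sprintf("%s.upconv.weight", pre)]]
    b <- p[[sprintf("%s.upconv.bias", pre)]]
    zin <- z
    up <- .convt2d_fw(z, w, b, st[1], st[2])
    skip <- skips[[ns - 1L - d]]
    cat_in <- abind4(up, skip)
    c0 <- block_fw(p, pre, 0L, cat_in, c(1L, 1L))
    c1 <- block_fw(p, pre, 1L, c0$y, c(1L, 1L))
    z <- c1$y
    if (keep_cache) {
      caches$dec[[d + 1L]] <- list(zin = zin, up_ch = dim(up)[3], st = st,
                                   c0 = c0, c1 = c1)
    }
  }
  wh <- p[["head.weight"]]
  logits <- .conv2d_fw(z, wh, p[["head.bias"]], 1L, 1L, 0L, 0L)
  if (keep_cache) caches$head_in <- z
  list(logits = logits, caches = if (keep_cache) caches else NULL)
}

# channel concatenation of two (H,W,C,N) arrays
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# softmax over the class axis of (H,W,K,N) logits
softmax4 <- function(logits) {
  d <- dim(logits)
  HW <- d[1] * d[2]; K <- d[3]; N <- d[4]
  P <- array(0, d)
  for (n in seq_len(N)) {
    M <- matrix(logits[, , , n], HW, K)
    M <- M - apply(M, 1, max)
    E <- exp(M)
    P[, , , n] <- array(E / rowSums(E), c(d[1], d[2], K))
  }
  P
}

# Equally weighted cross-entropy + soft Dice (batch dice over foreground
# classes). Returns loss and gradient w.r.t. logits.
seg_loss <- function(logits, y, n_classes, grad = TRUE) {
  d <- dim(logits)
  HW <- d[1] * d[2]; K <- d[3]; N <- d[4]
  P <- softmax4(logits)
  Y <- array(0, d)
  for (k in seq_len(K) - 1L) Y[, , k + 1L, ] <- (y == k) * 1
  npix <- HW * N
  eps <- 1e-5
  py <- pmax(apply(P * Y, c(1, 2, 4), sum), 1e-12)
  ce <- -mean(log(py))
  fg <- seq_len(K - 1L) + 1L  # class indices 2..K (labels 1..K-1)
  A <- vapply(fg, function(k) sum(P[, , k, ] * Y[, , k, ]), numeric(1))
  Bp <- vapply(fg, function(k) sum(P[, , k, ]), numeric(1))
  By <- vapply(fg, function(k) sum(Y[, , k, ]), numeric(1))
  dice_k <- (2 * A + eps) / (Bp + By + eps)
  dice_loss <- 1 - mean(dice_k)
  loss <- ce + dice_loss
  if (!grad) return(list(loss = loss, ce = ce, dice = dice_loss))
  # CE gradient closed form through softmax
  G <- (P - Y) / npix
  # Dice gradient wrt probabilities, chained through softmax
  Gp <- array(0, d)
  for (ki in seq_along(fg)) {
    k <- fg[ki]
    denom <- (Bp[ki] + By[ki] + eps)
    Gp[, , k, ] <- -(2 * Y[, , k, ] * denom - (2 * A[ki] + eps)) / denom^2 / length(fg)
  }
  inner <- apply(Gp * P, c(1, 2, 4), sum)
  Gd <- array(0, d)
  for (k in seq_len(K)) Gd[, , k, ] <- P[, , k, ] * (Gp[, , k, ] - inner)
  list(loss = loss, ce = ce, dice = dice_loss, dlogits = G + Gd)
}

# full backward; returns named gradient list covering every parameter
net_bw <- function(state, arch, fw, dlogits) {
  p <- state$params
  topo <- arch_topology(arch)
  ns <- topo$ns
  grads <- list()
  wh <- p[["head.weight"]]
  hb <- .conv2d_bw(fw$caches$head_in, wh, dlogits, 1L, 1L, 0L, 0L)
  grads[["head.weight"]] <- hb$gw
  grads[["head.bias"]] <- hb$gb
  dz <- hb$gx
  dskip <- vector("list", ns)  # gradients flowing into encoder outputs
  for (d in rev(seq_len(ns - 1L) - 1L)) {
    cache <- fw$caches$dec[[d + 1L]]
    pre <- sprintf("decoder.stages.%d", d)
    b1 <- block_bw(p, cache$c1, dz, grads); grads <- b1$grads
    b0 <- block_bw(p, cache$c0, b1$dx, grads); grads <- b0$grads
    dcat <- b0$dx
    nup <- cache$up_ch
    dup <- dcat[, , seq_len(nup), , drop = FALSE]
    dsk <- dcat[, , nup + seq_len(dim(dcat)[3] - nup), , drop = FALSE]
    lev <- ns - 1L - d  # encoder level of the skip (1-based)
    dskip[[lev]] <- if (is.null(dskip[[lev]])) dsk else dskip[[lev]] + dsk
    ub <- .convt2d_bw(cache$zin, p[[sprintf("%s.upconv.weight", pre)]], dup,
                      cache$st[1], cache$st[2])
    grads[[sprintf("%s.upconv.weight", pre)]] <- ub$gw
    grads[[sprintf("%s.upconv.bias", pre)]] <- ub$gb
    dz <- ub$gx
  }
  # dz now hits the deepest encoder output; add any skip gradient
  for (i in rev(seq_len(ns) - 1L)) {
    lev <- i + 1L
    dh <- if (lev == ns) dz else dskip[[lev]]
    if (is.null(dh)) dh <- 0
    cache <- fw$caches$enc[[lev]]
    b1 <- block_bw(p, cache$c1, dh, grads); grads <- b1$grads
    b0 <- block_bw(p, cache$c0, b1$dx, grads); grads <- b0$grads
    if (i > 0L) {
      lev_below <- i
      dskip[[lev_below]] <- if (is.null(dskip[[lev_below]])) b0$dx else dskip[[lev_below]] + b0$dx
    }
  }
  grads
}
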