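# Minimal CPU engine for the encoder-decoder: forward and analytic backward
# passes for 3x3 same-padding convolution, batch normalization, leaky ReLU,
# 2x2 max pooling, and x2 bilinear upsampling.
#
# Activation layout: 4-D arrays dim (H, W, N, C) — batch before channels so
# that flattening the first three dims gives a (H*W*N) x C matrix on which a
# 3x3 convolution is nine shifted GEMMs. All heavy lifting is BLAS; the
# engine is deterministic for a fixed seed and thread count.

# ---- 3x3 convolution, zero padding 1 ----------------------------------------

# Compiled im2col + GEMM path (src/conv3x3.cpp); convForwardR/convBackwardR
# below are the plain-R reference used to cross-check the compiled kernels.
convForward <- function(x, W, b) .conv3x3Fwd(x, W, as.numeric(b))

convBackward <- function(x, W, dy) .conv3x3Bwd(x, W, dy)

convForwardR <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  xmat <- matrix(x, H * Wd * N, Cin)
  y <- array(rep(b, each = H * Wd * N), c(H, Wd, N, Cout))
  for (di in -1:1) for (dj in -1:1) {
    Wk <- matrix(W[di + 2, dj + 2, , ], Cin, Cout)
    Z <- array(xmat %*% Wk, c(H, Wd, N, Cout))
    i0 <- max(1, 1 - di); i1 <- min(H, H - di)
    j0 <- max(1, 1 - dj); j1 <- min(Wd, Wd - dj)
    y[i0:i1, j0:j1, , ] <- y[i0:i1, j0:j1, , , drop = FALSE] +
      Z[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj), , , drop = FALSE]
  }
  y
}

convBackwardR <- function(x, W, dy) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  dymat <- matrix(dy, H * Wd * N, Cout)
  db <- colSums(dymat)
  dW <- array(0, dim(W))
  dx <- array(0, dim(x))
  for (di in -1:1) for (dj in -1:1) {
    Wk <- matrix(W[di + 2, dj + 2, , ], Cin, Cout)
    i0 <- max(1, 1 - di); i1 <- min(H, H - di)
    j0 <- max(1, 1 - dj); j1 <- min(Wd, Wd - dj)
    G <- array(dymat %*% t(Wk), c(H, Wd, N, Cin))
    dx[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj), , ] <-
      dx[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj), , , drop = FALSE] +
      G[i0:i1, j0:j1, , , drop = FALSE]
    xs <- x[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj), , , drop = FALSE]
    ds <- dy[i0:i1, j0:j1, , , drop = FALSE]
    dW[di + 2, dj + 2, , ] <- crossprod(matrix(xs, length(xs) / Cin, Cin),
                                        matrix(ds, length(ds) / Cout, Cout))
  }
  list(dx = dx, dW = dW, db = db)
}

conv1x1Forward <- function(x, W, b) {
  d <- dim(x); Cin <- d[4]; Cout <- ncol(W)
  y <- matrix(x, prod(d[1:3]), Cin) %*% W
  y <- sweep(y, 2, b, "+")
  array(y, c(d[1:3], Cout))
}

conv1x1Backward <- function(x, W, dy) {
  d <- dim(x); Cin <- d[4]; Cout <- ncol(W)
  xmat <- matrix(x, prod(d[1:3]), Cin)
  dymat <- matrix(dy, prod(d[1:3]), Cout)
  list(dx = array(dymat %*% t(W), d),
       dW = crossprod(xmat, dymat),
       db = colSums(dymat))
}

# ---- batch normalization -----------------------------------------------------

bnForward <- function(x, gamma, beta, buf, training, eps = 1e-5,
                      momentum = 0.1) {
  d <- dim(x); M <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, M, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu  # biased batch variance
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * v
  } else {
    mu <- buf$mean; v <- buf$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(invstd, each = M)
  y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  list(y = array(y, d), xhat = xhat, invstd = invstd, buf = buf)
}

bnBackward <- function(cache, gamma, dy) {
  d <- dim(dy); M <- prod(d[1:3]); C <- d[4]
  dym <- matrix(dy, M, C)
  xhat <- cache$xhat
  dbeta <- colSums(dym)
  dgamma <- colSums(dym * xhat)
  dxhat <- dym * rep(gamma, each = M)
  sx <- colSums(dxhat)
  sxx <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(sx / M, each = M) - xhat * rep(sxx / M, each = M)) *
    rep(cache$invstd, each = M)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -------------------------------------------------------------

lreluForward <- function(x, slope = 0.01) {
  pmax(x, 0) + slope * pmin(x, 0)
}

lreluBackward <- function(x, dy, slope = 0.01) {
  dy * (slope + (1 - slope) * (x > 0))
}

# ---- 2x2 max pooling ---------------------------------------------------------

poolForward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  if (H %% 2L || W %% 2L) stop("pooling requires even spatial dims")
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  a <- x[ri, ci, , , drop = FALSE];      b <- x[ri, ci + 1L, , , drop = FALSE]
  cc <- x[ri + 1L, ci, , , drop = FALSE]; dd <- x[ri + 1L, ci + 1L, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  list(y = y, parts = list(a = a, b = b, c = cc, d = dd))
}

poolBackward <- function(cache, dy, dimx) {
  y <- pmax(cache$parts$a, cache$parts$b, cache$parts$c, cache$parts$d)
  # fixed precedence a > b > c > d breaks ties deterministically
  ma <- cache$parts$a == y
  mb <- cache$parts$b == y & !ma
  mc <- cache$parts$c == y & !ma & !mb
  md <- !ma & !mb & !mc
  dx <- array(0, dimx)
  H <- dimx[1]; W <- dimx[2]
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  dx[ri, ci, , ] <- dy * ma
  dx[ri, ci + 1L, , ] <- dy * mb
  dx[ri + 1L, ci, , ] <- dy * mc
  dx[ri + 1L, ci + 1L, , ] <- dy * md
  dx
}

# ---- x2 bilinear upsampling --------------------------------------------------

# Interpolation matrix mapping n source rows to 2n output rows (half-pixel
# centre convention, edges clamped); cached per size.
upsampleMatrixCache <- new.env(parent = emptyenv())

upsampleMatrix <- function(n) {
  key <- as.character(n)
  if (!is.null(upsampleMatrixCache[[key]])) return(upsampleMatrixCache[[key]])
  i <- seq_len(2L * n)
  src <- (i - 0.5) / 2 + 0.5
  lo <- floor(src)
  frac <- src - lo
  frac[lo < 1] <- 0; lo[lo < 1] <- 1
  frac[lo >= n] <- 0; lo[lo >= n] <- n
  hi <- pmin(lo + 1, n)
  M <- Matrix::sparseMatrix(i = c(i, i), j = c(lo, hi),
                            x = c(1 - frac, frac), dims = c(2L * n, n))
  upsampleMatrixCache[[key]] <- M
  M
}

upsampleForward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  Rh <- upsampleMatrix(H); Rw <- upsampleMatrix(W)
  y <- array(as.matrix(Rh %*% matrix(x, H, W * d[3] * d[4])),
             c(2L * H, W, d[3], d[4]))
  yp <- aperm(y, c(2, 1, 3, 4))
  y2 <- array(as.matrix(Rw %*% matrix(yp, W, 2L * H * d[3] * d[4])),
              c(2L * W, 2L * H, d[3], d[4]))
  aperm(y2, c(2, 1, 3, 4))
}

upsampleBackward <- function(dy, dimx) {
  H <- dimx[1]; W <- dimx[2]
  Rh <- upsampleMatrix(H); Rw <- upsampleMatrix(W)
  dp <- aperm(dy, c(2, 1, 3, 4))  # (2W, 2H, N, C)
  g1 <- array(as.matrix(Matrix::crossprod(Rw, matrix(dp, 2L * W,
                                                     2L * H * dimx[3] * dimx[4]))),
              c(W, 2L * H, dimx[3], dimx[4]))
  g1 <- aperm(g1, c(2, 1, 3, 4))  # (2H, W, N, C)
  array(as.matrix(Matrix::crossprod(Rh, matrix(g1, 2L * H,
                                               W * dimx[3] * dimx[4]))), dimx)
}

# ---- channel concatenation ---------------------------------------------------

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1:3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}

splitChannels <- function(dy, c1) {
  C <- dim(dy)[4]
  list(a = dy[, , , seq_len(c1), drop = FALSE],
       b = dy[, , , (c1 + 1):C, drop = FALSE])
}
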