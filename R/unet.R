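# Encoder-decoder architecture: five encoder double-convolution blocks with
# 2x2 max pooling between them, four decoder blocks of bilinear upsampling +
# skip concatenation + double convolution, and a 1x1 sigmoid output head.
# Every convolution is 3x3 with padding 1, bias, batch normalization, and a
# leaky rectifier, so spatial dimensions are preserved end to end.

#' Architecture specification
#'
#' The reference configuration (`base = 64`) has encoder widths
#' 64-128-256-512-512 and decoder widths 256-128-64-64 with an input side of
#' 576. `base` scales every width by `base / 64`, which keeps the skip
#' wiring intact and lets reduced configurations train quickly on phantom
#' data; the network is fully convolutional, so any input side divisible by
#' 16 is accepted at run time.
#'
#' @param base width of the first encoder block (default 64).
#' @param side nominal input side (default 576); must be divisible by 16.
#' @param slope leaky-rectifier negative slope.
#' @return list with encoder/decoder widths and layer hyperparameters.
#' @export
unetSpec <- function(base = 64, side = 576, slope = 0.01) {
  base <- as.integer(base)
  if (base < 1) stop("base width must be >= 1")
  if (side %% 16L != 0L) stop("input side must be divisible by 16")
  list(encoder = base * c(1L, 2L, 4L, 8L, 8L),
       decoder = base * c(4L, 2L, 1L, 1L),
       side = as.integer(side), slope = slope,
       bnEps = 1e-5, bnMomentum = 0.1)
}

# Kaiming-uniform init for one conv array (kh x kw x Cin x Cout).
kaimingConv <- function(kh, kw, cin, cout, slope = 0.01) {
  fanIn <- kh * kw * cin
  gain <- sqrt(2 / (1 + slope^2))
  bound <- gain * sqrt(3 / fanIn)
  list(W = array(stats::runif(kh * kw * cin * cout, -bound, bound),
                 c(kh, kw, cin, cout)),
       b = stats::runif(cout, -1 / sqrt(fanIn), 1 / sqrt(fanIn)))
}

newDoubleConv <- function(cin, cout, slope) {
  c1 <- kaimingConv(3, 3, cin, cout, slope)
  c2 <- kaimingConv(3, 3, cout, cout, slope)
  list(W1 = c1$W, b1 = c1$b, g1 = rep(1, cout), be1 = rep(0, cout),
       W2 = c2$W, b2 = c2$b, g2 = rep(1, cout), be2 = rep(0, cout))
}

newBnBuffers <- function(cout) {
  list(bn1 = list(mean = rep(0, cout), var = rep(1, cout)),
       bn2 = list(mean = rep(0, cout), var = rep(1, cout)))
}

blockWidths <- function(spec) {
  e <- spec$encoder; d <- spec$decoder
  list(
    enc1 = c(1L, e[1]), enc2 = c(e[1], e[2]), enc3 = c(e[2], e[3]),
    enc4 = c(e[3], e[4]), enc5 = c(e[4], e[5]),
    dec1 = c(e[5] + e[4], d[1]), dec2 = c(d[1] + e[3], d[2]),
    dec3 = c(d[2] + e[2], d[3]), dec4 = c(d[3] + e[1], d[4])
  )
}

#' Build the segmentation network
#'
#' Allocates and initializes all learnable arrays (Kaiming-uniform
#' convolution weights, unit-scale/zero-shift batch norm) in a fixed order
#' under the given seed, so two builds from the same seed are identical.
#'
#' @param spec a [unetSpec()].
#' @param seed integer seed for the weight draw.
#' @return a [UNetModel-class].
#' @examples
#' m <- buildUNet(unetSpec(base = 4, side = 64), seed = 1)
#' countParameters(m)
#' @export
buildUNet <- function(spec = unetSpec(), seed = 1L) {
  seed <- as.integer(seed)
  set.seed(seed)
  bw <- blockWidths(spec)
  params <- list()
  buffers <- list()
  for (nm in names(bw)) {
    params[[nm]] <- newDoubleConv(bw[[nm]][1], bw[[nm]][2], spec$slope)
    buffers[[nm]] <- newBnBuffers(bw[[nm]][2])
  }
  oc <- kaimingConv(1, 1, spec$decoder[4], 1, spec$slope)
  params$out <- list(W = matrix(oc$W, spec$decoder[4], 1), b = oc$b)
  new("UNetModel", spec = spec, params = params, buffers = buffers,
      seed = seed)
}

# DoubleConv forward: conv + fused BN/leaky-ReLU, twice. Returns output,
# cache for the backward pass, and updated running statistics.
doubleConvForward <- function(x, p, buf, spec, training) {
  z1 <- convForward(x, p$W1, p$b1)
  f1 <- .bnLreluFwd(z1, p$g1, p$be1, buf$bn1$mean, buf$bn1$var, training,
                    spec$bnEps, spec$bnMomentum, spec$slope)
  z2 <- convForward(f1$y, p$W2, p$b2)
  f2 <- .bnLreluFwd(z2, p$g2, p$be2, buf$bn2$mean, buf$bn2$var, training,
                    spec$bnEps, spec$bnMomentum, spec$slope)
  list(y = f2$y,
       cache = list(x = x, z1 = z1, a1 = f1$y, z2 = z2,
                    mu1 = f1$mu, is1 = f1$invstd,
                    mu2 = f2$mu, is2 = f2$invstd),
       buf = list(bn1 = list(mean = f1$runMean, var = f1$runVar),
                  bn2 = list(mean = f2$runMean, var = f2$runVar)))
}

doubleConvBackward <- function(cache, p, spec, dy) {
  b2 <- .bnLreluBwd(cache$z2, p$g2, p$be2, cache$mu2, cache$is2, dy,
                    spec$slope, TRUE)
  c2 <- convBackward(cache$a1, p$W2, b2$dx)
  b1 <- .bnLreluBwd(cache$z1, p$g1, p$be1, cache$mu1, cache$is1, c2$dx,
                    spec$slope, TRUE)
  c1 <- convBackward(cache$x, p$W1, b1$dx)
  list(dx = c1$dx,
       grads = list(W1 = c1$dW, b1 = c1$db, g1 = b1$dgamma, be1 = b1$dbeta,
                    W2 = c2$dW, b2 = c2$db, g2 = b2$dgamma, be2 = b2$dbeta))
}

#' Network forward pass
#'
#' Runs a batch through the network. In training mode batch statistics are
#' used for normalization (and running statistics updated); in inference
#' mode the stored running statistics are used, making prediction
#' deterministic.
#'
#' @param model a [UNetModel-class].
#' @param x input batch, array dim `(H, W, N, 1)` with values in `[0, 1]`;
#'   H and W must be divisible by 16.
#' @param training logical; training or inference mode.
#' @return list with `p` (sigmoid probabilities, same dim as `x`), `cache`
#'   (for the backward pass; `NULL` unless training) and `model` (with
#'   updated running statistics when training).
#' @export
unetForward <- function(model, x, training = FALSE) {
  spec <- model@spec
  d <- dim(x)
  if (length(d) != 4 || d[4] != 1) stop("input must be (H, W, N, 1)")
  if (d[1] %% 16L || d[2] %% 16L) stop("spatial dims must be divisible by 16")
  p <- model@params; buf <- model@buffers
  caches <- list()
  skips <- list()
  h <- x
  for (k in 1:5) {
    nm <- paste0("enc", k)
    fc <- doubleConvForward(h, p[[nm]], buf[[nm]], spec, training)
    buf[[nm]] <- fc$buf
    caches[[nm]] <- fc$cache
    if (k < 5) {
      skips[[k]] <- fc$y
      pl <- .pool2Fwd(fc$y)
      caches[[paste0("pool", k)]] <- list(idx = pl$idx, dimx = dim(fc$y))
      h <- pl$y
    } else h <- fc$y
  }
  for (k in 1:4) {
    nm <- paste0("dec", k)
    up <- upsampleForward(h)
    caches[[paste0("up", k)]] <- dim(h)
    skip <- skips[[5 - k]]
    cat2 <- concatChannels(up, skip)
    caches[[paste0("cat", k)]] <- dim(up)[4]
    fc <- doubleConvForward(cat2, p[[nm]], buf[[nm]], spec, training)
    buf[[nm]] <- fc$buf
    caches[[nm]] <- fc$cache
    h <- fc$y
  }
  z <- conv1x1Forward(h, p$out$W, p$out$b)
  prob <- 1 / (1 + exp(-z))
  model@buffers <- buf
  list(p = prob,
       cache = if (training) list(caches = caches, z = z, hLast = h,
                                  dimx = d) else NULL,
       model = model)
}

# Backward pass from dL/dp; returns gradients named like the params.
unetBackward <- function(model, fw, dLdp) {
  spec <- model@spec
  p <- model@params
  caches <- fw$cache$caches
  prob <- 1 / (1 + exp(-fw$cache$z))
  dz <- dLdp * prob * (1 - prob)
  grads <- list()
  ob <- conv1x1Backward(fw$cache$hLast, p$out$W, dz)
  grads$out <- list(W = ob$dW, b = ob$db)
  dy <- ob$dx
  skipGrads <- list()
  for (k in 4:1) {
    nm <- paste0("dec", k)
    bk <- doubleConvBackward(caches[[nm]], p[[nm]], spec, dy)
    grads[[nm]] <- bk$grads
    sp <- splitChannels(bk$dx, caches[[paste0("cat", k)]])
    skipGrads[[5 - k]] <- sp$b
    dy <- upsampleBackward(sp$a, caches[[paste0("up", k)]])
  }
  for (k in 5:1) {
    nm <- paste0("enc", k)
    if (k < 5) {
      pc <- caches[[paste0("pool", k)]]
      dy <- .pool2Bwd(dy, pc$idx, pc$dimx) + skipGrads[[k]]
    }
    bk <- doubleConvBackward(caches[[nm]], p[[nm]], spec, dy)
    grads[[nm]] <- bk$grads
    dy <- bk$dx
  }
  grads
}

#' Learnable-term ledger
#'
#' Walks the model's actual parameter arrays and reports, per block, the
#' number of learnable terms: each double-convolution block with input width
#' C1 and output width C2 contributes `9*(C1+C2)*C2 + 6*C2` (two biased 3x3
#' convolutions plus two scale/shift pairs), and the 1x1 output head
#' contributes `C+1`. Batch-norm running statistics are buffers, not
#' learnable, and are excluded.
#'
#' @param model a [UNetModel-class].
#' @return data.frame with columns `block` and `count`, plus attribute
#'   `total`; rows follow the architecture order.
#' @export
countParameters <- function(model) {
  entries <- vapply(model@params, function(p)
    sum(vapply(p, length, numeric(1))), numeric(1))
  nm <- names(entries)
  pretty <- ifelse(grepl("^enc", nm), paste0("DoubleConv_", substring(nm, 4)),
            ifelse(grepl("^dec", nm),
                   paste0("DoubleConv_", 5L + as.integer(substring(nm, 4))),
                   "Output"))
  ledger <- data.frame(block = pretty, count = as.integer(entries),
                       row.names = NULL)
  attr(ledger, "total") <- sum(entries)
  ledger
}

#' Build one double-convolution block and count its learnable terms
#'
#' Convenience used for architecture auditing: allocates the block for the
#' given widths and counts the terms of its actual arrays.
#'
#' @param cin,cout input and output feature widths.
#' @return integer count, `9*(cin+cout)*cout + 6*cout`.
#' @export
doubleConvParams <- function(cin, cout) {
  p <- newDoubleConv(as.integer(cin), as.integer(cout), 0.01)
  sum(vapply(p, length, numeric(1)))
}

#' Print the ledger in the architecture-table layout
#' @param model a [UNetModel-class].
#' @return the ledger, invisibly.
#' @export
printParamLedger <- function(model) {
  led <- countParameters(model)
  cat(sprintf("%-14s %12s\n", "Block", "Parameters"))
  cat(sprintf("%-14s %12d\n", "Input", 0L))
  for (i in seq_len(nrow(led)))
    cat(sprintf("%-14s %12d\n", led$block[i], led$count[i]))
  cat(sprintf("%-14s %12d\n", "Total", as.integer(attr(led, "total"))))
  invisible(led)
}
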