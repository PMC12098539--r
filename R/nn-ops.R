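# Differentiable image ops on H x W x C arrays (single tile, channels last).
# Convolution is cross-correlation in the deep-learning convention, realised as
# im2col + BLAS matrix multiply; odd kernel sizes with `same` zero padding.

# Patch matrix: rows = pixels (column-major over H,W), columns = kernel offset
# (dj major, di minor) x channel. Weight matrices must use the same row layout;
# see kernel_to_matrix().
im2col <- function(x, k, pad = c("zero", "reflect")) {
  pad <- match.arg(pad)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (k == 1L) return(matrix(x, H * W, C))
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, C))
  xp[p + seq_len(H), p + seq_len(W), ] <- x
  if (pad == "reflect") {
    for (q in seq_len(p)) {
      xp[p + 1L - q, , ] <- xp[p + 1L + q, , ]
      xp[p + H + q, , ] <- xp[p + H - q, , ]
    }
    for (q in seq_len(p)) {
      xp[, p + 1L - q, ] <- xp[, p + 1L + q, ]
      xp[, p + W + q, ] <- xp[, p + W - q, ]
    }
  }
  cols <- matrix(0, H * W, k * k * C)
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    cols[, o * C + seq_len(C)] <- matrix(xp[di + seq_len(H), dj + seq_len(W), ], H * W, C)
    o <- o + 1L
  }
  cols
}

# Adjoint of im2col for zero padding: scatter patch-gradient columns back.
col2im <- function(gcols, H, W, C, k) {
  if (k == 1L) return(array(gcols, c(H, W, C)))
  p <- (k - 1L) %/% 2L
  gxp <- array(0, c(H + 2L * p, W + 2L * p, C))
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    gxp[di + seq_len(H), dj + seq_len(W), ] <-
      gxp[di + seq_len(H), dj + seq_len(W), ] +
      array(gcols[, o * C + seq_len(C)], c(H, W, C))
    o <- o + 1L
  }
  gxp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

#' Flatten a k x k x Cin x Cout kernel to the im2col weight-matrix layout
#' @keywords internal
kernel_to_matrix <- function(karr) {
  d <- dim(karr)
  matrix(aperm(karr, c(3L, 1L, 2L, 4L)), d[1] * d[2] * d[3], d[4])
}

# 2-D convolution, stride 1, same padding. w: (k*k*Cin x Cout) matrix, b: Cout.
# Gradient through the input is only supported for zero padding (reflect is
# used on the raw image, which never requires a gradient).
ag_conv2d <- function(x, w, b, k, pad = "zero") {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  cout <- length(b$value)
  cols <- im2col(x$value, k, pad)
  ymat <- cols %*% w$value
  ymat <- ymat + rep(b$value, each = H * W)
  val <- array(ymat, c(H, W, cout))
  ag_op(val, list(x, w, b), function(g) {
    gmat <- matrix(g, H * W, cout)
    gx <- NULL
    if (x$requires_grad) {
      if (pad != "zero") stop("input gradient unsupported for reflect padding")
      gx <- col2im(gmat %*% t(w$value), H, W, C, k)
    }
    gw <- if (w$requires_grad) crossprod(im2col(x$value, k, pad), gmat) else NULL
    gb <- if (b$requires_grad) colSums(gmat) else NULL
    list(gx, gw, gb)
  })
}

# Per-channel normalization over the tile's spatial extent (batch norm with the
# single-tile batch, i.e. instance normalization); population variance.
ag_norm_channels <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$value); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x$value, n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)
  isd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, isd, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  ag_op(array(ym, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, n, C)
    ggamma <- if (gamma$requires_grad) colSums(gm * xhat) else NULL
    gbeta <- if (beta$requires_grad) colSums(gm) else NULL
    gx <- NULL
    if (x$requires_grad) {
      gy <- sweep(gm, 2L, gamma$value, `*`)
      t1 <- sweep(gy, 2L, colMeans(gy))
      t2 <- sweep(xhat, 2L, colMeans(gy * xhat), `*`)
      gx <- array(sweep(t1 - t2, 2L, isd, `*`), d)
    }
    list(gx, ggamma, gbeta)
  })
}

# 2x2 max pooling (H, W even).
ag_maxpool2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  s1 <- x$value[io, jo, , drop = FALSE]
  s2 <- x$value[io + 1L, jo, , drop = FALSE]
  s3 <- x$value[io, jo + 1L, , drop = FALSE]
  s4 <- x$value[io + 1L, jo + 1L, , drop = FALSE]
  val <- pmax(s1, s2, s3, s4)
  # winner = first slab attaining the max (deterministic tie-break)
  which4 <- array(1L, dim(val))
  which4[s2 == val & s1 != val] <- 2L
  which4[s3 == val & s1 != val & s2 != val] <- 3L
  which4[s4 == val & s1 != val & s2 != val & s3 != val] <- 4L
  ag_op(val, list(x), function(g) {
    gx <- array(0, d)
    gx[io, jo, ] <- g * (which4 == 1L)
    gx[io + 1L, jo, ] <- g * (which4 == 2L)
    gx[io, jo + 1L, ] <- g * (which4 == 3L)
    gx[io + 1L, jo + 1L, ] <- g * (which4 == 4L)
    list(gx)
  })
}

# 2x2 average pooling (H, W even)
ag_avgpool2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  val <- (x$value[io, jo, , drop = FALSE] + x$value[io + 1L, jo, , drop = FALSE] +
          x$value[io, jo + 1L, , drop = FALSE] +
          x$value[io + 1L, jo + 1L, , drop = FALSE]) / 4
  ag_op(val, list(x), function(g) {
    gx <- array(0, d)
    gx[io, jo, ] <- g / 4; gx[io + 1L, jo, ] <- g / 4
    gx[io, jo + 1L, ] <- g / 4; gx[io + 1L, jo + 1L, ] <- g / 4
    list(gx)
  })
}

# cache of 1-D bilinear x2 interpolation matrices
.up_cache <- new.env(parent = emptyenv())

upsample_matrix <- function(n) {
  key <- as.character(n)
  m <- .up_cache[[key]]
  if (!is.null(m)) return(m)
  U <- matrix(0, 2L * n, n)
  for (o in seq_len(2L * n)) {
    pos <- (o - 0.5) / 2 - 0.5          # source coordinate, 0-based centres
    lo <- floor(pos)
    whi <- pos - lo
    ilo <- min(max(lo, 0), n - 1)
    ihi <- min(max(lo + 1, 0), n - 1)
    U[o, ilo + 1L] <- U[o, ilo + 1L] + (1 - whi)
    U[o, ihi + 1L] <- U[o, ihi + 1L] + whi
  }
  .up_cache[[key]] <- U
  U
}

# Bilinear x2 upsampling as a separable linear operator; the backward pass is
# the exact adjoint.
ag_upsample2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  Uh <- upsample_matrix(H); Uw <- upsample_matrix(W)
  val <- array(0, c(2L * H, 2L * W, C))
  for (c in seq_len(C)) val[, , c] <- Uh %*% x$value[, , c] %*% t(Uw)
  ag_op(val, list(x), function(g) {
    gx <- array(0, d)
    for (c in seq_len(C)) gx[, , c] <- crossprod(Uh, g[, , c]) %*% Uw
    list(gx)
  })
}

# channel concatenation
ag_concat_c <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[1:2] == db[1:2]))
  val <- array(0, c(da[1], da[2], da[3] + db[3]))
  val[, , seq_len(da[3])] <- a$value
  val[, , da[3] + seq_len(db[3])] <- b$value
  ag_op(val, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# inverted dropout; draws from R's global RNG (callers seed the run)
ag_dropout <- function(x, p, active = TRUE) {
  x <- as_ag(x)
  if (!active || p <= 0) return(x)
  keep <- array(stats::runif(length(x$value)) >= p, dim(x$value)) / (1 - p)
  ag_op(x$value * keep, list(x), function(g) list(g * keep))
}

# log-softmax over the channel dimension (numerically stable)
ag_logsoftmax_c <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x$value, n, C)
  m <- do.call(pmax, lapply(seq_len(C), function(c) xm[, c]))
  z <- xm - m
  lse <- log(rowSums(exp(z)))
  ls <- z - lse
  pm <- exp(ls)
  ag_op(array(ls, d), list(x), function(g) {
    gm <- matrix(g, n, C)
    gx <- gm - pm * rowSums(gm)
    list(array(gx, d))
  })
}

ag_softmax_c <- function(x) ag_exp(ag_logsoftmax_c(x))

# slice one channel -> H x W matrix node
ag_slice_c <- function(x, cidx) {
  x <- as_ag(x)
  d <- dim(x$value)
  ag_op(x$value[, , cidx], list(x), function(g) {
    gx <- array(0, d)
    gx[, , cidx] <- g
    list(gx)
  })
}

# multiply an H x W x C array by an H x W map, broadcast over channels
ag_mul_spatial <- function(x, m) {
  x <- as_ag(x); m <- as_ag(m)
  d <- dim(x$value); C <- d[3]
  mv <- as.vector(m$value)
  val <- array(x$value * rep(mv, times = C), d)
  ag_op(val, list(x, m), function(g) {
    gx <- if (x$requires_grad) array(g * rep(mv, times = C), d) else NULL
    gm <- if (m$requires_grad) {
      matrix(rowSums(matrix(g * x$value, d[1] * d[2], C)), d[1], d[2])
    } else NULL
    list(gx, gm)
  })
}

# sum each channel over the spatial extent -> length-C vector
ag_chan_sum <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); n <- d[1] * d[2]; C <- d[3]
  ag_op(colSums(matrix(x$value, n, C)), list(x), function(g) {
    list(array(rep(g, each = n), d))
  })
}

ag_chan_mean <- function(x) {
  x <- as_ag(x)
  n <- prod(dim(x$value)[1:2])
  ag_mul(ag_chan_sum(x), 1 / n)
}

# per-channel spatial max -> length-C vector
ag_chan_max <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x$value, n, C)
  idx <- max.col(t(xm), ties.method = "first")
  val <- xm[cbind(idx, seq_len(C))]
  ag_op(val, list(x), function(g) {
    gx <- matrix(0, n, C)
    gx[cbind(idx, seq_len(C))] <- g
    list(array(gx, d))
  })
}

# scale channel c of x by w[c]
ag_channel_scale <- function(x, w) {
  x <- as_ag(x); w <- as_ag(w)
  d <- dim(x$value); n <- d[1] * d[2]; C <- d[3]
  val <- array(x$value * rep(w$value, each = n), d)
  ag_op(val, list(x, w), function(g) {
    gx <- if (x$requires_grad) array(g * rep(w$value, each = n), d) else NULL
    gw <- if (w$requires_grad) colSums(matrix(g * x$value, n, C)) else NULL
    list(gx, gw)
  })
}

# cosine similarity of two vectors (error on zero norm)
ag_cosine <- function(u, v) {
  u <- as_ag(u); v <- as_ag(v)
  if (sqrt(sum(u$value^2)) == 0 || sqrt(sum(v$value^2)) == 0)
    stop("cosine similarity undefined for zero-norm vector")
  num <- ag_sum(ag_mul(u, v))
  den <- ag_sqrt(ag_mul(ag_sum(ag_mul(u, u)), ag_sum(ag_mul(v, v))))
  ag_div(num, den)
}
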