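## Minimal neural-network layer library with explicit reverse-mode
## gradients, written over base R matrix algebra (BLAS).  Feature maps are
## 3-D arrays with dim (channels, length, batch); token matrices used by
## the attention stack are (features, tokens).
##
## Every layer is an environment holding `par` (named list of parameter
## arrays), `grad` (matching shapes, accumulated by backward), a `forward`
## closure caching what backward needs, and a `backward` closure returning
## the gradient with respect to the layer input.

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$grad <- list()
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

zero_grads <- function(layers) {
  for (l in layers) for (nm in names(l$par)) l$grad[[nm]][] <- 0
  invisible(NULL)
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$par, length, 1L)), numeric(1)))
}

## He-uniform initialization
init_w <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

as_mat <- function(x) {            # (C, L, B) -> (C, L*B) view
  dim(x) <- c(dim(x)[1], dim(x)[2] * dim(x)[3])
  x
}

## 1-D convolution ------------------------------------------------------

#' @noRd
nn_conv1d <- function(in_ch, out_ch, k, pad_left = 0, pad_right = pad_left,
                      dilation = 1, bias = TRUE) {
  l <- new_layer("conv1d")
  l$k <- k; l$dil <- dilation; l$pl <- pad_left; l$pr <- pad_right
  l$in_ch <- in_ch; l$out_ch <- out_ch; l$bias <- bias
  l$par$W <- init_w(c(out_ch, in_ch, k), in_ch * k)
  l$grad$W <- array(0, dim = c(out_ch, in_ch, k))
  if (bias) { l$par$b <- numeric(out_ch); l$grad$b <- numeric(out_ch) }
  ## im2col with a cached gather index: one GEMM per pass instead of k
  gather_idx <- function(C, Lp, B, L_out) {
    key <- paste(C, Lp, B, L_out)
    if (!identical(l$idx_key, key)) {
      row_base <- rep(seq_len(C), l$k) +
        C * rep((seq_len(l$k) - 1) * l$dil, each = C)       # C*k
      col_off <- C * (rep(0:(L_out - 1), times = B) +
                        Lp * rep(0:(B - 1), each = L_out))  # L_out*B
      l$idx <- outer(row_base, col_off, `+`)
      l$idx_key <- key
    }
    l$idx
  }
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    Lp <- L + l$pl + l$pr
    L_out <- Lp - (l$k - 1) * l$dil
    if (L_out < 1) stop_data("conv1d: input shorter than kernel extent")
    xpad <- array(0, dim = c(C, Lp, B))
    xpad[, (l$pl + 1):(l$pl + L), ] <- x
    Xcol <- xpad
    dim(Xcol) <- NULL
    Xcol <- matrix(Xcol[gather_idx(C, Lp, B, L_out)], C * l$k)
    W2 <- l$par$W
    dim(W2) <- c(l$out_ch, l$in_ch * l$k)
    Y <- W2 %*% Xcol
    if (l$bias) Y <- Y + l$par$b
    l$cache <- list(Xcol = Xcol, Lp = Lp, L = L, L_out = L_out, B = B,
                    C = C)
    dim(Y) <- c(l$out_ch, L_out, B)
    Y
  }
  l$backward <- function(gy) {
    cc <- l$cache
    GY <- gy; dim(GY) <- c(l$out_ch, cc$L_out * cc$B)
    gW2 <- tcrossprod(GY, cc$Xcol)
    dim(gW2) <- dim(l$grad$W)
    l$grad$W <- l$grad$W + gW2
    if (l$bias) l$grad$b <- l$grad$b + rowSums(GY)
    W2 <- l$par$W
    dim(W2) <- c(l$out_ch, l$in_ch * l$k)
    gXcol <- crossprod(W2, GY)               # C*k x L_out*B
    dim(gXcol) <- c(cc$C, l$k, cc$L_out, cc$B)
    gxpad <- array(0, dim = c(cc$C, cc$Lp, cc$B))
    for (i in seq_len(l$k)) {                # scatter-add per tap
      off <- (i - 1) * l$dil
      gi <- gXcol[, i, , , drop = FALSE]
      dim(gi) <- c(cc$C, cc$L_out, cc$B)
      gxpad[, (1 + off):(cc$L_out + off), ] <-
        gxpad[, (1 + off):(cc$L_out + off), , drop = FALSE] + gi
    }
    gxpad[, (l$pl + 1):(l$pl + cc$L), , drop = FALSE]
  }
  l
}

## Batch normalization over (length, batch) per channel ------------------

#' @noRd
nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  l <- new_layer("bn")
  l$eps <- eps; l$momentum <- momentum
  l$par$gamma <- rep(1, ch); l$par$beta <- numeric(ch)
  l$grad$gamma <- numeric(ch); l$grad$beta <- numeric(ch)
  l$run_mean <- numeric(ch); l$run_var <- rep(1, ch)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    X <- x; dim(X) <- c(d[1], d[2] * d[3])
    if (train) {
      mu <- rowMeans(X)
      v <- rowMeans(X^2) - mu^2
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
      l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
    } else {
      mu <- l$run_mean; v <- l$run_var
    }
    inv_sd <- 1 / sqrt(v + l$eps)
    xhat <- (X - mu) * inv_sd
    Y <- l$par$gamma * xhat + l$par$beta
    l$cache <- list(xhat = xhat, inv_sd = inv_sd, d = d, train = train)
    dim(Y) <- d
    Y
  }
  l$backward <- function(gy) {
    cc <- l$cache
    GY <- gy; dim(GY) <- c(cc$d[1], cc$d[2] * cc$d[3])
    l$grad$gamma <- l$grad$gamma + rowSums(GY * cc$xhat)
    l$grad$beta <- l$grad$beta + rowSums(GY)
    dxhat <- GY * l$par$gamma
    if (cc$train) {
      gx <- cc$inv_sd *
        (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat))
    } else {
      gx <- cc$inv_sd * dxhat
    }
    dim(gx) <- cc$d
    gx
  }
  l
}

## Pointwise layers ------------------------------------------------------

#' @noRd
nn_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, train = TRUE) {
    l$cache <- x > 0
    x * l$cache
  }
  l$backward <- function(gy) gy * l$cache
  l
}

#' @noRd
nn_dropout <- function(p = 0.1) {
  l <- new_layer("dropout")
  l$p <- p
  l$forward <- function(x, train = TRUE) {
    if (!train || l$p <= 0) { l$cache <- NULL; return(x) }
    keep <- 1 - l$p
    m <- array(runif(length(x)) < keep, dim = dim(x)) / keep
    l$cache <- m
    x * m
  }
  l$backward <- function(gy) if (is.null(l$cache)) gy else gy * l$cache
  l
}

## Pooling along the length axis ----------------------------------------

#' @noRd
nn_maxpool2 <- function() {
  l <- new_layer("maxpool2")
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); L2 <- d[2] %/% 2
    a <- x[, 2 * seq_len(L2) - 1, , drop = FALSE]
    b <- x[, 2 * seq_len(L2), , drop = FALSE]
    sel <- a >= b
    l$cache <- list(sel = sel, d = d, L2 = L2)
    pmax(a, b)
  }
  l$backward <- function(gy) {
    cc <- l$cache
    gx <- array(0, dim = cc$d)
    gx[, 2 * seq_len(cc$L2) - 1, ] <- gy * cc$sel
    gx[, 2 * seq_len(cc$L2), ] <- gy * !cc$sel
    gx
  }
  l
}

#' @noRd
nn_avgpool2 <- function() {
  l <- new_layer("avgpool2")
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); L2 <- d[2] %/% 2
    l$cache <- list(d = d, L2 = L2)
    (x[, 2 * seq_len(L2) - 1, , drop = FALSE] +
       x[, 2 * seq_len(L2), , drop = FALSE]) / 2
  }
  l$backward <- function(gy) {
    cc <- l$cache
    gx <- array(0, dim = cc$d)
    gx[, 2 * seq_len(cc$L2) - 1, ] <- gy / 2
    gx[, 2 * seq_len(cc$L2), ] <- gy / 2
    gx
  }
  l
}

## Linear-interpolation upsampling by 2 ----------------------------------

#' @noRd
nn_upsample2 <- function() {
  l <- new_layer("upsample2")
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); L <- d[2]
    y <- array(0, dim = c(d[1], 2 * L, d[3]))
    y[, 2 * seq_len(L) - 1, ] <- x
    nxt <- x[, c(seq_len(L - 1) + 1, L), , drop = FALSE]  # replicate edge
    y[, 2 * seq_len(L), ] <- (x + nxt) / 2
    l$cache <- list(L = L, d = d)
    y
  }
  l$backward <- function(gy) {
    cc <- l$cache; L <- cc$L
    g_odd <- gy[, 2 * seq_len(L) - 1, , drop = FALSE]
    g_even <- gy[, 2 * seq_len(L), , drop = FALSE]
    gx <- g_odd + g_even / 2
    gshift <- g_even / 2
    gx[, seq_len(L - 1) + 1, ] <- gx[, seq_len(L - 1) + 1, ] +
      gshift[, seq_len(L - 1), ]
    gx[, L, ] <- gx[, L, ] + gshift[, L, ]
    gx
  }
  l
}

## Dense layer on token matrices (features x tokens) ----------------------

#' @noRd
nn_linear <- function(d_in, d_out, bias = TRUE) {
  l <- new_layer("linear")
  l$bias <- bias
  l$par$W <- init_w(c(d_out, d_in), d_in)
  l$grad$W <- array(0, dim = c(d_out, d_in))
  if (bias) { l$par$b <- numeric(d_out); l$grad$b <- numeric(d_out) }
  l$forward <- function(x, train = TRUE) {
    l$cache <- x
    y <- l$par$W %*% x
    if (l$bias) y <- y + l$par$b
    y
  }
  l$backward <- function(gy) {
    l$grad$W <- l$grad$W + gy %*% t(l$cache)
    if (l$bias) l$grad$b <- l$grad$b + rowSums(gy)
    t(l$par$W) %*% gy
  }
  l
}

## Layer normalization over the feature axis per token --------------------

#' @noRd
nn_layernorm <- function(d, eps = 1e-5) {
  l <- new_layer("layernorm")
  l$eps <- eps
  l$par$gamma <- rep(1, d); l$par$beta <- numeric(d)
  l$grad$gamma <- numeric(d); l$grad$beta <- numeric(d)
  l$forward <- function(x, train = TRUE) {
    d3 <- dim(x)
    if (length(d3) == 3) dim(x) <- c(d3[1], d3[2] * d3[3])
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    inv_sd <- 1 / sqrt(v + l$eps)
    xhat <- sweep(x, 2, mu, `-`) * rep(inv_sd, each = nrow(x))
    l$cache <- list(xhat = xhat, inv_sd = inv_sd, d3 = d3)
    y <- l$par$gamma * xhat + l$par$beta
    dim(y) <- d3
    y
  }
  l$backward <- function(gy) {
    cc <- l$cache
    if (length(cc$d3) == 3) dim(gy) <- c(cc$d3[1], cc$d3[2] * cc$d3[3])
    dxhat <- gy * l$par$gamma
    l$grad$gamma <- l$grad$gamma + rowSums(gy * cc$xhat)
    l$grad$beta <- l$grad$beta + rowSums(gy)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cc$xhat)
    gx <- sweep(dxhat, 2, m1, `-`) - sweep(cc$xhat, 2, m2, `*`)
    gx <- gx * rep(cc$inv_sd, each = nrow(gy))
    dim(gx) <- cc$d3
    gx
  }
  l
}

softmax_rows <- function(s) {
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  e / rowSums(e)
}
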