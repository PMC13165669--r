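## Multi-head self-attention and the sigmoid-gated feed-forward stage of
## the global relation module.  Token matrices are (d_model, L) per batch
## item; the layer input/output is an array (d_model, L, B).

#' @noRd
nn_mhsa <- function(d_model, n_heads) {
  stopifnot(d_model %% n_heads == 0)
  l <- new_layer("mhsa")
  l$h <- n_heads
  l$dh <- d_model %/% n_heads
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    l$par[[nm]] <- init_w(c(d_model, d_model), d_model)
    l$grad[[nm]] <- array(0, dim = c(d_model, d_model))
  }
  l$par$bo <- numeric(d_model); l$grad$bo <- numeric(d_model)

  l$forward <- function(x, train = TRUE) {
    d <- dim(x); dm <- d[1]; L <- d[2]; B <- d[3]
    X2 <- x; dim(X2) <- c(dm, L * B)
    Q <- l$par$Wq %*% X2; K <- l$par$Wk %*% X2; V <- l$par$Wv %*% X2
    O <- matrix(0, dm, L * B)
    Acache <- vector("list", B)
    scale <- 1 / sqrt(l$dh)
    for (b in seq_len(B)) {
      cols <- ((b - 1) * L + 1):(b * L)
      Ab <- vector("list", l$h)
      for (h in seq_len(l$h)) {
        rows <- ((h - 1) * l$dh + 1):(h * l$dh)
        S <- crossprod(Q[rows, cols, drop = FALSE],
                       K[rows, cols, drop = FALSE]) * scale   # L x L
        A <- softmax_rows(S)
        Ab[[h]] <- A
        O[rows, cols] <- tcrossprod(V[rows, cols, drop = FALSE], A)
      }
      Acache[[b]] <- Ab
    }
    Y <- l$par$Wo %*% O + l$par$bo
    l$cache <- list(X2 = X2, Q = Q, K = K, V = V, O = O, A = Acache,
                    d = d, scale = scale)
    dim(Y) <- d
    Y
  }

  l$backward <- function(gy) {
    cc <- l$cache
    dm <- cc$d[1]; L <- cc$d[2]; B <- cc$d[3]
    GY <- gy; dim(GY) <- c(dm, L * B)
    l$grad$Wo <- l$grad$Wo + GY %*% t(cc$O)
    l$grad$bo <- l$grad$bo + rowSums(GY)
    GO <- t(l$par$Wo) %*% GY
    GQ <- matrix(0, dm, L * B); GK <- GQ; GV <- GQ
    for (b in seq_len(B)) {
      cols <- ((b - 1) * L + 1):(b * L)
      for (h in seq_len(l$h)) {
        rows <- ((h - 1) * l$dh + 1):(h * l$dh)
        A <- cc$A[[b]][[h]]
        GOh <- GO[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        ## O_h = V_h %*% t(A) => dL/dA[i,j] = <GO_i, V_j>
        GA <- crossprod(GOh, Vh)           # dL/dA, L x L
        GV[rows, cols] <- GOh %*% A
        ## softmax rows: dS = (GA - rowSums(GA*A)) * A
        GS <- (GA - rowSums(GA * A)) * A
        Qh <- cc$Q[rows, cols, drop = FALSE]
        Kh <- cc$K[rows, cols, drop = FALSE]
        GQ[rows, cols] <- tcrossprod(Kh, GS) * cc$scale
        GK[rows, cols] <- Qh %*% GS * cc$scale
      }
    }
    l$grad$Wq <- l$grad$Wq + GQ %*% t(cc$X2)
    l$grad$Wk <- l$grad$Wk + GK %*% t(cc$X2)
    l$grad$Wv <- l$grad$Wv + GV %*% t(cc$X2)
    gx <- t(l$par$Wq) %*% GQ + t(l$par$Wk) %*% GK + t(l$par$Wv) %*% GV
    dim(gx) <- cc$d
    gx
  }
  l
}

## Gated feed-forward: G = sigmoid(Wg2 ReLU(Wg1 X)); Y = G * X.
## The residual and layer norm around it live in the GRMM assembly.

#' @noRd
nn_gated_ffn <- function(d_model, d_ff = 2 * d_model) {
  l <- new_layer("gated_ffn")
  l$par$Wg1 <- init_w(c(d_ff, d_model), d_model)
  l$par$Wg2 <- init_w(c(d_model, d_ff), d_ff)
  l$par$b1 <- numeric(d_ff); l$par$b2 <- numeric(d_model)
  for (nm in names(l$par)) l$grad[[nm]] <- l$par[[nm]] * 0
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    X2 <- x; dim(X2) <- c(d[1], d[2] * d[3])
    Z1 <- l$par$Wg1 %*% X2 + l$par$b1
    A1 <- Z1 * (Z1 > 0)
    Z2 <- l$par$Wg2 %*% A1 + l$par$b2
    G <- 1 / (1 + exp(-Z2))
    Y <- G * X2
    l$cache <- list(X2 = X2, Z1 = Z1, A1 = A1, G = G, d = d)
    dim(Y) <- d
    Y
  }
  l$backward <- function(gy) {
    cc <- l$cache
    GY <- gy; dim(GY) <- c(cc$d[1], cc$d[2] * cc$d[3])
    dG <- GY * cc$X2
    gx <- GY * cc$G
    dZ2 <- dG * cc$G * (1 - cc$G)
    l$grad$Wg2 <- l$grad$Wg2 + dZ2 %*% t(cc$A1)
    l$grad$b2 <- l$grad$b2 + rowSums(dZ2)
    dA1 <- t(l$par$Wg2) %*% dZ2
    dZ1 <- dA1 * (cc$Z1 > 0)
    l$grad$Wg1 <- l$grad$Wg1 + dZ1 %*% t(cc$X2)
    l$grad$b1 <- l$grad$b1 + rowSums(dZ1)
    gx <- gx + t(l$par$Wg1) %*% dZ1
    dim(gx) <- cc$d
    gx
  }
  l
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Learnable positional encoding added to every batch item ----------------

#' @noRd
nn_posenc <- function(d_model, L) {
  l <- new_layer("posenc")
  l$par$P <- array(rnorm(d_model * L, 0, 0.02), dim = c(d_model, L))
  l$grad$P <- array(0, dim = c(d_model, L))
  l$forward <- function(x, train = TRUE) {
    l$cache <- dim(x)
    x + as.vector(l$par$P)        # recycled over the batch axis
  }
  l$backward <- function(gy) {
    B <- l$cache[3]
    g <- gy; dim(g) <- c(length(l$par$P), B)
    l$grad$P <- l$grad$P + array(rowSums(g), dim = dim(l$par$P))
    gy
  }
  l
}
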