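## Spectral attention: FFT along time, fixed ECG-band amplitude mask,
## learned channel-frequency attention weights, phase-preserving inverse
## transform, residual add.  Because the attention weight multiplies the
## amplitude spectrum while the phase is kept, the reconstruction path is
## |S| M W e^{j phi} = M W S, i.e. a per-bin real filter; gradients are
## derived from that form (plus the dependency of W on |S|).

#' Frequency mask over the real-FFT bins
#'
#' 1 inside `band` (Hz), `floor` outside; evaluated on the two-sided FFT
#' bin frequencies of a length-`n` transform at sampling rate `fs` (each
#' bin uses its aliased magnitude frequency, so the mask is symmetric and
#' the filtered signal stays real).
#'
#' @param n transform length.
#' @param fs sampling rate of the sequence entering the block, Hz.
#' @param band numeric length 2, Hz.
#' @param floor attenuation outside the band, in `(0, 1)`.
#' @return Numeric vector of length `n`.
#' @export
sa_frequency_mask <- function(n, fs, band = c(0.5, 40), floor = 0.1) {
  j <- 0:(n - 1)
  f <- pmin(j, n - j) * fs / n
  ifelse(f >= band[1] & f <= band[2], 1, floor)
}

#' @noRd
nn_sa_block <- function(channels, n, fs_effective, band = c(0.5, 40),
                        mask_floor = 0.1, attn_kernel = 3) {
  l <- new_layer("sa")
  l$n <- n; l$fs <- fs_effective
  l$mask <- sa_frequency_mask(n, fs_effective, band, mask_floor)
  l$Fh <- n %/% 2 + 1                      # half-spectrum bins (n even)
  l$conv1 <- nn_conv1d(channels, channels, attn_kernel,
                       pad_left = (attn_kernel - 1) %/% 2,
                       pad_right = attn_kernel %/% 2)
  l$bn <- nn_bn(channels)
  l$relu <- nn_relu()
  l$conv2 <- nn_conv1d(channels, channels, attn_kernel,
                       pad_left = (attn_kernel - 1) %/% 2,
                       pad_right = attn_kernel %/% 2)
  l$sub <- list(l$conv1, l$bn, l$conv2)
  l$wsa_override <- NULL     # set to 1 to force all-pass attention weights
  l$residual <- TRUE

  ## (C, n, B) -> (n, C*B) with FFT columns
  to_cols <- function(x) {
    d <- dim(x)
    x <- aperm(x, c(2, 1, 3))
    dim(x) <- c(d[2], d[1] * d[3])
    x
  }
  from_cols <- function(m, C, B) {
    dim(m) <- c(l$n, C, B)
    aperm(m, c(2, 1, 3))
  }
  l$to_cols <- to_cols; l$from_cols <- from_cols

  l$forward <- function(x, train = TRUE) {
    d <- dim(x); C <- d[1]; B <- d[3]
    Xc <- to_cols(x)                        # n x (C*B)
    S <- mvfft(Xc)
    Amp <- Mod(S)
    if (is.null(l$wsa_override)) {
      Ah <- Amp[seq_len(l$Fh), , drop = FALSE]    # half spectrum
      Ah3 <- array(0, dim = c(C, l$Fh, B))
      dim(Ah) <- c(l$Fh, C, B)
      Ah3 <- aperm(Ah, c(2, 1, 3))
      z <- l$conv1$forward(Ah3, train)
      z <- l$bn$forward(z, train)
      z <- l$relu$forward(z, train)
      z <- l$conv2$forward(z, train)
      Wh <- 1 / (1 + exp(-z))                     # (C, Fh, B)
      ## mirror to the full, symmetric spectrum
      Wc <- aperm(Wh, c(2, 1, 3)); dim(Wc) <- c(l$Fh, C * B)
      Wfull <- matrix(0, l$n, C * B)
      Wfull[seq_len(l$Fh), ] <- Wc
      if (l$n > 2) {
        mir <- (l$Fh + 1):l$n
        Wfull[mir, ] <- Wc[l$n - mir + 2, , drop = FALSE]
      }
    } else {
      Wh <- NULL
      Wfull <- matrix(l$wsa_override, l$n, C * B)
    }
    H <- l$mask * Wfull
    Shat_f <- H * S
    Shat <- Re(mvfft(Shat_f, inverse = TRUE)) / l$n
    y <- from_cols(Shat, C, B)
    if (l$residual) y <- y + x
    l$cache <- list(S = S, Amp = Amp, Wh = Wh, Wfull = Wfull, H = H,
                    C = C, B = B, train = train)
    y
  }

  l$backward <- function(gy) {
    cc <- l$cache
    C <- cc$C; B <- cc$B
    Gc <- to_cols(gy)                       # n x (C*B)
    FG <- mvfft(Gc)
    ## filter path (W treated fixed): adjoint of a real symmetric per-bin
    ## filter is the same filter
    gx_cols <- Re(mvfft(cc$H * FG, inverse = TRUE)) / l$n
    gx <- from_cols(gx_cols, C, B)
    if (l$residual) gx <- gx + gy
    if (!is.null(cc$Wh)) {
      ## gradient wrt W at every bin: Re(M * S * conj(FFT(g))) / n
      gWfull <- Re(l$mask * cc$S * Conj(FG)) / l$n
      ## fold mirrored bins back onto the half spectrum
      gWh_cols <- gWfull[seq_len(l$Fh), , drop = FALSE]
      if (l$n > 2) {
        mir <- (l$Fh + 1):l$n
        tgt <- l$n - mir + 2
        gWh_cols[tgt, ] <- gWh_cols[tgt, ] + gWfull[mir, , drop = FALSE]
      }
      dim(gWh_cols) <- c(l$Fh, C, B)
      gWh <- aperm(gWh_cols, c(2, 1, 3))          # (C, Fh, B)
      gz <- gWh * cc$Wh * (1 - cc$Wh)             # sigmoid
      gz <- l$conv2$backward(gz)
      gz <- l$relu$backward(gz)
      gz <- l$bn$backward(gz)
      gAh <- l$conv1$backward(gz)                 # (C, Fh, B)
      ## amplitude path: dL/dy = Re(IFFT(gA * S/|S|)) * n / n
      gA_cols <- aperm(gAh, c(2, 1, 3)); dim(gA_cols) <- c(l$Fh, C * B)
      gA_full <- matrix(0, l$n, C * B)
      gA_full[seq_len(l$Fh), ] <- gA_cols
      u <- cc$S / pmax(cc$Amp, 1e-12)
      gx_amp <- Re(mvfft(gA_full * u, inverse = TRUE))
      gx <- gx + from_cols(gx_amp, C, B)
    }
    gx
  }
  l
}
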