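## Maximal-overlap discrete wavelet transform (non-decimated, shift
## invariant) with the Daubechies db4 filter pair, its inverse, and the
## additive multiresolution analysis.  Implemented from the standard
## pyramid definitions; boundaries are handled by reflection so segment
## edges do not ring.

## db4 (8-tap Daubechies) scaling filter, sum = sqrt(2).
.db4_g <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
            -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
            0.0328830116669829, -0.0105974017849973)

wavelet_filters <- function(wavelet = "db4") {
  g <- switch(wavelet,
              db4 = .db4_g,
              haar = c(1, 1) / sqrt(2),
              stop_config("unsupported wavelet '", wavelet, "'"))
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)      # quadrature mirror
  list(g = g / sqrt(2), h = h / sqrt(2))   # MODWT rescaling
}

## circular filtering with the level-j upsampled filter:
## out[t] = sum_l f[l+1] * v[(t - 2^(j-1) l) mod N]
circ_filt <- function(v, f, j) {
  n <- length(v)
  out <- numeric(n)
  step <- 2^(j - 1)
  idx0 <- seq_len(n)
  for (l in seq_along(f)) {
    sh <- ((idx0 - 1 - step * (l - 1)) %% n) + 1
    out <- out + f[l] * v[sh]
  }
  out
}

## adjoint shift direction, used by the inverse
circ_filt_adj <- function(v, f, j) {
  n <- length(v)
  out <- numeric(n)
  step <- 2^(j - 1)
  idx0 <- seq_len(n)
  for (l in seq_along(f)) {
    sh <- ((idx0 - 1 + step * (l - 1)) %% n) + 1
    out <- out + f[l] * v[sh]
  }
  out
}

#' Maximal-overlap discrete wavelet transform
#'
#' Non-decimated pyramid transform: at each level j the detail
#' coefficients W_j and smooth V_j are obtained by circularly filtering
#' V_{j-1} with the level-upsampled (a trous) wavelet and scaling filters.
#' All coefficient vectors have the length of the input.
#'
#' @param x numeric signal.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param J number of decomposition levels, at least 1.
#' @return A list with `W` (list of J detail vectors), `V` (final smooth),
#'   `J`, `wavelet`, `n`.
#' @export
modwt <- function(x, wavelet = "db4", J = 6) {
  n <- length(x)
  if (J < 1) stop_config("J must be at least 1")
  filt <- wavelet_filters(wavelet)
  if (2^J > n)
    stop_data("J = ", J, " too large for signal length ", n)
  W <- vector("list", J)
  v <- x
  for (j in seq_len(J)) {
    W[[j]] <- circ_filt(v, filt$h, j)
    v <- circ_filt(v, filt$g, j)
  }
  list(W = W, V = v, J = J, wavelet = wavelet, n = n)
}

#' Inverse maximal-overlap discrete wavelet transform
#'
#' Reconstructs the signal from detail and smooth coefficients by the
#' adjoint pyramid recursion; exact inverse of [modwt()].
#'
#' @param dec a decomposition from [modwt()].
#' @return The reconstructed signal.
#' @export
imodwt <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  v <- dec$V
  for (j in rev(seq_len(dec$J))) {
    v <- circ_filt_adj(dec$W[[j]], filt$h, j) + circ_filt_adj(v, filt$g, j)
  }
  v
}

#' Additive multiresolution analysis with reflection boundary
#'
#' Extends the signal by reflection to length 2n, runs the circular MODWT,
#' and back-projects each detail level (and the final smooth) to the time
#' domain, truncated to the original support. The returned detail arrays
#' D1..DJ plus the smooth SJ sum to the input exactly. Each detail level
#' Dj has nominal frequency band `[fs/2^(j+1), fs/2^j]`.
#'
#' @param x numeric signal.
#' @param wavelet `"db4"` or `"haar"`.
#' @param J number of levels.
#' @param fs sampling rate, Hz (for the reported level bands).
#' @return An object of class `modwt_mra` with `D` (list of J detail
#'   arrays, input length), `S` (smooth), `level_band` (J x 2 matrix, Hz),
#'   `J`, `wavelet`.
#' @export
modwt_mra <- function(x, wavelet = "db4", J = 6, fs = 100) {
  n <- length(x)
  xe <- c(x, rev(x))
  dec <- modwt(xe, wavelet, J)
  filt <- wavelet_filters(wavelet)
  zero_dec <- function() {
    list(W = lapply(seq_len(J), function(i) numeric(2 * n)),
         V = numeric(2 * n), J = J, wavelet = wavelet, n = 2 * n)
  }
  D <- lapply(seq_len(J), function(j) {
    d <- zero_dec(); d$W[[j]] <- dec$W[[j]]
    imodwt(d)[seq_len(n)]
  })
  dS <- zero_dec(); dS$V <- dec$V
  S <- imodwt(dS)[seq_len(n)]
  band <- cbind(fs / 2^(seq_len(J) + 1), fs / 2^seq_len(J))
  colnames(band) <- c("low_hz", "high_hz")
  structure(list(D = D, S = S, level_band = band, J = J, wavelet = wavelet),
            class = "modwt_mra")
}
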