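## PMG-SATNet: encoder-decoder mapping a 10 s radar cardiac-motion segment
## (1000 samples at 100 Hz) to the synchronized ECG.  Encoder = parallel
## multi-scale CNN branches (MFEM) and a lightweight self-attention module
## (GRMM), merged by a learned fusion unit; decoder = causal dilated TCN
## blocks with spectral attention, residual to the fused features, and a
## final 2x linear-interpolation upsample.

#' Model configuration
#'
#' All architecture hyperparameters plus the ablation toggles. The three
#' CNN branch geometries are fixed by design -- small (kernel 3, padding 1,
#' dilation 1), medium (7, 3, 1), large (7, 6, 2), stride 1 everywhere --
#' giving, with `n_blocks_* = 4`, receptive fields of 9/25/49 samples
#' (0.09/0.25/0.49 s at 100 Hz). The encoder halves the temporal length to
#' `l = L/2`, so the sequence entering spectral attention spans the same
#' 10 s at `fs_effective = 50` Hz.
#'
#' @param L input length in samples (10 s at 100 Hz).
#' @param channels_branch channels per CNN branch.
#' @param n_blocks_s,n_blocks_m,n_blocks_l blocks per branch.
#' @param fusion_channels width of the fused encoder feature.
#' @param d_model,n_heads,m_layers,d_ff,dropout GRMM geometry.
#' @param tcn_channels,tcn_kernel,tcn_dilations,n_tcnsa_blocks decoder
#'   schedule; `tcn_dilations` must have `n_tcnsa_blocks` entries.
#' @param mask_band,mask_floor spectral-attention band (Hz) and out-of-band
#'   attenuation.
#' @param fs_effective sampling rate (Hz) of the sequence entering the SA
#'   blocks.
#' @param use_mfem,use_grmm,parallel,use_sa ablation toggles;
#'   `parallel = FALSE` (with both encoders on) routes the CNN features
#'   through the attention module sequentially.
#' @param loss `"rmse"` (root of the per-segment mean squared error) or
#'   `"mse"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(L = 1000, channels_branch = 16,
                         n_blocks_s = 4, n_blocks_m = 4, n_blocks_l = 4,
                         fusion_channels = 32,
                         d_model = 64, n_heads = 4, m_layers = 2,
                         d_ff = 2 * d_model, dropout = 0.1,
                         tcn_channels = 64, tcn_kernel = 3,
                         tcn_dilations = c(1, 2, 4), n_tcnsa_blocks = 3,
                         mask_band = c(0.5, 40), mask_floor = 0.1,
                         fs_effective = 50,
                         use_mfem = TRUE, use_grmm = TRUE, parallel = TRUE,
                         use_sa = TRUE, loss = "rmse") {
  if (L %% 2 != 0) stop_config("L must be even")
  if (mask_floor <= 0 || mask_floor >= 1)
    stop_config("mask_floor must lie in (0, 1)")
  if (length(tcn_dilations) != n_tcnsa_blocks)
    stop_config("tcn_dilations must have n_tcnsa_blocks entries")
  if (d_model %% n_heads != 0) stop_config("n_heads must divide d_model")
  if (!parallel && !(use_mfem && use_grmm))
    stop_config("sequential routing requires both encoders")
  if (!use_mfem && !use_grmm) stop_config("at least one encoder required")
  if (!loss %in% c("rmse", "mse")) stop_config("loss must be rmse or mse")
  structure(list(L = L, l = L %/% 2, channels_branch = channels_branch,
                 n_blocks_s = n_blocks_s, n_blocks_m = n_blocks_m,
                 n_blocks_l = n_blocks_l, fusion_channels = fusion_channels,
                 d_model = d_model, n_heads = n_heads, m_layers = m_layers,
                 d_ff = d_ff, dropout = dropout,
                 tcn_channels = tcn_channels, tcn_kernel = tcn_kernel,
                 tcn_dilations = tcn_dilations,
                 n_tcnsa_blocks = n_tcnsa_blocks,
                 mask_band = mask_band, mask_floor = mask_floor,
                 fs_effective = fs_effective,
                 use_mfem = use_mfem, use_grmm = use_grmm,
                 parallel = parallel, use_sa = use_sa, loss = loss),
            class = "model_config")
}

#' Ablation variants by name
#'
#' `"full"` is the complete model; `"model1"` drops the attention encoder
#' (CNN branches only), `"model2"` drops the CNN branches, `"model3"`
#' chains the CNN branches into the attention module instead of running
#' them in parallel, `"model4"` removes spectral attention from the
#' decoder.
#'
#' @param name one of `"full"`, `"model1"` ... `"model4"`.
#' @param ... further arguments to [model_config()].
#' @return A `model_config`.
#' @export
ablation_config <- function(name = "full", ...) {
  switch(name,
         full = model_config(...),
         model1 = model_config(use_grmm = FALSE, ...),
         model2 = model_config(use_mfem = FALSE, ...),
         model3 = model_config(parallel = FALSE, ...),
         model4 = model_config(use_sa = FALSE, ...),
         stop_config("unknown ablation '", name, "'"))
}

#' Reduced-width configuration for desk-scale experiments
#'
#' Same architecture, narrower: 8 channels per branch, 32-dim single-layer
#' attention with 2 heads, 2 TCN-SA blocks of 32 channels. Used by the
#' package's synthetic end-to-end experiments so a full training run fits
#' in minutes on one CPU core.
#'
#' @param ablation ablation name passed to [ablation_config()].
#' @param ... overrides.
#' @return A `model_config`.
#' @export
desk_model_config <- function(ablation = "full", ...) {
  args <- utils::modifyList(
    list(channels_branch = 8, fusion_channels = 16,
         d_model = 32, n_heads = 2, m_layers = 1,
         tcn_channels = 32, n_tcnsa_blocks = 2,
         tcn_dilations = c(1, 2)),
    list(...))
  do.call(ablation_config, c(list(name = ablation), args))
}

## CNN branch geometry (kernel, padding, dilation); stride 1 -------------

branch_geometry <- function(scale) {
  switch(scale,
         S = list(k = 3, pad = 1, dil = 1),
         M = list(k = 7, pad = 3, dil = 1),
         L = list(k = 7, pad = 6, dil = 2),
         stop_config("scale must be one of S, M, L"))
}

#' Receptive field of a stacked CNN branch
#'
#' `RF = 1 + n_blocks * (k - 1) * dilation` samples; each block is
#' length-preserving so receptive fields add.
#'
#' @param scale `"S"`, `"M"` or `"L"`.
#' @param n_blocks number of stacked blocks.
#' @param fs sampling rate, Hz.
#' @return A list with `samples` and `seconds`.
#' @export
branch_receptive_field <- function(scale, n_blocks = 4, fs = 100) {
  g <- branch_geometry(scale)
  rf <- 1 + n_blocks * (g$k - 1) * g$dil
  list(samples = rf, seconds = rf / fs)
}

## One CNN block: conv -> BN -> ReLU, length-preserving ------------------

make_cnn_block <- function(in_ch, out_ch, scale) {
  g <- branch_geometry(scale)
  list(conv = nn_conv1d(in_ch, out_ch, g$k, pad_left = g$pad,
                        dilation = g$dil),
       bn = nn_bn(out_ch), relu = nn_relu())
}

seq_forward <- function(blocks, x, train) {
  for (b in blocks) for (l in b) x <- l$forward(x, train)
  x
}

seq_backward <- function(blocks, g) {
  for (b in rev(blocks)) for (l in rev(b)) g <- l$backward(g)
  g
}

## Model assembly --------------------------------------------------------

#' Build a PMG-SATNet model
#'
#' Instantiates every layer with seeded He-uniform initialization and
#' returns a model object exposing `forward`, `backward`, and the flat
#' layer list consumed by the optimizer.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the initialization draws.
#' @return An object of class `pmg_satnet`.
#' @export
build_model <- function(cfg = model_config(), seed = 1) {
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  cb <- cfg$channels_branch
  with_seed(child_seed(seed, "init"), {
    if (cfg$use_mfem) {
      mk_branch <- function(scale, n) {
        lapply(seq_len(n), function(i)
          make_cnn_block(if (i == 1) 1 else cb, cb, scale))
      }
      m$branch_s <- mk_branch("S", cfg$n_blocks_s)
      m$branch_m <- mk_branch("M", cfg$n_blocks_m)
      m$branch_l <- mk_branch("L", cfg$n_blocks_l)
      m$mfem_fuse1 <- nn_conv1d(3 * cb, 2 * cb, 3, pad_left = 1)
      m$mfem_relu1 <- nn_relu()
      m$mfem_fuse2 <- nn_conv1d(2 * cb, cb, 3, pad_left = 1)
      m$mfem_pool <- nn_maxpool2()
    }
    if (cfg$use_grmm) {
      g_in <- if (cfg$parallel) 1 else cb
      m$g_embed <- nn_conv1d(g_in, cfg$d_model, 1)
      m$g_pos <- nn_posenc(cfg$d_model, cfg$l)
      m$g_drop <- nn_dropout(cfg$dropout)
      m$g_blocks <- lapply(seq_len(cfg$m_layers), function(i) list(
        mhsa = nn_mhsa(cfg$d_model, cfg$n_heads),
        drop1 = nn_dropout(cfg$dropout),
        ln1 = nn_layernorm(cfg$d_model),
        ffn = nn_gated_ffn(cfg$d_model, cfg$d_ff),
        drop2 = nn_dropout(cfg$dropout),
        ln2 = nn_layernorm(cfg$d_model)))
      if (cfg$parallel) m$g_pool <- nn_avgpool2()
      m$g_proj <- nn_conv1d(cfg$d_model, cb, 1)
    }
    dual <- cfg$use_mfem && cfg$use_grmm && cfg$parallel
    if (dual) {
      m$fuse_projM <- nn_conv1d(cb, cb, 1); m$fuse_reluM <- nn_relu()
      m$fuse_projG <- nn_conv1d(cb, cb, 1); m$fuse_reluG <- nn_relu()
      m$fuse_wc <- nn_conv1d(2 * cb, cfg$fusion_channels, 1)
    } else {
      m$fuse_wc <- nn_conv1d(cb, cfg$fusion_channels, 1)
    }
    m$fuse_bn <- nn_bn(cfg$fusion_channels)
    m$fuse_relu <- nn_relu()
    m$fuse_wf <- nn_conv1d(cfg$fusion_channels, cfg$fusion_channels, 1)
    m$dual <- dual

    m$dec_in <- nn_conv1d(cfg$fusion_channels, cfg$tcn_channels, 1)
    m$dec_blocks <- lapply(seq_len(cfg$n_tcnsa_blocks), function(i) {
      blk <- list(conv = nn_conv1d(cfg$tcn_channels, cfg$tcn_channels,
                                   cfg$tcn_kernel,
                                   pad_left = (cfg$tcn_kernel - 1) *
                                     cfg$tcn_dilations[i],
                                   pad_right = 0,
                                   dilation = cfg$tcn_dilations[i]),
                  bn = nn_bn(cfg$tcn_channels), relu = nn_relu())
      if (cfg$use_sa)
        blk$sa <- nn_sa_block(cfg$tcn_channels, cfg$l, cfg$fs_effective,
                              cfg$mask_band, cfg$mask_floor)
      blk
    })
    m$dec_out <- nn_conv1d(cfg$tcn_channels, 1, 1)
    m$dec_up <- nn_upsample2()
  })

  m$layers <- collect_layers(m)
  class(m) <- c("pmg_satnet", class(m))
  m
}

collect_layers <- function(m) {
  out <- list()
  add <- function(x) {
    if (inherits(x, "nn_layer")) {
      out[[length(out) + 1]] <<- x
      for (s in x$sub %||% list()) add(s)
    } else if (is.list(x)) for (e in x) add(e)
  }
  for (nm in c("branch_s", "branch_m", "branch_l", "mfem_fuse1",
               "mfem_relu1", "mfem_fuse2", "mfem_pool",
               "g_embed", "g_pos", "g_drop", "g_blocks", "g_pool", "g_proj",
               "fuse_projM", "fuse_reluM", "fuse_projG", "fuse_reluG",
               "fuse_wc", "fuse_bn", "fuse_relu", "fuse_wf",
               "dec_in", "dec_blocks", "dec_out", "dec_up")) {
    if (!is.null(m[[nm]])) add(m[[nm]])
  }
  ## keep only parameterized layers for the optimizer, but return all for
  ## mode handling; parameterized subset computed on demand
  out
}

param_layers <- function(m) {
  Filter(function(l) length(l$par) > 0, m$layers)
}

#' Count trainable parameters
#' @param model a `pmg_satnet`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  n_parameters(param_layers(model))
}

mfem_forward <- function(m, x, train) {
  fs <- seq_forward(m$branch_s, x, train)
  fm <- seq_forward(m$branch_m, x, train)
  fl <- seq_forward(m$branch_l, x, train)
  d <- dim(fs)
  cat3 <- array(0, dim = c(3 * d[1], d[2], d[3]))
  cat3[1:d[1], , ] <- fs
  cat3[(d[1] + 1):(2 * d[1]), , ] <- fm
  cat3[(2 * d[1] + 1):(3 * d[1]), , ] <- fl
  m$mfem_cat_dim <- d
  z <- m$mfem_fuse1$forward(cat3, train)
  z <- m$mfem_relu1$forward(z, train)
  z <- m$mfem_fuse2$forward(z, train)
  m$mfem_pool$forward(z, train)
}

mfem_backward <- function(m, g) {
  g <- m$mfem_pool$backward(g)
  g <- m$mfem_fuse2$backward(g)
  g <- m$mfem_relu1$backward(g)
  g <- m$mfem_fuse1$backward(g)
  d <- m$mfem_cat_dim
  gs <- g[1:d[1], , , drop = FALSE]
  gm <- g[(d[1] + 1):(2 * d[1]), , , drop = FALSE]
  gl <- g[(2 * d[1] + 1):(3 * d[1]), , , drop = FALSE]
  seq_backward(m$branch_s, gs) + seq_backward(m$branch_m, gm) +
    seq_backward(m$branch_l, gl)
}

## Temporal reduction to l happens right after the embedding (average
## pooling), so the quadratic-cost attention runs on the 50 Hz grid the
## decoder uses; positional encoding is added on the pooled grid.
grmm_forward <- function(m, x, train) {
  z <- m$g_embed$forward(x, train)
  if (!is.null(m$g_pool)) z <- m$g_pool$forward(z, train)
  z <- m$g_pos$forward(z, train)
  z <- m$g_drop$forward(z, train)
  for (blk in m$g_blocks) {
    a <- blk$mhsa$forward(z, train)
    a <- blk$drop1$forward(a, train)
    z <- blk$ln1$forward(z + a, train)
    f <- blk$ffn$forward(z, train)
    f <- blk$drop2$forward(f, train)
    z <- blk$ln2$forward(z + f, train)
  }
  m$g_proj$forward(z, train)
}

grmm_backward <- function(m, g) {
  g <- m$g_proj$backward(g)
  for (blk in rev(m$g_blocks)) {
    g2 <- blk$ln2$backward(g)
    gf <- blk$ffn$backward(blk$drop2$backward(g2))
    g <- g2 + gf
    g1 <- blk$ln1$backward(g)
    ga <- blk$mhsa$backward(blk$drop1$backward(g1))
    g <- g1 + ga
  }
  g <- m$g_drop$backward(g)
  g <- m$g_pos$backward(g)
  if (!is.null(m$g_pool)) g <- m$g_pool$backward(g)
  m$g_embed$backward(g)
}

fuse_forward <- function(m, FM, FG, train) {
  if (m$dual) {
    pm <- m$fuse_reluM$forward(m$fuse_projM$forward(FM, train), train)
    pg <- m$fuse_reluG$forward(m$fuse_projG$forward(FG, train), train)
    d <- dim(pm)
    cat2 <- array(0, dim = c(2 * d[1], d[2], d[3]))
    cat2[1:d[1], , ] <- pm
    cat2[(d[1] + 1):(2 * d[1]), , ] <- pg
    m$fuse_cat_dim <- d
    z <- cat2
  } else {
    z <- if (is.null(FG)) FM else FG
  }
  z <- m$fuse_wc$forward(z, train)
  z <- m$fuse_bn$forward(z, train)
  z <- m$fuse_relu$forward(z, train)
  m$fuse_wf$forward(z, train)
}

fuse_backward <- function(m, g) {
  g <- m$fuse_wf$backward(g)
  g <- m$fuse_relu$backward(g)
  g <- m$fuse_bn$backward(g)
  g <- m$fuse_wc$backward(g)
  if (m$dual) {
    d <- m$fuse_cat_dim
    gm <- m$fuse_projM$backward(
      m$fuse_reluM$backward(g[1:d[1], , , drop = FALSE]))
    gg <- m$fuse_projG$backward(
      m$fuse_reluG$backward(g[(d[1] + 1):(2 * d[1]), , , drop = FALSE]))
    list(gM = gm, gG = gg)
  } else {
    list(g = g)
  }
}

decoder_forward <- function(m, ffs, train) {
  z0 <- m$dec_in$forward(ffs, train)
  z <- z0
  for (blk in m$dec_blocks) {
    zin <- z
    z <- blk$conv$forward(z, train)
    z <- blk$bn$forward(z, train)
    z <- blk$relu$forward(z, train)
    z <- z + zin                               # residual within TCN block
    if (!is.null(blk$sa)) z <- blk$sa$forward(z, train)
  }
  z <- z + z0                                  # residual to fused features
  y <- m$dec_out$forward(z, train)
  m$dec_up$forward(y, train)
}

decoder_backward <- function(m, g) {
  g <- m$dec_up$backward(g)
  g <- m$dec_out$backward(g)
  g0 <- g                                      # residual to z0
  for (blk in rev(m$dec_blocks)) {
    if (!is.null(blk$sa)) g <- blk$sa$backward(g)
    gres <- g
    g <- blk$relu$backward(g)
    g <- blk$bn$backward(g)
    g <- blk$conv$backward(g)
    g <- g + gres
  }
  m$dec_in$backward(g + g0)
}

#' Forward pass
#'
#' @param model a `pmg_satnet` from [build_model()].
#' @param x numeric matrix, batch x L (each row one z-normalized radar
#'   cardiac segment), or a vector of length L.
#' @param train logical; training mode enables dropout and batch
#'   statistics.
#' @return Matrix batch x L of reconstructed ECG.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$cfg$L)
    stop_data("input length ", ncol(x), " != configured L = ", model$cfg$L)
  assert_finite(x, "model input")
  B <- nrow(x)
  xa <- array(t(x), dim = c(1, model$cfg$L, B))
  cfg <- model$cfg
  FM <- NULL; FG <- NULL
  if (cfg$use_mfem) FM <- mfem_forward(model, xa, train)
  if (cfg$use_grmm) {
    g_in <- if (cfg$parallel) xa else FM
    FG <- grmm_forward(model, g_in, train)
  }
  ffs <- fuse_forward(model, FM, FG, train)
  y <- decoder_forward(model, ffs, train)
  model$fwd_mode <- list(B = B)
  t(matrix(y, nrow = cfg$L))
}

## Backward: gy is batch x L matrix of dLoss/dy. Accumulates parameter
## gradients; returns nothing of interest.
model_backward <- function(model, gy) {
  cfg <- model$cfg
  B <- nrow(gy)
  g <- array(t(gy), dim = c(1, cfg$L, B))
  g <- decoder_backward(model, g)
  fb <- fuse_backward(model, g)
  if (model$dual) {
    gM <- fb$gM + 0
    gG <- fb$gG
    grmm_backward(model, gG)
    mfem_backward(model, gM)
  } else if (cfg$use_grmm && !cfg$parallel) {
    gFM <- grmm_backward(model, fb$g)
    mfem_backward(model, gFM)
  } else if (cfg$use_grmm) {
    grmm_backward(model, fb$g)
  } else {
    mfem_backward(model, fb$g)
  }
  invisible(NULL)
}

## Loss ------------------------------------------------------------------

#' Root-mean-square-error loss
#'
#' Per segment, the square root of the mean squared difference; averaged
#' over the batch.
#'
#' @param ecg_hat,ecg equal-shape vectors or batch x L matrices.
#' @return Scalar loss.
#' @export
rmse_loss <- function(ecg_hat, ecg) {
  loss_value(ecg_hat, ecg, "rmse")
}

loss_value <- function(yhat, y, type = "rmse") {
  if (is.vector(yhat)) { yhat <- matrix(yhat, 1); y <- matrix(y, 1) }
  if (!all(dim(yhat) == dim(y))) stop_data("loss: shape mismatch")
  per <- rowMeans((yhat - y)^2)
  if (type == "rmse") mean(sqrt(per)) else mean(per)
}

loss_grad <- function(yhat, y, type = "rmse") {
  L <- ncol(yhat); B <- nrow(yhat)
  diffs <- yhat - y
  if (type == "rmse") {
    r <- sqrt(rowMeans(diffs^2))
    r[r == 0] <- Inf                      # zero residual -> zero gradient
    diffs / (L * r * B)
  } else {
    2 * diffs / (L * B)
  }
}
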