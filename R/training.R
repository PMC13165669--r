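## Subject-disjoint cross-validated training with Adam, cosine-annealed
## learning rate and early stopping on an internal validation split.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam at initial learning rate
#' 0.001, 300 epochs, batch size 64, five subject-disjoint folds. The
#' validation slice for early stopping is carved from the training
#' subjects (10%, at least one subject) so test subjects never influence
#' any parameter update or stopping decision.
#'
#' @param lr initial learning rate.
#' @param epochs training epochs (cosine annealing horizon).
#' @param batch_size segments per optimizer step.
#' @param k_folds number of cross-validation folds.
#' @param patience epochs without validation improvement before stopping.
#' @param lr_min final learning rate of the cosine schedule.
#' @param val_frac fraction of training subjects held out for validation.
#' @param loss `"rmse"` or `"mse"`.
#' @param seed integer seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, epochs = 300, batch_size = 64,
                         k_folds = 5, patience = 20, lr_min = 1e-6,
                         val_frac = 0.1, loss = "rmse", seed = 1) {
  if (lr <= 0) stop_config("lr must be positive")
  if (k_folds < 2) stop_config("k_folds must be at least 2")
  structure(list(lr = lr, epochs = epochs, batch_size = batch_size,
                 k_folds = k_folds, patience = patience, lr_min = lr_min,
                 val_frac = val_frac, loss = loss, seed = seed),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_min + (lr0 - lr_min) * (1 + cos(pi * e / E)) / 2` for
#' 0-based epoch `e` over horizon `E`.
#'
#' @param epoch 0-based epoch index.
#' @param epochs horizon E.
#' @param lr0 initial learning rate.
#' @param lr_min floor.
#' @return Learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, epochs, lr0 = 0.001, lr_min = 1e-6) {
  lr_min + (lr0 - lr_min) * (1 + cos(pi * epoch / epochs)) / 2
}

#' Subject-level k-fold split
#'
#' Shuffles the subject list under `seed` and partitions it into `k` folds
#' whose sizes differ by at most one; every subject appears in exactly one
#' test fold, so segments are never split across train and test.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of `k` lists with `train_ids` and `test_ids`.
#' @export
split_subject_kfold <- function(subject_ids, k, seed = 1) {
  ids <- unique(subject_ids)
  if (length(ids) < k)
    stop_config("fewer subjects (", length(ids), ") than folds (", k, ")")
  shuffled <- with_seed(child_seed(seed, "kfold"), sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  lapply(seq_len(k), function(f) {
    list(train_ids = shuffled[fold_of != f], test_ids = shuffled[fold_of == f])
  })
}

## Early stopping: returns TRUE when `patience` consecutive evaluations
## fail to improve on the best seen loss.
early_stopper <- function(patience) {
  best <- Inf
  bad <- 0L
  evals <- 0L
  function(loss) {
    evals <<- evals + 1L
    if (loss < best) {
      best <<- loss
      bad <<- 0L
    } else {
      bad <<- bad + 1L
    }
    list(stop = bad >= patience, improved = bad == 0L, evals = evals,
         best = best)
  }
}

## Adam over the model's parameterized layers ----------------------------

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in layers) {
    if (is.null(l$opt_m)) {
      l$opt_m <- lapply(l$par, function(p) p * 0)   # keep structure/class
      l$opt_v <- l$opt_m
    }
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$opt_m[[nm]] <- beta1 * l$opt_m[[nm]] + (1 - beta1) * g
      l$opt_v[[nm]] <- beta2 * l$opt_v[[nm]] + (1 - beta2) * g^2
      l$par[[nm]] <- l$par[[nm]] -
        lr * (l$opt_m[[nm]] / c1) / (sqrt(l$opt_v[[nm]] / c2) + eps)
    }
  }
}

## Flat parameter vector (checkpointing, best-state restore) -------------

get_flat_params <- function(model) {
  unlist(lapply(param_layers(model), function(l) lapply(l$par, as.vector)),
         use.names = FALSE)
}

set_flat_params <- function(model, flat) {
  i <- 0L
  for (l in param_layers(model)) {
    for (nm in names(l$par)) {
      n <- length(l$par[[nm]])
      l$par[[nm]][] <- flat[(i + 1):(i + n)]
      i <- i + n
    }
  }
  if (i != length(flat)) stop_data("checkpoint parameter count mismatch")
  invisible(model)
}

## BN running statistics must travel with the parameters
get_bn_state <- function(model) {
  lapply(Filter(function(l) inherits(l, "nn_bn"), model$layers),
         function(l) list(mean = l$run_mean, var = l$run_var))
}

set_bn_state <- function(model, state) {
  bns <- Filter(function(l) inherits(l, "nn_bn"), model$layers)
  for (i in seq_along(bns)) {
    bns[[i]]$run_mean <- state[[i]]$mean
    bns[[i]]$run_var <- state[[i]]$var
  }
  invisible(model)
}

#' Save a model checkpoint
#'
#' Single JSON file embedding the model configuration, seed, flattened
#' parameters and batch-norm running statistics, at full precision.
#'
#' @param model a `pmg_satnet`.
#' @param path output file.
#' @param seed seed recorded alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, seed = NA) {
  bn <- get_bn_state(model)
  obj <- list(config = unclass(model$cfg), seed = seed,
              params = get_flat_params(model),
              bn_mean = unlist(lapply(bn, `[[`, "mean")),
              bn_var = unlist(lapply(bn, `[[`, "var")))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return A `pmg_satnet` with restored parameters.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- as.list(obj$config)
  cfgl$l <- NULL
  cfg <- do.call(model_config, cfgl)
  model <- build_model(cfg, seed = if (is.na(obj$seed)) 1 else obj$seed)
  set_flat_params(model, obj$params)
  if (length(obj$bn_mean)) {
    bns <- Filter(function(l) inherits(l, "nn_bn"), model$layers)
    i <- 0L
    state <- lapply(bns, function(l) {
      n <- length(l$run_mean)
      s <- list(mean = obj$bn_mean[(i + 1):(i + n)],
                var = obj$bn_var[(i + 1):(i + n)])
      i <<- i + n
      s
    })
    set_bn_state(model, state)
  }
  model
}

## Segment matrices ------------------------------------------------------

#' Assemble training matrices from a preprocessed dataset
#'
#' Stacks per-segment z-normalized radar cardiac traces (`x_card`) and
#' z-normalized target ECG (`ecg_clean` when present, else `ecg`) into
#' batch x L matrices. Per-segment z-normalization puts the dimensionless
#' morphology residuals of the loss on a comparable scale across segments.
#'
#' @param dataset a preprocessed `radar_dataset`.
#' @param subject_ids optional subset of subjects.
#' @return A list with `X`, `Y` (matrices), `subjects`, `scenarios`,
#'   `r_peaks` (list), `fs`.
#' @export
segment_matrices <- function(dataset, subject_ids = NULL) {
  segs <- dataset$segments
  if (!is.null(subject_ids))
    segs <- Filter(function(s) s$subject_id %in% subject_ids, segs)
  if (!length(segs)) stop_config("no segments for the requested subjects")
  xs <- lapply(segs, function(s) {
    if (is.null(s$x_card)) stop_data("dataset not preprocessed: x_card missing")
    znorm(s$x_card)
  })
  ys <- lapply(segs, function(s) znorm(s$ecg_clean %||% s$ecg))
  list(X = do.call(rbind, xs), Y = do.call(rbind, ys),
       subjects = vapply(segs, `[[`, character(1), "subject_id"),
       scenarios = vapply(segs, `[[`, character(1), "scenario"),
       r_peaks = lapply(segs, `[[`, "r_peak_times"),
       fs = dataset$cfg$fs)
}

#' Batched prediction
#'
#' @param model a `pmg_satnet`.
#' @param X batch x L input matrix.
#' @param batch_size forward-pass batch size.
#' @return Batch x L matrix of reconstructed ECG.
#' @export
predict_batches <- function(model, X, batch_size = 32) {
  out <- matrix(0, nrow(X), ncol(X))
  i <- 1L
  while (i <= nrow(X)) {
    j <- min(i + batch_size - 1L, nrow(X))
    out[i:j, ] <- model_forward(model, X[i:j, , drop = FALSE], train = FALSE)
    i <- j + 1L
  }
  out
}

#' Train a model on explicit matrices
#'
#' Adam with cosine-annealed learning rate and early stopping monitored on
#' the validation matrices; restores the best-validation parameters before
#' returning. Aborts with a diagnostic if the loss turns non-finite.
#'
#' @param X,Y training matrices (batch x L).
#' @param Xv,Yv validation matrices; `NULL` disables early stopping.
#' @param cfg a [train_config()].
#' @param mcfg a [model_config()].
#' @param verbose print per-epoch progress.
#' @return A list with `model` and `history` (data frame of epoch,
#'   train_loss, val_loss, lr).
#' @export
train_model <- function(X, Y, Xv = NULL, Yv = NULL, cfg = train_config(),
                        mcfg = model_config(), verbose = FALSE) {
  model <- build_model(mcfg, seed = cfg$seed)
  layers <- param_layers(model)
  n <- nrow(X)
  stopper <- early_stopper(cfg$patience)
  hist <- list()
  best_params <- NULL
  best_bn <- NULL
  step <- 0L
  with_seed(child_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cosine_lr(epoch - 1L, cfg$epochs, cfg$lr, cfg$lr_min)
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + cfg$batch_size - 1L, n)
        idx <- ord[i:j]
        zero_grads(layers)
        yhat <- model_forward(model, X[idx, , drop = FALSE], train = TRUE)
        lo <- loss_value(yhat, Y[idx, , drop = FALSE], cfg$loss)
        if (!is.finite(lo))
          stop_data("non-finite training loss at epoch ", epoch)
        model_backward(model, loss_grad(yhat, Y[idx, , drop = FALSE],
                                        cfg$loss))
        step <- step + 1L
        adam_step(layers, lr, step)
        ep_loss <- ep_loss + lo
        nb <- nb + 1L
        i <- j + 1L
      }
      ep_loss <- ep_loss / nb
      val_loss <- NA_real_
      stop_now <- FALSE
      if (!is.null(Xv)) {
        yv <- predict_batches(model, Xv, cfg$batch_size)
        val_loss <- loss_value(yv, Yv, cfg$loss)
        st <- stopper(val_loss)
        if (st$improved) {
          best_params <- get_flat_params(model)
          best_bn <- get_bn_state(model)
        }
        stop_now <- st$stop
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                  val_loss = val_loss, lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s  lr %.2e", epoch,
                        ep_loss, format(val_loss, digits = 4), lr))
      if (stop_now) break
    }
  })
  if (!is.null(best_params)) {
    set_flat_params(model, best_params)
    set_bn_state(model, best_bn)
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Train one cross-validation fold of a dataset
#'
#' Splits the fold's training subjects again into a subject-disjoint
#' validation slice (`val_frac`, at least one subject), asserts that no
#' test subject leaks into training, and runs [train_model()].
#'
#' @param dataset a preprocessed `radar_dataset`.
#' @param fold a list with `train_ids` and `test_ids` from
#'   [split_subject_kfold()].
#' @param cfg a [train_config()].
#' @param mcfg a [model_config()].
#' @param verbose print per-epoch progress.
#' @return A list with `model`, `history`, `train_ids`, `val_ids`,
#'   `test_ids`.
#' @export
train_fold <- function(dataset, fold, cfg = train_config(),
                       mcfg = model_config(), verbose = FALSE) {
  if (!length(fold$train_ids)) stop_config("empty training fold")
  if (length(fold$train_ids) >= 2) {
    n_val <- max(1L, ceiling(cfg$val_frac * length(fold$train_ids)))
    val_ids <- with_seed(child_seed(cfg$seed, "val-slice"),
                         sample(fold$train_ids, n_val))
  } else {
    val_ids <- character(0)     # single training subject: no early stopping
  }
  fit_ids <- setdiff(fold$train_ids, val_ids)
  stopifnot(length(intersect(fit_ids, fold$test_ids)) == 0,
            length(intersect(val_ids, fold$test_ids)) == 0)
  tr <- segment_matrices(dataset, fit_ids)
  va <- if (length(val_ids)) segment_matrices(dataset, val_ids) else NULL
  out <- train_model(tr$X, tr$Y, va$X, va$Y, cfg, mcfg, verbose)
  out$train_ids <- fit_ids
  out$val_ids <- val_ids
  out$test_ids <- fold$test_ids
  out
}
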