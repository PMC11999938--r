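#' Configuration of the stacked-LSTM force estimator
#'
#' One to three LSTM layers, each followed by batch normalization and
#' dropout, terminated by a single-output dense layer that reads the last
#' time step. The defaults are the best-performing grid cell of the
#' architecture search (three layers of 256-128-64 units, dropout 0.4,
#' batch size 100, initial learning rate 0.001), with RMSE as the
#' training loss and early stopping on validation loss.
#'
#' @param layer_units ordered unit counts, one per LSTM layer (1-3
#'   layers).
#' @param dropout dropout fraction in `[0, 1)` applied after each layer
#'   during training.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param patience early-stopping patience in epochs (used when a
#'   validation set is supplied).
#' @param max_epochs default epoch cap for [train_estimator()].
#' @param input_stride decimation factor applied to the envelope window
#'   before it enters the recurrent stack. The envelope is band-limited
#'   to the low-pass cutoff (5 Hz), so a window sampled at 1-2 kHz is
#'   heavily oversampled; a stride of 10 shortens the sequence tenfold
#'   with no information loss and proportional training speedup. Default
#'   1 (feed the raw window).
#' @param seed seed controlling parameter initialization.
#' @return an `estimator_config`.
#' @export
estimator_config <- function(layer_units = c(256L, 128L, 64L),
                             dropout = 0.4, batch_size = 100L,
                             learning_rate = 0.001, patience = 20L,
                             max_epochs = 300L, input_stride = 1L,
                             seed = 1L) {
  if (length(layer_units) < 1L) {
    stop_named("bad_config", "layer_units must name at least one layer")
  }
  if (length(layer_units) > 3L) {
    stop_named("bad_config", "at most 3 LSTM layers are supported")
  }
  stopifnot(all(layer_units >= 1), dropout >= 0, dropout < 1,
            batch_size >= 1, learning_rate > 0, max_epochs >= 0,
            input_stride >= 1)
  structure(
    list(layer_units = as.integer(layer_units), dropout = dropout,
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, patience = as.integer(patience),
         max_epochs = as.integer(max_epochs),
         input_stride = as.integer(input_stride), seed = as.integer(seed)),
    class = "estimator_config"
  )
}

#' Build an (untrained) stacked-LSTM force estimator
#'
#' Allocates and seeds the parameters: Glorot-uniform input and recurrent
#' weights, forget-gate bias initialized to 1, unit batch-norm scale.
#' Identical `(cfg, input_len)` give bitwise-identical initial
#' parameters.
#'
#' @param cfg an [estimator_config()].
#' @param input_len window length in samples the network expects
#'   (sequence length of the univariate envelope input).
#' @return an `lstm_estimator` (untrained).
#' @export
build_estimator <- function(cfg, input_len = 500L) {
  stopifnot(inherits(cfg, "estimator_config"), input_len >= 1L)
  with_seed(derive_seed(cfg$seed, "init"), {
    layers <- list()
    D <- 1L
    for (l in seq_along(cfg$layer_units)) {
      H <- cfg$layer_units[l]
      lim_x <- sqrt(6 / (D + 4 * H))
      lim_h <- sqrt(6 / (H + 4 * H))
      b <- rep(0, 4 * H)
      b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      layers[[l]] <- list(
        Wx = matrix(runif(D * 4 * H, -lim_x, lim_x), nrow = D),
        Wh = matrix(runif(H * 4 * H, -lim_h, lim_h), nrow = H),
        b = b,
        gamma = rep(1, H), beta = rep(0, H),
        run_mean = rep(0, H), run_var = rep(1, H)
      )
      D <- H
    }
    lim_d <- sqrt(6 / (D + 1))
    dense <- list(w = runif(D, -lim_d, lim_d), b = 0)
    structure(
      list(config = cfg, layers = layers, dense = dense,
           input_len = as.integer(input_len), trained = FALSE,
           history = data.frame()),
      class = "lstm_estimator"
    )
  })
}

#' @export
print.lstm_estimator <- function(x, ...) {
  cat(sprintf("<lstm_estimator> %s units, dropout %.2g, input length %d, %s\n",
              paste(x$config$layer_units, collapse = "-"),
              x$config$dropout, x$input_len,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

# -- internal forward/backward ------------------------------------------------

.bn_eps <- 1e-5

# (B, H, T) cube <-> (B*T, H) matrix with row order b-fastest-then-t
cube_to_mat <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
}
mat_to_cube <- function(m, B, T) {
  aperm(array(m, dim = c(B, T, ncol(m))), c(1, 3, 2))
}

# Forward pass over one minibatch.
#   x: (B, 1, T) array. train: dropout + batch-statistics BN on layers
#   above frozen_depth; frozen (and inference) layers use running stats.
# Dropout masks are drawn from the current RNG stream; callers seed it.
forward_pass <- function(est, x, train = FALSE, frozen_depth = 0L,
                         update_stats = train) {
  cfg <- est$config
  B <- dim(x)[1]
  T <- dim(x)[3]
  caches <- vector("list", length(est$layers))
  inp <- x
  for (l in seq_along(est$layers)) {
    par <- est$layers[[l]]
    lf <- lstm_forward_cpp(inp, par$Wx, par$Wh, par$b)
    hm <- cube_to_mat(lf$H)
    batch_mode <- train && l > frozen_depth
    if (batch_mode) {
      bm <- colMeans(hm)
      bv <- colMeans(hm^2) - bm^2
      if (update_stats) {
        est$layers[[l]]$run_mean <- 0.9 * par$run_mean + 0.1 * bm
        est$layers[[l]]$run_var <- 0.9 * par$run_var + 0.1 * bv
      }
    } else {
      bm <- par$run_mean
      bv <- par$run_var
    }
    invstd <- 1 / sqrt(bv + .bn_eps)
    xhat <- sweep(sweep(hm, 2L, bm), 2L, invstd, `*`)
    ym <- sweep(sweep(xhat, 2L, par$gamma, `*`), 2L, par$beta, `+`)
    mask <- NULL
    if (train && cfg$dropout > 0) {
      mask <- matrix(runif(length(ym)) >= cfg$dropout, nrow = nrow(ym))
      ym <- ym * mask / (1 - cfg$dropout)
    }
    caches[[l]] <- list(x = inp, lf = lf, xhat = xhat, invstd = invstd,
                        batch_mode = batch_mode, mask = mask)
    inp <- mat_to_cube(ym, B, T)
  }
  y_last <- matrix(inp[, , T], nrow = B)
  pred <- as.numeric(y_last %*% est$dense$w + est$dense$b)
  list(pred = pred, y_last = y_last, caches = caches, est = est,
       B = B, T = T)
}

# Backward pass; returns gradients for dense and layers > frozen_depth.
backward_pass <- function(est, fw, dpred, frozen_depth = 0L) {
  cfg <- est$config
  B <- fw$B
  T <- fw$T
  nl <- length(est$layers)
  grads <- list(dense = list(
    w = as.numeric(crossprod(fw$y_last, dpred)),
    b = sum(dpred)
  ), layers = vector("list", nl))

  Hl <- ncol(fw$y_last)
  dym <- matrix(0, nrow = B * T, ncol = Hl)
  dym[(T - 1L) * B + seq_len(B), ] <- outer(dpred, est$dense$w)

  for (l in rev(seq_len(nl))) {
    if (l <= frozen_depth) break
    par <- est$layers[[l]]
    cache <- fw$caches[[l]]
    if (!is.null(cache$mask)) {
      dym <- dym * cache$mask / (1 - cfg$dropout)
    }
    dgamma <- colSums(dym * cache$xhat)
    dbeta <- colSums(dym)
    dxhat <- sweep(dym, 2L, par$gamma, `*`)
    if (cache$batch_mode) {
      m <- nrow(dym)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dhm <- sweep(dxhat, 2L, s1 / m, `-`) -
        sweep(cache$xhat, 2L, s2 / m, `*`)
      dhm <- sweep(dhm, 2L, cache$invstd, `*`)
    } else {
      dhm <- sweep(dxhat, 2L, cache$invstd, `*`)
    }
    dH <- mat_to_cube(dhm, B, T)
    need_dx <- l > frozen_depth + 1L
    lb <- lstm_backward_cpp(dH, cache$x, cache$lf$H, cache$lf$C,
                            cache$lf$G, par$Wx, par$Wh, need_dx)
    grads$layers[[l]] <- list(Wx = lb$dWx, Wh = lb$dWh,
                              b = as.numeric(lb$db),
                              gamma = dgamma, beta = dbeta)
    if (need_dx) dym <- cube_to_mat(lb$dX)
  }
  grads
}

adam_state_new <- function() new.env(parent = emptyenv())

adam_step <- function(par, grad, state, key, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state[[key]])) {
    state[[key]] <- list(m = par * 0, v = par * 0)
  }
  s <- state[[key]]
  s$m <- beta1 * s$m + (1 - beta1) * grad
  s$v <- beta2 * s$v + (1 - beta2) * grad^2
  state[[key]] <- s
  mhat <- s$m / (1 - beta1^t)
  vhat <- s$v / (1 - beta2^t)
  par - lr * mhat / (sqrt(vhat) + eps)
}

windows_to_array <- function(windows, stride = 1L) {
  if (stride > 1L) {
    windows <- windows[, seq(1L, ncol(windows), by = stride),
                       drop = FALSE]
  }
  B <- nrow(windows)
  T <- ncol(windows)
  a <- array(0, dim = c(B, 1L, T))
  a[, 1L, ] <- windows
  a
}

# -- training and prediction --------------------------------------------------

#' Train the stacked-LSTM estimator
#'
#' Minimizes the RMSE loss with Adam over shuffled minibatches. When a
#' validation set is supplied, validation loss is monitored each epoch
#' and the parameters with the best validation loss are returned (early
#' stopping with the configured patience); otherwise the final parameters
#' are returned. The first `frozen_depth` LSTM layers (and their
#' batch-norm parameters and running statistics) are excluded from all
#' updates — this is the mechanism behind the layer-freezing transfer
#' strategies.
#'
#' @param est an `lstm_estimator` from [build_estimator()].
#' @param train a non-empty `sample_set`.
#' @param val optional validation `sample_set`; `NULL` disables early
#'   stopping.
#' @param max_epochs epoch cap (default: the config's).
#' @param seed seed controlling shuffling and dropout.
#' @param frozen_depth number of leading LSTM layers to freeze
#'   (`0 <= frozen_depth < number of layers`).
#' @param verbose print per-epoch losses.
#' @return the trained `lstm_estimator`, with `history` (per-epoch
#'   train/validation loss, percent RMSE) and `trained = TRUE`.
#' @export
train_estimator <- function(est, train, val = NULL, max_epochs = NULL,
                            seed = 1L, frozen_depth = 0L,
                            verbose = FALSE) {
  stopifnot(inherits(est, "lstm_estimator"), inherits(train, "sample_set"))
  if (nrow(train$windows) == 0L) {
    stop_named("empty_training_set", "training set has no windows")
  }
  if (ncol(train$windows) != est$input_len) {
    stop_named("window_length_mismatch",
               sprintf("windows have %d samples, estimator expects %d",
                       ncol(train$windows), est$input_len))
  }
  if (frozen_depth >= length(est$layers)) {
    stop_named("bad_frozen_depth",
               "frozen_depth must be smaller than the layer count")
  }
  cfg <- est$config
  max_epochs <- max_epochs %||% cfg$max_epochs
  if (max_epochs == 0L) return(est)
  n <- nrow(train$windows)
  bs <- min(cfg$batch_size, n)
  use_val <- !is.null(val) && nrow(val$windows) > 0L

  state <- adam_state_new()
  t_adam <- 0L
  best_val <- Inf
  best <- NULL
  wait <- 0L
  history <- data.frame()

  with_seed(derive_seed(seed, "train"), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      batch_losses <- numeric(0)
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, n)]
        x <- windows_to_array(train$windows[idx, , drop = FALSE],
                              cfg$input_stride)
        y <- train$targets[idx]
        fw <- forward_pass(est, x, train = TRUE,
                           frozen_depth = frozen_depth)
        est <- fw$est  # running-statistic updates
        err <- fw$pred - y
        loss <- sqrt(mean(err^2))
        if (!is.finite(loss)) {
          stop_named("nan_loss",
                     sprintf("non-finite loss at epoch %d", epoch))
        }
        batch_losses <- c(batch_losses, loss)
        dpred <- err / (length(err) * max(loss, 1e-8))
        grads <- backward_pass(est, fw, dpred, frozen_depth)
        t_adam <- t_adam + 1L
        lr <- cfg$learning_rate
        for (l in seq_along(est$layers)) {
          if (l <= frozen_depth || is.null(grads$layers[[l]])) next
          for (p in c("Wx", "Wh", "b", "gamma", "beta")) {
            est$layers[[l]][[p]] <- adam_step(
              est$layers[[l]][[p]], grads$layers[[l]][[p]], state,
              paste0("l", l, ".", p), lr, t_adam)
          }
        }
        est$dense$w <- adam_step(est$dense$w, grads$dense$w, state,
                                 "dense.w", lr, t_adam)
        est$dense$b <- adam_step(est$dense$b, grads$dense$b, state,
                                 "dense.b", lr, t_adam)
      }
      train_loss <- mean(batch_losses) * 100
      val_loss <- NA_real_
      if (use_val) {
        vp <- predict_batches(est, val$windows)
        val_loss <- rmse_pct(val$targets, vp)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss))
      if (verbose) {
        cat(sprintf("epoch %3d  train %.3f%%  val %s\n", epoch,
                    train_loss,
                    if (use_val) sprintf("%.3f%%", val_loss) else "-"))
      }
      if (use_val) {
        if (val_loss < best_val - 1e-10) {
          best_val <- val_loss
          best <- list(layers = est$layers, dense = est$dense)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
  })
  if (use_val && !is.null(best)) {
    est$layers <- best$layers
    est$dense <- best$dense
  }
  est$history <- rbind(est$history, history)
  est$trained <- TRUE
  est
}

# Inference in batches (dropout off, running-statistic batch norm).
predict_batches <- function(est, windows) {
  n <- nrow(windows)
  bs <- min(est$config$batch_size, n)
  out <- numeric(n)
  for (s in seq(1L, n, by = bs)) {
    idx <- s:min(s + bs - 1L, n)
    fw <- forward_pass(est,
                       windows_to_array(windows[idx, , drop = FALSE],
                                        est$config$input_stride %||% 1L),
                       train = FALSE)
    out[idx] <- fw$pred
  }
  out
}

#' Predict force targets for a sample set
#'
#' Deterministic inference: dropout off, batch normalization on running
#' statistics. One scalar per window, order-preserving.
#'
#' @param object a trained `lstm_estimator`.
#' @param samples a `sample_set` whose window length matches the
#'   estimator's input length.
#' @param ... unused.
#' @return numeric vector of predicted normalized-force targets.
#' @export
predict.lstm_estimator <- function(object, samples, ...) {
  stopifnot(inherits(samples, "sample_set"))
  if (ncol(samples$windows) != object$input_len) {
    stop_named("window_length_mismatch",
               sprintf("windows have %d samples, estimator expects %d",
                       ncol(samples$windows), object$input_len))
  }
  if (nrow(samples$windows) == 0L) return(numeric(0))
  predict_batches(object, samples$windows)
}

#' Split a sample set into train/validation/test partitions
#'
#' Random window-level split at the given proportions (the protocol used
#' to train the source network, 8:1:1 by default). A subject-level split
#' is available via `by_subject = TRUE`, which assigns whole subjects to
#' partitions — window-level splitting leaks subject identity across
#' partitions, so subject-level splitting is the honest option when
#' between-subject generalization is the claim.
#'
#' @param ss a `sample_set`.
#' @param ratios length-3 nonnegative weights for train/val/test.
#' @param seed split seed.
#' @param by_subject split whole subjects instead of windows.
#' @return list of `sample_set`s: `train`, `val`, `test`.
#' @export
split_samples <- function(ss, ratios = c(8, 1, 1), seed = 1L,
                          by_subject = FALSE) {
  stopifnot(inherits(ss, "sample_set"), length(ratios) == 3L,
            all(ratios >= 0), sum(ratios) > 0)
  with_seed(derive_seed(seed, "split"), {
    if (by_subject) {
      subjects <- unique(ss$provenance$subject)
      ns <- length(subjects)
      sh <- sample(subjects)
      cuts <- round(cumsum(ratios) / sum(ratios) * ns)
      grp <- rep(3L, ns)
      grp[seq_len(cuts[1])] <- 1L
      if (cuts[2] > cuts[1]) grp[(cuts[1] + 1L):cuts[2]] <- 2L
      part <- grp[match(ss$provenance$subject, sh)]
    } else {
      n <- nrow(ss$windows)
      sh <- sample.int(n)
      cuts <- round(cumsum(ratios) / sum(ratios) * n)
      part <- integer(n)
      part[sh[seq_len(cuts[1])]] <- 1L
      if (cuts[2] > cuts[1]) part[sh[(cuts[1] + 1L):cuts[2]]] <- 2L
      part[part == 0L] <- 3L
    }
    list(train = subset_samples(ss, part == 1L),
         val = subset_samples(ss, part == 2L),
         test = subset_samples(ss, part == 3L))
  })
}
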