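# 1D convolutional network for optical-property regression.
#
# Architecture: two convolution blocks (kernel (9,1), zero padding, batch
# normalization, leaky ReLU, max pooling (2,1)) followed by a hidden fully
# connected layer and a linear 4-output layer.  Forward pass, back
# propagation and the Adam optimizer are implemented directly with matrix
# algebra: activations are held as (length, batch, channels) arrays and
# convolutions evaluated as a sum over the K kernel offsets of
# (L*B x Cin) %*% (Cin x Cout) products, so everything runs through BLAS.
# Features and labels are z-scored with training-split statistics; the MSE
# loss is taken over the four normalized outputs so that parameters whose
# scales differ by two orders of magnitude contribute comparably.

#' CNN configuration
#'
#' Training hyper-parameters and architecture sizes.  Defaults follow the
#' training schedule used throughout the package: Adam (beta1 = 0.9) at
#' learning rate 1e-3 decayed by 0.1 every 100 epochs, batch size 32,
#' 200 epochs, early stopping checked on a held-out validation fold every
#' 5 epochs with patience 3 checks.
#'
#' @param filters channel counts of the two convolution blocks.
#' @param kernel convolution kernel length.
#' @param fc_width width of the hidden fully connected layer.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param lr,lr_decay,lr_decay_every learning-rate schedule.
#' @param beta1,beta2,adam_eps Adam moments.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param val_fraction fraction of the training split held out for early
#'   stopping.
#' @param early_stop_every validation-loss check interval, epochs.
#' @param patience checks without improvement before stopping (0 disables).
#' @param input_len feature-vector length (must be divisible by 4).
#' @param n_out number of regression outputs.
#' @param seed RNG seed controlling initialization and batch order.
#' @return object of class \code{cnn_config}.
#' @export
cnn_config <- function(filters = c(16L, 32L), kernel = 9L, fc_width = 128L,
                       leaky_slope = 0.01, lr = 1e-3, lr_decay = 0.1,
                       lr_decay_every = 100L, beta1 = 0.9, beta2 = 0.999,
                       adam_eps = 1e-8, batch_size = 32L, epochs = 200L,
                       val_fraction = 0.1, early_stop_every = 5L,
                       patience = 3L, input_len = 256L, n_out = 4L,
                       seed = 1L) {
  if (input_len %% 4L != 0L) stop("input_len must be divisible by 4 (two pools)")
  if (kernel %% 2L != 1L) stop("kernel length must be odd (zero same-padding)")
  structure(as.list(environment()), class = "cnn_config")
}

he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

cnn_init_params <- function(cfg) {
  K <- cfg$kernel; f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
  flat <- (cfg$input_len %/% 4L) * f2
  list(
    conv1_W = array(he_init(K * 1 * f1, K), c(K, 1, f1)),
    conv1_b = numeric(f1),
    bn1_gamma = rep(1, f1), bn1_beta = numeric(f1),
    conv2_W = array(he_init(K * f1 * f2, K * f1), c(K, f1, f2)),
    conv2_b = numeric(f2),
    bn2_gamma = rep(1, f2), bn2_beta = numeric(f2),
    fc1_W = matrix(he_init(flat * cfg$fc_width, flat), flat, cfg$fc_width),
    fc1_b = numeric(cfg$fc_width),
    out_W = matrix(he_init(cfg$fc_width * cfg$n_out, cfg$fc_width),
                   cfg$fc_width, cfg$n_out),
    out_b = numeric(cfg$n_out))
}

cnn_init_state <- function(cfg) {
  list(bn1_mean = numeric(cfg$filters[1]), bn1_var = rep(1, cfg$filters[1]),
       bn2_mean = numeric(cfg$filters[2]), bn2_var = rep(1, cfg$filters[2]))
}

# ---- fast layer primitives -------------------------------------------------
#
# Activations are channel-major (C x L*B) matrices whose columns run l
# fastest, then batch.  Per-channel affine operations (batch norm, biases)
# then recycle a length-C vector down the columns with no indexing
# overhead, and each convolution is one gather plus one BLAS product.
# Gather/scatter index vectors depend only on the shapes and are cached.

.plan_cache <- new.env(parent = emptyenv())

conv_plan <- function(L, B, K) {
  key <- paste(L, B, K, sep = ":")
  pl <- .plan_cache[[key]]
  if (!is.null(pl)) return(pl)
  Lp <- L + K - 1L
  pad <- (K - 1L) %/% 2L
  b_off <- rep((0:(B - 1L)) * Lp, each = L)
  pcols <- rep(pad + seq_len(L), B) + b_off          # data columns inside pad
  Rk <- matrix(0L, L * B, K)                         # gather columns per offset
  for (k in seq_len(K))
    Rk[, k] <- rep(seq_len(L) + (k - 1L), B) + b_off
  pl <- list(Lp = Lp, pcols = pcols, Rk = Rk)
  .plan_cache[[key]] <- pl
  pl
}

pool_plan <- function(L, B) {
  key <- paste("pool", L, B, sep = ":")
  pl <- .plan_cache[[key]]
  if (!is.null(pl)) return(pl)
  b_off <- rep((0:(B - 1L)) * L, each = L %/% 2L)
  odd <- rep(seq(1L, L, 2L), B) + b_off
  pl <- list(odd = odd, even = odd + 1L)
  .plan_cache[[key]] <- pl
  pl
}

flat_plan <- function(L4, B, C) {
  key <- paste("flat", L4, B, C, sep = ":")
  pl <- .plan_cache[[key]]
  if (!is.null(pl)) return(pl)
  # Xf[b, (c-1)*L4 + l] = M[c, l + (b-1)*L4]: linear indices into the
  # (C x L4*B) matrix in Xf's column-major fill order (b fastest, l, c)
  cc <- rep(seq_len(C), each = B * L4)
  ll <- rep(rep(seq_len(L4), each = B), C)
  bb <- rep(rep(seq_len(B), times = L4), C)
  pl <- list(idx = cc + ((ll + (bb - 1L) * L4) - 1L) * C)
  .plan_cache[[key]] <- pl
  pl
}

# W (K, Cin, Cout) flattened so rows run c fastest within k, matching the
# row order of the im2col gather below
w_flat <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(2, 1, 3)), d[1] * d[2], d[3])
}

w_unflat <- function(W2, K, Cin, Cout) {
  aperm(array(W2, c(Cin, K, Cout)), c(2, 1, 3))
}

# convolution forward: M (Cin x L*B) -> (Cout x L*B)
conv_fwd <- function(M, W, b, L, B) {
  K <- dim(W)[1]; Cin <- dim(W)[2]
  pl <- conv_plan(L, B, K)
  Mpad <- matrix(0, Cin, pl$Lp * B)
  Mpad[, pl$pcols] <- M
  Xcol <- matrix(0, K * Cin, L * B)
  for (k in seq_len(K))
    Xcol[(k - 1L) * Cin + seq_len(Cin), ] <- Mpad[, pl$Rk[, k]]
  Y <- crossprod(w_flat(W), Xcol) + b
  list(Y = Y, Xcol = Xcol, pl = pl)
}

conv_bwd <- function(dY, cache, W, L, B) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  pl <- cache$pl
  dW <- w_unflat(tcrossprod(cache$Xcol, dY), K, Cin, Cout)
  dXcol <- w_flat(W) %*% dY
  dMpad <- matrix(0, Cin, pl$Lp * B)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * Cin + seq_len(Cin)
    dMpad[, pl$Rk[, k]] <- dMpad[, pl$Rk[, k]] +
      dXcol[rows, , drop = FALSE]
  }
  list(dW = dW, db = rowSums(dY), dM = dMpad[, pl$pcols, drop = FALSE])
}

bn_fwd_train <- function(X, gamma, beta, eps = 1e-5) {
  C <- nrow(X); n <- ncol(X)
  mu <- .rowMeans(X, C, n)
  xc <- X - mu
  v <- .rowMeans(xc * xc, C, n)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(Y = xhat * gamma + beta, xhat = xhat, istd = istd, mu = mu, v = v)
}

bn_fwd_infer <- function(X, gamma, beta, rmean, rvar, eps = 1e-5) {
  ((X - rmean) / sqrt(rvar + eps)) * gamma + beta
}

bn_bwd <- function(dY, cache, gamma) {
  C <- nrow(dY); n <- ncol(dY)
  dxhat <- dY * gamma
  m1 <- .rowMeans(dxhat, C, n)
  m2 <- .rowMeans(dxhat * cache$xhat, C, n)
  list(dX = (dxhat - m1 - cache$xhat * m2) * cache$istd,
       dgamma = rowSums(dY * cache$xhat), dbeta = rowSums(dY))
}

leaky_fwd <- function(X, slope) X * (slope + (1 - slope) * (X > 0))
leaky_bwd <- function(dY, X, slope) dY * (slope + (1 - slope) * (X > 0))

pool_fwd <- function(M, L, B) {
  pl <- pool_plan(L, B)
  v1 <- M[, pl$odd, drop = FALSE]
  v2 <- M[, pl$even, drop = FALSE]
  m <- v1 >= v2
  list(Y = pmax(v1, v2), m = m, pl = pl)
}

pool_bwd <- function(dY, cache, L, B) {
  dM <- matrix(0, nrow(dY), L * B)
  dM[, cache$pl$odd] <- dY * cache$m
  dM[, cache$pl$even] <- dY * !cache$m
  dM
}

# X: B x input_len matrix of normalized features.  Returns B x n_out output
# and (in training mode) the caches required for back propagation.
cnn_forward <- function(params, cfg, state, X, train = TRUE) {
  B <- nrow(X); L <- cfg$input_len
  f2 <- cfg$filters[2]
  L2 <- L %/% 2L; L4 <- L %/% 4L
  M0 <- matrix(as.vector(t(X)), 1L)            # 1 x L*B
  cv1 <- conv_fwd(M0, params$conv1_W, params$conv1_b, L, B)
  if (train) bn1 <- bn_fwd_train(cv1$Y, params$bn1_gamma, params$bn1_beta)
  else bn1 <- list(Y = bn_fwd_infer(cv1$Y, params$bn1_gamma, params$bn1_beta,
                                    state$bn1_mean, state$bn1_var))
  a1 <- leaky_fwd(bn1$Y, cfg$leaky_slope)
  p1 <- pool_fwd(a1, L, B)                     # f1 x L2*B
  cv2 <- conv_fwd(p1$Y, params$conv2_W, params$conv2_b, L2, B)
  if (train) bn2 <- bn_fwd_train(cv2$Y, params$bn2_gamma, params$bn2_beta)
  else bn2 <- list(Y = bn_fwd_infer(cv2$Y, params$bn2_gamma, params$bn2_beta,
                                    state$bn2_mean, state$bn2_var))
  a2 <- leaky_fwd(bn2$Y, cfg$leaky_slope)
  p2 <- pool_fwd(a2, L2, B)                    # f2 x L4*B
  fp <- flat_plan(L4, B, f2)
  Xf <- matrix(p2$Y[fp$idx], B, L4 * f2)
  h_pre <- Xf %*% params$fc1_W + rep(params$fc1_b, each = B)
  h <- leaky_fwd(h_pre, cfg$leaky_slope)
  out <- h %*% params$out_W + rep(params$out_b, each = B)
  if (!train) return(list(out = out))
  list(out = out, cache = list(
    cv1 = cv1, bn1 = bn1, p1 = p1, cv2 = cv2, bn2 = bn2, p2 = p2,
    fp = fp, Xf = Xf, h_pre = h_pre, h = h, B = B))
}

cnn_backward <- function(params, cfg, cache, dOut) {
  B <- cache$B; L <- cfg$input_len
  f2 <- cfg$filters[2]
  L2 <- L %/% 2L; L4 <- L %/% 4L
  g <- list()
  g$out_W <- crossprod(cache$h, dOut)
  g$out_b <- colSums(dOut)
  dh <- leaky_bwd(tcrossprod(dOut, params$out_W), cache$h_pre,
                  cfg$leaky_slope)
  g$fc1_W <- crossprod(cache$Xf, dh)
  g$fc1_b <- colSums(dh)
  dXf <- tcrossprod(dh, params$fc1_W)          # B x flat
  dP2 <- matrix(0, f2, L4 * B)
  dP2[cache$fp$idx] <- dXf
  dA2 <- pool_bwd(dP2, cache$p2, L2, B)
  dZ2 <- leaky_bwd(dA2, cache$bn2$Y, cfg$leaky_slope)
  bb2 <- bn_bwd(dZ2, cache$bn2, params$bn2_gamma)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  cb2 <- conv_bwd(bb2$dX, cache$cv2, params$conv2_W, L2, B)
  g$conv2_W <- cb2$dW; g$conv2_b <- cb2$db
  dA1 <- pool_bwd(cb2$dM, cache$p1, L, B)
  dZ1 <- leaky_bwd(dA1, cache$bn1$Y, cfg$leaky_slope)
  bb1 <- bn_bwd(dZ1, cache$bn1, params$bn1_gamma)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  cb1 <- conv_bwd(bb1$dX, cache$cv1, params$conv1_W, L, B)
  g$conv1_W <- cb1$dW; g$conv1_b <- cb1$db
  g
}

adam_step <- function(params, grads, mstate, vstate, t, lr, cfg) {
  for (nm in names(grads)) {
    mstate[[nm]] <- cfg$beta1 * mstate[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    vstate[[nm]] <- cfg$beta2 * vstate[[nm]] + (1 - cfg$beta2) * grads[[nm]]^2
    mhat <- mstate[[nm]] / (1 - cfg$beta1^t)
    vhat <- vstate[[nm]] / (1 - cfg$beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + cfg$adam_eps)
  }
  list(params = params, m = mstate, v = vstate)
}

# Exact batch-norm population statistics for a fixed set of weights:
# forward passes in training mode over the data, averaging the per-batch
# moments.  Running averages collected during optimization always lag the
# drifting batch statistics (weight norms grow freely under batch norm's
# scale invariance), so inference-time statistics are re-estimated this
# way at every validation checkpoint and after training.
refresh_bn_stats <- function(params, cfg, X, chunk = 256L) {
  acc <- cnn_init_state(cfg)
  acc <- lapply(acc, function(x) x * 0)
  nb <- 0L
  for (i0 in seq(1L, nrow(X), chunk)) {
    sel <- i0:min(i0 + chunk - 1L, nrow(X))
    if (length(sel) < 2L) next
    fw <- cnn_forward(params, cfg, NULL, X[sel, , drop = FALSE],
                      train = TRUE)
    acc$bn1_mean <- acc$bn1_mean + fw$cache$bn1$mu
    acc$bn1_var <- acc$bn1_var + fw$cache$bn1$v
    acc$bn2_mean <- acc$bn2_mean + fw$cache$bn2$mu
    acc$bn2_var <- acc$bn2_var + fw$cache$bn2$v
    nb <- nb + 1L
  }
  lapply(acc, function(x) x / nb)
}

# average validation loss in inference mode, in chunks to bound memory
cnn_eval_loss <- function(params, cfg, state, X, Y) {
  n <- nrow(X)
  tot <- 0
  for (i0 in seq(1L, n, 256L)) {
    sel <- i0:min(i0 + 255L, n)
    out <- cnn_forward(params, cfg, state, X[sel, , drop = FALSE],
                       train = FALSE)$out
    tot <- tot + sum((out - Y[sel, , drop = FALSE])^2)
  }
  tot / (n * ncol(Y))
}

run_training <- function(params, state, cfg, Xn, Yn, lr_base, epochs,
                         mstate = NULL, vstate = NULL, t0 = 0L) {
  n <- nrow(Xn)
  # internal validation fold for early stopping (no fold when early
  # stopping is disabled: every example trains)
  if (cfg$patience > 0L) {
    n_val <- max(1L, round(cfg$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- seq_len(min(2L, n))
    tr_idx <- seq_len(n)
  }
  Xtr <- Xn[tr_idx, , drop = FALSE]; Ytr <- Yn[tr_idx, , drop = FALSE]
  Xval <- Xn[val_idx, , drop = FALSE]; Yval <- Yn[val_idx, , drop = FALSE]
  if (is.null(mstate)) {
    mstate <- lapply(params, function(p) p * 0)
    vstate <- lapply(params, function(p) p * 0)
  }
  t <- t0
  best <- list(loss = Inf, params = params, state = state)
  bad_checks <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  ntr <- nrow(Xtr)
  for (epoch in seq_len(epochs)) {
    lr <- lr_base * cfg$lr_decay^((epoch - 1L) %/% cfg$lr_decay_every)
    ord <- sample.int(ntr)
    ep_loss <- 0; nb <- 0L
    for (i0 in seq(1L, ntr, cfg$batch_size)) {
      sel <- ord[i0:min(i0 + cfg$batch_size - 1L, ntr)]
      if (length(sel) < 2L) next  # batch norm needs >= 2 examples
      fw <- cnn_forward(params, cfg, state, Xtr[sel, , drop = FALSE],
                        train = TRUE)
      diff <- fw$out - Ytr[sel, , drop = FALSE]
      loss <- mean(diff^2)
      if (!is.finite(loss)) {
        err <- simpleError("training diverged: non-finite loss")
        err$history <- hist
        stop(err)
      }
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      grads <- cnn_backward(params, cfg, fw$cache,
                            2 * diff / length(diff))
      t <- t + 1L
      upd <- adam_step(params, grads, mstate, vstate, t, lr, cfg)
      params <- upd$params; mstate <- upd$m; vstate <- upd$v
    }
    vl <- NA_real_
    if (cfg$patience > 0L && epoch %% cfg$early_stop_every == 0L) {
      state <- refresh_bn_stats(params, cfg, Xtr)
      vl <- cnn_eval_loss(params, cfg, state, Xval, Yval)
      if (vl < best$loss * (1 - 1e-6)) {
        best <- list(loss = vl, params = params, state = state)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_loss = vl, lr = lr))
    if (cfg$patience > 0L && bad_checks >= cfg$patience) break
  }
  if (cfg$patience > 0L && is.finite(best$loss)) {
    params <- best$params
    state <- best$state
  } else {
    state <- refresh_bn_stats(params, cfg, Xtr)
  }
  list(params = params, state = state, history = hist,
       m = mstate, v = vstate, t = t,
       val_loss = if (is.finite(best$loss)) best$loss else
         cnn_eval_loss(params, cfg, state, Xval, Yval))
}

#' Train the CNN optical-property estimator
#'
#' Trains the two-block CNN on the training split of a labelled dataset.
#' Features and labels are z-scored with statistics computed from the
#' training split only; those statistics are frozen into the returned
#' estimator and reused verbatim at prediction time.  Training follows the
#' configured schedule (Adam, stepwise learning-rate decay, early stopping
#' on an internal validation fold) and is deterministic given
#' \code{config$seed}.
#'
#' @param dataset a \code{dot_dataset} (see [make_simulation_dataset()])
#'   with at least 500 training examples, or a list with elements
#'   \code{features}, \code{labels} (and optionally \code{split}).
#' @param config a \code{cnn_config}.
#' @param min_examples minimum number of labelled training examples.
#' @return object of class \code{dot_cnn}: trained weights, frozen
#'   normalization statistics, configuration and per-epoch loss history.
#' @seealso [predict.dot_cnn()], [cnn_fine_tune()]
#' @export
cnn_train <- function(dataset, config = cnn_config(), min_examples = 500L) {
  tr <- dataset_split(dataset, "train")
  if (nrow(tr$features) < min_examples)
    stop("need at least ", min_examples, " labelled training examples")
  if (ncol(tr$features) != config$input_len)
    stop("feature length ", ncol(tr$features), " does not match config input_len")
  stats <- norm_stats(tr$features, tr$labels)
  Xn <- zscore_apply(tr$features, stats$feature_mean, stats$feature_sd)
  Yn <- zscore_apply(tr$labels, stats$label_mean, stats$label_sd)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  params <- cnn_init_params(config)
  state <- cnn_init_state(config)
  res <- run_training(params, state, config, Xn, Yn,
                      lr_base = config$lr, epochs = config$epochs)
  structure(list(params = res$params, state = res$state, config = config,
                 stats = stats, history = res$history,
                 val_loss = res$val_loss, fine_tuned = FALSE),
            class = "dot_cnn")
}

#' Fine-tune a trained estimator on new data
#'
#' Continues optimization from the existing weights at a reduced learning
#' rate (default 1e-4 for 100 epochs), e.g. on calibrated lab-phantom data
#' to adapt the simulation-trained network to instrument characteristics.
#' Normalization statistics are NOT recomputed: the new data must live in
#' the feature space the estimator was trained on.
#'
#' @param est a \code{dot_cnn}.
#' @param dataset dataset whose training split is used for fine-tuning.
#' @param lr fine-tuning learning rate.
#' @param epochs fine-tuning epochs; 0 returns the estimator unchanged.
#' @param seed RNG seed for batch order.
#' @return the fine-tuned \code{dot_cnn}.
#' @export
cnn_fine_tune <- function(est, dataset, lr = 1e-4, epochs = 100L, seed = 1L) {
  stopifnot(inherits(est, "dot_cnn"))
  if (epochs == 0L) return(est)
  tr <- dataset_split(dataset, "train")
  if (ncol(tr$features) != est$config$input_len)
    stop("fine-tuning data does not match the estimator's feature space")
  Xn <- zscore_apply(tr$features, est$stats$feature_mean, est$stats$feature_sd)
  Yn <- zscore_apply(tr$labels, est$stats$label_mean, est$stats$label_sd)
  cfg <- est$config
  cfg$lr_decay_every <- .Machine$integer.max  # constant fine-tune rate
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  res <- run_training(est$params, est$state, cfg, Xn, Yn,
                      lr_base = lr, epochs = epochs)
  est$params <- res$params
  est$state <- res$state
  est$history <- rbind(est$history, res$history)
  est$val_loss <- res$val_loss
  est$fine_tuned <- TRUE
  est
}

#' @export
print.dot_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "CNN optical-property estimator: %d parameters, %d epochs trained%s\n",
    np, nrow(x$history), if (x$fine_tuned) " (fine-tuned)" else ""))
  cat(sprintf("  final validation MSE (normalized): %.4g\n", x$val_loss))
  invisible(x)
}

#' Predict optical properties from feature vectors
#'
#' Normalizes the input with the estimator's frozen training statistics,
#' runs the forward pass in inference mode (batch-norm running statistics)
#' and de-normalizes the four outputs, clipping them to be positive.
#'
#' @param object a \code{dot_cnn}.
#' @param newdata a 256-element feature vector or an (n x 256) matrix.
#' @param ... unused.
#' @return matrix (n x 4) with columns mua, musp, mua_chest, musp_chest
#'   (cm^-1); for a single vector input, a \code{dot_fit} is available via
#'   [cnn_fit()].
#' @export
predict.dot_cnn <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1L)
  if (ncol(newdata) != object$config$input_len)
    stop("feature length ", ncol(newdata), " does not match the estimator (",
         object$config$input_len, ")")
  Xn <- zscore_apply(newdata, object$stats$feature_mean,
                     object$stats$feature_sd)
  out <- matrix(NA_real_, nrow(Xn), object$config$n_out)
  for (i0 in seq(1L, nrow(Xn), 512L)) {
    sel <- i0:min(i0 + 511L, nrow(Xn))
    out[sel, ] <- cnn_forward(object$params, object$config, object$state,
                              Xn[sel, , drop = FALSE], train = FALSE)$out
  }
  est <- zscore_invert(out, object$stats$label_mean, object$stats$label_sd)
  est <- pmax(est, 1e-4)
  colnames(est) <- c("mua", "musp", "mua_chest", "musp_chest")
  est
}

#' CNN prediction as a fit result
#'
#' @param est a \code{dot_cnn}.
#' @param fv a single 256-element feature vector.
#' @return a \code{dot_fit} with method "cnn".
#' @export
cnn_fit <- function(est, fv) {
  dot_fit(predict(est, fv)[1, ], method = "cnn")
}

#' K-fold cross-validation harness
#'
#' The alternative reading of "k-fold validation during training": trains
#' one estimator per fold, each using that fold as its early-stopping
#' validation set, and reports per-fold held-out errors.  The default
#' training path uses a single random split; this harness exists for
#' reporting and for ensembling (average the fold models' predictions).
#'
#' @param dataset a \code{dot_dataset}; folds partition its training split.
#' @param config a \code{cnn_config}.
#' @param folds number of folds (10 in the full protocol).
#' @return list with \code{estimators} (one \code{dot_cnn} per fold) and
#'   \code{fold_errors} (folds x 4 matrix of mean relative errors, \%, on
#'   each fold's held-out part).
#' @export
cnn_cross_validate <- function(dataset, config = cnn_config(), folds = 10L) {
  tr <- dataset_split(dataset, "train")
  n <- nrow(tr$features)
  if (folds < 2L || folds > n) stop("folds must be in [2, n_train]")
  assign_fold <- with_seed(config$seed, sample(rep_len(seq_len(folds), n)))
  ests <- vector("list", folds)
  errs <- matrix(NA_real_, folds, 4L,
                 dimnames = list(NULL, c("mua", "musp", "mua_chest",
                                         "musp_chest")))
  for (f in seq_len(folds)) {
    hold <- assign_fold == f
    cfg <- config
    cfg$seed <- config$seed + f
    est <- cnn_train(list(features = tr$features[!hold, , drop = FALSE],
                          labels = tr$labels[!hold, , drop = FALSE]),
                     cfg, min_examples = 2L)
    pred <- predict(est, tr$features[hold, , drop = FALSE])
    errs[f, ] <- 100 * colMeans(abs(pred - tr$labels[hold, , drop = FALSE]) /
                                  abs(tr$labels[hold, , drop = FALSE]))
    ests[[f]] <- est
  }
  list(estimators = ests, fold_errors = errs)
}
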