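# Bidirectional LSTM classifier, written from first principles in base R:
# forward pass, backpropagation through time, Adam, and a step learning-rate
# schedule. The network is small (one BiLSTM layer, one hidden
# fully-connected layer, two-class softmax head) and trains on CPU in
# seconds to minutes at the problem sizes this package targets.
#
# Architecture (sequence-to-label):
#   input frames -> ReLU -> BiLSTM (final forward state ++ final backward
#   state) -> FC + ReLU -> linear -> softmax over {NSR, AF}.
# Label order is fixed: NSR = 0 (column 1), AF = 1 (column 2); prediction
# ties break toward NSR.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

# One direction's LSTM parameters; gate order in the stacked weight
# matrices is [input, forget, cell-candidate, output].
init_lstm_dir <- function(input_dim, h) {
  b <- numeric(4 * h)
  b[seq.int(h + 1L, 2L * h)] <- 1  # forget-gate bias starts open
  list(W = glorot(input_dim, 4 * h), U = glorot(h, 4 * h), b = b)
}

init_params <- function(input_dim, hidden, fc_units) {
  list(
    fwd = init_lstm_dir(input_dim, hidden),
    bwd = init_lstm_dir(input_dim, hidden),
    W_fc = glorot(2 * hidden, fc_units),
    b_fc = rep(0.01, fc_units),  # small positive bias keeps ReLU units live
    W_out = glorot(fc_units, 2L),
    b_out = numeric(2L)
  )
}

n_params <- function(p) {
  sum(vapply(rapply(p, identity, how = "unlist"), length, integer(1)))
}

# Run one LSTM direction over a batch. xs: list of T matrices (batch x d),
# already in processing order (reversed for the backward direction).
# Returns the final hidden state and, if keep_cache, everything BPTT needs.
lstm_forward <- function(par, xs, h, keep_cache = FALSE) {
  T_len <- length(xs)
  batch <- nrow(xs[[1L]])
  H <- matrix(0, batch, h)
  C <- matrix(0, batch, h)
  cache <- if (keep_cache) vector("list", T_len) else NULL
  i1 <- seq_len(h); i2 <- i1 + h; i3 <- i2 + h; i4 <- i3 + h
  for (t in seq_len(T_len)) {
    z <- xs[[t]] %*% par$W + H %*% par$U + rep(par$b, each = batch)
    gi <- sigmoid(z[, i1, drop = FALSE])
    gf <- sigmoid(z[, i2, drop = FALSE])
    gg <- tanh(z[, i3, drop = FALSE])
    go <- sigmoid(z[, i4, drop = FALSE])
    C_new <- gf * C + gi * gg
    tc <- tanh(C_new)
    H_new <- go * tc
    if (keep_cache) {
      cache[[t]] <- list(x = xs[[t]], H_prev = H, C_prev = C,
                         gi = gi, gf = gf, gg = gg, go = go, tc = tc)
    }
    H <- H_new
    C <- C_new
  }
  list(H = H, cache = cache)
}

# BPTT for one direction given the gradient at the final hidden state.
lstm_backward <- function(par, cache, dH_final, h) {
  T_len <- length(cache)
  batch <- nrow(dH_final)
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  dU <- matrix(0, h, 4 * h)
  db <- numeric(4 * h)
  dH <- dH_final
  dC <- matrix(0, batch, h)
  i1 <- seq_len(h); i2 <- i1 + h; i3 <- i2 + h; i4 <- i3 + h
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    d_o <- dH * cc$tc
    dC <- dC + dH * cc$go * (1 - cc$tc^2)
    d_i <- dC * cc$gg
    d_g <- dC * cc$gi
    d_f <- dC * cc$C_prev
    dC <- dC * cc$gf
    dz <- cbind(d_i * cc$gi * (1 - cc$gi),
                d_f * cc$gf * (1 - cc$gf),
                d_g * (1 - cc$gg^2),
                d_o * cc$go * (1 - cc$go))
    dW <- dW + crossprod(cc$x, dz)
    dU <- dU + crossprod(cc$H_prev, dz)
    db <- db + colSums(dz)
    dH <- dz %*% t(par$U)
  }
  list(W = dW, U = dU, b = db)
}

# Full forward pass. X: list of records, each a T x d matrix (equal T).
# Returns probabilities (batch x 2, columns NSR then AF) and caches.
network_forward <- function(params, X, hidden, keep_cache = FALSE) {
  batch <- length(X)
  T_len <- nrow(X[[1L]])
  # relu on the (already nonnegative-scaled) input, then per-timestep stacks
  xs <- lapply(seq_len(T_len), function(t) {
    m <- t(vapply(X, function(r) r[t, ], numeric(ncol(X[[1L]]))))
    m[m < 0] <- 0
    m
  })
  fw <- lstm_forward(params$fwd, xs, hidden, keep_cache)
  bw <- lstm_forward(params$bwd, rev(xs), hidden, keep_cache)
  Hcat <- cbind(fw$H, bw$H)
  A1 <- Hcat %*% params$W_fc + rep(params$b_fc, each = batch)
  R1 <- A1; R1[R1 < 0] <- 0
  logits <- R1 %*% params$W_out + rep(params$b_out, each = batch)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs,
       cache = if (keep_cache) list(fw = fw, bw = bw, Hcat = Hcat,
                                    A1 = A1, R1 = R1) else NULL)
}

# Gradients of mean cross-entropy over the batch. y01: 0 = NSR, 1 = AF.
network_gradients <- function(params, X, y01, hidden) {
  out <- network_forward(params, X, hidden, keep_cache = TRUE)
  batch <- length(X)
  Y <- cbind(1 - y01, y01)
  dlogits <- (out$probs - Y) / batch
  cache <- out$cache
  dW_out <- crossprod(cache$R1, dlogits)
  db_out <- colSums(dlogits)
  dR1 <- dlogits %*% t(params$W_out)
  dA1 <- dR1 * (cache$A1 > 0)
  dW_fc <- crossprod(cache$Hcat, dA1)
  db_fc <- colSums(dA1)
  dHcat <- dA1 %*% t(params$W_fc)
  g_fwd <- lstm_backward(params$fwd, cache$fw$cache,
                         dHcat[, seq_len(hidden), drop = FALSE], hidden)
  g_bwd <- lstm_backward(params$bwd, cache$bw$cache,
                         dHcat[, hidden + seq_len(hidden), drop = FALSE], hidden)
  eps <- 1e-12
  loss <- -mean(log(pmax(out$probs[cbind(seq_len(batch), y01 + 1L)], eps)))
  list(grads = list(fwd = g_fwd, bwd = g_bwd, W_fc = dW_fc, b_fc = db_fc,
                    W_out = dW_out, b_out = db_out),
       loss = loss, probs = out$probs)
}

# Flatten/unflatten parameter trees (used by Adam and the gradient check).
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

relist_params <- function(v, skeleton) {
  out <- skeleton
  pos <- 1L
  assign_leaf <- function(x) {
    n <- length(x)
    leaf <- v[seq.int(pos, pos + n - 1L)]
    pos <<- pos + n
    if (is.matrix(x)) matrix(leaf, nrow(x), ncol(x)) else leaf
  }
  for (nm in names(out)) {
    if (is.list(out[[nm]])) {
      for (nm2 in names(out[[nm]])) out[[nm]][[nm2]] <- assign_leaf(out[[nm]][[nm2]])
    } else {
      out[[nm]] <- assign_leaf(out[[nm]])
    }
  }
  out
}

adam_init <- function(par_vec) {
  list(m = numeric(length(par_vec)), v = numeric(length(par_vec)), t = 0L)
}

adam_step <- function(state, par_vec, grad_vec, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad_vec
  state$v <- beta2 * state$v + (1 - beta2) * grad_vec^2
  m_hat <- state$m / (1 - beta1^state$t)
  v_hat <- state$v / (1 - beta2^state$t)
  list(state = state, par = par_vec - lr * m_hat / (sqrt(v_hat) + eps))
}

#' Learning rate at a given epoch under the step-decay schedule
#'
#' `lr(e) = initial_lr * lrdf^floor((e - 1) / decay_period)` for 1-based
#' epoch `e`: the rate is multiplied by the learning-rate drop factor
#' (LRDF) once every `decay_period` epochs.
#'
#' @param epoch 1-based epoch number.
#' @param initial_lr Initial learning rate.
#' @param lrdf Learning-rate drop factor in (0, 1].
#' @param decay_period Epochs between drops.
#' @return The learning rate in effect at `epoch`.
#' @export
lr_at_epoch <- function(epoch, initial_lr = 0.01525, lrdf = 0.5,
                        decay_period = 10L) {
  initial_lr * lrdf^floor((epoch - 1) / decay_period)
}

# ---- model assembly -------------------------------------------------------

# Convert a feature_matrix (or plain matrix) into the network's T x d input:
# band features per frame with the record's time-domain features appended to
# every frame.
net_input <- function(fm) {
  if (inherits(fm, "feature_matrix")) {
    cbind(fm$values,
          matrix(fm$time_features, nrow = nrow(fm$values),
                 ncol = length(fm$time_features), byrow = TRUE))
  } else if (is.matrix(fm)) {
    fm
  } else {
    stop_invalid("features must be feature_matrix objects or matrices")
  }
}

labels_to01 <- function(y) {
  y <- as.character(y)
  if (!all(y %in% c("AF", "NSR"))) stop_invalid("labels must be 'AF' or 'NSR'")
  as.integer(y == "AF")
}

# Per-feature max-scaling fitted on the training set; inputs are
# nonnegative, so dividing by the column max maps them into [0, 1] and the
# input ReLU is an identity.
fit_scaler <- function(Xlist) {
  mx <- Reduce(pmax, lapply(Xlist, function(m) apply(m, 2L, max)))
  mx[mx <= 0] <- 1
  mx
}

apply_scaler <- function(Xlist, mx) {
  lapply(Xlist, function(m) sweep(m, 2L, mx, "/"))
}

#' Build an untrained BiLSTM classifier
#'
#' Initializes the network weights (Glorot-uniform, forget-gate bias 1)
#' deterministically from the seed. Usually called through [af_bilstm()].
#'
#' @param input_dim Features per frame (bands + time-domain features).
#' @param hidden_units Hidden units per LSTM direction.
#' @param fc_units Width of the fully-connected layer.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `af_bilstm` with `trained = FALSE`.
#' @export
build_bilstm <- function(input_dim, hidden_units = 64L, fc_units = 32L,
                         seed = 1L) {
  if (!is_count(input_dim, 1L)) stop_invalid("input_dim must be >= 1")
  if (!is_count(hidden_units, 1L) || !is_count(fc_units, 1L)) {
    stop_invalid("hidden_units and fc_units must be positive integers")
  }
  params <- with_seed(seed, init_params(input_dim, hidden_units, fc_units))
  structure(
    list(params = params, input_dim = as.integer(input_dim),
         hidden_units = as.integer(hidden_units),
         fc_units = as.integer(fc_units), seed = as.integer(seed),
         scaler = NULL, trained = FALSE, history = NULL, config = NULL),
    class = "af_bilstm"
  )
}

#' Fit a BiLSTM atrial-fibrillation classifier
#'
#' Trains the bidirectional-LSTM network on per-record feature matrices with
#' minibatch Adam and a step learning-rate schedule: the rate starts at
#' `initial_lr` and is multiplied by `lrdf` every `decay_period` epochs.
#' Training is deterministic for a fixed `seed` (weights, feature scaling
#' and batch shuffling all derive from it).
#'
#' @param x List of [extract_cepncc()] feature matrices (or plain
#'   frames-by-features matrices, all with the same dimensions).
#' @param y Labels, `"AF"` or `"NSR"`; taken from the feature matrices'
#'   `rhythm_label` when omitted. Both classes must be present with at
#'   least two examples each.
#' @param hidden_units Hidden units per LSTM direction.
#' @param fc_units Fully-connected layer width.
#' @param initial_lr Initial learning rate (default 0.01525, the value the
#'   range test selects on the reference task).
#' @param lrdf Learning-rate drop factor (default 0.5).
#' @param decay_period Epochs between learning-rate drops.
#' @param max_epochs Maximum training epochs (default 100).
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss and accuracy.
#' @return An object of class `af_bilstm` with the fitted weights, the
#'   feature scaler, and a per-epoch `history` data.frame (`epoch`, `lr`,
#'   `loss`, `accuracy`).
#' @seealso [predict.af_bilstm()], [lr_range_test()]
#' @export
af_bilstm <- function(x, y = NULL, hidden_units = 64L, fc_units = 32L,
                      initial_lr = 0.01525, lrdf = 0.5, decay_period = 10L,
                      max_epochs = 100L, batch_size = 16L, seed = 1L,
                      verbose = FALSE) {
  if (!is.list(x) || !length(x)) stop_invalid("x must be a non-empty list")
  if (is.null(y)) {
    y <- vapply(x, function(f) {
      if (!inherits(f, "feature_matrix")) {
        stop_invalid("y must be given when x are plain matrices")
      }
      f$rhythm_label
    }, character(1))
  }
  if (length(y) != length(x)) stop_invalid("x and y lengths differ")
  y01 <- labels_to01(y)
  if (sum(y01 == 1L) < 2L || sum(y01 == 0L) < 2L) {
    stop_invalid("need at least 2 examples of each class (AF and NSR)")
  }
  if (!is_number(lrdf) || lrdf <= 0 || lrdf > 1) {
    stop_invalid("lrdf must lie in (0, 1]")
  }
  if (!is_count(max_epochs, 1L)) stop_invalid("max_epochs must be >= 1")

  Xraw <- lapply(x, net_input)
  dims <- vapply(Xraw, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_invalid("all feature matrices must share the same dimensions")
  }
  scaler <- fit_scaler(Xraw)
  X <- apply_scaler(Xraw, scaler)

  model <- build_bilstm(ncol(X[[1L]]), hidden_units, fc_units, seed = seed)
  params <- model$params
  skeleton <- params
  pv <- flatten_params(params)
  opt <- adam_init(pv)
  n <- length(X)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), accuracy = numeric(0))

  batch_orders <- with_seed(seed + 1L,
                            lapply(seq_len(max_epochs),
                                   function(e) sample.int(n)))
  for (epoch in seq_len(max_epochs)) {
    lr <- lr_at_epoch(epoch, initial_lr, lrdf, decay_period)
    ord <- batch_orders[[epoch]]
    losses <- numeric(0)
    n_correct <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[seq.int(start, min(start + batch_size - 1L, n))]
      gr <- network_gradients(params, X[idx], y01[idx], model$hidden_units)
      step <- adam_step(opt, pv, flatten_params(gr$grads), lr)
      opt <- step$state
      pv <- step$par
      params <- relist_params(pv, skeleton)
      losses <- c(losses, gr$loss * length(idx))
      pred <- as.integer(gr$probs[, 2L] > gr$probs[, 1L])
      n_correct <- n_correct + sum(pred == y01[idx])
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss = sum(losses) / n,
      accuracy = n_correct / n))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.5g  loss %.4f  acc %.3f",
                      epoch, lr, sum(losses) / n, n_correct / n))
    }
  }

  model$params <- params
  model$scaler <- scaler
  model$trained <- TRUE
  model$history <- history
  model$config <- list(initial_lr = initial_lr, lrdf = lrdf,
                       decay_period = as.integer(decay_period),
                       max_epochs = as.integer(max_epochs),
                       batch_size = as.integer(batch_size), seed = seed)
  model
}

#' Predict rhythm labels with a fitted BiLSTM classifier
#'
#' @param object A trained [af_bilstm()] model.
#' @param newdata List of feature matrices (as in training).
#' @param type `"label"` for a data.frame of labels and class
#'   probabilities, `"prob"` for the probability matrix only.
#' @param ... Unused.
#' @return For `type = "label"` a data.frame with columns `label`,
#'   `p_nsr`, `p_af`; predicted label is the argmax probability, with exact
#'   ties resolved to `"NSR"`. Predictions are independent of batch order.
#' @export
predict.af_bilstm <- function(object, newdata, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) {
    stop_invalid("model has not been trained; call af_bilstm() first")
  }
  Xraw <- lapply(newdata, net_input)
  if (any(vapply(Xraw, ncol, integer(1)) != object$input_dim)) {
    stop_invalid("feature dimension does not match the fitted model (",
                 object$input_dim, " expected)")
  }
  X <- apply_scaler(Xraw, object$scaler)
  probs <- network_forward(object$params, X, object$hidden_units)$probs
  colnames(probs) <- c("NSR", "AF")
  if (type == "prob") return(probs)
  label <- ifelse(probs[, "AF"] > probs[, "NSR"], "AF", "NSR")
  data.frame(label = label, p_nsr = probs[, "NSR"], p_af = probs[, "AF"],
             stringsAsFactors = FALSE)
}

#' @export
print.af_bilstm <- function(x, ...) {
  cat(sprintf("BiLSTM AF classifier (%s)\n",
              if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  input dim %d, %d hidden units/direction, FC width %d (%s parameters)\n",
              x$input_dim, x$hidden_units, x$fc_units,
              format(n_params(x$params), big.mark = ",")))
  if (isTRUE(x$trained)) {
    h <- x$history
    cat(sprintf("  %d epochs; final loss %.4f, training accuracy %.1f%%\n",
                nrow(h), h$loss[nrow(h)], 100 * h$accuracy[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.af_bilstm <- function(object, ...) {
  print(object)
  if (isTRUE(object$trained)) {
    cat("\nLearning-rate schedule:\n")
    first <- !duplicated(object$history$lr)
    print(object$history[first, c("epoch", "lr")], row.names = FALSE)
  }
  invisible(object)
}

#' Plot the training history of a fitted BiLSTM classifier
#'
#' @param x A trained [af_bilstm()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.af_bilstm <- function(x, ...) {
  if (!isTRUE(x$trained)) stop_invalid("nothing to plot: model untrained")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Count trainable parameters of a BiLSTM classifier
#'
#' @param model An [af_bilstm()] or [build_bilstm()] object.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  n_params(model$params)
}

# ---- learning-rate range test --------------------------------------------

#' Suggest a learning rate from a range-test loss curve
#'
#' Smooths the per-batch losses with a 5-point moving average, truncates at
#' the first divergence (non-finite loss), and returns the learning rate at
#' the minimum of the smoothed curve's descending branch (the first global
#' minimum). An all-constant curve yields `lrs[1]`.
#'
#' @param lrs Strictly increasing learning-rate grid.
#' @param losses Loss recorded at each rate.
#' @return List with `suggested_lr`, `smoothed` losses and the `valid`
#'   index range used.
#' @export
suggest_lr <- function(lrs, losses) {
  stopifnot(length(lrs) == length(losses))
  bad <- which(!is.finite(losses))
  valid <- if (length(bad)) seq_len(bad[1L] - 1L) else seq_along(losses)
  if (!length(valid)) return(list(suggested_lr = lrs[1L],
                                  smoothed = numeric(0), valid = valid))
  l <- losses[valid]
  k <- length(l)
  sm <- vapply(seq_len(k), function(i) {
    mean(l[max(1L, i - 2L):min(k, i + 2L)])
  }, numeric(1))
  best <- which.min(sm)  # first index at the minimum: the descending branch
  list(suggested_lr = lrs[valid][best], smoothed = sm, valid = valid)
}

#' Learning-rate range test
#'
#' Trains fresh minibatches with a geometrically increasing learning rate,
#' retaining the loss from each batch, then suggests an initial rate via
#' [suggest_lr()]. Divergence (non-finite loss) truncates the curve and the
#' suggestion comes from the valid prefix.
#'
#' @param model An untrained [build_bilstm()] model (a trained model's
#'   architecture is reused with re-initialized weights).
#' @param x,y Features and labels as in [af_bilstm()].
#' @param lr_start,lr_end Range endpoints, `lr_start < lr_end`.
#' @param n_steps Number of batches / rates (>= 10).
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @return List with `lr` (the grid), `loss` (per-batch losses),
#'   `smoothed`, and `suggested_lr`.
#' @export
lr_range_test <- function(model, x, y = NULL, lr_start = 1e-5, lr_end = 1,
                          n_steps = 60L, batch_size = 16L, seed = 1L) {
  if (!is_number(lr_start) || !is_number(lr_end) || lr_start >= lr_end) {
    stop_invalid("need lr_start < lr_end")
  }
  if (!is_count(n_steps, 10L)) stop_invalid("n_steps must be >= 10")
  if (is.null(y)) y <- vapply(x, `[[`, character(1), "rhythm_label")
  y01 <- labels_to01(y)
  Xraw <- lapply(x, net_input)
  scaler <- fit_scaler(Xraw)
  X <- apply_scaler(Xraw, scaler)

  lrs <- exp(seq(log(lr_start), log(lr_end), length.out = n_steps))
  params <- model$params
  skeleton <- params
  pv <- flatten_params(params)
  opt <- adam_init(pv)
  n <- length(X)
  losses <- rep(NA_real_, n_steps)
  batches <- with_seed(seed, lapply(seq_len(n_steps), function(i) {
    sample.int(n, min(batch_size, n))
  }))
  for (i in seq_len(n_steps)) {
    gr <- network_gradients(params, X[batches[[i]]], y01[batches[[i]]],
                            model$hidden_units)
    losses[i] <- gr$loss
    if (!is.finite(gr$loss)) break
    step <- adam_step(opt, pv, flatten_params(gr$grads), lrs[i])
    opt <- step$state
    pv <- step$par
    params <- relist_params(pv, skeleton)
  }
  sug <- suggest_lr(lrs, losses)
  list(lr = lrs, loss = losses, smoothed = sug$smoothed,
       suggested_lr = sug$suggested_lr)
}
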