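# LSTM classifier with focal loss: parameter handling, reference cell
# step, losses, Nadam, the ecg_lstm() fitting front end and its methods.
# The batched forward/BPTT hot path lives in src/lstm.cpp; lstm_step()
# here is an independent pure-R statement of the cell equations used for
# documentation and cross-checking.

#' Initialize LSTM parameters
#'
#' Gate matrices act on the concatenation `[a_(t-1), x_t, c_(t-1)]`, so
#' each has shape `hidden x (2 * hidden + input_size)`. Weights are drawn
#' from the Glorot (scaled uniform) distribution. Gate biases follow
#' chrono initialization: each unit is assigned a memory timescale drawn
#' log-uniformly from `[1, timescale_max]`, the forget-gate bias is the
#' log of that timescale and the input-gate bias its negative, so that at
#' initialization the cell states behave like leaky integrators of the
#' input with time constants spanning the whole sequence. This matters
#' for 250-step beat sequences: with a flat small forget bias the final
#' hidden state initially carries no information about the QRS complex
#' (~125 steps earlier) and short training runs collapse to the majority
#' class. Candidate and output biases start at zero.
#'
#' @param hidden Hidden size H (default 64).
#' @param input_size Per-timestep input size D (default 1; one ECG sample
#'   per step).
#' @param fc Width of the first fully connected layer (default 32).
#' @param n_classes Number of output classes C (default 8).
#' @param timescale_max Upper bound of the chrono-init memory timescales,
#'   normally the sequence length (default 250).
#' @param input_gain Multiplier applied to the `x_t` column of the gate
#'   matrices at initialization (default 4). One ECG sample per step is a
#'   1-dimensional input competing with `2H` recurrent inputs of similar
#'   scale; boosting its initial weight makes the cell states track the
#'   waveform from the first updates instead of mostly talking to
#'   themselves, which speeds up short training runs considerably.
#' @param seed Integer seed; identical seeds give identical parameters.
#' @return Named list of class `lstm_params`: gate matrices `W_f`, `W_i`,
#'   `W_c`, `W_o`, biases `b_f`, `b_i`, `b_c`, `b_o`, and the two FC
#'   layers `W_fc1`/`b_fc1` (ReLU) and `W_fc2`/`b_fc2` (linear).
#' @export
init_lstm_params <- function(hidden = 64, input_size = 1, fc = 32,
                             n_classes = 8, timescale_max = 250,
                             input_gain = 4, seed = NULL) {
  if (hidden < 1 || input_size < 1 || fc < 1 || n_classes < 1) {
    stop("all layer dimensions must be >= 1")
  }
  if (timescale_max < 1) stop("timescale_max must be >= 1")
  .with_seed(seed, {
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    nin <- 2L * hidden + input_size
    gate <- function() {
      w <- glorot(hidden, nin)
      w[, hidden + seq_len(input_size)] <-
        w[, hidden + seq_len(input_size)] * input_gain
      w
    }
    b_forget <- stats::runif(hidden, 0, log(timescale_max))  # log timescales
    p <- list(
      W_f = gate(), W_i = gate(), W_c = gate(), W_o = gate(),
      b_f = b_forget, b_i = -b_forget,
      b_c = rep(0, hidden), b_o = rep(0, hidden),
      W_fc1 = glorot(fc, hidden), b_fc1 = rep(0, fc),
      W_fc2 = glorot(n_classes, fc), b_fc2 = rep(0, n_classes)
    )
    structure(p, class = "lstm_params",
              dims = list(H = as.integer(hidden), D = as.integer(input_size),
                          H1 = as.integer(fc), C = as.integer(n_classes)))
  })
}

#' One LSTM cell step (reference implementation)
#'
#' Evaluates the cell equations for a single timestep: all three sigmoid
#' gates and the tanh candidate read the concatenation
#' `[a_(t-1), x_t, c_(t-1)]` (the `c_(t-1)` block is a peephole-style
#' input; set `peephole = FALSE` to drop it), then
#' `c_t = f_t * c_(t-1) + i_t * c_in` and `a_t = o_t * tanh(c_t)`,
#' all elementwise.
#'
#' @param params `lstm_params` (see [init_lstm_params()]).
#' @param x_t Numeric vector of length `input_size`.
#' @param state Previous state: list with `a` and `c` (length-H vectors),
#'   or `NULL` for the zero initial state.
#' @param peephole Feed `c_(t-1)` into the gate pre-activations
#'   (default TRUE).
#' @return List with `a`, `c` and the gate activations `f`, `i`, `c_in`,
#'   `o` (diagnostics).
#' @export
lstm_step <- function(params, x_t, state = NULL, peephole = TRUE) {
  H <- nrow(params$W_f)
  D <- ncol(params$W_f) - 2L * H
  if (length(x_t) != D) stop("x_t must have length ", D)
  if (is.null(state)) state <- list(a = rep(0, H), c = rep(0, H))
  if (length(state$a) != H || length(state$c) != H) {
    stop("state vectors must have length ", H)
  }
  sig <- function(z) 1 / (1 + exp(-z))
  u <- c(state$a, x_t, if (peephole) state$c else rep(0, H))
  f <- sig(drop(params$W_f %*% u) + params$b_f)
  i <- sig(drop(params$W_i %*% u) + params$b_i)
  c_in <- tanh(drop(params$W_c %*% u) + params$b_c)
  ct <- f * state$c + i * c_in
  o <- sig(drop(params$W_o %*% u) + params$b_o)
  list(a = o * tanh(ct), c = ct, f = f, i = i, c_in = c_in, o = o)
}

#' Numerically stable softmax
#'
#' `softmax(z)_j = exp(z_j) / sum_k exp(z_k)`, computed with
#' max-subtraction so that large logits do not overflow. Invariant to
#' adding a constant to all logits.
#'
#' @param z Numeric vector of logits, or a matrix with one logit vector
#'   per row.
#' @return Probability vector (or matrix of row-wise probabilities):
#'   positive entries summing to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    s <- exp(z - apply(z, 1L, max))
    return(s / rowSums(s))
  }
  s <- exp(z - max(z))
  s / sum(s)
}

#' Cross-entropy loss on the true-class probability
#'
#' `-log(p)` with natural logarithm; probabilities below `1e-12` are
#' clamped before the log so the loss stays finite.
#'
#' @param p_true Probabilities assigned to the true class (vectorized).
#' @return Loss values, same length as `p_true`.
#' @export
cross_entropy <- function(p_true) {
  -log(pmax(p_true, 1e-12))
}

#' Focal loss on the true-class probability
#'
#' `-(1 - p)^gamma * log(p)`: cross-entropy scaled by the modulating
#' factor `(1 - p)^gamma`, which downweights confidently classified
#' examples so that abundant easy (typically normal-beat) examples do not
#' dominate training. With `gamma = 0` this is exactly the cross-entropy.
#' No class-balance weight is applied.
#'
#' @param p_true Probabilities assigned to the true class (vectorized);
#'   clamped at `1e-12` as in [cross_entropy()].
#' @param gamma Focusing parameter, `gamma >= 0` (default 2).
#' @return Loss values, same length as `p_true`.
#' @export
focal_loss <- function(p_true, gamma = 2) {
  if (gamma < 0) stop("gamma must be >= 0")
  (1 - p_true)^gamma * cross_entropy(p_true)
}

#' Mean loss over a batch
#'
#' Arithmetic mean of the per-example loss evaluated at each example's
#' true-class probability.
#'
#' @param prob Matrix of class probabilities, one row per example.
#' @param labels 0-based integer class labels.
#' @param loss `"focal"` or `"cross_entropy"`.
#' @param gamma Focusing parameter for the focal loss.
#' @return Scalar mean loss.
#' @export
batch_loss <- function(prob, labels, loss = c("focal", "cross_entropy"),
                       gamma = 2) {
  loss <- match.arg(loss)
  if (!is.matrix(prob) || nrow(prob) == 0L) stop("empty batch")
  stopifnot(length(labels) == nrow(prob))
  p_true <- prob[cbind(seq_len(nrow(prob)), as.integer(labels) + 1L)]
  per <- if (loss == "focal") focal_loss(p_true, gamma) else cross_entropy(p_true)
  mean(per)
}

#' Forward pass over a batch of beats
#'
#' Runs the LSTM over all timesteps (one sample per step, zero initial
#' state), takes the final hidden vector as the beat representation, and
#' applies FC1 + ReLU, FC2 and softmax.
#'
#' @param params `lstm_params`.
#' @param x Numeric matrix, beats in rows (or a single beat vector).
#' @param peephole Feed `c_(t-1)` to the gates (default TRUE).
#' @param dropout_mask Optional `hidden x n` matrix applied to the final
#'   hidden vectors (inverted-dropout convention: entries are 0 or
#'   `1/(1-p)`). `NULL` disables dropout (evaluation mode).
#' @return List with `prob` (n x C), `logits` (n x C) and `hidden`
#'   (n x H, final hidden vectors).
#' @export
lstm_forward <- function(params, x, peephole = TRUE, dropout_mask = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  out <- .lstm_batch_cpp(params, t(x), integer(0), 0, FALSE, peephole,
                         if (is.null(dropout_mask)) matrix(0, 0, 0) else dropout_mask,
                         FALSE)
  out[c("prob", "logits", "hidden")]
}

#' Loss and exact BPTT gradients for a batch
#'
#' Backpropagation through time over all timesteps, including the
#' `(1-p)^gamma` factor of the focal loss and the cell-state pathways
#' into the gate pre-activations. No gradient clipping is applied.
#'
#' @inheritParams lstm_forward
#' @param labels 0-based integer class labels, one per row of `x`.
#' @param loss `"focal"` or `"cross_entropy"`. @param gamma Focusing
#'   parameter.
#' @return List with `loss` (scalar mean batch loss), `grads` (list
#'   shaped like `params`), and `prob`.
#' @export
lstm_gradients <- function(params, x, labels, loss = c("focal", "cross_entropy"),
                           gamma = 2, peephole = TRUE, dropout_mask = NULL) {
  loss <- match.arg(loss)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  stopifnot(nrow(x) == length(labels))
  out <- .lstm_batch_cpp(params, t(x), as.integer(labels), gamma,
                         loss == "focal", peephole,
                         if (is.null(dropout_mask)) matrix(0, 0, 0) else dropout_mask,
                         TRUE)
  out[c("loss", "grads", "prob")]
}

#' Create an empty Nadam optimizer state
#'
#' @param params `lstm_params` the state should mirror.
#' @return List with zeroed first/second-moment accumulators `m`, `v`
#'   (shaped like `params`) and step counter `t = 0`.
#' @export
nadam_state <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

#' One Nadam update
#'
#' Nesterov-accelerated Adam (Dozat's formulation): bias-corrected first
#' and second moments with a Nesterov-style lookahead on the first
#' moment,
#' `theta <- theta - lr * ((1-beta1) g_hat + beta1 m_hat) / (sqrt(v_hat) + eps)`
#' where `g_hat = g / (1 - beta1^t)`, `m_hat = m_t / (1 - beta1^(t+1))`,
#' `v_hat = v_t / (1 - beta2^t)`.
#'
#' @param params `lstm_params`. @param grads Gradients shaped like
#'   `params`. @param state Optimizer state from [nadam_state()].
#' @param learning_rate Step size (default 0.002). @param beta1,beta2
#'   Moment decay rates (defaults 0.9, 0.999). @param epsilon Numerical
#'   floor (default 1e-8).
#' @return List with updated `params` and `state`.
#' @export
nadam_update <- function(params, grads, state, learning_rate = 0.002,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^(t + 1))
    g_hat <- g / (1 - beta1^t)
    v_hat <- state$v[[nm]] / (1 - beta2^t)
    step <- learning_rate * ((1 - beta1) * g_hat + beta1 * m_hat) /
      (sqrt(v_hat) + epsilon)
    params[[nm]] <- params[[nm]] - step
  }
  state$t <- t
  list(params = params, state = state)
}

.as_xy <- function(x, y = NULL) {
  if (inherits(x, "beat_dataset")) {
    list(x = x$x, y = x$label)
  } else if (is.list(x) && !is.null(x$x)) {
    list(x = as.matrix(x$x), y = as.integer(x$y))
  } else {
    if (is.null(y)) stop("labels 'y' required when 'x' is a matrix")
    list(x = as.matrix(x), y = as.integer(y))
  }
}

#' Fit an LSTM arrhythmia classifier
#'
#' Trains a recurrent classifier on fixed-length ECG beats: an LSTM layer
#' reading one sample per timestep (peephole-style gate inputs by
#' default), a ReLU fully connected layer, a linear output layer and
#' softmax over the eight beat classes. Training minimizes the focal loss
#' (or plain cross-entropy) by exact backpropagation through time with
#' the Nadam optimizer, in shuffled mini-batches; the focal loss's
#' modulating factor `(1-p)^gamma` keeps the abundant, easily classified
#' normal beats from dominating the gradient on heavily imbalanced data.
#'
#' @param x A `beat_dataset`, or numeric matrix with one beat per row
#'   (typically Z-score normalized, 250 samples).
#' @param y 0-based integer class labels (ignored if `x` is a
#'   `beat_dataset`).
#' @param validation Optional held-out data: a `beat_dataset` or
#'   `list(x, y)`; per-epoch validation loss/accuracy are recorded.
#' @param hidden LSTM hidden size (default 64).
#' @param fc Width of the first fully connected layer (default 32).
#' @param loss `"focal"` (default) or `"cross_entropy"`.
#' @param gamma Focal-loss focusing parameter (default 2).
#' @param epochs Training epochs (default 350).
#' @param batch_size Mini-batch size (default 128); the last partial
#'   batch of each epoch is kept.
#' @param dropout Dropout probability on the final hidden vector before
#'   FC1, inverted-dropout convention (default 0).
#' @param learning_rate,beta1,beta2,epsilon Nadam hyperparameters
#'   (defaults 0.004, 0.9, 0.999, 1e-8; the step size is chosen so that
#'   short desk-scale runs converge — smaller rates undertrain, much
#'   larger ones make optimization seed-sensitive). `learning_rate` may
#'   be a vector of per-epoch rates (shorter vectors keep their last
#'   value for the remaining epochs), allowing step schedules such as a
#'   fast initial rate followed by a smaller stable one.
#' @param peephole Feed `c_(t-1)` into the gate pre-activations (default
#'   TRUE); `FALSE` gives the standard LSTM cell.
#' @param restore_best When a validation set is supplied, return the
#'   parameters of the epoch with the highest validation accuracy rather
#'   than the final epoch (default TRUE). Long unclipped BPTT runs can
#'   suffer late gradient spikes that damage an already-good fit;
#'   validation-based selection is the standard guard. Ignored without
#'   validation data.
#' @param n_starts Number of random restarts (default 1). Small-sample
#'   recurrent training occasionally never leaves the majority-class
#'   solution; with `n_starts > 1` the model is trained from up to that
#'   many independent initializations (seeds derived from `seed`) and
#'   the fit with the best validation accuracy (or final training
#'   accuracy, without validation data) is returned — the standard
#'   multi-start remedy.
#' @param start_target Validation (or training) accuracy at which no
#'   further restarts are launched (default 0.95); only relevant when
#'   `n_starts > 1`.
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout; identical seed and configuration give identical fits.
#' @param verbose Print per-epoch progress.
#' @return An object of class `ecg_lstm`: list with `params`
#'   (`lstm_params`), `config`, `history` (data frame with one row per
#'   epoch: `epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`),
#'   and `classes`. Methods: [predict.ecg_lstm()], `print`, `summary`,
#'   `coef`, `plot`.
#' @export
#' @examples
#' ds <- gen_beat_dataset(c(N = 60, LBBB = 60), noise = noise_spec(0, 0, 0.02),
#'                        seed = 1)
#' fit <- ecg_lstm(ds, hidden = 8, fc = 8, epochs = 3, batch_size = 32,
#'                 seed = 1)
#' print(fit)
ecg_lstm <- function(x, y = NULL, validation = NULL, hidden = 64, fc = 32,
                     loss = c("focal", "cross_entropy"), gamma = 2,
                     epochs = 350, batch_size = 128, dropout = 0,
                     learning_rate = 0.004, beta1 = 0.9, beta2 = 0.999,
                     epsilon = 1e-8, peephole = TRUE, restore_best = TRUE,
                     n_starts = 1L, start_target = 0.95,
                     seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  if (gamma < 0) stop("gamma must be >= 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  train <- .as_xy(x, y)
  n <- nrow(train$x)
  if (n == 0L) stop("empty training set")
  val <- if (!is.null(validation)) .as_xy(validation, validation$y) else NULL

  config <- list(hidden = hidden, fc = fc, loss = loss, gamma = gamma,
                 epochs = epochs, batch_size = batch_size, dropout = dropout,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, peephole = peephole,
                 restore_best = restore_best, n_starts = n_starts,
                 seed = seed, n_classes = 8L, beat_length = ncol(train$x))

  best_fit <- NULL
  best_score <- -Inf
  for (start in seq_len(n_starts)) {
    fit <- .train_once(train, val, config, seed + 9973L * (start - 1L),
                       verbose)
    score <- if (!is.null(val)) max(fit$history$val_acc)
             else fit$history$train_acc[[config$epochs]]
    if (score > best_score) {
      best_score <- score
      best_fit <- fit
    }
    if (best_score >= start_target) break
  }
  best_fit
}

.train_once <- function(train, val, config, seed, verbose) {
  n <- nrow(train$x)
  hidden <- config$hidden; fc <- config$fc; loss <- config$loss
  gamma <- config$gamma; epochs <- config$epochs
  batch_size <- config$batch_size; dropout <- config$dropout
  learning_rate <- config$learning_rate
  beta1 <- config$beta1; beta2 <- config$beta2; epsilon <- config$epsilon
  peephole <- config$peephole; restore_best <- config$restore_best

  .with_seed(seed, {
    params <- init_lstm_params(hidden, 1L, fc, 8L,
                               timescale_max = ncol(train$x), seed = NULL)
    opt <- nadam_state(params)
    history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                          train_acc = NA_real_, val_loss = NA_real_,
                          val_acc = NA_real_)
    best <- list(acc = -Inf, params = params, epoch = NA_integer_)
    for (ep in seq_len(epochs)) {
      lr_ep <- learning_rate[[min(ep, length(learning_rate))]]
      idx <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (s in starts) {
        b <- idx[s:min(s + batch_size - 1L, n)]
        mask <- if (dropout > 0) {
          matrix(stats::rbinom(hidden * length(b), 1L, 1 - dropout),
                 hidden, length(b)) / (1 - dropout)
        } else NULL
        res <- lstm_gradients(params, train$x[b, , drop = FALSE],
                              train$y[b], loss = loss, gamma = gamma,
                              peephole = peephole, dropout_mask = mask)
        if (!is.finite(res$loss)) {
          stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
        }
        upd <- nadam_update(params, res$grads, opt, lr_ep,
                            beta1, beta2, epsilon)
        params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + res$loss * length(b)
        pred <- max.col(res$prob, ties.method = "first") - 1L
        ep_correct <- ep_correct + sum(pred == train$y[b])
      }
      history$train_loss[ep] <- ep_loss / n
      history$train_acc[ep] <- ep_correct / n
      if (!is.null(val) && nrow(val$x)) {
        vp <- .predict_prob(params, val$x, peephole)
        history$val_loss[ep] <- batch_loss(vp, val$y, loss, gamma)
        history$val_acc[ep] <-
          mean(max.col(vp, ties.method = "first") - 1L == val$y)
        if (restore_best && history$val_acc[ep] > best$acc) {
          best <- list(acc = history$val_acc[ep], params = params, epoch = ep)
        }
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.4f%s", ep,
                        history$train_loss[ep], history$train_acc[ep],
                        if (!is.null(val)) sprintf("  val_loss %.4f  val_acc %.4f",
                                                   history$val_loss[ep],
                                                   history$val_acc[ep]) else ""))
      }
    }
    restored <- NA_integer_
    if (restore_best && !is.null(val) && is.finite(best$acc)) {
      params <- best$params
      restored <- best$epoch
    }
    structure(
      list(params = params, config = config, history = history,
           classes = beat_classes(), n_train = n, best_epoch = restored),
      class = "ecg_lstm"
    )
  })
}

# chunked evaluation-mode probability computation
.predict_prob <- function(params, x, peephole, chunk = 512L) {
  n <- nrow(x)
  C <- length(params$b_fc2)
  prob <- matrix(0, n, C)
  for (s in seq(1L, n, by = chunk)) {
    i <- s:min(s + chunk - 1L, n)
    prob[i, ] <- lstm_forward(params, x[i, , drop = FALSE],
                              peephole = peephole)$prob
  }
  prob
}

#' Predict beat classes
#'
#' Evaluation-mode prediction (dropout disabled). Class labels are the
#' argmax of the class probabilities; ties break toward the lowest class
#' index. Predictions are independent of how the input is partitioned
#' into batches.
#'
#' @param object Fitted `ecg_lstm` model.
#' @param newdata A `beat_dataset` or matrix of beats (rows).
#' @param type `"class"` (0-based integer labels), `"prob"` (n x 8
#'   probability matrix) or `"both"` (list with `label` and `prob`).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.ecg_lstm <- function(object, newdata,
                             type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "beat_dataset")) newdata$x else as.matrix(newdata)
  prob <- .predict_prob(object$params, x, object$config$peephole)
  colnames(prob) <- object$classes
  label <- max.col(prob, ties.method = "first") - 1L
  switch(type, class = label, prob = prob, both = list(label = label, prob = prob))
}

#' @export
coef.ecg_lstm <- function(object, ...) object$params

#' @export
print.ecg_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("LSTM beat classifier (%s%s, peephole gates: %s)\n",
              cfg$loss, if (cfg$loss == "focal") sprintf(", gamma = %g", cfg$gamma) else "",
              if (cfg$peephole) "yes" else "no"))
  cat(sprintf("  hidden %d, fc %d, %d classes, beat length %d\n",
              cfg$hidden, cfg$fc, cfg$n_classes, cfg$beat_length))
  cat(sprintf("  trained %d epochs on %d beats (batch %d, dropout %g, Nadam lr %g)\n",
              cfg$epochs, x$n_train, cfg$batch_size, cfg$dropout,
              cfg$learning_rate))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f, train accuracy %.4f\n",
              last$train_loss, last$train_acc))
  if (!is.na(last$val_acc)) {
    cat(sprintf("  final val loss %.4f, val accuracy %.4f\n",
                last$val_loss, last$val_acc))
  }
  if (!is.null(x$best_epoch) && !is.na(x$best_epoch)) {
    cat(sprintf("  parameters restored from epoch %d (best validation accuracy %.4f)\n",
                x$best_epoch, x$history$val_acc[x$best_epoch]))
  }
  invisible(x)
}

#' @export
summary.ecg_lstm <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$params, length, 0L))
  cat(sprintf("  %d trainable parameters\n", n_par))
  invisible(object)
}

#' Plot training history
#'
#' Two panels: per-epoch training (and validation, if recorded) loss and
#' accuracy.
#'
#' @param x Fitted `ecg_lstm` model. @param ... Passed to
#'   [graphics::matplot()].
#' @export
plot.ecg_lstm <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  has_val <- !all(is.na(h$val_loss))
  graphics::matplot(h$epoch, cbind(h$train_loss, if (has_val) h$val_loss),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", main = "Loss", ...)
  graphics::matplot(h$epoch, cbind(h$train_acc, if (has_val) h$val_acc),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  if (has_val) {
    graphics::legend("bottomright", c("train", "validation"),
                     lty = 1, col = c("black", "red"), bty = "n")
  }
  invisible(x)
}

#' Save a fitted model checkpoint
#'
#' Writes a single JSON file containing the configuration, training
#' history and every parameter array at full double precision, so that
#' reloading and predicting is bit-reproducible.
#'
#' @param model Fitted `ecg_lstm`. @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_checkpoint()]
#' @export
write_checkpoint <- function(model, path) {
  # array entries are stored as 17-significant-digit strings: that is the
  # shortest representation guaranteed to round-trip IEEE doubles exactly
  arrays <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p),
         data = sprintf("%.17g", as.vector(p)))
  })
  payload <- list(
    format = "ecglstm-checkpoint-1",
    config = model$config,
    classes = model$classes,
    n_train = model$n_train,
    best_epoch = model$best_epoch,
    history = model$history,
    params = arrays
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [write_checkpoint()].
#' @return The restored `ecg_lstm` model.
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, "ecglstm-checkpoint-1")) {
    stop("not an ecglstm checkpoint: ", path)
  }
  params <- lapply(payload$params, function(a) {
    v <- as.numeric(a$data)
    if (length(a$dim) == 2L) matrix(v, a$dim[[1]], a$dim[[2]]) else v
  })
  H <- length(params$b_f)
  attr(params, "dims") <- list(H = H, D = ncol(params$W_f) - 2L * H,
                               H1 = length(params$b_fc1),
                               C = length(params$b_fc2))
  class(params) <- "lstm_params"
  structure(
    list(params = params, config = payload$config,
         history = as.data.frame(payload$history),
         classes = payload$classes, n_train = payload$n_train,
         best_epoch = payload$best_epoch %||% NA_integer_),
    class = "ecg_lstm"
  )
}
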