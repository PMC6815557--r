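tiny_params <- function(H = 4, fc = 3, C = 2, seed = 11) {
  init_lstm_params(hidden = H, input_size = 1, fc = fc, n_classes = C,
                   seed = seed)
}

zero_params <- function(H = 4, fc = 3, C = 2) {
  p <- tiny_params(H, fc, C)
  for (nm in names(p)) p[[nm]][] <- 0
  p
}

test_that("initialization has documented shapes, biases and determinism", {
  p <- init_lstm_params(hidden = 64, input_size = 1, fc = 32, n_classes = 8,
                        seed = 5)
  expect_equal(dim(p$W_f), c(64L, 129L))      # H x (2H + D)
  expect_equal(dim(p$W_fc2), c(8L, 32L))
  # chrono biases: b_i = -b_f, forget biases are log timescales in [1, 250]
  expect_equal(p$b_i, -p$b_f)
  expect_true(all(p$b_f >= 0 & p$b_f <= log(250)))
  expect_equal(p$b_c, rep(0, 64))
  expect_equal(p$b_o, rep(0, 64))
  expect_identical(p, init_lstm_params(64, 1, 32, 8, seed = 5))
  expect_false(identical(p$W_f, init_lstm_params(64, 1, 32, 8, seed = 6)$W_f))
  expect_error(init_lstm_params(hidden = 0), ">= 1")
})

test_that("the cell step follows the gate equations at hand-checkable points", {
  p <- zero_params()
  s <- lstm_step(p, 0.7)
  expect_equal(s$f, rep(0.5, 4))              # sigmoid(0)
  expect_equal(s$i, rep(0.5, 4))
  expect_equal(s$o, rep(0.5, 4))
  expect_equal(s$c_in, rep(0, 4))             # tanh(0)
  expect_equal(s$c, rep(0, 4))
  expect_equal(s$a, rep(0, 4))
  # zero weights, prev c = v: c_t = 0.5 v, a_t = 0.5 tanh(0.5 v)
  v <- c(0.3, -0.2, 1, 0.05)
  s2 <- lstm_step(p, 0, state = list(a = rep(0, 4), c = v), peephole = FALSE)
  expect_equal(s2$c, 0.5 * v)
  expect_equal(s2$a, 0.5 * tanh(0.5 * v))
  # gate codomains on arbitrary input
  pr <- tiny_params()
  st <- lstm_step(pr, 2.5, state = list(a = runif(4, -0.9, 0.9),
                                        c = rnorm(4)))
  expect_true(all(st$f > 0 & st$f < 1))
  expect_true(all(st$i > 0 & st$i < 1))
  expect_true(all(st$o > 0 & st$o < 1))
  expect_true(all(abs(st$c_in) < 1))
  expect_true(all(abs(st$a) < 1))
  expect_error(lstm_step(pr, c(1, 2)), "length")
})

test_that("iterating the reference step reproduces the batched forward pass", {
  withr::with_seed(31, {
    p <- init_lstm_params(5, 1, 4, 3, seed = 7)
    beat <- rnorm(40)
    for (pe in c(TRUE, FALSE)) {
      st <- NULL
      for (t in seq_along(beat)) st <- lstm_step(p, beat[[t]], st, peephole = pe)
      fw <- lstm_forward(p, matrix(beat, 1), peephole = pe)
      expect_equal(drop(fw$hidden), st$a, tolerance = 1e-12)
    }
  })
})

test_that("softmax is a stable probability map", {
  expect_equal(softmax(rep(0, 8)), rep(1 / 8, 8))
  withr::with_seed(32, {
    z <- rnorm(8, sd = 3)
    expect_equal(sum(softmax(z)), 1, tolerance = 1e-12)
    expect_true(all(softmax(z) > 0))
    expect_equal(softmax(z + 17.3), softmax(z), tolerance = 1e-12)
  })
  big <- softmax(c(1000, 0, 0, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  # matrix form is row-wise
  m <- softmax(rbind(c(0, 0), c(100, 100)))
  expect_equal(unname(m), matrix(0.5, 2, 2))
})

test_that("loss functions satisfy their closed forms and identities", {
  expect_equal(cross_entropy(1), 0)
  expect_equal(cross_entropy(exp(-1)), 1)
  expect_equal(cross_entropy(0.5), -log(0.5))
  expect_equal(focal_loss(1, 3.7), 0)
  expect_equal(focal_loss(0.5, 2), -0.25 * log(0.5))
  expect_lt(focal_loss(0.5, 2), cross_entropy(0.5))
  expect_error(focal_loss(0.5, -1), "gamma")
  # gamma = 0 reduces focal loss to cross-entropy on a dense grid
  grid <- seq(1e-6, 1, length.out = 10000)
  expect_lt(max(abs(focal_loss(grid, 0) - cross_entropy(grid))), 1e-12)
  # focal <= CE everywhere, strictly decreasing in p and in gamma
  expect_true(all(focal_loss(grid, 2) <= cross_entropy(grid)))
  inner <- seq(0.05, 0.95, length.out = 200)
  expect_true(all(diff(focal_loss(inner, 2)) < 0))
  expect_true(all(focal_loss(inner, 3) < focal_loss(inner, 2)))
  # clamping keeps the loss finite at p = 0
  expect_true(is.finite(cross_entropy(0)))
})

test_that("batch loss is the mean of per-example losses", {
  prob <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.5, 0.5))
  y <- c(0L, 1L, 1L)
  manual <- mean(focal_loss(c(0.7, 0.8, 0.5), 2))
  expect_equal(batch_loss(prob, y, "focal", 2), manual)
  expect_equal(batch_loss(prob[1, , drop = FALSE], 0L, "cross_entropy"),
               cross_entropy(0.7))
  expect_equal(batch_loss(rbind(c(1, 0), c(0, 1)), c(0L, 1L), "focal", 2), 0)
  expect_error(batch_loss(matrix(0, 0, 2), integer(0)), "empty")
})

test_that("forward collapses to softmax(b_fc2) when the hidden path is zero", {
  p <- zero_params(H = 4, fc = 3, C = 4)
  v <- c(0.2, -1, 0.5, 0)
  p$b_fc2 <- v
  withr::with_seed(33, {
    out <- lstm_forward(p, matrix(rnorm(2 * 30), 2))
    expect_equal(unname(out$prob[1, ]), softmax(v), tolerance = 1e-12)
    expect_equal(unname(out$prob[2, ]), softmax(v), tolerance = 1e-12)
  })
})

test_that("BPTT gradients match central finite differences on tiny nets", {
  withr::with_seed(34, {
    p <- tiny_params(H = 3, fc = 3, C = 2, seed = 41)
    x <- matrix(rnorm(2 * 5), 2, 5)       # batch 2, T = 5
    y <- c(0L, 1L)
    for (case in list(list(loss = "focal", gamma = 2, pe = TRUE),
                      list(loss = "focal", gamma = 0.5, pe = FALSE),
                      list(loss = "cross_entropy", gamma = 0, pe = TRUE))) {
      an <- lstm_gradients(p, x, y, loss = case$loss, gamma = case$gamma,
                           peephole = case$pe)$grads
      fd <- fd_gradients(p, x, y, case$loss, case$gamma, case$pe)
      expect_lt(max_rel_err(an, fd), 1e-4)
    }
  })
})

test_that("gamma = 0 gradients equal cross-entropy gradients exactly", {
  withr::with_seed(35, {
    p <- tiny_params(seed = 43)
    x <- matrix(rnorm(3 * 8), 3, 8)
    y <- c(0L, 1L, 0L)
    gf <- lstm_gradients(p, x, y, loss = "focal", gamma = 0)$grads
    gc <- lstm_gradients(p, x, y, loss = "cross_entropy")$grads
    expect_lt(max(unlist(Map(function(a, b) max(abs(a - b)), gf, gc))), 1e-10)
  })
})

test_that("Nadam follows the hand-derived update at t = 1 and is inert at zero", {
  p <- tiny_params(seed = 45)
  zero_g <- lapply(p, function(m) m * 0)
  st <- nadam_state(p)
  upd <- nadam_update(p, zero_g, st)
  expect_identical(upd$params, p)           # zero gradient: no movement
  expect_equal(upd$state$t, 1L)
  # constant gradient from zero moments: direction -sign(g), magnitude
  # lr * (1 + 2 b1) / (1 + b1) elementwise (hand evaluation at t = 1)
  g <- lapply(p, function(m) { m[] <- 0.37; m })
  lr <- 0.002; b1 <- 0.9
  upd2 <- nadam_update(p, g, nadam_state(p), learning_rate = lr, beta1 = b1)
  delta <- upd2$params$W_f - p$W_f
  expect_true(all(delta < 0))               # -sign(g)
  expect_equal(max(abs(delta)), lr * (1 + 2 * b1) / (1 + b1), tolerance = 1e-6)
  # determinism
  upd3 <- nadam_update(p, g, nadam_state(p), learning_rate = lr, beta1 = b1)
  expect_identical(upd2, upd3)
})

test_that("training learns a trivially separable 2-class problem", {
  x <- rbind(matrix(0.5, 20, 50), matrix(-0.5, 20, 50))
  y <- rep(c(0L, 1L), each = 20)
  fit <- ecg_lstm(x, y, hidden = 8, fc = 8, epochs = 5, batch_size = 8,
                  seed = 2, loss = "focal", gamma = 2)
  expect_equal(nrow(fit$history), 5L)       # history length = epochs
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_equal(mean(predict(fit, x) == y), 1)
  # determinism: same config and seed reproduce the parameters exactly
  fit2 <- ecg_lstm(x, y, hidden = 8, fc = 8, epochs = 5, batch_size = 8,
                   seed = 2, loss = "focal", gamma = 2)
  expect_identical(fit$params, fit2$params)
})

test_that("training validates inputs and records validation metrics", {
  x <- rbind(matrix(0.5, 10, 30), matrix(-0.5, 10, 30))
  y <- rep(c(0L, 1L), each = 10)
  expect_error(ecg_lstm(x, y, gamma = -1, epochs = 1), "gamma")
  expect_error(ecg_lstm(x, y, dropout = 1, epochs = 1), "dropout")
  expect_error(ecg_lstm(matrix(0, 0, 30), integer(0), epochs = 1), "empty")
  fit <- ecg_lstm(x, y, validation = list(x = x, y = y), hidden = 4, fc = 4,
                  epochs = 2, batch_size = 8, seed = 3)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(is.finite(fit$history$val_acc)))
})

test_that("dropout masks are applied only in training and keep gradients exact", {
  withr::with_seed(36, {
    p <- tiny_params(H = 3, fc = 3, C = 2, seed = 47)
    x <- matrix(rnorm(2 * 5), 2, 5)
    y <- c(0L, 1L)
    mask <- matrix(rbinom(3 * 2, 1, 0.5), 3, 2) / 0.5
    an <- lstm_gradients(p, x, y, loss = "focal", gamma = 2,
                         dropout_mask = mask)$grads
    lossfun <- function(pp) lstm_gradients(pp, x, y, loss = "focal",
                                           gamma = 2, dropout_mask = mask)$loss
    eps <- 1e-6
    pp <- p; pp$W_fc1[1, 1] <- pp$W_fc1[1, 1] + eps; lp <- lossfun(pp)
    pp$W_fc1[1, 1] <- pp$W_fc1[1, 1] - 2 * eps; lm <- lossfun(pp)
    expect_equal(an$W_fc1[1, 1], (lp - lm) / (2 * eps), tolerance = 1e-5)
  })
})

test_that("prediction is deterministic, batch-invariant and tie-breaks low", {
  withr::with_seed(37, {
    x <- matrix(rnorm(700 * 40), 700)
    p <- init_lstm_params(4, 1, 3, 8, seed = 51)
    model <- structure(list(params = p,
                            config = list(peephole = TRUE),
                            classes = beat_classes()),
                       class = "ecg_lstm")
    both <- predict(model, x, type = "both")
    expect_identical(both$label, predict(model, x))           # repeatable
    # batch partition invariance (chunking at 512 exercised by n = 700)
    one_by_one <- vapply(seq_len(50), function(i) {
      predict(model, x[i, , drop = FALSE])
    }, integer(1))
    expect_identical(both$label[1:50], one_by_one)
    expect_identical(both$label, max.col(both$prob, ties.method = "first") - 1L)
    # engineered uniform probabilities choose class 0
    pz <- zero_params(H = 4, fc = 3, C = 8)
    mz <- structure(list(params = pz, config = list(peephole = TRUE),
                         classes = beat_classes()), class = "ecg_lstm")
    expect_equal(unique(predict(mz, x[1:5, ])), 0L)
  })
})

test_that("checkpoints round-trip bit-reproducibly", {
  x <- rbind(matrix(0.4, 8, 30), matrix(-0.4, 8, 30))
  y <- rep(c(0L, 1L), each = 8)
  fit <- ecg_lstm(x, y, hidden = 4, fc = 4, epochs = 2, batch_size = 8, seed = 9)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.json")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_identical(back$params, fit$params)
  expect_identical(predict(back, x, type = "prob"),
                   predict(fit, x, type = "prob"))
  expect_equal(back$history$train_loss, fit$history$train_loss)
  expect_error(read_checkpoint(file.path(dir, "nope.json")), "nope.json")
})
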