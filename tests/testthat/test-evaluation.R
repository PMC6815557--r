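test_that("confusion matrix counts by hand examples", {
  m <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), n_classes = 2)
  expect_equal(unname(unclass(m)), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(sum(confusion_matrix(integer(0), integer(0), 4)), 0L)
  y <- c(0, 3, 3, 7)
  d <- confusion_matrix(y, y, 8)
  expect_equal(diag(d), setNames(c(1L, 0L, 0L, 2L, 0L, 0L, 0L, 1L), beat_classes()))
  expect_equal(sum(d) - sum(diag(d)), 0L)
  expect_error(confusion_matrix(0, 8, 8), "lie in")
})

test_that("one-vs-rest counts match hand counting and partition the total", {
  m <- matrix(c(1, 1, 0, 1), 2, byrow = TRUE)
  cc <- one_vs_rest_counts(m, 0)
  expect_equal(cc, c(TP = 1, FP = 0, TN = 1, FN = 1))
  for (cl in 0:1) expect_equal(sum(one_vs_rest_counts(m, cl)), sum(m))
  withr::with_seed(11, {
    r <- matrix(rpois(64, 5), 8)
    for (cl in 0:7) {
      expect_equal(sum(one_vs_rest_counts(r, cl)), sum(r))
      oc <- oracle_class_metrics(r, cl)
      expect_equal(one_vs_rest_counts(r, cl), oc[c("TP", "FP", "TN", "FN")])
    }
  })
})

test_that("classification report matches the enumeration oracle", {
  m <- matrix(c(8, 2, 1, 4), 2, byrow = TRUE)
  rep <- classification_report(m)
  # per-class metrics against item-level enumeration
  for (cl in 0:1) {
    oc <- oracle_class_metrics(m, cl)
    expect_equal(rep$per_class$RE[cl + 1], unname(oc["RE"]))
    expect_equal(rep$per_class$PR[cl + 1], unname(oc["PR"]))
    expect_equal(rep$per_class$SP[cl + 1], unname(oc["SP"]))
    expect_equal(rep$per_class$F1[cl + 1], unname(oc["F1"]))
  }
  # aggregates: support-weighted means of the oracle values
  o0 <- oracle_class_metrics(m, 0); o1 <- oracle_class_metrics(m, 1)
  w <- rowSums(m) / sum(m)
  expect_equal(rep$weighted[["RE"]], w[1] * o0[["RE"]] + w[2] * o1[["RE"]])
  expect_equal(rep$weighted[["F1"]], w[1] * o0[["F1"]] + w[2] * o1[["F1"]])
  expect_equal(rep$accuracy, (8 + 4) / 15)
  # perfect predictions give all-ones metrics
  perfect <- classification_report(diag(c(5L, 3L, 2L)))
  expect_equal(unname(perfect$weighted), rep(1, 4))
  expect_equal(perfect$accuracy, 1)
  expect_error(classification_report(matrix(0, 2, 2)), "empty")
})

test_that("support-weighted recall equals overall accuracy identically", {
  withr::with_seed(12, {
    for (k in 1:200) {
      m <- matrix(rpois(64, lambda = sample(c(0.5, 3, 20), 1)), 8)
      if (sum(m) == 0) next
      rep <- suppressWarnings(classification_report(m))
      expect_lt(abs(rep$weighted[["RE"]] - rep$accuracy), 1e-12)
    }
  })
})

test_that("reports are equivariant under class permutation", {
  withr::with_seed(13, {
    m <- matrix(rpois(16, 6), 4)
    dimnames(m) <- NULL
    perm <- c(3L, 1L, 4L, 2L)
    mp <- m[perm, perm]
    r1 <- suppressWarnings(classification_report(m))
    r2 <- suppressWarnings(classification_report(mp))
    expect_equal(r2$per_class$RE, r1$per_class$RE[perm])
    expect_equal(r2$per_class$F1, r1$per_class$F1[perm])
    expect_equal(r2$weighted, r1$weighted)
    expect_equal(r2$accuracy, r1$accuracy)
  })
})

test_that("degenerate 0/0 metric cells are zero-filled with a warning", {
  m <- matrix(0L, 3, 3); m[1, 1] <- 5L   # classes 1 and 2 absent
  expect_warning(rep <- classification_report(m), "0/0")
  expect_true(rep$degenerate)
  expect_equal(rep$per_class$RE[2:3], c(0, 0))
  expect_equal(rep$accuracy, 1)
})

test_that("PR curves match exhaustive threshold enumeration", {
  # perfectly separating scores
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.1)
  pc <- pr_curve(y, s)
  expect_equal(pc$area, 1)
  # all-equal scores: one point, area = positive fraction
  flat <- pr_curve(c(1, 0, 0, 1, 0), rep(0.5, 5))
  expect_equal(length(flat$recall), 1L)
  expect_equal(flat$area, 2 / 5)
  # 6-item hand example with ties, against the brute-force oracle
  y6 <- c(1, 0, 1, 1, 0, 0)
  s6 <- c(0.9, 0.9, 0.7, 0.3, 0.3, 0.1)
  pc6 <- pr_curve(y6, s6)
  expect_equal(pc6$area, oracle_average_precision(y6, s6))
  expect_true(all(diff(pc6$recall) >= 0))
  # random cases
  withr::with_seed(14, {
    for (k in 1:25) {
      yk <- rbinom(20, 1, 0.3)
      if (sum(yk) == 0) yk[1] <- 1
      sk <- round(runif(20), 2)
      expect_equal(pr_curve(yk, sk)$area, oracle_average_precision(yk, sk))
    }
  })
  expect_error(pr_curve(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("average precision is invariant to monotone score transforms", {
  withr::with_seed(15, {
    y <- rbinom(30, 1, 0.4); y[1] <- 1
    s <- runif(30)
    a0 <- pr_curve(y, s)$area
    expect_equal(pr_curve(y, 10 * s - 3)$area, a0)
    expect_equal(pr_curve(y, exp(s))$area, a0)
    expect_equal(pr_curve(y, rank(s, ties.method = "min"))$area, a0)
  })
})

test_that("report CSV has the five-metric layout", {
  m <- diag(c(5L, 3L))
  rep <- classification_report(m)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.csv")
  write_report_csv(rep, path)
  got <- read.csv(path)
  expect_equal(names(got), c("class", "support", "ACC", "RE", "SP", "PR", "F1"))
  expect_equal(got$class[nrow(got) - 1], "weighted")
  expect_equal(got$ACC[nrow(got)], 100)
})
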