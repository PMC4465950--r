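fixture_data <- function(seed = 601, n = 100, p = 4) {
  generate_ph_data(sim_spec(n = n, p = p, beta = c(1.2, rep(0, p - 1)),
                            censoring = 0.25, seed = seed))
}

test_that("fits are reproducible and member-wise invariant to ensemble size", {
  d <- fixture_data()
  f1 <- rotsf(d, trees = 8, seed = 42)
  f2 <- rotsf(d, trees = 8, seed = 42)
  expect_equal(predict(f1, d$x), predict(f2, d$x))
  expect_identical(f1$inbag, f2$inbag)

  # the i-th member does not depend on how many trees follow it
  f3 <- rotsf(d, trees = 3, seed = 42)
  expect_equal(f3$members[[2]]$partition, f1$members[[2]]$partition)
  expect_equal(f3$members[[2]]$loadings, f1$members[[2]]$loadings)
  expect_identical(f3$inbag[1:3, ], f1$inbag[1:3, ])
})

test_that("fit validates its configuration", {
  d <- fixture_data()
  expect_error(rotsf(d, trees = 0), "at least one tree")
  expect_error(rotsf(d, trees = 2, M = 9), "1 <= M <= p")
})

test_that("outer bootstrap bookkeeping matches bootstrap theory", {
  d <- fixture_data(n = 60)
  f <- rotsf(d, trees = 50, seed = 7)
  expect_equal(unname(rowSums(f$inbag)), rep(60, 50))  # n draws per member
  oob_frac <- rowMeans(f$inbag == 0)
  # exclusion probability (1 - 1/n)^n ~ e^-1; 50-member average is tight
  expect_equal(mean(oob_frac), (1 - 1 / 60)^60, tolerance = 0.05)
  # with 50 members every subject is OOB somewhere with high probability
  expect_true(all(colSums(f$inbag == 0) > 0))
})

test_that("a single-member ensemble predicts exactly its tree", {
  d <- fixture_data()
  f <- rotsf(d, trees = 1, seed = 9)
  m <- f$members[[1]]
  pred <- predict_tree_chf(m$tree, rotate(d$x, m$rotation))
  manual <- rotsf:::step_interp(pred$grid, pred$chf, f$grid)
  ens <- predict(f, d$x, type = "chf")
  expect_equal(ens$chf, manual)
  expect_equal(predict(f, d$x), rowSums(manual))
})

test_that("ensemble CHFs are monotone and averaging preserves order", {
  d <- fixture_data()
  f <- rotsf(d, trees = 15, seed = 10)
  ens <- predict(f, d$x, type = "chf")
  expect_true(all(ens$chf >= 0))
  expect_true(all(apply(ens$chf, 1, function(h) all(diff(h) >= -1e-12))))
  # a pointwise-larger CHF must map to a strictly larger risk score
  i <- which.max(ens$chf[, ncol(ens$chf)])
  j <- which.min(ens$chf[, ncol(ens$chf)])
  if (all(ens$chf[i, ] >= ens$chf[j, ]) && any(ens$chf[i, ] > ens$chf[j, ])) {
    r <- predict(f, d$x)
    expect_gt(r[i], r[j])
  }
})

test_that("member order does not affect predictions", {
  d <- fixture_data()
  f <- rotsf(d, trees = 10, seed = 11)
  g <- f
  perm <- rev(seq_along(g$members))
  g$members <- g$members[perm]
  g$inbag <- g$inbag[perm, ]
  expect_equal(predict(g, d$x), predict(f, d$x))
})

test_that("double and single bagging share outer bags but differ in rotation", {
  d <- fixture_data()
  fd <- rotsf(d, trees = 6, seed = 12, double_bagging = TRUE)
  fs <- rotsf(d, trees = 6, seed = 12, double_bagging = FALSE)
  expect_identical(fd$inbag, fs$inbag)  # outer bootstrap drawn first
  expect_identical(fd$members[[1]]$partition, fs$members[[1]]$partition)
  same <- vapply(seq_len(6), function(i) {
    isTRUE(all.equal(fd$members[[i]]$loadings, fs$members[[i]]$loadings))
  }, logical(1))
  expect_false(all(same))  # inner resample must change the loadings
})

test_that("OOB risks average exactly the excluding members", {
  d <- fixture_data(n = 50)
  f <- rotsf(d, trees = 12, seed = 13)
  r <- oob_risk(f, d)
  # brute-force member filtering per subject
  for (q in c(1, 7, 25, 50)) {
    excl <- which(f$inbag[, q] == 0)
    if (!length(excl)) {
      expect_true(is.na(r[q]))
    } else {
      risks <- vapply(excl, function(i) {
        rotsf:::member_risk(f, i, d$x[q, , drop = FALSE])
      }, numeric(1))
      expect_equal(r[q], mean(risks), tolerance = 1e-12)
    }
  }
  # L = 1: OOB risks defined exactly on the excluded set
  f1 <- rotsf(d, trees = 1, seed = 14)
  r1 <- oob_risk(f1, d)
  expect_identical(is.na(r1), f1$inbag[1, ] > 0)
})

test_that("risk ordering recovers the true linear predictor on signal data", {
  d <- generate_ph_data(sim_spec(n = 200, p = 3, beta = c(1.5, 0, 0),
                                 censoring = 0.2, seed = 615))
  f <- rotsf(d, trees = 40, seed = 615)
  eta <- d$x %*% c(1.5, 0, 0)
  expect_gt(cor(predict(f, d$x), eta, method = "spearman"), 0.4)
})

test_that("serialization round-trips predictions bit for bit", {
  d <- fixture_data(n = 40)
  f <- rotsf(d, trees = 5, seed = 16)
  path <- withr::local_tempfile(fileext = ".json")
  write_rotsf(f, path)
  g <- read_rotsf(path)
  expect_equal(predict(g, d$x), predict(f, d$x))
  expect_equal(predict(g, d$x, type = "chf"), predict(f, d$x, type = "chf"))
  expect_equal(oob_risk(g, d), oob_risk(f, d))
  expect_identical(g$inbag, f$inbag)
  expect_error(read_rotsf(withr::local_tempfile(lines = "{}")),
               "container")
})

test_that("prediction validates covariate dimensionality", {
  d <- fixture_data()
  f <- rotsf(d, trees = 2, seed = 17)
  expect_error(predict(f, d$x[, 1:2]), "expects 4 covariates")
})
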