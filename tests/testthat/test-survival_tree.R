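test_that("log-rank statistic matches hand-computable cases", {
  # identical time/event vectors in both groups: perfect balance
  time <- c(1, 2, 3, 1, 2, 3)
  status <- rep(1, 6)
  expect_equal(logrank_split_stat(time, status, c(1, 1, 1, 0, 0, 0)), 0)

  # complete separation: group A events at {1,2}, B at {3,4}
  s <- logrank_split_stat(c(1, 2, 3, 4), rep(1, 4), c(1, 1, 0, 0))
  expect_equal(s, oracle_logrank(c(1, 2, 3, 4), rep(1, 4), c(1, 1, 0, 0)),
               tolerance = 1e-12)
  expect_gt(s, 0)  # group 1 dies earlier than expected under the null
})

test_that("log-rank statistic is antisymmetric and agrees with the oracle", {
  set.seed(401)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    d <- random_surv_fixture(n)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    s <- logrank_split_stat(d$time, d$status, g)
    o <- oracle_logrank(d$time, d$status, g)
    if (is.na(o)) {
      expect_true(is.na(s))
    } else {
      expect_equal(s, o, tolerance = 1e-10)
      expect_equal(logrank_split_stat(d$time, d$status, 1 - g), -s,
                   tolerance = 1e-10)
    }
  }
})

test_that("zero-variance configurations return the sentinel, not an error", {
  # the only event happens when a single subject remains at risk
  expect_true(is.na(logrank_split_stat(c(1, 2, 3, 4), c(0, 0, 0, 1),
                                       c(0, 0, 0, 1))))
  s <- logrank_split_stat(c(5, 5, 5, 5), c(1, 1, 0, 0), c(1, 0, 1, 0))
  o <- oracle_logrank(c(5, 5, 5, 5), c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(is.na(s), is.na(o))
  if (!is.na(o)) expect_equal(s, o, tolerance = 1e-10)
})

test_that("Nelson-Aalen CHF reproduces hand risk tables", {
  # single subject with an event: jump of 1/1
  expect_equal(nelson_aalen_chf(5, 1, grid = c(4, 5, 6)), c(0, 1, 1))
  # three events, no censoring: 1/3, 1/3+1/2, +1/1
  expect_equal(nelson_aalen_chf(c(1, 2, 3), c(1, 1, 1), grid = 1:3),
               c(1 / 3, 1 / 3 + 1 / 2, 11 / 6))
  # all censored: identically zero
  expect_equal(nelson_aalen_chf(c(1, 2, 3), c(0, 0, 0), grid = 1:3),
               c(0, 0, 0))
  # censoring ties: censored subject at an event time stays at risk
  set.seed(402)
  for (rep in 1:20) {
    d <- random_surv_fixture(sample(3:12, 1))
    grid <- sort(unique(d$time[d$status == 1]))
    expect_equal(nelson_aalen_chf(d$time, d$status, grid),
                 oracle_nelson_aalen(d$time, d$status, grid),
                 tolerance = 1e-12)
  }
})

test_that("best_split finds a perfect separator and matches brute force", {
  # covariate 2 perfectly separates early deaths from late deaths
  x <- cbind(rep(1, 8), c(0, 0, 0, 0, 1, 1, 1, 1))
  d <- surv_data(c(1, 2, 3, 4, 10, 11, 12, 13), rep(1, 8), x)
  sp <- best_split(d, min_node_size = 2)
  expect_equal(sp$var, 2)
  expect_equal(sp$thresh, 0.5)

  # constant covariates: no candidate thresholds
  dc <- surv_data(1:6, rep(1, 6), matrix(1, 6, 2))
  expect_null(best_split(dc, min_node_size = 2))

  set.seed(403)
  for (rep in 1:25) {
    d <- random_surv_fixture(10, p = 3)
    got <- best_split(d, min_node_size = 2)
    want <- oracle_best_split(d$time, d$status, d$x, 2)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$var, want$var)
      expect_equal(got$thresh, want$thresh, tolerance = 1e-12)
      expect_equal(got$stat, want$stat, tolerance = 1e-10)
    }
  }
})

test_that("grow_tree stops at a single leaf that carries the pooled estimate", {
  set.seed(404)
  d <- random_surv_fixture(30, p = 2)
  tr <- grow_tree(d, min_node_size = 30)
  expect_equal(length(tr$var), 1L)
  expect_equal(tr$chf[[1]],
               nelson_aalen_chf(d$time, d$status, tr$grid))
})

test_that("a single driving binary covariate yields a depth-1 tree on it", {
  set.seed(405)
  d <- generate_ph_data(sim_spec(n = 120, p = 3, beta = c(2, 0, 0),
                                 binary = 1L, seed = 405))
  tr <- grow_tree(d, min_node_size = 50)
  expect_equal(tr$var[1], oracle_best_split(d$time, d$status, d$x, 50)$var - 1)
  expect_equal(tr$var[1], 0L)  # 0-based: splits on covariate 1
  expect_equal(sum(tr$var >= 0), 1L)  # one internal node
})

test_that("grown trees partition the training data above the size floor", {
  set.seed(406)
  for (rep in 1:5) {
    d <- generate_ph_data(sim_spec(n = 80, p = 3,
                                   beta = c(1, -1, 0), censoring = 0.2,
                                   seed = 406 + rep))
    tr <- grow_tree(d, min_node_size = 5)
    leaves <- which(tr$var < 0)
    # every subject lands in exactly one leaf
    expect_true(all((tr$leaf_of + 1L) %in% leaves))
    counts <- table(factor(tr$leaf_of, levels = leaves - 1L))
    expect_equal(as.integer(counts), tr$size[leaves])
    expect_true(all(tr$size[leaves] >= 5))
    # routing training subjects reaches the leaf that contains them
    expect_equal(rotsf:::tree_leaf_of(tr, d$x), tr$leaf_of)
    # predicted CHFs are non-negative, non-decreasing step functions
    pred <- predict_tree_chf(tr, d$x)
    expect_true(all(pred$chf >= 0))
    expect_true(all(apply(pred$chf, 1, function(h) all(diff(h) >= -1e-12))))
  }
})

test_that("prediction routes ties left and checks dimensions", {
  x <- cbind(c(rep(0, 6), rep(2, 6)))
  d <- surv_data(c(1:6, 101:106), rep(1, 12), x)
  tr <- grow_tree(d, min_node_size = 3)
  expect_equal(tr$thresh[1], 1)
  # x == threshold goes left (the low-value, early-death leaf)
  at_thr <- predict_tree_chf(tr, matrix(1, 1, 1))
  left_leaf <- predict_tree_chf(tr, matrix(0, 1, 1))
  expect_equal(at_thr$chf, left_leaf$chf)
  expect_error(predict_tree_chf(tr, matrix(1, 1, 3)), "expects 1 covariates")
})
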