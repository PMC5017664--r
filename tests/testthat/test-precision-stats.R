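test_that("node precision follows the normalized formula", {
  expect_equal(rp_node(c(0.5, 0.5, 0, 0), 4), 1 / 3, tolerance = 1e-12)
  expect_equal(round(rp_node(c(0.5, 0.5, 0, 0), 4), 2), 0.33)
  expect_equal(rp_node(c(1, 0, 0), 3), 1)
  expect_equal(rp_node(rep(1 / 5, 5), 5), 0)
  expect_equal(rp_node(c(1), 1), 1)    # single reconstructible state
  expect_error(rp_node(c(0.1, 0.1, 0.1), 5), "1/C_X")
  # bounded in [0,1] and strictly increasing in the maximum
  set.seed(31)
  for (i in 1:2000) {
    p <- stats::runif(sample(2:6, 1L)); p <- p / sum(p)
    v <- rp_node(p)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  c_x <- 4
  vals <- vapply(seq(1 / c_x, 1, length.out = 20),
                 function(mx) (c_x * mx - 1) / (c_x - 1), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("state unions pool states above the cutoff", {
  r1 <- matrix(c(0.99, 0.01, 0, 0.6, 0.4, 0), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), c("9", "10", "11")))
  u <- build_state_union(r1, 1e-2)
  expect_equal(u$states, c(9L, 10L))
  expect_equal(u$c_x, 2L)
  r2 <- matrix(c(0, 0, 1), 1, 3, dimnames = list("c", c("9", "10", "11")))
  u2 <- build_state_union(list(r1, r2), 1e-2)
  expect_equal(u2$states, c(9L, 10L, 11L))
  # raising the cutoff never enlarges the union
  u3 <- build_state_union(list(r1, r2), 0.5)
  expect_true(all(u3$states %in% u2$states))
  # every node certain: a single state
  rc <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("11", "12")))
  expect_equal(build_state_union(rc)$c_x, 1L)
})

test_that("tree precision is the bounded arithmetic mean", {
  expect_equal(rp_tree(c(1, 1, 1)), 1)
  expect_equal(rp_tree(c(0.33, 1.0)), 0.665)
  v <- runif(10)
  expect_gte(rp_tree(v), min(v)); expect_lte(rp_tree(v), max(v))
})

test_that("G-L summaries report the Chernoff mode", {
  g <- gl_summary(c(0, 0, 0, 10))
  expect_equal(g$mode, 0)
  expect_equal(g$range, c(0, 10))
  gc <- gl_summary(rep(2.5, 6))
  expect_equal(gc$mean, 2.5); expect_equal(gc$median, 2.5)
  expect_equal(gc$mode, 2.5); expect_equal(gc$range, c(2.5, 2.5))
  # the estimator attains the exhaustive maximum window count
  set.seed(17)
  for (i in 1:300) {
    x <- round(stats::rnorm(sample(5:30, 1L), 0, 2), 2)
    g <- gl_summary(x, bandwidth = 0.5)
    n_at_mode <- sum(x >= g$mode - 0.5 & x <= g$mode + 0.5)
    expect_equal(n_at_mode, max_window_count(x, 0.5))
    expect_gte(g$mode, min(x)); expect_lte(g$mode, max(x))
  }
  # tie goes to the smallest center
  expect_equal(gl_summary(c(0, 5))$mode, 0)
  # MCC value is attached
  expect_equal(gl_summary(c(1, 2, 3), mcc_value = 1.5)$mcc_value, 1.5)
})

test_that("precision correlation matches closed forms", {
  integ <- c(a = 1, b = 2, c = 3)
  per_tree <- list(a = c(1, 1), b = c(1, 0.8), c = c(0.8, 0.8))
  # proportions at 0.95: (1, 0.5, 0) -> perfectly anti-ordered with (1,2,3)
  out <- precision_correlation(integ, per_tree, 0.95)
  expect_equal(out$r, -1, tolerance = 1e-12)
  # integrated values equal to the proportions exactly: r = 1
  integ2 <- c(a = 0.5, b = 0.75, c = 1)
  pt2 <- list(a = c(1, 0.9, 0.9, 1), b = c(1, 1, 1, 0.9), c = c(1, 1, 1, 1))
  expect_equal(precision_correlation(integ2, pt2, 0.95)$r, 1, tolerance = 1e-12)
  out3 <- precision_correlation(10 + 5 * integ, per_tree, 0.95)
  expect_equal(out3$r, -1, tolerance = 1e-12)
  # zero variance flagged
  flat <- precision_correlation(c(a = 1, b = 1, c = 1), per_tree, 0.95)
  expect_true(is.na(flat$r))
})

test_that("MCC deviation table flags departures beyond ten percent", {
  cons <- c(c1 = 0.50, c2 = 0.8, c3 = 0.9, c4 = 0)
  mcc <- c(c1 = 0.55, c2 = 0.8, c3 = 0.7, c4 = 0.2)
  tab <- mcc_deviation_table(cons, mcc)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$ratio[tab$clade == "c1"], 1.1)
  expect_equal(tab$flag[tab$clade == "c1"], "over")
  expect_equal(tab$flag[tab$clade == "c2"], "")
  expect_equal(tab$flag[tab$clade == "c3"], "under")
  expect_equal(tab$flag[tab$clade == "c4"], "undefined")
  ident <- mcc_deviation_table(cons[1:3], cons[1:3])
  expect_true(all(ident$ratio == 1) && all(ident$flag == ""))
})

test_that("accession thresholds take the overlap-zone median", {
  intra <- c(0.001, 0.002, 0.01)
  inter <- c(0.005, 0.02, 0.03)
  th <- accession_threshold(inter, intra)
  expect_equal(as.numeric(th), 0.005)
  expect_equal(attr(th, "note"), "overlap")
  expect_gte(as.numeric(th), min(inter)); expect_lte(as.numeric(th), max(intra))
  # disjoint ranges: minimum interspecific distance, flagged
  th2 <- accession_threshold(c(0.1, 0.2), c(0.001, 0.002))
  expect_equal(as.numeric(th2), 0.1)
  expect_equal(attr(th2, "note"), "no-overlap")
})

test_that("precision_stats ties the pieces together", {
  rec <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("9", "10")))
  ps <- precision_stats(rec)
  expect_equal(unname(ps$rp_n), c(1, 0))
  expect_equal(ps$rp_t, 0.5)
  expect_equal(ps$c_x, 2L)
})
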