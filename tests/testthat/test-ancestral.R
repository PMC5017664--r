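test_that("marginal reconstruction matches Bayes-rule enumeration", {
  set.seed(21)
  for (case in 1:25) {
    n_tips <- sample(3:4, 1L)
    n_states <- sample(2:3, 1L)
    tr <- random_tree(n_tips, seed = 700 + case)
    states <- seq(9, 8 + n_states)
    counts <- random_counts(tr, states, seed = 800 + case)
    sp <- chrom_state_space(states, 9, 8 + n_states)
    m <- build_q(chrom_model_spec("CRND"),
                 c(gain = runif(1, 0.2, 1.5), loss = runif(1, 0.2, 1.5)), sp)
    rec <- marginal_reconstruction(tr, counts, m)
    oracle <- enum_marginals(tr, counts, m)
    expect_equal(rec[rownames(oracle), , drop = FALSE],
                 oracle[, , drop = FALSE],
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(abs(rowSums(rec) - 1) < 1e-9))
  }
})

test_that("a zero-rate model pins every node to the root state", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  m <- ladder_model(c(10, 11), 1e-300, 1e-300, root_prior = 10)
  m$Q[] <- 0
  rec <- marginal_reconstruction(tr, c(A = 10, B = 10, C = 10), m)
  expect_true(all(rec[, "10"] == 1))
})

test_that("stochastic mapping classifies events and matches telescoping", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  counts <- c(A = 10, B = 10, C = 10)
  # zero rates: no events at all
  m0 <- ladder_model(c(10, 11), 1e-300, 1e-300, root_prior = 10)
  m0$Q[] <- 0
  ev0 <- expected_events(tr, counts, m0, n_maps = 100L, seed = 1L)
  expect_equal(ev0$gains_total, 0)
  expect_equal(ev0$losses_total, 0)

  # doubling-only model: no dysploid gains or losses, duplications possible
  sp <- chrom_state_space(c(10, 20), 10, 20)
  md <- build_q(chrom_model_spec("CRD"),
                c(gain = 1e-300, loss = 1e-300, dupl = 0.4), sp)
  md$components$gain[] <- 0; md$components$loss[] <- 0
  evd <- expected_events(tr, c(A = 10, B = 20, C = 10), md,
                         n_maps = 300L, seed = 2L)
  expect_equal(evd$gains_total, 0)
  expect_equal(evd$losses_total, 0)
  expect_gt(evd$duplications_total, 0)

  # determinism by seed
  fx <- melampodium_like_fixture(seed = 5L, n_trees = 1L)
  fit <- fit_ml(fx$tree, fx$counts, chrom_model_spec("CRND"),
                restarts = 1L, seed = 2L)
  e1 <- expected_events(fx$tree, fx$counts, fit$model, n_maps = 120L, seed = 9L)
  e2 <- expected_events(fx$tree, fx$counts, fit$model, n_maps = 120L, seed = 9L)
  expect_identical(e1$branch, e2$branch)

  # CRND per-branch gains-losses agrees with E[child]-E[parent]
  ev <- expected_events(fx$tree, fx$counts, fit$model, n_maps = 400L, seed = 3L)
  tel <- gl_telescoping(fx$tree, fx$counts, fit$model)
  glb <- attr(ev, "gl_branch_maps")
  n <- ncol(glb)
  # empirical SE with a Poisson floor for branches whose expected count is
  # so small that no event was sampled
  se <- apply(glb, 1L, stats::sd) / sqrt(n) +
    sqrt(pmax(abs(tel$delta), 1e-12) / n)
  diff <- abs(rowMeans(glb) - tel$delta)
  expect_true(all(diff <= 3 * se))
  expect_equal(ev$gl, sum(ev$branch$gains) - sum(ev$branch$losses),
               tolerance = 1e-9)
})

test_that("mapping standard error shrinks like one over root n", {
  fx <- melampodium_like_fixture(seed = 8L, n_trees = 1L)
  tr20 <- prune_taxa(fx$tree, fx$tree$tip.label[1:19])
  counts <- fx$counts[tr20$tip.label]
  fit <- fit_ml(tr20, counts, chrom_model_spec("CRND"), restarts = 1L, seed = 2L)
  sds <- vapply(c(250L, 1000L, 4000L), function(n) {
    gl <- attr(expected_events(tr20, counts, fit$model, n_maps = n, seed = 4L),
               "gl_maps")
    stats::sd(gl) / sqrt(n)
  }, 0)
  # SE at 4000 maps should be roughly 1/4 of SE at 250 (allow 2x slack)
  expect_lt(sds[3L], sds[1L] / 2)
})

test_that("model averaging is a weighted mean and G-L is linear in weights", {
  r1 <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE,
               dimnames = list(c("n1", "n2"), c("9", "10")))
  r2 <- matrix(c(0.4, 0.6, 0.2, 0.8), 2, byrow = TRUE,
               dimnames = list(c("n1", "n2"), c("9", "10")))
  expect_equal(model_average(list(r1, r2), c(1, 0)), r1)
  expect_equal(model_average(list(r1, r1), c(0.3, 0.7)), r1)
  avg <- model_average(list(r1, r2), c(0.5, 0.5))
  expect_equal(avg["n1", ], c(`9` = 0.6, `10` = 0.4))
  expect_true(all(abs(rowSums(avg) - 1) < 1e-12))
  r3 <- r2; rownames(r3) <- c("n1", "nX")
  expect_error(model_average(list(r1, r3), c(0.5, 0.5)), "mismatch")

  # averaged G-L equals the weight-weighted mean of per-model G-L
  fx <- melampodium_like_fixture(seed = 6L, n_trees = 1L)
  sp <- chrom_state_space(fx$counts)
  fits <- fit_chromevol_family(fx$tree, fx$counts, sp,
                               families = c("CRND", "CRDD"),
                               restarts = 1L, seed = 2L)
  recs <- lapply(fits, function(f)
    marginal_reconstruction(fx$tree, fx$counts, f$model))
  w <- c(0.7, 0.3)
  avg2 <- model_average(recs, w)
  states <- as.numeric(colnames(avg2))
  mean_avg <- as.vector(avg2 %*% states)
  mean_models <- w[1] * as.vector(recs[[1]] %*% states) +
    w[2] * as.vector(recs[[2]] %*% states)
  expect_equal(mean_avg, mean_models, tolerance = 1e-12)
})
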