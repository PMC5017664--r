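test_that("count tables round-trip in both layouts", {
  counts <- c(sp_a = 9L, sp_b = 11L, sp_c = 14L)
  f1 <- tempfile(); f2 <- tempfile()
  write_counts(counts, f1, "tsv")
  write_counts(counts, f2, "records")
  expect_identical(read_counts(f1), counts)
  expect_identical(read_counts(f2), counts)  # sniffed from ">"
  writeLines(c("a\t9", "a\t10"), f1)
  expect_error(read_counts(f1), "duplicate")
})

test_that("Q matrices follow the event definitions", {
  sp <- chrom_state_space(9:11, 9, 11)
  m <- build_q(chrom_model_spec("CRND"), c(gain = 1, loss = 2), sp)
  expect_equal(unname(m$Q),
               rbind(c(-1, 1, 0), c(2, -3, 1), c(0, 2, -2)))

  # demi-duplication from odd state 9 splits mu/2 to 13 and 14
  sp18 <- chrom_state_space(c(9, 12), 9, 18)
  m2 <- build_q(chrom_model_spec("CRDE"),
                c(gain = 0.1, loss = 0.1, dupl = 0.2, demi = 1), sp18)
  expect_equal(m2$Q["9", "13"], 0.5)
  expect_equal(m2$Q["9", "14"], 0.5)
  expect_equal(m2$Q["9", "18"], 0.2)   # duplication 9 -> 18
  # even state 12: all of mu to 18
  expect_equal(m2$components$demi[4L, 10L], 1)  # row = state 12, col = state 18
  # duplication beyond n_max dropped: 12 -> 24 absent
  expect_equal(sum(m2$components$dupl[4, ]), 0)

  # CRDD shares one parameter between duplication and demi-duplication
  m3 <- build_q(chrom_model_spec("CRDD"),
                c(gain = 0.1, loss = 0.1, dupl = 0.3), sp18)
  expect_equal(m3$Q["9", "18"], 0.3)
  expect_equal(m3$Q["9", "13"] + m3$Q["9", "14"], 0.3)

  # linear rates indexed from n_min, clamped at zero
  m4 <- suppressWarnings(build_q(chrom_model_spec("LRND"),
          c(gain = 1, loss = 1, gain_lin = -0.6, loss_lin = 0.5),
          chrom_state_space(9:12, 9, 12)))
  expect_equal(m4$Q["10", "11"], 0.4)       # 1 - 0.6*1
  expect_equal(m4$Q["12", "11"], 1 + 0.5 * 3)
  expect_equal(m4$Q["11", "12"], 0)         # 1 - 1.2 clamped
  expect_warning(build_q(chrom_model_spec("LRND"),
          c(gain = 1, loss = 1, gain_lin = -0.6, loss_lin = 0.5),
          chrom_state_space(9:12, 9, 12)), "clamped")

  # ordered ladder: 12 and 14 are neighbors
  lad <- chrom_state_space(c(9, 10, 11, 12, 14), 9, 14)
  lad$observed <- c(9L, 10L, 11L, 12L, 14L)
  m5 <- build_q(chrom_model_spec("ORDERED_K", "two", lad),
                c(rate_up = 0.3, rate_down = 0.7), lad)
  expect_equal(m5$Q["12", "14"], 0.3)
  expect_equal(m5$Q["14", "12"], 0.7)
  expect_equal(m5$Q["12", "9"], 0)

  # row sums vanish for every family
  for (fam in c("CRND", "CRD", "CRDD", "CRDE", "LRND", "LRD", "LRDD", "LRDE")) {
    pn <- chromphylo:::family_param_names(fam)
    p <- stats::setNames(ifelse(grepl("_lin$", pn), 0.01, 0.5), pn)
    q <- build_q(chrom_model_spec(fam), p, chrom_state_space(c(6, 12), 4, 26))
    expect_lt(max(abs(rowSums(q$Q))), 1e-12)
    expect_true(all(q$Q - diag(diag(q$Q)) >= 0))
  }
})

test_that("transition matrices are stochastic across time scales", {
  set.seed(42)
  for (rep in 1:5) {
    sp <- chrom_state_space(c(8, 13), 6, 20)
    m <- build_q(chrom_model_spec("CRDE"),
                 c(gain = runif(1, 0, 2), loss = runif(1, 0, 2),
                   dupl = runif(1, 0, 1), demi = runif(1, 0, 1)), sp)
    for (t in c(0.01, 1, 100)) {
      P <- transition_matrix(m, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
      expect_true(all(P >= 0))
    }
  }
})

test_that("pruning likelihood matches closed forms and enumeration", {
  # two-tip symmetric two-state ladder: closed-form check
  r <- 0.7; t <- 0.4
  tr <- ape::read.tree(text = "(A:0.4,B:0.4);")
  m <- ladder_model(c(1, 2), r, r)
  ll <- tree_log_likelihood(tr, c(A = 1, B = 1), m)
  paa <- (1 + exp(-2 * r * t)) / 2; pba <- (1 - exp(-2 * r * t)) / 2
  expect_equal(ll, log(0.5 * (paa^2 + pba^2)), tolerance = 1e-12)

  # zero rate matrix: likelihood is the root prior of the shared state
  m0 <- ladder_model(c(1, 2), 1e-300, 1e-300)
  m0$Q[] <- 0
  expect_equal(tree_log_likelihood(tr, c(A = 1, B = 1), m0), log(0.5),
               tolerance = 1e-9)

  # exhaustive enumeration on random trees (<= 4 tips x <= 4 states)
  set.seed(7)
  for (case in 1:40) {
    n_tips <- sample(2:4, 1L)
    n_states <- sample(2:4, 1L)
    tr <- random_tree(n_tips, seed = 500 + case)
    states <- seq(9, 8 + n_states)
    counts <- random_counts(tr, states, seed = 600 + case)
    sp <- chrom_state_space(states, 9, 8 + n_states)
    m <- build_q(chrom_model_spec("CRND"),
                 c(gain = runif(1, 0.1, 2), loss = runif(1, 0.1, 2)), sp)
    expect_equal(tree_log_likelihood(tr, counts, m),
                 enum_loglik(tr, counts, m), tolerance = 1e-9)
  }
  # tip count outside the space errors
  tr_ab <- ape::read.tree(text = "(A:0.4,B:0.4);")
  sp <- chrom_state_space(9:10, 9, 10)
  m <- build_q(chrom_model_spec("CRND"), c(gain = 1, loss = 1), sp)
  expect_error(tree_log_likelihood(tr_ab, c(A = 9, B = 22), m), "state space")
})

test_that("ML fitting is deterministic and respects model nesting", {
  fx <- melampodium_like_fixture(seed = 3L, n_trees = 1L)
  sp <- chrom_state_space(fx$counts)
  f1 <- fit_ml(fx$tree, fx$counts, chrom_model_spec("CRND"), sp,
               restarts = 2L, seed = 11L)
  f2 <- fit_ml(fx$tree, fx$counts, chrom_model_spec("CRND"), sp,
               restarts = 2L, seed = 11L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$logL, f2$logL)
  expect_equal(f1$AIC, 2 * f1$k - 2 * f1$logL)

  f_crd <- fit_ml(fx$tree, fx$counts, chrom_model_spec("CRD"), sp,
                  restarts = 2L, seed = 12L)
  f_crde <- fit_ml(fx$tree, fx$counts, chrom_model_spec("CRDE"), sp,
                   restarts = 2L, seed = 13L)
  # nesting, allowing for the optimizer's lower rate bound of 1e-6
  expect_gte(f_crd$logL, f1$logL - 1e-3)
  expect_gte(f_crde$logL, f_crd$logL - 1e-3)
})

test_that("AIC table computes weights, ratios and 0.95 exclusions", {
  fake_fit <- function(fam, logl, k) {
    structure(list(model = list(spec = list(family = fam)), logL = logl,
                   k = k, AIC = 2 * k - 2 * logl, data_id = "d"),
              class = "chrom_fit")
  }
  # AICs 100 and 102: weights 0.731 / 0.269
  f1 <- fake_fit("CRND", -48, 2)   # AIC 100
  f2 <- fake_fit("CRD", -48, 3)    # AIC 102
  tab <- aic_table(list(f1, f2))
  expect_equal(tab$delta_AIC, c(0, 2))
  expect_equal(tab$akaike_weight, c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(sum(tab$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(attr(tab, "weight_ratio_2nd_best"),
               exp(-1), tolerance = 1e-12)
  expect_equal(attr(tab, "n_excluded_at_0.95"), 0L)

  # equal AICs: symmetric weights
  tab2 <- aic_table(list(fake_fit("A", -50, 2), fake_fit("B", -51, 1)))
  expect_equal(tab2$akaike_weight, c(0.5, 0.5))

  # a dominant model excludes the rest at cumulative 0.95
  tab3 <- aic_table(list(fake_fit("A", -10, 2), fake_fit("B", -20, 2),
                         fake_fit("C", -21, 2)))
  expect_equal(attr(tab3, "n_excluded_at_0.95"), 2L)

  # AIC ordering invariant to a constant shift of all logLs
  tab4 <- aic_table(list(fake_fit("A", -10 + 7, 2), fake_fit("B", -20 + 7, 2),
                         fake_fit("C", -21 + 7, 2)))
  expect_equal(tab4$model, tab3$model)
  expect_equal(tab4$delta_AIC, tab3$delta_AIC)

  f_other <- fake_fit("D", -5, 2); f_other$data_id <- "other"
  expect_error(aic_table(list(f1, f_other)), "different data")
})

test_that("Bell numbers count the rate-class model space", {
  expect_equal(rj_model_space_size(1), 1)
  expect_equal(rj_model_space_size(3), 5)      # {abc},{ab|c},{ac|b},{bc|a},{a|b|c}
  expect_equal(rj_model_space_size(4), 15)
  expect_equal(rj_model_space_size(5), 52)
  expect_gt(rj_model_space_size(20), 51e12)
})
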