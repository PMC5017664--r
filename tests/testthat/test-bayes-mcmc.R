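flat_tree <- function() {
  # zero-length branches make the likelihood independent of the rates
  ape::read.tree(text = "((A:0,B:0):0,C:0);")
}

test_that("fixed-model chains are reproducible with sane acceptance", {
  fx <- melampodium_like_fixture(seed = 2L, n_trees = 1L)
  tr <- prune_taxa(fx$tree, fx$tree$tip.label[1:31])
  counts <- fx$counts[tr$tip.label]
  lsp <- chrom_state_space(counts, min(counts), max(counts))
  spec <- chrom_model_spec("ORDERED_K", "two", lsp)
  ch1 <- suppressWarnings(mcmc_fixed(tr, counts, spec, iterations = 2000L,
                                     burnin = 200L, thin = 5L, seed = 7L,
                                     space = lsp))
  ch2 <- suppressWarnings(mcmc_fixed(tr, counts, spec, iterations = 2000L,
                                     burnin = 200L, thin = 5L, seed = 7L,
                                     space = lsp))
  expect_identical(ch1$samples, ch2$samples)
  expect_true(all(ch1$acceptance > 0 & ch1$acceptance < 1))
  expect_true(all(c("rate_up", "rate_down", "m", "v", "logL") %in%
                    names(ch1$samples)))
})

test_that("a flat likelihood leaves the hyperparameters at their hyperprior", {
  tr <- flat_tree()
  counts <- c(A = 9L, B = 9L, C = 9L)
  lsp <- chrom_state_space(c(9L, 10L), 9L, 10L)
  spec <- chrom_model_spec("ORDERED_K", "one", lsp)
  ch <- suppressWarnings(mcmc_fixed(tr, counts, spec, iterations = 12000L,
                                    burnin = 2000L, thin = 2L, seed = 3L,
                                    space = lsp))
  expect_equal(stats::sd(ch$samples$logL), 0)   # likelihood really is flat
  # m and v marginally uniform on (0, 1); subsample past the random-walk
  # autocorrelation before applying the KS test
  sub <- ch$samples[seq(1L, nrow(ch$samples), by = 20L), ]
  expect_gt(suppressWarnings(
    stats::ks.test(sub$m, "punif")$p.value), 1e-3)
  expect_gt(suppressWarnings(
    stats::ks.test(sub$v, "punif")$p.value), 1e-3)
})

test_that("harmonic-mean Bayes factors follow the defining arithmetic", {
  s1 <- data.frame(logL = rep(-10, 50))
  s2 <- data.frame(logL = rep(-11, 50))
  expect_equal(as.numeric(log_bayes_factor(s1, s2)), 2)
  expect_equal(as.numeric(log_bayes_factor(s1, s1)), 0)
  expect_equal(attr(log_bayes_factor(s1, s2), "threshold"), 2)
  # harmonic mean of a constant-likelihood chain is that likelihood
  expect_equal(chromphylo:::log_harmonic_mean(rep(-123.4, 77)), -123.4)
  # invariance to sample order
  set.seed(1)
  x <- rnorm(200, -50, 3)
  expect_equal(chromphylo:::log_harmonic_mean(x),
               chromphylo:::log_harmonic_mean(sample(x)))
})

test_that("reversible jump explores the augmented partition space uniformly", {
  # flat likelihood; 3 rates -> Bell(4) = 15 configurations
  flat_ll <- function(z, theta) 0
  rj <- chromphylo:::rj_sampler(flat_ll, n_rates = 3L,
                                iterations = 60000L, burnin = 2000L,
                                thin = 2L, seed = 5L)
  tab <- table(rj$samples$config)
  expect_equal(length(tab), 15L)
  chi <- suppressWarnings(stats::chisq.test(as.vector(tab)))
  # frequencies consistent with uniform over the 15 configurations
  expect_gt(chi$p.value, 1e-4)
})

test_that("RJ on real data reports coherent summaries", {
  fx <- melampodium_like_fixture(seed = 4L, n_trees = 1L)
  tr <- prune_taxa(fx$tree, fx$tree$tip.label[1:29])
  counts <- fx$counts[tr$tip.label]
  lsp <- chrom_state_space(counts, min(counts), max(counts))
  rj <- suppressWarnings(rj_mcmc(tr, counts, iterations = 2000L,
                                 burnin = 200L, thin = 5L, seed = 2L,
                                 space = lsp))
  n_states <- length(lsp$observed)
  expect_equal(rj$n_rates, n_states * (n_states - 1L))
  expect_length(rj$summary$zero_proportion, rj$n_rates)
  expect_true(all(rj$summary$zero_proportion >= 0 &
                    rj$summary$zero_proportion <= 1))
  expect_true(all(rj$samples$n_classes >= 0))
  expect_gte(rj$summary$n_classes_mean, rj$summary$n_classes_range[1L])
  # determinism
  rj2 <- suppressWarnings(rj_mcmc(tr, counts, iterations = 2000L,
                                  burnin = 200L, thin = 5L, seed = 2L,
                                  space = lsp))
  expect_identical(rj$samples, rj2$samples)
})

test_that("informative data pull active rates out of the RJ zero class", {
  # flat-likelihood reference: how often a rate sits in the zero class
  # under the uniform augmented-partition prior alone
  flat <- chromphylo:::rj_sampler(function(z, theta) 0, n_rates = 6L,
                                  iterations = 20000L, burnin = 1000L,
                                  thin = 3L, seed = 2L)
  prior_zero <- mean(flat$samples$n_zero) / 6
  expect_gt(prior_zero, 0.1)

  # single-class ladder data at 40 tips: the well-informed neighbour rates
  # (many observed 9<->10 transitions) must be zeroed far less often
  tr <- simulate_yule_tree(40L, 1, seed = 31L)
  m <- ladder_model(c(9, 10, 11), 0.25, 0.25)
  sim <- simulate_counts(tr, m, 10L, seed = 32L)
  lsp <- chrom_state_space(sim$counts, min(sim$counts), max(sim$counts))
  rj <- suppressWarnings(rj_mcmc(tr, sim$counts, iterations = 6000L,
                                 burnin = 600L, thin = 5L, seed = 33L,
                                 space = lsp))
  zp <- rj$summary$zero_proportion
  expect_lt(zp[["9->10"]], 0.6 * prior_zero)
  expect_lt(zp[["10->9"]], 0.6 * prior_zero)
})
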