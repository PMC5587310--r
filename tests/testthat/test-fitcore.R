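test_that("null EM reduces to parental allele counting on complete data", {
  ## complete single-SNP data: every family has exactly one configuration,
  ## so the EM must equal the (t, u, f) slot count = parental allele count
  set.seed(21)
  d <- simulate_triads(snp_sim_spec(0.25, 1, n_triads = 120, seed = 21))
  fw <- families_for(d)
  nf <- fit_null(fw$families, fw$haps)
  n <- length(d$families)
  count2 <- sum(d$mother1 == 2L) + sum(d$mother2 == 2L) + sum(d$father == 2L)
  expect_equal(nf$haps$frequencies[2], count2 / (3 * n), tolerance = 1e-9)
  expect_true(nf$converged)
  ## reference is the most frequent haplotype
  expect_equal(nf$haps$reference, which.max(nf$haps$frequencies))
})

test_that("EM log-likelihood is monotone non-decreasing under missing data", {
  d <- simulate_triads(sim_spec(c(0.5, 0.2, 0.2, 0.1), c(1, 1.3, 0.8, 1),
                                n_triads = 80, missing_rate = 0.25, seed = 22))
  fw <- families_for(d)
  nf <- fit_null(fw$families, fw$haps)
  expect_true(all(diff(nf$trace) >= -1e-10))
  expect_true(nf$converged)
})

test_that("a dataset carrying only one haplotype estimates its frequency as 1", {
  n <- 10
  d <- triad_dataset(snp_map(1L), sprintf("f%d", 1:n), rep(1L, n),
                     matrix(1L, n, 1), matrix(1L, n, 1), matrix(1L, n, 1),
                     matrix(1L, n, 1), matrix(NA_integer_, n, 1))
  fw <- families_for(d)
  nf <- fit_null(fw$families, fw$haps)
  expect_equal(nf$haps$frequencies, c(1, 0), tolerance = 1e-9)
})

test_that("rare-haplotype pruning renormalizes, reindexes and drops stranded families", {
  map <- snp_map(2L)
  haps <- enumerate_haplotypes(list(start_index = 0L, length = 2L), map)
  haps$frequencies <- c(0.70, 0.25, 0.04, 0.01)
  fams <- list(list(sex = 1L, configs = cbind(t = 1L, u = 2L, f = 1L), weight = 5),
               list(sex = 2L, configs = cbind(t = 3L, u = 3L, f = 3L), weight = 2),
               list(sex = 1L, configs = rbind(c(2L, 2L, 2L), c(4L, 2L, 1L)), weight = 1))
  pr <- prune_rare(haps, 0.05, fams)
  expect_equal(pr$pruned, haps$haplotypes[3:4])
  expect_equal(pr$haps$frequencies, c(0.70, 0.25) / 0.95, tolerance = 1e-12)
  ## family 2 only explainable through a pruned haplotype: excluded
  expect_length(pr$families, 2)
  expect_equal(pr$n_families_dropped, 2)
  ## surviving configs are reindexed into the reduced table
  expect_equal(unname(pr$families[[2]]$configs), rbind(c(2L, 2L, 2L)))

  ## nothing below threshold: identity
  haps2 <- haps; haps2$frequencies <- c(0.4, 0.3, 0.2, 0.1)
  pr2 <- prune_rare(haps2, 0.05, fams)
  expect_equal(pr2$haps$frequencies, haps2$frequencies)
  expect_length(pr2$families, 3)

  ## pruning to fewer than two haplotypes is an uninformative window
  haps3 <- haps; haps3$frequencies <- c(0.97, 0.01, 0.01, 0.01)
  expect_error(prune_rare(haps3, 0.05, fams), class = "xtriad_uninformative")
})

test_that("sex-stratified MLE equals the transmission ratio on balanced complete data", {
  ## 30 het mothers of affected boys: variant transmitted 20 times, 10 not
  d <- transmission_fixture(20, 10, sex = 1L)
  f <- fit_window(d, spec = "males_only", min_freq = 0, reference = "A")
  expect_equal(f$rr_single_dose[2], 2, tolerance = 1e-6)
  expect_true(f$converged)
  ## girls: fathers mirror the untransmitted counts
  dg <- transmission_fixture(20, 10, sex = 2L)
  fg <- fit_window(dg, spec = "females_only", min_freq = 0, reference = "A")
  expect_equal(fg$rr_single_dose[2], 2, tolerance = 1e-6)
  ## perfectly balanced transmissions: RR 1 and a null LRT
  db <- transmission_fixture(15, 15, sex = 1L)
  fb <- fit_window(db, spec = "males_only", min_freq = 0, reference = "A")
  expect_equal(fb$rr_single_dose[2], 1, tolerance = 1e-6)
  expect_lt(fb$lrt_statistic, 1e-6)
  expect_equal(fb$p_value, 1, tolerance = 1e-3)
})

test_that("model couplings propagate into the reported boy relative risks", {
  d <- simulate_triads(snp_sim_spec(0.25, 1.6, model = "xinactivation",
                                    n_triads = 300, seed = 23))
  fx <- fit_window(d, spec = "xinactivation")
  expect_equal(fx$rr_boys, fx$rr_single_dose^2, tolerance = 1e-12)
  expect_equal(fx$rr_double_dose, fx$rr_single_dose^2, tolerance = 1e-12)
  fn <- fit_window(d, spec = "no_xinactivation")
  expect_equal(fn$rr_boys, fn$rr_single_dose, tolerance = 1e-12)
})

test_that("LRT p-values follow the chi-square reference", {
  expect_equal(lrt_pvalue(-10, -10, 1), 1)
  expect_equal(lrt_pvalue(-10 + 3.841459 / 2, -10, 1), 0.05, tolerance = 1e-6)
  expect_equal(lrt_pvalue(-10 + 7.815 / 2, -10, 3), 0.05, tolerance = 1e-3)
  expect_error(lrt_pvalue(-11, -10, 1), "consistency")
})

test_that("switching the reference haplotype inverts the relative risk", {
  d <- simulate_triads(snp_sim_spec(0.35, 1.8, n_triads = 250, seed = 24))
  f1 <- fit_window(d, spec = "no_xinactivation", reference = 1L)
  f2 <- fit_window(d, spec = "no_xinactivation", reference = 2L)
  expect_equal(f2$rr_single_dose[1], 1 / f1$rr_single_dose[2], tolerance = 1e-6)
  ## the window LRT is invariant to the reference choice
  expect_equal(f2$lrt_statistic, f1$lrt_statistic, tolerance = 1e-6)
})

test_that("the full model never falls below the null (monotone nesting)", {
  for (s in 25:28) {
    d <- simulate_triads(sim_spec(c(0.5, 0.3, 0.15, 0.05), c(1, 1.2, 0.9, 1),
                                  model = "no_xinactivation", n_triads = 100,
                                  missing_rate = 0.1, seed = s))
    f <- fit_window(d, spec = "no_xinactivation", min_freq = 0.02)
    expect_gte(f$loglik_full, f$loglik_null - 1e-8)
    expect_gte(f$lrt_statistic, 0)
    expect_true(f$p_value >= 0 && f$p_value <= 1)
  }
})

test_that("complete separation is capped and flagged rather than diverging", {
  ## variant always transmitted: the MLE for r is at +infinity
  d <- transmission_fixture(25, 0, sex = 1L)
  ## with U = 0 every het mother transmitted the variant
  d$child1[, 1] <- 2L
  f <- fit_window(d, spec = "males_only", min_freq = 0, reference = "A")
  expect_true(f$boundary)
  expect_true(is.finite(f$rr_single_dose[2]))
  expect_lte(log(f$rr_single_dose[2]), 15 + 1e-6)
})
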