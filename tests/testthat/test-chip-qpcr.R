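test_that("percent input matches the closed-form worked values", {
  expect_equal(percent_input(20, 20, dilution_factor = 10), 10)       # 2^(-log2 10)
  expect_equal(percent_input(23, 20, dilution_factor = 10), 1.25)    # 1/80
  expect_equal(percent_input(20, 20, dilution_factor = 1), 100)      # dCt = 0
  expect_error(percent_input(20, 20, dilution_factor = 0), "> 0")
  expect_error(percent_input(50, 20), "plausible")
})

test_that("percent input is monotone in Ct values and dilution", {
  ct_chip <- seq(18, 26, by = 0.5)
  p <- percent_input(ct_chip, 20)
  expect_true(all(diff(p) < 0))                       # decreasing in ct_chip
  p_in <- percent_input(22, seq(18, 26, by = 0.5))
  expect_true(all(diff(p_in) > 0))                    # increasing in ct_input
  # a larger input dilution factor means a more concentrated original input,
  # hence a smaller fraction recovered: %input decreases in dilution_factor
  p_dil <- vapply(c(1, 2, 5, 10, 20), function(d) percent_input(22, 20, d), 0)
  expect_true(all(diff(p_dil) < 0))
})

test_that("simulated Ct tables round-trip exactly at zero noise", {
  truth <- data.frame(region = c("ndr1R11", "ndr1R11", "ndr2R3"),
                      antibody = c("anti-Myc", "IgG", "anti-Myc"),
                      percent = c(10, 1.25, 0.5))
  ct <- simulate_ct_table(truth, dilution_factor = 10, noise_sd = 0,
                          n_replicates = 3)
  expect_equal(nrow(ct), 9)
  # the 10% row inverts to Ct_ChIP == Ct_Input, the 1.25% row to a +3 shift
  myc <- ct$antibody == "anti-Myc" & ct$region == "ndr1R11"
  igg <- ct$antibody == "IgG"
  expect_equal(ct$ct_chip[myc], ct$ct_input[myc])
  expect_equal(ct$ct_chip[igg] - ct$ct_input[igg], rep(3, 3))
  pct <- percent_input(ct)
  expect_equal(pct$percent,
               rep(truth$percent, each = 3), tolerance = 1e-12)

  noisy <- simulate_ct_table(truth, noise_sd = 0.1, seed = 5L)
  expect_identical(noisy, simulate_ct_table(truth, noise_sd = 0.1, seed = 5L))
  expect_error(simulate_ct_table(truth, dilution_factor = -1), "> 0")
  expect_error(simulate_ct_table(transform(truth, percent = -1)), "> 0")
})

test_that("antibody-vs-IgG t-tests with degenerate and strong cases", {
  same <- compare_to_igg(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")

  jitter <- c(-0.01, 0, 0.01)
  strong <- compare_to_igg(c(10, 10, 10) + jitter, c(1, 1, 1) + jitter)
  expect_lt(strong$p, 0.001)
  expect_equal(strong$stars, "***")

  # non-degenerate path is the standard two-sample t-test
  a <- c(8.2, 9.1, 7.6, 8.8); b <- c(2.1, 3.4, 2.8, 2.2)
  ours <- compare_to_igg(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  welch <- compare_to_igg(a, b, var_equal = FALSE)
  expect_equal(welch$p, t.test(a, b)$p.value)

  expect_warning(compare_to_igg(c(10, 11), c(1, 2)), "low power")
  expect_error(compare_to_igg(5, c(1, 2)), "2 replicates")
})

test_that("significance stars follow the reporting thresholds", {
  expect_equal(significance_stars(c(0.5, 0.05, 0.03, 0.009, 0.0009)),
               c("ns", "ns", "*", "**", "***"))
})

test_that("test_enrichment compares every antibody to IgG per region", {
  truth <- data.frame(region = rep(c("R1", "R2"), each = 2),
                      antibody = rep(c("anti-Myc", "IgG"), 2),
                      percent = c(10, 1, 1, 1))
  ct <- simulate_ct_table(truth, noise_sd = 0.05, n_replicates = 4, seed = 2L)
  res <- suppressWarnings(test_enrichment(percent_input(ct)))
  expect_equal(nrow(res), 2)
  expect_lt(res$p[res$region == "R1"], 0.01)
  expect_gt(res$p[res$region == "R2"], 0.05)

  bonf <- suppressWarnings(test_enrichment(percent_input(ct),
                                           p_adjust = "bonferroni"))
  expect_equal(bonf$p_adj, pmin(1, res$p * 2))
})
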