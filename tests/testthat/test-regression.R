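test_that("exact fits: constant and noise-free responses", {
  X <- cbind(intercept = 1, a = rep(0:1, each = 10), b = seq(0, 1, length.out = 20))
  fit <- fit_ols(X, rep(3.5, 20))
  expect_equal(unname(coef(fit)), c(3.5, 0, 0), tolerance = 1e-12)
  expect_equal(fit$residual_variance, 0, tolerance = 1e-20)

  # a residual sum of squares of exactly zero degenerates the t-tests to NA
  exact <- fit_ols(matrix(1, 8, 1, dimnames = list(NULL, "intercept")),
                   rep(0, 8))
  expect_identical(exact$residual_variance, 0)
  expect_true(all(is.na(exact$p_values)))

  y <- 2 - 4 * X[, "a"] + 7 * X[, "b"]
  fit2 <- fit_ols(X, y)
  expect_equal(unname(coef(fit2)), c(2, -4, 7), tolerance = 1e-10)
  expect_lt(max(abs(fit2$residuals)), 1e-10)
})

test_that("fit_ols agrees with lm on random designs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(20:60, 1); p <- sample(2:5, 1)
    X <- cbind(intercept = 1,
               matrix(rnorm(n * (p - 1)), n,
                      dimnames = list(NULL, paste0("v", seq_len(p - 1)))))
    y <- rnorm(n)
    ours <- fit_ols(X, y)
    ref <- summary(lm(y ~ X - 1))$coefficients
    expect_equal(unname(coef(ours)), unname(ref[, 1]), tolerance = 1e-10)
    expect_equal(unname(ours$standard_errors), unname(ref[, 2]), tolerance = 1e-10)
    expect_equal(unname(ours$t_stats), unname(ref[, 3]), tolerance = 1e-10)
    expect_equal(unname(ours$p_values), unname(ref[, 4]), tolerance = 1e-10)
    expect_equal(ours$log_likelihood, as.numeric(logLik(lm(y ~ X - 1))),
                 tolerance = 1e-8)
    # residual orthogonality: X'r = 0
    expect_lt(max(abs(crossprod(X, ours$residuals))), 1e-8)
  }
})

test_that("singular and undersized designs error informatively", {
  X <- cbind(intercept = 1, a = 1:10, a_copy = 1:10)
  expect_error(fit_ols(X, rnorm(10)), "a_copy")
  expect_error(fit_ols(cbind(intercept = 1, a = 1:3, b = c(2, 1, 7)), rnorm(3)),
               "must exceed")

  dat <- default_dataset()
  expect_error(fit_full_model(dat[dat$treatment == "DMSO", ], "ndr1"),
               "x_smad2")
})

test_that("full-model fits recover generating coefficients within 3 SE", {
  scm <- scm_params()
  dat <- default_dataset(seed = 5L, n_per_group = c(10L, 10L), scm = scm)
  fit1 <- fit_full_model(dat, "ndr1")
  expect_lt(abs(coef(fit1)["bcatenin"] - 800), 3 * fit1$standard_errors["bcatenin"])
  fit2 <- fit_full_model(dat, "ndr2")
  expect_lt(abs(coef(fit2)["eomesa"] - 700), 3 * fit2$standard_errors["eomesa"])
  expect_equal(names(coef(fit1)),
               c("intercept", "eomesa", "bcatenin", "smad2", "time"))
})

test_that("per-timepoint fits recover stage-specific truth", {
  dat <- default_dataset(scm = noiseless_scm())
  tp <- fit_per_timepoint(dat, "ndr1")
  expect_length(tp$fits, 4)
  # time-constant generating coefficients: identical factor effects per stage
  for (f in c("eomesa", "bcatenin", "smad2")) {
    effs <- vapply(tp$fits, function(x) coef(x)[[f]], 0)
    expect_equal(unname(effs), rep(effs[[1]], 4), tolerance = 1e-8)
  }

  sched <- data.frame(time_hpf = c(3.7, 4.0, 4.3, 4.7), intercept = 100,
                      eomesa = 40, bcatenin = c(900, 700, 500, 300),
                      smad2 = c(300, 500, 700, 900))
  dat2 <- default_dataset(scm = noiseless_scm(gene1_schedule = sched))
  tp2 <- fit_per_timepoint(dat2, "ndr1")
  for (i in 1:4) {
    expect_equal(coef(tp2$fits[[i]])[["bcatenin"]], sched$bcatenin[i],
                 tolerance = 1e-8)
    expect_equal(coef(tp2$fits[[i]])[["smad2"]], sched$smad2[i],
                 tolerance = 1e-8)
  }
})

test_that("undersized stages are skipped with a warning, not a crash", {
  dat <- default_dataset()
  keep <- dat$time_hpf != 4.0 | seq_len(nrow(dat)) %in% which(dat$time_hpf == 4.0)[1:3]
  expect_warning(tp <- fit_per_timepoint(dat[keep, ], "ndr1"), "skipped")
  expect_length(tp$fits, 3)
  expect_false("4" %in% names(tp$fits))
})

test_that("contribution shares are normalized absolute coefficients", {
  sched <- data.frame(time_hpf = c(3.7, 4.0, 4.3, 4.7), intercept = 50,
                      eomesa = 0, bcatenin = 300, smad2 = 100)
  dat <- default_dataset(scm = noiseless_scm(gene1_schedule = sched))
  tp <- fit_per_timepoint(dat, "ndr1")
  prof <- relative_contributions(tp, factors = c("bcatenin", "smad2"))
  expect_equal(prof$share[prof$factor == "bcatenin"], rep(0.75, 4),
               tolerance = 1e-8)
  expect_equal(prof$share[prof$factor == "smad2"], rep(0.25, 4),
               tolerance = 1e-8)

  single <- relative_contributions(tp, factors = "bcatenin")
  expect_equal(single$share, rep(1, 4))

  full <- relative_contributions(fit_per_timepoint(default_dataset(), "ndr1"))
  sums <- tapply(full$share, full$time_hpf, sum)
  expect_equal(as.vector(sums), rep(1, 4), tolerance = 1e-12)

  tp0 <- tp
  for (i in seq_along(tp0$fits))
    tp0$fits[[i]]$coefficients[c("eomesa", "bcatenin", "smad2")] <- 0
  expect_error(relative_contributions(tp0), "shares undefined")
  expect_error(relative_contributions(tp, factors = c("intercept", "smad2")),
               "intercept")
})

test_that("screening classifies by the strict p-threshold rule", {
  fit <- fit_full_model(default_dataset(), "ndr1")
  fit$p_values[c("eomesa", "bcatenin", "smad2")] <- c(0.5, 0.01, 0.2)
  screen <- screen_variables(fit)
  expect_equal(screen$common_causes, "eomesa")        # p = 0.5  > 0.2
  expect_true("bcatenin" %in% screen$treatments)      # p = 0.01
  expect_true("smad2" %in% screen$treatments)         # p = 0.2 exactly: strict >
  expect_true("time" %in% screen$treatments)          # time always a treatment

  fit$p_values["eomesa"] <- NA
  expect_error(screen_variables(fit), "missing p-value")
  expect_error(variable_screen(c("bcatenin", "smad2", "time"),
                               c("eomesa", "smad2")), "disjoint")
})
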