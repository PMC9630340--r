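test_that("default graphs mirror the two-gene study structure", {
  screen1 <- variable_screen(treatments = c("bcatenin", "smad2", "time"),
                             common_causes = "eomesa", gene = "ndr1")
  g1 <- build_causal_graph(screen1, "ndr1")
  expect_setequal(g1$treatments, c("bcatenin", "smad2", "time"))
  expect_setequal(g1$common_causes, c("eomesa", "ndr2"))
  expect_true(igraph::is_dag(g1$igraph))
  expect_equal(igraph::degree(g1$igraph, v = "ndr1", mode = "out"), c(ndr1 = 0))

  screen2 <- variable_screen(treatments = c("eomesa", "smad2", "time"),
                             common_causes = "bcatenin", gene = "ndr2")
  g2 <- build_causal_graph(screen2, "ndr2")
  expect_setequal(g2$common_causes, c("bcatenin", "ndr1"))

  expect_error(build_causal_graph(screen1, "ndr1",
                                  extra_edges = data.frame(from = "ndr1",
                                                           to = "bcatenin")),
               "outgoing|cyclic")
  expect_error(build_causal_graph(screen1, "ndr1",
                                  extra_edges = data.frame(
                                    from = c("bcatenin", "smad2"),
                                    to = c("smad2", "bcatenin"))),
               "acyclic")

  dot <- tempfile(fileext = ".dot")
  export_graph_dot(g1, dot)
  expect_true(any(grepl("ndr1", readLines(dot))))
})

test_that("backdoor identification returns the common causes and checks observability", {
  dat <- default_dataset()
  est <- ndr1_estimand(dat)
  expect_setequal(est$adjustment_set, c("eomesa", "ndr2"))

  screen_all_treat <- variable_screen(
    treatments = c("eomesa", "bcatenin", "smad2", "time"),
    common_causes = character(0))
  g0 <- build_causal_graph(screen_all_treat, "ndr1", include_other_gene = FALSE)
  est0 <- identify_backdoor(g0)
  expect_length(est0$adjustment_set, 0)

  no_ndr2 <- dat[, setdiff(names(dat), "y_ndr2")]
  screen1 <- variable_screen(treatments = c("bcatenin", "smad2", "time"),
                             common_causes = "eomesa")
  g1 <- build_causal_graph(screen1, "ndr1")
  expect_error(identify_backdoor(g1, no_ndr2), "identification fails")
})

test_that("per-treatment backdoor estimates equal the adjustment regression exactly", {
  dat <- default_dataset(seed = 2L)
  est <- estimate_effect(dat, ndr1_estimand(dat))
  X <- cbind(intercept = 1, bcatenin = dat$x_bcatenin, smad2 = dat$x_smad2,
             time = dat$time_hpf, eomesa = dat$x_eomesa, ndr2 = dat$y_ndr2)
  oracle <- fit_ols(X, dat$y_ndr1)
  for (tr in c("bcatenin", "smad2", "time"))
    expect_identical(est$effects$effect[est$effects$term == tr],
                     unname(coef(oracle)[tr]))
  expect_equal(est$joint$effect,
               unname(sum(coef(oracle)[c("bcatenin", "smad2")])))
})

test_that("known interventional truths and nulls are recovered", {
  scm <- scm_params()
  scm$gene1$coef["bcatenin"] <- 700
  dat <- default_dataset(seed = 13L, scm = scm)
  est <- estimate_effect(dat, ndr1_estimand(dat))
  b <- est$effects[est$effects$term == "bcatenin", ]
  expect_lt(abs(b$effect - 700), 3 * b$se)

  scm0 <- scm_params()
  scm0$gene1$coef["bcatenin"] <- 0
  dat0 <- default_dataset(seed = 17L, scm = scm0)
  b0 <- estimate_effect(dat0, ndr1_estimand(dat0))$effects
  b0 <- b0[b0$term == "bcatenin", ]
  expect_lt(abs(b0$effect), 3 * b0$se)

  expect_error(estimate_effect(dat[dat$treatment == "DMSO", ],
                               ndr1_estimand(dat)), "constant")
})

test_that("backdoor adjustment beats naive difference-in-means under confounding", {
  scm <- confounded_scm(0.8)
  truth <- truth_ate(scm)
  truth_b <- truth$ate[truth$gene == "ndr1" & truth$factor == "bcatenin"]
  dat <- default_dataset(seed = 23L, scm = scm)
  naive <- mean(dat$y_ndr1[dat$x_bcatenin == 1]) -
    mean(dat$y_ndr1[dat$x_bcatenin == 0])
  adj <- estimate_effect(dat, ndr1_estimand(dat))$effects
  adj_b <- adj$effect[adj$term == "bcatenin"]
  expect_lt(abs(adj_b - truth_b), abs(naive - truth_b))
})

test_that("estimates converge towards truth with sample size", {
  sizes <- c(3L, 10L, 40L)  # 72, 240, 960 embryos
  med_err <- vapply(sizes, function(npg) {
    errs <- vapply(1:30, function(r) {
      dat <- default_dataset(seed = 100 + r, n_per_group = c(npg, npg))
      eff <- estimate_effect(dat, ndr1_estimand(dat))$effects
      abs(eff$effect[eff$term == "bcatenin"] - 800)
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med_err) < 0))
})

test_that("duplicate adjustment columns are dropped without changing the estimate", {
  dat <- default_dataset(seed = 6L)
  est0 <- estimate_effect(dat, ndr1_estimand(dat))
  dat$x_eomesa_dup <- dat$x_eomesa
  dup_estimand <- ndr1_estimand(dat)
  dup_estimand$adjustment_set <- c(dup_estimand$adjustment_set, "x_eomesa_dup")
  expect_error(estimate_effect(dat, dup_estimand), "collinear")
  est1 <- estimate_effect(dat, dup_estimand, drop_collinear = TRUE)
  expect_equal(est1$joint$effect, est0$joint$effect, tolerance = 1e-8)
  expect_equal(est1$effects$effect, est0$effects$effect, tolerance = 1e-8)
})
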