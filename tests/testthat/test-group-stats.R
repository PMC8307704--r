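test_that("normality gate routes Gaussian and heavy-tailed data correctly", {
  # two compared groups: expected parametric rate 0.95^2 ~ 0.90 under the
  # per-group gate
  para <- 0; nonpara <- 0
  for (s in 1:100) {
    set.seed(s)
    g <- rep(c("CONT", "gNAC"), each = 50)
    gauss <- normality_gate(rnorm(100, 10, 2), g)
    if (gauss$branch == "parametric") para <- para + 1
    heavy <- normality_gate(rlnorm(100, 0, 1.5), g)
    if (heavy$branch == "nonparametric") nonpara <- nonpara + 1
  }
  expect_gte(para, 85)
  expect_gte(nonpara, 90)
})

test_that("tiny groups force the nonparametric branch with a warning", {
  v <- c(1, 2, 5, 6, 7, 8)
  g <- c("A", "A", "B", "B", "B", "B")
  expect_warning(res <- normality_gate(v, g), "nonparametric")
  expect_equal(res$branch, "nonparametric")
  expect_true(is.na(res$shapiro_p[["A"]]))
})

test_that("NAC omnibus comparison validates its inputs", {
  tab <- data.frame(value = rnorm(30), group = rep(c("NAC15", "NAC30"), 15))
  expect_error(compare_nac_groups(tab, "parametric"), "NAC45")
  const <- data.frame(value = rep(1, 30),
                      group = rep(c("NAC15", "NAC30", "NAC45"), 10))
  expect_error(compare_nac_groups(const, "parametric"), "degenerate")
})

test_that("omnibus test is calibrated under the null and powered under a shift", {
  rej <- 0
  for (s in 1:400) {
    set.seed(s)
    tab <- data.frame(value = rnorm(36, 5, 1),
                      group = rep(c("NAC15", "NAC30", "NAC45"), each = 12))
    if (compare_nac_groups(tab, "parametric")$p <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / 400 - 0.05), 0.03)
  powered <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    v <- c(rnorm(12, 5, 1), rnorm(12, 8, 1), rnorm(12, 5, 1))
    tab <- data.frame(value = v,
                      group = rep(c("NAC15", "NAC30", "NAC45"), each = 12))
    res <- compare_nac_groups(tab, "parametric")
    if (res$p <= 0.05) powered <- powered + 1
    expect_true(all(res$tukey >= 0 & res$tukey <= 1))
  }
  expect_gte(powered, 95)
})

test_that("pooling rule is strict at the threshold", {
  expect_true(pool_decision(0.5))
  expect_false(pool_decision(0.01))
  expect_false(pool_decision(0.05))   # p == alpha keeps arms separate
  tab <- data.frame(value = 1:8,
                    group = c("CONT", "CONT", "NAC15", "NAC15", "NAC30",
                              "NAC30", "NAC45", "NAC45"))
  pooled <- pool_groups(tab)
  expect_equal(sort(unique(pooled$group)), c("CONT", "gNAC"))
})

test_that("two-group comparison is symmetric and validated", {
  set.seed(3)
  tab <- data.frame(value = rnorm(24), group = rep(c("A", "B"), each = 12))
  p1 <- compare_two_groups(tab, "parametric", c("A", "B"))
  p2 <- compare_two_groups(tab, "parametric", c("B", "A"))
  expect_equal(p1, p2)
  pnp <- compare_two_groups(tab, "nonparametric", c("A", "B"))
  expect_true(pnp >= 0 && pnp <= 1)
  expect_error(compare_two_groups(tab, "parametric", c("A", "C")), "empty")
})

test_that("published DPA effect size is detectable at the study scale", {
  # NAC30 vs CONT dermal proliferation area, published moments, n = 36
  rej <- 0
  for (s in 1:100) {
    set.seed(s)
    tab <- data.frame(
      value = c(scarkit:::rnorm_trunc0(36, 134280.2, 60364.62),
                scarkit:::rnorm_trunc0(36, 353591.2, 314148.8)),
      group = rep(c("CONT", "NAC30"), each = 36))
    if (compare_two_groups(tab, "parametric", c("NAC30", "CONT")) <= 0.05)
      rej <- rej + 1
  }
  expect_gt(rej, 60)
})

test_that("run_endpoint takes the pooled path for exchangeable arms", {
  set.seed(11)
  tab <- data.frame(value = rnorm(48, 10, 2),
                    group = rep(c("CONT", "NAC15", "NAC30", "NAC45"),
                                each = 12),
                    endpoint = "D", day = 7)
  res <- run_endpoint(tab)
  expect_s3_class(res, "comparison_result")
  expect_true(res$pooled)
  expect_false(is.na(res$gnac_vs_cont_p))
  expect_true(is.na(res$nac30_vs_cont_p))
  # deterministic given the table
  expect_identical(unclass(res), unclass(run_endpoint(tab)))
})

test_that("run_endpoint keeps arms separate under a strong NAC30 shift", {
  set.seed(12)
  v <- c(rnorm(12, 10, 1), rnorm(12, 10, 1), rnorm(12, 16, 1),
         rnorm(12, 10, 1))
  tab <- data.frame(value = v,
                    group = rep(c("CONT", "NAC15", "NAC30", "NAC45"),
                                each = 12),
                    endpoint = "DPA", day = 7)
  res <- run_endpoint(tab)
  expect_false(res$pooled)
  expect_lt(res$nac30_vs_cont_p, 0.05)
  expect_true(res$rejected)
  expect_true(all(res$tukey >= 0 & res$tukey <= 1))
})
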