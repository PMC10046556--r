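make_design <- function(n, a = 4, b = 3, seed = 42, values = NULL) {
  d <- expand.grid(subject = sprintf("s%02d", 1:n),
                   test = paste0("T", 1:a),
                   scenario = paste0("L", 0:(b - 1)),
                   stringsAsFactors = FALSE)
  if (is.null(values)) {
    set.seed(seed)
    d$value <- rnorm(nrow(d))
  } else {
    d$value <- values
  }
  d
}

test_that("F ratios and dfs match the base-R aov error-strata oracle", {
  d <- make_design(6, seed = 42)
  res <- rm_anova_2way(d)
  da <- d
  da$subject <- factor(da$subject); da$test <- factor(da$test)
  da$scenario <- factor(da$scenario)
  fit <- summary(aov(value ~ test * scenario + Error(subject / (test * scenario)),
                     data = da))
  f_aov <- c(fit[["Error: subject:test"]][[1]]["test", "F value"],
             fit[["Error: subject:scenario"]][[1]]["scenario", "F value"],
             fit[["Error: subject:test:scenario"]][[1]]["test:scenario", "F value"])
  expect_equal(res$F, f_aov, tolerance = 1e-10)
  expect_equal(res$df1, c(3, 2, 6))
  expect_equal(res$df2, c(15, 10, 30))
  # eta_g2 from the aov SS by hand
  ss <- function(tab, row) tab[[1]][row, "Sum Sq"]
  ss_s <- ss(fit[["Error: subject"]], "Residuals")
  ss_err <- ss(fit[["Error: subject:test"]], "Residuals") +
    ss(fit[["Error: subject:scenario"]], "Residuals") +
    ss(fit[["Error: subject:test:scenario"]], "Residuals")
  eta_a <- ss(fit[["Error: subject:test"]], "test") /
    (ss(fit[["Error: subject:test"]], "test") + ss_s + ss_err)
  expect_equal(res$eta_g2[1], eta_a, tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon matches the Box eigenvalue oracle", {
  for (seed in c(1, 7, 19)) {
    d <- make_design(8, seed = seed)
    res <- rm_anova_2way(d)
    # subject x level matrices of marginal means
    M_A <- tapply(d$value, list(d$subject, d$test), mean)
    M_B <- tapply(d$value, list(d$subject, d$scenario), mean)
    expect_equal(res$epsilon[1], oracle_box_epsilon(M_A), tolerance = 1e-10)
    expect_equal(res$epsilon[2], oracle_box_epsilon(M_B), tolerance = 1e-10)
    expect_true(all(res$epsilon >= 1 / res$df1 & res$epsilon <= 1))
  }
})

test_that("constant data give F = 0, and 2-level factors have epsilon 1", {
  d <- make_design(5, values = 5)
  res <- rm_anova_2way(d)
  expect_equal(res$F, c(0, 0, 0))
  expect_equal(res$p, c(1, 1, 1))
  expect_equal(res$eta_g2, c(0, 0, 0))
  d2 <- make_design(6, b = 2, seed = 3)
  expect_identical(rm_anova_2way(d2)$epsilon[2], 1)
})

test_that("sums of squares are conserved and the design is validated", {
  for (seed in 1:5) {
    d <- make_design(5, seed = seed)
    res <- rm_anova_2way(d)
    total <- sum(res$SS) + sum(res$SS_error) + attr(res, "SS_subject")
    expect_equal(total, attr(res, "SS_total"), tolerance = 1e-8)
  }
  d <- make_design(4)
  expect_error(rm_anova_2way(d[-1, ]), "offending cells")
  expect_error(rm_anova_2way(make_design(2)), "3 subjects")
})

test_that("a single-level second factor reduces to one-way RM-ANOVA", {
  d <- make_design(7, a = 4, b = 1, seed = 9)
  res <- rm_anova_2way(d)
  expect_equal(nrow(res), 1L)
  da <- d
  da$subject <- factor(da$subject); da$test <- factor(da$test)
  fit <- summary(aov(value ~ test + Error(subject / test), data = da))
  expect_equal(res$F, fit[["Error: subject:test"]][[1]]["test", "F value"],
               tolerance = 1e-10)
  M <- tapply(d$value, list(d$subject, d$test), mean)
  expect_equal(res$epsilon, oracle_box_epsilon(M), tolerance = 1e-10)
})

test_that("paired post hocs handle identical and zero-variance cells", {
  d <- make_design(6, seed = 12)
  cmp <- list(list(c("T1", "L0"), c("T1", "L0")),
              list(c("T1", "L0"), c("T2", "L1")))
  res <- posthoc_paired(d, cmp, family_size = 4)
  expect_equal(res$t[1], 0)
  expect_equal(res$p_corrected[1], 1)
  expect_false(res$degenerate[1])
  # hand-check the second comparison against t.test
  v1 <- d$value[d$test == "T1" & d$scenario == "L0"]
  v2 <- d$value[d$test == "T2" & d$scenario == "L1"]
  tt <- t.test(v1, v2, paired = TRUE)
  expect_equal(res$t[2], unname(tt$statistic))
  expect_equal(res$p_corrected[2], min(1, tt$p.value * 4))
  # constant non-zero difference -> degenerate, not infinite t
  dd <- d
  dd$value[dd$test == "T2" & dd$scenario == "L1"] <-
    dd$value[dd$test == "T1" & dd$scenario == "L0"] + 1
  res2 <- posthoc_paired(dd, cmp[2], family_size = 1)
  expect_true(res2$degenerate)
  expect_true(is.na(res2$t))
})

test_that("paired t rejection rate matches the noncentral-t power calculation", {
  n <- 20
  reps <- 400
  set.seed(77)
  rejections <- 0
  for (r in seq_len(reps)) {
    base <- rnorm(n)
    d <- data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
                    test = rep(c("T1", "T2"), each = n),
                    scenario = "L0",
                    value = c(base, base + rnorm(n) + 1))  # delta = 1 SD of diffs
    # differences have sd sqrt(1) = 1 and mean 1
    res <- posthoc_paired(d, list(list(c("T2", "L0"), c("T1", "L0"))),
                          family_size = 1)
    if (res$p_corrected < 0.05) rejections <- rejections + 1
  }
  power_hat <- rejections / reps
  power_exact <- oracle_paired_t_power(1, n)
  expect_lt(abs(power_hat - power_exact), 0.05)
})

test_that("mass-univariate Bonferroni divisors follow the unit count", {
  labs <- default_montage()
  pairs <- t(combn(labs, 2))
  units <- paste(pairs[, 1], pairs[, 2], sep = "-")
  expect_length(units, 276)
  set.seed(5)
  d <- expand.grid(subject = sprintf("s%d", 1:4), test = c("T1", "T2"),
                   scenario = c("L0", "L1"), unit = units,
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  res <- mass_univariate(d)
  expect_equal(attr(res, "divisor"), 276)
  dch <- expand.grid(subject = sprintf("s%d", 1:4), test = c("T1", "T2"),
                     scenario = c("L0", "L1"), unit = labs,
                     stringsAsFactors = FALSE)
  dch$value <- rnorm(nrow(dch))
  res_ch <- mass_univariate(dch)
  expect_equal(attr(res_ch, "divisor"), 24)
})

test_that("the family-wise error of Bonferroni flagging is controlled under the null", {
  n_units <- 60
  reps <- 120
  set.seed(99)
  fwe_hits <- 0
  grid <- expand.grid(subject = sprintf("s%02d", 1:10), test = paste0("T", 1:3),
                      scenario = paste0("L", 0:1), unit = seq_len(n_units),
                      stringsAsFactors = FALSE)
  for (r in seq_len(reps)) {
    grid$value <- rnorm(nrow(grid))
    res <- suppressMessages(mass_univariate(grid))
    if (any(res$significant)) fwe_hits <- fwe_hits + 1
  }
  expect_lte(fwe_hits / reps, 0.07)
})

test_that("trial-level scores collapse to cell means", {
  d <- data.frame(subject = "s1", test = "T1", scenario = "L0",
                  value = c(1, 2, 3, 4))
  expect_equal(condition_average(d)$value, 2.5)
  d2 <- d
  d2$value <- 7
  expect_equal(condition_average(d2)$value, 7)
  # a full session: 16 trials collapse to 4 scenario cells
  d3 <- expand.grid(subject = "s1", test = "T1", scenario = paste0("L", 0:3),
                    trial = 1:4, stringsAsFactors = FALSE)
  d3$value <- rnorm(16)
  expect_equal(nrow(condition_average(d3)), 4L)
  d4 <- d3[d3$scenario != "L3", ]
  d4$scenario <- factor(d4$scenario, levels = paste0("L", 0:3))
  expect_error(condition_average(d4), "empty")
})
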