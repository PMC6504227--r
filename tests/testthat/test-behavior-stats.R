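test_that("activity suppression ratio identities and invariances", {
  expect_equal(activity_suppression_ratio(90, 30), 0.25)
  expect_equal(activity_suppression_ratio(120, 120), 0.5)
  expect_equal(activity_suppression_ratio(200, 0), 0)
  expect_warning(r <- activity_suppression_ratio(0, 0), "undefined")
  expect_true(is.na(r))
  expect_error(activity_suppression_ratio(-1, 5), ">= 0")
  # scale invariance and range
  set.seed(61)
  train <- runif(50, 10, 500); test <- runif(50, 0, 500)
  r1 <- activity_suppression_ratio(train, test)
  expect_equal(r1, activity_suppression_ratio(7.3 * train, 7.3 * test))
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("Cohen's d: unit case, identity, invariances", {
  set.seed(62)
  a <- rnorm(40); b <- rnorm(40) + 1
  expect_lt(abs(cohens_d(a, b) - 1), 0.35)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  d0 <- cohens_d(a, b)
  expect_equal(cohens_d(2 * a + 5, 2 * b + 5), d0)  # scale+shift invariant
  expect_equal(cohens_d(b, a), d0)                  # magnitude convention
  expect_warning(dd <- cohens_d(c(1, 1), c(1, 1)), "pooled SD")
  expect_true(is.na(dd))
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
})

test_that("group_compare: null identity, paired contract, exact Wilcoxon", {
  x <- c(1.2, 3.4, 2.2, 4.1)
  r <- group_compare(x, x, "unpaired_t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df1, 6)
  expect_error(group_compare(1:4, 1:3, "paired_t"), "equal-length")

  # a={1,2,3} vs b={4,5,6}: U = 0; exact two-sided p = 2/choose(6,3) = 0.1
  rw <- group_compare(c(1, 2, 3), c(4, 5, 6), "wilcoxon")
  expect_equal(unname(rw$statistic), 0)
  expect_equal(rw$p, 0.1)
  rs <- group_compare(c(1, 2, 3), c(4, 5, 6), "wilcoxon",
                      w_convention = "rank_sum")
  expect_equal(unname(rs$statistic), 6)  # U + n1(n1+1)/2
})

test_that("exact Wilcoxon p equals full rank enumeration for small n", {
  set.seed(63)
  for (rep in 1:3) {
    a <- sample(1:100, 5); b <- sample(101:200, 4) - 100.5
    got <- group_compare(a, b, "wilcoxon")$p
    # enumeration oracle: all C(9,5) assignments of ranks to group a
    pooled <- c(a, b)
    ranks <- rank(pooled)
    Ua <- sum(ranks[1:5]) - 5 * 6 / 2
    combs <- combn(9, 5)
    Us <- apply(combs, 2, function(ii) sum(ranks[ii]) - 15)
    mu <- 5 * 4 / 2
    p_enum <- mean(abs(Us - mu) >= abs(Ua - mu))
    expect_equal(got, p_enum)
  }
})

test_that("two-factor ANOVA: no-variance F=0, empty-cell naming, type III = type I when balanced", {
  const <- cohort_from_values(list(`-:+/+` = rep(2, 4), `-:+/ls` = rep(2, 4),
                                   `+:+/+` = rep(2, 4), `+:+/ls` = rep(2, 4)))
  # R warns about the perfect fit; the degenerate result is what matters
  res <- suppressWarnings(two_factor_anova(const, "y"))
  expect_equal(res$statistic, rep(0, 3))
  expect_equal(res$p, rep(1, 3))

  missing_cell <- cohort_from_values(list(`-:+/+` = rnorm(4), `-:+/ls` = rnorm(4),
                                          `+:+/+` = rnorm(4), `+:+/ls` = rnorm(1)))
  expect_error(two_factor_anova(missing_cell, "y"), "cell \\(cre=\\+, genotype=\\+/ls\\)")

  set.seed(64)
  bal <- cohort_from_values(list(`-:+/+` = rnorm(6, 1), `-:+/ls` = rnorm(6, 2),
                                 `+:+/+` = rnorm(6, 1.2), `+:+/ls` = rnorm(6, 1.4)))
  t3 <- two_factor_anova(bal, "y")
  df <- as.data.frame(bal)
  t1 <- summary(aov(value ~ cre * genotype, data = df))[[1]]
  expect_equal(t3$statistic, t1[1:3, "F value"], tolerance = 1e-10)
  expect_equal(t3$p, t1[1:3, "Pr(>F)"], tolerance = 1e-10)
})

test_that("unbalanced type-III differs from sequential but stays calibrated", {
  set.seed(65)
  unb <- cohort_from_values(list(`-:+/+` = rnorm(12, 1), `-:+/ls` = rnorm(4, 2),
                                 `+:+/+` = rnorm(5, 1), `+:+/ls` = rnorm(9, 2)))
  t3 <- two_factor_anova(unb, "y")
  df <- as.data.frame(unb)
  t1 <- summary(aov(value ~ cre * genotype, data = df))[[1]]
  # interaction term is identical under any SS type
  expect_equal(t3$statistic[3], t1[3, "F value"], tolerance = 1e-10)
  expect_equal(t3$df2, rep(nrow(df) - 4, 3))
})

test_that("mixed RM ANOVA matches the balanced algebraic cross-check", {
  set.seed(66)
  n <- 8
  d <- expand.grid(animal_id = sprintf("a%02d", 1:(2 * n)),
                   within = c("pre", "post"), stringsAsFactors = FALSE)
  d$genotype <- ifelse(as.integer(sub("a", "", d$animal_id)) <= n, "+/+", "+/ls")
  d$cre <- "+"; d$tmx <- "-"; d$endpoint <- "rate"
  d$value <- rnorm(nrow(d)) + ifelse(d$genotype == "+/ls", 1.5, 0) +
    ifelse(d$within == "post", -0.8, 0) +
    ifelse(d$genotype == "+/ls" & d$within == "post", -1.2, 0)
  ct <- cohort_table(d)
  res <- mixed_rm_anova(ct, "rate", within = "within")
  expect_equal(res$df1, rep(1, 3))
  expect_equal(res$df2, c(2 * n - 2, 2 * n - 2, 2 * n - 2))

  # oracle for the within-stratum terms: ordinary two-factor ANOVA on
  # animal-mean-centered data (balanced design algebraic identity), with the
  # error df corrected for the (2n - 1) estimated animal means
  cen <- d
  am <- tapply(d$value, d$animal_id, mean)
  cen$value <- d$value - am[d$animal_id]
  t1 <- summary(aov(value ~ genotype * within, data = cen))[[1]]
  err_df <- 2 * n - 2
  ms_err <- t1["Residuals", "Sum Sq"] / err_df
  f_within <- (t1["within", "Sum Sq"] / 1) / ms_err
  f_int <- (t1["genotype:within", "Sum Sq"] / 1) / ms_err
  expect_equal(res$statistic[2], f_within, tolerance = 1e-8)
  expect_equal(res$statistic[3], f_int, tolerance = 1e-8)

  # between oracle: one-way ANOVA on animal means (SS in both numerator and
  # denominator scale by the number of within levels, so F is unchanged)
  amd <- data.frame(g = tapply(d$genotype, d$animal_id, `[`, 1), m = am)
  f_between <- summary(aov(m ~ g, data = amd))[[1]][1, "F value"]
  expect_equal(res$statistic[1], f_between, tolerance = 1e-8)

  # identical within-levels per animal: within-effect F = 0
  d0 <- d
  d0$value <- rep(rnorm(2 * n), 2)[match(d0$animal_id, unique(d0$animal_id))]
  res0 <- mixed_rm_anova(cohort_table(d0), "rate", within = "within")
  expect_equal(res0$statistic[2], 0)

  # missing within level: excluded with warning, df adjust
  d_miss <- d[!(d$animal_id == "a01" & d$within == "post"), ]
  expect_warning(res_m <- mixed_rm_anova(cohort_table(d_miss), "rate",
                                         within = "within"), "a01")
  expect_equal(res_m$df2[1], 2 * n - 3)
})

test_that("MANOVA: Pillai under null is calibrated; degenerate copies match univariate", {
  ps <- vapply(1:400, function(s) {
    ct <- simulate_seizure_cohort(sim_cohort_params(
      5, seizure_cells(rep(300, 4), rep(400, 4), rep(600, 4), sd = 30),
      seed = 7000 + s))
    res <- manova_pillai(ct)
    res$p[res$comparison == "genotype"]
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))

  # strong single-endpoint effect drives the joint test
  ct_eff <- simulate_seizure_cohort(sim_cohort_params(
    8, seizure_cells(c(300, 120, 300, 120), rep(400, 4), rep(600, 4), sd = 30),
    seed = 8))
  res_eff <- manova_pillai(ct_eff)
  expect_lt(res_eff$p[res_eff$comparison == "genotype"], 1e-4)

  # identical copies: collapses to the univariate ANOVA
  ct1 <- simulate_seizure_cohort(sim_cohort_params(
    6, seizure_cells(c(300, 200, 300, 200), rep(400, 4), rep(600, 4), sd = 25),
    seed = 9))
  dd <- as.data.frame(ct1)
  for (s in c("tc", "the"))
    dd$value[dd$endpoint == s] <- dd$value[dd$endpoint == "clonus"]
  expect_warning(res_deg <- manova_pillai(cohort_table(dd)), "singular")
  uni <- summary(aov(value ~ cre * genotype,
                     data = dd[dd$endpoint == "clonus", ]))[[1]]
  expect_equal(res_deg$p, uni[1:3, "Pr(>F)"], tolerance = 1e-8)
})

test_that("Bonferroni pairwise: arithmetic, two-group reduction, null cap", {
  set.seed(67)
  four <- cohort_from_values(list(`-:+/+` = rnorm(6, 1), `-:+/ls` = rnorm(6, 3),
                                  `+:+/+` = rnorm(6, 1), `+:+/ls` = rnorm(6, 3)))
  pw <- bonferroni_pairwise(four, "y")
  expect_equal(nrow(pw), 6)
  expect_equal(pw$p_adj, pmin(1, 6 * pw$p))

  two <- cohort_from_values(list(`-:+/+` = rnorm(6, 1), `-:+/ls` = rnorm(6, 2)))
  pw2 <- bonferroni_pairwise(two, "y")
  expect_equal(pw2$p_adj, pw2$p)  # single comparison: unadjusted

  null4 <- cohort_from_values(list(`-:+/+` = rep(c(1, 2), 3),
                                   `-:+/ls` = rep(c(1, 2), 3),
                                   `+:+/+` = rep(c(1, 2), 3),
                                   `+:+/ls` = rep(c(1, 2), 3)))
  expect_true(all(bonferroni_pairwise(null4, "y")$p_adj == 1))
})

test_that("cohort table validation and CSV round trip", {
  expect_error(cohort_table(data.frame(animal_id = 1, genotype = "het",
                                       cre = "-", tmx = "-", endpoint = "y",
                                       value = 1)), "genotype")
  ct <- cohort_from_values(list(`-:+/+` = 1:3, `-:+/ls` = 4:6))
  path <- tempfile(fileext = ".csv")
  write_cohort_table(ct, path)
  expect_equal(as.data.frame(read_cohort_table(path)), as.data.frame(ct))
  unlink(path)
})
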