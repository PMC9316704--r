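test_that("single and homogeneous inputs pool to the obvious answers", {
  one <- constancer:::new_effect(0.42, 0.05, 120)
  for (m in c("fixed", "random_dl")) {
    p <- pool_smd(one, m)
    expect_equal(p$smd, 0.42)
    expect_equal(p$se, sqrt(0.05))
    expect_equal(p$tau2, 0)
    expect_equal(p$k, 1)
  }

  two <- constancer:::new_effect(c(0.3, 0.3), c(0.08, 0.08), c(50, 50))
  p <- pool_smd(two, "fixed")
  expect_equal(p$smd, 0.3)
  expect_equal(p$se^2, 0.08 / 2, tolerance = 1e-14)
  expect_equal(p$q, 0)
  expect_equal(p$tau2, 0)
  expect_equal(p$i2, 0)
})

test_that("three crafted effects match the brute-force formulas", {
  eff <- constancer:::new_effect(c(0.1, 0.5, 0.9), c(0.04, 0.02, 0.08),
                                 c(100, 200, 50))
  for (m in c("fixed", "random_dl")) {
    p <- pool_smd(eff, m)
    o <- oracle_pool(eff$smd, eff$var, m)
    expect_equal(p$smd, o$smd, tolerance = 1e-10)
    expect_equal(p$se, o$se, tolerance = 1e-10)
    expect_equal(p$tau2, o$tau2, tolerance = 1e-10)
  }
})

test_that("pooling satisfies its invariants on random instances", {
  set.seed(42)
  for (i in 1:100) {
    eff <- random_effects(sample(2:12, 1))
    for (m in c("fixed", "random_dl")) {
      p <- pool_smd(eff, m)
      expect_true(p$smd >= min(eff$smd) - 1e-12 &&
                    p$smd <= max(eff$smd) + 1e-12)
      expect_true(p$tau2 >= 0)
      expect_true(p$i2 >= 0 && p$i2 <= 100)
      expect_true(p$se > 0)
    }
    # order invariance
    perm <- sample(nrow(eff))
    expect_equal(pool_smd(eff, "random_dl")$smd,
                 pool_smd(eff[perm, ], "random_dl")$smd, tolerance = 1e-12)
    # fixed-effect estimate equals independent loop
    expect_equal(pool_smd(eff, "fixed")$smd,
                 oracle_pool(eff$smd, eff$var, "fixed")$smd,
                 tolerance = 1e-12)
  }
})

test_that("DL reduces to fixed when tau2 is zero", {
  eff <- constancer:::new_effect(c(0.30, 0.31, 0.29), c(0.5, 0.5, 0.5),
                                 c(20, 20, 20))
  p_dl <- pool_smd(eff, "random_dl")
  p_f <- pool_smd(eff, "fixed")
  expect_equal(p_dl$tau2, 0)
  expect_identical(p_dl$smd, p_f$smd)
  expect_identical(p_dl$se, p_f$se)
})

test_that("pooling agrees with metafor as an independent cross-check", {
  skip_if_not_installed("metafor")
  set.seed(11)
  eff <- random_effects(8)
  f <- metafor::rma(yi = eff$smd, vi = eff$var, method = "EE")
  r <- metafor::rma(yi = eff$smd, vi = eff$var, method = "DL")
  expect_equal(pool_smd(eff, "fixed")$smd, as.numeric(f$beta), tolerance = 1e-8)
  p <- pool_smd(eff, "random_dl")
  expect_equal(p$smd, as.numeric(r$beta), tolerance = 1e-8)
  expect_equal(p$tau2, r$tau2, tolerance = 1e-8)
  expect_equal(p$q, as.numeric(r$QE), tolerance = 1e-8)
})

test_that("pooling rejects degenerate input", {
  expect_error(pool_smd(constancer:::new_effect(numeric(0), numeric(0),
                                                numeric(0))), "empty")
  expect_error(pool_smd(constancer:::new_effect(0.3, 0, 10)), "variances")
})

test_that("recency split partitions by maximum year and flags eligibility", {
  tr <- make_cont_review(2000:2004, c(0.5, 0.4, 0.45, 0.3, 0.2))
  s <- recency_split(tr)
  expect_equal(s$k_last, 1)
  expect_equal(s$k_dl, 4)
  expect_equal(s$k_all, s$k_dl + s$k_last)
  expect_true(s$eligible)
  expect_equal(s$year_of_last, 2004)
  expect_equal(s$year_diff, 2003 - 2000)   # span of the historical set
  expect_equal(s$year_diff_all, 4)

  # 4 trials, two tied at the max year -> only 2 historical -> ineligible
  tr2 <- make_cont_review(c(2000, 2001, 2005, 2005), c(0.5, 0.4, 0.3, 0.2))
  s2 <- recency_split(tr2)
  expect_equal(s2$k_last, 2)
  expect_equal(s2$k_dl, 2)
  expect_false(s2$eligible)

  expect_error(recency_split(make_cont_review(rep(2005, 4), 1:4 / 10)),
               "same-year")
})

test_that("last-set pooling is the equal-weight mean for equal variances", {
  tr <- make_cont_review(c(2000:2003, 2010, 2010), c(0.5, 0.4, 0.3, 0.35, 0, 0))
  # overwrite the two last-year trials so their SMDs are 0.2 and 0.4 with
  # equal variance: same arm sizes, sds 1, means equal to the target SMD
  tr$active_mean[5:6] <- c(0.2, 0.4)
  s <- recency_split(tr, method = "fixed", hedges = FALSE)
  e5 <- smd_continuous(0.2, 1, 50, 0, 1, 50, hedges = FALSE)
  e6 <- smd_continuous(0.4, 1, 50, 0, 1, 50, hedges = FALSE)
  w <- 1 / c(e5$var, e6$var)
  expect_equal(s$smd_lt$smd, sum(w * c(e5$smd, e6$smd)) / sum(w),
               tolerance = 1e-12)
  # variances differ slightly (d enters var), so compare to the weighted
  # mean; with identical inputs it is the plain mean
  tr$active_mean[5:6] <- c(0.3, 0.3)
  s2 <- recency_split(tr, method = "fixed", hedges = FALSE)
  expect_equal(s2$smd_lt$smd, 0.3, tolerance = 1e-12)
})

test_that("splits harmonize direction before pooling", {
  tr <- make_cont_review(2000:2004, rep(0.5, 5), direction = "harm")
  s <- recency_split(tr, hedges = FALSE)
  expect_equal(s$smd_all$smd, -0.5, tolerance = 1e-12)
})

test_that("split_corpus excludes same-year reviews and keeps the rest", {
  tr <- rbind(make_cont_review(2000:2004, rep(0.3, 5), review_id = "A"),
              make_cont_review(rep(2001, 4), rep(0.3, 4), review_id = "B"),
              make_bin_review(c(2000, 2001, 2003), c(30, 25, 20),
                              c(20, 20, 20), review_id = "C"))
  sp <- split_corpus(tr)
  expect_equal(length(sp$splits), 2)
  expect_equal(sp$same_year, "B")
  st <- splits_table(sp)
  expect_equal(st$review_id, c("A", "C"))
  expect_equal(st$eligible, c(TRUE, FALSE))
})

test_that("corpus summary counts match hand computation", {
  tr <- rbind(make_cont_review(2000:2006, rep(0.3, 7), review_id = "A"),
              make_cont_review(1990:1993, rep(0.2, 4), review_id = "B"),
              make_cont_review(c(2001, 2001, 2002), rep(0.1, 3),
                               review_id = "C"))
  cs <- corpus_summary(split_corpus(tr))
  expect_equal(cs$n_reviews, 3)
  expect_equal(cs$n_trials, 14)
  expect_equal(cs$trials_median, 4)
  expect_equal(cs$trials_mean, 14 / 3)
  expect_equal(cs$year_min, 1990)
  expect_equal(cs$year_max, 2006)
  expect_equal(cs$n_eligible, 2)
})
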