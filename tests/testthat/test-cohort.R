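test_that("BCVA change and success follow the logMAR sign convention", {
  expect_equal(bcva_change(1.0, 0.6), 0.4)
  expect_equal(bcva_change(0.5, 0.5), 0.0)
  expect_equal(bcva_change(0.3, 0.5), -0.2)
  expect_true(classify_success(1.0, 0.7))     # boundary inclusive
  expect_false(classify_success(1.0, 0.71))
  expect_true(classify_success(0.2, -0.1))
})

test_that("Mann-Whitney exact path matches full-enumeration probabilities", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.10)
  # exhaustive check for all tie-free splits of ranks 1..n, n <= 10
  for (n in c(5, 8, 10)) {
    for (nx in 1:(n - 1)) {
      splits <- combn(n, nx)
      # enumeration oracle: null distribution of U over all labelings
      u_all <- apply(splits, 2, function(s) sum(s) - nx * (nx + 1) / 2)
      for (k in seq_len(min(ncol(splits), 12))) {
        s <- splits[, k]
        u_obs <- sum(s) - nx * (nx + 1) / 2
        p_enum <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
        got <- mann_whitney(seq_len(n)[s], seq_len(n)[-s])
        expect_equal(got$p_value, p_enum, tolerance = 1e-12)
        expect_equal(unname(got$statistic), u_obs)
      }
    }
  }
})

test_that("Mann-Whitney identities and tie handling", {
  set.seed(3)
  for (i in 1:15) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1))
    ux <- unname(mann_whitney(x, y)$statistic)
    uy <- unname(mann_whitney(y, x)$statistic)
    expect_equal(ux + uy, length(x) * length(y))
  }
  v <- c(1, 2, 3, 7, 9, 11, 13, 15)
  expect_equal(mann_whitney(v, v)$p_value, 1.0)  # identical multisets
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("repeated-measures ANOVA partitions subject and visit variance", {
  set.seed(8)
  m <- cbind(rnorm(12), rnorm(12, 0.4))
  ra <- rm_anova(m)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(unname(ra$statistic), unname(tt$statistic^2))  # F = t^2 at v = 2
  expect_equal(ra$p_value, tt$p.value)
  expect_equal(ra$effect$df, c(1, 11))
  # constant subjects: no visit effect
  mc <- matrix(rep(c(1, 5, 3, 2), times = 3), 4)
  expect_equal(unname(rm_anova(mc)$statistic), 0)
  expect_equal(rm_anova(mc)$p_value, 1)
  # shift invariance
  m3 <- matrix(rnorm(30), 10, 3)
  expect_equal(unname(rm_anova(m3)$statistic),
               unname(rm_anova(m3 + 100)$statistic))
  m3[2, 3] <- NA
  expect_error(rm_anova(m3), "missing")
  expect_error(rm_anova(matrix(1:3, 3, 1)), "visits")
})

test_that("contingency test routes to Fisher or chi-square and reports ad/bc", {
  ft <- contingency_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ft$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_match(ft$method, "Fisher")
  sym <- contingency_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$effect$odds_ratio, 1.0)
  expect_equal(sym$p_value, 1.0)
  big <- contingency_test(matrix(c(20, 10, 5, 15), 2))
  expect_equal(big$effect$odds_ratio, 6.0)
  expect_match(big$method, "chi-square")
  # Fisher p equals the hypergeometric enumeration on random small tables
  set.seed(12)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || !any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)) next
    k <- tab[1, 1]; m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
    support <- max(0, n1 - m2):min(n1, m1)
    d <- dhyper(support, m1, m2, n1)
    expect_equal(sum(d), 1, tolerance = 1e-12)       # support sums to one
    p_enum <- sum(d[d <= dhyper(k, m1, m2, n1) * (1 + 1e-7)])
    expect_equal(contingency_test(tab)$p_value, p_enum, tolerance = 1e-7)
  }
  # Haldane-Anscombe correction with a zero cell
  hz <- contingency_test(matrix(c(8, 0, 2, 6), 2))
  expect_equal(hz$effect$odds_ratio, (8.5 * 6.5) / (0.5 * 2.5))
  expect_error(contingency_test(matrix(0L, 2, 2)), "all-zero")
})

test_that("logistic OR on a binary predictor equals the 2x2 cross-ratio", {
  set.seed(31)
  for (i in 1:10) {
    tab <- matrix(sample(3:25, 4), 2)  # exposed/unexposed x success/failure
    x <- rep(c(1, 1, 0, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    y <- rep(c(1, 0, 1, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    u <- univariate_logistic(x, y)
    expect_equal(u$effect$odds_ratio,
                 (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
                 tolerance = 1e-6)
  }
  # balanced independence: OR exactly 1, p = 1
  x <- rep(c(1, 0), each = 20)
  y <- rep(c(1, 0, 1, 0), each = 10)
  u0 <- univariate_logistic(x, y)
  expect_equal(u0$effect$odds_ratio, 1.0, tolerance = 1e-9)
  expect_gt(u0$p_value, 0.99)
  expect_error(univariate_logistic(rnorm(10), rep(1, 10)), "constant")
})

test_that("logistic regression recovers a known slope and flags separation", {
  set.seed(7)
  betas <- replicate(50, {
    x <- rnorm(400)
    y <- rbinom(400, 1, plogis(-0.3 + 1.5 * x))
    unname(univariate_logistic(x, y)$statistic)
  })
  expect_lt(abs(mean(betas) - 1.5), 0.3)
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  sep <- univariate_logistic(xs, ys)
  expect_true(sep$effect$separated)
  expect_null(sep$effect$odds_ratio)
})

test_that("backward selection implements the entry/stay screening protocol", {
  set.seed(19)
  n <- 120
  strong <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * strong))
  d <- data.frame(y = y, strong = strong,
                  noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  bs <- backward_selection(d, "y", c("strong", "noise1", "noise2", "noise3"))
  expect_identical(bs$selected, "strong")
  expect_lt(bs$univariate$p[1], 0.01)
  expect_false(bs$null_model)
  # deterministic rerun
  bs2 <- backward_selection(d, "y", c("strong", "noise1", "noise2", "noise3"))
  expect_identical(bs$model, bs2$model)
  # nothing passes the entry screen: null model
  d2 <- data.frame(y = rep(c(0, 1), 30), a = rep(c(1, 0, 0, 1), 15))
  set.seed(4); d2$b <- rnorm(60)
  quiet <- backward_selection(d2, "y", c("b"))
  expect_true(quiet$null_model)
  expect_length(quiet$selected, 0)
})

test_that("Spearman inter-eye correlation uses midranks and exact small-n p", {
  expect_equal(unname(paired_correlation(1:5, 2 * (1:5))$statistic), 1.0)
  expect_equal(unname(paired_correlation(1:5, 5:1)$statistic), -1.0)
  r <- paired_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(unname(r$statistic), 0.6)
  expect_match(r$method, "exact")
  expect_match(paired_correlation(rnorm(20), rnorm(20))$method, "approximation")
  expect_error(paired_correlation(1:2, 2:1), "n >= 3")
})

test_that("cohort summaries report n/mean/SD/median/IQR and percentages", {
  rec <- data.frame(group = "all", visit = "v1",
                    x = c(1, 2, 3, 4), lens = c("ph", "ph", "ps", "ph"))
  s <- summarize_cohort(rec, variables = c("x", "lens"))
  expect_equal(s$numeric$median, 2.5)
  expect_equal(s$numeric$q1, 1.75)           # linear interpolation
  expect_equal(s$numeric$n, 4L)
  expect_equal(s$categorical$n, c(3L, 1L))
  expect_equal(s$categorical$pct, c(75, 25))
  sc <- summarize_cohort(data.frame(group = "g", visit = "v", x = rep(7, 5)))
  expect_equal(sc$numeric$sd, 0)
  # 25 of 44 eyes: 56.8%
  cnt <- data.frame(group = "RRD", visit = "m6",
                    success = rep(c("yes", "no"), c(25, 19)))
  p <- summarize_cohort(cnt, variables = "success")$categorical
  expect_equal(round(p$pct[p$level == "yes"], 1), 56.8)
})

test_that("simulated cohorts mirror the study structure", {
  rec <- simulate_rrd_cohort(44, seed = 2)
  expect_equal(nrow(rec), 44 * 2 * 4)
  expect_setequal(unique(rec$visit), c("preop", "m1", "m3", "m6"))
  # RRD preop metrics are unmeasurable; BCVA is
  pre_rrd <- rec[rec$group == "RRD" & rec$visit == "preop", ]
  expect_true(all(is.na(pre_rrd$vad_scp)))
  expect_true(all(is.finite(pre_rrd$bcva_logmar)))
  # determinism
  expect_identical(rec, simulate_rrd_cohort(44, seed = 2))
  fs <- functional_success_frame(rec)
  expect_equal(nrow(fs), 44)
  expect_true(all(fs$improvement == fs$preop_bcva - fs$bcva_m6))
  # surrogate preop metrics come from the fellow eye
  fel_pre <- rec[rec$group == "fellow" & rec$visit == "preop", ]
  expect_equal(fs$vad_scp[match(fel_pre$eye_id, fs$eye_id)], fel_pre$vad_scp)
  # visit matrices for the two analysis variants
  va <- visit_matrix(rec, "vad_scp", use_surrogate_preop = TRUE)
  vb <- visit_matrix(rec, "vad_scp", use_surrogate_preop = FALSE)
  expect_equal(dim(va), c(44, 4))
  expect_equal(dim(vb), c(44, 3))
  expect_false(anyNA(va))
  expect_equal(va[, -1], vb, ignore_attr = TRUE)
})
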