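# independent enumeration oracles, written against the definitions only
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  N <- length(r)
  obs <- sum(r[seq_len(n1)])
  ws <- apply(combn(N, n1), 2, function(i) sum(r[i]))
  mu <- n1 * (N + 1) / 2
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

oracle_signedrank_p <- function(pre, post) {
  d <- (post - pre)
  d <- d[d != 0]
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

oracle_spearman_p <- function(a, b) {
  n <- length(a)
  obs <- abs(cor(rank(a), rank(b)))
  perm_rho <- function(p) cor(rank(a), rank(b)[p])
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(q) c(v[i], q)))
    out
  }
  ps <- perms(seq_len(n))
  mean(vapply(ps, function(p) abs(perm_rho(p)), numeric(1)) >= obs - 1e-9)
}

test_that("rank-sum exact p equals full enumeration on all small splits", {
  vals <- c(2.3, 0.1, 1.7, 4.2, 3.3, 0.9, 2.8, 5.1)
  for (n1 in 3:5) {
    picks <- combn(8, n1)
    for (j in seq(1, ncol(picks), by = 7)) { # subsample splits for speed
      x <- vals[picks[, j]]
      y <- vals[-picks[, j]]
      ct <- wilcoxon_rank_sum(x, y)
      expect_equal(ct$p, oracle_ranksum_p(x, y), tolerance = 1e-12)
    }
  }
  # a tied fixture exercises the midrank enumeration path
  x <- c(1, 2, 2, 5)
  y <- c(2, 3, 6, 7)
  expect_equal(wilcoxon_rank_sum(x, y)$p, oracle_ranksum_p(x, y),
               tolerance = 1e-12)
  # most extreme split of {1..6}: exact two-sided p = 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1,
               tolerance = 1e-12)
})

test_that("rank-sum handles identity and label-swap symmetry", {
  x <- c(1, 2, 3, 4)
  expect_warning(r <- wilcoxon_rank_sum(rep(1, 4), rep(1, 4)), "identical")
  expect_equal(r$p, 1)
  a <- c(0.3, 1.2, 2.2, 0.7, 1.9)
  b <- c(1.1, 2.5, 3.0, 0.9, 2.1, 1.4)
  r1 <- wilcoxon_rank_sum(a, b)
  r2 <- wilcoxon_rank_sum(b, a)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$z, -r2$z, tolerance = 1e-9)
  expect_true(r1$p > 0 && r1$p <= 1)
  # large-sample mode agrees with the base implementation
  set.seed(8)
  x2 <- rnorm(15)
  y2 <- rnorm(18, 0.5)
  ours <- wilcoxon_rank_sum(x2, y2)
  ref <- wilcox.test(x2, y2, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("signed-rank exact p equals the 2^n sign enumeration", {
  pre <- c(0.31, 0.45, 0.12, 0.80, 0.55, 0.66)
  post <- c(0.42, 0.41, 0.25, 0.94, 0.57, 0.60)
  ct <- wilcoxon_signed_rank(pre, post)
  expect_equal(ct$p, oracle_signedrank_p(pre, post), tolerance = 1e-12)
  # tied absolute differences go through midrank enumeration
  pre2 <- c(1, 2, 3, 4, 5, 6)
  post2 <- c(2, 1, 5, 6, 7, 8) # |d| ties
  expect_equal(wilcoxon_signed_rank(pre2, post2)$p,
               oracle_signedrank_p(pre2, post2), tolerance = 1e-12)
  # uniform improvement: W (smaller rank sum) hits the floor of 0
  up <- wilcoxon_signed_rank(1:8, 1:8 + 0.5)
  expect_equal(unname(up$statistic["W"]), 0)
  expect_lt(up$p, 0.01)
  # symmetric alternation of +/- eps is null-like
  d <- rep(c(0.1, -0.1), 4)
  sym <- wilcoxon_signed_rank(rep(0, 8), d)
  expect_gt(sym$p, 0.6)
  expect_warning(z <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(z$p, 1)
  # zero differences are dropped before ranking (classical procedure)
  ct2 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7),
                              c(1, 2.4, 3.3, 4.8, 5.2, 6.9, 7.1))
  expect_equal(unname(ct2$n["n"]), 6)
})

test_that("Welch t matches the reported group summary and raw data", {
  ct <- welch_t(list(mean = 5.75, sd = 1.55, n = 12),
                list(mean = 8.21, sd = 2.15, n = 19))
  expect_equal(unname(ct$statistic["t"]), -3.701, tolerance = 0.02)
  expect_lt(ct$p, 0.001)

  set.seed(3)
  x <- rnorm(10, 5, 2)
  y <- rnorm(14, 6, 1)
  raw <- welch_t(x, y)
  summ <- welch_t(list(mean = mean(x), sd = sd(x), n = 10),
                  list(mean = mean(y), sd = sd(y), n = 14))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  ref <- t.test(x, y)
  expect_equal(unname(raw$statistic["t"]), unname(ref$statistic),
               tolerance = 1e-9)
  expect_equal(raw$p, ref$p.value, tolerance = 1e-9)
  # identical groups -> t = 0
  expect_equal(unname(welch_t(c(x, 1), c(x, 1))$statistic["t"]), 0)
  expect_error(welch_t(rep(2, 5), rep(2, 7)), "variance")
  # pooled flag reproduces the classical Student form
  pooled <- welch_t(x, y, pooled = TRUE)
  ref2 <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(pooled$statistic["t"]), unname(ref2$statistic),
               tolerance = 1e-9)
})

test_that("Pearson chi-square matches the closed form and the sex table", {
  tab <- matrix(c(8, 4, 16, 3), 2, byrow = TRUE)
  ct <- pearson_chi2(tab)
  expect_equal(unname(ct$statistic["chi2"]), 1.295, tolerance = 5e-4)
  expect_equal(unname(pearson_chi2(matrix(5, 2, 2))$statistic["chi2"]), 0)
  set.seed(11)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 8) + 1, 2)
    ours <- pearson_chi2(t2)
    ref <- suppressWarnings(chisq.test(t2, correct = FALSE))
    expect_equal(unname(ours$statistic["chi2"]), unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Spearman rho matches exact enumeration and detects monotonicity", {
  a <- c(3.2, 1.1, 4.8, 2.0, 5.5, 0.3, 3.9)
  b <- c(2.5, 1.8, 4.1, 3.3, 5.0, 1.2, 2.9)
  cr <- spearman_rho(a, b, n_boot = 200, seed = 1)
  expect_equal(cr$p, oracle_spearman_p(a, b), tolerance = 1e-12)
  expect_equal(cr$method, "exact_permutation")

  up <- spearman_rho(1:8, (1:8)^3, n_boot = 100)
  expect_equal(up$rho, 1)
  dn <- spearman_rho(1:8, -(1:8) + 0.5, n_boot = 100)
  expect_equal(dn$rho, -1)
  expect_error(spearman_rho(rep(1, 6), 1:6), "constant")

  # large-sample t approximation against the base implementation
  set.seed(12)
  x <- rnorm(25)
  y <- x + rnorm(25)
  ours <- spearman_rho(x, y, n_boot = 100, seed = 2)
  ref <- cor.test(x, y, method = "spearman")
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 0.02)
  # bootstrap CI is seeded-deterministic and brackets rho
  again <- spearman_rho(x, y, n_boot = 100, seed = 2)
  expect_identical(ours$ci, again$ci)
  expect_true(ours$ci[1] <= ours$rho && ours$rho <= ours$ci[2])
})

test_that("contrast tables have the Table-2 shape and internal consistency", {
  set.seed(21)
  subj <- sprintf("S%02d", 1:20)
  grp <- rep(c("UWS", "MCS"), each = 10)
  rpt <- expand.grid(subject_id = subj, condition = c("rest", "task"),
                     region = c("frontal", "parietal"),
                     band = analysis_bands()$band,
                     stringsAsFactors = FALSE)
  rpt$group <- grp[match(rpt$subject_id, subj)]
  rpt$rel_power <- runif(nrow(rpt), 0.05, 0.4)
  # plant one strong within-MCS effect: parietal theta up under task
  sel <- rpt$group == "MCS" & rpt$region == "parietal" &
    rpt$band == "theta" & rpt$condition == "task"
  rpt$rel_power[sel] <- rpt$rel_power[sel] + 0.5
  tabs <- build_contrast_tables(rpt)
  expect_equal(nrow(tabs$table2_within), 2 * 5 * 2) # region x band x group
  expect_equal(nrow(tabs$table2_between), 2 * 5)
  pv <- docbci:::contrast_pvals(tabs)
  expect_length(pv, 20 + 30)
  expect_true(all(pv > 0 & pv <= 1))
  hit <- tabs$table2_within[tabs$table2_within$region == "parietal" &
                              tabs$table2_within$band == "theta" &
                              tabs$table2_within$group == "MCS", ]
  expect_lt(hit$p, 0.01)
  expect_gt(hit$delta_median, 0.3)
  # quartile convention: type-7 linear interpolation
  v <- c(1, 2, 3, 10)
  expect_equal(unname(docbci:::quartile_summary(v)),
               unname(quantile(v, c(0.5, 0.25, 0.75), type = 7)))
})
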