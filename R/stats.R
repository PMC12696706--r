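# Nonparametric group-contrast battery: Wilcoxon rank-sum / signed-rank
# with exact small-sample modes and midrank tie handling, Welch t,
# Pearson chi-square, Spearman correlation with bootstrap CI, and the
# assembly of the Table-1/Table-2-shaped outputs.

# median (Q1, Q3), type-7 linear interpolation everywhere
quartile_summary <- function(v) {
  q <- quantile(v, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

new_group_contrast <- function(method, statistic, z, p, n, summaries,
                               extra = list()) {
  structure(c(list(method = method, statistic = statistic, z = z, p = p,
                   n = n, summaries = summaries), extra),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  st <- paste(names(x$statistic), signif(unname(x$statistic), 4),
              sep = "=", collapse = ", ")
  cat(sprintf("<%s> %s, Z=%s, p=%.4g\n", x$method, st,
              signif(x$z, 4), x$p))
  invisible(x)
}

tie_correction_ranksum <- function(r, N) {
  t <- table(r)
  sum(t^3 - t) / (N * (N - 1))
}

#' Wilcoxon rank-sum test (Mann-Whitney) for two independent samples
#'
#' Midranks for ties. For combined sample sizes up to `exact_max` the
#' two-sided p comes from the exact permutation distribution (the
#' classical rank-sum distribution when there are no ties, full subset
#' enumeration with ties); larger samples use the normal approximation
#' with continuity and tie correction.
#'
#' @param x,y numeric samples (each of length at least 3).
#' @param exact_max largest combined n for which the exact mode is used.
#' @return a `group_contrast` with statistics `W` (rank sum of `x`),
#'   `U` (Mann-Whitney), standardized `z`, two-sided `p`, and type-7
#'   quartile summaries of both samples.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- anyDuplicated(pooled) > 0
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_correction_ranksum(r, N))
  all_equal <- sig2 <= 0
  z <- if (all_equal) 0
       else (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  if (all_equal) {
    warning("all values identical across both samples")
    p <- 1
  } else if (N <= exact_max) {
    if (!ties) {
      p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                          1 - stats::pwilcox(U - 1, n1, n2)))
    } else {
      # enumerate every assignment of n1 pooled ranks to group x
      us <- apply(combn(N, n1), 2, function(i) sum(r[i])) -
        n1 * (n1 + 1) / 2
      eps <- 1e-9
      lo <- min(U, 2 * mu - U)
      p <- min(1, mean(us <= lo + eps | us >= 2 * mu - lo - eps))
    }
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  new_group_contrast("wilcoxon_rank_sum",
                     c(W = W, U = U), z, p, c(n1 = n1, n2 = n2),
                     list(x = quartile_summary(x), y = quartile_summary(y)))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of zero are dropped (classical procedure), midranks are
#' used for tied absolute differences. Exact p (signed-rank distribution,
#' or full sign enumeration under ties) for up to `exact_max` non-zero
#' pairs; normal approximation with continuity and tie correction beyond.
#' The reported `W` is the smaller of the positive- and negative-rank
#' sums, so a uniform shift gives the floor value 0.
#'
#' @param pre,post paired numeric vectors.
#' @param exact_max largest non-zero-pair count for the exact mode.
#' @return a `group_contrast` with statistics `W`, `W_plus`, `W_minus`,
#'   standardized `z`, two-sided `p`, and a quartile summary of the
#'   differences.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_max = 15) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[d != 0]
  if (!length(d)) {
    warning("all differences zero")
    return(new_group_contrast("wilcoxon_signed_rank",
                              c(W = 0, W_plus = 0, W_minus = 0), 0, 1,
                              c(n = 0), list(delta = c(median = 0, q1 = 0,
                                                       q3 = 0))))
  }
  if (length(d) < 5) stop("fewer than 5 non-zero pairs")
  n <- length(d)
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  wminus <- sum(r[d < 0])
  W <- min(wplus, wminus)
  mu <- n * (n + 1) / 4
  ties <- anyDuplicated(abs(d)) > 0
  t <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(t^3 - t) / 48
  z <- (wplus - mu - sign(wplus - mu) * 0.5) / sqrt(sig2)
  if (n <= exact_max) {
    if (!ties) {
      p <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
    } else {
      # enumerate all 2^n sign assignments of the midranks
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      wp <- as.numeric(signs %*% r)
      eps <- 1e-9
      lo <- min(wplus, 2 * mu - wplus)
      p <- min(1, mean(wp <= lo + eps | wp >= 2 * mu - lo - eps))
    }
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  new_group_contrast("wilcoxon_signed_rank",
                     c(W = W, W_plus = wplus, W_minus = wminus), z, p,
                     c(n = n),
                     list(delta = quartile_summary(post - pre)))
}

#' Welch's unequal-variance t test
#'
#' Accepts raw samples or `(mean, sd, n)` summary lists, with the
#' Welch-Satterthwaite degrees of freedom; the pooled-variance Student
#' form is available behind a flag.
#'
#' @param x,y numeric vectors, or lists with elements `mean`, `sd`, `n`.
#' @param pooled use the pooled-variance (classical Student) form.
#' @return a `group_contrast` with statistic `t`, `df`, two-sided `p`,
#'   and mean +/- SD summaries.
#' @export
#' @examples
#' welch_t(list(mean = 5.75, sd = 1.55, n = 12),
#'         list(mean = 8.21, sd = 2.15, n = 19))
welch_t <- function(x, y, pooled = FALSE) {
  s <- function(v) {
    if (is.list(v)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(v)), v$n >= 2)
      list(m = v$mean, s = v$sd, n = v$n)
    } else {
      stopifnot(length(v) >= 2)
      list(m = mean(v), s = sd(v), n = length(v))
    }
  }
  a <- s(x); b <- s(y)
  if (a$s == 0 && b$s == 0) stop("zero variance in both groups")
  if (pooled) {
    sp2 <- ((a$n - 1) * a$s^2 + (b$n - 1) * b$s^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$s^2 / a$n; vb <- b$s^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tstat <- (a$m - b$m) / se
  p <- 2 * pt(-abs(tstat), df)
  new_group_contrast(if (pooled) "student_t" else "welch_t",
                     c(t = tstat, df = df), tstat, p,
                     c(n1 = a$n, n2 = b$n),
                     list(x = c(mean = a$m, sd = a$s),
                          y = c(mean = b$m, sd = b$s)))
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected Pearson statistic `n (ad - bc)^2 / (r1 r2 c1 c2)` with the
#' chi-square p on 1 degree of freedom; Fisher's exact p is reported
#' alongside.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return a `group_contrast` with statistics `chi2` and the Fisher exact
#'   p in `fisher_p`.
#' @export
#' @examples
#' pearson_chi2(matrix(c(8, 4, 16, 3), 2, byrow = TRUE))
pearson_chi2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table")
  n <- sum(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fp <- fisher.test(tab)$p.value
  new_group_contrast("pearson_chi2", c(chi2 = chi2), sqrt(chi2), p,
                     c(n = n), list(table = tab),
                     extra = list(fisher_p = fp))
}

# all permutations of 1..n as a matrix (rows), built incrementally
all_perms <- function(n) {
  P <- matrix(1L, 1, 1)
  for (k in 2:n) {
    blocks <- lapply(seq_len(k), function(pos)
      cbind(P[, seq_len(pos - 1L), drop = FALSE], k,
            P[, seq_len(k - pos) + (pos - 1L), drop = FALSE]))
    P <- do.call(rbind, blocks)
  }
  P
}

#' Spearman rank correlation with bootstrap confidence interval
#'
#' Midrank-based rho. The two-sided p uses the exact permutation
#' distribution for n up to `exact_max` and the t approximation beyond;
#' a seeded percentile bootstrap (default 2000 resamples) supplies the
#' 95% interval.
#'
#' @param a,b numeric vectors of equal length (n at least 3).
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap (and nothing else).
#' @param exact_max largest n for the exact permutation p.
#' @return list of class `correlation_result`: `rho`, `p`, `n`, `ci`
#'   (2.5/97.5 percentiles), `method`.
#' @export
spearman_rho <- function(a, b, n_boot = 2000, seed = 1, exact_max = 9) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0) stop("constant input: rho undefined")
  n <- length(a)
  ra <- rank(a); rb <- rank(b)
  rho <- cor(ra, rb)
  if (n <= exact_max) {
    P <- all_perms(n)
    rac <- ra - mean(ra)
    rbc <- rb - mean(rb)
    denom <- sqrt(sum(rac^2) * sum(rbc^2))
    rhos <- as.numeric(matrix(rbc[P], nrow(P)) %*% rac) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    method <- "exact_permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * pt(-abs(tt), n - 2)
    method <- "t_approximation"
  }
  ci <- with_seed(derive_seed(seed, "spearman_boot"), {
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(a[idx]) == 0 || sd(b[idx]) == 0) return(NA_real_)
      cor(rank(a[idx]), rank(b[idx]))
    }, numeric(1))
    quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE, type = 7)
  })
  structure(list(rho = rho, p = p, n = n, ci = ci, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (95%% CI %.3f..%.3f), p = %.4g, n = %d [%s]\n",
              x$rho, x$ci[1], x$ci[2], x$p, x$n, x$method))
  invisible(x)
}

#' Assemble the Table-1/Table-2-shaped statistical outputs
#'
#' For each of frontal/parietal x five bands: the within-group signed-rank
#' test (rest vs task) per group with median (Q1, Q3) summaries and the
#' per-subject delta, and the between-group rank-sum tests at rest, at
#' task, and on the delta. Alongside: the demographics table (Welch t and
#' chi-square), the accuracy contrast, and the attention-index / CRS-R
#' Spearman correlation. Raw p values are reported for all 10 region-band
#' blocks without multiplicity correction; the count of contrasts is
#' attached so readers can judge the multiple-testing burden.
#'
#' @param rpt relative-power table: data.frame with columns `subject_id`,
#'   `group`, `condition` (`rest`/`task`), `region`, `band`, `rel_power`.
#' @param sessions session results from [run_cohort_sessions()] (may be
#'   `NULL` to skip accuracy/correlation outputs).
#' @param meta cohort metadata from [cohort_metadata()] (may be `NULL` to
#'   skip the demographics table).
#' @param regions regions to tabulate.
#' @return list with `table2_within`, `table2_between`, `table1`,
#'   `accuracy`, `correlation`, `skipped`.
#' @export
build_contrast_tables <- function(rpt, sessions = NULL, meta = NULL,
                                  regions = c("frontal", "parietal")) {
  bands <- analysis_bands()$band
  within <- NULL
  between <- NULL
  skipped <- character(0)
  for (rg in regions) for (bd in bands) {
    cell <- rpt[rpt$region == rg & rpt$band == bd, , drop = FALSE]
    wide <- merge(
      cell[cell$condition == "rest", c("subject_id", "group", "rel_power")],
      cell[cell$condition == "task", c("subject_id", "rel_power")],
      by = "subject_id", suffixes = c("_rest", "_task"))
    if (!nrow(wide)) {
      skipped <- c(skipped, paste(rg, bd, "no complete pairs"))
      next
    }
    for (g in c("MCS", "UWS")) {
      gw <- wide[wide$group == g, , drop = FALSE]
      if (nrow(gw) < 5) {
        skipped <- c(skipped, paste(rg, bd, g, "too few pairs"))
        next
      }
      ct <- wilcoxon_signed_rank(gw$rel_power_rest, gw$rel_power_task)
      rest_q <- quartile_summary(gw$rel_power_rest)
      task_q <- quartile_summary(gw$rel_power_task)
      delta_q <- quartile_summary(gw$rel_power_task - gw$rel_power_rest)
      within <- rbind(within, data.frame(
        region = rg, band = bd, group = g, n = nrow(gw),
        rest_median = rest_q[1], rest_q1 = rest_q[2], rest_q3 = rest_q[3],
        task_median = task_q[1], task_q1 = task_q[2], task_q3 = task_q[3],
        W = unname(ct$statistic["W"]), Z = ct$z, p = ct$p,
        delta_median = delta_q[1], delta_q1 = delta_q[2],
        delta_q3 = delta_q[3], row.names = NULL))
    }
    m <- wide[wide$group == "MCS", , drop = FALSE]
    u <- wide[wide$group == "UWS", , drop = FALSE]
    if (nrow(m) >= 3 && nrow(u) >= 3) {
      bt <- function(vm, vu) wilcoxon_rank_sum(vm, vu)
      r_rest <- bt(m$rel_power_rest, u$rel_power_rest)
      r_task <- bt(m$rel_power_task, u$rel_power_task)
      r_delta <- bt(m$rel_power_task - m$rel_power_rest,
                    u$rel_power_task - u$rel_power_rest)
      between <- rbind(between, data.frame(
        region = rg, band = bd,
        z_rest = r_rest$z, p_rest = r_rest$p,
        z_task = r_task$z, p_task = r_task$p,
        z_delta = r_delta$z, p_delta = r_delta$p, row.names = NULL))
    } else {
      skipped <- c(skipped, paste(rg, bd, "too few subjects between-group"))
    }
  }

  table1 <- NULL
  if (!is.null(meta)) {
    m <- meta[meta$group == "MCS", ]
    u <- meta[meta$group == "UWS", ]
    row1 <- function(label, ct, extra = NA_real_)
      data.frame(variable = label,
                 uws = paste0(round(ct$summaries$y["mean"], 2), " ± ",
                              round(ct$summaries$y["sd"], 2)),
                 mcs = paste0(round(ct$summaries$x["mean"], 2), " ± ",
                              round(ct$summaries$x["sd"], 2)),
                 statistic = unname(ct$statistic[1]), p = ct$p,
                 fisher_p = extra, row.names = NULL)
    t_age <- welch_t(m$age, u$age)
    t_dur <- welch_t(m$duration_months, u$duration_months)
    sex_tab <- matrix(c(sum(u$sex == "male"), sum(u$sex != "male"),
                        sum(m$sex == "male"), sum(m$sex != "male")),
                      2, byrow = TRUE)
    cs <- pearson_chi2(sex_tab)
    table1 <- rbind(
      row1("age_years", t_age),
      row1("duration_months", t_dur),
      data.frame(variable = "sex_male",
                 uws = paste0(sex_tab[1, 1], "/", sum(sex_tab[1, ])),
                 mcs = paste0(sex_tab[2, 1], "/", sum(sex_tab[2, ])),
                 statistic = unname(cs$statistic["chi2"]), p = cs$p,
                 fisher_p = cs$fisher_p, row.names = NULL))
  }

  accuracy <- NULL
  correlation <- NULL
  if (!is.null(sessions) && nrow(sessions) >= 6) {
    ms <- sessions[sessions$group == "MCS", ]
    us <- sessions[sessions$group == "UWS", ]
    if (nrow(ms) >= 2 && nrow(us) >= 2) {
      tt <- welch_t(ms$n_success, us$n_success)
      rs <- wilcoxon_rank_sum(ms$accuracy_pct, us$accuracy_pct)
      accuracy <- data.frame(
        mcs_mean_success = mean(ms$n_success),
        uws_mean_success = mean(us$n_success),
        mcs_accuracy_pct = mean(ms$accuracy_pct),
        uws_accuracy_pct = mean(us$accuracy_pct),
        t = unname(tt$statistic["t"]), t_p = tt$p,
        ranksum_z = rs$z, ranksum_p = rs$p, row.names = NULL)
    }
    if (!is.null(meta)) {
      idx <- merge(sessions[, c("subject_id", "mean_attention_index")],
                   meta[, c("subject_id", "crs_r")], by = "subject_id")
      cr <- spearman_rho(idx$mean_attention_index, idx$crs_r)
      correlation <- data.frame(rho = cr$rho, p = cr$p, n = cr$n,
                                ci_lo = cr$ci[1], ci_hi = cr$ci[2],
                                row.names = NULL)
    }
  }

  list(table2_within = within, table2_between = between, table1 = table1,
       accuracy = accuracy, correlation = correlation, skipped = skipped,
       n_contrasts = if (is.null(within)) 0L else
         nrow(within) + 3L * if (is.null(between)) 0L else nrow(between))
}

# all p values of the Table-2 analog (used for type-I calibration)
contrast_pvals <- function(tabs) {
  c(tabs$table2_within$p,
    tabs$table2_between$p_rest,
    tabs$table2_between$p_task,
    tabs$table2_between$p_delta)
}
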