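#' Statistic container for cohort tests
#'
#' @param statistic Named statistic value.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param effect Optional named list (difference, OR with CI, rho, ...).
#' @param method Human-readable description of the computation path.
#' @return A list of class `stat_result`.
#' @keywords internal
stat_result <- function(statistic, p_value, effect = NULL, method = "") {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, p_value = min(1, p_value),
                 effect = effect, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (%s)\n", names(x$statistic)[1],
              x$statistic[[1]], x$p_value, x$method))
  if (!is.null(x$effect)) {
    cat("  effect:", paste(names(x$effect),
        vapply(x$effect, function(e) paste(signif(unlist(e), 4), collapse = " to "),
               ""), sep = " = ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' BCVA change between two visits
#'
#' Visual acuity is in logMAR, where lower is better, so improvement is
#' `pre - post`: positive values mean the eye sees better after surgery.
#'
#' @param pre,post BCVA in logMAR.
#' @return `pre - post`.
#' @export
bcva_change <- function(pre, post) {
  stopifnot(is.finite(pre), is.finite(post))
  pre - post
}

#' Functional-success classification
#'
#' Success is a BCVA improvement of at least `threshold` logMAR at month 6
#' (default 0.3, boundary inclusive).
#'
#' @param pre,post BCVA in logMAR.
#' @param threshold Improvement cut-off (default 0.3).
#' @return Logical.
#' @export
classify_success <- function(pre, post, threshold = 0.3) {
  bcva_change(pre, post) >= threshold
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midranks. For small tie-free samples
#' (`n_x + n_y <= 12`) the p-value is exact (two-sided as twice the smaller
#' tail of the null U distribution); otherwise a normal approximation with
#' tie and continuity corrections is used.
#'
#' @param x,y Numeric samples (n >= 1 each).
#' @return A `stat_result` with the U statistic of `x`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && nx + ny <= 12L) {
    p <- 2 * min(pwilcox(u, nx, ny), 1 - pwilcox(u - 1, nx, ny))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tt <- table(c(x, y))
    n <- nx + ny
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1))))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation, tie/continuity corrected"
  }
  stat_result(c(U = u), min(1, p),
              effect = list(median_difference = median(x) - median(y)),
              method = method)
}

#' One-way repeated-measures ANOVA across visits
#'
#' `F = MS_visit / MS_error` with df `(v - 1)` and `(v - 1)(n - 1)`, fitted
#' with `stats::aov` using a within-subject error stratum. Missing cells are
#' an error: no imputation is performed.
#'
#' @param values Complete numeric matrix, subjects in rows, visits in
#'   columns (>= 2 of each).
#' @return A `stat_result` with the F statistic, df attached in `effect`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells: repeated-measures ANOVA needs complete data")
  n <- nrow(values); v <- ncol(values)
  if (n < 2L || v < 2L) stop("need >= 2 subjects and >= 2 visits")
  d <- data.frame(y = as.vector(values),
                  subject = factor(rep(seq_len(n), times = v)),
                  visit = factor(rep(seq_len(v), each = n)))
  fit <- aov(y ~ visit + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_visit <- tab["visit", "Sum Sq"]
  if (!is.finite(ss_visit) || ss_visit < 1e-12 * max(1, sum(values^2))) {
    f <- 0; p <- 1                      # no visit effect at all
  } else {
    f <- tab["visit", "F value"]
    p <- tab["visit", "Pr(>F)"]
    if (!is.finite(f)) { f <- Inf; p <- 0 }   # zero residual variance
  }
  stat_result(c(F = f), p,
              effect = list(df = c(v - 1, (v - 1) * (n - 1))),
              method = "one-way repeated-measures ANOVA")
}

#' 2x2 contingency test (chi-square or Fisher, as appropriate)
#'
#' Uses Fisher's exact test (two-sided, summing tables no more probable
#' than the observed one) when any expected cell count is below 5 or any
#' observed cell is zero, and the plain Pearson chi-square with 1 df
#' otherwise. The odds ratio is the
#' cross-ratio `ad/bc`, with the Haldane-Anscombe 0.5 correction applied to
#' every cell when a zero cell is present.
#'
#' @param table_2x2 Non-negative integer 2x2 matrix.
#' @return A `stat_result`; `effect$odds_ratio` holds the cross-ratio.
#' @export
contingency_test <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab))) {
    stop("need a non-negative integer 2x2 table")
  }
  if (sum(tab) == 0) stop("all-zero table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) || any(tab == 0)) {
    p <- fisher.test(tab)$p.value
    stat <- c(fisher = NA_real_)
    method <- "Fisher exact (two-sided)"
  } else {
    ct <- chisq.test(tab, correct = FALSE)
    p <- ct$p.value
    stat <- c(chi_square = unname(ct$statistic))
    method <- "Pearson chi-square, 1 df"
  }
  tor <- tab
  if (any(tab == 0)) tor <- tab + 0.5
  or <- (tor[1, 1] * tor[2, 2]) / (tor[1, 2] * tor[2, 1])
  stat_result(stat, p, effect = list(odds_ratio = or), method = method)
}

#' Univariate logistic regression
#'
#' Maximum-likelihood fit (IRLS via `stats::glm`) of a binary outcome on one
#' predictor, reporting the odds ratio `exp(beta)` with Wald 95% CI and
#' p-value. Complete or quasi-complete separation is detected and flagged
#' instead of reporting a divergent estimate.
#'
#' @param x Predictor (binary or continuous).
#' @param y Binary outcome (0/1 or logical), not constant.
#' @return A `stat_result`. Under separation `effect$separated` is `TRUE`
#'   and no odds ratio is reported.
#' @export
univariate_logistic <- function(x, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary (0/1 or logical)")
  if (length(unique(y)) < 2L) stop("constant outcome: logistic model undefined")
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- coef(fit)[["x"]]
  se <- summary(fit)$coefficients["x", "Std. Error"]
  if (sep_flag || abs(beta) > 15 || se > 100) {
    return(stat_result(c(beta = beta), 1,
                       effect = list(separated = TRUE),
                       method = "logistic regression: separation detected"))
  }
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  stat_result(c(beta = beta), p,
              effect = list(odds_ratio = exp(beta),
                            or_ci95 = exp(beta + c(-1, 1) * 1.959964 * se),
                            separated = FALSE),
              method = "logistic regression (Wald)")
}

#' Backward-selected multivariate logistic model
#'
#' Screening as in the study protocol: candidates with univariate p below
#' `entry_p` (default 0.1) form the initial multivariate model; the term
#' with the largest Wald p is dropped while that p is at or above `stay_p`
#' (default 0.05), refitting after each drop. Ties drop the later-listed
#' candidate, making the procedure deterministic.
#'
#' @param data Data frame holding outcome and candidate columns.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate predictor columns, in
#'   priority order.
#' @param entry_p,stay_p Screening and retention cut-offs.
#' @return A list of class `backward_model`: `selected` (character),
#'   `univariate` (data.frame: variable, or, p, separated), `model`
#'   (data.frame of the final fit: variable, or, ci_lo, ci_hi, p; empty for
#'   the null model) and `null_model` flag.
#' @export
backward_selection <- function(data, outcome, candidates,
                               entry_p = 0.1, stay_p = 0.05) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(candidates %in% names(data)))
  y <- as.numeric(data[[outcome]])
  uni <- lapply(candidates, function(v) univariate_logistic(data[[v]], y))
  uni_df <- data.frame(
    variable = candidates,
    or = vapply(uni, function(u)
      if (isTRUE(u$effect$separated)) NA_real_ else u$effect$odds_ratio, 0),
    p = vapply(uni, function(u)
      if (isTRUE(u$effect$separated)) NA_real_ else u$p_value, 0),
    separated = vapply(uni, function(u) isTRUE(u$effect$separated), TRUE),
    stringsAsFactors = FALSE
  )
  current <- candidates[!is.na(uni_df$p) & uni_df$p < entry_p]
  if (length(current) == 0L) {
    return(structure(list(selected = character(0), univariate = uni_df,
                          model = data.frame(), null_model = TRUE),
                     class = "backward_model"))
  }
  repeat {
    fml <- stats::reformulate(current, response = outcome)
    fit <- suppressWarnings(glm(fml, family = binomial(), data = data))
    cf <- summary(fit)$coefficients
    terms_p <- cf[match(current, rownames(cf)), "Pr(>|z|)"]
    terms_p[is.na(terms_p)] <- 1   # aliased/collinear terms drop first
    worst <- max(terms_p)
    if (worst < stay_p || length(current) == 0L) break
    drop_idx <- max(which(terms_p == worst))   # ties: drop the later-listed
    current <- current[-drop_idx]
    if (length(current) == 0L) {
      return(structure(list(selected = character(0), univariate = uni_df,
                            model = data.frame(), null_model = TRUE),
                       class = "backward_model"))
    }
  }
  est <- cf[match(current, rownames(cf)), , drop = FALSE]
  model <- data.frame(
    variable = current,
    or = exp(est[, "Estimate"]),
    ci_lo = exp(est[, "Estimate"] - 1.959964 * est[, "Std. Error"]),
    ci_hi = exp(est[, "Estimate"] + 1.959964 * est[, "Std. Error"]),
    p = est[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(selected = current, univariate = uni_df, model = model,
                 null_model = FALSE),
            class = "backward_model")
}

#' @export
print.backward_model <- function(x, ...) {
  if (x$null_model) {
    cat("Backward-selected logistic model: null model (no candidate entered/survived)\n")
  } else {
    cat("Backward-selected logistic model:\n")
    print(x$model, row.names = FALSE)
  }
  invisible(x)
}

#' Inter-eye (RRD vs fellow) correlation
#'
#' Spearman rank correlation on paired measurements, using midranks; the
#' p-value is exact for n <= 8 without ties and a t-approximation otherwise.
#'
#' @param x_rrd,y_fellow Paired samples (n >= 3).
#' @param method Only `"spearman"` is implemented.
#' @return A `stat_result` with rho.
#' @export
paired_correlation <- function(x_rrd, y_fellow, method = "spearman") {
  method <- match.arg(method, "spearman")
  if (length(x_rrd) != length(y_fellow)) stop("samples are not paired")
  n <- length(x_rrd)
  if (n < 3L) stop("need n >= 3 pairs")
  ties <- anyDuplicated(x_rrd) > 0L || anyDuplicated(y_fellow) > 0L
  exact <- n <= 8L && !ties
  ct <- suppressWarnings(cor.test(x_rrd, y_fellow, method = "spearman",
                                  exact = exact))
  stat_result(c(rho = unname(ct$estimate)), ct$p.value,
              method = if (exact) "Spearman, exact" else "Spearman, t approximation")
}

#' Descriptive cohort summary
#'
#' Per group x visit x variable: n (non-missing), mean, SD, median and
#' quartiles (linear interpolation); for categorical variables, counts and
#' percentages per level.
#'
#' @param records Data frame of visit records.
#' @param variables Columns to summarize; defaults to every column outside
#'   `by` (numerics go to the numeric table, everything else to the
#'   categorical one).
#' @param by Grouping columns present in `records` (default `group`, `visit`
#'   where available).
#' @return List with data.frames `numeric` (group cols, variable, n, mean,
#'   sd, median, q1, q3) and `categorical` (group cols, variable, level, n,
#'   pct).
#' @export
summarize_cohort <- function(records, variables = NULL,
                             by = intersect(c("group", "visit"), names(records))) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (is.null(variables)) variables <- setdiff(names(records), by)
  key <- if (length(by)) interaction(records[by], drop = TRUE, sep = "|")
         else factor(rep("all", nrow(records)))
  num_rows <- list(); cat_rows <- list()
  for (g in levels(key)) {
    sub <- records[key == g, , drop = FALSE]
    gcols <- if (length(by)) sub[1, by, drop = FALSE] else data.frame(group = "all")
    for (v in variables) {
      col <- sub[[v]]
      if (is.numeric(col)) {
        x <- col[!is.na(col)]
        q <- if (length(x)) quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
             else rep(NA_real_, 3)
        num_rows[[length(num_rows) + 1L]] <- cbind(
          gcols, data.frame(variable = v, n = length(x),
                            mean = if (length(x)) mean(x) else NA_real_,
                            sd = if (length(x) > 1) sd(x) else if (length(x)) 0 else NA_real_,
                            median = q[2], q1 = q[1], q3 = q[3]))
      } else {
        tt <- table(col, useNA = "no")
        if (length(tt)) {
          cat_rows[[length(cat_rows) + 1L]] <- cbind(
            gcols[rep(1, length(tt)), , drop = FALSE],
            data.frame(variable = v, level = names(tt), n = as.integer(tt),
                       pct = 100 * as.integer(tt) / sum(tt)))
        }
      }
    }
  }
  list(
    numeric = if (length(num_rows)) do.call(rbind, c(num_rows, make.row.names = FALSE))
              else data.frame(),
    categorical = if (length(cat_rows)) do.call(rbind, c(cat_rows, make.row.names = FALSE))
                  else data.frame()
  )
}
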