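#' ROUT outlier detection (robust fit + FDR test)
#'
#' Identifies outliers in a single sample the way GraphPad Prism's ROUT
#' method (Q = 1% by default) does for a column of values, following
#' Motulsky & Brown (2006): (1) a robust location estimate from an
#' iteratively reweighted fit minimizing the Lorentzian merit function;
#' (2) the robust standard deviation of the residuals (RSDR) from the
#' 68.27th percentile of absolute residuals scaled by `n / (n - K)` with
#' `K = 1` fitted parameter; (3) a two-tailed t-probability for each point
#' from `|residual| / RSDR` with `n - K` degrees of freedom; (4) flagging by
#' a false-discovery-rate schedule at level `Q`, testing residuals from the
#' most extreme inward (threshold `Q * (n - i + 1) / n` for the i-th most
#' extreme) and stopping at the first non-significant one.
#'
#' Full nonlinear-regression ROUT is out of scope: applied to kinetics
#' columns the "fit" is a robust location, which is exactly how the method
#' is used here.
#'
#' @param values numeric vector, `n >= 3`.
#' @param Q false-discovery level (default 0.01 = 1%).
#' @return object of class `rout_result`: list with `robust_center`, `rsdr`,
#'   `outlier_flag` (logical, input order), `p` (per-point t-probability)
#'   and `Q`.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 3) stop("ROUT needs at least 3 values")
  if (Q <= 0 || Q >= 1) stop("Q must be in (0, 1)")
  center <- median(values)
  rsdr <- 0
  for (iter in 1:100) {
    resid <- values - center
    p68 <- as.numeric(quantile(abs(resid), 0.6827))
    rsdr <- p68 * n / (n - 1)
    if (rsdr == 0) break
    w <- 1 / (1 + (resid / rsdr)^2)
    new_center <- sum(w * values) / sum(w)
    if (abs(new_center - center) < 1e-12 * max(1, abs(center))) {
      center <- new_center
      break
    }
    center <- new_center
  }
  resid <- values - center
  if (rsdr == 0) {
    # all (or >68%) of the values identical: no spread, nothing to flag
    return(structure(list(robust_center = center, rsdr = 0,
                          outlier_flag = rep(FALSE, n),
                          p = rep(1, n), Q = Q), class = "rout_result"))
  }
  p <- 2 * pt(-abs(resid) / rsdr, df = n - 1)
  ord <- order(abs(resid), decreasing = TRUE)
  flag <- rep(FALSE, n)
  for (i in seq_len(n)) {
    alpha_i <- Q * (n - i + 1) / n
    if (p[ord[i]] < alpha_i) flag[ord[i]] <- TRUE else break
  }
  structure(list(robust_center = center, rsdr = rsdr, outlier_flag = flag,
                 p = p, Q = Q), class = "rout_result")
}

#' @export
print.rout_result <- function(x, ...) {
  cat(sprintf("<rout_result> center %.4g, RSDR %.4g, %d/%d flagged (Q = %g%%)\n",
              x$robust_center, x$rsdr, sum(x$outlier_flag),
              length(x$outlier_flag), 100 * x$Q))
  invisible(x)
}

# Tukey-Kramer pairwise comparisons of the levels of `fac` given cell means,
# sizes, residual mean square and df; harmonic-mean-free Kramer form:
# q = |m_i - m_j| / sqrt((MSE / 2) * (1 / n_i + 1 / n_j))
tukey_kramer_pairs <- function(means, ns, mse, df_resid, n_means) {
  lv <- names(means)
  pairs <- utils::combn(seq_along(lv), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diffm <- means[i] - means[j]
    se <- sqrt((mse / 2) * (1 / ns[i] + 1 / ns[j]))
    q <- abs(diffm) / se
    data.frame(comparison = paste(lv[i], "vs", lv[j]),
               diff = as.numeric(diffm), se = se, q = q,
               p_adj = ptukey(q, nmeans = n_means, df = df_resid,
                              lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Two-way ANOVA with Tukey-Kramer comparisons within timepoints
#'
#' Ordinary (fixed-effects) two-way ANOVA of `value ~ group * timepoint`
#' with Type-II sums of squares — appropriate for the unbalanced layouts that
#' larval dropout produces — followed by Tukey-Kramer multiple comparisons of
#' the groups within each timepoint, using the studentized-range distribution
#' and the Kramer adjustment for unequal cell sizes. The residual mean square
#' of the full model is the pooled error term.
#'
#' @param data data.frame containing the response and both factors.
#' @param value response column name.
#' @param factor_a primary factor (default `"group"`).
#' @param factor_b secondary factor (default `"timepoint"`); comparisons are
#'   made between `factor_a` levels within each `factor_b` level.
#' @param ss_type `2` (default) or `3`, the sum-of-squares convention.
#' @return object of class `anova_result`: list with `anova_table`
#'   (effect, sum_sq, df, F, p), `comparisons` (per `factor_b` level) and
#'   `residuals`.
#' @export
two_way_anova_tukey <- function(data, value = "normalized_area",
                                factor_a = "group", factor_b = "timepoint",
                                ss_type = 2) {
  stopifnot(value %in% names(data), factor_a %in% names(data),
            factor_b %in% names(data))
  df <- data.frame(y = data[[value]], A = factor(data[[factor_a]]),
                   B = factor(data[[factor_b]]))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2)
    stop("both factors need at least 2 levels")
  cells <- table(df$A, df$B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  fit <- lm(y ~ A * B, data = df)
  a2 <- as.data.frame(car::Anova(fit, type = ss_type))
  rows <- c("A", "B", "A:B", "Residuals")   # drop "(Intercept)" under type 3
  a2 <- a2[rows, ]
  tab <- data.frame(effect = c(factor_a, factor_b,
                               paste0(factor_a, ":", factor_b), "residuals"),
                    sum_sq = a2[["Sum Sq"]],
                    df = a2[["Df"]],
                    F = c(a2[["F value"]][1:3], NA),
                    p = c(a2[["Pr(>F)"]][1:3], NA),
                    stringsAsFactors = FALSE)
  mse <- tab$sum_sq[4] / tab$df[4]
  comps <- lapply(levels(df$B), function(b) {
    sub <- df[df$B == b, ]
    means <- tapply(sub$y, droplevels(sub$A), mean)
    ns <- tapply(sub$y, droplevels(sub$A), length)
    cbind(data.frame(timepoint = b, stringsAsFactors = FALSE),
          tukey_kramer_pairs(means, ns, mse, tab$df[4], nlevels(df$A)))
  })
  structure(list(anova_table = tab, comparisons = do.call(rbind, comps),
                 residuals = stats::residuals(fit)),
            class = "anova_result")
}

#' One-way ANOVA with Tukey-Kramer comparisons
#'
#' Ordinary one-way ANOVA followed by Tukey-Kramer multiple comparisons of
#' all group pairs (studentized range, Kramer adjustment for unequal n) —
#' the workflow used to compare crispant phenotyping conditions.
#'
#' @param values numeric response.
#' @param groups group labels, at least 2 levels with n >= 2 each.
#' @return an `anova_result` (see [two_way_anova_tukey()]).
#' @export
one_way_anova_tukey <- function(values, groups) {
  g <- factor(groups)
  ok <- !is.na(values)
  values <- values[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  fit <- lm(values ~ g)
  a <- anova(fit)
  tab <- data.frame(effect = c("group", "residuals"),
                    sum_sq = a[["Sum Sq"]], df = a[["Df"]],
                    F = c(a[["F value"]][1], NA),
                    p = c(a[["Pr(>F)"]][1], NA), stringsAsFactors = FALSE)
  mse <- tab$sum_sq[2] / tab$df[2]
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  structure(list(anova_table = tab,
                 comparisons = tukey_kramer_pairs(means, ns, mse, tab$df[2],
                                                  nlevels(g)),
                 residuals = stats::residuals(fit)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(x$anova_table, row.names = FALSE)
  cat("Tukey-Kramer comparisons:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' Two-sided pooled-variance t-test, the Prism default for an "unpaired
#' t test", used to compare a treated condition to the ablated control.
#' Welch's unequal-variance form is available via `var_equal = FALSE`.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, and `flag`
#'   (`"degenerate"` when both samples are constant).
#' @export
ttest_unpaired <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    # zero pooled variance: p defined by the limit
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b), flag = "degenerate"))
    return(list(t = Inf, df = length(a) + length(b) - 2, p = 0,
                mean_a = mean(a), mean_b = mean(b), flag = "degenerate"))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b), flag = "")
}

#' Residual normality checks (Anderson-Darling and Shapiro-Wilk)
#'
#' Advisory tests of ANOVA residual normality; they never gate the pipeline.
#' Below `n = 8` both are reported as missing (the Anderson-Darling
#' implementation requires n >= 8, and smaller samples carry no usable
#' information about the residual distribution anyway).
#'
#' @param residuals numeric vector.
#' @return data.frame with rows `anderson_darling` and `shapiro_wilk`,
#'   columns `statistic` and `p`.
#' @export
normality_tests <- function(residuals) {
  residuals <- residuals[!is.na(residuals)]
  out <- data.frame(test = c("anderson_darling", "shapiro_wilk"),
                    statistic = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(residuals) < 8 || sd(residuals) == 0) return(out)
  ad <- nortest::ad.test(residuals)
  sw <- shapiro.test(residuals)
  out$statistic <- c(unname(ad$statistic), unname(sw$statistic))
  out$p <- c(ad$p.value, sw$p.value)
  out
}
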