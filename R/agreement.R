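#' Intraclass correlation: absolute agreement, average measures
#'
#' Two-way ANOVA decomposition of a complete subjects x raters matrix into
#' row, column and error mean squares, returning the absolute-agreement
#' average-measures coefficient
#' `(MS_rows - MS_err) / (MS_rows + (MS_cols - MS_err) / n)`.
#' This is the "mean-rating, absolute-agreement, two-way model"
#' coefficient; the mixed-versus-random distinction changes interpretation
#' only, not the estimate.  The confidence interval is the standard
#' F-based interval for the single-measures absolute-agreement coefficient
#' (with a Satterthwaite denominator df), stepped up to average measures
#' by the Spearman-Brown relation.
#'
#' @param mat numeric matrix, one row per subject (or pooled
#'   subject-minute), one column per rater/method; no missing cells
#' @param conf confidence level (default 0.95)
#' @return list with `icc`, `ci` (length-2), `ms` (mean squares), `df`
#' @export
icc_agreement <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("matrix must be complete")
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 3L) stop("need at least 3 rows")
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= mse) {
    if (ss_rows == 0 && ss_err == 0) {
      stop("ICC undefined: no between-row variance (constant matrix)")
    }
  }
  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  ## single-measures CI (F-based, Satterthwaite df), then Spearman-Brown
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (1 - icc_1 < 1e-12) {   # perfect agreement: degenerate F interval
    return(list(icc = icc_k, ci = c(icc_k, icc_k),
                ms = c(rows = msr, cols = msc, error = mse),
                df = c(rows = n - 1, cols = k - 1,
                       error = (n - 1) * (k - 1))))
  }
  alpha <- 1 - conf
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  low1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  list(icc = icc_k, ci = c(sb(low1), sb(up1)),
       ms = c(rows = msr, cols = msc, error = mse),
       df = c(rows = n - 1, cols = k - 1, error = (n - 1) * (k - 1)))
}

#' Bland-Altman agreement
#'
#' Differences `d = a - b`, bias `mean(d)`, limits of agreement
#' `bias +/- 1.96 * sd(d)`, plus the (mean, difference) pairs for
#' plotting.
#'
#' @param a,b paired numeric vectors (same length >= 2)
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, and a
#'   data.frame `points` (`mean`, `diff`)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Within-condition coefficient of variation
#'
#' `100 * sd / mean` of a small sample of representative breath values.
#'
#' @param values numeric vector (>= 2 values, positive mean)
#' @return CV in percent
#' @export
within_cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive for a meaningful CV")
  100 * sd(values) / m
}

#' Pearson correlation of paired values
#'
#' @param a,b paired numeric vectors (>= 3 pairs, both with nonzero
#'   variance)
#' @return the product-moment correlation coefficient
#' @export
pearson_pairs <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance")
  stats::cor(a, b)
}

#' Method-by-time interaction (repeated measures)
#'
#' Two-within-factor repeated-measures ANOVA on a complete
#' subject x method x time table; returns the method x time interaction F
#' against its subject-interaction error term
#' (`MS[method:time] / MS[method:time:subject]`).  Parallel method curves
#' (a constant offset per subject) give F near 0; a time-growing
#' divergence between methods makes the interaction significant.  No
#' sphericity correction is applied by default; `gg = TRUE` applies the
#' Greenhouse-Geisser epsilon to the df.
#'
#' @param df data.frame with columns `subject`, `method`, `time`, `value`;
#'   every subject must have every method x time cell exactly once
#' @param gg apply the Greenhouse-Geisser correction
#' @return list with `F`, `df1`, `df2`, `p` (and `epsilon` when `gg`)
#' @export
method_time_interaction <- function(df, gg = FALSE) {
  need <- c("subject", "method", "time", "value")
  if (!all(need %in% names(df))) {
    stop("df needs columns subject, method, time, value")
  }
  df$subject <- factor(df$subject)
  df$method <- factor(df$method)
  df$time <- factor(df$time)
  ns <- nlevels(df$subject); nm <- nlevels(df$method); nt <- nlevels(df$time)
  if (ns < 2L) stop("need at least 2 subjects for the interaction error term")
  if (nrow(df) != ns * nm * nt ||
      any(table(df$subject, df$method, df$time) != 1L)) {
    stop("unbalanced design: truncate all series to a common minute grid ",
         "with one value per subject x method x time cell")
  }
  grand <- mean(df$value)
  cell <- function(...) tapply(df$value, list(...), mean)
  y_mt <- cell(df$method, df$time)
  y_m <- tapply(df$value, df$method, mean)
  y_t <- tapply(df$value, df$time, mean)
  ss_mt <- ns * sum((sweep(sweep(y_mt, 1, y_m), 2, y_t) + grand)^2)
  df1 <- (nm - 1) * (nt - 1)
  ## three-way residual: (method x time x subject) interaction
  y_smt <- tapply(df$value, list(df$subject, df$method, df$time), mean)
  y_sm <- tapply(df$value, list(df$subject, df$method), mean)
  y_st <- tapply(df$value, list(df$subject, df$time), mean)
  y_s <- tapply(df$value, df$subject, mean)
  resid3 <- y_smt
  for (s in seq_len(ns)) for (m in seq_len(nm)) for (t_ in seq_len(nt)) {
    resid3[s, m, t_] <- y_smt[s, m, t_] - y_sm[s, m] - y_st[s, t_] -
      y_mt[m, t_] + y_s[s] + y_m[m] + y_t[t_] - grand
  }
  ss_err <- sum(resid3^2)
  df2 <- (nm - 1) * (nt - 1) * (ns - 1)
  fval <- (ss_mt / df1) / (ss_err / df2)
  out <- list(F = fval, df1 = df1, df2 = df2)
  if (gg) {
    ## Greenhouse-Geisser epsilon from the covariance of the subject-level
    ## interaction contrasts
    wide <- matrix(NA_real_, ns, nm * nt)
    lev <- expand.grid(m = levels(df$method), t = levels(df$time))
    for (j in seq_len(nrow(lev))) {
      sel <- df$method == lev$m[[j]] & df$time == lev$t[[j]]
      wide[, j] <- df$value[sel][order(df$subject[sel])]
    }
    cm <- crossprod(scale(wide, scale = FALSE)) / (ns - 1)
    eps <- sum(diag(cm))^2 / (length(diag(cm)) * sum(cm^2))
    eps <- max(min(eps, 1), 1 / df1)
    out$epsilon <- eps
    out$p <- pf(fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  } else {
    out$p <- pf(fval, df1, df2, lower.tail = FALSE)
  }
  out
}

#' Agreement report between two per-minute activation series
#'
#' Aligns two analyses on (subject, minute) pairs and computes the full
#' agreement panel: absolute-agreement average-measures ICC with CI,
#' Bland-Altman bias and limits, Pearson r, and (when both series cover a
#' common minute grid per subject) the method x time interaction.
#'
#' @param series_a,series_b data.frames with columns `subject`,
#'   `minute_index`, `emgdi_pct` (a single-recording `minutes` table may
#'   be given; subject defaults to "s1")
#' @param label_a,label_b method labels recorded in the report
#' @return list of class `agreement_report`
#' @export
agreement_report <- function(series_a, series_b, label_a = "method_a",
                             label_b = "method_b") {
  fix <- function(x) {
    if (!"subject" %in% names(x)) x$subject <- "s1"
    x[, c("subject", "minute_index", "emgdi_pct")]
  }
  a <- fix(series_a); b <- fix(series_b)
  pairs <- merge(a, b, by = c("subject", "minute_index"),
                 suffixes = c("_a", "_b"))
  pairs <- pairs[complete.cases(pairs), ]
  if (nrow(pairs) < 3L) stop("need at least 3 aligned (subject, minute) pairs")
  icc <- icc_agreement(cbind(pairs$emgdi_pct_a, pairs$emgdi_pct_b))
  ba <- bland_altman(pairs$emgdi_pct_a, pairs$emgdi_pct_b)
  r <- pearson_pairs(pairs$emgdi_pct_a, pairs$emgdi_pct_b)
  interaction <- NULL
  long <- rbind(
    data.frame(subject = pairs$subject, method = label_a,
               time = pairs$minute_index, value = pairs$emgdi_pct_a),
    data.frame(subject = pairs$subject, method = label_b,
               time = pairs$minute_index, value = pairs$emgdi_pct_b))
  interaction <- tryCatch(method_time_interaction(long),
                          error = function(e) NULL)
  structure(list(label_a = label_a, label_b = label_b,
                 n_pairs = nrow(pairs), icc = icc$icc, icc_ci = icc$ci,
                 bias = ba$bias, loa_low = ba$loa_low,
                 loa_high = ba$loa_high, pearson_r = r,
                 interaction = interaction, pairs = pairs),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s vs %s (n = %d subject-minutes)\n",
              x$label_a, x$label_b, x$n_pairs))
  cat(sprintf("  ICC (absolute agreement, average measures): %.3f [%.3f, %.3f]\n",
              x$icc, x$icc_ci[[1L]], x$icc_ci[[2L]]))
  cat(sprintf("  Bland-Altman bias %.2f%%, limits [%.2f, %.2f]%%\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  Pearson r = %.3f\n", x$pearson_r))
  if (!is.null(x$interaction)) {
    cat(sprintf("  method x time interaction: F(%d, %d) = %.2f, p = %.3f\n",
                x$interaction$df1, x$interaction$df2, x$interaction$F,
                x$interaction$p))
  }
  invisible(x)
}

#' Serialise an agreement report to JSON
#'
#' @param report an `agreement_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_agreement_report <- function(report, path) {
  out <- report
  class(out) <- NULL
  out$pairs <- as.list(report$pairs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
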