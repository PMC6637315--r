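# Fixture ratings: 8 pooled subject-minutes x 2 raters
fix_mat <- matrix(c(12.1, 15.3, 33.8, 47.2, 52.9, 61.0, 64.8, 70.3,
                    10.9, 18.2, 30.1, 49.9, 50.2, 63.5, 61.7, 74.0),
                  ncol = 2)

## independent oracle for the two-way decomposition via stats::aov
aov_ms <- function(mat) {
  d <- data.frame(y = as.vector(mat),
                  row = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                  col = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  tab <- summary(stats::aov(y ~ row + col, data = d))[[1L]]
  ms <- tab[["Mean Sq"]]
  names(ms) <- trimws(rownames(tab))
  ms
}

test_that("ICC matches an independent ANOVA oracle", {
  res <- icc_agreement(fix_mat)
  ms <- aov_ms(fix_mat)
  n <- nrow(fix_mat)
  icc_oracle <- (ms[["row"]] - ms[["Residuals"]]) /
    (ms[["row"]] + (ms[["col"]] - ms[["Residuals"]]) / n)
  expect_equal(res$icc, unname(icc_oracle), tolerance = 1e-10)
  expect_equal(unname(res$ms), unname(ms[c("row", "col", "Residuals")]),
               tolerance = 1e-10)
  expect_true(res$ci[[1L]] < res$icc && res$icc < res$ci[[2L]])
})

test_that("ICC boundary behaviour and invariances", {
  expect_equal(icc_agreement(cbind(fix_mat[, 1L], fix_mat[, 1L]))$icc, 1)
  expect_error(icc_agreement(matrix(5, 4, 2)), "undefined")
  expect_error(icc_agreement(fix_mat[, 1L, drop = FALSE]), "2 raters")
  expect_error(icc_agreement(fix_mat[1:2, ]), "3 rows")

  ## same constant added to every cell: unchanged
  expect_equal(icc_agreement(fix_mat + 7)$icc, icc_agreement(fix_mat)$icc,
               tolerance = 1e-12)
  ## constant added to one rater only: decreases (absolute agreement
  ## penalises systematic offset), and drops below the consistency form
  shifted <- fix_mat; shifted[, 2L] <- shifted[, 2L] + 20
  res_s <- icc_agreement(shifted)
  expect_lt(res_s$icc, icc_agreement(fix_mat)$icc)
  ms <- aov_ms(shifted)
  icc_consistency <- (ms[["row"]] - ms[["Residuals"]]) / ms[["row"]]
  expect_lt(res_s$icc, icc_consistency)
})

test_that("Bland-Altman closed forms and Monte-Carlo recovery", {
  a <- c(1, 2, 3, 4)
  expect_equal(bland_altman(a, a),
               list(bias = 0, loa_low = 0, loa_high = 0, sd_diff = 0,
                    points = data.frame(mean = a, diff = rep(0, 4))))

  ## d = {-1, +1}: sd = sqrt(2), limits -/+ 1.96 sqrt(2)
  ba <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1, 1) * 1.96 * sqrt(2))

  set.seed(21)
  n <- 1000; delta <- 4; sigma <- 3
  x <- runif(n, 10, 80)
  ba2 <- bland_altman(x + delta + rnorm(n, 0, sigma), x)
  expect_lt(abs(ba2$bias - delta), 3 * sigma / sqrt(n))
  expect_equal(ba2$loa_high, delta + 1.96 * sigma, tolerance = 0.1)
  expect_equal(ba2$loa_low, delta - 1.96 * sigma, tolerance = 0.1)

  expect_error(bland_altman(1, 1), "2 pairs")
  expect_error(bland_altman(1:3, 1:2), "paired")
})

test_that("within-rater CV closed forms and scale invariance", {
  expect_equal(within_cv(rep(5, 5)), 0)
  expect_equal(within_cv(c(8, 10, 12)), 20)
  v <- c(14, 11, 19, 16, 12)
  expect_equal(within_cv(3.3 * v), within_cv(v), tolerance = 1e-12)
  expect_error(within_cv(7), "2 values")
  expect_error(within_cv(c(-2, 2)), "positive")
})

test_that("pearson_pairs equals the definitional covariance ratio", {
  a <- c(3.2, 5.1, 7.4, 2.2, 9.9, 4.4, 6.1, 8.3, 1.5, 0.7)
  b <- c(2.9, 6.0, 7.1, 1.8, 9.1, 5.2, 5.9, 8.8, 2.2, 1.1)
  r_def <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_pairs(a, b), r_def, tolerance = 1e-12)
  expect_equal(pearson_pairs(a, 2 * a + 1), 1)
  expect_equal(pearson_pairs(a, -a), -1)
  expect_error(pearson_pairs(a, rep(1, 10)), "variance")
  expect_error(pearson_pairs(1:2, 1:2), "3 pairs")
})

make_rm_table <- function(n_subj = 6, n_time = 5, diverge = 0, noise = 2,
                          seed = 31) {
  set.seed(seed)
  base <- outer(runif(n_subj, 10, 30), seq(0, 40, length.out = n_time), `+`)
  df <- expand.grid(subject = seq_len(n_subj), time = seq_len(n_time),
                    method = c("a", "b"))
  df$value <- NA_real_
  for (i in seq_len(nrow(df))) {
    v <- base[df$subject[[i]], df$time[[i]]] + rnorm(1, 0, noise)
    if (df$method[[i]] == "b") {
      v <- v + 3 + diverge * (df$time[[i]] - 1)
    }
    df$value[[i]] <- v
  }
  df
}

test_that("interaction F matches the aov error-stratum oracle", {
  df <- make_rm_table(diverge = 5)
  res <- method_time_interaction(df)
  fit <- stats::aov(value ~ method * time + Error(subject / (method * time)),
                    data = transform(df, subject = factor(subject),
                                     method = factor(method),
                                     time = factor(time)))
  tab <- summary(fit)[["Error: subject:method:time"]][[1L]]
  expect_equal(res$F, tab["method:time", "F value"], tolerance = 1e-8)
  expect_equal(res$p, tab["method:time", "Pr(>F)"], tolerance = 1e-8)
})

test_that("interaction: parallel curves give F near 0, divergence is detected", {
  df <- make_rm_table(diverge = 0, noise = 0)
  ## method b = a + constant: interaction SS exactly zero
  res0 <- method_time_interaction(make_rm_table(diverge = 0, noise = 1))
  expect_gt(res0$p, 0.2)

  ## 10 pp/min divergence, 2 pp noise, 7 subjects: clearly significant
  res1 <- method_time_interaction(make_rm_table(n_subj = 7, diverge = 10,
                                                noise = 2, seed = 8))
  expect_lt(res1$p, 0.05)

  ## Greenhouse-Geisser correction only shrinks the df
  resg <- method_time_interaction(make_rm_table(diverge = 5), gg = TRUE)
  expect_true(resg$epsilon <= 1)

  bad <- make_rm_table()[-1L, ]
  expect_error(method_time_interaction(bad), "unbalanced")
})

test_that("agreement_report aligns pairs and assembles the panel", {
  a <- data.frame(subject = rep(1:3, each = 4),
                  minute_index = rep(1:4, 3),
                  emgdi_pct = c(20, 30, 40, 50, 25, 33, 47, 60,
                                18, 28, 42, 55))
  b <- a
  b$emgdi_pct <- b$emgdi_pct + 2
  rep_ <- agreement_report(a, b, "x", "y")
  expect_equal(rep_$n_pairs, 12L)
  expect_equal(rep_$bias, -2)      # d = a - b, b is 2 higher
  expect_equal(rep_$loa_low, -2)   # zero-variance differences
  expect_equal(rep_$pearson_r, 1)
  expect_gt(rep_$icc, 0.97)

  path <- tempfile(fileext = ".json")
  write_agreement_report(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$bias, -2)
  expect_equal(back$n_pairs, 12L)
})
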