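# clinimetrics: ICC family via explicit ANOVA mean squares with F tests and
# 95% confidence intervals (single-measure forms: one-way random ICC(1),
# two-way absolute agreement ICC(A,1), two-way consistency ICC(C,1)), SEM,
# MDC, and absolute/relative device agreement.

#' Validate and clean a subjects-by-sessions measurement matrix
#'
#' Rows (subjects) with any missing cell are dropped listwise; the count of
#' dropped rows is kept in attribute `n_dropped`.
#'
#' @param values Numeric matrix or data frame, n subjects x k
#'   sessions/devices; n >= 2, k >= 2 after dropping incomplete rows.
#' @return A numeric matrix of complete cases.
#' @export
measurement_matrix <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop_coptools("need at least 2 sessions/raters (columns)", "parameter_error")
  complete <- rowSums(!is.finite(m)) == 0
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L) stop_coptools("need at least 2 complete subjects (rows)", "parameter_error")
  attr(m, "n_dropped") <- n_dropped
  m
}

#' ANOVA mean squares of a measurement matrix
#'
#' Explicit sums-of-squares decomposition used by the ICC formulas:
#' one-way (between-rows `msr_oneway`, within-rows `msw`) and two-way
#' (rows `msr`, columns `msc`, error `mse`).
#'
#' @param m A [measurement_matrix()].
#' @return List `msr`, `msw`, `msc`, `mse`, `n`, `k`, `grand_mean`,
#'   `degenerate` (TRUE when the total variance is zero).
#' @export
anova_mean_squares <- function(m) {
  m <- measurement_matrix(m)
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - gm)^2)
  ss_rows <- k * sum((row_means - gm)^2)
  ss_cols <- n * sum((col_means - gm)^2)
  ss_within <- sum((m - row_means)^2)          # one-way residual
  ss_error <- ss_total - ss_rows - ss_cols     # two-way residual
  list(msr = ss_rows / (n - 1),
       msw = ss_within / (n * (k - 1)),
       msc = ss_cols / (k - 1),
       mse = ss_error / ((n - 1) * (k - 1)),
       n = n, k = k, grand_mean = gm,
       degenerate = ss_total <= .Machine$double.eps * max(1, abs(gm))^2)
}

#' Intraclass correlation coefficient (single measures)
#'
#' Single-rater ICC from ANOVA mean squares:
#' \describe{
#'   \item{oneway, ICC(1)}{`(MSR - MSW) / (MSR + (k - 1) MSW)`, one-way
#'     random model; CI from F-distribution quantiles of `MSR / MSW`.}
#'   \item{consistency, ICC(C,1)}{`(MSR - MSE) / (MSR + (k - 1) MSE)`; CI
#'     from `MSR / MSE`.}
#'   \item{agreement, ICC(A,1)}{`(MSR - MSE) / (MSR + (k - 1) MSE +
#'     (k / n)(MSC - MSE))`; CI by the Satterthwaite approximation.}
#' }
#' The F test reported is the test for absence of subject-independent
#' variance (`MSR / MSW` or `MSR / MSE`). Negative estimates are reported
#' as computed, never truncated.
#'
#' @param m A [measurement_matrix()] (or coercible).
#' @param kind `"oneway"`, `"agreement"` or `"consistency"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `kind`, `estimate`, `ci95_low`,
#'   `ci95_high`, `f_value`, `df1`, `df2`, `p_value`, `n`, `k`,
#'   `degenerate`.
#' @export
icc <- function(m, kind = c("oneway", "agreement", "consistency"),
                conf_level = 0.95) {
  kind <- match.arg(kind)
  ms <- anova_mean_squares(m)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf_level
  res <- list(kind = kind, n = n, k = k, degenerate = ms$degenerate)
  if (ms$degenerate) {
    res[c("estimate", "ci95_low", "ci95_high", "f_value", "p_value")] <- NA_real_
    res$df1 <- n - 1
    res$df2 <- if (kind == "oneway") n * (k - 1) else (n - 1) * (k - 1)
    return(structure(res, class = "icc_result"))
  }
  if (kind == "oneway") {
    est <- (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw)
    f <- ms$msr / ms$msw
    df1 <- n - 1; df2 <- n * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else if (kind == "consistency") {
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    f <- ms$msr / ms$mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    est <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    f <- ms$msr / ms$mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    # Satterthwaite df for the CI of the absolute-agreement form
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    if (!is.finite(v) || v <= 0) {
      ci <- c(NA_real_, NA_real_)
    } else {
      f_star <- qf(1 - alpha / 2, n - 1, v)
      fl2 <- qf(1 - alpha / 2, v, n - 1)
      ci <- c(
        n * (ms$msr - f_star * ms$mse) /
          (f_star * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr),
        n * (fl2 * ms$msr - ms$mse) /
          (k * ms$msc + (k * n - k - n) * ms$mse + n * fl2 * ms$msr)
      )
    }
  }
  res$estimate <- est
  res$ci95_low <- min(ci); res$ci95_high <- max(ci)
  res$f_value <- f; res$df1 <- df1; res$df2 <- df2
  res$p_value <- pf(f, df1, df2, lower.tail = FALSE)
  structure(res, class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  lab <- c(oneway = "ICC(1)", agreement = "ICC(A,1)", consistency = "ICC(C,1)")[x$kind]
  if (isTRUE(x$degenerate)) {
    cat(sprintf("<icc_result> %s: undefined (zero total variance), n=%d k=%d\n",
                lab, x$n, x$k))
  } else {
    cat(sprintf("<icc_result> %s = %.3f (95%% CI %.3f..%.3f), F(%g, %g) = %.3f, p = %.4g\n",
                lab, x$estimate, x$ci95_low, x$ci95_high, x$df1, x$df2,
                x$f_value, x$p_value))
  }
  invisible(x)
}

#' SEM and MDC from a pooled SD and an ICC
#'
#' Standard error of measurement `SEM = SD * sqrt(1 - ICC)` and minimal
#' detectable change `MDC = SEM * 1.96 * sqrt(2)`. A negative ICC in
#' \eqn{[-1, 0)} is accepted with a warning (the SEM then exceeds the SD);
#' values outside \eqn{[-1, 1]} are an error.
#'
#' @param pooled_sd SD of the metric in its own units (>= 0).
#' @param icc_estimate ICC in \eqn{[-1, 1]}.
#' @return List `sem`, `mdc`.
#' @export
sem_mdc <- function(pooled_sd, icc_estimate) {
  if (!is.finite(icc_estimate) || icc_estimate > 1 || icc_estimate < -1) {
    stop_coptools("ICC must lie in [-1, 1]", "parameter_error")
  }
  if (!is.finite(pooled_sd) || pooled_sd < 0) {
    stop_coptools("pooled SD must be >= 0", "parameter_error")
  }
  if (icc_estimate < 0) {
    warn_coptools("negative ICC: SEM exceeds the pooled SD", "clinimetrics_warning")
  }
  sem <- pooled_sd * sqrt(1 - icc_estimate)
  list(sem = sem, mdc = sem * 1.96 * sqrt(2))
}

#' Absolute and relative agreement between reference and index device
#'
#' Per subject `d = reference - index`; absolute agreement is the mean and
#' SD of `d`, relative agreement the mean and SD of `100 * d / reference`
#' (%). Subjects with `|reference| < eps` are excluded from the relative
#' part only, with their count reported.
#'
#' @param reference,index Paired per-subject values (equal length).
#' @param eps Smallest reference magnitude admissible for the relative part.
#' @return An object of class `agreement_report`: `absolute` (mean, sd, n),
#'   `relative` (mean_pct, sd_pct, n, n_excluded).
#' @export
agreement <- function(reference, index, eps = 1e-6) {
  if (length(reference) != length(index)) {
    stop_coptools("reference and index must be paired (equal length)", "parameter_error")
  }
  ok <- is.finite(reference) & is.finite(index)
  reference <- reference[ok]; index <- index[ok]
  if (length(reference) < 1L) stop_coptools("no complete pairs", "parameter_error")
  d <- reference - index
  rel_ok <- abs(reference) >= eps
  rel <- 100 * d[rel_ok] / reference[rel_ok]
  structure(list(
    absolute = list(mean = mean(d),
                    sd = if (length(d) > 1L) sd(d) else NA_real_,
                    n = length(d)),
    relative = list(mean_pct = if (any(rel_ok)) mean(rel) else NA_real_,
                    sd_pct = if (sum(rel_ok) > 1L) sd(rel) else NA_real_,
                    n = sum(rel_ok), n_excluded = sum(!rel_ok))
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> absolute %.3f (SD %.3f, n=%d); relative %.2f%% (SD %.2f, n=%d, %d excluded)\n",
              x$absolute$mean, x$absolute$sd, x$absolute$n,
              x$relative$mean_pct, x$relative$sd_pct, x$relative$n,
              x$relative$n_excluded))
  invisible(x)
}

#' Decide which ICC form(s) to report
#'
#' If the three single-measure ICCs agree within `threshold` (default 0.01,
#' i.e. to the second decimal) measurement bias is negligible and the
#' one-way ICC(1) alone is reported; otherwise both two-way forms are
#' reported with a non-negligible-bias flag.
#'
#' @param results Named list with elements `oneway`, `agreement`,
#'   `consistency` (each an [icc()] result).
#' @param threshold Largest pairwise difference still called marginal.
#' @return List `report` (`"oneway"` or `"two_way_forms"`), `max_difference`,
#'   `bias_flag`.
#' @export
icc_discrepancy_gate <- function(results, threshold = 0.01) {
  need <- c("oneway", "agreement", "consistency")
  if (!all(need %in% names(results))) {
    stop_coptools("results must contain oneway, agreement and consistency ICCs",
                  "parameter_error")
  }
  est <- vapply(results[need], function(r) r$estimate, numeric(1))
  max_diff <- max(dist(est))
  if (max_diff < threshold) {
    list(report = "oneway", max_difference = max_diff, bias_flag = FALSE)
  } else {
    list(report = "two_way_forms", max_difference = max_diff, bias_flag = TRUE)
  }
}

#' Test-retest reliability report for one or more metrics
#'
#' For each metric's subjects-by-sessions matrix: all three ICC forms, the
#' discrepancy gate, the pooled SD (SD of all n*k observations about the
#' grand mean; configurable to the first session's SD), and SEM/MDC based
#' on the gated primary ICC.
#'
#' @param matrices Named list of subjects-by-sessions matrices (one per
#'   metric), or a single matrix.
#' @param sd_source `"pooled"` (all observations) or `"session1"`.
#' @param gate_threshold Passed to [icc_discrepancy_gate()].
#' @return An object of class `reliability_report`: per metric the three
#'   `icc_result`s, gate decision, `pooled_sd`, `sem`, `mdc`, `n_dropped`.
#' @export
reliability_report <- function(matrices, sd_source = c("pooled", "session1"),
                               gate_threshold = 0.01) {
  sd_source <- match.arg(sd_source)
  if (!is.list(matrices)) matrices <- list(metric = matrices)
  out <- lapply(matrices, function(values) {
    m <- measurement_matrix(values)
    iccs <- list(oneway = icc(m, "oneway"),
                 agreement = icc(m, "agreement"),
                 consistency = icc(m, "consistency"))
    gate <- icc_discrepancy_gate(iccs, gate_threshold)
    primary <- if (gate$report == "oneway") iccs$oneway else iccs$agreement
    pooled_sd <- if (sd_source == "pooled") sd(as.vector(m)) else sd(m[, 1])
    sm <- sem_mdc(pooled_sd, primary$estimate)
    list(icc = iccs, gate = gate, primary_kind = primary$kind,
         pooled_sd = pooled_sd, sd_source = sd_source,
         sem = sm$sem, mdc = sm$mdc,
         n = nrow(m), n_dropped = attr(m, "n_dropped"))
  })
  structure(out, class = "reliability_report")
}

#' Concurrent-validity report (index vs reference device)
#'
#' For each metric: ICC(A,1) on the subjects-by-devices matrix plus the
#' absolute/relative agreement of the paired values.
#'
#' @param index_values,reference_values Named lists (one numeric vector per
#'   metric) or single numeric vectors of paired per-subject values.
#' @return An object of class `validity_report`: per metric `icc_a1` and
#'   `agreement`.
#' @export
validity_report <- function(index_values, reference_values) {
  if (!is.list(index_values)) index_values <- list(metric = index_values)
  if (!is.list(reference_values)) reference_values <- list(metric = reference_values)
  metrics <- intersect(names(index_values), names(reference_values))
  if (length(metrics) == 0L) stop_coptools("no shared metric names", "parameter_error")
  out <- lapply(setNames(metrics, metrics), function(nm) {
    idx <- index_values[[nm]]; ref <- reference_values[[nm]]
    m <- measurement_matrix(cbind(index = idx, reference = ref))
    list(icc_a1 = icc(m, "agreement"),
         agreement = agreement(m[, "reference"], m[, "index"]),
         n = nrow(m), n_dropped = attr(m, "n_dropped"))
  })
  structure(out, class = "validity_report")
}

# flatten icc_result for JSON reports
.icc_to_list <- function(r) {
  r <- unclass(r)
  r[c("kind", "estimate", "ci95_low", "ci95_high", "f_value", "df1", "df2",
      "p_value", "n", "k", "degenerate")]
}
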