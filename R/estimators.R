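# Suspect-handling strategies and accuracy estimators.
#
# A three-category test (positive / suspect / negative) can be forced into a
# 2x2 table in several ways, or analysed as-is with conditional measures in
# which sensitivity and specificity are defined among definitive results and
# the probability of obtaining a definitive result becomes a measure of its
# own (the test yields Y+ and Y-).

#' Drop suspect results (conventional strategy)
#'
#' @param m a [matrix_3x2()].
#' @return A [matrix_2x2()] with the suspect row excluded.
#' @export
collapse_conventional <- function(m) {
  stopifnot(inherits(m, "matrix_3x2"))
  matrix_2x2(m$a, m$b, m$c, m$d)
}

#' Worst-case reassignment of suspect results
#'
#' Suspect results count as negative among diseased and as positive among
#' non-diseased, giving the most pessimistic accuracy consistent with the
#' data.
#'
#' @param m a [matrix_3x2()].
#' @return A [matrix_2x2()].
#' @export
collapse_worst <- function(m) {
  stopifnot(inherits(m, "matrix_3x2"))
  matrix_2x2(m$a, m$b + m$f, m$c + m$e, m$d)
}

#' Best-case reassignment of suspect results
#'
#' Suspect results count as positive among diseased and as negative among
#' non-diseased.
#'
#' @param m a [matrix_3x2()].
#' @return A [matrix_2x2()].
#' @export
collapse_best <- function(m) {
  stopifnot(inherits(m, "matrix_3x2"))
  matrix_2x2(m$a + m$e, m$b, m$c, m$d + m$f)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from the beta quantile representation. Accepts
#' fractional "counts" so it can also be applied to redistributed
#' (verification-bias-corrected) cells.
#'
#' @param successes number of successes (0 <= successes <= trials).
#' @param trials number of trials (> 0).
#' @param conf_level confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(815, 840)   # about [0.957, 0.981]
clopper_pearson <- function(successes, trials, conf_level = 0.95) {
  if (trials <= 0) stop("trials must be positive", call. = FALSE)
  if (successes < 0 || successes > trials) {
    stop("successes must lie in [0, trials]", call. = FALSE)
  }
  alpha <- 1 - conf_level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

# Log-method CI for a ratio of two independent binomial proportions p1/p2:
# exp(log(p1/p2) +/- z * sqrt((1-p1)/(n1 p1) + (1-p2)/(n2 p2))).
ratio_ci_log <- function(x1, n1, x2, n2, conf_level) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  est <- p1 / p2
  if (x1 == 0 || x2 == 0) {
    return(list(estimate = est, lower = NA_real_, upper = NA_real_,
                flag = "degenerate"))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt((1 - p1) / (n1 * p1) + (1 - p2) / (n2 * p2))
  list(estimate = est,
       lower = est * exp(-z * se),
       upper = est * exp(z * se),
       flag = "ok")
}

#' Simel log-method confidence interval for a likelihood ratio
#'
#' Interval for a ratio of two independent binomial proportions on the log
#' scale. `which = "positive"` gives the CI of LR+ = Se/(1-Sp),
#' `"negative"` that of LR- = (1-Se)/Sp; both need a 2x2 matrix.
#' `which = "suspect"` gives the CI of the conditional likelihood ratio of
#' suspect results, (1-Y+)/(1-Y-), and needs a 3x2 matrix.
#'
#' @param m a [matrix_2x2()] (`positive`/`negative`) or [matrix_3x2()]
#'   (`suspect`).
#' @param which one of `"positive"`, `"negative"`, `"suspect"`.
#' @param conf_level confidence level, default 0.95.
#' @return Named numeric vector `c(estimate, lower, upper)`; bounds are `NA`
#'   when a defining numerator count is zero (the ratio is degenerate).
#' @export
simel_lr_ci <- function(m, which = c("positive", "negative", "suspect"),
                        conf_level = 0.95) {
  which <- match.arg(which)
  if (which == "suspect") {
    stopifnot(inherits(m, "matrix_3x2"))
    r <- ratio_ci_log(m$e, m$a + m$e + m$c, m$f, m$b + m$f + m$d, conf_level)
  } else {
    stopifnot(inherits(m, "matrix_2x2") || inherits(m, "matrix_3x2"))
    if (inherits(m, "matrix_3x2")) m <- collapse_conventional(m)
    r <- switch(which,
      positive = ratio_ci_log(m$a, m$a + m$c, m$b, m$b + m$d, conf_level),
      negative = ratio_ci_log(m$c, m$a + m$c, m$d, m$b + m$d, conf_level))
  }
  c(estimate = r$estimate, lower = r$lower, upper = r$upper)
}

new_report <- function(measures, m, conf_level, type) {
  structure(list(measures = measures, matrix = m, conf_level = conf_level,
                 type = type),
            class = c(if (type == "conditional") "conditional_report",
                      "accuracy_report"))
}

measure_row <- function(name, est, lower, upper, flag = "ok") {
  data.frame(measure = name, estimate = est, lower = lower, upper = upper,
             flag = flag, stringsAsFactors = FALSE)
}

prop_row <- function(name, x, n, conf_level) {
  ci <- clopper_pearson(x, n, conf_level)
  measure_row(name, x / n, ci[["lower"]], ci[["upper"]])
}

#' Standard accuracy estimates from a 2x2 matrix
#'
#' Sensitivity, specificity, likelihood ratios, accuracy and disease
#' prevalence with 95% intervals: exact Clopper-Pearson for proportions and
#' the Simel log-method for likelihood ratios. When the false-positive cell
#' is zero, LR+ is reported as infinite and flagged rather than raising an
#' error (symmetrically for LR- when the false-negative cell is zero).
#'
#' @param m a [matrix_2x2()].
#' @param conf_level confidence level, default 0.95.
#' @param haldane add 0.5 to every cell when any cell is zero (off by
#'   default; the default reports infinite LRs with a flag instead).
#' @return An `accuracy_report`; see [report_values()].
#' @export
#' @examples
#' m <- collapse_conventional(pool_to_3x2(builtin_study_table()))
#' estimate_2x2(m)
estimate_2x2 <- function(m, conf_level = 0.95, haldane = FALSE) {
  stopifnot(inherits(m, "matrix_2x2"))
  if (isTRUE(haldane) && any(unlist(m[c("a", "b", "c", "d")]) == 0)) {
    m <- matrix_2x2(m$a + 0.5, m$b + 0.5, m$c + 0.5, m$d + 0.5)
  }
  n_dpos <- m$a + m$c
  n_dneg <- m$b + m$d
  if (n_dpos <= 0 || n_dneg <= 0) {
    stop("both disease margins must be positive for estimation", call. = FALSE)
  }
  n <- n_dpos + n_dneg
  se <- m$a / n_dpos
  sp <- m$d / n_dneg
  rows <- rbind(
    prop_row("se", m$a, n_dpos, conf_level),
    prop_row("sp", m$d, n_dneg, conf_level),
    lr_row("lr_pos", se / (1 - sp), m, "positive", conf_level, m$b > 0),
    lr_row("lr_neg", (1 - se) / sp, m, "negative", conf_level, m$c > 0),
    prop_row("accuracy", m$a + m$d, n, conf_level),
    prop_row("prevalence", n_dpos, n, conf_level)
  )
  new_report(rows, m, conf_level, "2x2")
}

lr_row <- function(name, est, m, which, conf_level, finite) {
  if (!is.finite(est) || !finite) {
    return(measure_row(name, if (finite) est else Inf, NA_real_, NA_real_,
                       flag = "infinite"))
  }
  ci <- simel_lr_ci(m, which, conf_level)
  if (anyNA(ci[c("lower", "upper")])) {
    measure_row(name, est, NA_real_, NA_real_, flag = "degenerate")
  } else {
    measure_row(name, est, ci[["lower"]], ci[["upper"]])
  }
}

#' Conditional accuracy estimates from a 3x2 matrix
#'
#' Keeps the three-category structure of the test. Sensitivity and
#' specificity are conditional on a definitive (positive or negative)
#' result, which makes them numerically identical to the conventional
#' strategy's estimates; in addition the report carries the positive and
#' negative test yields Y+ = (a+c)/(a+e+c) and Y- = (b+d)/(b+f+d), the
#' conditional likelihood ratio of suspect results (1-Y+)/(1-Y-), the
#' overall test yield, and accuracy and prevalence computed over all six
#' cells.
#'
#' @param m a [matrix_3x2()].
#' @param conf_level confidence level, default 0.95.
#' @return A `conditional_report` (inherits from `accuracy_report`).
#' @export
#' @examples
#' estimate_conditional_3x2(pool_to_3x2(builtin_study_table()))
estimate_conditional_3x2 <- function(m, conf_level = 0.95) {
  stopifnot(inherits(m, "matrix_3x2"))
  n_dpos <- m$a + m$e + m$c
  n_dneg <- m$b + m$f + m$d
  if (n_dpos <= 0 || n_dneg <= 0) {
    stop("both disease margins must be positive for estimation", call. = FALSE)
  }
  n <- n_dpos + n_dneg
  n_def <- m$a + m$b + m$c + m$d
  y_pos <- (m$a + m$c) / n_dpos
  y_neg <- (m$b + m$d) / n_dneg
  m2 <- collapse_conventional(m)
  se <- m$a / (m$a + m$c)
  sp <- m$d / (m$b + m$d)

  lr_sus <- if (y_pos == 1 && y_neg == 1) {
    measure_row("lr_suspect", NaN, NA_real_, NA_real_, flag = "indeterminate")
  } else if (y_neg == 1) {
    measure_row("lr_suspect", Inf, NA_real_, NA_real_, flag = "infinite")
  } else {
    est <- (1 - y_pos) / (1 - y_neg)
    ci <- simel_lr_ci(m, "suspect", conf_level)
    if (anyNA(ci[c("lower", "upper")])) {
      measure_row("lr_suspect", est, NA_real_, NA_real_, flag = "degenerate")
    } else {
      measure_row("lr_suspect", est, ci[["lower"]], ci[["upper"]])
    }
  }

  rows <- rbind(
    prop_row("se", m$a, m$a + m$c, conf_level),
    prop_row("sp", m$d, m$b + m$d, conf_level),
    lr_row("lr_pos", se / (1 - sp), m2, "positive", conf_level, m$b > 0),
    lr_row("lr_neg", (1 - se) / sp, m2, "negative", conf_level, m$c > 0),
    prop_row("y_pos", m$a + m$c, n_dpos, conf_level),
    prop_row("y_neg", m$b + m$d, n_dneg, conf_level),
    lr_sus,
    prop_row("overall_yield", n_def, n, conf_level),
    prop_row("accuracy", m$a + m$d, n, conf_level),
    prop_row("prevalence", n_dpos, n, conf_level)
  )
  new_report(rows, m, conf_level, "conditional")
}

#' Extract point estimates from an accuracy report
#'
#' @param report an `accuracy_report`.
#' @return Named numeric vector of point estimates.
#' @export
report_values <- function(report) {
  stopifnot(inherits(report, "accuracy_report"))
  stats::setNames(report$measures$estimate, report$measures$measure)
}

#' Serialize an accuracy report to JSON
#'
#' Fields are named `se`, `sp`, `lr_pos`, `lr_neg`, `accuracy`,
#' `prevalence` (plus `y_pos`, `y_neg`, `lr_suspect`, `overall_yield` for
#' conditional reports), each an object with `estimate`, `lower`, `upper`,
#' `flag`.
#'
#' @param report an `accuracy_report`.
#' @param ... passed to [jsonlite::toJSON()].
#' @return JSON string.
#' @export
report_to_json <- function(report, ...) {
  stopifnot(inherits(report, "accuracy_report"))
  out <- lapply(seq_len(nrow(report$measures)), function(i) {
    r <- report$measures[i, ]
    list(estimate = unbox_num(r$estimate), lower = unbox_num(r$lower),
         upper = unbox_num(r$upper), flag = jsonlite::unbox(r$flag))
  })
  names(out) <- report$measures$measure
  out$conf_level <- jsonlite::unbox(report$conf_level)
  jsonlite::toJSON(out, digits = NA, na = "null", ...)
}

unbox_num <- function(x) jsonlite::unbox(as.numeric(x))

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  cat(sprintf("Accuracy report (%s matrix, %.0f%% CI)\n",
              x$type, 100 * x$conf_level))
  tab <- x$measures
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits, format = "fg"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-13s %8s  [%s, %s]%s\n", tab$measure[i],
                fmt(tab$estimate[i]), fmt(tab$lower[i]), fmt(tab$upper[i]),
                if (tab$flag[i] != "ok") paste0("  <", tab$flag[i], ">") else ""))
  }
  invisible(x)
}
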