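# Partial-verification-bias corrections.
#
# Under a missing-at-random verification mechanism (verification decided by
# the test result and other observed information, never by disease status
# directly), the disease proportions observed among verified samples with a
# given test result apply to the non-verified samples with the same result.
# Begg and Greenes' closed form redistributes the non-verified totals
# accordingly; the 3x2 extension redistributes the suspect row too.

round_half_up <- function(x) floor(x + 0.5)

bg_split <- function(x_pos, x_neg, t0, label) {
  tot <- x_pos + x_neg
  if (t0 > 0 && tot <= 0) {
    stop("cannot redistribute ", t0, " non-verified '", label,
         "' samples: no verified samples in that row", call. = FALSE)
  }
  if (tot <= 0) return(c(0, 0))
  p <- x_pos / tot
  c(p * t0, (1 - p) * t0)
}

#' Begg-Greenes correction for a 2x2 matrix
#'
#' Redistributes the non-verified totals `t0_pos` (positive test) and
#' `t0_neg` (negative test) over disease states in the proportions observed
#' among verified samples with the same test result, then adds them to the
#' verified counts. With `round_cells = TRUE` (default) each redistributed
#' cell is rounded half-up to the nearest integer before combination;
#' unrounded redistribution conserves the totals exactly and is available
#' with `round_cells = FALSE`.
#'
#' @param verified a [matrix_2x2()] of histology-verified counts.
#' @param t0_pos,t0_neg non-verified totals for the positive and negative
#'   test categories.
#' @param round_cells round redistributed cells to integers (default `TRUE`).
#' @return A `corrected_matrix`: list with elements `verified`,
#'   `redistributed` (named vector), `combined` (a `matrix_2x2`), `t0`,
#'   `rounded`.
#' @export
#' @examples
#' tab <- builtin_study_table()
#' m <- collapse_conventional(pool_to_3x2(tab,
#'        gold_policy(include_followup_as_gold = FALSE)))
#' t0 <- unverified_totals(tab)
#' begg_greenes_2x2(m, t0[["t0_pos"]], t0[["t0_neg"]])
begg_greenes_2x2 <- function(verified, t0_pos, t0_neg, round_cells = TRUE) {
  stopifnot(inherits(verified, "matrix_2x2"), t0_pos >= 0, t0_neg >= 0)
  ab <- bg_split(verified$a, verified$b, t0_pos, "positive")
  cd <- bg_split(verified$c, verified$d, t0_neg, "negative")
  redist <- c(a = ab[1], b = ab[2], c = cd[1], d = cd[2])
  if (isTRUE(round_cells)) redist <- round_half_up(redist)
  combined <- matrix_2x2(verified$a + redist[["a"]], verified$b + redist[["b"]],
                         verified$c + redist[["c"]], verified$d + redist[["d"]])
  structure(list(verified = verified, redistributed = redist,
                 combined = combined,
                 t0 = c(t0_pos = t0_pos, t0_neg = t0_neg),
                 rounded = isTRUE(round_cells)),
            class = "corrected_matrix")
}

#' Begg-Greenes correction extended to the 3x2 matrix
#'
#' As [begg_greenes_2x2()] but keeping the suspect row: the non-verified
#' suspect total `t0_sus` is redistributed as
#' e' = e/(e+f) x t0_sus, f' = t0_sus - e'. The combined matrix can be fed
#' to [estimate_conditional_3x2()] for verification-bias-adjusted
#' conditional measures and test yields.
#'
#' @param verified a [matrix_3x2()] of histology-verified counts.
#' @param t0_pos,t0_sus,t0_neg non-verified totals per test category.
#' @param round_cells round redistributed cells to integers (default `TRUE`).
#' @return A `corrected_matrix` whose `combined` element is a `matrix_3x2`.
#' @export
begg_greenes_3x2 <- function(verified, t0_pos, t0_sus, t0_neg,
                             round_cells = TRUE) {
  stopifnot(inherits(verified, "matrix_3x2"),
            t0_pos >= 0, t0_sus >= 0, t0_neg >= 0)
  ab <- bg_split(verified$a, verified$b, t0_pos, "positive")
  ef <- bg_split(verified$e, verified$f, t0_sus, "suspect")
  cd <- bg_split(verified$c, verified$d, t0_neg, "negative")
  redist <- c(a = ab[1], b = ab[2], e = ef[1], f = ef[2],
              c = cd[1], d = cd[2])
  if (isTRUE(round_cells)) redist <- round_half_up(redist)
  combined <- matrix_3x2(verified$a + redist[["a"]], verified$b + redist[["b"]],
                         verified$e + redist[["e"]], verified$f + redist[["f"]],
                         verified$c + redist[["c"]], verified$d + redist[["d"]])
  structure(list(verified = verified, redistributed = redist,
                 combined = combined,
                 t0 = c(t0_pos = t0_pos, t0_sus = t0_sus, t0_neg = t0_neg),
                 rounded = isTRUE(round_cells)),
            class = "corrected_matrix")
}

#' @export
print.corrected_matrix <- function(x, ...) {
  cat("Begg-Greenes corrected matrix",
      if (x$rounded) "(redistributed cells rounded)" else "(unrounded)", "\n")
  cat("redistributed:",
      paste(sprintf("%s'=%.6g", names(x$redistributed), x$redistributed),
            collapse = ", "), "\n")
  print(x$combined)
  invisible(x)
}

#' Serialize a corrected matrix to JSON
#'
#' The report embeds the verified cells, the redistributed cells and the
#' rounding flag, so any downstream estimate is attributable to one of the
#' two redistribution modes.
#'
#' @param x a `corrected_matrix`.
#' @param ... passed to [jsonlite::toJSON()].
#' @return JSON string.
#' @export
corrected_to_json <- function(x, ...) {
  stopifnot(inherits(x, "corrected_matrix"))
  jsonlite::toJSON(list(
    verified = lapply(unclass(x$verified), jsonlite::unbox),
    redistributed = as.list(x$redistributed),
    combined = lapply(unclass(x$combined), jsonlite::unbox),
    t0 = as.list(x$t0),
    rounded = jsonlite::unbox(x$rounded)), digits = NA, auto_unbox = TRUE, ...)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' Total variance is the mean within-imputation variance plus
#' (1 + 1/M) times the between-imputation variance; the interval uses a
#' t reference with Barnard-Rubin degrees of freedom (falling back to the
#' classical Rubin df when no complete-data df is supplied, and to a normal
#' reference when the between-imputation variance is zero).
#'
#' @param point_estimates numeric vector of per-imputation estimates.
#' @param within_variances numeric vector of per-imputation variances
#'   (same length).
#' @param conf_level confidence level, default 0.95.
#' @param df_com complete-data degrees of freedom (optional).
#' @return List with `estimate`, `lower`, `upper`, `within`, `between`,
#'   `total_variance`, `df`, `m`.
#' @export
#' @examples
#' rubin_pool(c(0.90, 0.92, 0.91), c(1e-4, 1.2e-4, 9e-5))
rubin_pool <- function(point_estimates, within_variances, conf_level = 0.95,
                       df_com = NULL) {
  m <- length(point_estimates)
  if (length(within_variances) != m) {
    stop("point_estimates and within_variances must have the same length",
         call. = FALSE)
  }
  if (m < 2) stop("Rubin pooling needs at least 2 imputations", call. = FALSE)
  qbar <- mean(point_estimates)
  w <- mean(within_variances)
  b <- stats::var(point_estimates)
  total <- w + (1 + 1 / m) * b
  if (b <= 0 || total <= 0) {
    df <- Inf
  } else {
    lambda <- (1 + 1 / m) * b / total
    df_old <- (m - 1) / lambda^2
    if (!is.null(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      df <- df_old
    }
  }
  tq <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df) else
    stats::qnorm(1 - (1 - conf_level) / 2)
  half <- tq * sqrt(total)
  list(estimate = qbar, lower = qbar - half, upper = qbar + half,
       within = w, between = b, total_variance = total, df = df, m = m)
}
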