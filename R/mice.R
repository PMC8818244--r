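# Multiple imputation by chained equations, and its application to
# verification-bias correction on individual-level cohort records.
#
# The engine is deliberately small: binary targets are imputed from a
# Bayesian logistic draw (coefficients drawn from the asymptotic normal
# posterior of a fitted glm, then Bernoulli draws), continuous targets by
# predictive mean matching with parameter draws. Incomplete variables are
# visited cyclically for a fixed number of iterations per imputation.

#' Imputation settings
#'
#' @param m number of imputed datasets (at least 2). The cohort analyses
#'   here follow the convention of matching M to the percentage of missing
#'   data; 38 is the default used for verification correction of the
#'   built-in study (38% of samples lack histology).
#' @param iter chained-equation cycles per imputation (default 10).
#' @param seed random seed recorded in reports; `NULL` leaves the RNG state
#'   untouched.
#' @param predictors covariate columns used in every imputation model.
#' @return An object of class `imputation_settings`.
#' @export
imputation_settings <- function(m = 38, iter = 10, seed = NULL,
                                predictors = c("age", "side", "size_mm",
                                               "acr", "echoguided")) {
  if (m < 2) stop("at least 2 imputations are required (m >= 2)", call. = FALSE)
  if (iter < 1) stop("iter must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), iter = as.integer(iter), seed = seed,
                 predictors = predictors),
            class = "imputation_settings")
}

# Design matrix over ALL rows at once, so factor levels that only occur
# among the rows being imputed cannot break prediction.
build_design <- function(rhs, df) {
  if (length(rhs) == 0) {
    return(matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(stats::reformulate(rhs), df)
}

fit_coefs_glm <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  b <- fit$coefficients
  b[is.na(b)] <- 0
  b
}

# one chained-equations pass over the incomplete columns
cycle_impute <- function(df, targets, miss_idx, predictors) {
  for (target in targets) {
    mi <- miss_idx[[target]]
    if (length(mi) == 0) next
    rhs <- setdiff(unique(c(predictors,
                            setdiff(targets, target))), target)
    rhs <- rhs[rhs %in% names(df)]
    # drop predictors constant on the observed rows
    usable <- rhs[vapply(rhs, function(v) {
      x <- df[[v]][-mi]
      length(unique(x[!is.na(x)])) > 1
    }, logical(1))]
    X <- build_design(usable, df)
    Xobs <- X[-mi, , drop = FALSE]
    Xmis <- X[mi, , drop = FALSE]
    # parameter uncertainty via the bootstrap variant: refit on a resample
    # of the observed rows (robust to the separation-inflated vcov that
    # plagues asymptotic-normal draws when a cell is almost pure)
    bi <- sample.int(nrow(Xobs), nrow(Xobs), replace = TRUE)
    y <- df[[target]]
    if (is.numeric(y) && length(unique(y[-mi])) > 2) {
      # linear fit + predictive mean matching (5 donors)
      yobs <- y[-mi]
      beta_boot <- stats::lm.fit(Xobs[bi, , drop = FALSE], yobs[bi])$coefficients
      beta_boot[is.na(beta_boot)] <- 0
      beta_hat <- stats::lm.fit(Xobs, yobs)$coefficients
      beta_hat[is.na(beta_hat)] <- 0
      pred_mis <- drop(Xmis %*% beta_boot)
      pred_obs <- drop(Xobs %*% beta_hat)
      imp <- vapply(pred_mis, function(p) {
        d <- abs(pred_obs - p)
        donors <- order(d)[seq_len(min(5, length(d)))]
        yobs[sample(donors, 1)]
      }, numeric(1))
      df[[target]][mi] <- imp
    } else {
      # binary target: logistic fit on a bootstrap resample, Bernoulli draws
      lev <- sort(unique(y[-mi]))
      if (is.factor(lev)) lev <- as.character(lev)
      if (length(lev) < 2) {
        df[[target]][mi] <- lev[1]
        next
      }
      yobs <- as.integer(y[-mi] == lev[2])
      beta <- fit_coefs_glm(Xobs[bi, , drop = FALSE], yobs[bi])
      p <- stats::plogis(drop(Xmis %*% beta))
      df[[target]][mi] <- ifelse(stats::runif(length(mi)) < p, lev[2], lev[1])
    }
  }
  df
}

#' Multiple imputation by chained equations
#'
#' Fills every `NA` in `targets` (default: all incomplete columns) `m`
#' times, returning a list of completed data frames. Predictors must be
#' fully observed or themselves listed as targets.
#'
#' @param data a data.frame.
#' @param settings an [imputation_settings()].
#' @param targets columns to impute; defaults to every column containing
#'   `NA`.
#' @return List of `settings$m` completed data frames.
#' @export
chained_impute <- function(data, settings = imputation_settings(),
                           targets = NULL) {
  stopifnot(is.data.frame(data), inherits(settings, "imputation_settings"))
  if (is.null(targets)) {
    targets <- names(data)[vapply(data, anyNA, logical(1))]
  }
  for (p in settings$predictors) {
    if (p %in% names(data) && all(is.na(data[[p]]))) {
      stop("predictor '", p, "' is entirely missing", call. = FALSE)
    }
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)
  miss_idx <- lapply(data[targets], function(x) which(is.na(x)))
  names(miss_idx) <- targets
  lapply(seq_len(settings$m), function(i) {
    df <- data
    # initialize by sampling observed values
    for (target in targets) {
      mi <- miss_idx[[target]]
      if (length(mi) > 0) {
        pool <- df[[target]][-mi]
        df[[target]][mi] <- sample(pool, length(mi), replace = TRUE)
      }
    }
    for (it in seq_len(settings$iter)) {
      df <- cycle_impute(df, targets, miss_idx, settings$predictors)
    }
    df
  })
}

records_to_3x2 <- function(records) {
  k <- factor(records$fnac, levels = c("positive", "suspect", "negative"))
  d <- records$disease
  cnt <- function(kk, dd) sum(k == kk & d == dd, na.rm = TRUE)
  matrix_3x2(a = cnt("positive", 1), b = cnt("positive", 0),
             e = cnt("suspect", 1),  f = cnt("suspect", 0),
             c = cnt("negative", 1), d = cnt("negative", 0))
}

apply_strategy <- function(m3, strategy) {
  switch(strategy,
         conventional = collapse_conventional(m3),
         worst = collapse_worst(m3),
         best = collapse_best(m3),
         stop("unknown strategy: ", strategy, call. = FALSE))
}

#' MICE-based accuracy correction on cohort records
#'
#' In `mode = "verification"` (partial verification bias) histology is the
#' sole gold standard: disease status of every sample not verified by
#' histology is set to missing and multiply imputed from the covariates and
#' the FNAC result. In `mode = "suspect"` the suspect FNAC results are the
#' missing values, imputed as positive/negative from covariates and disease
#' status. Insufficient FNAC results are excluded up front. Per completed
#' dataset, sensitivity and specificity (and accuracy, prevalence) are
#' computed under `strategy`; estimates are pooled across imputations by
#' Rubin's rules on the probability scale (set `logit_scale = TRUE` to pool
#' on the logit scale) and the likelihood ratios are derived from the
#' pooled sensitivity and specificity.
#'
#' @param records individual-level data.frame with columns `age`, `side`,
#'   `size_mm`, `acr`, `echoguided`, `fnac`, `verification`, `disease`.
#' @param settings an [imputation_settings()].
#' @param strategy suspect-handling strategy for the per-dataset 2x2
#'   (`"conventional"`, `"worst"`, `"best"`); ignored in suspect mode.
#' @param mode `"verification"` or `"suspect"`.
#' @param conf_level confidence level, default 0.95.
#' @param logit_scale pool proportions on the logit scale (default `FALSE`).
#' @return A `mice_report`: list with `measures` (as in an
#'   `accuracy_report`), `pooled` (full Rubin output per measure), `m`,
#'   `mode`, `seed`.
#' @export
mice_accuracy_correct <- function(records,
                                  settings = imputation_settings(),
                                  strategy = "conventional",
                                  mode = c("verification", "suspect"),
                                  conf_level = 0.95,
                                  logit_scale = FALSE) {
  mode <- match.arg(mode)
  records <- as.data.frame(records)
  need <- c(settings$predictors, "fnac", "disease")
  miss_cols <- setdiff(need, names(records))
  if (length(miss_cols) > 0) {
    stop("records lack column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[records$fnac != "insufficient", , drop = FALSE]
  if (mode == "verification") {
    if (!"verification" %in% names(records)) {
      stop("verification mode needs a 'verification' column", call. = FALSE)
    }
    records$disease <- ifelse(records$verification == "histology",
                              records$disease, NA)
    records$fnac <- factor(records$fnac,
                           levels = c("positive", "suspect", "negative"))
    targets <- "disease"
  } else {
    records <- records[!is.na(records$disease), , drop = FALSE]
    records$fnac <- as.character(records$fnac)
    records$fnac[records$fnac == "suspect"] <- NA
    records$fnac <- factor(records$fnac, levels = c("positive", "negative"))
    targets <- "fnac"
  }
  for (v in c("side", "acr")) {
    if (v %in% names(records)) records[[v]] <- factor(records[[v]])
  }
  preds <- unique(c(settings$predictors,
                    if (mode == "verification") "fnac" else "disease"))
  eng_settings <- settings
  eng_settings$predictors <- preds
  completed <- chained_impute(records, eng_settings, targets = targets)

  per_prop <- function(df, name) {
    m3 <- records_to_3x2(df)
    m2 <- if (mode == "suspect") matrix_2x2(m3$a, m3$b, m3$c, m3$d) else
      apply_strategy(m3, strategy)
    n <- m2$a + m2$b + m2$c + m2$d
    vals <- c(se = m2$a / (m2$a + m2$c), sp = m2$d / (m2$b + m2$d),
              accuracy = (m2$a + m2$d) / n,
              prevalence = (m2$a + m2$c) / n)
    ns <- c(se = m2$a + m2$c, sp = m2$b + m2$d, accuracy = n, prevalence = n)
    list(est = vals, var = vals * (1 - vals) / ns)
  }
  per <- lapply(completed, per_prop)
  pooled <- lapply(c("se", "sp", "accuracy", "prevalence"), function(nm) {
    est <- vapply(per, function(x) x$est[[nm]], numeric(1))
    va <- vapply(per, function(x) x$var[[nm]], numeric(1))
    if (isTRUE(logit_scale)) {
      eps <- 1e-8
      p <- pmin(pmax(est, eps), 1 - eps)
      lo <- log(p / (1 - p))
      lv <- va / (p * (1 - p))^2   # delta method
      r <- rubin_pool(lo, lv, conf_level)
      inv <- function(x) stats::plogis(x)
      r$lower <- inv(r$lower); r$upper <- inv(r$upper)
      r$estimate <- inv(r$estimate)
      r
    } else {
      rubin_pool(est, va, conf_level)
    }
  })
  names(pooled) <- c("se", "sp", "accuracy", "prevalence")
  se <- pooled$se$estimate
  sp <- pooled$sp$estimate
  rows <- rbind(
    measure_row("se", se, max(0, pooled$se$lower), min(1, pooled$se$upper)),
    measure_row("sp", sp, max(0, pooled$sp$lower), min(1, pooled$sp$upper)),
    measure_row("lr_pos", if (sp < 1) se / (1 - sp) else Inf,
                NA_real_, NA_real_, flag = "derived"),
    measure_row("lr_neg", (1 - se) / sp, NA_real_, NA_real_, flag = "derived"),
    measure_row("accuracy", pooled$accuracy$estimate,
                max(0, pooled$accuracy$lower), min(1, pooled$accuracy$upper)),
    measure_row("prevalence", pooled$prevalence$estimate,
                max(0, pooled$prevalence$lower), min(1, pooled$prevalence$upper))
  )
  structure(list(measures = rows, pooled = pooled, m = settings$m,
                 mode = mode, strategy = strategy, seed = settings$seed,
                 conf_level = conf_level, type = "mice"),
            class = c("mice_report", "accuracy_report"))
}
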