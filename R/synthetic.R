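# Synthetic cohort generator.
#
# Emulates the statistical structure the correction methods assume: a
# three-category index test plus an insufficient-material failure mode,
# covariates whose distributions shift with the test category, a
# triple-test-driven verification rule (histology for positive/suspect
# cytology or high-risk imaging, otherwise mostly follow-up), loss to
# follow-up concentrated among test-negatives, and an imperfect follow-up
# reference. Verification depends only on the test category and the ACR
# imaging class - observed quantities - never on true disease status
# directly, so verification is missing-at-random by construction, which is
# exactly the assumption the Begg-Greenes and MICE corrections require.

CAT4 <- c("positive", "suspect", "negative", "insufficient")

#' Synthetic cohort generator configuration
#'
#' Defaults are calibrated once to the margins of the built-in breast-FNAC
#' study: prevalence 0.6; P(positive | diseased) = 0.85,
#' P(suspect | diseased) = 0.125; P(negative | non-diseased) = 0.946;
#' age/size/ACR/side/echo-guidance distributions per test category follow
#' the study's descriptive table (tumor size uses a gamma with the stated
#' mean and SD: sizes are positive and right-skewed); histology is nearly
#' certain for positive/suspect cytology, likelier for ACR 4-5 than for
#' low-risk imaging otherwise; marginal loss to follow-up is 21% for
#' negative and 3% for positive cytology; follow-up classifies disease with
#' sensitivity = specificity = 0.85; 3% of samples are insufficient,
#' independently of disease (missing completely at random).
#'
#' @param n cohort size.
#' @param prevalence disease prevalence.
#' @param fnac_given_dpos,fnac_given_dneg named probability vectors over
#'   `positive`, `suspect`, `negative` (must sum to 1).
#' @param insufficient_rate probability that a sample yields insufficient
#'   material, independent of everything else.
#' @param age_mean,age_sd,size_mean,size_sd named per-category vectors.
#' @param acr_probs list of per-category probability vectors over ACR 1-5.
#' @param side_left,echoguided named per-category probabilities.
#' @param p_hist_possus probability of histology for positive/suspect FNAC.
#' @param p_hist_acr_high,p_hist_low probability of histology for other
#'   samples with ACR >= 4 / ACR < 4.
#' @param loss_marginal named per-category marginal loss-to-follow-up
#'   probabilities.
#' @param followup_se,followup_sp accuracy of the follow-up reference.
#' @param seed default seed used by [generate_cohort()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n = 2000,
    prevalence = 0.6,
    fnac_given_dpos = c(positive = 0.85, suspect = 0.125, negative = 0.025),
    fnac_given_dneg = c(positive = 0.002, suspect = 0.052, negative = 0.946),
    insufficient_rate = 0.03,
    age_mean = c(positive = 61, suspect = 57, negative = 50, insufficient = 55),
    age_sd = c(positive = 14, suspect = 13, negative = 13, insufficient = 14),
    size_mean = c(positive = 28, suspect = 17, negative = 15, insufficient = 16),
    size_sd = c(positive = 41, suspect = 15, negative = 37, insufficient = 20),
    acr_probs = list(
      positive = c(0.001, 0.004, 0.015, 0.21, 0.77),
      suspect = c(0.001, 0.004, 0.08, 0.41, 0.505),
      negative = c(0.01, 0.125, 0.57, 0.245, 0.05),
      insufficient = c(0.01, 0.12, 0.50, 0.27, 0.10)),
    side_left = c(positive = 0.55, suspect = 0.54, negative = 0.52,
                  insufficient = 0.5),
    echoguided = c(positive = 0.41, suspect = 0.62, negative = 0.81,
                   insufficient = 0.7),
    p_hist_possus = 0.96,
    p_hist_acr_high = 0.5,
    p_hist_low = 0.08,
    loss_marginal = c(positive = 0.03, suspect = 0.015, negative = 0.21,
                      insufficient = 0.06),
    followup_se = 0.85,
    followup_sp = 0.85,
    seed = 1L) {
  chk_prob <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop("probabilities in '", nm,
                                 "' must lie in [0,1]", call. = FALSE)
  }
  for (v in list(prevalence = prevalence, insufficient_rate = insufficient_rate,
                 p_hist_possus = p_hist_possus,
                 p_hist_acr_high = p_hist_acr_high, p_hist_low = p_hist_low,
                 followup_se = followup_se, followup_sp = followup_sp)) {
    chk_prob(v, "scalar probability")
  }
  chk_prob(fnac_given_dpos, "fnac_given_dpos")
  chk_prob(fnac_given_dneg, "fnac_given_dneg")
  chk_prob(side_left, "side_left"); chk_prob(echoguided, "echoguided")
  chk_prob(loss_marginal, "loss_marginal")
  for (nm in c("fnac_given_dpos", "fnac_given_dneg")) {
    x <- get(nm)
    if (abs(sum(x) - 1) > 1e-8) stop(nm, " must sum to 1", call. = FALSE)
  }
  for (nm in names(acr_probs)) {
    chk_prob(acr_probs[[nm]], paste0("acr_probs$", nm))
    if (abs(sum(acr_probs[[nm]]) - 1) > 1e-8) {
      stop("acr_probs$", nm, " must sum to 1", call. = FALSE)
    }
  }
  structure(list(n = n, prevalence = prevalence,
                 fnac_given_dpos = fnac_given_dpos,
                 fnac_given_dneg = fnac_given_dneg,
                 insufficient_rate = insufficient_rate,
                 age_mean = age_mean, age_sd = age_sd,
                 size_mean = size_mean, size_sd = size_sd,
                 acr_probs = acr_probs, side_left = side_left,
                 echoguided = echoguided,
                 p_hist_possus = p_hist_possus,
                 p_hist_acr_high = p_hist_acr_high,
                 p_hist_low = p_hist_low,
                 loss_marginal = loss_marginal,
                 followup_se = followup_se, followup_sp = followup_sp,
                 seed = seed),
            class = "generator_config")
}

#' True conventional-strategy accuracy implied by a generator configuration
#'
#' The sensitivity and specificity a conventional (suspect-excluding)
#' analysis targets under the generating model:
#' `se = P(pos|D+) / (P(pos|D+) + P(neg|D+))` and symmetrically for
#' specificity.
#'
#' @param config a [generator_config()].
#' @return Named vector `c(se, sp, prevalence)`.
#' @export
generator_truth <- function(config) {
  p <- config$fnac_given_dpos
  q <- config$fnac_given_dneg
  c(se = unname(p[["positive"]] / (p[["positive"]] + p[["negative"]])),
    sp = unname(q[["negative"]] / (q[["positive"]] + q[["negative"]])),
    prevalence = config$prevalence)
}

sample_cat <- function(n, levels, prob) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

#' Generate a synthetic cohort
#'
#' Draws records along the generative chain disease -> FNAC category ->
#' covariates -> verification route -> observed disease status (exact under
#' histology, misclassified at the configured follow-up accuracy under
#' follow-up, missing when lost).
#'
#' @param config a [generator_config()].
#' @param n cohort size (defaults to `config$n`).
#' @param seed seed (defaults to `config$seed`).
#' @return data.frame with columns `age`, `side`, `size_mm`, `acr`,
#'   `echoguided`, `fnac`, `verification`, `disease` (observed; `NA` when
#'   lost) and `disease_true` (generator-internal truth).
#' @export
generate_cohort <- function(config = generator_config(), n = config$n,
                            seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(data.frame(age = numeric(0), side = character(0),
                      size_mm = numeric(0), acr = integer(0),
                      echoguided = integer(0), fnac = character(0),
                      verification = character(0), disease = integer(0),
                      disease_true = integer(0)))
  }
  d <- stats::rbinom(n, 1, config$prevalence)
  fnac <- character(n)
  cats3 <- c("positive", "suspect", "negative")
  fnac[d == 1] <- sample_cat(sum(d == 1), cats3, config$fnac_given_dpos[cats3])
  fnac[d == 0] <- sample_cat(sum(d == 0), cats3, config$fnac_given_dneg[cats3])
  fnac[stats::runif(n) < config$insufficient_rate] <- "insufficient"

  age <- round(stats::rnorm(n, config$age_mean[fnac], config$age_sd[fnac]))
  sm <- config$size_mean[fnac]; ss <- config$size_sd[fnac]
  size <- round(stats::rgamma(n, shape = (sm / ss)^2, rate = sm / ss^2), 1)
  acr <- integer(n)
  for (cat in CAT4) {
    idx <- fnac == cat
    if (any(idx)) acr[idx] <- sample_cat(sum(idx), 1:5, config$acr_probs[[cat]])
  }
  side <- ifelse(stats::runif(n) < config$side_left[fnac], "left", "right")
  echo <- as.integer(stats::runif(n) < config$echoguided[fnac])

  # verification route: depends only on fnac and acr (MAR by construction)
  p_hist <- ifelse(fnac %in% c("positive", "suspect"), config$p_hist_possus,
                   ifelse(acr >= 4, config$p_hist_acr_high, config$p_hist_low))
  hist <- stats::runif(n) < p_hist
  p_lost_cond <- pmin(1, config$loss_marginal[fnac] / pmax(1e-12, 1 - p_hist))
  lost <- !hist & (stats::runif(n) < p_lost_cond)
  verification <- ifelse(hist, "histology", ifelse(lost, "lost", "followup"))

  fu_pos_prob <- ifelse(d == 1, config$followup_se, 1 - config$followup_sp)
  fu_obs <- as.integer(stats::runif(n) < fu_pos_prob)
  disease_obs <- ifelse(verification == "histology", d,
                        ifelse(verification == "followup", fu_obs, NA))
  data.frame(age = age, side = side, size_mm = size, acr = acr,
             echoguided = echo, fnac = fnac, verification = verification,
             disease = as.integer(disease_obs), disease_true = d,
             stringsAsFactors = FALSE)
}

#' Cross-tabulate a cohort into a verification table
#'
#' Uses the observed disease status: histology columns for
#' histology-verified samples, follow-up columns for follow-up-verified
#' samples, the lost column for samples lost to follow-up.
#'
#' @param records cohort data.frame (as from [generate_cohort()] or
#'   [read_cohort()]).
#' @return A [verification_table()].
#' @export
tabulate_cohort <- function(records) {
  cnt <- function(cat, vr, dv) {
    idx <- records$fnac == cat & records$verification == vr
    if (is.null(dv)) sum(idx) else sum(idx & records$disease == dv, na.rm = TRUE)
  }
  verification_table(data.frame(
    test_result = CAT4,
    hist_dpos = vapply(CAT4, cnt, numeric(1), vr = "histology", dv = 1),
    hist_dneg = vapply(CAT4, cnt, numeric(1), vr = "histology", dv = 0),
    fu_dpos = vapply(CAT4, cnt, numeric(1), vr = "followup", dv = 1),
    fu_dneg = vapply(CAT4, cnt, numeric(1), vr = "followup", dv = 0),
    lost = vapply(CAT4, cnt, numeric(1), vr = "lost", dv = NULL)
  ))
}

#' Descriptive summary of a cohort by test category
#'
#' Mean (SD) for continuous covariates, n (%) for categorical ones and for
#' the verification/disease outcome, one column per FNAC category.
#'
#' @param records cohort data.frame.
#' @return data.frame of class `cohort_summary`, one row per
#'   characteristic.
#' @export
summarize_cohort <- function(records) {
  cats <- CAT4[CAT4 %in% unique(records$fnac)]
  col_for <- function(cat) {
    r <- records[records$fnac == cat, , drop = FALSE]
    n <- nrow(r)
    msd <- function(x) if (n == 0) "-" else
      sprintf("%.1f (%.1f)", mean(x), if (n > 1) stats::sd(x) else 0)
    npct <- function(idx) {
      k <- sum(idx, na.rm = TRUE)
      if (n == 0) "0 (0%)" else sprintf("%d (%.1f%%)", k, 100 * k / n)
    }
    c(n = as.character(n),
      age = msd(r$age),
      size_mm = msd(r$size_mm),
      side_left = npct(r$side == "left"),
      acr_1 = npct(r$acr == 1), acr_2 = npct(r$acr == 2),
      acr_3 = npct(r$acr == 3), acr_4 = npct(r$acr == 4),
      acr_5 = npct(r$acr == 5),
      echoguided = npct(r$echoguided == 1),
      hist_benign = npct(r$verification == "histology" & r$disease == 0),
      hist_malignant = npct(r$verification == "histology" & r$disease == 1),
      fu_benign = npct(r$verification == "followup" & r$disease == 0),
      fu_malignant = npct(r$verification == "followup" & r$disease == 1),
      lost = npct(r$verification == "lost"))
  }
  cols <- lapply(cats, col_for)
  out <- data.frame(characteristic = names(cols[[1]]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(cats)) out[[cats[i]]] <- unname(cols[[i]])
  structure(out, class = c("cohort_summary", "data.frame"))
}

#' Write a cohort to CSV
#'
#' Writes the individual-level dialect: columns `age`, `side`, `size_mm`,
#' `acr`, `echoguided`, `fnac`, `verification`, `disease` (the internal
#' `disease_true` column is not written).
#'
#' @param records cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  cols <- c("age", "side", "size_mm", "acr", "echoguided", "fnac",
            "verification", "disease")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path path to an individual-level CSV (dialect of
#'   [write_cohort()]).
#' @return data.frame of cohort records.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fnac", "verification", "disease")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$fnac), CAT4)
  if (length(bad) > 0) stop("unknown fnac value(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$verification), c("histology", "followup", "lost"))
  if (length(bad) > 0) stop("unknown verification value(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  df
}
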