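#' @keywords internal
"_PACKAGE"

TEST_CATEGORIES <- c("positive", "suspect", "negative", "insufficient")
COUNT_COLS <- c("hist_dpos", "hist_dneg", "fu_dpos", "fu_dneg", "lost")

#' Construct a verification table
#'
#' A verification table cross-classifies tumor samples by test category
#' (positive / suspect / negative / insufficient) and verification outcome:
#' disease-positive or disease-negative on histology, disease-positive or
#' disease-negative on imaging follow-up, or lost to follow-up.
#'
#' The unit of analysis is the tumor sample, not the patient; rows are
#' never deduplicated.
#'
#' @param counts data.frame with columns `test_result`, `hist_dpos`,
#'   `hist_dneg`, `fu_dpos`, `fu_dneg`, `lost`; one row per test category.
#' @return An object of class `verification_table` (a data.frame).
#' @export
verification_table <- function(counts) {
  stopifnot(is.data.frame(counts))
  missing_cols <- setdiff(c("test_result", COUNT_COLS), names(counts))
  if (length(missing_cols) > 0) {
    stop("verification table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  counts$test_result <- as.character(counts$test_result)
  unknown <- setdiff(counts$test_result, c(TEST_CATEGORIES, "total"))
  if (length(unknown) > 0) {
    stop("unknown test category label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tot_row <- counts[counts$test_result == "total", , drop = FALSE]
  counts <- counts[counts$test_result != "total", , drop = FALSE]
  if (anyDuplicated(counts$test_result)) {
    stop("duplicated test category row", call. = FALSE)
  }
  # absent categories are zero-filled so the four categories are exhaustive
  for (cat in setdiff(TEST_CATEGORIES, counts$test_result)) {
    counts <- rbind(counts,
                    cbind(data.frame(test_result = cat),
                          as.data.frame(as.list(stats::setNames(rep(0L, 5), COUNT_COLS)))))
  }
  counts <- counts[match(TEST_CATEGORIES, counts$test_result), ]
  rownames(counts) <- NULL
  for (cc in COUNT_COLS) {
    x <- counts[[cc]]
    if (!is.numeric(x) || anyNA(x)) {
      stop("non-numeric or missing count in column '", cc, "'", call. = FALSE)
    }
    if (any(x < 0) || any(x != round(x))) {
      bad <- which(x < 0 | x != round(x))[1]
      stop("count must be a non-negative integer: column '", cc, "', row '",
           counts$test_result[bad], "' has value ", x[bad], call. = FALSE)
    }
    counts[[cc]] <- as.integer(round(x))
  }
  if (nrow(tot_row) == 1) {
    for (cc in COUNT_COLS) {
      declared <- as.numeric(tot_row[[cc]])
      found <- sum(counts[[cc]])
      if (!is.na(declared) && declared != found) {
        stop("declared total for column '", cc, "' is ", declared,
             " but cells sum to ", found, call. = FALSE)
      }
    }
  }
  structure(counts, class = c("verification_table", "data.frame"))
}

#' Read a verification table from CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `test_result,hist_dpos,hist_dneg,fu_dpos,fu_dneg,lost`, one row per test
#' category (`positive`, `suspect`, `negative`, `insufficient`) and an
#' optional final `total` row whose cells, when present, are checked against
#' the column sums.
#'
#' @param path path to a CSV file.
#' @return A validated [verification_table()].
#' @export
#' @examples
#' path <- system.file("extdata", "breast_fnac_table.csv",
#'                     package = "dxverify")
#' load_verification_table(path)
load_verification_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  verification_table(raw)
}

#' Write a verification table to CSV
#'
#' Writes the dialect read by [load_verification_table()], including a
#' `total` row, so that a write/load round trip reproduces the counts.
#'
#' @param table a `verification_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_verification_table <- function(table, path) {
  stopifnot(inherits(table, "verification_table"))
  out <- as.data.frame(table)
  tot <- c(list(test_result = "total"),
           lapply(out[COUNT_COLS], sum))
  out <- rbind(out, as.data.frame(tot))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The built-in breast-FNAC study table
#'
#' Verification table of 1820 breast tumor samples from a single-center
#' fine-needle-aspiration-cytology (FNAC) cohort: FNAC category versus
#' disease status on histology, disease status on 18-month imaging
#' follow-up, or lost to follow-up.
#'
#' @return A `verification_table` with grand total 1820.
#' @export
#' @examples
#' tab <- builtin_study_table()
#' sum(tab$lost)   # 191 samples lost to follow-up
builtin_study_table <- function() {
  verification_table(data.frame(
    test_result = c("positive", "suspect", "negative", "insufficient"),
    hist_dpos   = c(803L, 120L,  24L, 18L),
    hist_dneg   = c(  1L,  31L, 115L, 26L),
    fu_dpos     = c( 12L,   0L,   1L,  0L),
    fu_dneg     = c(  0L,   1L, 471L,  6L),
    lost        = c( 26L,   2L, 160L,  3L)
  ))
}

#' Gold-standard pooling policy
#'
#' Controls how a verification table is collapsed to an analysis matrix:
#' whether follow-up results are pooled with histology as disease status,
#' and whether lost-to-follow-up and insufficient samples are dropped.
#' Insufficient FNAC results are treated as missing completely at random
#' and are always excluded before estimation (`drop_insufficient` must be
#' `TRUE`); the row is still validated and stored so declared totals check.
#'
#' @param include_followup_as_gold pool follow-up with histology (`TRUE`,
#'   default) or use histology alone.
#' @param drop_lost exclude samples lost to follow-up (default `TRUE`).
#' @param drop_insufficient exclude insufficient FNAC results (must be `TRUE`).
#' @return An object of class `gold_policy`.
#' @export
gold_policy <- function(include_followup_as_gold = TRUE,
                        drop_lost = TRUE,
                        drop_insufficient = TRUE) {
  if (!isTRUE(drop_insufficient)) {
    stop("insufficient results must be excluded (drop_insufficient = TRUE)",
         call. = FALSE)
  }
  structure(list(include_followup_as_gold = isTRUE(include_followup_as_gold),
                 drop_lost = isTRUE(drop_lost),
                 drop_insufficient = TRUE),
            class = "gold_policy")
}

#' Construct a 3x2 decision matrix
#'
#' Cells follow the usual decision-matrix notation: `a` positive & diseased,
#' `b` positive & non-diseased, `e` suspect & diseased, `f` suspect &
#' non-diseased, `c` negative & diseased, `d` negative & non-diseased.
#' Cells are integers for raw data but may be fractional after an unrounded
#' verification-bias correction.
#'
#' @param a,b,e,f,c,d non-negative cell counts.
#' @return An object of class `matrix_3x2`.
#' @export
matrix_3x2 <- function(a, b, e, f, c, d) {
  x <- c(a = a, b = b, e = e, f = f, c = c, d = d)
  if (anyNA(x) || any(x < 0)) stop("all cells must be non-negative", call. = FALSE)
  structure(as.list(x), class = "matrix_3x2")
}

#' Construct a 2x2 decision matrix
#'
#' @param a,b,c,d non-negative cell counts (`a` true positive, `b` false
#'   positive, `c` false negative, `d` true negative).
#' @return An object of class `matrix_2x2`.
#' @export
matrix_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (anyNA(x) || any(x < 0)) stop("all cells must be non-negative", call. = FALSE)
  structure(as.list(x), class = "matrix_2x2")
}

#' @export
print.matrix_3x2 <- function(x, ...) {
  m <- matrix(unlist(x[c("a", "b", "e", "f", "c", "d")]), ncol = 2, byrow = TRUE,
              dimnames = list(c("positive", "suspect", "negative"),
                              c("D+", "D-")))
  cat("3x2 decision matrix\n")
  print(m)
  invisible(x)
}

#' @export
print.matrix_2x2 <- function(x, ...) {
  m <- matrix(unlist(x[c("a", "b", "c", "d")]), ncol = 2, byrow = TRUE,
              dimnames = list(c("positive", "negative"), c("D+", "D-")))
  cat("2x2 decision matrix\n")
  print(m)
  invisible(x)
}

#' @export
print.verification_table <- function(x, ...) {
  cat("Verification table (", sum(unlist(x[COUNT_COLS])), " samples)\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Collapse a verification table to a 3x2 decision matrix
#'
#' Applies the gold-standard policy: by default disease status is pooled
#' over histology and follow-up, samples lost to follow-up are excluded,
#' and the insufficient row is excluded.
#'
#' @param table a `verification_table`.
#' @param policy a [gold_policy()].
#' @return A [matrix_3x2()].
#' @export
#' @examples
#' pool_to_3x2(builtin_study_table())         # pooled gold standards
#' pool_to_3x2(builtin_study_table(),
#'             gold_policy(include_followup_as_gold = FALSE))
pool_to_3x2 <- function(table, policy = gold_policy()) {
  stopifnot(inherits(table, "verification_table"), inherits(policy, "gold_policy"))
  if (!policy$drop_lost && !policy$include_followup_as_gold) {
    stop("lost samples carry no disease status; drop_lost = FALSE requires pooling",
         call. = FALSE)
  }
  row_of <- function(cat) table[table$test_result == cat, ]
  dpos <- function(r) r$hist_dpos + if (policy$include_followup_as_gold) r$fu_dpos else 0L
  dneg <- function(r) r$hist_dneg + if (policy$include_followup_as_gold) r$fu_dneg else 0L
  p <- row_of("positive"); s <- row_of("suspect"); n <- row_of("negative")
  matrix_3x2(a = dpos(p), b = dneg(p),
             e = dpos(s), f = dneg(s),
             c = dpos(n), d = dneg(n))
}

#' Non-verified totals per test category
#'
#' When histology is treated as the sole gold standard, every sample
#' verified only by follow-up or lost to follow-up counts as non-verified.
#' Returns those totals for the three informative test categories
#' (insufficient excluded).
#'
#' @param table a `verification_table`.
#' @return Named integer vector `c(t0_pos, t0_sus, t0_neg)`.
#' @export
#' @examples
#' unverified_totals(builtin_study_table())  # 38, 3, 632
unverified_totals <- function(table) {
  stopifnot(inherits(table, "verification_table"))
  t0 <- function(cat) {
    r <- table[table$test_result == cat, ]
    as.integer(r$fu_dpos + r$fu_dneg + r$lost)
  }
  c(t0_pos = t0("positive"), t0_sus = t0("suspect"), t0_neg = t0("negative"))
}
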