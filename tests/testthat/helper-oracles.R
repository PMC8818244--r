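# Independent oracles and fixture builders used across the suite.

# random non-degenerate 3x2 matrices for property tests
random_3x2 <- function(rng_n = 1) {
  lapply(seq_len(rng_n), function(i) {
    repeat {
      x <- stats::rpois(6, lambda = sample(c(3, 20, 200), 1)) +
        c(1, 0, 0, 0, 1, 1) # keep a, c, d positive so estimators are defined
      m <- matrix_3x2(x[1], x[2], x[3], x[4], x[5], x[6])
      if (m$a + m$c > 0 && m$b + m$d > 0) return(m)
    }
  })
}

# exhaustive tail-probability search for the Clopper-Pearson bounds,
# independent of qbeta: bisection on the exact binomial tail sums
cp_oracle <- function(x, n, conf_level = 0.95, tol = 1e-12) {
  alpha <- 1 - conf_level
  tail_ge <- function(p) sum(stats::dbinom(x:n, n, p))   # P(X >= x)
  tail_le <- function(p) sum(stats::dbinom(0:x, n, p))   # P(X <= x)
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else bisect(function(p) tail_ge(p) > alpha / 2, 0, 1)
  upper <- if (x == n) 1 else bisect(function(p) tail_le(p) < alpha / 2, 0, 1)
  c(lower = lower, upper = upper)
}

# brute-force joint-probability-table oracle for the reference-positive
# conditionals: enumerate (disease, index test, reference) outcomes
eq_oracle <- function(sT, cT, prev, sD, cD) {
  states <- expand.grid(d = c(1, 0), t = c("pos", "neg"), r = c(1, 0))
  p <- apply(states, 1, function(s) {
    d <- as.numeric(s[["d"]]); r <- as.numeric(s[["r"]]); t <- s[["t"]]
    pd <- if (d == 1) prev else 1 - prev
    pt <- if (d == 1) {
      if (t == "pos") sT else 1 - sT
    } else {
      if (t == "pos") 1 - cT else cT
    }
    pr <- if (d == 1) {
      if (r == 1) sD else 1 - sD
    } else {
      if (r == 1) 1 - cD else cD
    }
    pd * pt * pr
  })
  states$p <- p
  joint <- function(t, r) sum(states$p[states$t == t & states$r == r])
  c(p_rpos_tpos = joint("pos", 1) / (joint("pos", 1) + joint("pos", 0)),
    p_rpos_tneg = joint("neg", 1) / (joint("neg", 1) + joint("neg", 0)))
}

# builtin-table derived matrices reused by several files
pooled_3x2 <- function() pool_to_3x2(builtin_study_table())
hist_3x2 <- function() {
  pool_to_3x2(builtin_study_table(),
              gold_policy(include_followup_as_gold = FALSE))
}

# small cohort generator wrapper with quiet defaults for fast tests
quick_cohort <- function(n = 800, seed = 11, ...) {
  cfg <- generator_config(n = n, seed = seed, ...)
  generate_cohort(cfg)
}

count_cols <- c("hist_dpos", "hist_dneg", "fu_dpos", "fu_dneg", "lost")

# direct cross-tabulation of records into a 3x2 matrix (test-side re-count)
records_to_3x2_oracle <- function(records) {
  cnt <- function(cat, d) {
    sum(records$fnac == cat & records$disease == d, na.rm = TRUE)
  }
  matrix_3x2(cnt("positive", 1), cnt("positive", 0),
             cnt("suspect", 1), cnt("suspect", 0),
             cnt("negative", 1), cnt("negative", 0))
}

prior_mean_oracle <- function(a, b) a / (a + b)
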