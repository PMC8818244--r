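test_that("suspect-handling collapses follow their reassignment rules", {
  m <- pooled_3x2()
  conv <- collapse_conventional(m)
  expect_equal(unlist(unclass(conv)), c(a = 815, b = 1, c = 25, d = 586))
  worst <- collapse_worst(m)
  expect_equal(unlist(unclass(worst)), c(a = 815, b = 33, c = 145, d = 586))
  best <- collapse_best(m)
  expect_equal(unlist(unclass(best)), c(a = 935, b = 1, c = 25, d = 618))
  # worst-case sensitivity on the study data
  expect_equal(worst$a / (worst$a + worst$c), 815 / 960, tolerance = 1e-12)
  # best-case sensitivity matches the published estimate
  expect_equal(best$a / (best$a + best$c), 935 / 960, tolerance = 1e-12)
  expect_equal(round(best$a / (best$a + best$c), 3), 0.974)

  # with no suspect results all three strategies coincide
  m0 <- matrix_3x2(12, 3, 0, 0, 4, 30)
  expect_equal(unclass(collapse_worst(m0)), unclass(collapse_conventional(m0)))
  expect_equal(unclass(collapse_best(m0)), unclass(collapse_conventional(m0)))

  # suspect-only input collapses to an empty conventional matrix
  expect_equal(unlist(unclass(collapse_conventional(matrix_3x2(0, 0, 5, 7, 0, 0)))),
               c(a = 0, b = 0, c = 0, d = 0))
})

test_that("2x2 estimates reproduce the study's conventional column", {
  r <- estimate_2x2(matrix_2x2(815, 1, 25, 586))
  v <- report_values(r)
  expect_equal(unname(v["se"]), 815 / 840, tolerance = 1e-12)
  expect_equal(round(unname(v["se"]), 3), 0.970)
  expect_equal(round(unname(v["sp"]), 3), 0.998)
  expect_equal(unname(v["lr_pos"]), (815 / 840) / (1 / 587), tolerance = 1e-12)
  expect_equal(round(unname(v["prevalence"]), 3), 0.589, tolerance = 0.002)
  lr <- r$measures[r$measures$measure == "lr_pos", ]
  expect_equal(lr$lower, 80.4, tolerance = 0.01)
  expect_equal(lr$upper, 4037, tolerance = 0.01)
})

test_that("degenerate 2x2 inputs are flagged, not fatal", {
  perfect <- estimate_2x2(matrix_2x2(10, 0, 0, 10))
  v <- report_values(perfect)
  expect_equal(unname(v["se"]), 1)
  expect_equal(unname(v["sp"]), 1)
  expect_true(is.infinite(v[["lr_pos"]]))
  expect_equal(perfect$measures$flag[perfect$measures$measure == "lr_pos"],
               "infinite")
  expect_error(estimate_2x2(matrix_2x2(0, 5, 0, 5)), "margins")
  # optional Haldane correction gives finite LRs
  h <- report_values(estimate_2x2(matrix_2x2(10, 0, 0, 10), haldane = TRUE))
  expect_true(is.finite(h[["lr_pos"]]))
})

test_that("conditional 3x2 estimates reproduce the study's conditional column", {
  r <- estimate_conditional_3x2(pooled_3x2())
  v <- report_values(r)
  expect_equal(unname(v["y_pos"]), 840 / 960, tolerance = 1e-12)
  expect_equal(round(unname(v["y_neg"]), 3), 0.948)
  expect_equal(round(unname(v["lr_suspect"]), 1), 2.4)
  expect_equal(round(unname(v["overall_yield"]), 3), 0.904, tolerance = 0.002)
  expect_equal(round(unname(v["accuracy"]), 3), 0.887)
  expect_equal(round(unname(v["prevalence"]), 3), 0.608)
  ls <- r$measures[r$measures$measure == "lr_suspect", ]
  expect_equal(round(ls$lower, 1), 1.7)
  expect_equal(round(ls$upper, 1), 3.5)
})

test_that("conditional se/sp equal the conventional strategy on random matrices", {
  set.seed(401)
  for (m in random_3x2(25)) {
    cond <- report_values(estimate_conditional_3x2(m))
    conv <- report_values(estimate_2x2(collapse_conventional(m)))
    expect_equal(cond[["se"]], conv[["se"]], tolerance = 1e-12)
    expect_equal(cond[["sp"]], conv[["sp"]], tolerance = 1e-12)
    expect_equal(cond[["lr_pos"]], conv[["lr_pos"]], tolerance = 1e-12)
  }
})

test_that("worst <= conventional <= best for se and sp when suspects exist", {
  set.seed(402)
  for (m in random_3x2(25)) {
    se_of <- function(m2) m2$a / (m2$a + m2$c)
    sp_of <- function(m2) m2$d / (m2$b + m2$d)
    if (m$e > 0) {
      expect_lte(se_of(collapse_worst(m)), se_of(collapse_conventional(m)))
      expect_lte(se_of(collapse_conventional(m)), se_of(collapse_best(m)))
    }
    if (m$f > 0) {
      expect_lte(sp_of(collapse_worst(m)), sp_of(collapse_conventional(m)))
      expect_lte(sp_of(collapse_conventional(m)), sp_of(collapse_best(m)))
    }
    # yields and suspect-free limit
    cond <- report_values(estimate_conditional_3x2(m))
    expect_true(all(cond[c("y_pos", "y_neg", "overall_yield")] >= 0))
    expect_true(all(cond[c("y_pos", "y_neg", "overall_yield")] <= 1))
  }
  # no suspects: yields are 1 and conditional se/sp equal plain se/sp
  v <- report_values(estimate_conditional_3x2(matrix_3x2(20, 2, 0, 0, 5, 40)))
  expect_equal(unname(v["y_pos"]), 1)
  expect_equal(unname(v["y_neg"]), 1)
  expect_equal(unname(v["overall_yield"]), 1)
  expect_equal(v[["se"]], 20 / 25)
})

test_that("Clopper-Pearson matches the exhaustive tail-search oracle for n <= 12", {
  for (n in c(1, 3, 7, 12)) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n)
      want <- cp_oracle(x, n)
      expect_equal(got[["lower"]], want[["lower"]], tolerance = 1e-9)
      expect_equal(got[["upper"]], want[["upper"]], tolerance = 1e-9)
    }
  }
})

test_that("Clopper-Pearson interval contains the point and shrinks with n", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  ci <- clopper_pearson(840, 960)
  expect_lt(ci[["lower"]], 840 / 960)
  expect_gt(ci[["upper"]], 840 / 960)
  ci815 <- clopper_pearson(815, 840)
  expect_equal(round(unname(ci815), 2), c(0.96, 0.98))
  widths <- sapply(c(1, 4, 16, 64), function(k) {
    ci <- clopper_pearson(30 * k, 40 * k)
    ci[["upper"]] - ci[["lower"]]
  })
  expect_true(all(diff(widths) < 0))
  expect_error(clopper_pearson(1, 0), "positive")
})

test_that("Simel log-method interval is symmetric on the log scale for p1 = p2", {
  m <- matrix_2x2(30, 30, 70, 70)  # se = 0.3, 1 - sp = 0.3, equal n
  ci <- simel_lr_ci(m, "positive")
  expect_equal(ci[["estimate"]], 1)
  expect_equal(log(ci[["lower"]]) + log(ci[["upper"]]), 0, tolerance = 1e-12)
  # degenerate numerator is flagged with NA bounds
  ci0 <- simel_lr_ci(matrix_2x2(0, 3, 10, 50), "positive")
  expect_true(is.na(ci0[["lower"]]))
  # suspect LR interval reproduces the published [1.7, 3.5]
  cis <- simel_lr_ci(pooled_3x2(), "suspect")
  expect_equal(round(unname(cis), 1)[2:3], c(1.7, 3.5))
})
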