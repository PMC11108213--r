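test_that("standard curves fit by least squares with diagnostics", {
  std <- tibble::tibble(concentration = c(0.25, 0.5, 1),
                        absorbance = 0.05 + 0.5 * c(0.25, 0.5, 1))
  cv <- suppressWarnings(fit_standard_curve(std))
  expect_equal(cv$slope, 0.5, tolerance = 1e-12)
  expect_equal(cv$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1)
  expect_s3_class(suppressWarnings(generics::tidy(cv)), "tbl_df")
  expect_equal(generics::glance(cv)$slope, 0.5)

  expect_error(fit_standard_curve(std[1:2, ]), "3 distinct")
  expect_error(fit_standard_curve(
    tibble::tibble(concentration = c(1, 1, 1), absorbance = c(1, 2, 3))),
    "3 distinct")

  # seeded simulation with known truth: slope recovered within 3 SE
  set.seed(5)
  conc <- rep(c(0.125, 0.25, 0.5, 1), each = 3)
  sim <- tibble::tibble(concentration = conc,
                        absorbance = 0.02 + 0.5 * conc + rnorm(12, 0, 0.01))
  cv2 <- fit_standard_curve(sim)
  se <- generics::tidy(cv2)$std.error[2]
  expect_lt(abs(cv2$slope - 0.5), 3 * se)
})

test_that("quantify inverts the curve with background and clipping", {
  cv <- suppressWarnings(fit_standard_curve(tibble::tibble(
    concentration = c(0.25, 0.5, 1), absorbance = 0.05 + 0.5 * c(0.25, 0.5, 1))))
  # absorbance equal to background + intercept maps to zero
  q <- quantify(0.05 + 0.1, cv, background = 0.1)
  expect_equal(q$concentration, 0)
  # round trip through the known curve
  conc <- c(0.3, 0.6, 0.9)
  q2 <- quantify(0.05 + 0.5 * conc + 0.1, cv, background = 0.1)
  expect_equal(q2$concentration, conc, tolerance = 1e-10)
  expect_false(any(q2$clipped))
  # negative results clip with a flag
  q3 <- quantify(0.01, cv)
  expect_equal(q3$concentration, 0)
  expect_true(q3$clipped)
  # out-of-range flag
  expect_true(quantify(0.05 + 0.5 * 3, cv)$extrapolated)
})

test_that("enzyme activity converts absorbance to U/mL definitionally", {
  gc <- suppressWarnings(fit_standard_curve(tibble::tibble(
    concentration = c(0.5, 1, 2, 4), absorbance = 0.02 + 0.35 * c(0.5, 1, 2, 4))))
  # at the curve intercept: zero activity
  expect_equal(enzyme_activity(0.02, gc)$activity_U_ml, 0)
  # doubling incubation halves activity
  a30 <- enzyme_activity(0.7, gc, incubation_min = 30)$activity_U_ml
  a60 <- enzyme_activity(0.7, gc, incubation_min = 60)$activity_U_ml
  expect_equal(a30, 2 * a60)
  # definitional check: glucose_mM * Vrxn / (t * Venz)
  out <- enzyme_activity(0.02 + 0.35 * 2, gc, incubation_min = 30,
                         volume_mL = 0.5, reaction_volume_mL = 1)
  expect_equal(out$glucose_mM, 2, tolerance = 1e-10)
  expect_equal(out$activity_U_ml, 2 * 1 / (30 * 0.5), tolerance = 1e-10)
})

test_that("group comparison computes percent increases and fold changes", {
  tab <- tibble::tibble(
    arm = "AC",
    group = rep(c("control", "240"), each = 4),
    replicate = rep(1:4, 2),
    assay = "Bradford_A595",
    value = c(rep(1, 4), rep(1.45, 4)))
  res <- compare_groups(tab)
  r240 <- res[res$group == "240", ]
  expect_equal(r240$percent_increase, 45, tolerance = 1e-10)
  expect_equal(r240$fold, 1.45, tolerance = 1e-10)
  expect_equal(res$percent_increase[res$group == "control"], 0)
  # treated mean equal to control: 0% and fold 1
  tab$value <- 1
  res0 <- compare_groups(tab)
  expect_equal(res0$percent_increase, c(0, 0))
  expect_equal(res0$fold, c(1, 1))
  expect_error(compare_groups(tab[tab$group != "control", ]), "control")
})

test_that("percent increase and fold are invariant under common rescaling", {
  tabs <- make_assay_tables(assay_spec(seed = 3))
  r1 <- compare_groups(tabs$bradford)
  t2 <- tabs$bradford
  t2$value <- t2$value * 7.3
  r2 <- compare_groups(t2)
  expect_equal(r1$percent_increase, r2$percent_increase, tolerance = 1e-10)
  expect_equal(r1$fold, r2$fold, tolerance = 1e-10)
})

test_that("densitometry calibrates and inverts lane areas", {
  bsa <- tibble::tibble(concentration = c(0.25, 0.5, 1),
                        area = 10000 * c(0.25, 0.5, 1))
  out <- suppressWarnings(densitometry_concentrations(5000, bsa))
  expect_equal(out$concentration, 0.5, tolerance = 1e-10)
  expect_error(densitometry_concentrations(5000, bsa[1, ]), "3 distinct")
})

test_that("null-effect simulations stay within sampling noise", {
  # viability/growth generated with unit multipliers: the estimated
  # percent increase should be statistically indistinguishable from zero
  hits <- 0; total <- 0; n_rep <- 100
  for (s in seq_len(n_rep)) {
    tabs <- make_assay_tables(assay_spec(seed = s))
    res <- compare_groups(tabs$od600)
    r <- res[res$group == "240", ]
    hits <- hits + sum(r$p_welch > 0.05)
    total <- total + nrow(r)
  }
  expect_gte(hits / total, 0.9)
})
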