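test_that("paired t-test matches an independent textbook implementation", {
  a <- c(1, 2, 3, 4, 5)
  b <- a + c(1, -1, 1, -1, 1)
  expect_equal(paired_t_test(a, b), oracle_paired_t_p(a, b), tolerance = 1e-12)
  expect_equal(paired_t_test(b, a), paired_t_test(a, b))  # two-tailed symmetry

  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(13); y <- rnorm(13, mean = 0.3)
    expect_equal(paired_t_test(x, y), oracle_paired_t_p(x, y), tolerance = 1e-12)
  }
})

test_that("paired t-test degenerate and error cases", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(paired_t_test(c(1, 2, 3), c(0, 1, 2)), 0)  # constant nonzero diff
  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 1), "at least 2")
})

test_that("significance flags use strict inequalities in both modes", {
  expect_true(flag_significance(0.01, "discrepancy"))
  expect_false(flag_significance(0.2, "discrepancy"))
  expect_true(flag_significance(0.6, "agreement"))
  expect_false(flag_significance(0.01, "agreement"))
  expect_false(flag_significance(0.05, "discrepancy"))
  expect_false(flag_significance(0.05, "agreement"))
  expect_true(flag_significance(0.09, "discrepancy", alpha = 0.1))
  expect_error(flag_significance(1.2, "agreement"), "0, 1")
})

make_test_case <- function(seed, discrepancy = 0) {
  make_synthetic_cohort(2, seed, discrepancy,
                        geom = grid_geometry(c(24, 24, 20), c(1.5, 1.5, 2.5)))[[1]]
}

test_that("analyze_patient assembles the per-patient pipeline", {
  case <- make_test_case(50, discrepancy = 5)
  rec <- analyze_patient(
    fields = list(algA = case$field_a, algB = case$field_b),
    masks_target = case$masks,
    masks_moving = case$masks["gtv"],
    volume_ratios = case$truth$volume_ratio,
    patient_id = "p1",
    x_list = c(2.5, 10)
  )
  expect_s3_class(rec, "patient_record")
  expect_setequal(unique(rec$structure), names(case$masks))
  # DICE only for the structure present in the moving set
  expect_setequal(rec$structure[rec$metric == "dice_orig"], "gtv")
  expect_equal(sum(rec$metric == "dice_deformed"), 2L)
  # SD sections present for the single algorithm pair, at both X values
  expect_equal(sum(rec$metric == "sd_2.5"), length(case$masks))
  expect_true(all(rec$value[rec$metric == "sd_2.5"] > 0))
  expect_true(all(is.finite(rec$value)))
  # jvh_ratio close to 1 by construction
  expect_true(all(abs(rec$value[rec$metric == "jvh_ratio"] - 1) < 0.03))
})

test_that("single-algorithm records omit SD sections; identity fields leave DICE alone", {
  g <- grid_geometry(c(24, 24, 20), c(1.5, 1.5, 2.5))
  ident <- displacement_field(g, array(0, dim = c(g$dims, 3)))
  masks <- list(organ = make_sphere_mask(c(17, 17, 24), 9, g, "organ"))
  rec <- analyze_patient(list(only = ident), masks, masks_moving = masks,
                         patient_id = "p")
  expect_false(any(startsWith(rec$metric, "sd_")))
  expect_equal(rec$value[rec$metric == "dice_deformed"],
               rec$value[rec$metric == "dice_orig"])
  expect_equal(rec$value[rec$metric == "jvh_mean"], 1)
  expect_equal(rec$value[rec$metric == "jvh_std"], 0)
})

test_that("zero-discrepancy cases yield identically zero SD statistics", {
  case <- make_test_case(51, discrepancy = 0)
  rec <- analyze_patient(list(a = case$field_a, b = case$field_b), case$masks,
                         patient_id = "p", x_list = c(2.5, 35))
  sd_rows <- rec[startsWith(rec$metric, "sd_"), ]
  expect_gt(nrow(sd_rows), 0)
  expect_true(all(sd_rows$value == 0))
  jvh <- rec[rec$metric == "jvh_mean", ]
  expect_equal(jvh$value[jvh$algorithm == "a"], jvh$value[jvh$algorithm == "b"])
})

test_that("summarize_cohort aggregates cells and honours declared comparisons", {
  rec1 <- analyze_patient(
    list(a = make_test_case(52)$field_a), make_test_case(52)$masks,
    volume_ratios = make_test_case(52)$truth$volume_ratio, patient_id = "p1")
  rec2 <- rec1
  rec2$patient <- "p2"
  summ <- summarize_cohort(list(rec1, rec2))
  expect_true(all(summ$stats$sd == 0))
  expect_equal(summ$stats$min, summ$stats$mean)
  expect_equal(summ$stats$max, summ$stats$mean)
  expect_true(all(summ$stats$n == 2))
  expect_null(summ$tests)
  expect_error(summarize_cohort(list(rec1)), "at least 2")

  cmp <- comparison("gtv",
                    a = list(metric = "jvh_mean", algorithm = "a"),
                    b = list(metric = "contour_volume_ratio"),
                    mode = "agreement")
  summ2 <- summarize_cohort(list(rec1, rec2), comparisons = list(cmp))
  expect_equal(nrow(summ2$tests), 1L)
  expect_true(summ2$tests$p_value >= 0 && summ2$tests$p_value <= 1)

  tdy <- tidy(summ2)
  expect_identical(tdy, summ2$stats)
  gl <- glance(summ2)
  expect_equal(gl$n_patients, 2L)
  expect_equal(gl$n_tests, 1L)

  tbl <- cohort_table(summ2, "jvh_mean")
  expect_true("a" %in% names(tbl))
  expect_equal(nrow(tbl), 3L)
})

test_that("a constant bias of 3x the per-patient noise is flagged at n = 13", {
  set.seed(53)
  noise_sd <- 0.02
  base <- rnorm(13, mean = 1, sd = noise_sd)
  biased <- base + 3 * noise_sd + rnorm(13, sd = noise_sd / 10)
  records <- dplyr::bind_rows(lapply(1:13, function(i) {
    tibble::tibble(
      patient = sprintf("p%02d", i),
      structure = "lung",
      metric = "jvh_mean",
      algorithm = c("ref", "biased"),
      algorithm_b = NA_character_,
      value = c(base[i], biased[i])
    )
  }))
  summ <- summarize_cohort(records, comparisons = list(
    comparison("lung", a = list(metric = "jvh_mean", algorithm = "biased"),
               b = list(metric = "jvh_mean", algorithm = "ref"),
               mode = "discrepancy")
  ))
  expect_true(summ$tests$significant)
  expect_lt(summ$tests$p_value, 0.001)
})

test_that("end-to-end determinism: identical inputs give identical records", {
  case <- make_test_case(54, discrepancy = 3)
  args <- list(list(a = case$field_a, b = case$field_b), case$masks)
  rec1 <- do.call(analyze_patient, args)
  rec2 <- do.call(analyze_patient, args)
  expect_identical(rec1, rec2)
})
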