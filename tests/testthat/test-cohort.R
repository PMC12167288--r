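test_that("read_cohort maps fields, treats empty cells as missing, keeps order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "lesion_id,b_type,suv_max,depth,macro_type,treatment",
    "L1,B2,3.2,SM2,0-Is,ER",
    "L2,B1,,LPM,0-IIc,ER"
  ), f)
  co <- read_cohort(f)
  expect_equal(co$lesion_id, c("L1", "L2"))
  expect_equal(as.character(co$b_type), c("B2", "B1"))
  expect_equal(co$suv_max, c(3.2, NA_real_))
  expect_equal(as.character(co$depth), c("SM2", "LPM"))
  expect_equal(co$elevated, c(TRUE, FALSE))
})

test_that("validation errors name the offending row and column", {
  bad_depth <- data.frame(lesion_id = "L1", b_type = "B2", depth = "SM9")
  expect_error(validate_cohort(bad_depth), "depth 'SM9' in row 1")
  bad_b <- data.frame(lesion_id = c("L1", "L2"), b_type = c("B1", "B9"),
                      depth = "EP")
  expect_error(validate_cohort(bad_b), "b_type 'B9' in row 2")
  neg_suv <- data.frame(lesion_id = "L1", b_type = "B1", depth = "EP",
                        suv_max = -1)
  expect_error(validate_cohort(neg_suv), "negative suv_max in row 1")
  clash <- data.frame(lesion_id = "L1", b_type = "B1", depth = "EP",
                      macro_type = "0-IIa", elevated = FALSE)
  expect_error(validate_cohort(clash), "contradicts macro_type")
})

test_that("write/read round-trips all field values", {
  co <- generate_cohort(np_cohort_config(n = 40, seed = 3))
  co$suv_max[c(2, 5)] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back, co)
})

test_that("eligibility excludes prior therapy and beyond-T1b depth with reasons", {
  co <- make_cohort(
    b_type = rep("B1", 5), depth = rep("EP", 5),
    prior_therapy = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    depth_over_t1b = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  res <- apply_eligibility(co)
  expect_equal(nrow(res$kept), 3)
  expect_setequal(res$excluded$reason,
                  c("prior_therapy", "depth_beyond_T1b"))
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(co))

  empty <- apply_eligibility(co[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("the study-scale eligibility flow keeps 127 of 525 records", {
  co <- make_cohort(
    b_type = rep("B2", 525), depth = rep("MM", 525),
    prior_therapy = rep(c(TRUE, FALSE), c(377, 148)),
    depth_over_t1b = rep(c(FALSE, TRUE, FALSE), c(377, 21, 127))
  )
  res <- apply_eligibility(co)
  expect_equal(nrow(res$kept), 127)
  expect_equal(nrow(res$excluded), 398)
})

test_that("apply_eligibility is idempotent", {
  co <- generate_cohort(np_cohort_config(n = 30, seed = 8))
  co$prior_therapy[1:4] <- TRUE
  once <- apply_eligibility(co)$kept
  twice <- apply_eligibility(once)$kept
  expect_equal(twice, once)
})

test_that("depth grouping is total, surjective and ordered as specified", {
  expect_equal(
    as.character(depth_group(c("EP", "LPM", "MM", "SM1", "SM2", "SM3"))),
    c("EP_LPM", "EP_LPM", "MM_SM1", "MM_SM1", "SM2_SM3", "SM2_SM3")
  )
  expect_setequal(as.character(depth_group(depth_levels())),
                  depth_group_levels())
  expect_equal(is_deep(c("SM1", "SM2", "SM3")), c(FALSE, TRUE, TRUE))
  expect_error(depth_group("SM9"), "unknown depth code")
})

test_that("macroscopic types 0-IIa and 0-Is are elevated, others are not", {
  expect_equal(
    as.character(classify_morphology(c("0-IIa", "0-Is", "0-IIb", "0-IIc",
                                       "0-III"))),
    c("elevated", "elevated", "non_elevated", "non_elevated",
      "non_elevated")
  )
  expect_error(classify_morphology(""), "empty")
})

test_that("SUV normalises concentration by dose per gram of body weight", {
  expect_equal(compute_suv(0.01, 200, 60000), 3.0)
  expect_equal(compute_suv(0.005, 300, 60000), 1.0)
  # normalisation identity: concentration equal to dose/weight gives SUV 1
  for (d in c(150, 250)) {
    for (w in c(50000, 70000)) {
      expect_equal(compute_suv(d / w, d, w), 1.0)
    }
  }
  expect_error(compute_suv(0, 200, 60000), "positive")
  expect_error(compute_suv(0.01, -5, 60000), "positive")
})

test_that("cohort summary counts are consistent with cohort size", {
  co <- generate_cohort(np_cohort_config(n = 137, seed = 2))
  s <- cohort_summary(co)
  expect_equal(s$n_lesions, 137)
  expect_equal(sum(unlist(s$n_per_depth_group)), 137)
  expect_lte(sum(unlist(s$n_elevated_per_binary_depth)), 137)
  expect_equal(sum(unlist(s$n_treatment)), 137)
  f <- withr::local_tempfile(fileext = ".json")
  write_cohort_summary(s, f)
  expect_equal(jsonlite::read_json(f)$n_lesions, 137)
})
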