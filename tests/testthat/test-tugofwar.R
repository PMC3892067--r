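# Printed values of the packaged CDC20 deletion-panel summary (ratio and
# relative change at 2 d.p. as published).
published_ratio <- c(
  "Wild type" = 0.40, bck2 = 0.57, bub2 = 0.68, cdh1 = 0.29, cin8 = 0.69,
  clb1 = 0.33, clb2 = 0.36, clb3 = 0.36, clb4 = 0.32, clb5 = 0.34,
  clb6 = 0.42, cln1 = 0.26, cln2 = 0.52, cln3 = 0.47, lte1 = 0.38,
  mad2 = 0.74, mbp1 = 0.69, mih1 = 0.46, sic1 = 0.28, swe1 = 0.34,
  swi4 = 0.37, swi5 = 0.40, swi6 = 0.55, whi5 = 0.49)
published_change <- c(
  bck2 = 0.43, bub2 = 0.70, cdh1 = -0.27, cin8 = 0.73, clb1 = -0.16,
  clb2 = -0.10, clb3 = -0.11, clb4 = -0.19, clb5 = -0.14, clb6 = 0.04,
  cln1 = -0.35, cln2 = 0.30, cln3 = 0.17, lte1 = -0.06, mad2 = 0.86,
  mbp1 = 0.73, mih1 = 0.14, sic1 = -0.29, swe1 = -0.15, swi4 = -0.07,
  swi5 = -0.01, swi6 = 0.38, whi5 = 0.22)

test_that("ratio and relative change reproduce worked values", {
  wt <- strain_record("Wild type", vector = list(mean = 149.7), tev = list(mean = 59.8))
  bck2 <- strain_record("bck2", vector = list(mean = 44.3), tev = list(mean = 25.3))
  cln1 <- strain_record("cln1", vector = list(mean = 80.1), tev = list(mean = 20.7))
  expect_equal(round(tev_vector_ratio(wt), 2), 0.40)
  expect_equal(round(tev_vector_ratio(bck2), 2), 0.57)
  expect_equal(tev_vector_ratio(strain_record("eq", list(mean = 3), list(mean = 3))), 1)
  expect_equal(round(relative_copy_number_change(bck2, wt), 2), 0.43)
  expect_equal(round(relative_copy_number_change(cln1, wt), 2), -0.35)
  expect_equal(relative_copy_number_change(wt, wt), 0)
  expect_error(strain_record("bad", list(mean = 0), list(mean = 2)),
               class = "tipigtow_invalid_input")
})

test_that("relative change is reciprocal and scale invariant", {
  set.seed(7)
  for (i in 1:20) {
    a <- strain_record("a", list(mean = runif(1, 10, 200)), list(mean = runif(1, 5, 80)))
    b <- strain_record("b", list(mean = runif(1, 10, 200)), list(mean = runif(1, 5, 80)))
    x <- relative_copy_number_change(a, b)
    y <- relative_copy_number_change(b, a)
    expect_equal((1 + x) * (1 + y), 1, tolerance = 1e-12)
    cc <- runif(1, 0.1, 10)
    a2 <- strain_record("a", list(mean = cc * a$vector$mean),
                        list(mean = cc * a$tev$mean))
    expect_equal(tev_vector_ratio(a2), tev_vector_ratio(a), tolerance = 1e-12)
    expect_equal(relative_copy_number_change(a2, b), x, tolerance = 1e-12)
  }
})

test_that("interaction classification respects the dead band", {
  expect_identical(classify_interaction(-0.35, 0.05), "lower-limit-increased")
  expect_identical(classify_interaction(0.86, 0.05), "lower-limit-decreased")
  expect_identical(classify_interaction(0, 0.05), "neutral")
  expect_identical(classify_interaction(c(-0.01, 0.051), 0.05),
                   c("neutral", "lower-limit-decreased"))
  expect_error(classify_interaction(0.1, -1), class = "tipigtow_invalid_input")
})

test_that("the packaged deletion panel reproduces the published columns", {
  report <- build_panel_report(cdc20_panel())
  expect_identical(nrow(report), 24L)
  expect_identical(sum(is.na(report$relative_change)), 1L)
  ratio <- setNames(report$ratio, report$strain)
  change <- setNames(report$relative_change, report$strain)
  # every cell within the rounding band of the published 2-d.p. values
  expect_true(all(abs(ratio - published_ratio[names(ratio)]) <= 0.015))
  expect_true(all(abs(change[names(published_change)] -
                        published_change) <= 0.015))
  # recomputation from 1-d.p. means matches the published rounding in
  # 23/24 ratio cells and 19/23 relative-change cells; the rest shift by
  # one unit in the last digit because the published table was rounded
  # from unrounded replicate means
  exact_ratio <- round(ratio, 2) == published_ratio[names(ratio)]
  expect_identical(sum(exact_ratio), 23L)
  expect_identical(names(which(!exact_ratio)), "mih1")
  exact_change <- round(change[names(published_change)], 2) == published_change
  expect_identical(sum(exact_change), 19L)
  expect_setequal(names(which(!exact_change)), c("cdh1", "clb1", "mbp1", "sic1"))
  # and the full columns agree with direct arithmetic on the means
  oracle <- panel_oracle()
  expect_equal(unname(ratio), oracle$ratio, tolerance = 1e-12)
  expect_equal(unname(change), oracle$relative_change, tolerance = 1e-12)
})

test_that("panel construction validates its inputs", {
  wt <- strain_record("Wild type", list(mean = 100), list(mean = 40))
  solo <- build_panel_report(list(wt))
  expect_identical(nrow(solo), 1L)
  expect_true(is.na(solo$relative_change))
  dup <- list(wt, strain_record("bck2", list(mean = 44), list(mean = 25)),
              strain_record("bck2", list(mean = 44), list(mean = 25)))
  expect_error(build_panel_report(dup), class = "tipigtow_invalid_input")
  expect_error(build_panel_report(list(wt), reference_name = "nope"),
               class = "tipigtow_invalid_input")
})

test_that("serialization rounds half to even at 2 d.p. and round-trips", {
  records <- list(strain_record("Wild type", list(mean = 100), list(mean = 40)),
                  strain_record("m1", list(mean = 80), list(mean = 33)))
  report <- build_panel_report(records, delta_method_se = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel_report(report, path)
  back <- utils::read.delim(path)
  expect_equal(back$ratio, round(report$ratio, 2))
  # delta-method SE column exists but is NA without replicate SDs
  expect_true(all(is.na(report$ratio_se)))
  rec2 <- strain_record("m2", list(mean = 80, sd = 8, n = 4),
                        list(mean = 33, sd = 3, n = 4))
  rep2 <- build_panel_report(c(records, list(rec2)), delta_method_se = TRUE)
  se <- rep2$ratio_se[rep2$strain == "m2"]
  expect_equal(se, (33 / 80) * sqrt((3 / 33)^2 / 4 + (8 / 80)^2 / 4),
               tolerance = 1e-12)
})
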