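test_that("quality CSV loading builds sorted series and handles markers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "attribute,packaging,temperature_c,time_weeks,value,sd,n,qualifier,terminated",
    "color_acceptance,clear_plastic,25,9,5.5,1.4,50,,0",
    "color_acceptance,clear_plastic,25,3,5.9,1.6,50,,0",
    "color_acceptance,clear_plastic,25,6,5.2,1.5,50,,0",
    "tbc,clear_plastic,25,0,2.5e-1,,,lt,0",
    "color_acceptance,al_bag_n2,45,9,,,,,1",
    "color_acceptance,al_bag_n2,45,3,5.6,1.7,50,,0",
    "color_acceptance,al_bag_n2,45,6,4.9,1.7,50,,0"
  ), path)
  ds <- load_quality_csv(path)
  expect_equal(nrow(ds$series), 3)

  s <- extract_series(ds, "color_acceptance", "clear_plastic", 25)
  expect_equal(s$time_weeks, c(3, 6, 9))
  expect_equal(s$value, c(5.9, 5.2, 5.5))
  expect_false(attr(s, "terminated_early"))

  # empty-value marker row is dropped but flags the series as terminated
  s2 <- extract_series(ds, "color_acceptance", "al_bag_n2", 45)
  expect_equal(nrow(s2), 2)
  expect_true(attr(s2, "terminated_early"))

  # detection-limit record carries the limit as value plus the flag
  tbc <- extract_series(ds, "tbc", "clear_plastic", 25)
  expect_true(tbc$below_detection)
  expect_equal(tbc$value, 0.25)
})

test_that("header-only files yield an empty dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("attribute,packaging,temperature_c,time_weeks,value,sd,n,qualifier,terminated",
             path)
  ds <- load_quality_csv(path)
  expect_s3_class(ds, "storage_dataset")
  expect_equal(nrow(ds$series), 0)
  expect_equal(nrow(compare_actual_predicted(ds)), 0)
})

test_that("malformed and duplicate rows fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "attribute,packaging,temperature_c,time_weeks,value,sd,n,qualifier,terminated",
    "color_acceptance,clear_plastic,25,3,5.9,,,,0",
    "color_acceptance,clear_plastic,25,six,5.2,,,,0"
  ), path)
  expect_error(load_quality_csv(path), "line 3",
               class = "shelfkin_parse_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "attribute,packaging,temperature_c,time_weeks,value,sd,n,qualifier,terminated",
    "color_acceptance,clear_plastic,25,3,5.9,,,,0",
    "color_acceptance,clear_plastic,25,3,5.2,,,,0"
  ), path2)
  expect_error(load_quality_csv(path2), "duplicate",
               class = "shelfkin_duplicate_error")
})

test_that("round trip write -> load preserves series, flags and qualifiers", {
  ds <- builtin_fixture("table2_sensory")
  ds$observations <- dplyr::bind_rows(
    ds$observations,
    builtin_fixture("table1_microbial")$observations)
  info <- ds$series
  info$terminated <- info$terminated_early
  ds <- storage_dataset(
    dplyr::left_join(
      ds$observations,
      info[, c("attribute", "packaging", "temperature_c", "terminated")],
      by = c("attribute", "packaging", "temperature_c")),
    baseline = ds$baseline)

  path <- withr::local_tempfile(fileext = ".csv")
  write_quality_csv(ds, path)
  back <- load_quality_csv(path, baseline = ds$baseline)
  expect_equal(back$observations, ds$observations)
  expect_equal(back$series, ds$series)

  # a second write is byte-identical (stable serialisation)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_quality_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("microbial count parsing distinguishes measured and non-detects", {
  m <- parse_count("65")
  expect_equal(m$qualifier, "measured")
  expect_equal(m$value, 65)

  lt <- parse_count("<2.5e-1")
  expect_equal(lt$qualifier, "below_detection")
  expect_equal(lt$limit, 0.25)
  expect_true(is.na(lt$value))

  expect_error(parse_count("0"), class = "shelfkin_parse_error")
  expect_error(parse_count("<abc"), class = "shelfkin_parse_error")
})

test_that("maximum measured counts skip detection limits", {
  ds <- builtin_fixture("table1_microbial")
  n2 <- max_measured_count(ds, "tbc", "al_bag_n2")
  expect_equal(n2$qualifier, "measured")
  expect_equal(n2$value, 65)
  air <- max_measured_count(ds, "tbc", "al_bag_air")
  expect_equal(air$value, 85)

  # yeast/mold never exceeded the detection limit in any packaging
  ymc <- max_measured_count(ds, "ymc", "al_bag_n2")
  expect_equal(ymc$qualifier, "below_detection")
  expect_equal(ymc$limit, 0.25)

  expect_error(max_measured_count(ds, "tbc", "no_such_bag"),
               class = "shelfkin_lookup_error")
})

test_that("delta_e is the CIE76 Euclidean distance and a metric", {
  expect_equal(delta_e(c(40.6, 0, 0), c(40.6, 0, 0)), 0)
  expect_equal(delta_e(c(3, 4, 0), c(0, 0, 0)), 5)
  # lightness-only change from the week-0 reference
  expect_equal(delta_e(c(31.92, 2, -1), c(40.6, 2, -1)), 8.68)

  withr::with_seed(42, {
    for (i in 1:50) {
      a <- runif(3, 0, 100); b <- runif(3, 0, 100); c <- runif(3, 0, 100)
      expect_gt(delta_e(a, b), 0)
      expect_equal(delta_e(a, b), delta_e(b, a))
      expect_lte(delta_e(a, c), delta_e(a, b) + delta_e(b, c) + 1e-12)
    }
  })
  expect_error(delta_e(c(1, 2, Inf), c(0, 0, 0)),
               class = "shelfkin_domain_error")
})

test_that("packaged tables match their hand-maintained checksums", {
  t2 <- builtin_fixture("table2_sensory")
  expect_equal(nrow(t2$observations), 177)
  expect_equal(sum(t2$observations$value), 962)
  expect_equal(sum(t2$observations$sd), 261.5)

  t1 <- builtin_fixture("table1_microbial")
  expect_equal(sum(t1$observations$value), 961)
  expect_equal(sum(t1$observations$below_detection), 124)

  t3 <- builtin_fixture("table3_Lstar_k")
  expect_equal(sum(t3$k), 7.695)
  expect_equal(sum(t3$r_squared), 18.892)
  expect_equal(t3$note[t3$order == "zero" & t3$packaging == "al_bag_n2" &
                         t3$temperature_c == 35], "scale_suspect")

  t4 <- builtin_fixture("table4_color_k")
  expect_equal(sum(t4$k), 3.594)
  expect_equal(sum(t4$r_squared), 20.422)
  expect_equal(printed_k("clear_plastic", 25), 0.028)

  t5 <- builtin_fixture("table5_shelf_life")
  expect_equal(sum(t5$actual_weeks), 135)
  expect_equal(sum(t5$predicted_weeks), 157)

  bl <- builtin_fixture("baselines")
  expect_equal(sum(bl$value), 82.68)
  expect_equal(bl$value[bl$attribute == "color_acceptance"], 6.3)

  expect_error(builtin_fixture("no_such_table"),
               class = "shelfkin_lookup_error")
})

test_that("sensory fixture preserves the censoring pattern", {
  # nitrogen-flushed bag at 45 C: color scored at weeks 3, 6 and 9 only
  s <- table2_color_series("al_bag_n2", 45)
  expect_equal(s$time_weeks, c(3, 6, 9))
  expect_equal(s$value, c(5.6, 4.9, 4.1))
  expect_true(attr(s, "terminated_early"))

  # air-packed aluminum at 4 C ran the full 24 weeks
  s4 <- table2_color_series("al_bag_air", 4)
  expect_equal(s4$time_weeks, seq(3, 24, 3))
  expect_false(attr(s4, "terminated_early"))
})
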