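test_that("shelf-life prediction inverts the kinetic model", {
  est <- predict_shelf_life("first", q0 = 6.3, qe = 5.0, k = 0.028)
  expect_equal(est$t_s_weeks, log(6.3 / 5) / 0.028, tolerance = 1e-12)
  expect_equal(est$reported_weeks, 8L)

  est14 <- predict_shelf_life("first", q0 = 6.3, qe = 5.0, k = 0.016)
  expect_equal(est14$reported_weeks, 14L)

  ez <- predict_shelf_life("zero", q0 = 10, qe = 5, k = 1)
  expect_equal(ez$t_s_weeks, 5)

  # consistency: evaluating the model at t_s returns Qe
  withr::with_seed(3, {
    for (i in 1:25) {
      order <- sample(c("zero", "first"), 1)
      q0 <- runif(1, 5, 10); qe <- runif(1, 1, q0 - 0.5)
      k <- runif(1, 0.01, 0.5)
      e <- predict_shelf_life(order, q0 = q0, qe = qe, k = k)
      expect_equal(predict_quality(order, t = e$t_s_weeks, q0 = q0, k = k),
                   qe, tolerance = 1e-9)
    }
  })

  # boundary and error behaviour
  expect_equal(predict_shelf_life("first", q0 = 6.3, qe = 6.3,
                                  k = 0.02)$t_s_weeks, 0)
  expect_warning(e0 <- predict_shelf_life("first", q0 = 5, qe = 6, k = 0.02),
                 "already rejected")
  expect_true(e0$already_rejected)
  expect_error(predict_shelf_life("first", q0 = 6.3, qe = 5, k = 0),
               class = "shelfkin_domain_error")
  expect_error(predict_shelf_life("first", q0 = 6.3, qe = -1, k = 0.02),
               class = "shelfkin_domain_error")
})

test_that("t_s is monotone in k, Q0 and Qe", {
  base <- predict_shelf_life("first", q0 = 6.3, qe = 5, k = 0.03)$t_s_weeks
  expect_lt(predict_shelf_life("first", q0 = 6.3, qe = 5, k = 0.04)$t_s_weeks,
            base)
  expect_gt(predict_shelf_life("first", q0 = 7.0, qe = 5, k = 0.03)$t_s_weeks,
            base)
  expect_lt(predict_shelf_life("first", q0 = 6.3, qe = 5.5, k = 0.03)$t_s_weeks,
            base)
  withr::with_seed(9, {
    for (order in c("zero", "first")) {
      k <- sort(runif(5, 0.01, 0.2))
      ts <- vapply(k, function(ki) predict_shelf_life(
        order, q0 = 8, qe = 4, k = ki)$t_s_weeks, numeric(1))
      expect_true(all(diff(ts) < 0))
    }
  })
})

test_that("rounding policy is floor by default and nearest on request", {
  e <- predict_shelf_life("first", q0 = 6.3, qe = 5, k = 0.016)
  expect_equal(e$reported_weeks, 14L)            # 14.44 truncates
  en <- predict_shelf_life("first", q0 = 6.3, qe = 5, k = 0.0155,
                           rounding = "nearest")
  expect_equal(en$reported_weeks, 15L)           # 14.91 rounds up
  ef <- predict_shelf_life("first", q0 = 6.3, qe = 5, k = 0.0155)
  expect_equal(ef$reported_weeks, 14L)
})

test_that("experimental shelf life applies the strict-threshold rule", {
  # first failing session at week 12 -> shelf life is week 9
  cp25 <- table2_color_series("clear_plastic", 25)
  e <- experimental_shelf_life(cp25)
  expect_equal(e$weeks, 9)
  expect_equal(e$bound, "exact")

  # a score of exactly 5.0 at week 24 still passes -> only a lower bound
  air4 <- table2_color_series("al_bag_air", 4)
  e4 <- experimental_shelf_life(air4)
  expect_equal(e4$weeks, 24)
  expect_equal(e4$bound, "greater_than")

  # first session already fails -> only an upper bound
  air35 <- table2_color_series("al_bag_air", 35)
  e35 <- experimental_shelf_life(air35)
  expect_equal(e35$weeks, 3)
  expect_equal(e35$bound, "less_than")

  expect_error(experimental_shelf_life(quality_series(numeric(0), numeric(0))),
               class = "shelfkin_insufficient_data")
})

test_that("raising the threshold never lengthens experimental shelf life", {
  withr::with_seed(17, {
    for (i in 1:40) {
      n <- sample(3:9, 1)
      s <- quality_series(seq(3, by = 3, length.out = n),
                          runif(n, 3, 7.5))
      th <- sort(runif(2, 3.5, 7))
      lo <- experimental_shelf_life(s, threshold = th[1])
      hi <- experimental_shelf_life(s, threshold = th[2])
      expect_lte(hi$weeks, lo$weeks)
      # bound coherence
      for (e in list(lo, hi)) {
        if (e$bound == "greater_than") {
          expect_true(all(s$value >= e$threshold))
        }
        if (e$bound == "less_than") {
          expect_lt(s$value[1], e$threshold)
        }
      }
    }
  })
})

test_that("actual-vs-predicted table reproduces the published comparison", {
  ds <- builtin_fixture("table2_sensory")
  cmp <- compare_actual_predicted(ds, analysis_config(k_source = "printed"))
  expect_equal(nrow(cmp), 12)
  row <- function(p, t) cmp[cmp$packaging == p & cmp$temperature_c == t, ]

  expect_equal(row("clear_plastic", 25)$predicted_weeks, 8L)
  expect_equal(row("al_bag_n2", 35)$predicted_weeks, 7L)
  expect_equal(row("al_bag_air", 25)$predicted_weeks, 14L)
  expect_equal(row("al_bag_n2", 25)$actual_weeks, 15)
  expect_equal(row("al_bag_air", 4)$actual_bound, "greater_than")
  expect_true(all(cmp$order == "first"))

  # fitted mode runs the kinetic fits itself and stays self-consistent
  fitted <- compare_actual_predicted(ds, analysis_config(k_source = "fitted"))
  ok <- !is.na(fitted$t_s_raw)
  expect_true(any(ok))
  for (i in which(ok)) {
    expect_equal(predict_quality(fitted$order[i], t = fitted$t_s_raw[i],
                                 q0 = 6.3, k = fitted$k[i]),
                 5.0, tolerance = 1e-9)
  }

  # a condition absent from the rate table is reported, not fatal
  small <- analysis_config(
    k_source = "printed",
    rate_table = data.frame(packaging = "clear_plastic",
                            temperature_c = 25, k = 0.028))
  cmp2 <- compare_actual_predicted(ds, small)
  expect_equal(sum(!is.na(cmp2$predicted_weeks)), 1)
  expect_equal(nrow(cmp2), 12)

  lines <- format_comparison(cmp)
  expect_length(lines, 13)
  expect_match(lines[grepl("al_bag_air +4 ", lines)], ">24")
})
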