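test_that("stays are classified by discharge date and admission presence", {
  w <- window_2013()
  expect_equal(classify_stay("2013-03-01", "2013-03-11", w), "type1")
  expect_equal(classify_stay("2012-12-20", "2013-01-10", w), "type1")
  expect_equal(classify_stay("2013-06-01", "2014-02-01", w), "type2")
  expect_equal(classify_stay("2012-06-01", NA, w), "type2")  # still open
  expect_equal(classify_stay(NA, "2013-05-05", w), "type3")
  expect_equal(classify_stay("2012-01-01", "2012-12-30", w), "out")
  expect_equal(classify_stay("2014-01-02", "2014-01-08", w), "out")
  expect_equal(classify_stay(NA, "2014-03-01", w), "out")  # no admission, late
  # boundary days are inside the window
  expect_equal(classify_stay("2013-12-31", "2013-12-31", w), "type1")
  expect_error(classify_stay(NA, NA, w), "neither")
  expect_error(classify_stay("2013-05-10", "2013-05-01", w), "before admission")
})

test_that("in-window stay days follow the boundary-clipping rules", {
  w <- window_2013()
  expect_equal(stay_days_in_window("2012-12-20", "2013-01-10", w), 9)
  expect_equal(stay_days_in_window("2012-06-15", NA, w), 364)
  expect_equal(stay_days_in_window("2013-11-01", "2014-02-01", w), 60)
  expect_equal(stay_days_in_window(NA, "2013-05-05", w, median_type1 = 10), 10)
  expect_equal(stay_days_in_window("2013-03-01", "2013-03-11", w), 10)
  expect_error(stay_days_in_window(NA, "2013-05-05", w), "median_type1")
  expect_error(stay_days_in_window("2012-01-01", "2012-06-01", w),
               "out-of-window")
})

test_that("stay days stay within [0, capacity] for random records", {
  w <- window_2013()
  set.seed(71)
  adm <- w$start + sample(-200:300, 400, replace = TRUE)
  dis <- adm + sample(0:250, 400, replace = TRUE)
  type <- classify_stay(adm, dis, w)
  keep <- type != "out"
  days <- stay_days_in_window(adm[keep], dis[keep], w, type = type[keep])
  expect_true(all(days >= 0))
  expect_true(all(days <= w$capacity_days))
})

test_that("department census sums the three stay types into the BOR", {
  w <- window_2013()
  rec <- data.frame(
    patient_id = sprintf("p%d", 1:6),
    department = c("D1", "D1", "D1", "D1", "D1", "D2"),
    admission_date = c("2013-02-01", "2012-12-22", "2013-12-01", NA,
                       "2011-05-01", "2013-03-05"),
    discharge_date = c("2013-02-21", "2013-01-05", "2014-01-15", "2013-06-10",
                       "2012-02-01", "2013-03-15"))
  cen <- quiet(department_census(rec, c(D1 = 10, D2 = 5), w))
  d1 <- cen[cen$department == "D1", ]
  # type1: 20 + 4 days, median 12; type2: Dec 31 - Dec 1 = 30; type3: 12
  expect_equal(d1$n_type1, 2)
  expect_equal(d1$n_type2, 1)
  expect_equal(d1$n_type3, 1)
  expect_equal(d1$median_los, 12)
  expect_equal(d1$los_total, 24 + 30 + 12)
  expect_equal(d1$bor, 66 / (10 * 365))
  # conservation: totals equal the record-level sum
  type <- classify_stay(rec$admission_date, rec$discharge_date, w)
  keep <- type != "out" & rec$department == "D1"
  days <- stay_days_in_window(rec$admission_date[keep],
                              rec$discharge_date[keep], w,
                              median_type1 = d1$median_los)
  expect_equal(d1$los_total, sum(days))
  # the pre-window discharge was dropped with a message
  expect_message(department_census(rec, c(D1 = 10, D2 = 5), w), "dropped")
})

test_that("BOR is homogeneous of degree -1 in the bed count", {
  w <- window_2013()
  reg <- generate_registry(small_registry_spec(seed = 5))
  beds1 <- c(D1 = 30, D2 = 15)
  c1 <- quiet(department_census(reg$records, beds1, w))
  c2 <- quiet(department_census(reg$records, beds1 * 2, w))
  expect_equal(c2$bor, c1$bor / 2)
})

test_that("type3 counts can be supplied externally as discharges minus type1", {
  w <- window_2013()
  rec <- data.frame(patient_id = c("a", "b"), department = "D1",
                    admission_date = c("2013-01-10", "2013-04-01"),
                    discharge_date = c("2013-01-20", "2013-04-09"))
  cen <- department_census(rec, c(D1 = 5), w, type3_counts = c(D1 = 3))
  expect_equal(cen$n_type3, 3)
  expect_equal(cen$median_los, 9)
  expect_equal(cen$los_total, 10 + 8 + 3 * 9)
  # median undefined without any type1 stay
  rec2 <- data.frame(patient_id = "c", department = "D1",
                     admission_date = "2013-06-01", discharge_date = NA)
  expect_error(department_census(rec2, c(D1 = 5), w,
                                 type3_counts = c(D1 = 2)), "median")
})

test_that("occupancy grouping partitions departments with an inclusive band", {
  g <- group_departments(c(0.752, 1.02, 0.85, 0.90, 0.8499, 0.9001))
  expect_equal(as.character(g), c("A", "B", "C", "C", "A", "B"))
  expect_true(all(table(g) >= 0) && !anyNA(g))
  expect_error(group_departments(0.5, low = 0.9, high = 0.8), "low < high")
})

test_that("registry CSV round-trips with empty fields as absent dates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,department,admission_date,discharge_date",
               "p1,D1,2013-02-01,2013-02-11",
               "p2,D1,,2013-03-05",
               "p3,D2,2013-12-20,"), f)
  reg <- read_registry(f)
  expect_s3_class(reg$admission_date, "Date")
  expect_true(is.na(reg$admission_date[2]))
  expect_true(is.na(reg$discharge_date[3]))
  expect_equal(classify_stay(reg$admission_date, reg$discharge_date,
                             window_2013()),
               c("type1", "type3", "type2"))
  unlink(f)
})
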