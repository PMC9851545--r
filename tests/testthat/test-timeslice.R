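make_raw <- function(offsets, id = "A", epoch = as.Date("2020-01-01")) {
  data.frame(id = id, date = epoch + offsets, surv_time = 1000 - offsets,
             status = 1, stringsAsFactors = FALSE)
}

test_that("records are binned by window membership around slice centers", {
  raw <- make_raw(c(0, 92, 178, 400))
  out <- divide_time(raw, "id", "date", slice_config(period = 90))
  # centers 0, 90, 180, 270, 360 with half-width 45: offset 400 -> slice 5
  expect_identical(out$time_slice, c(1L, 2L, 3L, 5L))

  one <- divide_time(make_raw(0), "id", "date", slice_config(period = 90))
  expect_identical(one$time_slice, 1L)
  expect_identical(nrow(one), 1L)
})

test_that("competing records in one window keep the one nearest the center", {
  raw <- make_raw(c(0, 85, 92))   # offset 0 anchors the patient's zero point
  out <- divide_time(raw, "id", "date", slice_config(period = 90))
  # 85 and 92 both fall in the slice-2 window [45, 135); |92-90| < |85-90|
  expect_identical(out$time_slice, c(1L, 2L))
  expect_identical(as.numeric(out$date - as.Date("2020-01-01")), c(0, 92))

  # equidistant tie goes to the earlier date
  tie <- make_raw(c(0, 85, 95))
  out2 <- divide_time(tie, "id", "date", slice_config(period = 90))
  expect_identical(as.numeric(out2$date - as.Date("2020-01-01")), c(0, 85))
})

test_that("window assignment matches a brute-force scan over (record, slice) pairs", {
  set.seed(71)
  for (rep in 1:20) {
    period <- sample(c(30, 45, 90), 1L)
    li <- runif(1, 0.1, 0.5); ri <- runif(1, 0.1, 0.5)
    offsets <- sort(sample(0:600, 25))
    offsets <- offsets - min(offsets)
    raw <- make_raw(unique(offsets))
    out <- divide_time(raw, "id", "date", slice_config(period, li, ri))
    # brute force: every (record, slice) pair
    for (d in unique(offsets)) {
      hits <- Filter(function(k) {
        ctr <- (k - 1) * period
        d >= ctr - li * period && d < ctr + ri * period
      }, 1:30)
      row <- out[as.numeric(out$date - as.Date("2020-01-01")) == d, ]
      if (!length(hits)) {
        expect_identical(nrow(row), 0L)
      } else if (nrow(row)) {          # may lose to a nearer record
        expect_identical(row$time_slice, as.integer(hits[1L]))
      }
    }
    # never two records of one patient in the same slice
    expect_false(anyDuplicated(out[c("id", "time_slice")]) > 0)
  }
})

test_that("date problems are rejected with row identification", {
  raw <- make_raw(c(0, 30))
  raw$date <- as.character(raw$date)
  raw$date[2] <- "not-a-date"
  expect_error(divide_time(raw, "id", "date", slice_config(30)), "unparseable")

  dup <- make_raw(c(0, 0))
  expect_error(divide_time(dup, "id", "date", slice_config(30)), "duplicate")
})

test_that("build_dtsd fills missing covariates with the within-slice average", {
  sliced <- data.frame(
    id = c("A", "B", "C", "A", "B"),
    time_slice = c(1L, 1L, 1L, 2L, 2L),
    surv_time = c(100, 200, 300, 70, 170),
    status = c(1, 1, 0, 1, 1),
    x = c(1, NA, 3, 10, 20),       # continuous: mean fill
    b = c(0, 1, NA, 1, 1),         # binary: majority fill
    stringsAsFactors = FALSE)
  dtsd <- build_dtsd(sliced, "time_slice", "id", "surv_time", "status",
                     c("x", "b"), ifclassify = FALSE, isfill = TRUE)
  expect_identical(dtsd$length, 2L)
  expect_identical(dtsd$ts_size, c(3L, 2L))
  expect_identical(dtsd$tsdata[[1]]$x, c(1, 2, 3))
  expect_true(dtsd$tsdata[[1]]$b[3] %in% c(0, 1))
  # complete columns are untouched
  expect_identical(dtsd$tsdata[[2]]$x, c(10, 20))
  # already-binary variable stays out of the cutoff map under classification
  dtsd2 <- build_dtsd(sliced, "time_slice", "id", "surv_time", "status",
                      "b", ifclassify = TRUE, predict_time = 150)
  expect_length(dtsd2$cutoffs, 0L)
  expect_identical(dtsd2$tsdata[[1]]$b[1:2], c(0, 1))
})

test_that("build_dtsd validates status and per-slice variable availability", {
  sliced <- data.frame(id = c("A", "B"), time_slice = c(1L, 1L),
                       surv_time = c(10, 20), status = c(1, 2), x = c(1, 2))
  expect_error(build_dtsd(sliced, "time_slice", "id", "surv_time", "status",
                          "x", ifclassify = FALSE), "status")
  sliced$status <- c(1, 0)
  sliced2 <- rbind(sliced, data.frame(id = "A", time_slice = 2L,
                                      surv_time = 5, status = 1, x = NA))
  expect_error(build_dtsd(sliced2, "time_slice", "id", "surv_time", "status",
                          "x", ifclassify = FALSE),
               "missing in all rows of slice 2")
})

test_that("dtsd slice sizes match the generator's per-slice row counts", {
  coh <- planted_cohort(3, n = 120, max_visits = 4)
  sliced <- divide_time(coh, "id", "date", slice_config(90))
  dtsd <- build_dtsd(sliced, "time_slice", "id", "surv_time", "status",
                     "adverse", ifclassify = FALSE)
  counts <- as.integer(table(sliced$time_slice))
  expect_identical(dtsd$ts_size, counts)
  for (i in seq_len(dtsd$length)) {
    expect_identical(length(dtsd$time[[i]]), dtsd$ts_size[i])
    expect_identical(length(dtsd$status[[i]]), dtsd$ts_size[i])
    expect_identical(nrow(dtsd$tsdata[[i]]), dtsd$ts_size[i])
    expect_false(anyDuplicated(dtsd$tsid[[i]]) > 0)
  }
})

test_that("match_subgroup re-zeroes patients at condition onset", {
  sliced <- data.frame(
    id = rep(c("A", "B", "C"), times = c(5, 3, 2)),
    time_slice = c(1:5, 1:3, 1:2),
    surv_time = c(500, 400, 300, 200, 100, 300, 200, 100, 200, 100),
    status = 1,
    flag = c(0, 0, 1, 1, 1,  1, 1, 0,  0, 0),
    stringsAsFactors = FALSE)
  dtsd <- build_dtsd(sliced, "time_slice", "id", "surv_time", "status",
                     "flag", ifclassify = FALSE)
  sub <- match_subgroup(dtsd, "flag", 1)
  # A first matches at slice 3 -> its slices {3,4,5} become {1,2,3}
  a_slices <- which(vapply(seq_len(sub$length),
                           function(i) "A" %in% sub$tsid[[i]], logical(1L)))
  expect_identical(sub$slices[a_slices], 1:3)
  # C never matches -> absent
  expect_false("C" %in% unlist(sub$tsid))
  # slice-1 rows all satisfy the condition
  expect_true(all(sub$tsdata[[1]]$flag == 1))
  # nobody matches -> explicit empty-cohort error
  expect_error(match_subgroup(dtsd, "flag", 99), "empty cohort")
})

test_that("match_subgroup is the identity when all patients match at slice 1", {
  fx <- planted_tree(11, n = 100, time_slices = 2)
  dtsd <- fx$dtsd
  # match on a condition every patient satisfies at slice 1: adverse in {0,1}
  # use a constant helper column instead
  for (i in seq_len(dtsd$length)) dtsd$tsdata[[i]]$always <- 1
  dtsd$variables <- c(dtsd$variables, "always")
  sub <- match_subgroup(dtsd, "always", 1)
  expect_identical(sub$ts_size, dtsd$ts_size)
  expect_identical(sub$slices, dtsd$slices)
  for (i in seq_len(dtsd$length))
    expect_setequal(sub$tsid[[i]], dtsd$tsid[[i]])
})
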