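test_that("a minimal recording round-trips exactly through the text format", {
  d <- tibble::tibble(time_s = (0:2) / 125, ppg = c(0.1, 0.5, 0.2),
                      sbp_ref = c(120, 120, 121), dbp_ref = c(70, 70, 70))
  rec <- ppg_recording(d, 125,
                       tibble::tibble(label = "rest", start_sample = 0L, end_sample = 3L),
                       subject_meta = list(age = 25))
  expect_equal(n_samples(rec), 3)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  rec2 <- read_recording(path)
  expect_identical(rec2$data$ppg, rec$data$ppg)
  expect_identical(rec2$data$sbp_ref, rec$data$sbp_ref)
  expect_equal(rec2$sampling_rate_hz, 125)
  expect_equal(rec2$phases$label, "rest")
  expect_equal(rec2$subject_meta$age, 25)
})

test_that("a long synthetic recording round-trips losslessly, byte and value", {
  syn <- make_clean_synth(durations = c(40, 40, 40), seed = 3)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.csv"); p2 <- file.path(dir, "b.csv")
  write_recording(syn$recording, p1)
  rt <- read_recording(p1)
  expect_identical(rt$data$ppg, syn$recording$data$ppg)
  expect_identical(rt$data$sbp_ref, syn$recording$data$sbp_ref)
  write_recording(rt, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the reader rejects malformed inputs naming the violated rule", {
  dir <- withr::local_tempdir()
  d <- tibble::tibble(time_s = (0:2) / 125, ppg = c(0, 1, 0))
  rec <- ppg_recording(d, 125, tibble::tibble(label = "rest", start_sample = 0L,
                                              end_sample = 3L))
  path <- file.path(dir, "rec.csv")
  write_recording(rec, path)

  # missing sidecar
  file.remove(sub("csv$", "json", path))
  expect_error(read_recording(path), "missing JSON sidecar")
  write_recording(rec, path)

  # time grid inconsistent with the declared rate (0.008 s steps vs 100 Hz)
  meta <- jsonlite::read_json(sub("csv$", "json", path), simplifyVector = TRUE)
  meta$sampling_rate_hz <- 100
  jsonlite::write_json(meta, sub("csv$", "json", path), auto_unbox = TRUE)
  expect_error(read_recording(path), "non-uniform time grid at index")

  # unknown phase label
  meta$sampling_rate_hz <- 125
  meta$phases$label <- "warmup"
  jsonlite::write_json(meta, sub("csv$", "json", path), auto_unbox = TRUE)
  expect_error(read_recording(path), "unknown phase label")
})

test_that("recording invariants are enforced at construction", {
  d <- tibble::tibble(time_s = (0:9) / 10, ppg = rnorm(10))
  ph <- function(s, e, lab = "rest") tibble::tibble(label = lab, start_sample = s,
                                                    end_sample = e)
  expect_error(ppg_recording(d, -1, ph(0L, 10L)), "sampling_rate")
  expect_error(ppg_recording(d, 10, ph(0L, 11L)), "outside")
  expect_error(ppg_recording(d, 10, ph(5L, 5L)), "exceed")
  expect_error(
    ppg_recording(d, 10, dplyr::bind_rows(ph(0L, 6L), ph(4L, 10L, "exercise"))),
    "disjoint"
  )
})

test_that("optional BP channels are omitted and restored as absent", {
  d <- tibble::tibble(time_s = (0:2) / 125, ppg = c(0, 1, 0))
  rec <- ppg_recording(d, 125, tibble::tibble(label = "rest", start_sample = 0L,
                                              end_sample = 3L))
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  header <- readLines(path, n = 1)
  expect_false(grepl("sbp_ref", header))
  rec2 <- read_recording(path)
  expect_false("sbp_ref" %in% names(rec2$data))
})

test_that("feature tables round-trip: empty, zeros, and 1000 random rows", {
  dir <- withr::local_tempdir()
  schema <- c("beat_id", "phase", feature_names(), "sbp_ref", "dbp_ref")

  empty <- tibble::as_tibble(stats::setNames(
    c(list(integer(0), character(0)), rep(list(numeric(0)), 19)), schema))
  p <- file.path(dir, "empty.csv")
  write_feature_table(empty, p)
  expect_equal(length(readLines(p)), 1)  # header only
  expect_equal(nrow(read_feature_table(p)), 0)

  one <- tibble::as_tibble(stats::setNames(
    c(list(1L, "rest"), rep(list(0), 19)), schema))
  p1 <- file.path(dir, "one.csv")
  write_feature_table(one, p1)
  expect_equal(unlist(read_feature_table(p1)[, feature_names()]),
               unlist(one[, feature_names()]))

  set.seed(11)
  big <- tibble::as_tibble(c(
    list(beat_id = 1:1000, phase = sample(c("rest", "exercise", "recovery"), 1000, TRUE)),
    stats::setNames(lapply(1:19, function(i) rnorm(1000) * 10^sample(-3:3, 1)),
                    c(feature_names(), "sbp_ref", "dbp_ref"))
  ))
  p2 <- file.path(dir, "big.csv")
  write_feature_table(big, p2)
  back <- read_feature_table(p2)
  num <- c(feature_names(), "sbp_ref", "dbp_ref")
  expect_lt(max(abs(as.matrix(back[, num]) - as.matrix(big[, num]))), 1e-10)

  expect_error(write_feature_table(big[, -3], p2), "schema mismatch")
})
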