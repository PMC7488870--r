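weekly <- function(lengths, from = "2016-04-04")
  growth_series("s1", as.Date(from) + 7 * (seq_along(lengths) - 1), lengths)

test_that("growth CSV parsing: valid rows, duplicates, degenerate input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("shoot_id,date,length_cm",
               "a,2016-04-04,2", "a,2016-04-11,6", "a,2016-04-18,9"), p)
  rec <- read_growth_records(p)
  expect_length(rec$series, 1)
  expect_equal(rec$series$a$lengths_cm, c(2, 6, 9))
  expect_equal(rec$report$rows_read, 3)
  expect_equal(rec$report$rows_rejected, 0)

  writeLines(c("shoot_id,date,length_cm",
               "a,2016-04-04,2", "a,2016-04-04,3", "a,2016-04-11,6",
               "a,2016-04-18,9", "b,2016-05-02,notanumber",
               "b,bad-date,4"), p)
  rec <- read_growth_records(p)
  expect_equal(rec$report$rows_rejected, 3)
  expect_true(any(grepl("duplicated \\(shoot,date\\): a 2016-04-04",
                        rec$report$problems$reason)))
  expect_true(any(rec$report$problems$reason == "unparseable date"))

  # shrinkage beyond the 1 cm tolerance is rejected with its line number
  writeLines(c("shoot_id,date,length_cm",
               "a,2016-04-04,2", "a,2016-04-11,8", "a,2016-04-18,6",
               "a,2016-04-25,9"), p)
  rec <- read_growth_records(p)
  expect_equal(rec$report$problems$line, 4L)
  expect_match(rec$report$problems$reason, "shrinks")

  writeLines("shoot_id,date,length_cm", p)
  expect_warning(rec <- read_growth_records(p), "header only")
  expect_length(rec$series, 0)
})

test_that("cessation detection applies the 0.5 cm / two-week rule", {
  # the first qualifying date has a trailing-two-week gain below 0.5 cm
  s <- weekly(c(5, 10, 15, 15.3, 15.4))
  cess <- detect_cessations(s)
  expect_equal(cess, as.Date("2016-04-04") + 28)   # the 15.4 observation

  # strictly linear growth never stagnates
  expect_length(detect_cessations(weekly(5 + 3 * (0:6))), 0)

  # stagnation, renewed growth of more than 5 cm, second stagnation
  s2 <- weekly(c(5, 10, 15, 15.2, 15.3, 20, 26, 30, 30.1, 30.2))
  cess2 <- detect_cessations(s2)
  expect_length(cess2, 2)
  expect_equal(cess2, as.Date("2016-04-04") + 7 * c(4, 9))

  # a sub-5cm noise bump between qualifying runs does not split the episode
  s3 <- weekly(c(5, 10, 15, 15.2, 15.3, 16.1, 16.2, 16.3))
  expect_length(detect_cessations(s3), 1)

  # series shorter than the window: no-assessment, distinct from none
  short <- growth_series("s", as.Date("2016-04-04") + c(0, 7), c(3, 6))
  expect_true(is.na(detect_cessations(short)))
})

test_that("start dates: first crossing, undefined start, second GU", {
  s <- weekly(c(2, 4, 6), from = "2016-04-20")
  expect_equal(compute_start_date(s), as.Date("2016-05-04"))
  expect_true(is.na(compute_start_date(weekly(c(1, 2, 3)))))
  # second GU: 5 cm above the length at the previous cessation
  s2 <- weekly(c(5, 10, 15, 15.2, 15.3, 18, 21, 30, 30.1, 30.2))
  c1 <- detect_cessations(s2)[1]
  expect_equal(compute_start_date(s2, after = c1),
               as.Date("2016-04-04") + 7 * 6)     # first obs >= 20.3 cm
})

test_that("classification honours GD/GP thresholds and boundaries", {
  cfg <- category_config()
  span1 <- function(gd, start) data.frame(
    index = 1L, start_date = as.Date(start),
    cessation_date = as.Date(start) + gd, gd_days = gd)
  c1 <- classify_shoot(span1(30, "2016-05-10"), cfg)
  expect_equal(c(c1$cyclicity, c1$gd_class, c1$gp_class),
               c("one-GU", "medium", "early"))
  c2 <- classify_shoot(span1(90, "2016-05-10"), cfg)    # 90 d is still medium
  expect_equal(c2$gd_class, "medium")
  c3 <- classify_shoot(span1(100, "2016-06-10"), cfg)
  expect_equal(c(c3$gd_class, c3$gp_class), c("long", "late"))
  # start exactly on the threshold date counts as early
  c4 <- classify_shoot(span1(20, "2016-06-03"), cfg)
  expect_equal(c4$gp_class, "early")

  two <- rbind(span1(20, "2016-05-01"),
               data.frame(index = 2L, start_date = as.Date("2016-07-25"),
                          cessation_date = as.Date("2016-07-25") + 50,
                          gd_days = 50))
  c5 <- classify_shoot(two, cfg)
  expect_equal(c5$cyclicity, "two-GUs")
  expect_equal(c5$gd_class, c("short", "long"))
  expect_equal(c5$gp_class, c("early", "late"))

  expect_error(classify_shoot(rbind(two, two[2, ])), "1 or 2 growth units")

  # monotone threshold property: growing GD never shortens the class
  ord <- c(short = 1, medium = 2, long = 3)
  cls <- vapply(1:150, function(gd)
    classify_shoot(span1(gd, "2016-05-01"), cfg)$gd_class, character(1))
  expect_true(all(diff(ord[cls]) >= 0))
})

test_that("sequence TSV round-trips and rejects bad symbols", {
  cat_ <- classify_shoot(data.frame(index = 1L,
                                    start_date = as.Date("2016-05-01"),
                                    cessation_date = as.Date("2016-05-21"),
                                    gd_days = 20))
  s1 <- branching_sequence("a", c(0, 0, 3, 1), cat_)
  two_cat <- structure(list(cyclicity = "two-GUs",
                            gd_class = c("short", "long"),
                            gp_class = c("early", "late")),
                       class = "shoot_category")
  s2 <- branching_sequence("b", c(0, 0, 3, 5, 5, 0, 0, 2), two_cat)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_sequences(list(s1, s2), p)
  back <- read_sequences(p)
  expect_equal(back[[1]]$symbols, s1$symbols)
  expect_equal(back[[2]]$symbols, s2$symbols)
  expect_equal(back[[2]]$category$gd_class, c("short", "long"))
  # write -> read -> write is byte-identical
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sequences(back, p2)
  expect_identical(readLines(p), readLines(p2))

  expect_error(branching_sequence("x", c(0, 7, 1)), "node index 1")
  expect_error(branching_sequence("x", c(5, 0, 5)), "contiguous")
  expect_error(branching_sequence("x", c(0, 5, 5), cat_), "two-GU")
})

test_that("categorization is total: category or logged exclusion", {
  series <- list(weekly(c(5, 10, 15, 15.2, 15.3)),       # classifiable
                 weekly(c(1, 2, 3, 3.1, 3.2)),           # never starts
                 weekly(5 + 3 * (0:5)))                  # never stops
  series[[2]]$shoot_id <- "s2"; series[[3]]$shoot_id <- "s3"
  cats <- categorize_shoots(series)
  expect_equal(nrow(cats), 3)
  expect_true(all(xor(is.na(cats$category), is.na(cats$reason))))
  expect_match(cats$reason[2], "start criterion")
  expect_match(cats$reason[3], "no growth cessation")
})

test_that("category configuration round-trips through structured text", {
  cfg <- category_config(cessation_delta_cm = 0.4,
                         gp_threshold_first = "2016-06-01")
  p <- withr::local_tempfile(fileext = ".yaml")
  write_category_config(cfg, p)
  expect_equal(read_category_config(p), cfg)
})
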