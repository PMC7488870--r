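gt <- default_ground_truth()

test_that("default ground truth encodes the published zone frequencies", {
  a <- gt$specs[["one-GU_short"]]
  expect_equal(a$transitions[1, 2], 0.26)      # diffuse floral zone entry
  expect_equal(a$transitions[1, 3], 0.09)      # vegetative zone entry
  expect_equal(a$transitions[2, 3], 0)         # zones mutually exclusive

  # marginal visit probabilities of the bicyclic model, by direct chain walk
  b <- gt$specs[["two-GUs"]]
  visit <- numeric(7); visit[1] <- 1
  for (j in 2:7) visit[j] <- sum(visit[1:(j - 1)] * b$transitions[1:(j - 1), j])
  expect_equal(visit, c(1, 0.65, 1, 1, 0.62, 0.47, 0.73), tolerance = 1e-12)

  # monocyclic long-duration shoots never traverse the bud-scar zone
  l <- gt$specs[["one-GU_long"]]
  expect_equal(l$transitions[, 3], rep(0, 7))
  for (s in gt$specs) expect_silent(validate_hsmm(s))
})

test_that("ground truth serializes with provenance and round-trips", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(gt, p)
  txt <- readLines(p)
  expect_true(any(grepl("provenance", txt)))
  back <- read_ground_truth(p)
  expect_equal(back$mix, gt$mix, tolerance = 1e-11)
  for (nm in names(gt$specs)) {
    expect_equal(back$specs[[nm]]$transitions, gt$specs[[nm]]$transitions,
                 tolerance = 1e-11)
    expect_equal(back$specs[[nm]]$emission, gt$specs[[nm]]$emission,
                 tolerance = 1e-11)
  }
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("growth trajectories reproduce their target categories", {
  set.seed(61)
  s <- simulate_growth_series("one-GU_medium_early", gt)
  sp <- assemble_gu_spans(s)
  expect_false(sp$excluded)
  cat_ <- classify_shoot(sp)
  expect_equal(cat_$cyclicity, "one-GU")
  expect_equal(cat_$gd_class, "medium")

  s2 <- simulate_growth_series("two-GUs_short-early_long-late", gt)
  sp2 <- assemble_gu_spans(s2)
  expect_equal(nrow(sp2$spans), 2)             # both growth units detected
  expect_equal(classify_shoot(sp2)$cyclicity, "two-GUs")
})

test_that("spring cohort mean start date is late April", {
  set.seed(62)
  starts <- replicate(150, {
    s <- simulate_growth_series("one-GU_short_early", gt)
    as.numeric(compute_start_date(s))
  })
  expect_lt(abs(mean(starts) - as.numeric(as.Date("2016-04-30"))), 3)
})

test_that("a simulated study is reproducible and internally consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st <- simulate_study(120, gt, seed = 3, out_dir = d1)
  st2 <- simulate_study(120, gt, seed = 3, out_dir = d2)
  for (f in c("growth.csv", "sequences.tsv", "truth.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # the written files are readable by the data layer
  rec <- read_growth_records(file.path(d1, "growth.csv"))
  expect_equal(length(rec$series), 120)
  expect_equal(rec$report$rows_rejected, 0)
  seqs <- read_sequences(file.path(d1, "sequences.tsv"))
  expect_equal(length(seqs), 120)

  # the scar symbol appears exactly in the bicyclic sequences
  scar <- vapply(st$sequences, function(s) any(s$symbols == 5), logical(1))
  expect_equal(scar, st$truth$spec == "two-GUs")

  # one-GU fraction within 3 binomial standard errors of the target mix
  frac <- mean(st$truth$spec != "two-GUs")
  expect_lt(abs(frac - 0.71), 3 * sqrt(0.71 * 0.29 / 120))
})

test_that("generated shoots re-classify into their generating category", {
  st <- simulate_study(250, gt, seed = 8)
  cats <- categorize_shoots(st$growth)
  agree <- mean(!is.na(cats$category) & cats$category == st$truth$category)
  expect_gte(agree, 0.95)
})
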