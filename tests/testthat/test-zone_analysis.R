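test_that("zone extraction is run-length encoding with a partition", {
  z <- extract_zones(c(1, 1, 1, 2, 2, 3))
  expect_equal(z$state, 1:3)
  expect_equal(z$start, c(0, 3, 5))
  expect_equal(z$end, c(3, 5, 6))
  expect_equal(z$length, c(3, 2, 1))

  z2 <- extract_zones(c(1, 1, 3, 3))      # middle state skipped
  expect_equal(z2$state, c(1, 3))
  expect_equal(extract_zones(2)$length, 1)
  expect_error(extract_zones(c(2, 1)), "non-decreasing")
})

test_that("occurrence probabilities are per-group visit fractions", {
  mk <- function(states) extract_zones(states)
  profs <- c(replicate(26, mk(c(1, 1, 2)), simplify = FALSE),
             replicate(74, mk(c(1, 1, 1)), simplify = FALSE))
  occ <- occurrence_probabilities(profs, rep("all", 100), 3,
                                  c("S0", "S1", "S2"))
  expect_equal(occ$S0, 1)
  expect_equal(occ$S1, 0.26)
  expect_equal(occ$S2, 0)
  expect_equal(occ$n, 100)
})

test_that("zone-length comparison: null, power, and no-test path", {
  same <- c(3, 5, 8, 2, 7, 4, 6, 5, 3, 9)
  r <- compare_zone_lengths(same, same)
  expect_true(r$tested)
  expect_gt(r$p_value, 0.05)
  expect_equal(r$code, "ns")

  # zone-length means far apart: the test detects the difference
  set.seed(31)
  hits <- replicate(25, {
    a <- rocc(50, occupancy_dist("nbinom", size = 2, mu = 12.4))
    b <- rocc(50, occupancy_dist("nbinom", size = 2, mu = 2.9))
    suppressWarnings(compare_zone_lengths(a, b))$code %in% c("*", "**")
  })
  expect_gte(mean(hits), 0.95)

  expect_false(compare_zone_lengths(c(1, 2), c(3, 4, 5))$tested)
})

test_that("Fisher exact agrees with full enumeration", {
  r <- compare_lateral_distributions(rbind(c(3, 1), c(1, 3)))
  expect_equal(r$p_value, 34 / 70, tolerance = 1e-9)
  expect_equal(r$method, "exact")

  # independence-exact table
  expect_equal(compare_lateral_distributions(rbind(c(2, 4), c(3, 6)))$p_value,
               1, tolerance = 1e-9)

  # every 2x2 table with total <= 15 and positive margins
  for (n in 2:15)
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      tab <- matrix(c(a, b, cc, n - a - b - cc), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(stats::fisher.test(tab)$p.value, fisher_enum(tab),
                   tolerance = 1e-9)
    }
  # a handful of wider tables
  set.seed(17)
  for (k in 1:15) {
    tab <- matrix(rmultinom(1, sample(6:15, 1), rep(1, 6)), 2, 3)
    if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) next
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    expect_equal(compare_lateral_distributions(tab)$p_value, fisher_enum(tab),
                 tolerance = 1e-9)
  }

  # Monte-Carlo route is flagged and deterministic
  big <- rbind(c(150, 80, 40), c(120, 95, 60))
  m1 <- compare_lateral_distributions(big)
  m2 <- compare_lateral_distributions(big)
  expect_equal(m1$method, "monte-carlo")
  expect_identical(m1$p_value, m2$p_value)
})

test_that("NB-GLM zone-length test attains nominal type-I error", {
  set.seed(99)
  rej <- mean(replicate(1000, {
    a <- rocc(50, occupancy_dist("nbinom", size = 2, mu = 5))
    b <- rocc(50, occupancy_dist("nbinom", size = 2, mu = 5))
    isTRUE(suppressWarnings(compare_zone_lengths(a, b))$p_value < 0.05)
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("zone-length/total-length correlation behaves", {
  mk <- function(l1, l2) extract_zones(c(rep(1, l1), rep(2, l2)))
  profs <- lapply(3:12, function(k) mk(k, 2 * k))
  r <- correlate_zone_vs_total(profs, 1)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  const <- lapply(3:12, function(k) mk(4, k))
  rc <- correlate_zone_vs_total(const, 1)
  expect_true(is.na(rc$r))
  expect_equal(rc$reason, "zero variance")

  few <- lapply(1:2, function(k) mk(k, k))
  expect_match(correlate_zone_vs_total(few, 1)$reason, "fewer than 3")

  # analytic R^2 for zone = 0.6 * total + noise
  set.seed(5)
  total <- round(runif(300, 20, 60))
  zone <- pmax(round(0.6 * total + rnorm(300, 0, 2)), 1)
  profs <- lapply(seq_along(total), function(i)
    extract_zones(c(rep(1, zone[i]), rep(2, total[i] - zone[i]))))
  r <- correlate_zone_vs_total(profs, 1, totals = total)
  r2_analytic <- var(0.6 * total) / (var(0.6 * total) + 4)
  expect_lt(abs(r$r_squared - r2_analytic), 0.15)
})
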