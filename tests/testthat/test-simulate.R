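test_that("simulation is reproducible and respects the model structure", {
  spec <- default_ground_truth()$specs[["one-GU_short"]]
  a <- simulate_hsmm(spec, 25, seed = 9)
  b <- simulate_hsmm(spec, 25, seed = 9)
  expect_identical(a, b)

  # point-mass occupancy: every zone of that state has the same length
  pm <- hsmm_spec(1, matrix(c(0, 1), 1, 2),
                  list(occupancy_dist("point", at = 5)),
                  rbind(c(1, 0, 0, 0, 0, 0)))
  sim <- simulate_hsmm(pm, 10, seed = 1)
  expect_true(all(lengths(sim$sequences) == 5))

  # paths and sequences agree in length; zones partition every path
  for (i in seq_along(a$paths)) {
    expect_equal(length(a$paths[[i]]), length(a$sequences[[i]]))
    z <- extract_zones(a$paths[[i]])
    expect_equal(sum(z$length), length(a$paths[[i]]))
  }
})

test_that("empirical visit fractions match the branch probabilities", {
  spec <- default_ground_truth()$specs[["one-GU_short"]]
  sim <- simulate_hsmm(spec, 4000, seed = 13)
  visit_s1 <- mean(vapply(sim$paths, function(p) 2 %in% p, logical(1)))
  visit_s2 <- mean(vapply(sim$paths, function(p) 3 %in% p, logical(1)))
  se <- function(p) sqrt(p * (1 - p) / 4000)
  expect_lt(abs(visit_s1 - 0.26), 3 * se(0.26))
  expect_lt(abs(visit_s2 - 0.09), 3 * se(0.09))
  # the two zones are mutually exclusive under this generator
  expect_false(any(vapply(sim$paths, function(p) all(2:3 %in% p),
                          logical(1))))
})

test_that("occupancy-family selection identifies the generating family", {
  expect_equal(select_occupancy_family(rep(3, 10))$family, "point")
  expect_equal(select_occupancy_family(rep(3, 10))$params$at, 3)

  set.seed(21)
  pois_wins <- mean(replicate(20, {
    d <- rpois(500, 5) + 1
    select_occupancy_family(d)$family == "poisson"
  }))
  expect_gte(pois_wins, 0.9)

  nb_wins <- mean(replicate(20, {
    d <- rnbinom(500, size = 1, mu = 6) + 1      # variance far above mean
    select_occupancy_family(d)$family == "nbinom"
  }))
  expect_gte(nb_wins, 0.9)
})

test_that("weighted occupancy fits maximize the within-family likelihood", {
  set.seed(4)
  d <- rpois(200, 4) + 1
  w <- runif(200)
  f <- fit_occupancy(d, "poisson", weights = w)
  expect_equal(f$occ$params$lambda, sum(w * (d - 1)) / sum(w))
  # profile-ML binomial fit beats naive endpoints
  fb <- fit_occupancy(d, "binom")
  grid <- sapply(max(d - 1):(max(d - 1) + 10), function(n)
    sum(dbinom(d - 1, n, mean(d - 1) / n, log = TRUE)))
  expect_gte(fb$loglik + 1e-6, max(grid))
})
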