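test_that("count-family selection separates Poisson from overdispersion", {
  set.seed(8)
  pois_ok <- mean(replicate(20, {
    select_count_family(rpois(300, 5))$family == "poisson"
  }))
  expect_gte(pois_ok, 0.9)

  nb_ok <- mean(replicate(20, {
    select_count_family(rnbinom(300, size = 1.2, mu = 5))$family == "nbinom"
  }))
  expect_gte(nb_ok, 0.9)

  # degenerate variance handled without error
  expect_equal(select_count_family(rep(4L, 20))$family, "poisson")
})

test_that("node-number comparison: letters, power, two-group reduction", {
  y <- rep(c(5, 7, 6, 8), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  r <- compare_node_numbers(y, g)
  expect_length(unique(r$letters), 1)          # identical data: one letter

  set.seed(14)
  seps <- replicate(10, {
    counts <- c(rpois(50, 8), rpois(50, 20), rpois(50, 35))
    groups <- rep(c("short", "medium", "long"), each = 50)
    r <- compare_node_numbers(counts, groups)
    length(unique(r$letters)) == 3
  })
  expect_gte(mean(seps), 0.95)

  r2 <- compare_node_numbers(c(rpois(30, 8), rpois(30, 20)),
                             rep(c("a", "b"), each = 30))
  expect_equal(nrow(r2$pairwise), 1)           # single Wald contrast

  # letter display consistent with the adjusted pairwise decisions
  set.seed(15)
  counts <- c(rpois(40, 8), rpois(40, 9), rpois(40, 30))
  groups <- factor(rep(c("a", "b", "c"), each = 40))
  r3 <- compare_node_numbers(counts, groups)
  for (k in seq_len(nrow(r3$pairwise))) {
    pair <- strsplit(r3$pairwise$contrast[k], " - ")[[1]]
    shares <- any(strsplit(r3$letters[[pair[1]]], "")[[1]] %in%
                    strsplit(r3$letters[[pair[2]]], "")[[1]])
    if (r3$pairwise$p_adj[k] < 0.05) expect_false(shares)
    else expect_true(shares)
  }
})

test_that("lateral-count comparisons route to the right test", {
  same <- rep(c(2, 3, 4), 4)
  r <- compare_lateral_counts(c(same, same), rep(c("a", "b"), each = 12))
  expect_equal(r$test, "mann-whitney")
  expect_gt(r$p_value, 0.05)

  ties <- compare_lateral_counts(rep(1, 12), rep(c("a", "b"), each = 6))
  expect_equal(ties$p_value, 1)
  expect_null(ties$pairwise)

  set.seed(23)
  hits <- replicate(20, {
    y <- c(rpois(40, 4), rpois(40, 4) + 3, rpois(40, 4) + 6)
    g <- rep(c("a", "b", "c"), each = 40)
    r <- compare_lateral_counts(y, g)
    r$test == "kruskal-wallis" && r$p_value < 0.05 && !is.null(r$pairwise)
  })
  expect_gte(mean(hits), 0.9)

  # Dunn's post hoc flags the separated groups
  set.seed(24)
  y <- c(rpois(40, 4), rpois(40, 4), rpois(40, 4) + 8)
  r <- compare_lateral_counts(y, rep(c("a", "b", "c"), each = 40))
  pw <- r$pairwise
  expect_gt(pw$p_adj[pw$contrast == "a - b"], 0.05)
  expect_lt(pw$p_adj[pw$contrast == "a - c"], 0.05)
})

test_that("proportion comparisons: chi-square route and exact route", {
  prop <- rbind(c(20, 40, 60), c(10, 20, 30))   # proportional rows
  r <- compare_lateral_proportions(prop)
  expect_equal(r$method, "chi-square")
  expect_gt(r$p_value, 0.99)
  expect_null(r$pairwise)

  r2 <- compare_lateral_proportions(rbind(c(10, 0), c(0, 10)))
  expect_lt(r2$p_value, 0.001)

  sparse <- rbind(c(3, 0, 1, 0, 2), c(0, 2, 0, 3, 1))
  r3 <- compare_lateral_proportions(sparse)
  expect_true(r3$flagged)
  expect_equal(r3$method, "fisher")

  # pairwise Holm-adjusted sub-tables appear for a 3-group separation
  big <- rbind(c(50, 50), c(52, 48), c(90, 10))
  r4 <- compare_lateral_proportions(big)
  expect_false(is.null(r4$pairwise))
  expect_lt(r4$p_value, 0.05)
})

test_that("nonparametric tests attain nominal type-I error", {
  set.seed(77)
  mw <- mean(replicate(1000, suppressWarnings(
    stats::wilcox.test(rpois(20, 5), rpois(20, 5),
                       correct = TRUE)$p.value < 0.05
  )))
  rej <- mean(replicate(1000, {
    y <- rpois(60, 5)
    compare_lateral_counts(y, rep(c("a", "b", "c"), each = 20))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
  expect_lt(abs(mw - 0.05), 0.02)
})

test_that("lateral-count records tabulate sequences correctly", {
  two_cat <- structure(list(cyclicity = "two-GUs",
                            gd_class = c("short", "long"),
                            gp_class = c("early", "late")),
                       class = "shoot_category")
  s <- branching_sequence("x", c(0, 0, 3, 5, 5, 0, 1, 2, 4), two_cat)
  rec <- lateral_count_records(list(s))
  expect_equal(rec$latent, 3)
  expect_equal(rec$bourse_short, 1)
  expect_equal(rec$scar, 2)
  expect_equal(rec$total_nodes, 9)
  # lateral-type counts never exceed total nodes; scar nodes excluded
  expect_lte(rec$latent + rec$veg_short + rec$veg_long + rec$bourse_short +
               rec$bourse_long, rec$total_nodes)
})
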