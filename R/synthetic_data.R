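#' Left-to-right transitions from target zone-visit probabilities
#'
#' Builds the transition matrix of a left-to-right chain in which each state
#' `j` is visited with marginal probability `visit[j]`, independently of which
#' earlier states were visited: from any state `i`, the next state is `j > i`
#' with probability `visit[j] * prod(1 - visit[m])` over the skipped states
#' `i < m < j`, and the end state absorbs the remaining mass.  Mandatory
#' states have `visit = 1`, impossible ones `visit = 0`.
#'
#' @param visit Numeric vector of marginal visit probabilities per transient
#'   state; `visit[1]` must be 1 (the chain starts in the first state).
#' @return A `K x (K + 1)` transition matrix (last column = end state).
#' @examples
#' routing_transitions(c(1, 0.65, 1, 1, 0.62, 0.47, 0.73))
#' @export
routing_transitions <- function(visit) {
  K <- length(visit)
  stopifnot(K >= 1, visit[1] == 1, all(visit >= 0), all(visit <= 1))
  A <- matrix(0, K, K + 1)
  for (i in seq_len(K)) {
    stay <- 1
    if (i < K) for (j in (i + 1):K) {
      A[i, j] <- stay * visit[j]
      stay <- stay * (1 - visit[j])
    }
    A[i, K + 1] <- stay
  }
  A
}

# emission row over symbols 0..5 from a named probability list
.emis_row <- function(...) {
  p <- c(...)
  row <- numeric(6)
  row[as.integer(names(p)) + 1L] <- p
  stopifnot(abs(sum(row) - 1) < 1e-9)
  row
}

.model_a_names <- c("S0", "S1", "S2")
.model_b_names <- c("L0", "L1", "L2", "L3", "L4", "L5", "L6")

# Model-A spec (3 transient states + end) from explicit transition rows.
.model_a_spec <- function(transitions, s1_emis, s2_emis, s0_occ, s1_occ,
                          s2_occ) {
  hsmm_spec(
    initial = c(1, 0, 0),
    transitions = transitions,
    occupancy = list(s0_occ, s1_occ, s2_occ),
    emission = rbind(.emis_row("0" = 1), s1_emis, s2_emis),
    trans_mask = rbind(c(FALSE, TRUE, TRUE, TRUE),
                       c(FALSE, FALSE, TRUE, TRUE),
                       c(FALSE, FALSE, FALSE, TRUE)),
    state_names = .model_a_names)
}

.model_b_spec <- function(visit, emission, occupancy, trans_mask = NULL) {
  hsmm_spec(
    initial = c(1, rep(0, 6)),
    transitions = routing_transitions(visit),
    occupancy = occupancy,
    emission = emission,
    trans_mask = trans_mask,
    state_names = .model_b_names)
}

.model_b_emission <- function(l1, l4, l5, l6) {
  rbind(.emis_row("0" = 1),        # L0 basal latent (forced)
        l1,                        # L1 diffuse floral
        .emis_row("5" = 1),        # L2 bud-scar / cessation (forced)
        .emis_row("0" = 1),        # L3 second-GU latent (forced)
        l4,                        # L4 short-shoot zone
        l5,                        # L5 floral zone
        l6)                        # L6 acrotonic vegetative
}

#' Default synthetic-study ground truth
#'
#' A fully specified generator for an orchard-like study: the shoot-category
#' mix, per-category growth parameters (start-date and growth-duration
#' distributions, trajectory rate, measurement noise) and one generating
#' hidden semi-Markov chain per category.  Category-mix weights, zone visit
#' probabilities, the diffuse-floral zone-length means and the start-date
#' centres are taken from published category frequencies and zone summaries
#' of a Fuji apple study; emission mixtures, occupancy families away from the
#' diffuse floral zone, trajectory shapes and noise level are package
#' defaults, annotated as such in the serialized form.
#'
#' @return An object of class `ground_truth`.
#' @examples
#' gt <- default_ground_truth()
#' names(gt$specs)
#' @export
default_ground_truth <- function() {
  mix <- list(
    cyclicity = c("one-GU" = 0.71, "two-GUs" = 0.29),
    one_gu_gd = c(short = 0.65, medium = 0.28, long = 0.07),
    one_gu_gp_early = c(short = 0.50, medium = 0.85, long = 1),
    gu1_gd = c(short = 0.33, long = 0.67),
    gu1_gp_early = c(short = 0.68, long = 1),
    gu2_gd = c(short = 0.42, long = 0.58),
    gu2_gp_early = c(short = 0, long = 0.39))

  # growth-duration windows (days) leave margin to the 30/90-day class
  # boundaries so that weekly sampling of the cessation rule cannot move a
  # shoot across a boundary
  growth <- list(
    start_early = list(mean = "04-30", sd = 8, lo = "04-10", hi = "05-31"),
    start_late = list(mean = "06-26", sd = 8, lo = "06-08", hi = "07-20"),
    gu2_early = list(mean = "07-08", sd = 4, lo = "06-25", hi = "07-13"),
    gu2_late_short = list(mean = "08-03", sd = 6, lo = "07-26", hi = "09-01"),
    gu2_late_long = list(mean = "07-30", sd = 6, lo = "07-26", hi = "08-20"),
    gd = list(one_gu_short = c(16, 19, 4, 22),    # lo, mean, sd, hi
              one_gu_medium = c(35, 55, 12, 82),
              one_gu_long = c(94, 105, 8, 125),
              gu1_short = c(16, 19, 4, 22),
              gu1_long = c(35, 42, 6, 48),
              gu2_short = c(16, 19, 4, 22),
              gu2_long = c(35, 42, 6, 50)),
    rate_cm_day = c(0.3, 0.5),
    creep_cm_day = 0.01,
    noise_sd_cm = 0.15,
    year = 2016)

  s0 <- occupancy_dist("poisson", lambda = 6)
  specs <- list(
    "one-GU_short" = .model_a_spec(
      transitions = rbind(c(0, 0.26, 0.09, 0.65),
                          c(0, 0, 0, 1),
                          c(0, 0, 0, 1)),
      s1_emis = .emis_row("0" = 0.28, "3" = 0.70, "4" = 0.02),
      s2_emis = .emis_row("0" = 0.15, "1" = 0.12, "2" = 0.70, "3" = 0.02,
                          "4" = 0.01),
      s0_occ = s0,
      s1_occ = occupancy_dist("nbinom", size = 2, mu = 2.9),
      s2_occ = occupancy_dist("poisson", lambda = 1.5)),
    "one-GU_medium" = .model_a_spec(
      transitions = rbind(c(0, 0.72, 0.13, 0.15),
                          c(0, 0, 0.13 / 0.72, 1 - 0.13 / 0.72),
                          c(0, 0, 0, 1)),
      s1_emis = .emis_row("0" = 0.20, "3" = 0.70, "4" = 0.10),
      s2_emis = .emis_row("0" = 0.10, "1" = 0.10, "2" = 0.70, "3" = 0.05,
                          "4" = 0.05),
      s0_occ = occupancy_dist("poisson", lambda = 8),
      s1_occ = occupancy_dist("nbinom", size = 2, mu = 12.4),
      s2_occ = occupancy_dist("poisson", lambda = 2.5)),
    "one-GU_long" = .model_b_spec(
      visit = c(1, 1, 0, 1, 0.64, 0.55, 0.82),
      emission = .model_b_emission(
        l1 = .emis_row("0" = 0.28, "3" = 0.70, "4" = 0.02),
        l4 = .emis_row("0" = 0.20, "1" = 0.70, "2" = 0.05, "4" = 0.05),
        l5 = .emis_row("0" = 0.10, "3" = 0.50, "4" = 0.40),
        l6 = .emis_row("0" = 0.15, "1" = 0.10, "2" = 0.70, "4" = 0.05)),
      occupancy = list(
        occupancy_dist("poisson", lambda = 6),
        occupancy_dist("nbinom", size = 2, mu = 15.1),
        occupancy_dist("point", at = 1),          # L2 unreachable here
        occupancy_dist("poisson", lambda = 5),
        occupancy_dist("poisson", lambda = 2.5),
        occupancy_dist("poisson", lambda = 2.3),
        occupancy_dist("poisson", lambda = 4))),
    "two-GUs" = .model_b_spec(
      visit = c(1, 0.65, 1, 1, 0.62, 0.47, 0.73),
      emission = .model_b_emission(
        l1 = .emis_row("0" = 0.28, "3" = 0.70, "4" = 0.02),
        l4 = .emis_row("0" = 0.20, "1" = 0.70, "2" = 0.05, "4" = 0.05),
        l5 = .emis_row("0" = 0.10, "3" = 0.70, "4" = 0.20),
        l6 = .emis_row("0" = 0.15, "1" = 0.10, "2" = 0.70, "4" = 0.05)),
      occupancy = list(
        occupancy_dist("poisson", lambda = 6),
        occupancy_dist("nbinom", size = 2, mu = 12),
        occupancy_dist("poisson", lambda = 1),
        occupancy_dist("poisson", lambda = 5),
        occupancy_dist("poisson", lambda = 2),
        occupancy_dist("poisson", lambda = 1.9),
        occupancy_dist("poisson", lambda = 3))))

  provenance <- list(
    literature = c("mix", "specs: zone visit probabilities",
                   "specs: diffuse floral zone mean lengths",
                   "growth: start-date centres, GD class windows"),
    default = c("specs: emission mixtures (0.7 on the zone's name-giving",
                "lateral type), non-floral occupancy families and means,",
                "trajectory rates, creep, measurement noise sd"))

  structure(list(mix = mix, growth = growth, specs = specs,
                 provenance = provenance),
            class = "ground_truth")
}

.date <- function(year, mmdd) as.Date(paste0(year, "-", mmdd))

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:200) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

.draw_gd <- function(gt, class) {
  w <- gt$growth$gd[[class]]
  round(.rtruncnorm1(w[2], w[3], w[1], w[4]))
}

.draw_date <- function(gt, block) {
  b <- gt$growth[[block]]
  y <- gt$growth$year
  round(.rtruncnorm1(as.numeric(.date(y, b$mean)), b$sd,
                     as.numeric(.date(y, b$lo)), as.numeric(.date(y, b$hi))))
}

# Draw a full shoot category plus growth targets (start dates and growth
# durations per GU).  GP feasibility overrides: a second GU can only start
# after the first has demonstrably stopped, so an infeasible early second GU
# is re-labelled late before the truth is recorded.
.draw_shoot_truth <- function(gt, cfg) {
  y <- gt$growth$year
  cyc <- sample(names(gt$mix$cyclicity), 1, prob = gt$mix$cyclicity)
  if (cyc == "one-GU") {
    gd_class <- sample(names(gt$mix$one_gu_gd), 1, prob = gt$mix$one_gu_gd)
    early <- stats::runif(1) < gt$mix$one_gu_gp_early[[gd_class]]
    s1 <- .draw_date(gt, if (early) "start_early" else "start_late")
    gd1 <- .draw_gd(gt, paste0("one_gu_", gd_class))
    return(list(cyclicity = cyc, gd_class = gd_class,
                gp_class = if (early) "early" else "late",
                start = as.Date(s1, origin = "1970-01-01"), gd_days = gd1,
                spec_name = paste0("one-GU_", gd_class)))
  }
  gd1c <- sample(names(gt$mix$gu1_gd), 1, prob = gt$mix$gu1_gd)
  early1 <- stats::runif(1) < gt$mix$gu1_gp_early[[gd1c]]
  s1 <- .draw_date(gt, if (early1) "start_early" else "start_late")
  gd1 <- .draw_gd(gt, paste0("gu1_", gd1c))
  gd2c <- sample(names(gt$mix$gu2_gd), 1, prob = gt$mix$gu2_gd)
  gd2 <- .draw_gd(gt, paste0("gu2_", gd2c))
  early2 <- stats::runif(1) < gt$mix$gu2_gp_early[[gd2c]]
  # first-GU cessation is observed one trailing window after growth stops,
  # on the weekly grid; the second GU needs ~17 d beyond that to register
  c1_obs <- s1 + 7 * ceiling(gd1 / 7)
  min_s2 <- c1_obs + 17
  if (early2 &&
      min_s2 > as.numeric(.date(y, gt$growth$gu2_early$hi))) early2 <- FALSE
  block <- if (early2) "gu2_early" else
    if (gd2c == "short") "gu2_late_short" else "gu2_late_long"
  s2 <- max(.draw_date(gt, block), min_s2)
  if (early2 && s2 > as.numeric(.date(y, "07-14"))) early2 <- FALSE
  list(cyclicity = cyc, gd_class = c(gd1c, gd2c),
       gp_class = c(if (early1) "early" else "late",
                    if (early2) "early" else "late"),
       start = as.Date(c(s1, s2), origin = "1970-01-01"),
       gd_days = c(gd1, gd2), spec_name = "two-GUs")
}

# Deterministic trajectory + noise for one shoot, given start-date and
# growth-duration targets per GU (see the methods vignette for the shape):
# a 10-day rise to the 5 cm start criterion, linear extension, an abrupt
# switch to a slow creep at the engineered stop date, and for two-GU shoots
# a second rise of 5 cm above the first plateau.
.sim_growth_targets <- function(shoot_id, starts, gds, gt,
                                cfg = category_config()) {
  rate <- stats::runif(length(starts), gt$growth$rate_cm_day[1],
                       gt$growth$rate_cm_day[2])
  creep <- gt$growth$creep_cm_day
  x1 <- as.numeric(starts[1]) - 4        # 5 cm crossing date (numeric days)
  b <- x1 - 10                           # budbreak; observation grid anchor
  d1 <- b + 7 * ceiling((as.numeric(starts[1]) + gds[1] - b) / 7)
  c1 <- d1 - 14                          # growth stops one window before
  traj <- function(t) {
    L <- ifelse(t <= x1, pmax(0.5 + 0.45 * (t - b), 0.2),
                5 + rate[1] * (pmin(t, c1) - x1) +
                  creep * pmax(t - c1, 0))
    if (length(starts) == 2) {
      p1 <- 5 + rate[1] * (c1 - x1)
      x2 <- as.numeric(starts[2]) - 3.5
      r2 <- x2 - 10
      d2 <- b + 7 * ceiling((x2 + 3.5 + gds[2] - b) / 7)
      c2 <- d2 - 14
      # rise of 0.5 cm/day from r2 to the 5 cm criterion at x2, extension at
      # the second GU's own rate, then creep after c2
      second <- ifelse(t <= r2, 0,
                       0.5 * (pmin(t, x2) - r2) +
                         rate[2] * pmax(pmin(t, c2) - x2, 0) +
                         creep * pmax(t - c2, 0))
      L <- L + second
    }
    L
  }
  obs_t <- seq(b, as.numeric(gt$growth$season_end %||%
                               .date(gt$growth$year, "10-31")), by = 7)
  len <- traj(obs_t) + stats::rnorm(length(obs_t), 0, gt$growth$noise_sd_cm)
  len[1] <- max(len[1], 0.1)
  for (i in seq_along(len)[-1]) len[i] <- max(len[i], len[i - 1] - 0.9, 0.1)
  growth_series(shoot_id, as.Date(obs_t, origin = "1970-01-01"), round(len, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one shoot's weekly growth series for a target category
#'
#' Draws start dates and growth durations for the category from the ground
#' truth, then builds a weekly-sampled trajectory engineered so that the
#' cessation rule (gain below 0.5 cm over a trailing two-week window) fires
#' one window after each growth unit's stop date, and the 5 cm start
#' criterion is met on the target start date.
#'
#' @param category Category label: `"one-GU_<gd>_<gp>"` with `<gd>` in
#'   short/medium/long and `<gp>` in early/late, or
#'   `"two-GUs_<gd1>-<gp1>_<gd2>-<gp2>"`.
#' @param gt A [default_ground_truth()]-style object.
#' @param seed Optional integer seed.
#' @param shoot_id Identifier for the series.
#' @return A [growth_series()] whose re-classification matches the target
#'   category (up to sampling noise).
#' @export
simulate_growth_series <- function(category, gt = default_ground_truth(),
                                   seed = NULL, shoot_id = "sim") {
  if (!is.null(seed)) set.seed(seed)
  parts <- strsplit(category, "_")[[1]]
  y <- gt$growth$year
  if (parts[1] == "one-GU") {
    gd_class <- parts[2]; gp <- parts[3]
    s1 <- .draw_date(gt, if (gp == "early") "start_early" else "start_late")
    gd <- .draw_gd(gt, paste0("one_gu_", gd_class))
    return(.sim_growth_targets(shoot_id,
                               as.Date(s1, origin = "1970-01-01"), gd, gt))
  }
  gu <- strsplit(parts[2:3], "-")
  gd1c <- gu[[1]][1]; gp1 <- gu[[1]][2]
  gd2c <- gu[[2]][1]; gp2 <- gu[[2]][2]
  s1 <- .draw_date(gt, if (gp1 == "early") "start_early" else "start_late")
  gd1 <- .draw_gd(gt, paste0("gu1_", gd1c))
  c1_obs <- s1 + 7 * ceiling(gd1 / 7)
  block <- if (gp2 == "early") "gu2_early" else
    if (gd2c == "short") "gu2_late_short" else "gu2_late_long"
  s2 <- max(.draw_date(gt, block), c1_obs + 17)
  gd2 <- .draw_gd(gt, paste0("gu2_", gd2c))
  .sim_growth_targets(shoot_id, as.Date(c(s1, s2), origin = "1970-01-01"),
                      c(gd1, gd2), gt)
}

#' Simulate a complete synthetic study
#'
#' Draws `n_shoots` shoots from the category mix, simulates the weekly growth
#' series and the bud-fate sequence of each (the sequence from the category's
#' generating hidden semi-Markov chain), and optionally writes the growth
#' CSV, sequence TSV and a ground-truth record readable by the data layer.
#'
#' @param n_shoots Number of shoots.
#' @param gt A [default_ground_truth()]-style object.
#' @param seed Integer seed; identical seeds give identical studies (and
#'   byte-identical files).
#' @param out_dir Optional directory to write `growth.csv`,
#'   `sequences.tsv` and `truth.yaml` into.
#' @return A list of class `synthetic_study`: `growth` (list of
#'   [growth_series()]), `sequences` (list of [branching_sequence()]),
#'   `truth` (data.frame: shoot_id, category label, spec name, per-GU start
#'   dates and growth durations), `paths` (generating state paths), and
#'   `files` when written.
#' @export
simulate_study <- function(n_shoots, gt = default_ground_truth(), seed = 1,
                           out_dir = NULL) {
  stopifnot(n_shoots >= 1)
  set.seed(seed)
  cfg <- category_config()
  growth <- vector("list", n_shoots)
  seqs <- vector("list", n_shoots)
  paths <- vector("list", n_shoots)
  truth <- vector("list", n_shoots)
  for (i in seq_len(n_shoots)) {
    id <- sprintf("shoot%04d", i)
    tr <- .draw_shoot_truth(gt, cfg)
    cat_ <- structure(list(cyclicity = tr$cyclicity, gd_class = tr$gd_class,
                           gp_class = tr$gp_class), class = "shoot_category")
    growth[[i]] <- .sim_growth_targets(id, tr$start, tr$gd_days, gt, cfg)
    spec <- gt$specs[[tr$spec_name]]
    sim <- simulate_hsmm(spec, 1)
    seqs[[i]] <- branching_sequence(id, sim$sequences[[1]], cat_)
    paths[[i]] <- sim$paths[[1]]
    truth[[i]] <- data.frame(shoot_id = id, category = category_label(cat_),
                             spec = tr$spec_name,
                             start_1 = tr$start[1],
                             start_2 = if (length(tr$start) == 2)
                               tr$start[2] else as.Date(NA),
                             gd_1 = tr$gd_days[1],
                             gd_2 = if (length(tr$gd_days) == 2)
                               tr$gd_days[2] else NA_real_,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  out <- structure(list(growth = growth, sequences = seqs, paths = paths,
                        truth = truth, seed = seed),
                   class = "synthetic_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gfile <- file.path(out_dir, "growth.csv")
    rows <- do.call(rbind, lapply(growth, function(s)
      data.frame(shoot_id = s$shoot_id, date = format(s$dates),
                 length_cm = formatC(s$lengths_cm, format = "f", digits = 1),
                 stringsAsFactors = FALSE)))
    utils::write.csv(rows, gfile, row.names = FALSE, quote = FALSE)
    sfile <- file.path(out_dir, "sequences.tsv")
    write_sequences(seqs, sfile)
    tfile <- file.path(out_dir, "truth.yaml")
    yaml::write_yaml(list(seed = seed, truth = lapply(seq_len(nrow(truth)),
      function(i) as.list(lapply(truth[i, ], as.character)))), tfile)
    out$files <- c(growth = gfile, sequences = sfile, truth = tfile)
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", length(x$sequences), "shoots (seed", x$seed, ")\n")
  print(table(x$truth$spec))
  invisible(x)
}
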