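delta_spec <- function(at = 4, symbol = 0) {
  em <- numeric(6); em[symbol + 1] <- 1
  hsmm_spec(1, matrix(c(0, 1), 1, 2),
            list(occupancy_dist("point", at = at)), rbind(em))
}

test_that("forward likelihood handles forced and impossible paths", {
  spec <- delta_spec(at = 4)
  expect_equal(log_likelihood(spec, c(0, 0, 0, 0)), 0)
  expect_identical(log_likelihood(spec, c(0, 0, 0)), -Inf)   # bad duration
  expect_identical(log_likelihood(spec, c(0, 0, 1, 0)), -Inf) # masked symbol
  expect_error(log_likelihood(spec, c(0, 9, 0, 0)), "alphabet")
})

test_that("forward likelihood equals exhaustive enumeration on toy specs", {
  set.seed(42)
  for (trial in 1:40) {
    spec <- random_toy_spec(K = sample(2:3, 1))
    obs <- sample(0:5, sample(3:8, 1), replace = TRUE)
    oracle <- enum_hsmm(spec, obs)
    fwd <- log_likelihood(spec, obs)
    if (is.finite(oracle$loglik)) {
      expect_equal(fwd, oracle$loglik, tolerance = 1e-10)
    } else {
      expect_identical(fwd, -Inf)
    }
  }
})

test_that("single state with geometric occupancy matches the closed form", {
  # geometric zone length (shifted NB with size 1) makes the sequence an
  # i.i.d. categorical sample with a geometric stopping time
  p_stop <- 0.3
  em <- c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05)
  spec <- hsmm_spec(1, matrix(c(0, 1), 1, 2),
                    list(occupancy_dist("nbinom", size = 1,
                                        mu = (1 - p_stop) / p_stop)),
                    rbind(em))
  obs <- c(0, 2, 1, 0, 4, 0, 3)
  closed <- sum(log(em[obs + 1])) + (length(obs) - 1) * log(1 - p_stop) +
    log(p_stop)
  expect_equal(log_likelihood(spec, obs), closed, tolerance = 1e-12)
})

test_that("Viterbi restores the optimum, with deterministic tie-breaks", {
  # fully forced chain: the unique feasible path is returned
  spec <- hsmm_spec(
    c(1, 0),
    rbind(c(0, 1, 0), c(0, 0, 1)),
    list(occupancy_dist("point", at = 2), occupancy_dist("point", at = 3)),
    rbind(c(1, 0, 0, 0, 0, 0), c(0, 0, 0, 1, 0, 0)))
  d <- viterbi_decode(spec, c(0, 0, 3, 3, 3))
  expect_equal(d$states, c(1, 1, 2, 2, 2))
  expect_equal(d$log_joint, log_likelihood(spec, c(0, 0, 3, 3, 3)))

  # agreement with enumeration on random toys
  set.seed(7)
  for (trial in 1:40) {
    spec <- random_toy_spec(K = sample(2:3, 1))
    obs <- sample(0:5, sample(3:8, 1), replace = TRUE)
    oracle <- enum_hsmm(spec, obs)
    if (!is.finite(oracle$loglik)) {
      expect_error(viterbi_decode(spec, obs), "inconsistent node")
      next
    }
    d <- viterbi_decode(spec, obs)
    expect_equal(d$log_joint, oracle$best, tolerance = 1e-10)
    expect_equal(d$log_joint,
                 sum(log(spec$emission[cbind(d$states, obs + 1)])) +
                   local({
                     z <- extract_zones(d)
                     lp <- log(spec$initial[z$state[1]])
                     for (i in seq_len(nrow(z))) {
                       lp <- lp + docc(z$length[i],
                                       spec$occupancy[[z$state[i]]],
                                       log = TRUE)
                       nxt <- if (i < nrow(z)) z$state[i + 1] else
                         spec$n_transient + 1
                       lp <- lp + log(spec$transitions[z$state[i], nxt])
                     }
                     lp
                   }), tolerance = 1e-10)
    # joint probability of the best path never exceeds the total
    expect_lte(d$log_joint, oracle$loglik + 1e-10)
  }

  # exact tie between two single-zone explanations: lowest state index wins
  em <- c(1, 0, 0, 0, 0, 0)
  tie <- hsmm_spec(
    c(0.5, 0.5),
    rbind(c(0, 0, 1), c(0, 0, 1)),
    list(occupancy_dist("point", at = 3), occupancy_dist("point", at = 3)),
    rbind(em, em))
  expect_equal(viterbi_decode(tie, c(0, 0, 0))$states, c(1, 1, 1))
})

test_that("impossible sequences report the first inconsistent node", {
  spec <- delta_spec(at = 4)
  expect_error(viterbi_decode(spec, c(0, 0, 3, 0)),
               "node index 2")
})

test_that("EM log-likelihood is non-decreasing and restarts are reproducible", {
  set.seed(11)
  for (trial in 1:3) {
    spec <- random_toy_spec(K = 3)
    sim <- simulate_hsmm(spec, 40, seed = trial)
    fit <- fit_em(sim$sequences, spec,
                  em_settings(n_restarts = 2, max_iter = 60, seed = trial))
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    fit2 <- fit_em(sim$sequences, spec,
                   em_settings(n_restarts = 2, max_iter = 60, seed = trial))
    expect_equal(fit$loglik, fit2$loglik)
    expect_equal(fit$spec$transitions, fit2$spec$transitions)
  }
})

test_that("forced structure survives EM on all-latent sequences", {
  template <- hsmm_spec(1, matrix(c(0, 1), 1, 2),
                        list(occupancy_dist("poisson", lambda = 3)),
                        rbind(c(1, 0, 0, 0, 0, 0)))
  set.seed(3)
  lens <- rpois(60, 5) + 1
  seqs <- lapply(lens, function(l) rep(0L, l))
  fit <- fit_em(seqs, template, em_settings(n_restarts = 2))
  expect_equal(fit$spec$emission[1, ], c(1, 0, 0, 0, 0, 0))
  # the occupancy mean matches the empirical zone-length distribution
  expect_equal(occ_mean(fit$spec$occupancy[[1]]), mean(lens),
               tolerance = 1e-6)
  expect_equal(fit$bic, -2 * fit$loglik + 1 * log(sum(lens)))
})

test_that("EM recovers a known three-state generator", {
  truth <- default_ground_truth()$specs[["one-GU_short"]]
  sim <- simulate_hsmm(truth, 500, seed = 5)
  fit <- fit_em(sim$sequences, truth, em_settings(n_restarts = 4, seed = 5))
  # entry probability into the diffuse floral zone, within +-0.05
  expect_lt(abs(fit$spec$transitions[1, 2] - truth$transitions[1, 2]), 0.05)
})

test_that("model serialization round-trips as decimal text", {
  spec <- default_ground_truth()$specs[["two-GUs"]]
  p <- withr::local_tempfile(fileext = ".yaml")
  write_hsmm(spec, p)
  back <- read_hsmm(p)
  expect_equal(back$transitions, spec$transitions, tolerance = 1e-11)
  expect_equal(back$emission, spec$emission, tolerance = 1e-11)
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_hsmm(back, p2)
  expect_identical(readLines(p), readLines(p2))
})
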