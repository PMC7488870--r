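# Independent brute-force oracles used to check the recursions.

# Exhaustive enumeration of every state path of a left-to-right HSMM over a
# short sequence: total probability, best joint log-probability and the best
# path (first found in lowest-state, shortest-first-duration order).
enum_hsmm <- function(spec, obs) {
  K <- spec$n_transient
  Tn <- length(obs)
  total <- 0
  best <- -Inf
  bestpath <- NULL
  rec <- function(t, j, logp, path) {
    for (u in 1:(Tn - t)) {
      lp <- logp + docc(u, spec$occupancy[[j]], log = TRUE) +
        sum(log(spec$emission[j, obs[(t + 1):(t + u)] + 1]))
      if (!is.finite(lp)) next
      if (t + u == Tn) {
        lpe <- lp + log(spec$transitions[j, K + 1])
        if (is.finite(lpe)) {
          total <<- total + exp(lpe)
          if (lpe > best + 1e-15) {
            best <<- lpe
            bestpath <<- c(path, rep(j, u))
          }
        }
      } else if (j < K) {
        for (k in (j + 1):K) {
          a <- spec$transitions[j, k]
          if (a > 0) rec(t + u, k, lp + log(a), c(path, rep(j, u)))
        }
      }
    }
  }
  for (j in 1:K) if (spec$initial[j] > 0)
    rec(0, j, log(spec$initial[j]), integer(0))
  list(loglik = log(total), best = best, path = bestpath)
}

# Random small left-to-right spec over the bud-fate alphabet, for
# property-style equivalence checks.
random_toy_spec <- function(K = 2) {
  v <- c(1, stats::runif(K - 1))
  occ <- lapply(seq_len(K), function(i)
    occupancy_dist("poisson", lambda = stats::runif(1, 0.5, 2)))
  B <- t(vapply(seq_len(K), function(i) {
    p <- stats::runif(6)
    p[sample(1:6, 2)] <- 0
    p / sum(p)
  }, numeric(6)))
  hsmm_spec(c(1, rep(0, K - 1)), routing_transitions(v), occ, B)
}

# Exact Fisher p-value by full enumeration of all tables with the observed
# margins; p = total probability of tables no more probable than the observed
# one (the two-sided definition used by the exact test).
fisher_enum <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  logp_tab <- function(m)
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(m))
  p_obs <- logp_tab(tab)
  total <- 0
  nr <- nrow(tab); nc <- ncol(tab)
  m <- matrix(0L, nr, nc)
  rec <- function(i, j, row_left, col_left) {
    if (i == nr) {                       # last row forced by column margins
      m[nr, ] <<- col_left
      lp <- logp_tab(m)
      if (lp <= p_obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    if (j == nc) {                       # last cell of the row forced
      if (row_left > col_left[nc]) return()
      m[i, nc] <<- row_left
      cl <- col_left; cl[nc] <- cl[nc] - row_left
      rec(i + 1, 1, rs[i + 1], cl)
      return()
    }
    for (x in 0:min(row_left, col_left[j])) {
      m[i, j] <<- x
      cl <- col_left; cl[j] <- cl[j] - x
      rec(i, j + 1, row_left - x, cl)
    }
  }
  rec(1, 1, rs[1], cs)
  total
}
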