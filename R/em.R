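#' EM settings for hidden semi-Markov chain estimation
#'
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of random restarts; the first restart uses the
#'   unjittered moment initialization, later ones jitter it.
#' @param emission_floor Probability floor applied to free emission cells
#'   during iterations (guards against absorbing zeros); cells that end below
#'   the floor are zeroed in the final reported model.
#' @param seed Base seed from which per-restart seeds derive.
#' @return A list of class `em_settings`.
#' @export
em_settings <- function(tol = 1e-6, max_iter = 500L, n_restarts = 10L,
                        emission_floor = 1e-6, seed = 1L) {
  stopifnot(tol > 0, max_iter >= 1, n_restarts >= 1, emission_floor >= 0)
  structure(list(tol = tol, max_iter = max_iter,
                 n_restarts = as.integer(n_restarts),
                 emission_floor = emission_floor, seed = as.integer(seed)),
            class = "em_settings")
}

# Moment-based initialization of a template: transitions uniform over allowed
# cells, emissions from global symbol frequencies renormalized under masks
# (floor 1e-3), occupancies shifted-Poisson-like with mean = mean sequence
# length / number of states (respecting each state's declared family).
.em_init <- function(template, seqs, jitter = FALSE) {
  K <- template$n_transient
  spec <- template
  A <- matrix(0, K, K + 1)
  for (i in seq_len(K)) {
    m <- template$trans_mask[i, ]
    A[i, m] <- 1 / sum(m)
  }
  freqs <- tabulate(unlist(seqs) + 1L, nbins = template$n_symbols)
  freqs <- freqs / sum(freqs)
  B <- matrix(0, K, template$n_symbols)
  for (i in seq_len(K)) {
    m <- template$emis_mask[i, ]
    if (sum(m) == 1L) { B[i, m] <- 1; next }
    b <- pmax(freqs[m], 1e-3)
    B[i, m] <- b / sum(b)
  }
  mlen <- mean(lengths(seqs))
  mu0 <- max(mlen / K, 1.2)
  occ <- lapply(seq_len(K), function(i) {
    fam <- template$occupancy[[i]]$family
    switch(fam,
      poisson = occupancy_dist("poisson", lambda = mu0 - 1),
      nbinom  = occupancy_dist("nbinom", size = 2, mu = mu0 - 1),
      binom   = occupancy_dist("binom", size = max(ceiling(2 * (mu0 - 1)), 1),
                               prob = 0.5),
      point   = template$occupancy[[i]])
  })
  if (jitter) {
    for (i in seq_len(K)) {
      m <- template$trans_mask[i, ]
      if (sum(m) > 1) {
        A[i, m] <- A[i, m] * exp(stats::runif(sum(m), -0.5, 0.5))
        A[i, m] <- A[i, m] / sum(A[i, m])
      }
      me <- template$emis_mask[i, ]
      if (sum(me) > 1) {
        B[i, me] <- B[i, me] * exp(stats::runif(sum(me), -0.5, 0.5))
        B[i, me] <- B[i, me] / sum(B[i, me])
      }
      f <- stats::runif(1, 0.7, 1.3)
      o <- occ[[i]]
      occ[[i]] <- switch(o$family,
        poisson = occupancy_dist("poisson", lambda = o$params$lambda * f),
        nbinom  = occupancy_dist("nbinom", size = o$params$size,
                                 mu = o$params$mu * f),
        o)
    }
  }
  spec$transitions <- A
  spec$emission <- B
  spec$occupancy <- occ
  spec$initial <- template$initial
  validate_hsmm(spec)
  spec
}

# One E-step over all sequences; returns summed expected counts and loglik.
.em_estep <- function(spec, seqs) {
  K <- spec$n_transient
  Tmax <- max(lengths(seqs))
  li <- .log_or_big(spec$initial)
  lt <- .log_or_big(spec$transitions)
  le <- .log_or_big(spec$emission)
  ld <- .log_dur_matrix(spec, Tmax)
  c_init <- numeric(K)
  c_trans <- matrix(0, K, K + 1)
  c_dur <- matrix(0, K, Tmax)
  c_emis <- matrix(0, K, spec$n_symbols)
  ll <- 0
  for (s in seqs) {
    Tn <- length(s)
    e <- .hsmm_estep_cpp(s, li, lt, ld[, seq_len(Tn), drop = FALSE], le)
    if (!is.finite(e$loglik)) return(list(loglik = -Inf))
    ll <- ll + e$loglik
    c_init <- c_init + e$init
    c_trans <- c_trans + e$trans
    c_dur[, seq_len(Tn)] <- c_dur[, seq_len(Tn)] + e$dur
    c_emis <- c_emis + e$emis
  }
  list(loglik = ll, init = c_init, trans = c_trans, dur = c_dur,
       emis = c_emis)
}

.em_mstep <- function(spec, counts, floor = 1e-6) {
  K <- spec$n_transient
  A <- spec$transitions
  for (i in seq_len(K)) {
    m <- spec$trans_mask[i, ]
    tot <- sum(counts$trans[i, m])
    if (tot > 0) { A[i, ] <- 0; A[i, m] <- counts$trans[i, m] / tot }
  }
  B <- spec$emission
  for (i in seq_len(K)) {
    m <- spec$emis_mask[i, ]
    if (sum(m) == 1L) next                        # forced state
    tot <- sum(counts$emis[i, m])
    if (tot > 0) {
      b <- pmax(counts$emis[i, m] / tot, floor)
      B[i, ] <- 0; B[i, m] <- b / sum(b)
    }
  }
  occ <- spec$occupancy
  for (i in seq_len(K)) {
    w <- counts$dur[i, ]
    if (sum(w) > 1e-12 && occ[[i]]$family != "point")
      occ[[i]] <- fit_occupancy(seq_along(w), occ[[i]]$family, weights = w)$occ
    else if (sum(w) > 1e-12 && occ[[i]]$family == "point")
      occ[[i]] <- fit_occupancy(seq_along(w), "point", weights = w)$occ
  }
  init <- spec$initial
  if (sum(spec$initial > 0) > 1) {
    sup <- spec$initial > 0
    tot <- sum(counts$init[sup])
    if (tot > 0) { init[] <- 0; init[sup] <- counts$init[sup] / tot }
  }
  spec$transitions <- A; spec$emission <- B
  spec$occupancy <- occ; spec$initial <- init
  spec
}

#' Estimate a constrained hidden semi-Markov chain by EM
#'
#' Explicit-duration forward-backward EM under the structural constraints of
#' a template: left-to-right allowed-transition mask, per-state symbol masks
#' (forced states keep their degenerate emissions), per-state occupancy
#' families, and a fixed or free initial vector.  The best of several random
#' restarts is returned; within each restart the log-likelihood is
#' non-decreasing up to numerical tolerance.
#'
#' @param seqs A `sequence_set`, a list of [branching_sequence()] objects, or
#'   a list of integer symbol vectors.
#' @param template An [hsmm_spec()] defining state count, masks, occupancy
#'   families and the initial vector.  Its probability values are only used
#'   as structure; estimation starts from moment-based initializations.
#' @param settings An [em_settings()] object.
#' @return An object of class `hsmm_fit`: list with `spec` (fitted
#'   [hsmm_spec()]), `loglik`, `n_iter`, `bic`, `restart_id`, and
#'   `loglik_trace` of the winning restart.
#' @examples
#' truth <- hsmm_spec(
#'   initial = c(1, 0),
#'   transitions = rbind(c(0, 0.7, 0.3), c(0, 0, 1)),
#'   occupancy = list(occupancy_dist("poisson", lambda = 3),
#'                    occupancy_dist("poisson", lambda = 2)),
#'   emission = rbind(c(1, 0, 0, 0, 0, 0),
#'                    c(0.3, 0, 0, 0.7, 0, 0)))
#' sim <- simulate_hsmm(truth, 60, seed = 1)
#' fit <- fit_em(sim$sequences, truth,
#'               em_settings(n_restarts = 2, max_iter = 50))
#' fit$spec$transitions
#' @export
fit_em <- function(seqs, template, settings = em_settings()) {
  validate_hsmm(template)
  if (inherits(seqs, "sequence_set")) seqs <- seqs$sequences
  seqs <- lapply(seqs, function(s) .check_symbols(.seq_symbols(s), template))
  if (length(seqs) < 1) stop("need at least one sequence")
  total_nodes <- sum(lengths(seqs))

  best <- NULL
  for (r in seq_len(settings$n_restarts)) {
    set.seed(settings$seed + 1000L * (r - 1L))
    spec <- .em_init(template, seqs, jitter = r > 1)
    trace <- numeric(0)
    ll_prev <- -Inf
    iter <- 0L
    ok <- TRUE
    repeat {
      iter <- iter + 1L
      counts <- .em_estep(spec, seqs)
      if (!is.finite(counts$loglik)) { ok <- FALSE; break }
      trace <- c(trace, counts$loglik)
      if (is.finite(ll_prev)) {
        rel <- abs(counts$loglik - ll_prev) / (abs(ll_prev) + 1e-12)
        if (rel < settings$tol || iter >= settings$max_iter) {
          spec <- .em_mstep(spec, counts, settings$emission_floor)
          break
        }
      }
      spec <- .em_mstep(spec, counts, settings$emission_floor)
      ll_prev <- counts$loglik
      if (iter >= settings$max_iter) break
    }
    if (!ok) {
      warning("restart ", r, " discarded: degenerate (zero-probability) fit")
      next
    }
    ll <- trace[length(trace)]
    if (is.null(best) || ll > best$loglik + 1e-9)
      best <- list(spec = spec, loglik = ll, n_iter = iter,
                   restart_id = r, loglik_trace = trace)
  }
  if (is.null(best))
    stop("all restarts degenerate: no sequence has positive probability ",
         "under the template structure")

  # drop sub-floor emission cells from the reported model
  spec <- best$spec
  for (i in seq_len(spec$n_transient)) {
    m <- spec$emis_mask[i, ]
    if (sum(m) > 1) {
      b <- spec$emission[i, ]
      b[b <= settings$emission_floor] <- 0
      spec$emission[i, ] <- b / sum(b)
    }
  }
  best$spec <- validate_hsmm(spec)

  k <- n_free_parameters(spec)
  best$bic <- -2 * best$loglik + k * log(total_nodes)
  best$n_free <- k
  best$total_nodes <- total_nodes
  class(best) <- "hsmm_fit"
  best
}

#' @export
print.hsmm_fit <- function(x, ...) {
  cat("hsmm_fit:", x$spec$n_transient, "transient states; loglik",
      format(x$loglik, digits = 8), "; BIC", format(x$bic, digits = 8),
      "; ", x$n_iter, "EM iterations (restart", x$restart_id, ")\n")
  invisible(x)
}
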