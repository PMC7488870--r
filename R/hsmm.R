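#' Constrained left-to-right hidden semi-Markov chain specification
#'
#' Defines a hidden semi-Markov chain over the bud-fate alphabet `0..5` with
#' `K` transient states and one absorbing, non-emitting end state.  Transitions
#' are unidirectional (strictly upper-triangular among the transient states):
#' a state can never be revisited.  Each transient state carries an explicit
#' occupancy distribution (zone length in nodes) and a categorical emission
#' distribution over the six bud fates.  Sequence length is governed entirely
#' by the transient occupancies; the final zone is treated as complete.
#'
#' Structural constraints are expressed through masks: `trans_mask` marks the
#' transitions allowed during estimation and `emis_mask` the symbols each state
#' may emit.  A state whose emission mask permits a single symbol is a forced
#' state (e.g. basal latent zones emitting only symbol 0, or a bud-scar zone
#' emitting only symbol 5); its emission row is never re-estimated.
#'
#' @param initial Numeric vector of length `K`; initial probabilities over the
#'   transient states (sums to 1).
#' @param transitions `K x (K + 1)` matrix; column `K + 1` is the absorbing end
#'   state.  Rows sum to 1 and entries `transitions[i, j]` with `j <= i` must
#'   be zero.
#' @param occupancy List of `K` [occupancy_dist()] objects.
#' @param emission `K x 6` matrix of emission probabilities over symbols
#'   `0..5`; rows sum to 1.
#' @param trans_mask Optional logical `K x (K + 1)` matrix of transitions
#'   allowed during estimation; defaults to `transitions > 0`.
#' @param emis_mask Optional logical `K x 6` matrix of permitted symbols;
#'   defaults to `emission > 0`.
#' @param state_names Optional character vector of state labels (e.g.
#'   `c("S0", "S1", "S2")`).
#' @return An object of class `hsmm`.
#' @examples
#' spec <- hsmm_spec(
#'   initial = c(1, 0),
#'   transitions = rbind(c(0, 0.4, 0.6), c(0, 0, 1)),
#'   occupancy = list(occupancy_dist("poisson", lambda = 3),
#'                    occupancy_dist("poisson", lambda = 2)),
#'   emission = rbind(c(1, 0, 0, 0, 0, 0),
#'                    c(0.2, 0, 0, 0.8, 0, 0)))
#' spec
#' @export
hsmm_spec <- function(initial, transitions, occupancy, emission,
                      trans_mask = NULL, emis_mask = NULL,
                      state_names = NULL) {
  K <- length(initial)
  transitions <- unname(as.matrix(transitions))
  emission <- unname(as.matrix(emission))
  if (!is.null(trans_mask)) trans_mask <- unname(as.matrix(trans_mask))
  if (!is.null(emis_mask)) emis_mask <- unname(as.matrix(emis_mask))
  if (is.null(trans_mask)) trans_mask <- transitions > 0
  if (is.null(emis_mask)) emis_mask <- emission > 0
  if (is.null(state_names)) state_names <- paste0("S", seq_len(K) - 1)
  spec <- structure(
    list(n_transient = K, initial = as.numeric(initial),
         transitions = transitions, occupancy = occupancy,
         emission = emission, trans_mask = trans_mask,
         emis_mask = emis_mask, state_names = state_names,
         n_symbols = ncol(emission)),
    class = "hsmm")
  validate_hsmm(spec)
  spec
}

#' Validate a hidden semi-Markov chain specification
#'
#' Checks dimensions, stochasticity, the left-to-right transient structure,
#' reachability of the end state and mask consistency.  Called by
#' [hsmm_spec()]; exported so estimation templates can be revalidated after
#' manual edits.
#'
#' @param spec An `hsmm` object.
#' @param tol Tolerance on probability row sums.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_hsmm <- function(spec, tol = 1e-8) {
  stopifnot(inherits(spec, "hsmm"))
  K <- spec$n_transient
  if (K < 1) stop("need at least one transient state")
  if (length(spec$initial) != K) stop("initial has wrong length")
  if (any(spec$initial < 0) || abs(sum(spec$initial) - 1) > tol)
    stop("initial probabilities must be non-negative and sum to 1")
  A <- spec$transitions
  if (!all(dim(A) == c(K, K + 1))) stop("transition matrix must be K x (K+1)")
  if (any(A < 0)) stop("negative transition probability")
  if (any(abs(rowSums(A) - 1) > tol)) stop("transition rows must sum to 1")
  for (i in seq_len(K)) if (any(A[i, seq_len(i)] > 0))
    stop("transitions must be strictly left-to-right (upper triangular), ",
         "violated in row ", i)
  # end reachable from every state: walk allowed transitions forward
  reach_end <- logical(K)
  for (i in K:1) {
    if (A[i, K + 1] > 0) reach_end[i] <- TRUE
    else if (i < K && any(A[i, (i + 1):K] > 0 & reach_end[(i + 1):K]))
      reach_end[i] <- TRUE
  }
  if (!all(reach_end))
    stop("end state unreachable from state(s): ",
         paste(spec$state_names[!reach_end], collapse = ", "))
  if (length(spec$occupancy) != K) stop("need one occupancy per state")
  ok <- vapply(spec$occupancy, inherits, logical(1), "occupancy_dist")
  if (!all(ok)) stop("occupancy entries must be occupancy_dist objects")
  B <- spec$emission
  if (nrow(B) != K) stop("emission matrix must have K rows")
  if (any(B < 0) || any(abs(rowSums(B) - 1) > tol))
    stop("emission rows must be probability vectors")
  if (any(B[!spec$emis_mask] > 0))
    stop("emission mass outside the permitted symbol mask")
  if (any(A[!spec$trans_mask] > 0))
    stop("transition mass outside the allowed-transition mask")
  invisible(spec)
}

#' @export
print.hsmm <- function(x, ...) {
  cat("Left-to-right hidden semi-Markov chain:", x$n_transient,
      "transient states + absorbing end\n")
  cat("States:", paste(x$state_names, collapse = ", "), "\n")
  cat("Mean zone lengths (nodes):",
      paste(format(vapply(x$occupancy, occ_mean, numeric(1)), digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}

BIG_NEG <- -1e100

.log_or_big <- function(p) ifelse(p > 0, log(p), BIG_NEG)

# Per-state duration log-pmf matrix truncated at Tmax (K x Tmax)
.log_dur_matrix <- function(spec, Tmax) {
  t(vapply(spec$occupancy, function(o) .log_or_big(docc(seq_len(Tmax), o)),
           numeric(Tmax)))
}

.check_symbols <- function(symbols, spec) {
  if (length(symbols) < 1) stop("empty sequence")
  if (any(symbols != round(symbols)) || any(symbols < 0) ||
      any(symbols >= spec$n_symbols))
    stop("symbol outside the alphabet 0..", spec$n_symbols - 1,
         " at node index ",
         which(symbols < 0 | symbols >= spec$n_symbols |
               symbols != round(symbols))[1] - 1)
  as.integer(symbols)
}

.seq_symbols <- function(seq) {
  if (inherits(seq, "branching_sequence")) seq$symbols else as.integer(seq)
}

#' Log-likelihood of a bud-fate sequence under an HSMM
#'
#' Computes `log P(sequence, termination into the end state exactly at the
#' last node)` by the explicit-duration forward recursion.  Returns `-Inf`
#' when no state path can produce the sequence (symbol masks or duration
#' support make it impossible).
#'
#' @param spec An [hsmm_spec()].
#' @param seq A [branching_sequence()] or an integer vector of symbols `0..5`.
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
log_likelihood <- function(spec, seq) {
  validate_hsmm(spec)
  obs <- .check_symbols(.seq_symbols(seq), spec)
  Tn <- length(obs)
  ll <- .hsmm_forward_cpp(obs, .log_or_big(spec$initial),
                          .log_or_big(spec$transitions),
                          .log_dur_matrix(spec, Tn),
                          .log_or_big(spec$emission))
  if (ll < BIG_NEG / 2) -Inf else ll
}

# Longest feasible prefix length under masks + duration supports; used to
# report the first inconsistent node of an impossible sequence.
.feasible_prefix <- function(spec, obs) {
  K <- spec$n_transient
  Tn <- length(obs)
  dmax <- vapply(spec$occupancy, function(o)
    if (o$family == "point") o$params$at
    else if (o$family == "binom") o$params$size + 1 else Inf, numeric(1))
  dok <- function(j, u) u <= dmax[j] && docc(u, spec$occupancy[[j]]) > 0
  # ends[t, j]: prefix 1..t can consist of complete zones ending in state j
  ends <- matrix(FALSE, Tn + 1, K)
  emit_ok <- function(j, a, b) all(spec$emis_mask[j, obs[a:b] + 1L])
  best <- 0L
  for (t in seq_len(Tn)) {
    for (j in seq_len(K)) {
      for (u in seq_len(t)) {
        if (!dok(j, u) || !emit_ok(j, t - u + 1L, t)) next
        entry <- if (u == t) spec$initial[j] > 0 else
          t - u >= 1 && any(ends[t - u + 1L, seq_len(j - 1L)] &
                            spec$trans_mask[seq_len(j - 1L), j])
        if (isTRUE(entry)) { ends[t + 1L, j] <- TRUE; break }
      }
    }
    # mid-zone feasibility: some state could still be running at t
    mid <- FALSE
    for (j in seq_len(K)) {
      for (s in seq_len(t)) {
        entry <- if (s == 1) spec$initial[j] > 0 else
          any(ends[s, seq_len(max(j - 1L, 0L))] &
              spec$trans_mask[seq_len(max(j - 1L, 0L)), j])
        if (isTRUE(entry) && (t - s + 1) <= dmax[j] && emit_ok(j, s, t)) {
          mid <- TRUE; break
        }
      }
      if (mid) break
    }
    if (!mid && !any(ends[t + 1L, ])) return(best)
    best <- t
  }
  best
}

#' Most probable state path (explicit-duration Viterbi)
#'
#' Restores the state path maximizing the joint probability of states and
#' observations, with explicit zone durations.  Ties are resolved toward the
#' lowest state index, then the shorter zone duration, so decoding is
#' deterministic.
#'
#' @inheritParams log_likelihood
#' @return An object of class `decoded_path`: list with `states` (1-based
#'   state index per node), `state_names`, `log_joint`, and `shoot_id` when
#'   the input carries one.
#' @export
viterbi_decode <- function(spec, seq) {
  validate_hsmm(spec)
  obs <- .check_symbols(.seq_symbols(seq), spec)
  Tn <- length(obs)
  res <- .hsmm_viterbi_cpp(obs, .log_or_big(spec$initial),
                           .log_or_big(spec$transitions),
                           .log_dur_matrix(spec, Tn),
                           .log_or_big(spec$emission))
  if (length(res$states) == 0 || res$log_joint < BIG_NEG / 2) {
    bad <- .feasible_prefix(spec, obs)
    stop("sequence impossible under the model; first inconsistent node index ",
         bad, " (0-based)")
  }
  structure(list(states = res$states,
                 state_names = spec$state_names[res$states],
                 log_joint = res$log_joint,
                 shoot_id = if (inherits(seq, "branching_sequence"))
                   seq$shoot_id else NA_character_),
            class = "decoded_path")
}

#' @export
print.decoded_path <- function(x, ...) {
  cat("decoded_path", if (!is.na(x$shoot_id)) paste0("[", x$shoot_id, "]"),
      ":", paste(x$state_names, collapse = " "),
      " log-joint", format(x$log_joint, digits = 6), "\n")
  invisible(x)
}

#' Simulate bud-fate sequences from an HSMM
#'
#' Draws i.i.d. sequences: initial state from the initial distribution, zone
#' length from the state's occupancy, symbols i.i.d. from the state's emission
#' within the zone, then the next state from the transition row, until the
#' absorbing end state.
#'
#' @param spec An [hsmm_spec()].
#' @param n Number of sequences.
#' @param seed Integer seed; the draw is reproducible given `seed`.
#' @return List with `sequences` (list of integer symbol vectors, `0..5`) and
#'   `paths` (list of 1-based state indices per node).
#' @export
simulate_hsmm <- function(spec, n, seed = NULL) {
  validate_hsmm(spec)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- spec$n_transient
  sequences <- vector("list", n)
  paths <- vector("list", n)
  for (r in seq_len(n)) {
    j <- sample.int(K, 1, prob = spec$initial)
    sym <- integer(0); path <- integer(0)
    repeat {
      u <- rocc(1, spec$occupancy[[j]])
      sym <- c(sym, sample.int(spec$n_symbols, u, replace = TRUE,
                               prob = spec$emission[j, ]) - 1L)
      path <- c(path, rep(j, u))
      nxt <- sample.int(K + 1, 1, prob = spec$transitions[j, ])
      if (nxt == K + 1) break
      j <- nxt
    }
    sequences[[r]] <- sym
    paths[[r]] <- path
  }
  list(sequences = sequences, paths = paths)
}

#' Count the free parameters of a constrained HSMM
#'
#' Free parameters: initial vector (support size minus one, when the support
#' has more than one state), each transition row (allowed cells minus one),
#' each non-forced emission row (masked cells minus one) and the occupancy
#' parameters of every state.
#'
#' @param spec An [hsmm_spec()].
#' @return Integer count of free parameters.
#' @export
n_free_parameters <- function(spec) {
  K <- spec$n_transient
  k <- 0L
  if (sum(spec$initial > 0) > 1) k <- k + sum(spec$initial > 0) - 1L
  for (i in seq_len(K)) {
    k <- k + max(sum(spec$trans_mask[i, ]) - 1L, 0L)
    k <- k + max(sum(spec$emis_mask[i, ]) - 1L, 0L)
    k <- k + n_occ_params(spec$occupancy[[i]])
  }
  k
}
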