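#' State-occupancy distributions
#'
#' A zone's length in nodes is modelled by a discrete distribution on
#' \eqn{d \ge 1}: a distribution on non-negative counts shifted by one node,
#' or a point mass.  Supported families are the shifted Poisson, the shifted
#' negative binomial, the shifted binomial and the point mass.
#'
#' Parameterizations (all supports are \eqn{d \ge 1}):
#' \describe{
#'   \item{`"poisson"`}{`lambda`; \eqn{d - 1 \sim} Poisson(`lambda`), mean
#'     `1 + lambda`.}
#'   \item{`"nbinom"`}{`size`, `mu`; \eqn{d - 1 \sim} NB(`size`, `mu`), mean
#'     `1 + mu`.  `size` is the usual dispersion parameter (variance
#'     `mu + mu^2 / size`).}
#'   \item{`"binom"`}{`size`, `prob`; \eqn{d - 1 \sim} Binomial, mean
#'     `1 + size * prob`, support bounded at `1 + size`.}
#'   \item{`"point"`}{`at`; all mass on the single duration `at`.}
#' }
#'
#' @param family One of `"poisson"`, `"nbinom"`, `"binom"`, `"point"`.
#' @param ... Named family parameters (see Details).
#' @return An object of class `occupancy_dist`.
#' @examples
#' occ <- occupancy_dist("poisson", lambda = 4)
#' occ_mean(occ)
#' sum(docc(1:100, occ))
#' @export
occupancy_dist <- function(family = c("poisson", "nbinom", "binom", "point"),
                           ...) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    poisson = "lambda", nbinom = c("size", "mu"),
    binom = c("size", "prob"), point = "at")
  if (!all(need %in% names(params)))
    stop("occupancy family '", family, "' needs parameters: ",
         paste(need, collapse = ", "))
  params <- params[need]
  if (any(!vapply(params, is.finite, logical(1))))
    stop("occupancy parameters must be finite")
  if (family == "poisson" && params$lambda < 0)
    stop("lambda must be >= 0")
  if (family == "nbinom" && (params$size <= 0 || params$mu < 0))
    stop("size must be > 0 and mu >= 0")
  if (family == "binom" &&
      (params$size < 1 || params$prob < 0 || params$prob > 1))
    stop("size must be >= 1 and prob in [0, 1]")
  if (family == "point" && (params$at < 1 || params$at != round(params$at)))
    stop("point mass must sit on an integer duration >= 1")
  structure(list(family = family, params = params), class = "occupancy_dist")
}

#' @export
print.occupancy_dist <- function(x, ...) {
  cat("occupancy_dist:", x$family, "(",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
      ") mean", format(occ_mean(x), digits = 4), "\n")
  invisible(x)
}

#' Occupancy probability mass function
#'
#' @param d Integer durations (nodes), `d >= 1`.
#' @param occ An [occupancy_dist()].
#' @param log Return log probabilities?
#' @return Probability (or log probability) of each duration.
#' @export
docc <- function(d, occ, log = FALSE) {
  stopifnot(inherits(occ, "occupancy_dist"))
  p <- switch(occ$family,
    poisson = stats::dpois(d - 1, occ$params$lambda),
    nbinom  = stats::dnbinom(d - 1, size = occ$params$size, mu = occ$params$mu),
    binom   = stats::dbinom(d - 1, size = occ$params$size,
                            prob = occ$params$prob),
    point   = as.numeric(d == occ$params$at))
  p[d < 1] <- 0
  if (log) base::log(p) else p
}

#' Draw random zone lengths
#'
#' @param n Number of draws.
#' @inheritParams docc
#' @return Integer vector of durations `>= 1`.
#' @export
rocc <- function(n, occ) {
  stopifnot(inherits(occ, "occupancy_dist"))
  switch(occ$family,
    poisson = stats::rpois(n, occ$params$lambda) + 1L,
    nbinom  = stats::rnbinom(n, size = occ$params$size, mu = occ$params$mu) + 1L,
    binom   = stats::rbinom(n, size = occ$params$size,
                            prob = occ$params$prob) + 1L,
    point   = rep(as.integer(occ$params$at), n))
}

#' Mean zone length of an occupancy distribution
#' @inheritParams docc
#' @return The mean duration in nodes.
#' @export
occ_mean <- function(occ) {
  stopifnot(inherits(occ, "occupancy_dist"))
  switch(occ$family,
    poisson = 1 + occ$params$lambda,
    nbinom  = 1 + occ$params$mu,
    binom   = 1 + occ$params$size * occ$params$prob,
    point   = occ$params$at)
}

n_occ_params <- function(occ) {
  switch(occ$family, poisson = 1L, nbinom = 2L, binom = 2L, point = 1L)
}

#' Fit one occupancy family to (possibly weighted) durations
#'
#' Maximum-likelihood fit of a single family to durations `d >= 1`.  Weights
#' may be fractional (expected counts from an EM pass).
#'
#' @param durations Integer durations, all `>= 1`.
#' @param family Occupancy family to fit.
#' @param weights Optional non-negative weights, one per duration.
#' @return A list with elements `occ` (the fitted [occupancy_dist()]) and
#'   `loglik` (weighted log-likelihood).
#' @export
fit_occupancy <- function(durations,
                          family = c("poisson", "nbinom", "binom", "point"),
                          weights = NULL) {
  family <- match.arg(family)
  if (is.null(weights)) weights <- rep(1, length(durations))
  stopifnot(length(weights) == length(durations), all(weights >= 0),
            all(durations >= 1))
  keep <- weights > 0
  d <- durations[keep]; w <- weights[keep]
  if (length(d) == 0) stop("no positive-weight durations to fit")
  wm <- sum(w * d) / sum(w)          # weighted mean duration
  y <- d - 1                         # shifted scale

  occ <- switch(family,
    poisson = occupancy_dist("poisson", lambda = max(wm - 1, 1e-8)),
    point   = {
      tab <- tapply(w, d, sum)
      occupancy_dist("point", at = as.integer(names(tab)[which.max(tab)]))
    },
    binom = {
      # profile ML over the size parameter n >= max(y)
      nmin <- max(max(y), 1L)
      best <- NULL
      for (n in nmin:(nmin + 30L)) {
        p <- min(max(sum(w * y) / (sum(w) * n), 1e-8), 1 - 1e-8)
        ll <- sum(w * stats::dbinom(y, n, p, log = TRUE))
        if (is.null(best) || ll > best$ll + 1e-9)
          best <- list(n = n, p = p, ll = ll)
      }
      occupancy_dist("binom", size = best$n, prob = best$p)
    },
    nbinom = {
      mu <- max(wm - 1, 1e-8)
      nll <- function(ls) -sum(w * stats::dnbinom(y, size = exp(ls), mu = mu,
                                                  log = TRUE))
      opt <- stats::optimize(nll, interval = c(-7, 12))
      occupancy_dist("nbinom", size = exp(opt$minimum), mu = mu)
    })
  list(occ = occ,
       loglik = sum(w * docc(d, occ, log = TRUE)))
}

#' Select an occupancy family by BIC
#'
#' Fits each supported family by maximum likelihood and returns the one with
#' the lowest BIC; ties go to the family with fewer parameters.  A degenerate
#' sample (all durations equal) returns the point mass directly.
#'
#' @param durations Integer durations, all `>= 1`; at least 5 values.
#' @return The selected [occupancy_dist()], with attributes `"bic"` (named
#'   vector of BIC per candidate family) and `"family_table"`.
#' @examples
#' set.seed(1)
#' d <- rpois(200, 5) + 1
#' select_occupancy_family(d)$family
#' @export
select_occupancy_family <- function(durations) {
  stopifnot(length(durations) >= 5, all(durations >= 1),
            all(durations == round(durations)))
  if (length(unique(durations)) == 1L)
    return(occupancy_dist("point", at = durations[1]))
  fams <- c("point", "poisson", "binom", "nbinom")  # simpler families first
  fits <- lapply(fams, function(f) fit_occupancy(durations, f))
  k <- vapply(fits, function(f) n_occ_params(f$occ), integer(1))
  bic <- vapply(fits, function(f) -2 * f$loglik, numeric(1)) +
    k * log(length(durations))
  names(bic) <- fams
  # strict ordering: lower BIC wins; within 1e-9, the earlier (simpler) family
  best <- which.min(bic + seq_along(bic) * 1e-12)
  out <- fits[[best]]$occ
  attr(out, "bic") <- bic
  out
}
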