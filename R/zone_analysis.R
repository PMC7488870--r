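#' Extract branching zones from a decoded state path
#'
#' Maximal runs of equal state become zones.  Node indices are 0-based with
#' half-open spans `[start, end)`; zones are ordered, disjoint and cover the
#' whole sequence.
#'
#' @param path A `decoded_path` from [viterbi_decode()], or an integer vector
#'   of per-node states.
#' @param state_names Optional state labels (taken from the path if present).
#' @return A data.frame of class `zone_profile` with columns `state`
#'   (1-based index), `label`, `start`, `end`, `length`.
#' @export
extract_zones <- function(path, state_names = NULL) {
  states <- if (inherits(path, "decoded_path")) path$states else
    as.integer(path)
  if (is.null(state_names) && inherits(path, "decoded_path")) {
    r0 <- rle(path$states)
    state_names_full <- path$state_names[cumsum(r0$lengths)]
  }
  if (any(diff(states) < 0))
    stop("state path must be non-decreasing (left-to-right chain)")
  r <- rle(states)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  lab <- if (!is.null(state_names)) state_names[r$values]
         else if (inherits(path, "decoded_path")) state_names_full
         else paste0("S", r$values - 1)
  out <- data.frame(state = r$values, label = lab, start = start, end = end,
                    length = r$lengths, stringsAsFactors = FALSE)
  class(out) <- c("zone_profile", "data.frame")
  attr(out, "shoot_id") <- if (inherits(path, "decoded_path")) path$shoot_id
                           else NA_character_
  out
}

#' Zone occurrence probabilities per category group
#'
#' The occurrence probability of a state is the fraction of decoded shoots in
#' a group whose most-probable state path visits that state (presence in the
#' restored path; posterior state probabilities are not used).
#'
#' @param profiles List of `zone_profile` objects (see [extract_zones()]).
#' @param groups Character/factor vector assigning each profile to a group.
#' @param n_states Number of transient states of the underlying model.
#' @param state_names Optional state labels for the columns.
#' @return A data.frame with one row per group: `group`, `n`, and one
#'   occurrence column per state.
#' @export
occurrence_probabilities <- function(profiles, groups, n_states,
                                     state_names = NULL) {
  stopifnot(length(profiles) == length(groups), length(profiles) >= 1)
  if (is.null(state_names)) state_names <- paste0("S", seq_len(n_states) - 1)
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    visit <- vapply(seq_len(n_states), function(j)
      mean(vapply(profiles[idx], function(p) j %in% p$state, logical(1))),
      numeric(1))
    cbind(data.frame(group = g, n = length(idx), stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(visit, state_names))))
  }))
  rownames(out) <- NULL
  out
}

.sig_code <- function(p) {
  if (is.na(p)) NA_character_
  else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare zone lengths between two groups (negative binomial GLM)
#'
#' Fits a negative binomial GLM (log link) of zone length on the group
#' indicator and reports the Wald p-value of the group coefficient, with
#' significance codes `*` (p < 0.05) and `**` (p < 0.01).  When the NB fit
#' fails to converge, a Poisson GLM is used and flagged.  Comparisons where
#' either group has fewer than 3 zones return a no-test result.
#'
#' @param lengths_a,lengths_b Zone lengths (nodes) of the two groups.
#' @param group_names Labels for the two groups.
#' @return A list of class `zone_comparison`: `groups`, `n`, `means`,
#'   `statistic` (Wald z), `p_value`, `code`, `family` (`"nbinom"` or
#'   `"poisson"` fallback), `tested`.
#' @export
compare_zone_lengths <- function(lengths_a, lengths_b,
                                 group_names = c("A", "B")) {
  n <- c(length(lengths_a), length(lengths_b))
  out <- list(groups = group_names, n = n,
              means = c(mean(lengths_a), mean(lengths_b)),
              statistic = NA_real_, p_value = NA_real_, code = NA_character_,
              family = NA_character_, tested = FALSE)
  class(out) <- "zone_comparison"
  if (any(n < 3)) return(out)
  df <- data.frame(length = c(lengths_a, lengths_b),
                   group = factor(rep(group_names, n), levels = group_names))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(length ~ group, data = df)),
    error = function(e) NULL)
  fam <- "nbinom"
  if (is.null(fit) || !isTRUE(fit$converged)) {
    warning("negative binomial GLM did not converge; Poisson fallback used")
    fit <- stats::glm(length ~ group, family = stats::poisson(), data = df)
    fam <- "poisson"
  }
  co <- summary(fit)$coefficients
  out$statistic <- co[2, 3]
  out$p_value <- co[2, 4]
  out$code <- .sig_code(out$p_value)
  out$family <- fam
  out$tested <- TRUE
  out
}

#' @export
print.zone_comparison <- function(x, ...) {
  if (!x$tested) {
    cat("zone length", paste(x$groups, collapse = " vs "),
        ": not tested (n =", paste(x$n, collapse = ", "), ")\n")
  } else {
    cat("zone length", paste(x$groups, collapse = " vs "), ": means",
        paste(format(x$means, digits = 3), collapse = " / "),
        sprintf("; %s GLM Wald z = %.3f, p = %.4g [%s]\n",
                x$family, x$statistic, x$p_value, x$code))
  }
  invisible(x)
}

#' Compare lateral-type distributions between groups (Fisher's exact test)
#'
#' Exact test of independence on a `groups x symbols` contingency table of
#' lateral-type counts within one state.  All-zero columns are dropped.  For
#' tables with total count <= 200 the exact network algorithm is used; larger
#' tables switch to a Monte-Carlo exact test (100,000 draws, fixed seed) and
#' are flagged.
#'
#' @param counts Matrix of counts, rows = groups, columns = lateral types.
#' @param mc_draws Monte-Carlo replicates for large tables.
#' @param mc_seed Seed for the Monte-Carlo path (determinism).
#' @return A list: `p_value`, `method` (`"exact"` or `"monte-carlo"`),
#'   `code`, `table` (after column dropping).
#' @export
compare_lateral_distributions <- function(counts, mc_draws = 1e5,
                                          mc_seed = 20160430) {
  counts <- as.matrix(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2 || nrow(counts) < 2)
    stop("need at least a 2 x 2 table after dropping empty columns")
  if (sum(counts) <= 200) {
    p <- stats::fisher.test(counts)$p.value
    method <- "exact"
  } else {
    p <- withr_seed(mc_seed, stats::fisher.test(
      counts, simulate.p.value = TRUE, B = mc_draws)$p.value)
    method <- "monte-carlo"
  }
  list(p_value = p, method = method, code = .sig_code(p), table = counts)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Correlation between zone length and total shoot length
#'
#' Pearson correlation between a state's zone length (nodes) and the total
#' node count of the shoot, computed over the shoots that possess the state
#' (shoots lacking it are excluded).
#'
#' @param profiles List of `zone_profile` objects.
#' @param state 1-based state index of the zone of interest.
#' @param totals Optional total node counts per shoot; defaults to each
#'   profile's sequence length.
#' @return A list: `r`, `r_squared`, `n`, `p_value`; or a no-result with
#'   `reason` when fewer than 3 shoots have the zone or its length has zero
#'   variance.
#' @export
correlate_zone_vs_total <- function(profiles, state, totals = NULL) {
  if (is.null(totals))
    totals <- vapply(profiles, function(p) max(p$end), numeric(1))
  stopifnot(length(totals) == length(profiles))
  has <- vapply(profiles, function(p) state %in% p$state, logical(1))
  if (sum(has) < 3)
    return(list(r = NA_real_, r_squared = NA_real_, n = sum(has),
                p_value = NA_real_,
                reason = "fewer than 3 shoots possess the zone"))
  zl <- vapply(profiles[has], function(p) sum(p$length[p$state == state]),
               numeric(1))
  tt <- totals[has]
  if (stats::sd(zl) == 0 || stats::sd(tt) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, n = sum(has),
                p_value = NA_real_, reason = "zero variance"))
  ct <- stats::cor.test(zl, tt, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       n = sum(has), p_value = ct$p.value, reason = NA_character_)
}
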