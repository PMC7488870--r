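#' Choose a count-GLM family by Poisson goodness of fit
#'
#' Pearson chi-square goodness-of-fit test of the Poisson distribution on
#' binned counts (expected frequencies pooled so every bin has expected count
#' at least 5); rejection at the 0.05 level selects the negative binomial.
#'
#' @param counts Non-negative integer counts, `n >= 10`.
#' @return A list: `family` (`"poisson"` or `"nbinom"`), `statistic`, `df`,
#'   `p_value`.
#' @examples
#' set.seed(1)
#' select_count_family(rpois(300, 5))$family
#' @export
select_count_family <- function(counts) {
  stopifnot(length(counts) >= 10, all(counts >= 0),
            all(counts == round(counts)))
  n <- length(counts)
  lam <- mean(counts)
  if (stats::var(counts) == 0)  # degenerate variance: Poisson rejected path
    return(list(family = "poisson", statistic = 0, df = NA_integer_,
                p_value = 1))
  kmax <- max(counts)
  exp_p <- c(stats::dpois(0:kmax, lam), stats::ppois(kmax, lam,
                                                     lower.tail = FALSE))
  obs <- c(tabulate(counts + 1L, nbins = kmax + 1L), 0)
  # pool adjacent bins until every expected frequency is >= 5
  bins <- list(); cur_o <- 0; cur_e <- 0
  for (i in seq_along(exp_p)) {
    cur_o <- cur_o + obs[i]; cur_e <- cur_e + n * exp_p[i]
    if (cur_e >= 5) { bins[[length(bins) + 1]] <- c(cur_o, cur_e)
                      cur_o <- 0; cur_e <- 0 }
  }
  if (cur_e > 0 && length(bins))
    bins[[length(bins)]] <- bins[[length(bins)]] + c(cur_o, cur_e)
  m <- do.call(rbind, bins)
  df <- nrow(m) - 1L - 1L  # one estimated parameter (the mean)
  if (df < 1) return(list(family = "poisson", statistic = NA_real_,
                          df = df, p_value = NA_real_))
  stat <- sum((m[, 1] - m[, 2])^2 / m[, 2])
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(family = if (p < 0.05) "nbinom" else "poisson",
       statistic = stat, df = df, p_value = p)
}

#' Compare node numbers across shoot categories
#'
#' Count GLM of node number on the category factor (family chosen by
#' [select_count_family()] on the pooled counts), followed by all pairwise
#' contrasts with single-step (Tukey-style) multiplicity adjustment and a
#' compact letter display: groups sharing a letter are not significantly
#' different at the 0.05 level.  With two groups the procedure reduces to a
#' single Wald contrast.
#'
#' @param counts Integer node counts.
#' @param groups Factor/character of the same length assigning categories;
#'   at least 2 groups of at least 3 shoots each.
#' @param alpha Significance level for the letter display.
#' @return A list: `family`, `omnibus_p` (likelihood-ratio test of the
#'   category factor), `pairwise` (data.frame of contrasts, estimates and
#'   adjusted p-values), `letters` (named character vector).
#' @export
compare_node_numbers <- function(counts, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(counts) == length(groups), nlevels(groups) >= 2)
  if (any(table(groups) < 3)) stop("every group needs at least 3 shoots")
  fam <- select_count_family(counts)$family
  df <- data.frame(y = counts, g = groups)
  fit <- if (fam == "nbinom")
    suppressWarnings(MASS::glm.nb(y ~ g, data = df))
  else stats::glm(y ~ g, family = stats::poisson(), data = df)
  fit0 <- if (fam == "nbinom")
    suppressWarnings(MASS::glm.nb(y ~ 1, data = df))
  else stats::glm(y ~ 1, family = stats::poisson(), data = df)
  omni <- stats::anova(fit0, fit)
  omnibus_p <- if (fam == "nbinom")
    stats::pchisq(2 * (stats::logLik(fit) - stats::logLik(fit0)),
                  df = nlevels(groups) - 1, lower.tail = FALSE)
  else stats::pchisq(omni$Deviance[2], omni$Df[2], lower.tail = FALSE)
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  sm <- summary(glht_fit)  # single-step adjustment
  pw <- data.frame(contrast = names(sm$test$coefficients),
                   estimate = unname(sm$test$coefficients),
                   z = unname(sm$test$tstat),
                   p_adj = unname(sm$test$pvalues),
                   stringsAsFactors = FALSE)
  letters <- multcomp::cld(glht_fit, level = alpha)$mcletters$Letters
  list(family = fam, omnibus_p = as.numeric(omnibus_p), pairwise = pw,
       letters = letters)
}

# Dunn's post-hoc z-test on mean ranks after a Kruskal-Wallis test, with the
# usual tie correction; no installed package provides it, so it is written
# out here.
.dunn_test <- function(y, g, adjust = "holm") {
  g <- factor(g)
  r <- rank(y)
  N <- length(y)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  n <- table(g)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- if (se == 0) 0 else (mr[[a]] - mr[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(contrast = paste(pairs[1, ], pairs[2, ], sep = " - "),
             z = z, p_adj = stats::p.adjust(p, adjust),
             stringsAsFactors = FALSE)
}

#' Compare lateral counts across categories (nonparametric)
#'
#' Two groups: two-sided Mann-Whitney test (with continuity correction).
#' Three or more: Kruskal-Wallis omnibus test, followed, when significant at
#' 0.05, by Dunn's pairwise z-tests with Holm adjustment.  Constant data
#' across all groups returns p = 1 with no post hoc.
#'
#' @param counts Per-shoot lateral counts.
#' @param groups Factor/character of group assignments; every group needs at
#'   least 3 shoots.
#' @return A list: `test` (`"mann-whitney"` or `"kruskal-wallis"`),
#'   `statistic`, `p_value`, `pairwise` (Dunn table or `NULL`).
#' @export
compare_lateral_counts <- function(counts, groups) {
  groups <- factor(groups)
  stopifnot(length(counts) == length(groups), nlevels(groups) >= 2)
  if (any(table(groups) < 3)) stop("every group needs at least 3 shoots")
  if (stats::var(counts) == 0)
    return(list(test = if (nlevels(groups) == 2) "mann-whitney"
                else "kruskal-wallis",
                statistic = NA_real_, p_value = 1, pairwise = NULL))
  if (nlevels(groups) == 2) {
    sp <- split(counts, groups)
    wt <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]],
                                              correct = TRUE))
    return(list(test = "mann-whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value, pairwise = NULL))
  }
  kw <- stats::kruskal.test(counts, groups)
  pairwise <- if (kw$p.value < 0.05) .dunn_test(counts, groups) else NULL
  list(test = "kruskal-wallis", statistic = unname(kw$statistic),
       p_value = kw$p.value, pairwise = pairwise)
}

#' Compare lateral-type proportions across categories
#'
#' Test of independence on a `groups x lateral types` contingency table.
#' When any expected cell count is below 5 the exact route
#' ([compare_lateral_distributions()]) is taken and flagged; otherwise a
#' chi-square omnibus test is followed, when significant at 0.05, by pairwise
#' chi-square tests on the 2 x k sub-tables with Holm adjustment.
#'
#' @param counts Matrix of counts, rows = groups (named), columns = types.
#' @return A list: `method` (`"chi-square"`, `"fisher"` or `"monte-carlo"`),
#'   `statistic`, `p_value`, `code`, `pairwise` (or `NULL`), `flagged`.
#' @export
compare_lateral_proportions <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    ex <- compare_lateral_distributions(counts)
    return(list(method = if (ex$method == "exact") "fisher" else ex$method,
                statistic = NA_real_, p_value = ex$p_value, code = ex$code,
                pairwise = NULL, flagged = TRUE))
  }
  ch <- suppressWarnings(stats::chisq.test(counts))
  pairwise <- NULL
  if (ch$p.value < 0.05 && nrow(counts) > 2) {
    if (is.null(rownames(counts)))
      rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    pr <- utils::combn(rownames(counts), 2)
    p <- vapply(seq_len(ncol(pr)), function(k)
      suppressWarnings(stats::chisq.test(counts[pr[, k], ]))$p.value,
      numeric(1))
    pairwise <- data.frame(contrast = paste(pr[1, ], pr[2, ], sep = " - "),
                           p_adj = stats::p.adjust(p, "holm"),
                           stringsAsFactors = FALSE)
  }
  list(method = "chi-square", statistic = unname(ch$statistic),
       p_value = ch$p.value, code = .sig_code(ch$p.value),
       pairwise = pairwise, flagged = FALSE)
}

#' Per-shoot lateral-type count records
#'
#' Tabulates each sequence into counts per lateral type (latent, short
#' vegetative, long vegetative, short bourse, long bourse) plus the total
#' node number.  Bud-scar nodes (symbol 5) are counted in `total_nodes` but
#' belong to no lateral type.
#'
#' @param seqs List of [branching_sequence()] objects.
#' @return A data.frame with one row per shoot: `shoot_id`, `category`,
#'   counts `latent`, `veg_short`, `veg_long`, `bourse_short`, `bourse_long`,
#'   `scar`, and `total_nodes`.
#' @export
lateral_count_records <- function(seqs) {
  if (inherits(seqs, "sequence_set")) seqs <- seqs$sequences
  out <- do.call(rbind, lapply(seqs, function(s) {
    tab <- tabulate(s$symbols + 1L, nbins = 6L)
    data.frame(shoot_id = s$shoot_id,
               category = if (is.null(s$category)) NA_character_
                          else category_label(s$category),
               latent = tab[1], veg_short = tab[2], veg_long = tab[3],
               bourse_short = tab[4], bourse_long = tab[5], scar = tab[6],
               total_nodes = length(s$symbols),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
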