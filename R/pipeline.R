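#' Estimation template for the short/medium-duration model
#'
#' Structure of the 3+1-state chain used for monocyclic shoots with short or
#' medium growth duration: basal latent zone (S0, forced to latent buds),
#' diffuse floral zone (S1), acrotonic vegetative zone (S2), absorbing end.
#' All left-to-right transitions are allowed during estimation; S1 and S2 may
#' emit any lateral fate except the bud scar.
#'
#' @return An [hsmm_spec()] usable as the `template` of [fit_em()].
#' @export
model_a_template <- function() {
  hsmm_spec(
    initial = c(1, 0, 0),
    transitions = rbind(c(0, 0.4, 0.3, 0.3),
                        c(0, 0, 0.3, 0.7),
                        c(0, 0, 0, 1)),
    occupancy = list(occupancy_dist("poisson", lambda = 5),
                     occupancy_dist("nbinom", size = 2, mu = 5),
                     occupancy_dist("poisson", lambda = 2)),
    emission = rbind(c(1, 0, 0, 0, 0, 0),
                     c(0.4, 0.05, 0.05, 0.4, 0.1, 0),
                     c(0.3, 0.2, 0.3, 0.1, 0.1, 0)),
    emis_mask = rbind(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    state_names = c("S0", "S1", "S2"))
}

#' Estimation template for the long-duration / bicyclic model
#'
#' Structure of the 7+1-state chain shared by monocyclic long-duration shoots
#' and bicyclic shoots: basal latent zone (L0), diffuse floral zone (L1),
#' bud-scar cessation zone (L2, forced to symbol 5; traversed only by
#' bicyclic shoots — monocyclic long shoots bypass it), second-GU latent zone
#' (L3, forced latent), short-shoot zone (L4), floral zone (L5), acrotonic
#' vegetative zone (L6), absorbing end.  The allowed transitions are the
#' left-to-right skips consistent with that zonation (zones L1, L4, L5, L6
#' optional; the end state reachable only after L3).
#'
#' @return An [hsmm_spec()] usable as the `template` of [fit_em()].
#' @export
model_b_template <- function() {
  gt <- default_ground_truth()
  a_two <- gt$specs[["two-GUs"]]$transitions
  a_long <- gt$specs[["one-GU_long"]]$transitions
  mask <- (a_two > 0) | (a_long > 0)
  spec <- gt$specs[["two-GUs"]]
  # neutral starting values on the union support
  trans <- matrix(0, 7, 8)
  for (i in 1:7) trans[i, mask[i, ]] <- 1 / sum(mask[i, ])
  hsmm_spec(
    initial = c(1, rep(0, 6)),
    transitions = trans,
    occupancy = spec$occupancy,
    emission = spec$emission,
    trans_mask = mask,
    emis_mask = rbind(
      c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
      c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    state_names = .model_b_names)
}

#' Categorize shoots from growth records
#'
#' Applies [assemble_gu_spans()] and [classify_shoot()] to every series;
#' every shoot receives exactly one category or one logged exclusion reason.
#'
#' @param records A `growth_records` object or a list of [growth_series()].
#' @param cfg A [category_config()].
#' @return A data.frame: `shoot_id`, `category` (label or `NA`), `cyclicity`,
#'   `gd_class`, `gp_class` (comma-joined per GU), `excluded`, `reason`.
#' @export
categorize_shoots <- function(records, cfg = category_config()) {
  series <- if (inherits(records, "growth_records")) records$series
            else records
  out <- lapply(series, function(s) {
    sp <- assemble_gu_spans(s, cfg)
    if (sp$excluded)
      return(data.frame(shoot_id = s$shoot_id, category = NA_character_,
                        cyclicity = NA_character_, gd_class = NA_character_,
                        gp_class = NA_character_, excluded = TRUE,
                        reason = sp$reason, stringsAsFactors = FALSE))
    cat_ <- classify_shoot(sp, cfg)
    data.frame(shoot_id = s$shoot_id, category = category_label(cat_),
               cyclicity = cat_$cyclicity,
               gd_class = paste(cat_$gd_class, collapse = ","),
               gp_class = paste(cat_$gp_class, collapse = ","),
               excluded = FALSE, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.cohort_of <- function(cat_) {
  if (is.null(cat_)) return(NA_character_)
  if (cat_$cyclicity == "two-GUs") return("B")
  if (cat_$gd_class %in% c("short", "medium")) "A" else "B"
}

.broad_group <- function(cat_) {
  if (is.null(cat_)) return(NA_character_)
  if (cat_$cyclicity == "two-GUs") "two-GUs"
  else paste0("one-GU_", cat_$gd_class)
}

#' Run the full branching-pattern analysis
#'
#' Stages, in order: categorize shoots from growth records (skipped when
#' sequences already carry categories and no growth input is given); split
#' the sequences into the two model cohorts (monocyclic short+medium duration
#' versus monocyclic long + bicyclic — a single chain across all categories
#' segments poorly because distal branching differs with shoot length); fit
#' both hidden semi-Markov chains by EM; decode every sequence; zone
#' analyses (occurrence table, zone-length comparisons, lateral-type
#' comparisons, zone-length/shoot-length correlation); comparative statistics
#' on node numbers and lateral counts; write TSV tables, serialized models
#' and a text report.
#'
#' @param sequences A list of [branching_sequence()] objects, or a path to a
#'   sequence TSV.
#' @param growth Optional `growth_records`, list of [growth_series()], or a
#'   path to a growth CSV; when given, categories are (re)computed from it.
#' @param out_dir Output directory.
#' @param cfg A [category_config()].
#' @param em [em_settings()] for both model fits.
#' @param min_cohort Minimum sequences per cohort; a smaller cohort's model
#'   is skipped with a logged reason.
#' @return A list of class `pipeline_result`: `categories`, `fits` (A and/or
#'   B), `decoded`, `profiles`, `occurrence`, `zone_length_tests`,
#'   `lateral_tests`, `correlations`, `node_number_test`, `files`, `log`.
#' @export
run_pipeline <- function(sequences, growth = NULL, out_dir = tempfile("bz_"),
                         cfg = category_config(), em = em_settings(),
                         min_cohort = 5) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  if (is.character(sequences) && length(sequences) == 1)
    sequences <- read_sequences(sequences)
  if (is.character(growth) && length(growth) == 1)
    growth <- read_growth_records(growth)

  # stage: categorize
  if (!is.null(growth)) {
    cats <- categorize_shoots(growth, cfg)
    note("categorize: ", sum(!cats$excluded), " classified, ",
         sum(cats$excluded), " excluded")
    lookup <- cats[!cats$excluded, ]
    sequences <- lapply(sequences, function(s) {
      i <- match(s$shoot_id, lookup$shoot_id)
      if (!is.na(i))
        s$category <- structure(
          list(cyclicity = lookup$cyclicity[i],
               gd_class = strsplit(lookup$gd_class[i], ",")[[1]],
               gp_class = strsplit(lookup$gp_class[i], ",")[[1]]),
          class = "shoot_category")
      s
    })
  } else {
    cats <- NULL
    note("categorize: skipped (categories taken from the sequence input)")
  }
  has_cat <- vapply(sequences, function(s) !is.null(s$category), logical(1))
  if (!all(has_cat))
    note("dropped ", sum(!has_cat), " sequence(s) without a category")
  sequences <- sequences[has_cat]
  if (!length(sequences)) stop("no categorized sequences to analyze")

  # stage: cohort split and model fits
  cohort <- vapply(sequences, function(s) .cohort_of(s$category),
                   character(1))
  fits <- list()
  decoded <- list(); profiles <- list(); groups <- character(0)
  seq_of <- list()
  for (co in c("A", "B")) {
    idx <- which(cohort == co)
    if (length(idx) < min_cohort) {
      note("cohort ", co, ": only ", length(idx),
           " sequences; model skipped")
      next
    }
    template <- if (co == "A") model_a_template() else model_b_template()
    fit <- fit_em(sequences[idx], template, em)
    fits[[co]] <- fit
    note("cohort ", co, ": ", length(idx), " sequences; loglik ",
         format(fit$loglik, digits = 8), "; BIC ",
         format(fit$bic, digits = 8))
    for (i in idx) {
      dp <- viterbi_decode(fit$spec, sequences[[i]])
      decoded[[length(decoded) + 1]] <- dp
      profiles[[length(profiles) + 1]] <- extract_zones(dp)
      groups <- c(groups, .broad_group(sequences[[i]]$category))
      seq_of[[length(seq_of) + 1]] <- sequences[[i]]
    }
  }
  if (!length(profiles)) stop("no cohort reached the minimum size")

  # stage: zone analyses
  occ_tables <- list()
  zl_tests <- list()
  lat_tests <- list()
  correlations <- list()
  for (co in names(fits)) {
    spec <- fits[[co]]$spec
    in_co <- vapply(seq_of, function(s) .cohort_of(s$category) == co,
                    logical(1))
    occ_tables[[co]] <- occurrence_probabilities(
      profiles[in_co], groups[in_co], spec$n_transient, spec$state_names)
    gl <- unique(groups[in_co])
    if (length(gl) >= 2) {
      prs <- utils::combn(gl, 2)
      for (k in seq_len(ncol(prs))) {
        g1 <- prs[1, k]; g2 <- prs[2, k]
        for (st in seq_len(spec$n_transient)) {
          if (spec$state_names[st] == "L2") next  # scar zone not compared
          len1 <- unlist(lapply(profiles[in_co][groups[in_co] == g1],
                                function(p) p$length[p$state == st]))
          len2 <- unlist(lapply(profiles[in_co][groups[in_co] == g2],
                                function(p) p$length[p$state == st]))
          zl <- compare_zone_lengths(len1, len2, c(g1, g2))
          zl_tests[[paste(co, spec$state_names[st], g1, "vs", g2)]] <- zl
          # lateral-type mixtures within the state
          cnt <- rbind(
            tabulate(unlist(lapply(which(in_co & groups == g1), function(i)
              seq_of[[i]]$symbols[decoded[[i]]$states == st])) + 1L, 6L),
            tabulate(unlist(lapply(which(in_co & groups == g2), function(i)
              seq_of[[i]]$symbols[decoded[[i]]$states == st])) + 1L, 6L))
          rownames(cnt) <- c(g1, g2)
          cnt <- cnt[, 1:5]            # scar nodes excluded from mixtures
          if (all(rowSums(cnt) > 0) && sum(colSums(cnt) > 0) >= 2)
            lat_tests[[paste(co, spec$state_names[st], g1, "vs", g2)]] <-
              compare_lateral_distributions(cnt)
        }
      }
    }
    # diffuse floral zone vs total length
    floral <- match(if (co == "A") "S1" else "L1", spec$state_names)
    correlations[[co]] <- correlate_zone_vs_total(profiles[in_co], floral)
  }

  # stage: comparative statistics
  recs <- lateral_count_records(seq_of)
  recs$group <- groups
  node_test <- if (length(unique(groups)) >= 2 &&
                   all(table(groups) >= 3))
    compare_node_numbers(recs$total_nodes, recs$group) else NULL

  # stage: outputs
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(cats)) wtsv(cats, "categories.tsv")
  for (co in names(fits)) {
    wtsv(occ_tables[[co]], paste0("occurrence_", co, ".tsv"))
    p <- file.path(out_dir, paste0("model_", co, ".yaml"))
    write_hsmm(fits[[co]]$spec, p)
    files <- c(files, p)
  }
  if (length(zl_tests)) {
    zl_df <- do.call(rbind, lapply(names(zl_tests), function(nm) {
      x <- zl_tests[[nm]]
      data.frame(comparison = nm, n1 = x$n[1], n2 = x$n[2],
                 mean1 = x$means[1], mean2 = x$means[2],
                 p_value = x$p_value, code = ifelse(x$tested, x$code, "-"),
                 stringsAsFactors = FALSE)
    }))
    wtsv(zl_df, "zone_length_tests.tsv")
  }
  if (length(lat_tests)) {
    lat_df <- do.call(rbind, lapply(names(lat_tests), function(nm)
      data.frame(comparison = nm, p_value = lat_tests[[nm]]$p_value,
                 code = lat_tests[[nm]]$code,
                 method = lat_tests[[nm]]$method, stringsAsFactors = FALSE)))
    wtsv(lat_df, "lateral_type_tests.tsv")
  }
  wtsv(recs, "lateral_counts.tsv")
  p <- file.path(out_dir, "config.yaml")
  write_category_config(cfg, p)
  files <- c(files, p)
  report <- c("branchzones pipeline report", "", log, "",
              if (!is.null(node_test))
                c("node-number comparison letters:",
                  paste(" ", names(node_test$letters), "=",
                        node_test$letters)))
  writeLines(report, file.path(out_dir, "report.txt"))
  files <- c(files, file.path(out_dir, "report.txt"))

  structure(list(categories = cats, fits = fits, decoded = decoded,
                 profiles = profiles, groups = groups,
                 occurrence = occ_tables, zone_length_tests = zl_tests,
                 lateral_tests = lat_tests, correlations = correlations,
                 node_number_test = node_test, records = recs,
                 files = files, log = log, out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("branchzones pipeline:", length(x$decoded), "decoded shoots;",
      length(x$fits), "model(s) fitted\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}
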