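#' Configuration for shoot categorization
#'
#' Thresholds of the categorization rules: a growth cessation is declared when
#' the length gain over a trailing two-week window falls below
#' `cessation_delta_cm`; the starting date is when a shoot (or, for a second
#' growth unit, the length above the previous cessation level) reaches
#' `start_length_cm`; growth-duration classes and growth-period classes use
#' the remaining thresholds.
#'
#' @param cessation_delta_cm Minimum two-week gain (cm) below which growth is
#'   considered stopped.
#' @param cessation_window_days Length of the trailing window (days); the gain
#'   is computed against the nearest observation at least this many days
#'   earlier, which tolerates irregular weekly visits.
#' @param start_length_cm Length (cm) defining the starting date; also the
#'   regrowth needed to open a second growth unit.
#' @param gd_thresholds_one_gu_days Pair of growth-duration thresholds (days)
#'   splitting one-GU shoots into short / medium / long.
#' @param gd_threshold_two_gu_days Single threshold (days) splitting each GU
#'   of a two-GU shoot into short / long.
#' @param gp_threshold_first Date splitting early/late growth periods for
#'   one-GU shoots and first GUs.
#' @param gp_threshold_second Date splitting early/late growth periods for
#'   second GUs.
#' @param season_end Last date of the growing season (used by the simulator).
#' @return A list of class `category_config`.
#' @export
category_config <- function(cessation_delta_cm = 0.5,
                            cessation_window_days = 14,
                            start_length_cm = 5,
                            gd_thresholds_one_gu_days = c(30, 90),
                            gd_threshold_two_gu_days = 30,
                            gp_threshold_first = as.Date("2016-06-03"),
                            gp_threshold_second = as.Date("2016-07-18"),
                            season_end = as.Date("2016-10-31")) {
  stopifnot(cessation_delta_cm > 0, cessation_window_days > 0,
            start_length_cm > 0,
            length(gd_thresholds_one_gu_days) == 2,
            gd_thresholds_one_gu_days[1] < gd_thresholds_one_gu_days[2],
            gd_threshold_two_gu_days > 0)
  structure(list(cessation_delta_cm = cessation_delta_cm,
                 cessation_window_days = cessation_window_days,
                 start_length_cm = start_length_cm,
                 gd_thresholds_one_gu_days = gd_thresholds_one_gu_days,
                 gd_threshold_two_gu_days = gd_threshold_two_gu_days,
                 gp_threshold_first = as.Date(gp_threshold_first),
                 gp_threshold_second = as.Date(gp_threshold_second),
                 season_end = as.Date(season_end)),
            class = "category_config")
}

#' A single shoot's weekly growth series
#'
#' @param shoot_id Shoot identifier.
#' @param dates Observation dates (coercible to `Date`), strictly increasing.
#' @param lengths_cm Cumulative shoot length (cm), non-negative;
#'   non-decreasing within a 1 cm measurement tolerance.
#' @return An object of class `shoot_growth_series`.
#' @export
growth_series <- function(shoot_id, dates, lengths_cm) {
  dates <- as.Date(dates)
  lengths_cm <- as.numeric(lengths_cm)
  if (length(dates) != length(lengths_cm))
    stop("dates and lengths differ in length")
  if (length(dates) < 2) stop("a growth series needs at least 2 observations")
  if (anyNA(dates)) stop("unparseable date in series ", shoot_id)
  if (any(duplicated(dates)))
    stop("duplicated observation date in shoot ", shoot_id, ": ",
         dates[duplicated(dates)][1])
  o <- order(dates)
  dates <- dates[o]; lengths_cm <- lengths_cm[o]
  if (any(lengths_cm < 0)) stop("negative length in shoot ", shoot_id)
  shrink <- diff(lengths_cm)
  if (any(shrink < -1))
    stop("shoot ", shoot_id, " shrinks by more than 1 cm at ",
         dates[which(shrink < -1)[1] + 1])
  structure(list(shoot_id = as.character(shoot_id),
                 dates = dates, lengths_cm = lengths_cm),
            class = "shoot_growth_series")
}

#' Read weekly growth records from CSV
#'
#' Expects a UTF-8 CSV with header `shoot_id,date,length_cm` (ISO 8601
#' dates).  Rows violating the series invariants (unparseable date,
#' duplicated shoot/date pair, shrinkage beyond 1 cm) are rejected with their
#' line number; shoots left with fewer than 2 valid rows are dropped.
#'
#' @param path Path to the CSV file.
#' @return A list of class `growth_records`: `series` (named list of
#'   [growth_series()]) and `report` (rows read / rejected and per-row
#'   problems).
#' @export
read_growth_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("shoot_id", "date", "length_cm")
  if (!all(need %in% names(raw)))
    stop("growth CSV must have columns: ", paste(need, collapse = ", "),
         "; missing: ", paste(setdiff(need, names(raw)), collapse = ", "))
  n_read <- nrow(raw)
  problems <- data.frame(line = integer(0), reason = character(0))
  reject <- function(lines, reason) {
    problems <<- rbind(problems, data.frame(line = lines + 1L,  # header line
                                            reason = reason))
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(date))
  if (length(bad_date)) reject(bad_date, "unparseable date")
  len <- suppressWarnings(as.numeric(raw$length_cm))
  bad_len <- setdiff(which(is.na(len) | len < 0), bad_date)
  if (length(bad_len)) reject(bad_len, "invalid length")
  keep <- setdiff(seq_len(n_read), c(bad_date, bad_len))

  dup <- keep[duplicated(paste(raw$shoot_id[keep], date[keep]))]
  if (length(dup))
    reject(dup, paste0("duplicated (shoot,date): ", raw$shoot_id[dup], " ",
                       date[dup]))
  keep <- setdiff(keep, dup)

  series <- list()
  for (id in unique(raw$shoot_id[keep])) {
    rows <- keep[raw$shoot_id[keep] == id]
    rows <- rows[order(date[rows])]
    shrink_at <- which(diff(len[rows]) < -1)
    if (length(shrink_at)) {
      reject(rows[shrink_at + 1L], "length shrinks by more than 1 cm")
      rows <- setdiff(rows, rows[shrink_at + 1L])
    }
    if (length(rows) < 2) {
      if (length(rows)) reject(rows, "fewer than 2 valid observations")
      next
    }
    series[[id]] <- growth_series(id, date[rows], len[rows])
  }
  if (n_read == 0) warning("growth CSV contains a header only; no records")
  structure(list(series = series,
                 report = list(rows_read = n_read,
                               rows_rejected = nrow(problems),
                               problems = problems)),
            class = "growth_records")
}

#' Detect growth-cessation episodes
#'
#' An observation date qualifies as stagnating when the length gain relative
#' to the nearest observation at least `cessation_window_days` earlier is
#' below `cessation_delta_cm`.  Consecutive qualifying dates form an episode;
#' adjacent episodes are merged unless the later episode starts at a length at
#' least `start_length_cm` above the earlier episode's starting length (i.e.
#' the intervening regrowth itself qualifies as a new growth-unit start).
#' Each episode is reported by its earliest qualifying date.
#'
#' @param series A [growth_series()].
#' @param cfg A [category_config()].
#' @return A `Date` vector of cessation dates (possibly empty), or `NA` (a
#'   no-assessment result, distinct from "no cessation") when the series is
#'   shorter than the trailing window.
#' @export
detect_cessations <- function(series, cfg = category_config()) {
  stopifnot(inherits(series, "shoot_growth_series"),
            inherits(cfg, "category_config"))
  d <- series$dates; len <- series$lengths_cm
  span <- as.numeric(max(d) - min(d))
  if (span < cfg$cessation_window_days) return(as.Date(NA))
  qual <- logical(length(d))
  for (i in seq_along(d)) {
    ref <- which(d <= d[i] - cfg$cessation_window_days)
    if (!length(ref)) next
    ref <- max(ref)  # nearest observation >= window earlier
    qual[i] <- (len[i] - len[ref]) < cfg$cessation_delta_cm
  }
  if (!any(qual)) return(as.Date(character(0)))
  r <- rle(qual)
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$values)][r$values]
  # merge runs whose start length has not regrown by >= start_length_cm
  merged <- starts[1]
  for (s in starts[-1])
    if (len[s] - len[merged[length(merged)]] >= cfg$start_length_cm)
      merged <- c(merged, s)
  d[merged]
}

#' Starting date of a growth unit
#'
#' The first observation date at which the shoot length reaches
#' `start_length_cm`; for a second growth unit, the first date after the first
#' unit's cessation at which the length exceeds the cessation-date length by
#' `start_length_cm`.
#'
#' @param series A [growth_series()].
#' @param cfg A [category_config()].
#' @param after Optional cessation date of the previous growth unit; when
#'   given, the second-GU rule is applied.
#' @return A `Date`, or `NA` when the criterion is never reached
#'   (undefined-start result).
#' @export
compute_start_date <- function(series, cfg = category_config(), after = NULL) {
  stopifnot(inherits(series, "shoot_growth_series"))
  d <- series$dates; len <- series$lengths_cm
  if (is.null(after)) {
    hit <- which(len >= cfg$start_length_cm)
  } else {
    base <- len[max(which(d <= after))]
    hit <- which(d > after & len >= base + cfg$start_length_cm)
  }
  if (!length(hit)) return(as.Date(NA))
  d[min(hit)]
}

#' Growth-unit spans of a shoot
#'
#' Combines [detect_cessations()] and [compute_start_date()] into ordered,
#' non-overlapping growth-unit spans (at most two: the study's shoots are at
#' most bicyclic).  Shoots that never reach the start criterion, or whose
#' series cannot be assessed, yield an exclusion with a reason.
#'
#' @param series A [growth_series()].
#' @param cfg A [category_config()].
#' @return A list of class `gu_spans`: `spans` (data.frame with `index`,
#'   `start_date`, `cessation_date`, `gd_days`) or `NULL`, plus `excluded`
#'   and `reason`.
#' @export
assemble_gu_spans <- function(series, cfg = category_config()) {
  cess <- detect_cessations(series, cfg)
  if (length(cess) == 1 && is.na(cess))
    return(structure(list(spans = NULL, excluded = TRUE,
                          reason = "series shorter than assessment window"),
                     class = "gu_spans"))
  s1 <- compute_start_date(series, cfg)
  if (is.na(s1))
    return(structure(list(spans = NULL, excluded = TRUE,
                          reason = "never reached the start criterion"),
                     class = "gu_spans"))
  cess <- cess[cess >= s1]
  if (!length(cess))
    return(structure(list(spans = NULL, excluded = TRUE,
                          reason = "no growth cessation observed"),
                     class = "gu_spans"))
  c1 <- cess[1]
  spans <- data.frame(index = 1L, start_date = s1, cessation_date = c1,
                      gd_days = as.numeric(c1 - s1))
  s2 <- compute_start_date(series, cfg, after = c1)
  if (!is.na(s2)) {
    c2 <- cess[cess > s2]
    if (length(c2)) {
      spans <- rbind(spans,
                     data.frame(index = 2L, start_date = s2,
                                cessation_date = c2[1],
                                gd_days = as.numeric(c2[1] - s2)))
    }
  }
  structure(list(spans = spans, excluded = FALSE, reason = NA_character_),
            class = "gu_spans")
}

#' Classify a shoot from its growth-unit spans
#'
#' One span makes a one-GU (monocyclic) shoot, two spans a two-GU (bicyclic)
#' shoot.  Growth duration (GD) classes: one-GU shoots are short
#' (`GD < 30` days), medium (`30 <= GD <= 90`) or long (`GD > 90`); each GU of
#' a two-GU shoot is short (`GD < 30`) or long otherwise.  Growth period (GP)
#' is early when the start date falls on or before the calendar threshold
#' (first threshold for one-GU shoots and first GUs, second threshold for
#' second GUs), late otherwise.
#'
#' @param spans A `gu_spans` object or its `spans` data.frame (1 or 2 rows).
#' @param cfg A [category_config()].
#' @return A list of class `shoot_category`: `cyclicity` (`"one-GU"` or
#'   `"two-GUs"`), `gd_class` and `gp_class` (one entry per GU).
#' @export
classify_shoot <- function(spans, cfg = category_config()) {
  if (inherits(spans, "gu_spans")) {
    if (isTRUE(spans$excluded))
      stop("cannot classify an excluded shoot: ", spans$reason)
    spans <- spans$spans
  }
  spans <- as.data.frame(spans)
  n <- nrow(spans)
  if (n < 1 || n > 2)
    stop("a shoot has 1 or 2 growth units; got ", n, " spans")
  if (any(spans$gd_days < 0)) stop("negative growth duration")
  if (n == 2 && spans$start_date[2] <= spans$cessation_date[1])
    stop("growth-unit spans overlap")
  th1 <- cfg$gd_thresholds_one_gu_days
  if (n == 1) {
    gd <- spans$gd_days[1]
    gd_class <- if (gd < th1[1]) "short" else if (gd <= th1[2]) "medium"
                else "long"
    gp_class <- if (spans$start_date[1] <= cfg$gp_threshold_first) "early"
                else "late"
    cyc <- "one-GU"
  } else {
    gd_class <- ifelse(spans$gd_days < cfg$gd_threshold_two_gu_days,
                       "short", "long")
    thr <- c(cfg$gp_threshold_first, cfg$gp_threshold_second)
    gp_class <- ifelse(spans$start_date <= thr[spans$index], "early", "late")
    cyc <- "two-GUs"
  }
  structure(list(cyclicity = cyc, gd_class = gd_class, gp_class = gp_class),
            class = "shoot_category")
}

#' @export
print.shoot_category <- function(x, ...) {
  cat(category_label(x), "\n")
  invisible(x)
}

#' Compact label for a shoot category
#'
#' @param category A `shoot_category`.
#' @param gu Optional GU index (1 or 2) to label a single growth unit of a
#'   two-GU shoot.
#' @return A string such as `"one-GU_short_early"` or `"two-GUs_GU1-short"`.
#' @export
category_label <- function(category, gu = NULL) {
  stopifnot(inherits(category, "shoot_category"))
  if (category$cyclicity == "one-GU")
    return(paste("one-GU", category$gd_class, category$gp_class, sep = "_"))
  if (is.null(gu))
    return(paste0("two-GUs_GU1-", category$gd_class[1], "-",
                  category$gp_class[1], "_GU2-", category$gd_class[2], "-",
                  category$gp_class[2]))
  paste0("two-GUs_GU", gu, "-", category$gd_class[gu], "-",
         category$gp_class[gu])
}

#' A bud-fate sequence with category metadata
#'
#' Symbols code lateral bud fates base-to-tip: 0 latent bud, 1 short
#' vegetative shoot (< 5 cm), 2 long vegetative shoot (>= 5 cm), 3 bourse
#' with short bourse shoot (a bourse with no bourse shoot is coded 3; of two
#' bourse shoots only the longer is recorded, at data entry), 4 bourse with
#' long bourse shoot, 5 bud scar / cessation marker.  Symbol 5 may appear
#' only in two-GU sequences and only as a single contiguous run.
#'
#' @param shoot_id Identifier.
#' @param symbols Integer vector in `0..5`, length >= 1.
#' @param category Optional `shoot_category`.
#' @return An object of class `branching_sequence`.
#' @export
branching_sequence <- function(shoot_id, symbols, category = NULL) {
  symbols <- as.integer(symbols)
  if (length(symbols) < 1) stop("empty symbol sequence for ", shoot_id)
  bad <- which(symbols < 0 | symbols > 5)
  if (length(bad))
    stop("invalid symbol ", symbols[bad[1]], " at node index ", bad[1] - 1,
         " in shoot ", shoot_id)
  runs <- rle(symbols == 5L)
  if (sum(runs$values) > 1)
    stop("bud-scar symbol 5 must form one contiguous run (shoot ",
         shoot_id, ")")
  if (!is.null(category)) {
    stopifnot(inherits(category, "shoot_category"))
    if (any(symbols == 5L) && category$cyclicity != "two-GUs")
      stop("bud scars are only valid in two-GU sequences (shoot ",
           shoot_id, ")")
  }
  structure(list(shoot_id = as.character(shoot_id), symbols = symbols,
                 category = category),
            class = "branching_sequence")
}

#' Write bud-fate sequences to TSV
#'
#' One line per shoot: `shoot_id`, `cyclicity`, comma-joined `gd_class` and
#' `gp_class` (one entry per GU), and the symbols space-separated base-to-tip.
#' Round-trips losslessly with [read_sequences()].
#'
#' @param seqs A list of [branching_sequence()] objects (or a `sequence_set`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  if (inherits(seqs, "sequence_set")) seqs <- seqs$sequences
  rows <- vapply(seqs, function(s) {
    stopifnot(inherits(s, "branching_sequence"))
    cat_ <- s$category
    paste(s$shoot_id,
          if (is.null(cat_)) "NA" else cat_$cyclicity,
          if (is.null(cat_)) "NA" else paste(cat_$gd_class, collapse = ","),
          if (is.null(cat_)) "NA" else paste(cat_$gp_class, collapse = ","),
          paste(s$symbols, collapse = " "),
          sep = "\t")
  }, character(1))
  writeLines(c("shoot_id\tcyclicity\tgd_class\tgp_class\tsymbols", rows),
             con = path)
  invisible(path)
}

#' Read bud-fate sequences from TSV
#'
#' @param path Path written by [write_sequences()].
#' @return A list of [branching_sequence()] objects.
#' @export
read_sequences <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("shoot_id", "cyclicity", "gd_class", "gp_class", "symbols")
  if (!all(need %in% names(tab)))
    stop("sequence TSV must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    cat_ <- if (tab$cyclicity[i] == "NA") NULL else
      structure(list(cyclicity = tab$cyclicity[i],
                     gd_class = strsplit(tab$gd_class[i], ",")[[1]],
                     gp_class = strsplit(tab$gp_class[i], ",")[[1]]),
                class = "shoot_category")
    branching_sequence(tab$shoot_id[i],
                       as.integer(strsplit(tab$symbols[i], " ")[[1]]),
                       cat_)
  })
}
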