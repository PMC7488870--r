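# Structured-text (YAML) serialization for configs, models and ground truth.
# Probabilities and parameters are written as decimal strings with 12
# significant digits so that write -> read -> write is byte-identical.

.fmt12 <- function(x) formatC(as.numeric(x), digits = 12, format = "g")

.hsmm_to_list <- function(spec) {
  list(
    states = as.list(spec$state_names),
    initial = as.list(.fmt12(spec$initial)),
    transitions = lapply(seq_len(nrow(spec$transitions)), function(i)
      as.list(.fmt12(spec$transitions[i, ]))),
    occupancy = lapply(spec$occupancy, function(o)
      list(family = o$family,
           params = lapply(o$params, .fmt12))),
    emission = lapply(seq_len(nrow(spec$emission)), function(i)
      as.list(.fmt12(spec$emission[i, ]))),
    trans_mask = lapply(seq_len(nrow(spec$trans_mask)), function(i)
      as.list(spec$trans_mask[i, ])),
    emis_mask = lapply(seq_len(nrow(spec$emis_mask)), function(i)
      as.list(spec$emis_mask[i, ])))
}

.hsmm_from_list <- function(x) {
  K <- length(x$states)
  num <- function(v) as.numeric(unlist(v))
  occ <- lapply(x$occupancy, function(o)
    do.call(occupancy_dist, c(list(family = o$family),
                              lapply(o$params, as.numeric))))
  hsmm_spec(
    initial = num(x$initial),
    transitions = do.call(rbind, lapply(x$transitions, num)),
    occupancy = occ,
    emission = do.call(rbind, lapply(x$emission, num)),
    trans_mask = do.call(rbind, lapply(x$trans_mask,
                                       function(r) unlist(r))),
    emis_mask = do.call(rbind, lapply(x$emis_mask, function(r) unlist(r))),
    state_names = unlist(x$states))
}

#' Write / read a hidden semi-Markov chain model as structured text
#'
#' YAML with explicit probability tables; numeric values are decimal strings
#' with 12 significant digits, so the file round-trips byte-identically.
#'
#' @param spec An [hsmm_spec()].
#' @param path File path.
#' @return `write_hsmm`: `path` invisibly; `read_hsmm`: the [hsmm_spec()].
#' @export
write_hsmm <- function(spec, path) {
  validate_hsmm(spec)
  yaml::write_yaml(.hsmm_to_list(spec), path)
  invisible(path)
}

#' @rdname write_hsmm
#' @export
read_hsmm <- function(path) .hsmm_from_list(yaml::read_yaml(path))

#' Write / read a categorization configuration
#'
#' @param cfg A [category_config()].
#' @param path File path.
#' @return `write_category_config`: `path` invisibly;
#'   `read_category_config`: the [category_config()].
#' @export
write_category_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "category_config"))
  x <- lapply(unclass(cfg), function(v)
    if (inherits(v, "Date")) format(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_category_config
#' @export
read_category_config <- function(path) {
  x <- yaml::read_yaml(path)
  category_config(
    cessation_delta_cm = x$cessation_delta_cm,
    cessation_window_days = x$cessation_window_days,
    start_length_cm = x$start_length_cm,
    gd_thresholds_one_gu_days = unlist(x$gd_thresholds_one_gu_days),
    gd_threshold_two_gu_days = x$gd_threshold_two_gu_days,
    gp_threshold_first = as.Date(x$gp_threshold_first),
    gp_threshold_second = as.Date(x$gp_threshold_second),
    season_end = as.Date(x$season_end))
}

#' Write / read a synthetic-study ground truth
#'
#' Serializes the category mix, growth parameters and per-category generating
#' models, together with the provenance annotations separating
#' literature-derived values from package defaults.
#'
#' @param gt A `ground_truth` (see [default_ground_truth()]).
#' @param path File path.
#' @return `write_ground_truth`: `path` invisibly; `read_ground_truth`: the
#'   `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  x <- list(
    mix = lapply(gt$mix, function(v) as.list(stats::setNames(.fmt12(v),
                                                             names(v)))),
    growth = gt$growth,
    specs = lapply(gt$specs, .hsmm_to_list),
    provenance = gt$provenance)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  mix <- lapply(x$mix, function(v)
    stats::setNames(as.numeric(unlist(v)), names(v)))
  growth <- x$growth
  growth$gd <- lapply(growth$gd, unlist)
  growth$rate_cm_day <- unlist(growth$rate_cm_day)
  structure(list(mix = mix, growth = growth,
                 specs = lapply(x$specs, .hsmm_from_list),
                 provenance = x$provenance),
            class = "ground_truth")
}
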