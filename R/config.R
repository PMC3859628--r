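# Run-wide configuration: provider options plus the evidence-combination
# settings, loadable from a YAML or JSON file.

#' Substantiation run configuration
#'
#' Bundles the tunables of a full run: the literature matching rule, the
#' co-occurrence significance level and Yates-correction switch, the
#' target-provider scoring mode, and the [combination_config()] (provider
#' weights, score-to-mass mode, tier thresholds, Y/N evidence cutoff).
#'
#' @param match_rule A [match_rule()].
#' @param alpha Co-occurrence significance level, default 0.05.
#' @param yates_correction Apply Yates' continuity correction? Default off.
#' @param target_mode,target_k See [score_intersection()].
#' @param combination A [combination_config()].
#' @return An object of class `substantiation_config`.
#' @export
substantiation_config <- function(match_rule = adrsub::match_rule(),
                                  alpha = 0.05,
                                  yates_correction = FALSE,
                                  target_mode = "binary",
                                  target_k = 1,
                                  combination = combination_config()) {
  if (!inherits(match_rule, "match_rule")) {
    abort_config("match_rule must be a match_rule object")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort_config("alpha must lie strictly between 0 and 1")
  }
  if (!inherits(combination, "combination_config")) {
    abort_config("combination must be a combination_config object")
  }
  structure(list(match_rule = match_rule, alpha = alpha,
                 yates_correction = isTRUE(yates_correction),
                 target_mode = target_mode, target_k = target_k,
                 combination = combination),
            class = "substantiation_config")
}

#' Read a substantiation configuration file
#'
#' Accepts YAML or JSON with any subset of the keys: `weights` (map
#' provider id to weight), `tier_thresholds` (`moderate`, `high`),
#' `evidence_cutoff`, `mass_mode`, `alpha`, `yates_correction`,
#' `match_mode`, `use_pharmacological_action`, `target_mode`, `target_k`.
#' Omitted keys keep their defaults.
#'
#' @param path Config file (`.yml`, `.yaml` or `.json`).
#' @return A [substantiation_config()].
#' @export
read_substantiation_config <- function(path) {
  if (!file.exists(path)) abort_not_found(sprintf("no such file: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  thresholds <- c(M = 0.3, H = 0.7)
  if (!is.null(raw$tier_thresholds)) {
    tt <- raw$tier_thresholds
    if (!is.null(tt$moderate)) thresholds[["M"]] <- as.numeric(tt$moderate)
    if (!is.null(tt$high)) thresholds[["H"]] <- as.numeric(tt$high)
  }
  weights <- numeric(0)
  if (!is.null(raw$weights)) {
    weights <- unlist(raw$weights)
    storage.mode(weights) <- "double"
  }
  substantiation_config(
    match_rule = match_rule(
      mode = raw$match_mode %||% "either",
      use_pharmacological_action = isTRUE(raw$use_pharmacological_action)),
    alpha = raw$alpha %||% 0.05,
    yates_correction = isTRUE(raw$yates_correction),
    target_mode = raw$target_mode %||% "binary",
    target_k = raw$target_k %||% 1,
    combination = combination_config(
      weights = weights,
      mode = raw$mass_mode %||% "one_sided",
      tier_thresholds = thresholds,
      evidence_cutoff = raw$evidence_cutoff %||% 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
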