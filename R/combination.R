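# Dempster-Shafer evidence combination over the binary frame
# {A, notA}, A = "true drug-event association". Each provider score is
# mapped to a basic mass assignment, the assignments are fused with
# Dempster's rule, and the combined belief in A is thresholded into a
# Low / Moderate / High risk tier.

MASS_TOL <- 1e-9

#' Basic mass assignment on the binary frame
#'
#' Masses on the focal sets \{A\}, \{notA\} and the whole frame, summing
#' to 1 within `1e-9`; no mass on the empty set.
#'
#' @param m_a,m_nota,m_omega Non-negative masses.
#' @return An object of class `mass_function`.
#' @export
mass_function <- function(m_a, m_nota = 0, m_omega = 1 - m_a - m_nota) {
  m <- c(m_a, m_nota, m_omega)
  if (!is.numeric(m) || length(m) != 3L || anyNA(m) || any(m < -MASS_TOL)) {
    abort_validation("masses must be non-negative numbers")
  }
  if (abs(sum(m) - 1) > MASS_TOL) {
    abort_validation("masses must sum to 1")
  }
  m <- pmax(m, 0)
  structure(list(m_a = m[1], m_nota = m[2], m_omega = m[3]),
            class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat(sprintf("<mass> m(A)=%.4f m(notA)=%.4f m(Omega)=%.4f\n",
              x$m_a, x$m_nota, x$m_omega))
  invisible(x)
}

#' Map a provider score to a mass function
#'
#' One-sided mode (the default) treats a score as positive evidence only:
#' `m(A) = w * s`, the rest stays on the frame (a zero score is ignorance,
#' not refutation, since providers return 0 when no matches are found).
#' Two-sided mode also reads the complement as evidence against:
#' `m(A) = w * s`, `m(notA) = w * (1 - s)`, `m(Omega) = 1 - w`. The weight
#' `w` is a reliability discount in \[0,1\].
#'
#' @param s Score in \[0,1\].
#' @param w Provider weight (reliability discount) in \[0,1\].
#' @param mode `"one_sided"` or `"two_sided"`.
#' @return A [mass_function()].
#' @export
mass_from_score <- function(s, w = 1, mode = c("one_sided", "two_sided")) {
  mode <- match.arg(mode)
  s <- as.numeric(s)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    abort_config("weight must be a single number in [0,1]")
  }
  if (is.na(s) || s < 0 || s > 1) {
    abort_validation("score must lie in [0,1]")
  }
  if (mode == "one_sided") {
    mass_function(w * s, 0, 1 - w * s)
  } else {
    mass_function(w * s, w * (1 - s), 1 - w)
  }
}

#' Combine two mass functions with Dempster's rule
#'
#' On the binary frame the conflict is
#' `K = m1(A) m2(notA) + m1(notA) m2(A)`; each combined focal mass is the
#' sum of products of intersecting focal sets, renormalized by `1 - K`.
#' Total conflict (`K = 1`) leaves the combination undefined.
#'
#' @param m1,m2 [mass_function()] objects.
#' @return The combined [mass_function()].
#' @examples
#' dempster_combine(mass_from_score(0.6), mass_from_score(0.5))
#' @export
dempster_combine <- function(m1, m2) {
  if (!inherits(m1, "mass_function") || !inherits(m2, "mass_function")) {
    abort_validation("both arguments must be mass functions")
  }
  K <- m1$m_a * m2$m_nota + m1$m_nota * m2$m_a
  if (1 - K <= MASS_TOL) {
    abort_conflict("total conflict (K = 1): combination undefined")
  }
  a <- m1$m_a * m2$m_a + m1$m_a * m2$m_omega + m1$m_omega * m2$m_a
  na <- m1$m_nota * m2$m_nota + m1$m_nota * m2$m_omega + m1$m_omega * m2$m_nota
  om <- m1$m_omega * m2$m_omega
  mass_function(a / (1 - K), na / (1 - K), om / (1 - K))
}

#' Classify a belief value into a risk tier
#'
#' `H` (high) when belief is at least the high threshold, `M` (moderate)
#' when at least the moderate threshold, else `L` (low). Boundaries are
#' inclusive upwards.
#'
#' @param belief Belief in \[0,1\].
#' @param thresholds Numeric vector `c(M = t_M, H = t_H)` with
#'   `0 <= t_M < t_H <= 1`.
#' @return `"L"`, `"M"` or `"H"`.
#' @export
classify_belief <- function(belief, thresholds = c(M = 0.3, H = 0.7)) {
  if (!is.numeric(belief) || length(belief) != 1L || is.na(belief) ||
      belief < 0 || belief > 1) {
    abort_validation("belief must be a single number in [0,1]")
  }
  check_thresholds(thresholds)
  if (belief >= thresholds[["H"]]) "H"
  else if (belief >= thresholds[["M"]]) "M"
  else "L"
}

check_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) != 2L ||
      !all(c("M", "H") %in% names(thresholds)) ||
      thresholds[["M"]] < 0 || thresholds[["H"]] > 1 ||
      thresholds[["M"]] >= thresholds[["H"]]) {
    abort_config("tier thresholds must satisfy 0 <= t_M < t_H <= 1")
  }
  invisible(thresholds)
}

#' Evidence-combination configuration
#'
#' @param weights Named numeric vector of provider weights in \[0,1\];
#'   providers absent from it default to weight 1 with a warning at
#'   combination time.
#' @param mode Score-to-mass mapping mode, see [mass_from_score()].
#' @param tier_thresholds `c(M =, H =)` belief thresholds for the
#'   Low/Moderate/High verdict.
#' @param evidence_cutoff Per-provider score cutoff for the Y/N
#'   sufficient-evidence flag.
#' @return An object of class `combination_config`.
#' @export
combination_config <- function(weights = numeric(0),
                               mode = c("one_sided", "two_sided"),
                               tier_thresholds = c(M = 0.3, H = 0.7),
                               evidence_cutoff = 0.5) {
  mode <- match.arg(mode)
  if (length(weights)) {
    if (is.null(names(weights)) || any(!nzchar(names(weights))) ||
        any(weights < 0 | weights > 1)) {
      abort_config("weights must be a named vector with values in [0,1]")
    }
  }
  check_thresholds(tier_thresholds)
  if (!is.numeric(evidence_cutoff) || evidence_cutoff < 0 ||
      evidence_cutoff > 1) {
    abort_config("evidence cutoff must lie in [0,1]")
  }
  structure(list(weights = weights, mode = mode,
                 tier_thresholds = tier_thresholds,
                 evidence_cutoff = evidence_cutoff),
            class = "combination_config")
}

#' Combine per-provider scores into a risk verdict
#'
#' Maps every provider score to a mass function (see [mass_from_score()]),
#' folds them with [dempster_combine()] in provider-id order (the result
#' is order-independent up to numerical tolerance), and reads off
#' belief `= m(A)`, plausibility `= m(A) + m(Omega)`, the L/M/H tier, and
#' a Y/N sufficient-evidence flag per provider.
#'
#' @param scores Named numeric vector or list, provider id to score.
#' @param config A [combination_config()].
#' @return An object of class `risk_verdict` with fields `belief`,
#'   `plausibility`, `tier`, `per_provider_flags`, `mass`.
#' @examples
#' combine_all(c(literature = 1, cooccurrence = 0.5, targets = 1))
#' @export
combine_all <- function(scores, config = combination_config()) {
  scores <- unlist(scores)
  if (!length(scores)) abort_validation("at least one provider score required")
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    abort_validation("scores must be named by provider id")
  }
  ids <- sort(names(scores))
  missing_w <- setdiff(ids, names(config$weights))
  if (length(missing_w) && length(config$weights)) {
    warning(sprintf("no weight configured for provider(s) %s; using 1.0",
                    paste(missing_w, collapse = ", ")), call. = FALSE)
  }
  weight_of <- function(id) {
    if (id %in% names(config$weights)) config$weights[[id]] else 1.0
  }
  combined <- NULL
  for (id in ids) {
    m <- mass_from_score(scores[[id]], weight_of(id), config$mode)
    combined <- if (is.null(combined)) m else dempster_combine(combined, m)
  }
  belief <- combined$m_a
  plausibility <- combined$m_a + combined$m_omega
  flags <- vapply(ids, function(id)
    if (scores[[id]] >= config$evidence_cutoff) "Y" else "N", character(1))
  structure(list(belief = belief, plausibility = plausibility,
                 tier = classify_belief(belief, config$tier_thresholds),
                 per_provider_flags = flags, mass = combined),
            class = "risk_verdict")
}

#' @export
print.risk_verdict <- function(x, ...) {
  cat(sprintf("<risk_verdict %s> belief %.4f, plausibility %.4f [%s]\n",
              x$tier, x$belief, x$plausibility,
              paste(sprintf("%s:%s", names(x$per_provider_flags),
                            x$per_provider_flags), collapse = " ")))
  invisible(x)
}
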