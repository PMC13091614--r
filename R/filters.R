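#' Phred-scaled genotype quality
#'
#' `Q = -10 * log10(P)` where `P = 1 - max(p)` is the probability the
#' called genotype is wrong. Saturated posteriors (error probability below
#' `10^(-cap/10)`, including exactly 0) are capped at `cap`.
#'
#' @param p_max numeric vector of maximum posterior probabilities (or an
#'   n x 3 posterior matrix / data.frame with columns `p_AA`, `p_AB`,
#'   `p_BB`, from which the row maximum is taken after a simplex check).
#' @param cap quality cap, default 99.
#' @return numeric vector of Phred qualities in `[0, cap]`.
#' @export
phredQuality <- function(p_max, cap = 99) {
  if (is.data.frame(p_max)) p_max <- as.matrix(p_max[c("p_AA", "p_AB", "p_BB")])
  if (is.matrix(p_max)) {
    if (any(p_max < -1e-9 | p_max > 1 + 1e-9) ||
        any(abs(rowSums(p_max) - 1) > 1e-6))
      stop("posterior rows must be probability simplices")
    p_max <- apply(p_max, 1, max)
  }
  if (any(p_max < -1e-9 | p_max > 1 + 1e-9)) stop("probabilities must lie in [0, 1]")
  p_err <- pmax(1 - p_max, 0)
  pmin(-10 * log10(pmax(p_err, 10^(-cap / 10 - 1e-12))), cap)
}

#' Retain calls at or above a Phred quality threshold
#'
#' `>=` semantics: a threshold of 0 retains everything, and retained sets
#' are nested across increasing thresholds.
#'
#' @param calls data.frame with a `q` column (from [predictProba()]).
#' @param threshold non-negative Phred threshold (the study grid is
#'   0/10/20/30).
#' @return the retained subset of `calls`.
#' @export
phredFilter <- function(calls, threshold) {
  stopifnot(is.numeric(threshold), threshold >= 0)
  calls[calls$q >= threshold, , drop = FALSE]
}

#' Rank-matched GenCall call set
#'
#' GenCall scores are not probabilities, so platform calls cannot be
#' filtered at a Phred threshold directly. Instead, for a classifier call
#' set of size `k` surviving a quality filter, the comparable platform set
#' is the `k` platform calls with the highest GenCall scores — equal
#' cardinality, matched by rank. Boundary ties are broken by lexicographic
#' `snp_id` (deterministic).
#'
#' @param k size of the classifier's retained set.
#' @param platform_calls data.frame with `snp_id` and `gencall` columns
#'   (one row per platform call).
#' @return the `k` retained platform rows.
#' @export
rankMatchGenCall <- function(k, platform_calls) {
  n <- nrow(platform_calls)
  if (k > n) stop("k (", k, ") exceeds available platform calls (", n, ")")
  ord <- order(-platform_calls$gencall, platform_calls$snp_id)
  platform_calls[ord[seq_len(k)], , drop = FALSE]
}

#' Concordance filter
#'
#' Retains classifier calls that agree with the platform call at the same
#' record; platform no-calls are never concordant.
#'
#' @param calls classifier calls with `sample_id`, `snp_id`, `call`.
#' @param platform data.frame with `sample_id`, `snp_id`, `gs_call`.
#' @return the concordant subset of `calls`.
#' @export
concordanceFilter <- function(calls, platform) {
  key <- function(d) paste(d$sample_id, d$snp_id, sep = "\r")
  plat <- setNames(platform$gs_call, key(platform))
  pc <- plat[key(calls)]
  keep <- !is.na(pc) & pc %in% GENO_LEVELS & pc == calls$call
  calls[keep, , drop = FALSE]
}
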