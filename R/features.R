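#' Angle errors of a polar intensity coordinate
#'
#' The expected angular positions of the three genotype clusters under equal
#' probe efficiency are 0 (AA), pi/4 (AB) and pi/2 (BB). The angle errors
#' are the signed deviations of the observed angle from each expectation:
#' `a_AA = theta`, `a_AB = pi/4 - theta`, `a_BB = pi/2 - theta`. No absolute
#' value is taken — the sign carries which side of the cluster the record
#' falls on.
#'
#' @param theta numeric vector of angles in radians, in `[0, pi/2]`.
#' @return a data.frame with columns `a_AA`, `a_AB`, `a_BB` (radians).
#' @export
angleErrors <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > pi / 2))
    stop("theta must lie in [0, pi/2] radians")
  data.frame(a_AA = theta, a_AB = pi / 4 - theta, a_BB = pi / 2 - theta)
}

#' Subtended arcs of a polar intensity coordinate
#'
#' The arc length associated with each angle error at total intensity `r`:
#' `s_g = r * a_g`. A record with zero intensity subtends no arc.
#'
#' @param r numeric vector of total intensities, `>= 0`.
#' @param theta numeric vector of angles in radians, in `[0, pi/2]`.
#' @return a data.frame with columns `s_AA`, `s_AB`, `s_BB`.
#' @export
subtendedArcs <- function(r, theta) {
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be non-negative")
  a <- angleErrors(theta)
  data.frame(s_AA = r * a$a_AA, s_AB = r * a$a_AB, s_BB = r * a$a_BB)
}

#' Per-sample intensity summaries
#'
#' Mean and unbiased variance of the total intensity `R` over one sample's
#' QC-passing records. Both track DNA input (mean falls and variability
#' rises as input drops), so they act as record-level proxies for sample
#' quality in the classifier.
#'
#' @param r numeric vector of total intensities for one sample (>= 2 values).
#' @return named numeric vector `c(sample_mean_r, sample_var_r)`.
#' @export
sampleSummaries <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) < 2) stop("need at least 2 records to summarize a sample")
  c(sample_mean_r = mean(r), sample_var_r = var(r))
}

#' Canonical feature names of the recaller
#' @return character vector of the 15 engineered feature names.
#' @export
featureNames <- function() {
  c("gencall", "gentrain", "cluster_sep", "r", "x", "y", "theta",
    "a_AA", "a_AB", "a_BB", "s_AA", "s_AB", "s_BB",
    "sample_mean_r", "sample_var_r")
}

#' Build the engineered feature table
#'
#' Converts an [IntensitySet-class] (typically QC-filtered) into the long
#' feature table used for training and prediction: per-record raw summaries
#' (GenCall, GenTrain, cluster separation, R, X, Y), the angle in radians
#' (`theta = theta_norm * pi/2`), signed angle errors and subtended arcs,
#' and per-sample intensity mean/variance broadcast to every record of the
#' sample. Features are raw here; z-normalization is fit on training data
#' only via [fitNormalizer()].
#'
#' @param x an [IntensitySet-class].
#' @return a data.frame with identifier columns (`sample_id`,
#'   `individual_id`, `dna_input_ng`, `is_truth`, `snp_id`, `gs_call`,
#'   `gencall_score`) and the [featureNames()] columns.
#' @export
buildFeatures <- function(x) {
  rec <- as.data.table(recordTable(x))
  rec[, theta := theta_norm * (pi / 2)]
  rec <- rec[!is.na(theta) & !is.na(r)]
  ae <- angleErrors(rec$theta)
  sa <- subtendedArcs(rec$r, rec$theta)
  rec <- cbind(rec, ae, sa)
  rec[, c("sample_mean_r", "sample_var_r") :=
        .(mean(r), var(r)), by = sample_id]
  if (any(is.na(rec$sample_var_r)))
    stop("need at least 2 records per sample for intensity summaries")
  rec[, gencall_score := gencall]
  cols <- c("sample_id", "individual_id", "dna_input_ng", "is_truth",
            "snp_id", "gs_call", "gencall_score", featureNames())
  out <- rec[, cols, with = FALSE]
  setDF(out)
  out
}

#' Fit a z-score normalizer on training features
#'
#' Stores per-feature mean and standard deviation (n-1 convention) from the
#' training partition only. Constant features are dropped with a warning
#' and recorded in the normalizer.
#'
#' @param df training feature data.frame (from [buildFeatures()]).
#' @param features feature columns to normalize (default [featureNames()]
#'   intersected with `names(df)`).
#' @return a `Normalizer` object.
#' @export
fitNormalizer <- function(df, features = intersect(featureNames(), names(df))) {
  mu <- vapply(features, function(f) mean(df[[f]]), numeric(1))
  sdev <- vapply(features, function(f) sd(df[[f]]), numeric(1))
  dropped <- features[!is.na(sdev) & sdev == 0 | is.na(sdev)]
  if (length(dropped))
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
  keep <- setdiff(features, dropped)
  structure(list(features = keep, mean = mu[keep], sd = sdev[keep],
                 dropped = dropped),
            class = "Normalizer")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param norm a `Normalizer` from [fitNormalizer()].
#' @param df a feature data.frame containing the normalizer's features.
#' @param invert if `TRUE`, undo the transform instead.
#' @return `df` with the normalizer's feature columns transformed; dropped
#'   (constant) features are removed.
#' @export
applyNormalizer <- function(norm, df, invert = FALSE) {
  stopifnot(inherits(norm, "Normalizer"))
  miss <- setdiff(norm$features, names(df))
  if (length(miss))
    stop("feature(s) missing from data: ", paste(miss, collapse = ", "))
  for (f in norm$features) {
    df[[f]] <- if (invert) df[[f]] * norm$sd[[f]] + norm$mean[[f]]
               else (df[[f]] - norm$mean[[f]]) / norm$sd[[f]]
  }
  df[setdiff(names(df), norm$dropped)]
}

#' @export
print.Normalizer <- function(x, ...) {
  cat("Normalizer over", length(x$features), "features")
  if (length(x$dropped))
    cat(" (", length(x$dropped), " constant dropped)", sep = "")
  cat("\n")
  invisible(x)
}
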