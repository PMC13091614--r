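#' Absolute and relative call rates
#'
#' The absolute call rate divides called sites by the full autosomal
#' content of the chip; the relative call rate divides by the sites
#' actually assayed for that DNA input. Since the input's sites are a
#' subset of the chip's, absolute <= relative always.
#'
#' @param n_called number of called (retained) sites.
#' @param n_input_sites sites assayed for this DNA input (relative
#'   denominator).
#' @param n_chip_sites autosomal sites on the chip (absolute denominator;
#'   the full-chip constant is 4198873 for the array the method targets,
#'   configurable).
#' @return named numeric vector `c(absolute, relative)`.
#' @export
callRates <- function(n_called, n_input_sites, n_chip_sites = 4198873) {
  if (n_input_sites <= 0 || n_chip_sites <= 0)
    stop("call-rate denominators must be positive")
  stopifnot(n_input_sites <= n_chip_sites, n_called <= n_input_sites)
  c(absolute = n_called / n_chip_sites, relative = n_called / n_input_sites)
}

#' Genotype accuracy over called sites
#'
#' `accuracy = (called - wrong) / called`: uncalled sites appear in
#' neither numerator nor denominator, so this measures the correctness of
#' the genotypes actually delivered.
#'
#' @param calls character vector of calls (AA/AB/BB; NC entries are treated
#'   as uncalled and excluded).
#' @param truth character vector of matching truth genotypes.
#' @return accuracy in `[0, 1]`, or `NA` when no sites are called.
#' @export
genotypeAccuracy <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  called <- calls %in% GENO_LEVELS
  if (!any(called)) return(NA_real_)
  mean(calls[called] == truth[called])
}

#' Confusion matrix of calls against truth
#'
#' @param calls character vector of calls (AA/AB/BB/NC).
#' @param truth character vector of truth genotypes (AA/AB/BB).
#' @return 3 x 4 integer table: rows = truth, columns = call (AA, AB, BB,
#'   NC).
#' @export
confusionCounts <- function(calls, truth) {
  table(truth = factor(truth, levels = GENO_LEVELS),
        call = factor(ifelse(calls %in% GENO_LEVELS, calls, "NC"),
                      levels = c(GENO_LEVELS, "NC")))
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest over called sites. The heterozygote (AB) class mixes two
#' probe signals and is the failure-prone class in degraded samples, so
#' its F1 is the most informative single cell. A class absent from both
#' calls and truth yields `NA`.
#'
#' @inheritParams genotypeAccuracy
#' @return data.frame with rows AA/AB/BB and columns `precision`,
#'   `recall`, `f1`.
#' @export
perClassF1 <- function(calls, truth) {
  called <- calls %in% GENO_LEVELS
  calls <- calls[called]; truth <- truth[called]
  out <- do.call(rbind, lapply(GENO_LEVELS, function(g) {
    tp <- sum(calls == g & truth == g)
    fp <- sum(calls == g & truth != g)
    fn <- sum(calls != g & truth == g)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    # F1 = 2tp / (2tp + fp + fn): 0 when the class is predicted or present
    # but never matched; undefined only if absent from calls and truth
    f1 <- if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    data.frame(class = g, precision = prec, recall = rec, f1 = f1)
  }))
  rownames(out) <- out$class
  out
}

#' Exact two-sided paired sign test
#'
#' Tests whether paired differences are symmetric about zero: zeros are
#' dropped, and the count of positive signs among the `n` nonzero
#' differences is referred to Binomial(n, 1/2);
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @param diffs numeric vector of paired differences.
#' @return two-sided p-value, or `NA` if every difference is zero.
#' @export
pairedSignTest <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) return(NA_real_)
  k <- sum(d > 0)
  lower <- sum(dbinom(0:k, n, 0.5))
  upper <- sum(dbinom(k:n, n, 0.5))
  min(1, 2 * min(lower, upper))
}

#' Full evaluation report for one call set
#'
#' Bundles the study's evaluation statistics: call rates, accuracy,
#' per-class precision/recall/F1 and the confusion matrix.
#'
#' @param calls data.frame with `call` (AA/AB/BB/NC) and `truth_genotype`
#'   columns, one row per evaluated site.
#' @param n_chip_sites absolute call-rate denominator; `NA` skips the
#'   absolute rate.
#' @param n_input_sites relative denominator; defaults to `nrow(calls)`.
#' @return a `MetricsReport` list: `n_total_sites`, `n_called`,
#'   `n_uncalled`, `n_wrong`, `absolute_call_rate`, `relative_call_rate`,
#'   `accuracy`, `per_class` and `confusion`.
#' @export
metricsReport <- function(calls, n_chip_sites = NA, n_input_sites = nrow(calls)) {
  cl <- calls$call; tr <- calls$truth_genotype
  called <- cl %in% GENO_LEVELS
  n_called <- sum(called)
  n_wrong <- sum(cl[called] != tr[called])
  structure(list(
    n_total_sites = length(cl),
    n_called = n_called,
    n_uncalled = length(cl) - n_called,
    n_wrong = n_wrong,
    absolute_call_rate = if (is.na(n_chip_sites)) NA_real_
                         else n_called / n_chip_sites,
    relative_call_rate = n_called / n_input_sites,
    accuracy = genotypeAccuracy(cl, tr),
    per_class = perClassF1(cl, tr),
    confusion = confusionCounts(cl, tr)
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "MetricsReport: %d sites, %d called (relative call rate %.4f)\n",
    x$n_total_sites, x$n_called, x$relative_call_rate))
  if (!is.na(x$accuracy))
    cat(sprintf("  accuracy %.4f (%d wrong)\n", x$accuracy, x$n_wrong))
  f1 <- x$per_class$f1
  cat(sprintf("  F1: AA %.4f | AB %.4f | BB %.4f\n", f1[1], f1[2], f1[3]))
  invisible(x)
}
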