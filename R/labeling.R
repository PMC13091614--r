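#' Build ground-truth genotype labels from the designated truth runs
#'
#' Each individual's high-input run flagged `is_truth` in the manifest
#' provides its reference genotypes. Sites the platform declined to call
#' (NC) in the truth run yield no label.
#'
#' @param x an [IntensitySet-class] (typically QC-filtered).
#' @return a data.frame with columns `individual_id`, `snp_id`,
#'   `truth_genotype` (AA/AB/BB).
#' @export
buildTruth <- function(x) {
  stopifnot(methods::is(x, "IntensitySet"))
  cd <- colData(x)
  inds <- unique(cd$individual_id)
  has_truth <- unique(cd$individual_id[cd$is_truth])
  miss <- setdiff(inds, has_truth)
  if (length(miss))
    stop("individual(s) without a designated truth run: ",
         paste(miss, collapse = ", "))
  tx <- x[, cd$is_truth]
  geno <- platformCalls(tx)
  dt <- data.table(
    individual_id = rep(colData(tx)$individual_id, each = nrow(tx)),
    snp_id = rep(rowData(tx)$snp_id, times = ncol(tx)),
    truth_genotype = as.vector(geno)
  )
  dt <- dt[truth_genotype %in% GENO_LEVELS]
  if (anyDuplicated(dt[, .(individual_id, snp_id)]))
    stop("duplicated (individual, snp) truth labels")
  setDF(dt)
  dt
}

#' Assemble labeled training examples
#'
#' Inner-joins lower-input feature records to the truth labels on
#' `(individual_id, snp_id)`. Records without a truth label are dropped and
#' counted (attribute `n_unlabeled`). Records the platform left uncalled
#' (gs_call NC) are retained by default — they still carry intensity
#' features — or dropped under `strict = TRUE`.
#'
#' @param features feature data.frame from [buildFeatures()]; truth-run
#'   records (`is_truth`) are excluded automatically.
#' @param truth truth labels from [buildTruth()].
#' @param strict drop records whose platform call is NC (default `FALSE`).
#' @return a data.frame of labeled examples: the feature columns plus
#'   `truth_genotype`; attribute `n_unlabeled` counts dropped records.
#' @export
makeExamples <- function(features, truth, strict = FALSE) {
  f <- as.data.table(features)
  if (!is.null(f$is_truth)) f <- f[!(is_truth)]
  if (strict) f <- f[gs_call != "NC"]
  t <- as.data.table(truth)
  out <- merge(f, t, by = c("individual_id", "snp_id"), sort = FALSE)
  n_unlabeled <- nrow(f) - nrow(out)
  setDF(out)
  attr(out, "n_unlabeled") <- n_unlabeled
  out
}

#' Partition examples by individual
#'
#' Group-wise split: every record of an individual lands in exactly one
#' partition, so no individual leaks across the train/test boundary.
#'
#' @param examples labeled examples (any data.frame with `individual_id`).
#' @param test_individuals nonempty character vector of held-out
#'   individual IDs; all must be present in the data.
#' @return list with `train` and `test` data.frames.
#' @export
splitByIndividual <- function(examples, test_individuals) {
  stopifnot(length(test_individuals) >= 1)
  unknown <- setdiff(test_individuals, unique(examples$individual_id))
  if (length(unknown))
    stop("unknown individual(s): ", paste(unknown, collapse = ", "))
  is_test <- examples$individual_id %in% test_individuals
  list(train = examples[!is_test, , drop = FALSE],
       test = examples[is_test, , drop = FALSE])
}

#' Down-sample to a balanced correct/incorrect set
#'
#' The platform gets the large majority of sites right, so "was the
#' platform call correct" is heavily imbalanced. For the model-selection
#' phase the majority class is down-sampled (uniformly, without
#' replacement) until correct and incorrect records are equally many. With
#' `mode = "genotype"` the three genotype classes are balanced to the
#' rarest class instead.
#'
#' @param examples labeled examples with `gs_call` and `truth_genotype`.
#' @param seed integer seed; sampling is reproducible.
#' @param mode `"binary"` (correct vs incorrect platform call; NC counts as
#'   incorrect) or `"genotype"` (balance AA/AB/BB truth classes).
#' @return the balanced subset of `examples`.
#' @export
downsampleBalanced <- function(examples, seed = 1L, mode = c("binary", "genotype")) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "binary") {
    correct <- examples$gs_call == examples$truth_genotype
    n_cor <- sum(correct); n_inc <- sum(!correct)
    if (n_cor == 0 || n_inc == 0)
      stop("both correct and incorrect platform calls are required")
    n <- min(n_cor, n_inc)
    idx <- c(sample(which(correct), n), sample(which(!correct), n))
  } else {
    sp <- split(seq_len(nrow(examples)), examples$truth_genotype)
    if (length(sp) < 3 || any(lengths(sp) == 0))
      stop("all three genotype classes are required")
    n <- min(lengths(sp))
    idx <- unlist(lapply(sp, sample, size = n), use.names = FALSE)
  }
  examples[sort(idx), , drop = FALSE]
}

#' Inverse-frequency class weights
#'
#' `weight(c) = N_total / (3 * N_c)`, so each genotype class carries equal
#' total mass — a flat prior on genotypes without discarding data. The
#' weighted class masses sum back to `N_total`.
#'
#' @param labels character vector of truth genotypes (AA/AB/BB).
#' @return named numeric vector of weights for AA, AB, BB.
#' @export
classWeights <- function(labels) {
  counts <- table(factor(labels, levels = GENO_LEVELS))
  if (any(counts == 0))
    stop("missing genotype class(es): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  w <- as.numeric(sum(counts)) / (3 * as.numeric(counts))
  setNames(w, GENO_LEVELS)
}
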