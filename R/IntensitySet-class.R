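#' IntensitySet: two-channel SNP array summary statistics
#'
#' An `IntensitySet` holds one microarray experiment as a
#' [SummarizedExperiment::SummarizedExperiment] with SNPs as rows and sample
#' runs (one individual at one DNA input) as columns. Assays are the
#' per-record summary statistics a GenomeStudio-style final report exports:
#'
#' * `X`, `Y` — normalized A- and B-channel intensities (non-negative);
#' * `R` — total intensity, `X + Y`;
#' * `Theta` — normalized angle in `[0, 1]` (Illumina convention,
#'   `(2/pi) * atan2(Y, X)`; 0 = pure A signal, 1 = pure B);
#' * `GenCall` — the platform's per-call quality score in `[0, 1]`;
#' * `GSCall` — the platform genotype call coded as B-allele dosage
#'   (0 = AA, 1 = AB, 2 = BB, `NA` = no-call).
#'
#' `rowData` carries per-SNP metadata: `snp_id`, `chrom` (verbatim string,
#' `"0"` meaning indeterminate), `pos` (1-based), `allele_a`, `allele_b`,
#' and the per-SNP cluster-quality scores `gentrain` and `cluster_sep` (both
#' in `[0, 1]`). `colData` is the sample manifest: `sample_id`,
#' `individual_id`, `dna_input_ng` (> 0) and `is_truth` (at most one `TRUE`
#' run per individual, designating its ground-truth run).
#'
#' Records absent from the report (e.g. dropped unparseable rows) are `NA`
#' across all assays for that cell.
#'
#' @name IntensitySet-class
#' @aliases IntensitySet
#' @exportClass IntensitySet
setClass("IntensitySet", contains = "SummarizedExperiment")

REQUIRED_ASSAYS <- c("X", "Y", "R", "Theta", "GenCall", "GSCall")
REQUIRED_ROWDATA <- c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                      "gentrain", "cluster_sep")
REQUIRED_COLDATA <- c("sample_id", "individual_id", "dna_input_ng", "is_truth")

setValidity("IntensitySet", function(object) {
  msgs <- character()
  miss <- setdiff(REQUIRED_ASSAYS, SummarizedExperiment::assayNames(object))
  if (length(miss))
    msgs <- c(msgs, paste("missing assays:", paste(miss, collapse = ", ")))
  miss <- setdiff(REQUIRED_ROWDATA, colnames(rowData(object)))
  if (length(miss))
    msgs <- c(msgs, paste("missing rowData columns:", paste(miss, collapse = ", ")))
  miss <- setdiff(REQUIRED_COLDATA, colnames(colData(object)))
  if (length(miss))
    msgs <- c(msgs, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (length(msgs)) return(msgs)

  th <- assay(object, "Theta")
  if (any(th < -1e-9 | th > 1 + 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "Theta must lie in [0, 1]")
  for (a in c("X", "Y", "R"))
    if (any(assay(object, a) < -1e-9, na.rm = TRUE))
      msgs <- c(msgs, paste(a, "must be non-negative"))
  gc <- assay(object, "GenCall")
  if (any(gc < -1e-9 | gc > 1 + 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "GenCall must lie in [0, 1]")
  gs <- assay(object, "GSCall")
  if (!all(gs %in% c(0L, 1L, 2L, NA)))
    msgs <- c(msgs, "GSCall codes must be 0, 1, 2 or NA")
  xy <- assay(object, "X") + assay(object, "Y")
  rr <- assay(object, "R")
  ok <- is.na(xy) | is.na(rr) | abs(rr - xy) <= 1e-4 + 1e-4 * rr
  if (!all(ok))
    msgs <- c(msgs, "R must equal X + Y (within tolerance) where both are present")
  cd <- colData(object)
  if (any(cd$dna_input_ng <= 0))
    msgs <- c(msgs, "dna_input_ng must be positive")
  tr <- cd$individual_id[cd$is_truth]
  if (anyDuplicated(tr))
    msgs <- c(msgs, "at most one is_truth run per individual")
  if (length(msgs)) msgs else TRUE
})

#' Construct an IntensitySet
#'
#' @param assays named list with matrices `X`, `Y`, `R`, `Theta`, `GenCall`
#'   (numeric) and `GSCall` (integer dosage codes, `NA` = no-call), all
#'   SNP x sample. `R` may be omitted and is then computed as `X + Y`.
#' @param rowData data.frame (or DataFrame) of per-SNP metadata with columns
#'   `snp_id`, `chrom`, `pos`, `allele_a`, `allele_b`, `gentrain`,
#'   `cluster_sep`.
#' @param colData data.frame of the sample manifest with columns `sample_id`,
#'   `individual_id`, `dna_input_ng`, `is_truth`.
#' @param metadata optional list stored in the object metadata.
#' @return an [IntensitySet-class] object.
#' @export
IntensitySet <- function(assays, rowData, colData, metadata = list()) {
  if (is.null(assays$R)) assays$R <- assays$X + assays$Y
  assays <- assays[REQUIRED_ASSAYS]
  storage.mode(assays$GSCall) <- "integer"
  rowData <- S4Vectors::DataFrame(rowData)
  colData <- S4Vectors::DataFrame(colData)
  rownames(colData) <- colData$sample_id
  se <- SummarizedExperiment(assays = assays, rowData = rowData,
                             colData = colData, metadata = metadata)
  rownames(se) <- rowData$snp_id
  methods::new("IntensitySet", se)
}

#' @describeIn IntensitySet-class platform genotype calls as a character
#'   matrix over `"AA"`, `"AB"`, `"BB"`, `"NC"`.
#' @param x an `IntensitySet`.
#' @export
platformCalls <- function(x) {
  dosageToGeno(assay(x, "GSCall"))
}

#' @describeIn IntensitySet-class platform genotype calls as a B-allele
#'   dosage matrix (0/1/2, `NA` = no-call).
#' @export
platformDosage <- function(x) assay(x, "GSCall")

#' @describeIn IntensitySet-class per-call GenCall score matrix.
#' @export
genCallScores <- function(x) assay(x, "GenCall")

#' @describeIn IntensitySet-class sample manifest as a data.frame.
#' @export
sampleManifest <- function(x) as.data.frame(colData(x))

#' Convert between genotype labels and B-allele dosages
#'
#' `genoToDosage()` maps `"AA"/"AB"/"BB"` to 0/1/2 (anything else, including
#' `"NC"`, becomes `NA`); `dosageToGeno()` is the inverse, mapping `NA` to
#' `"NC"`.
#'
#' @param g character vector/matrix of genotype labels.
#' @param d integer vector/matrix of dosages.
#' @return the converted vector/matrix, dimensions preserved.
#' @export
genoToDosage <- function(g) {
  d <- match(g, GENO_LEVELS) - 1L
  if (!is.null(dim(g))) dim(d) <- dim(g)
  dimnames(d) <- dimnames(g)
  d
}

#' @rdname genoToDosage
#' @export
dosageToGeno <- function(d) {
  g <- ifelse(is.na(d), "NC", GENO_LEVELS[d + 1L])
  if (!is.null(dim(d))) dim(g) <- dim(d)
  dimnames(g) <- dimnames(d)
  g
}

#' Long record table of an IntensitySet
#'
#' Flattens the SNP x sample assays into one row per observed record, the
#' form consumed by feature engineering and model training. Cells that are
#' `NA` across all intensity assays (records absent from the source report)
#' are omitted.
#'
#' @param x an [IntensitySet-class].
#' @return a `data.frame` with columns `sample_id`, `individual_id`,
#'   `dna_input_ng`, `is_truth`, `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `gentrain`, `cluster_sep`, `x`, `y`, `r`, `theta_norm`,
#'   `gencall`, `gs_call`.
#' @export
recordTable <- function(x) {
  stopifnot(methods::is(x, "IntensitySet"))
  rd <- as.data.frame(rowData(x))
  cd <- as.data.frame(colData(x))
  ns <- nrow(x); np <- ncol(x)
  dt <- data.table(
    sample_id     = rep(cd$sample_id, each = ns),
    individual_id = rep(cd$individual_id, each = ns),
    dna_input_ng  = rep(cd$dna_input_ng, each = ns),
    is_truth      = rep(cd$is_truth, each = ns),
    snp_id        = rep(rd$snp_id, times = np),
    chrom         = rep(rd$chrom, times = np),
    pos           = rep(rd$pos, times = np),
    allele_a      = rep(rd$allele_a, times = np),
    allele_b      = rep(rd$allele_b, times = np),
    gentrain      = rep(rd$gentrain, times = np),
    cluster_sep   = rep(rd$cluster_sep, times = np),
    x             = as.vector(assay(x, "X")),
    y             = as.vector(assay(x, "Y")),
    r             = as.vector(assay(x, "R")),
    theta_norm    = as.vector(assay(x, "Theta")),
    gencall       = as.vector(assay(x, "GenCall")),
    gs_call       = as.vector(dosageToGeno(assay(x, "GSCall")))
  )
  dt <- dt[!(is.na(dt$r) & is.na(dt$theta_norm) & is.na(dt$x) & is.na(dt$y)), ]
  setDF(dt)
  dt
}

setMethod("show", "IntensitySet", function(object) {
  cd <- colData(object)
  cat("IntensitySet:", nrow(object), "SNPs x", ncol(object), "sample runs\n")
  cat("  individuals:", length(unique(cd$individual_id)),
      " | DNA inputs (ng):",
      paste(sort(unique(cd$dna_input_ng), decreasing = TRUE), collapse = ", "),
      "\n")
  nc <- mean(is.na(assay(object, "GSCall")))
  cat(sprintf("  platform no-call rate: %.2f%%\n", 100 * nc))
  if (length(metadata(object)))
    cat("  metadata:", paste(names(metadata(object)), collapse = ", "), "\n")
  invisible(object)
})
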