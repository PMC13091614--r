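#' Default final-report column-name map
#'
#' Maps the internal field names onto the column headers of a
#' GenomeStudio-style final report. Override entries to accommodate dialects
#' (e.g. `list(x = "X Raw")`). Entries mapped to `NA` are treated as absent.
#'
#' @param ... named overrides of the defaults.
#' @return named character vector: internal field -> report column header.
#' @export
finalReportColumns <- function(...) {
  def <- c(
    sample_id   = "Sample ID",
    snp_id      = "SNP Name",
    chrom       = "Chr",
    pos         = "Position",
    allele_a    = "Allele1 - AB",
    allele_b    = "Allele2 - AB",
    x           = "X",
    y           = "Y",
    r           = "R",
    theta       = "Theta",
    gencall     = "GC Score",
    gentrain    = "GT Score",
    cluster_sep = "Cluster Sep",
    gs_call     = "Call"
  )
  ov <- c(...)
  if (length(ov)) def[names(ov)] <- ov
  def
}

# Columns that must be present in every report. R is optional (recomputed
# from X + Y when absent); X and Y may both be absent when R and Theta are
# present, in which case the channel intensities are left unset rather
# than reconstructed.
.mandatory_fields <- c("sample_id", "snp_id", "chrom", "pos",
                       "theta", "gencall", "gentrain", "cluster_sep",
                       "gs_call")

#' Read a sample manifest
#'
#' The manifest is a CSV with header
#' `sample_id,individual_id,dna_input_ng,is_truth`. It validates that DNA
#' inputs are positive and that each individual has at most one
#' ground-truth (`is_truth`) run.
#'
#' @param path path to the manifest CSV.
#' @return a `data.frame` with the four manifest columns.
#' @export
readManifest <- function(path) {
  m <- fread(path, colClasses = list(character = c("sample_id", "individual_id")))
  need <- c("sample_id", "individual_id", "dna_input_ng", "is_truth")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  m <- as.data.frame(m)[need]
  m$is_truth <- as.logical(m$is_truth)
  m$dna_input_ng <- as.numeric(m$dna_input_ng)
  if (anyNA(m$dna_input_ng) || any(m$dna_input_ng <= 0))
    stop("dna_input_ng must be positive for every sample")
  if (anyDuplicated(m$sample_id))
    stop("duplicated sample_id in manifest")
  tr <- m$individual_id[m$is_truth]
  if (anyDuplicated(tr))
    stop("more than one is_truth run for individual(s): ",
         paste(unique(tr[duplicated(tr)]), collapse = ", "))
  m
}

#' Read a GenomeStudio-style final report
#'
#' Parses a tab-separated final report (one row per sample x SNP record)
#' into an [IntensitySet-class]. Rows whose numeric fields do not parse are
#' dropped and counted (see `metadata(x)$n_dropped_rows`); a missing `R`
#' column is tolerated and recomputed as `X + Y`. Genotype calls are read
#' either as a single column (`AA/AB/BB/NC`, or `--`/`NC` for no-calls) or
#' reconstructed from the two allele columns when the call column maps two
#' alleles.
#'
#' @param path path to the tab-separated report. A `[Header]`/`[Data]`
#'   section structure is tolerated: parsing starts at the header line of
#'   the data section.
#' @param manifest sample manifest as returned by [readManifest()]. Every
#'   `Sample ID` in the report must appear in it.
#' @param columns column-name map from [finalReportColumns()].
#' @return an [IntensitySet-class]; `metadata()` records `n_dropped_rows`.
#' @export
readFinalReport <- function(path, manifest, columns = finalReportColumns()) {
  # tolerate the [Header] ... [Data] preamble of real exports
  top <- readLines(path, n = 50L)
  skip <- 0L
  dl <- grep("^\\[Data\\]", top)
  if (length(dl)) skip <- dl[1L]
  dt <- fread(path, sep = "\t", skip = skip, header = TRUE,
              colClasses = "character", quote = "")

  have <- names(columns)[columns %in% names(dt)]
  miss <- setdiff(.mandatory_fields, have)
  if (length(miss))
    stop("final report is missing mandatory column(s): ",
         paste(columns[miss], collapse = ", "))
  if (!all(c("x", "y") %in% have) && !("r" %in% have))
    stop("final report must carry X and Y, or R (with Theta)")

  keep <- columns[have]
  dt <- dt[, unname(keep), with = FALSE]
  data.table::setnames(dt, unname(keep), names(keep))

  num_fields <- intersect(c("pos", "x", "y", "r", "theta", "gencall",
                            "gentrain", "cluster_sep"), names(dt))
  for (f in num_fields)
    suppressWarnings(data.table::set(dt, j = f, value = as.numeric(dt[[f]])))
  bad <- !complete.cases(dt[, num_fields, with = FALSE])
  n_dropped <- sum(bad)
  if (n_dropped) {
    message("readFinalReport: dropped ", n_dropped,
            " row(s) with unparseable numeric fields")
    dt <- dt[!bad]
  }
  if (!nrow(dt)) stop("no parseable data rows in ", path)

  unknown <- setdiff(unique(dt$sample_id), manifest$sample_id)
  if (length(unknown))
    stop("sample_id absent from manifest: ", paste(unknown, collapse = ", "))

  if (is.null(dt$r)) dt[, r := x + y]
  if (is.null(dt$x)) dt[, x := NA_real_]
  if (is.null(dt$y)) dt[, y := NA_real_]
  if (is.null(dt$allele_a)) dt[, allele_a := "A"]
  if (is.null(dt$allele_b)) dt[, allele_b := "B"]
  dt[, gs_call := .normalize_call(gs_call)]

  # wide matrices: rows = SNPs (first-occurrence order), cols = manifest order
  snps <- dt[!duplicated(snp_id),
             .(snp_id, chrom, pos, allele_a, allele_b, gentrain, cluster_sep)]
  samples <- manifest[manifest$sample_id %in% unique(dt$sample_id), ]
  i <- match(dt$snp_id, snps$snp_id)
  j <- match(dt$sample_id, samples$sample_id)
  idx <- cbind(i, j)
  mk <- function(v, mode = "numeric") {
    m <- matrix(if (mode == "integer") NA_integer_ else NA_real_,
                nrow(snps), nrow(samples))
    m[idx] <- v
    m
  }
  assays <- list(
    X = mk(dt$x), Y = mk(dt$y), R = mk(dt$r),
    Theta = mk(dt$theta), GenCall = mk(dt$gencall),
    GSCall = mk(genoToDosage(dt$gs_call), "integer")
  )
  rowdat <- as.data.frame(snps)
  if (is.null(rowdat$allele_a)) rowdat$allele_a <- "A"
  if (is.null(rowdat$allele_b)) rowdat$allele_b <- "B"
  IntensitySet(assays, rowData = rowdat, colData = samples,
               metadata = list(n_dropped_rows = n_dropped, source = path))
}

.normalize_call <- function(g) {
  g <- toupper(trimws(g))
  g[!(g %in% GENO_LEVELS)] <- "NC"
  g
}

#' Write probabilistic genotype calls as VCF 4.2
#'
#' Emits one record per site with `REF` = allele A, `ALT` = allele B, and
#' per-sample `GT:GQ:PL` fields. `GT` encodes the posterior's argmax call
#' (AA -> `0/0`, AB -> `0/1`, BB -> `1/1`); filtered or no-call entries are
#' written `./.` with missing GQ/PL. `PL` is `-10*log10` of each genotype
#' probability shifted so the minimum is 0 and rounded to integer;
#' probabilities are floored at `1e-99` before log-scaling and `GQ` is
#' capped (default 99).
#'
#' @param calls data.frame of posteriors with columns `sample_id`, `snp_id`,
#'   `p_AA`, `p_AB`, `p_BB`, `call` (one of AA/AB/BB/NC; filtered entries may
#'   simply be absent or carry call = "NC").
#' @param sites data.frame of site metadata: `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`. Every call must reference a known site.
#' @param file output path.
#' @param gq_cap Phred cap for GQ (and PL entries), default 99.
#' @return invisibly, the output path.
#' @export
writeRecallVcf <- function(calls, sites, file, gq_cap = 99) {
  calls <- as.data.table(calls)
  sites <- as.data.table(sites)
  unknown <- setdiff(unique(calls$snp_id), sites$snp_id)
  if (length(unknown))
    stop("call(s) reference unknown site(s): ",
         paste(head(unknown, 5), collapse = ", "))
  samples <- sort(unique(calls$sample_id))
  sites <- sites[snp_id %in% unique(calls$snp_id)]
  setorder(sites, chrom, pos)

  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=snprecall-", as.character(packageVersion("snprecall"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods for AA,AB,BB\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  gt_map <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  fmt_one <- function(p, cl) {
    if (is.na(cl) || !(cl %in% GENO_LEVELS)) return("./.:.:.")
    pl <- round(-10 * log10(pmax(p, 1e-99)))
    pl <- pmin(pl - min(pl), 10 * gq_cap)
    gq <- min(round(phredQuality(max(p))), gq_cap)
    paste0(gt_map[[cl]], ":", gq, ":", paste(pl, collapse = ","))
  }

  key <- paste(calls$sample_id, calls$snp_id, sep = "\r")
  lut <- setNames(seq_len(nrow(calls)), key)
  lines <- vapply(seq_len(nrow(sites)), function(si) {
    s <- sites[si]
    cells <- vapply(samples, function(sm) {
      ix <- lut[paste(sm, s$snp_id, sep = "\r")]
      if (is.na(ix)) return("./.:.:.")
      fmt_one(c(calls$p_AA[ix], calls$p_AB[ix], calls$p_BB[ix]),
              calls$call[ix])
    }, character(1))
    paste(c(s$chrom, s$pos, s$snp_id, s$allele_a, s$allele_b, ".", ".", ".",
            "GT:GQ:PL", cells), collapse = "\t")
  }, character(1))

  writeLines(c(hdr, lines), file)
  invisible(file)
}
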