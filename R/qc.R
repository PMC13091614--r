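#' Quality-control configuration
#'
#' Record-level QC mirrors common array practice: restrict to autosomes,
#' drop SNPs with invalid identifiers, drop duplicated SNP names, and treat
#' calls under the platform's default GenCall threshold of 0.15 as no-calls.
#'
#' @param autosomes_only drop SNPs on chromosomes X, Y, MT and the
#'   indeterminate "0" (default `TRUE`).
#' @param drop_invalid_ids drop SNPs whose identifier is empty, `"."`, or
#'   contains a dash (default `TRUE`).
#' @param dedupe_snp_names drop *all* copies of any duplicated SNP name
#'   (default `TRUE`).
#' @param gencall_min GenCall score below which a platform call is demoted;
#'   the boundary value itself is kept (default 0.15).
#' @param drop_low_gencall if `TRUE`, records under `gencall_min` are
#'   removed outright rather than converted to no-calls (strict emulation
#'   of pipelines that delete sub-threshold rows). Default `FALSE`: the
#'   call becomes NC but the record's intensities remain available to the
#'   recaller.
#' @return a `QcConfig` list.
#' @export
qcConfig <- function(autosomes_only = TRUE, drop_invalid_ids = TRUE,
                     dedupe_snp_names = TRUE, gencall_min = 0.15,
                     drop_low_gencall = FALSE) {
  stopifnot(gencall_min >= 0, gencall_min <= 1)
  structure(list(autosomes_only = autosomes_only,
                 drop_invalid_ids = drop_invalid_ids,
                 dedupe_snp_names = dedupe_snp_names,
                 gencall_min = gencall_min,
                 drop_low_gencall = drop_low_gencall),
            class = "QcConfig")
}

NON_AUTOSOMES <- c("X", "Y", "MT", "0")

#' Apply record-level quality control
#'
#' Filters are applied in a fixed order: (1) non-autosomal and
#' indeterminate chromosomes removed; (2) SNPs with invalid identifiers
#' removed; (3) all copies of duplicated SNP names removed; (4) platform
#' calls with GenCall below `gencall_min` demoted to NC (or removed under
#' `drop_low_gencall`). The operation is idempotent.
#'
#' @param x an [IntensitySet-class].
#' @param cfg a [qcConfig()].
#' @return a list with `kept` (the filtered `IntensitySet`) and `report`, a
#'   named integer vector of per-rule record counts
#'   (`non_autosomal`, `invalid_id`, `duplicated_id` removals and
#'   `low_gencall_nc` conversions; all counts are in records, i.e. SNPs
#'   removed times samples).
#' @export
qcFilter <- function(x, cfg = qcConfig()) {
  stopifnot(methods::is(x, "IntensitySet"), inherits(cfg, "QcConfig"))
  ns <- ncol(x)
  report <- c(non_autosomal = 0L, invalid_id = 0L, duplicated_id = 0L,
              low_gencall_nc = 0L, low_gencall_removed = 0L)

  n_obs <- function(obj, rows) {
    # count records actually present (not all-NA holes) in the given rows
    if (!length(rows)) return(0L)
    sum(!is.na(assay(obj, "Theta")[rows, , drop = FALSE]))
  }

  rd <- rowData(x)
  if (cfg$autosomes_only) {
    bad <- which(toupper(rd$chrom) %in% NON_AUTOSOMES)
    report["non_autosomal"] <- n_obs(x, bad)
    if (length(bad)) x <- x[-bad, ]
    rd <- rowData(x)
  }
  if (cfg$drop_invalid_ids) {
    id <- rd$snp_id
    bad <- which(is.na(id) | id == "" | id == "." | grepl("-", id, fixed = TRUE))
    report["invalid_id"] <- n_obs(x, bad)
    if (length(bad)) x <- x[-bad, ]
    rd <- rowData(x)
  }
  if (cfg$dedupe_snp_names) {
    id <- rd$snp_id
    bad <- which(id %in% id[duplicated(id)])
    report["duplicated_id"] <- n_obs(x, bad)
    if (length(bad)) x <- x[-bad, ]
  }

  gc <- assay(x, "GenCall")
  gs <- assay(x, "GSCall")
  low <- !is.na(gc) & gc < cfg$gencall_min
  if (cfg$drop_low_gencall) {
    report["low_gencall_removed"] <- sum(low & !is.na(assay(x, "Theta")))
    for (a in c("X", "Y", "R", "Theta", "GenCall")) {
      m <- assay(x, a); m[low] <- NA_real_; assay(x, a) <- m
    }
    gs[low] <- NA_integer_
    assay(x, "GSCall") <- gs
  } else {
    report["low_gencall_nc"] <- sum(low & !is.na(gs))
    gs[low] <- NA_integer_
    assay(x, "GSCall") <- gs
  }
  list(kept = x, report = report)
}
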