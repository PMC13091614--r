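#' Default simulated pedigree
#'
#' Eight individuals: two founder pairs (`P1`x`P2`, `P3`x`P4`), full
#' siblings `O1`, `O2` (of `P1`x`P2`), `O3` (of `P3`x`P4`), and `H1` (of
#' `P1`x`P3`), a half-sibling of `O1`/`O2`. The pedigree therefore contains
#' parent-offspring (0.25), full-sib (0.25), half-sib (0.125) and
#' unrelated (0) pairs, and duplicates can be formed by repeating a
#' genotype vector.
#'
#' @return data.frame with columns `id`, `mother`, `father` (`NA` for
#'   founders).
#' @export
defaultPedigree <- function() {
  data.frame(
    id     = c("P1", "P2", "P3", "P4", "O1", "O2", "O3", "H1"),
    mother = c(NA, NA, NA, NA, "P2", "P2", "P4", "P3"),
    father = c(NA, NA, NA, NA, "P1", "P1", "P3", "P1")
  )
}

#' Simulation configuration
#'
#' Defines the generative model for a synthetic dilution series. Genotypes
#' follow Hardy-Weinberg founders and Mendelian transmission over a
#' pedigree. Intensities live in polar `(r, theta)` space: each genotype
#' has a cluster center at 0 (AA), pi/4 (AB), or pi/2 (BB) radians, offset
#' per SNP by a small probe effect. Observed angles are truncated-normal
#' around the center with a standard deviation that *grows* as DNA input
#' falls; total intensity is LogNormal with a mean that *shrinks* and a
#' spread that grows as input falls. Heterozygote dropout collapses a true
#' AB record partway toward a random homozygote center (with attenuated
#' intensity), the dominant genotype-dependent error mode of degraded
#' samples.
#'
#' The degradation laws interpolate in `log10(input)` between the anchor
#' inputs 50 ng (pristine) and 0.01 ng (heavily degraded); `frac(input)`
#' below denotes that 0-1 interpolant.
#'
#' @param n_snps number of autosomal SNPs (default 20000).
#' @param allele_freq_range B-allele frequencies are Uniform on this range
#'   (default `c(0.05, 0.95)`).
#' @param pedigree data.frame `id`/`mother`/`father` (default
#'   [defaultPedigree()]).
#' @param dilution_levels_ng DNA inputs of the titration series (ng);
#'   default `c(50, 1, 0.5, 0.1, 0.05, 0.01)`.
#' @param r_meanlog_50 LogNormal meanlog of total intensity at 50 ng
#'   (default `log(2)`, i.e. mean intensity near 2 at full input).
#' @param r_meanlog_slope drop in meanlog per unit `log10(input)` decrease
#'   (default `log(2)/log10(5000)`: mean intensity roughly halves across
#'   the full series).
#' @param r_sdlog_range LogNormal sdlog at the 50 ng and 0.01 ng anchors
#'   (default `c(0.2, 0.5)`).
#' @param theta_sd_range angular cluster standard deviation (radians) at
#'   the anchors (default `c(0.03, 0.35)`).
#' @param theta_sd_power exponent of the angular-noise interpolation:
#'   `sd = lo + (hi - lo) * frac^power`. The default 4 makes angular
#'   degradation punctuated — mild through mid inputs, collapsing at the
#'   lowest — matching how array genotyping quality falls off a cliff
#'   rather than linearly.
#' @param probe_offset_sd per-SNP cluster-center offset SD in radians
#'   (default 0.02, clamped at +/- 0.06).
#' @param het_dropout_max heterozygote dropout probability at the 0.01 ng
#'   anchor; dropout probability is `het_dropout_max * frac(input)^2`
#'   (default 0.25).
#' @param dropout_shrink range of the partial-collapse factor: a dropout
#'   record's center moves that fraction of the way from pi/4 to the
#'   chosen homozygote center, Uniform on this range (default
#'   `c(0.5, 1)`).
#' @param dropout_r_factor multiplicative intensity loss on dropout
#'   records (default 0.5 — losing one allele's signal roughly halves the
#'   total intensity, which is what lets a supervised model recognize
#'   collapsed heterozygotes the platform cannot).
#' @param nc_score_threshold surrogate GenCall no-call threshold (default
#'   0.15).
#' @param seed integer seed.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(n_snps = 20000L,
                      allele_freq_range = c(0.05, 0.95),
                      pedigree = defaultPedigree(),
                      dilution_levels_ng = c(50, 1, 0.5, 0.1, 0.05, 0.01),
                      r_meanlog_50 = log(2),
                      r_meanlog_slope = log(2) / log10(5000),
                      r_sdlog_range = c(0.2, 0.5),
                      theta_sd_range = c(0.03, 0.35),
                      theta_sd_power = 4,
                      probe_offset_sd = 0.02,
                      het_dropout_max = 0.25,
                      dropout_shrink = c(0.5, 1),
                      dropout_r_factor = 0.5,
                      nc_score_threshold = 0.15,
                      seed = 1L) {
  stopifnot(n_snps >= 1, all(dilution_levels_ng > 0),
            !anyDuplicated(dilution_levels_ng),
            nc_score_threshold >= 0, nc_score_threshold <= 1,
            het_dropout_max >= 0, het_dropout_max <= 1)
  structure(as.list(environment()), class = "SimConfig")
}

# 0 at the 50 ng anchor, 1 at the 0.01 ng anchor, clamped
.degradation_frac <- function(input_ng) {
  pmin(pmax(log10(50 / input_ng) / log10(50 / 0.01), 0), 1)
}

.theta_sd <- function(cfg, input_ng) {
  f <- .degradation_frac(input_ng)
  cfg$theta_sd_range[1] + f^cfg$theta_sd_power * diff(cfg$theta_sd_range)
}

.r_laws <- function(cfg, input_ng) {
  f <- .degradation_frac(input_ng)
  list(meanlog = cfg$r_meanlog_50 - cfg$r_meanlog_slope * log10(50 / input_ng),
       sdlog = cfg$r_sdlog_range[1] + f * diff(cfg$r_sdlog_range))
}

.het_dropout_p <- function(cfg, input_ng) {
  cfg$het_dropout_max * .degradation_frac(input_ng)^2
}

.order_pedigree <- function(ped) {
  # topological order; cyclic pedigrees fail
  done <- character(); left <- ped
  ord <- integer()
  while (nrow(left)) {
    ready <- (is.na(left$mother) | left$mother %in% done) &
             (is.na(left$father) | left$father %in% done)
    if (!any(ready)) stop("pedigree is cyclic or references unknown parents")
    ord <- c(ord, match(left$id[ready], ped$id))
    done <- c(done, left$id[ready])
    left <- left[!ready, , drop = FALSE]
  }
  ped[ord, , drop = FALSE]
}

#' Simulate pedigree genotypes
#'
#' Founders are drawn in Hardy-Weinberg proportions at each SNP's B-allele
#' frequency; offspring receive one allele from each parent by uniform
#' Mendelian transmission (sites unlinked). Also lays down the per-SNP
#' probe map: chromosome, position, REF/ALT bases, probe offset, and
#' per-SNP surrogate cluster-quality scores (`gentrain`, `cluster_sep`,
#' anti-correlated with probe-offset magnitude).
#'
#' @param cfg a [simConfig()].
#' @return a `SimTruth` list: `genotypes` (SNP x individual B-dosage
#'   matrix), `snps` (per-SNP map), `pedigree`, `cfg`.
#' @export
simulateGenotypes <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_snps
  ped <- .order_pedigree(cfg$pedigree)
  freq <- runif(n, cfg$allele_freq_range[1], cfg$allele_freq_range[2])

  G <- matrix(NA_integer_, n, nrow(ped),
              dimnames = list(NULL, ped$id))
  for (k in seq_len(nrow(ped))) {
    mo <- ped$mother[k]; fa <- ped$father[k]
    if (is.na(mo) && is.na(fa)) {
      G[, k] <- rbinom(n, 2L, freq)
    } else {
      # transmitted allele is B with probability dosage/2 for each parent
      gm <- if (is.na(mo)) rbinom(n, 2L, freq) else G[, mo]
      gf <- if (is.na(fa)) rbinom(n, 2L, freq) else G[, fa]
      G[, k] <- rbinom(n, 1L, gm / 2) + rbinom(n, 1L, gf / 2)
    }
  }

  off <- pmin(pmax(rnorm(n, 0, cfg$probe_offset_sd), -0.06), 0.06)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  snps <- data.frame(
    snp_id = sprintf("rs%07d", seq_len(n)),
    chrom = as.character(sort(sample(1:22, n, replace = TRUE))),
    pos = NA_integer_,
    allele_a = ref, allele_b = alt,
    freq = freq, probe_offset = off,
    gentrain = pmin(pmax(1 - 6 * abs(off) + rnorm(n, 0, 0.03), 0), 1),
    cluster_sep = pmin(pmax(0.95 - 4 * abs(off) + rnorm(n, 0, 0.05), 0), 1)
  )
  pos <- integer(n)
  for (ix in split(seq_len(n), snps$chrom))
    pos[ix] <- sort(sample.int(5e7, length(ix)))
  snps$pos <- pos
  structure(list(genotypes = G, snps = snps, pedigree = ped, cfg = cfg),
            class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", nrow(x$genotypes), "SNPs x", ncol(x$genotypes),
      "individuals\n")
  invisible(x)
}

# inverse-CDF truncated normal on [lo, hi], vectorized
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = pi / 2) {
  plo <- pnorm(lo, mean, sd); phi_ <- pnorm(hi, mean, sd)
  stats::qnorm(plo + runif(n) * (phi_ - plo), mean, sd)
}

#' Simulate two-channel intensities at one DNA input
#'
#' Draws one record per individual x SNP at the given input level under
#' the configuration's degradation laws (see [simConfig()]). The channel
#' split is consistent with the polar coordinates: `x = r cos(theta) /
#' (cos(theta) + sin(theta))`, `y = r - x`, so `atan2(y, x) = theta` and
#' `x + y = r` hold exactly.
#'
#' @param truth a `SimTruth` from [simulateGenotypes()].
#' @param input_ng one of the configured dilution levels.
#' @param cfg the [simConfig()] (defaults to the one stored in `truth`).
#' @return a data.frame with one row per record: `sample_id`,
#'   `individual_id`, `input_ng`, `snp_id`, `true_genotype`, `dropout`,
#'   `theta` (radians), `theta_norm`, `r`, `x`, `y`.
#' @export
simulateIntensities <- function(truth, input_ng, cfg = truth$cfg) {
  stopifnot(inherits(truth, "SimTruth"))
  if (!input_ng %in% cfg$dilution_levels_ng)
    stop("input_ng = ", input_ng, " is not a configured dilution level")
  set.seed(cfg$seed + 1000L * match(input_ng, cfg$dilution_levels_ng))
  n <- nrow(truth$genotypes); ids <- colnames(truth$genotypes)
  centers <- c(0, pi / 4, pi / 2)
  sd_th <- .theta_sd(cfg, input_ng)
  rl <- .r_laws(cfg, input_ng)
  p_drop <- .het_dropout_p(cfg, input_ng)

  out <- lapply(ids, function(ind) {
    g <- truth$genotypes[, ind]
    mu <- centers[g + 1L] + truth$snps$probe_offset
    dropout <- g == 1L & runif(n) < p_drop
    if (any(dropout)) {
      side <- sample(c(0, pi / 2), sum(dropout), replace = TRUE)
      shrink <- runif(sum(dropout), cfg$dropout_shrink[1], cfg$dropout_shrink[2])
      mu[dropout] <- (1 - shrink) * (pi / 4) + shrink * side +
        truth$snps$probe_offset[dropout]
    }
    mu <- pmin(pmax(mu, 0), pi / 2)
    theta <- .rtruncnorm(n, mu, sd_th)
    r <- rlnorm(n, rl$meanlog, rl$sdlog)
    r[dropout] <- r[dropout] * cfg$dropout_r_factor
    x <- r * cos(theta) / (cos(theta) + sin(theta))
    data.table(
      sample_id = paste0(ind, "_", format(input_ng, trim = TRUE), "ng"),
      individual_id = ind, input_ng = input_ng,
      snp_id = truth$snps$snp_id,
      true_genotype = GENO_LEVELS[g + 1L],
      dropout = dropout,
      theta = theta, theta_norm = theta / (pi / 2),
      r = r, x = x, y = r - x
    )
  })
  setDF(rbindlist(out))
}

#' Surrogate platform caller
#'
#' A stand-in for the proprietary on-platform clustering: each record is
#' assigned the genotype of the nearest cluster center in theta (centers
#' include the per-SNP probe offset), with a surrogate GenCall score that
#' decays linearly from 1 at a center to 0 at the midpoint between centers
#' (`gencall = max(0, 1 - d / (pi/8))`). Calls under the no-call threshold
#' become NC. Deterministic given the intensities.
#'
#' @param records intensity records from [simulateIntensities()].
#' @param truth the `SimTruth` (for the per-SNP probe offsets).
#' @param cfg the [simConfig()].
#' @return `records` with columns `gs_call` and `gencall` added.
#' @export
surrogatePlatformCalls <- function(records, truth, cfg = truth$cfg) {
  off <- truth$snps$probe_offset[match(records$snp_id, truth$snps$snp_id)]
  centers <- c(0, pi / 4, pi / 2)
  d <- vapply(1:3, function(k)
    abs(records$theta - pmin(pmax(centers[k] + off, 0), pi / 2)),
    numeric(nrow(records)))
  nearest <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(nrow(d)), nearest)]
  gencall <- pmax(0, 1 - dmin / (pi / 8))
  gs_call <- GENO_LEVELS[nearest]
  gs_call[gencall < cfg$nc_score_threshold] <- "NC"
  records$gs_call <- gs_call
  records$gencall <- gencall
  records
}

#' Simulate a full dilution-series experiment
#'
#' Generates pedigree genotypes, intensities at every configured dilution
#' level, and surrogate platform calls, assembled into an
#' [IntensitySet-class]. The highest input level is flagged as each
#' individual's ground-truth run. The `SimTruth` is stored in
#' `metadata(x)$truth`.
#'
#' @param cfg a [simConfig()].
#' @return an [IntensitySet-class] with `length(dilution_levels_ng)`
#'   columns per individual.
#' @export
simulateArrayData <- function(cfg = simConfig()) {
  truth <- simulateGenotypes(cfg)
  recs <- rbindlist(lapply(cfg$dilution_levels_ng, function(lv)
    surrogatePlatformCalls(simulateIntensities(truth, lv, cfg), truth, cfg)))

  ids <- colnames(truth$genotypes)
  samples <- data.frame(
    sample_id = unlist(lapply(cfg$dilution_levels_ng, function(lv)
      paste0(ids, "_", format(lv, trim = TRUE), "ng"))),
    individual_id = rep(ids, times = length(cfg$dilution_levels_ng)),
    dna_input_ng = rep(cfg$dilution_levels_ng, each = length(ids)),
    is_truth = rep(cfg$dilution_levels_ng == max(cfg$dilution_levels_ng),
                   each = length(ids))
  )
  n <- cfg$n_snps
  i <- match(recs$snp_id, truth$snps$snp_id)
  j <- match(recs$sample_id, samples$sample_id)
  idx <- cbind(i, j)
  mk <- function(v, int = FALSE) {
    m <- matrix(if (int) NA_integer_ else NA_real_, n, nrow(samples))
    m[idx] <- v
    m
  }
  assays <- list(X = mk(recs$x), Y = mk(recs$y), R = mk(recs$r),
                 Theta = mk(recs$theta_norm), GenCall = mk(recs$gencall),
                 GSCall = mk(genoToDosage(recs$gs_call), int = TRUE))
  rowdat <- truth$snps[c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                         "gentrain", "cluster_sep")]
  IntensitySet(assays, rowData = rowdat, colData = samples,
               metadata = list(truth = truth,
                               dropout = mk(as.numeric(recs$dropout))))
}

#' True genotype labels of a simulation
#'
#' @param truth a `SimTruth`.
#' @return data.frame `individual_id`, `snp_id`, `truth_genotype` — the
#'   simulated truth (as opposed to the platform calls of the truth run,
#'   see [buildTruth()]).
#' @export
simTruthLabels <- function(truth) {
  stopifnot(inherits(truth, "SimTruth"))
  data.frame(
    individual_id = rep(colnames(truth$genotypes),
                        each = nrow(truth$genotypes)),
    snp_id = rep(truth$snps$snp_id, times = ncol(truth$genotypes)),
    truth_genotype = GENO_LEVELS[as.vector(truth$genotypes) + 1L]
  )
}

#' Write a simulated fixture to disk
#'
#' Emits a final-report-dialect TSV (`final_report.tsv`, with
#' `[Header]`/`[Data]` sections), a `manifest.csv` and a `truth.tsv` into
#' `dir`. Numeric fields are written with 17 significant digits so that
#' [readFinalReport()] round-trips every value bit-exactly; a fixed seed
#' yields byte-identical files.
#'
#' @param x an [IntensitySet-class] from [simulateArrayData()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- recordTable(x)
  num <- function(v) sprintf("%.17g", v)
  rep_dt <- data.table(
    `SNP Name` = rec$snp_id, `Sample ID` = rec$sample_id,
    Chr = rec$chrom, Position = rec$pos,
    `Allele1 - AB` = rec$allele_a, `Allele2 - AB` = rec$allele_b,
    X = num(rec$x), Y = num(rec$y), R = num(rec$r),
    Theta = num(rec$theta_norm),
    `GC Score` = num(rec$gencall), `GT Score` = num(rec$gentrain),
    `Cluster Sep` = num(rec$cluster_sep), Call = rec$gs_call
  )
  report <- file.path(dir, "final_report.tsv")
  writeLines(c("[Header]",
               paste0("Processing Date\t", "simulated"),
               paste0("Num SNPs\t", nrow(x)),
               paste0("Num Samples\t", ncol(x)),
               "[Data]"), report)
  fwrite(rep_dt, report, sep = "\t", append = TRUE, col.names = TRUE,
         quote = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  fwrite(as.data.table(sampleManifest(x)), manifest)
  truth_path <- file.path(dir, "truth.tsv")
  tr <- metadata(x)$truth
  if (!is.null(tr))
    fwrite(as.data.table(simTruthLabels(tr)), truth_path, sep = "\t")
  invisible(c(report = report, manifest = manifest, truth = truth_path))
}
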