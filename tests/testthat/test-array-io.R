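test_that("final-report parsing joins the manifest and drops bad rows", {
  dir <- withr::local_tempdir()
  manifest <- data.frame(sample_id = c("s1", "s2"),
                         individual_id = c("i1", "i2"),
                         dna_input_ng = c(50, 1), is_truth = c(TRUE, FALSE))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)

  hdr <- paste("SNP Name", "Sample ID", "Chr", "Position", "Allele1 - AB",
               "Allele2 - AB", "X", "Y", "R", "Theta", "GC Score",
               "GT Score", "Cluster Sep", "Call", sep = "\t")
  row1 <- paste("rs1", "s1", "1", "123", "A", "B", "0.5", "0.5", "1.0",
                "0.5", "0.9", "0.8", "0.7", "AB", sep = "\t")
  row2 <- paste("rs2", "s2", "2", "456", "A", "B", "1.0", "0.0", "1.0",
                "0.0", "0.8", "0.8", "0.7", "AA", sep = "\t")
  path <- file.path(dir, "report.tsv")
  writeLines(c(hdr, row1, row2), path)

  x <- readFinalReport(path, readManifest(mpath))
  expect_s4_class(x, "IntensitySet")
  rec <- recordTable(x)
  expect_equal(nrow(rec), 2)
  expect_equal(S4Vectors::metadata(x)$n_dropped_rows, 0)
  expect_equal(rec$theta_norm[rec$snp_id == "rs1"], 0.5)
  expect_equal(rec$individual_id, c("i1", "i2"))

  # unparseable numeric -> row dropped and counted
  row3 <- paste("rs3", "s1", "3", "789", "A", "B", "1.0", "0.0", "1.0",
                "NaN", "0.8", "0.8", "0.7", "AA", sep = "\t")
  writeLines(c(hdr, row1, row2, row3), path)
  expect_message(x2 <- readFinalReport(path, readManifest(mpath)),
                 "dropped 1")
  expect_equal(S4Vectors::metadata(x2)$n_dropped_rows, 1)
  expect_equal(nrow(recordTable(x2)), 2)

  # missing mandatory column -> hard error naming it
  writeLines(c(sub("\tTheta", "\tSomething", hdr), row1), path)
  expect_error(readFinalReport(path, readManifest(mpath)), "Theta")

  # sample absent from manifest -> hard error listing the ID
  writeLines(c(hdr, sub("\ts1\t", "\tghost\t", row1)), path)
  expect_error(readFinalReport(path, readManifest(mpath)), "ghost")
})

test_that("a missing R column is recomputed as X + Y", {
  dir <- withr::local_tempdir()
  manifest <- data.frame(sample_id = "s1", individual_id = "i1",
                         dna_input_ng = 50, is_truth = TRUE)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)

  hdr_full <- paste("SNP Name", "Sample ID", "Chr", "Position", "X", "Y",
                    "R", "Theta", "GC Score", "GT Score", "Cluster Sep",
                    "Call", sep = "\t")
  hdr_nor <- paste("SNP Name", "Sample ID", "Chr", "Position", "X", "Y",
                   "Theta", "GC Score", "GT Score", "Cluster Sep", "Call",
                   sep = "\t")
  vals <- list(c("rs1", "s1", "1", "1", "0.25", "0.5", "0.75", "0.7",
                 "0.9", "0.8", "0.7", "AB"),
               c("rs2", "s1", "1", "2", "1.25", "0.25", "1.5", "0.1",
                 "0.9", "0.8", "0.7", "AA"))
  p_full <- file.path(dir, "full.tsv"); p_nor <- file.path(dir, "nor.tsv")
  writeLines(c(hdr_full, vapply(vals, paste, "", collapse = "\t")), p_full)
  writeLines(c(hdr_nor,
               vapply(vals, function(v) paste(v[-7], collapse = "\t"), "")),
             p_nor)
  m <- readManifest(mpath)
  full <- recordTable(readFinalReport(p_full, m))
  nor <- recordTable(readFinalReport(p_nor, m))
  expect_equal(nor$r, full$r)
  expect_equal(nor, full)

  # R + Theta without channels: tolerated, x/y left unset
  hdr_rt <- paste("SNP Name", "Sample ID", "Chr", "Position", "R", "Theta",
                  "GC Score", "GT Score", "Cluster Sep", "Call", sep = "\t")
  p_rt <- file.path(dir, "rt.tsv")
  writeLines(c(hdr_rt,
               vapply(vals, function(v) paste(v[-(5:6)], collapse = "\t"), "")),
             p_rt)
  rt <- recordTable(readFinalReport(p_rt, m))
  expect_equal(rt$r, full$r)
  expect_equal(rt$theta_norm, full$theta_norm)
  expect_true(all(is.na(rt$x)) && all(is.na(rt$y)))
})

test_that("manifest validation rejects bad inputs", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.csv")
  write.csv(data.frame(sample_id = c("a", "b"), individual_id = c("i", "i"),
                       dna_input_ng = c(50, 50),
                       is_truth = c(TRUE, TRUE)), p, row.names = FALSE)
  expect_error(readManifest(p), "is_truth")
  write.csv(data.frame(sample_id = "a", individual_id = "i",
                       dna_input_ng = -1, is_truth = TRUE), p,
             row.names = FALSE)
  expect_error(readManifest(p), "positive")
})

test_that("VCF output encodes GT/GQ/PL per convention", {
  sites <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                      chrom = c("1", "1", "2"), pos = c(10L, 5L, 1L),
                      allele_a = c("A", "C", "G"), allele_b = c("T", "G", "A"))
  calls <- data.frame(
    sample_id = "s1", snp_id = c("rs1", "rs2", "rs3"),
    p_AA = c(1, 0.1, 1 / 3), p_AB = c(0, 0.8, 1 / 3), p_BB = c(0, 0.1, 1 / 3),
    call = c("AA", "AB", "NC")
  )
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeRecallVcf(calls, sites, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 3)
  fields <- do.call(rbind, strsplit(body, "\t"))
  # sorted by chrom then pos: rs2 (1:5), rs1 (1:10), rs3 (2:1)
  expect_equal(fields[, 3], c("rs2", "rs1", "rs3"))
  gt <- setNames(fields[, 10], fields[, 3])
  # certainty: floored probabilities give PL 0,990,990 and capped GQ
  expect_equal(gt[["rs1"]], "0/0:99:0,990,990")
  # -10log10(0.1) - -10log10(0.8) = 9.03 -> 9
  expect_equal(gt[["rs2"]], "0/1:7:9,0,9")
  expect_equal(gt[["rs3"]], "./.:.:.")
  expect_error(writeRecallVcf(transform(calls, snp_id = "nope"), sites, vcf),
               "unknown site")
})

test_that("VCF output is parseable by an independent VCF reader", {
  skip_if_not_installed("vcfR")
  sim <- sim_small()
  flt <- qcFilter(sim$x)
  feats <- buildFeatures(flt$kept)
  feats1 <- feats[feats$sample_id == feats$sample_id[1], ][1:50, ]
  calls <- data.frame(sample_id = feats1$sample_id, snp_id = feats1$snp_id,
                      p_AA = 0.9, p_AB = 0.05, p_BB = 0.05, call = "AA")
  calls$call[1:5] <- "NC"
  sites <- as.data.frame(SummarizedExperiment::rowData(flt$kept))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeRecallVcf(calls, sites[c("snp_id", "chrom", "pos", "allele_a",
                                "allele_b")], vcf)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_equal(nrow(v@gt), 50)
  gt <- vcfR::extract.gt(v)
  expect_equal(sum(!is.na(gt) & gt != "./."), 45)
})

test_that("simulator fixtures round-trip through the reader bit-exactly", {
  sim <- sim_small()
  dir <- withr::local_tempdir()
  paths <- writeFixture(sim$x, dir)
  m <- readManifest(paths[["manifest"]])
  x2 <- readFinalReport(paths[["report"]], m)
  rec1 <- recordTable(sim$x)
  rec2 <- recordTable(x2)
  key <- function(d) order(d$sample_id, d$snp_id)
  rec1 <- rec1[key(rec1), ]; rec2 <- rec2[key(rec2), ]
  rownames(rec1) <- rownames(rec2) <- NULL
  for (col in c("x", "y", "r", "theta_norm", "gencall", "gentrain",
                "cluster_sep"))
    expect_identical(rec2[[col]], rec1[[col]], label = col)
  expect_identical(rec2$gs_call, rec1$gs_call)

  # same seed -> byte-identical files
  dir2 <- withr::local_tempdir()
  x3 <- simulateArrayData(sim$cfg)
  paths3 <- writeFixture(x3, dir2)
  expect_identical(readLines(paths3[["report"]]), readLines(paths[["report"]]))
})
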