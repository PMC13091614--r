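test_that("founder genotypes follow Hardy-Weinberg proportions", {
  ped <- data.frame(id = "solo", mother = NA, father = NA)
  cfg <- simConfig(n_snps = 1e5L, allele_freq_range = c(0.5, 0.5),
                   pedigree = ped, seed = 31L)
  truth <- simulateGenotypes(cfg)
  freqs <- tabulate(truth$genotypes[, 1] + 1L, 3) / 1e5
  expect_equal(freqs, c(0.25, 0.5, 0.25), tolerance = 0.04)
})

test_that("offspring genotypes are Mendelian-consistent", {
  cfg <- simConfig(n_snps = 3000L, seed = 5L)
  truth <- simulateGenotypes(cfg)
  G <- truth$genotypes
  ped <- truth$pedigree
  for (k in which(!is.na(ped$mother))) {
    gm <- G[, ped$mother[k]]; gf <- G[, ped$father[k]]; go <- G[, ped$id[k]]
    # child dosage must lie within reachable range of parental dosages
    lo <- pmax(0L, (gm > 1) + (gf > 1))
    hi <- 2L - pmax(0L, (gm < 1) + (gf < 1))
    expect_true(all(go >= lo & go <= hi), label = ped$id[k])
  }
  # AA x AA -> all offspring AA
  ped2 <- data.frame(id = c("m", "f", "c"), mother = c(NA, NA, "m"),
                     father = c(NA, NA, "f"))
  cfg2 <- simConfig(n_snps = 500L, allele_freq_range = c(1e-9, 1e-9),
                    pedigree = ped2, seed = 6L)
  t2 <- simulateGenotypes(cfg2)
  expect_true(all(t2$genotypes == 0L))
  # cyclic pedigrees are rejected
  bad <- data.frame(id = c("a", "b"), mother = c("b", "a"),
                    father = c(NA, NA))
  expect_error(simulateGenotypes(simConfig(pedigree = bad)), "cyclic")
})

test_that("the noiseless limit concentrates records at cluster centers", {
  cfg <- simConfig(n_snps = 300L, theta_sd_range = c(1e-9, 1e-9),
                   probe_offset_sd = 1e-9, het_dropout_max = 0, seed = 8L)
  truth <- simulateGenotypes(cfg)
  rec <- simulateIntensities(truth, 50, cfg)
  centers <- c(AA = 0, AB = pi / 4, BB = pi / 2)
  expect_equal(rec$theta, unname(centers[rec$true_genotype]),
               tolerance = 1e-6)
  # channel split is consistent: x + y = r and atan2 recovers theta
  expect_equal(rec$x + rec$y, rec$r, tolerance = 1e-12)
  expect_equal(atan2(rec$y, rec$x), rec$theta, tolerance = 1e-9)
  expect_equal(rec$theta_norm, rec$theta / (pi / 2))
})

test_that("degradation laws move intensity down and angle noise up", {
  sim <- sim_small()
  truth <- sim$truth; cfg <- sim$cfg
  centers <- c(AA = 0, AB = pi / 4, BB = pi / 2)
  stats <- lapply(cfg$dilution_levels_ng, function(lv) {
    rec <- simulateIntensities(truth, lv, cfg)
    rec <- rec[!rec$dropout, ]
    resid <- rec$theta - (centers[rec$true_genotype] +
      truth$snps$probe_offset[match(rec$snp_id, truth$snps$snp_id)])
    c(mean_r = mean(rec$r), var_resid = var(resid))
  })
  mean_r <- vapply(stats, `[[`, 0, "mean_r")
  var_resid <- vapply(stats, `[[`, 0, "var_resid")
  # levels are ordered high -> low input
  expect_true(all(diff(mean_r) < 0))
  expect_true(all(diff(var_resid) > 0))
  # sign structure of the input/intensity relationships
  lv <- log10(cfg$dilution_levels_ng)
  expect_gt(cor(lv, mean_r), 0)
  expect_lt(cor(lv, var_resid), 0)
})

test_that("dropout flags only true heterozygotes and tracks the input law", {
  sim <- sim_small()
  rec_lo <- simulateIntensities(sim$truth, 0.01, sim$cfg)
  expect_true(all(rec_lo$true_genotype[rec_lo$dropout] == "AB"))
  rec_hi <- simulateIntensities(sim$truth, 50, sim$cfg)
  expect_equal(sum(rec_hi$dropout), 0)
  frac_lo <- mean(rec_lo$dropout[rec_lo$true_genotype == "AB"])
  expect_equal(frac_lo, 0.25, tolerance = 0.15)
})

test_that("surrogate platform calls behave like a nearest-center caller", {
  cfg <- simConfig(n_snps = 400L, theta_sd_range = c(1e-9, 1e-9),
                   probe_offset_sd = 1e-9, het_dropout_max = 0, seed = 9L)
  truth <- simulateGenotypes(cfg)
  rec <- surrogatePlatformCalls(simulateIntensities(truth, 50, cfg), truth)
  expect_equal(rec$gs_call, rec$true_genotype)
  expect_true(all(rec$gencall > 0.99))

  # a record exactly between two centers has minimal score and goes NC
  rec2 <- rec[1:2, ]
  rec2$theta <- c(pi / 8, 3 * pi / 8)
  rec2 <- surrogatePlatformCalls(rec2, truth)
  expect_true(all(rec2$gencall < 0.01))
  expect_equal(rec2$gs_call, c("NC", "NC"))

  # call rate declines across the dilution series
  sim <- sim_small()
  cr <- vapply(c(50, 0.01), function(lv) {
    r <- surrogatePlatformCalls(simulateIntensities(sim$truth, lv, sim$cfg),
                                sim$truth)
    mean(r$gs_call != "NC")
  }, numeric(1))
  expect_lt(cr[2], cr[1])
})

test_that("simulated experiments assemble into a valid IntensitySet", {
  sim <- sim_small()
  expect_s4_class(sim$x, "IntensitySet")
  expect_true(methods::validObject(sim$x))
  cd <- SummarizedExperiment::colData(sim$x)
  expect_equal(nrow(cd), 8 * 6)
  expect_equal(sum(cd$is_truth), 8)
  expect_equal(unique(cd$dna_input_ng[cd$is_truth]), 50)
  # truth table rows = individuals x SNPs
  expect_equal(nrow(simTruthLabels(sim$truth)), 8 * sim$cfg$n_snps)
  # determinism: regenerating with the same config is identical
  x2 <- simulateArrayData(sim$cfg)
  expect_identical(SummarizedExperiment::assay(x2, "Theta"),
                   SummarizedExperiment::assay(sim$x, "Theta"))
})
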