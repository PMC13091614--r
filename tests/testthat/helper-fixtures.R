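# Shared fixtures, built in code.

# A tiny deterministic IntensitySet: 4 SNPs x 2 samples of one individual
# (50 ng truth run + 1 ng run), exact-decimal values.
tiny_iset <- function() {
  snps <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = c("1", "2", "2", "3"), pos = c(100L, 200L, 300L, 400L),
    allele_a = c("A", "C", "G", "T"), allele_b = c("G", "T", "A", "C"),
    gentrain = c(0.9, 0.8, 0.7, 0.6), cluster_sep = c(0.5, 0.6, 0.7, 0.8)
  )
  manifest <- data.frame(
    sample_id = c("ind1_50ng", "ind1_1ng"),
    individual_id = c("ind1", "ind1"),
    dna_input_ng = c(50, 1), is_truth = c(TRUE, FALSE)
  )
  X <- matrix(c(2, 1, 0.5, 0.25, 1.5, 0.75, 0.25, 0.125), 4, 2)
  Y <- matrix(c(0.5, 1, 0.25, 2, 0.25, 0.75, 0.125, 1.5), 4, 2)
  theta <- (2 / pi) * atan2(Y, X)
  gs <- matrix(c(0L, 1L, 0L, 2L, 0L, 1L, NA, 2L), 4, 2)
  IntensitySet(
    assays = list(X = X, Y = Y, R = X + Y, Theta = theta,
                  GenCall = matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2),
                                   4, 2),
                  GSCall = gs),
    rowData = snps, colData = manifest
  )
}

# Small simulated dilution grid, computed once per test session.
.sim_cache <- new.env(parent = emptyenv())
sim_small <- function() {
  if (is.null(.sim_cache$x)) {
    .sim_cache$cfg <- simConfig(n_snps = 800L, seed = 42L)
    .sim_cache$x <- simulateArrayData(.sim_cache$cfg)
  }
  list(x = .sim_cache$x, cfg = .sim_cache$cfg,
       truth = S4Vectors::metadata(.sim_cache$x)$truth)
}

# Perfectly separable three-cluster fixture in feature space: theta noise
# sigma -> 0, distinct r per genotype. Returns labeled examples.
separable_examples <- function(n_per_class = 60, inds = paste0("i", 1:6),
                               seed = 1) {
  set.seed(seed)
  centers <- c(AA = 0, AB = pi / 4, BB = pi / 2)
  rows <- do.call(rbind, lapply(names(centers), function(g) {
    n <- n_per_class
    theta <- pmin(pmax(centers[[g]] + rnorm(n, 0, 1e-4), 0), pi / 2)
    r <- 2 + rnorm(n, 0, 1e-3)
    data.frame(individual_id = sample(inds, n, replace = TRUE),
               snp_id = paste0("s", seq_len(n), "_", g),
               sample_id = "s1", dna_input_ng = 1,
               gs_call = g, truth_genotype = g,
               theta = theta, r = r,
               gencall = runif(n, 0.85, 0.95),
               gentrain = runif(n, 0.85, 0.95),
               cluster_sep = runif(n, 0.85, 0.95))
  }))
  n_all <- nrow(rows)
  ae <- angleErrors(rows$theta)
  sa <- subtendedArcs(rows$r, rows$theta)
  x <- rows$r * cos(rows$theta) / (cos(rows$theta) + sin(rows$theta))
  # sample summaries as distributionally stable nuisance features
  cbind(rows, ae, sa,
        data.frame(x = x, y = rows$r - x,
                   sample_mean_r = rnorm(n_all, 2, 0.05),
                   sample_var_r = rnorm(n_all, 0.1, 0.01)))
}
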