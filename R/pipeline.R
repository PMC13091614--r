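#' End-to-end training run
#'
#' Orchestrates the full training workflow on one experiment: QC ->
#' feature engineering -> truth labeling -> phase-1 model selection on a
#' balanced down-sample (grid search with group-wise CV) -> phase-2 final
#' fit on all training data with class reweighting. Artifacts (model
#' directory, fold scores, QC report) are written under `out_dir` when
#' given.
#'
#' @param x an [IntensitySet-class] (real or simulated).
#' @param family model family (`"gbt"`, `"rmlr"`, `"nn"`).
#' @param grid hyperparameter grid for [gridSearch()]; an empty list fits
#'   the family defaults.
#' @param test_individuals individuals held out entirely from training.
#' @param n_folds CV folds (default: number of training individuals, i.e.
#'   leave-one-individual-out).
#' @param seed integer seed.
#' @param qc a [qcConfig()].
#' @param out_dir optional output directory for artifacts.
#' @return list with `model` (the final `TrainedModel`), `search` (grid
#'   scores), `qc_report`, `truth`, `examples_train`, `examples_test`.
#' @export
runTrain <- function(x, family = "gbt", grid = list(),
                     test_individuals, n_folds = NULL, seed = 1L,
                     qc = qcConfig(), out_dir = NULL) {
  flt <- qcFilter(x, qc)
  feats <- buildFeatures(flt$kept)
  truth <- buildTruth(flt$kept)
  examples <- makeExamples(feats, truth)
  sp <- splitByIndividual(examples, test_individuals)
  n_train_ind <- length(unique(sp$train$individual_id))
  if (is.null(n_folds)) n_folds <- n_train_ind

  phase1 <- downsampleBalanced(sp$train, seed = seed)
  message("phase 1: ", nrow(phase1), " balanced examples (",
          sum(phase1$gs_call == phase1$truth_genotype), " correct / ",
          sum(phase1$gs_call != phase1$truth_genotype), " incorrect)")
  search <- gridSearch(family, grid, phase1, n_folds = n_folds, seed = seed)
  model <- fitFinal(family, search$best, sp$train)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveModel(model, file.path(out_dir, "model"))
    fwrite(as.data.table(search$scores), file.path(out_dir, "cv_scores.tsv"),
           sep = "\t")
    fwrite(data.table(rule = names(flt$report), n = as.integer(flt$report)),
           file.path(out_dir, "qc_report.tsv"), sep = "\t")
    jsonlite::write_json(
      list(seed = seed, family = family, n_folds = n_folds,
           test_individuals = test_individuals,
           best_params = search$best$params,
           data_hash = model$meta$data_hash,
           version = as.character(packageVersion("snprecall")),
           r_version = R.version.string),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(model = model, search = search, qc_report = flt$report, truth = truth,
       examples_train = sp$train, examples_test = sp$test)
}

#' End-to-end calling run
#'
#' Applies a trained model to an experiment: QC -> features -> posterior
#' prediction -> Phred filter (and optional concordance filter) -> VCF.
#' Records below the threshold, and platform-style no-calls, appear in the
#' VCF as `./.`.
#'
#' @param x an [IntensitySet-class].
#' @param model a `TrainedModel`.
#' @param threshold minimum Phred genotype quality (default 0: keep all).
#' @param concordance if `TRUE`, additionally require agreement with the
#'   platform call (see [concordanceFilter()]).
#' @param vcf_file optional VCF output path.
#' @param qc a [qcConfig()].
#' @return list with `calls` (all posteriors, plus `retained` flag),
#'   `retained` (the filtered call set) and `audit` (per-record filter
#'   decisions).
#' @export
runCall <- function(x, model, threshold = 0, concordance = FALSE,
                    vcf_file = NULL, qc = qcConfig()) {
  flt <- qcFilter(x, qc)
  feats <- buildFeatures(flt$kept)
  calls <- predictProba(model, feats)
  calls$gs_call <- feats$gs_call
  calls$gencall <- feats$gencall_score

  retained <- phredFilter(calls, threshold)
  if (concordance) retained <- concordanceFilter(retained, retained)
  keep_key <- paste(retained$sample_id, retained$snp_id)
  calls$retained <- paste(calls$sample_id, calls$snp_id) %in% keep_key
  audit <- calls[c("sample_id", "snp_id", "call", "q", "gs_call", "gencall",
                   "retained")]

  if (!is.null(vcf_file)) {
    vc <- calls
    vc$call[!vc$retained] <- "NC"
    sites <- as.data.frame(rowData(flt$kept))[
      c("snp_id", "chrom", "pos", "allele_a", "allele_b")]
    writeRecallVcf(vc, sites, vcf_file)
  }
  list(calls = calls, retained = retained, audit = audit)
}

#' Evaluate calls across the dilution grid
#'
#' Produces the study's evaluation shape — one row per (DNA input, Phred
#' threshold) — for both the recaller and the platform, against a truth
#' table. Because GenCall scores are not probabilities, the two methods
#' are compared on *equal-cardinality rank-matched sets*: at each
#' threshold, `k = min(#recaller calls with q >= threshold, #platform
#' called sites)`, and the comparison takes the recaller's top `k` calls
#' by Phred quality against the platform's top `k` calls by GenCall
#' score.
#'
#' @param calls posterior calls with `sample_id`, `individual_id`,
#'   `dna_input_ng`, `snp_id`, `call`, `q`, `gs_call`, `gencall` (as
#'   returned by [runCall()]`$calls`).
#' @param truth truth labels (`individual_id`, `snp_id`,
#'   `truth_genotype`).
#' @param thresholds Phred thresholds (default `c(0, 10, 20, 30)`).
#' @param n_chip_sites absolute call-rate denominator (`NA` to skip).
#' @return data.frame with one row per input x threshold x method
#'   (`recaller` / `platform`): call rates, accuracy, per-class F1. The
#'   attribute `sign_test` holds exact paired sign tests (see
#'   [pairedSignTest()]) of recaller-minus-platform accuracy and AB-F1
#'   differences across the (input, threshold) strata.
#' @export
runEval <- function(calls, truth, thresholds = c(0, 10, 20, 30),
                    n_chip_sites = NA) {
  dt <- merge(as.data.table(calls), as.data.table(truth),
              by = c("individual_id", "snp_id"))
  rows <- list()
  for (lv in sort(unique(dt$dna_input_ng), decreasing = TRUE)) {
    sub <- dt[dna_input_ng == lv]
    n_input <- nrow(sub)
    for (th in thresholds) {
      rec <- sub[q >= th]
      plat_all <- sub[gs_call %in% GENO_LEVELS]
      k <- min(nrow(rec), nrow(plat_all))
      # equal cardinality by rank on each method's own score
      rec <- as.data.table(rec[order(-rec$q, rec$snp_id), ][seq_len(k), ])
      plat <- rankMatchGenCall(k, as.data.frame(plat_all))
      for (m in c("recaller", "platform")) {
        d <- if (m == "recaller") rec else as.data.table(plat)
        cl <- if (m == "recaller") d$call else d$gs_call
        f1 <- perClassF1(cl, d$truth_genotype)
        rows[[length(rows) + 1L]] <- data.frame(
          dna_input_ng = lv, threshold = th, method = m,
          n_called = nrow(d),
          absolute_call_rate = if (is.na(n_chip_sites)) NA_real_
                               else nrow(d) / n_chip_sites,
          relative_call_rate = nrow(d) / n_input,
          accuracy = genotypeAccuracy(cl, d$truth_genotype),
          f1_AA = f1["AA", "f1"], f1_AB = f1["AB", "f1"],
          f1_BB = f1["BB", "f1"])
      }
    }
  }
  out <- do.call(rbind, rows)
  rec <- out[out$method == "recaller", ]
  plat <- out[out$method == "platform", ]
  d_acc <- rec$accuracy - plat$accuracy
  d_f1 <- rec$f1_AB - plat$f1_AB
  attr(out, "sign_test") <- list(
    p_accuracy = if (any(!is.na(d_acc))) pairedSignTest(d_acc[!is.na(d_acc)])
                 else NA_real_,
    p_f1_AB = if (any(!is.na(d_f1))) pairedSignTest(d_f1[!is.na(d_f1)])
              else NA_real_)
  out
}
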