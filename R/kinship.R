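#' KING-robust kinship coefficient for one pair
#'
#' Estimates pairwise kinship from hard genotype calls using the
#' between-family KING-robust form, which is robust to population
#' structure because it conditions on the less heterozygous individual:
#'
#' \deqn{\phi = \frac{N_{AB,AB} - 2 N_{opp}}{2\,m} + \frac{1}{2} -
#'   \frac{N^{(i)}_{AB} + N^{(j)}_{AB}}{4\,m}, \quad
#'   m = \min(N^{(i)}_{AB}, N^{(j)}_{AB})}
#'
#' where counts run over sites called in both individuals: \eqn{N_{AB,AB}}
#' both heterozygous, \eqn{N_{opp}} opposite homozygotes (AA vs BB), and
#' \eqn{N^{(i)}_{AB}} each individual's heterozygote count. Expected
#' values: 0.5 duplicate/self, 0.25 first-degree, 0.125 second-degree, 0
#' unrelated; genotyping error biases estimates toward 0 for related
#' pairs.
#'
#' @param gt_i,gt_j genotype vectors for the two individuals over the same
#'   sites — character (AA/AB/BB/NC) or dosage (0/1/2, `NA` = no-call).
#'   Sites with a no-call in either individual are excluded pairwise.
#' @param id_i,id_j optional individual identifiers carried into the
#'   result.
#' @return a `KinshipResult` list: `id_i`, `id_j`, `n_shared`, `n_het_i`,
#'   `n_het_j`, `n_both_het`, `n_opp_hom`, `phi`.
#' @export
kingRobust <- function(gt_i, gt_j, id_i = "i", id_j = "j") {
  stopifnot(length(gt_i) == length(gt_j))
  if (is.character(gt_i)) gt_i <- genoToDosage(gt_i)
  if (is.character(gt_j)) gt_j <- genoToDosage(gt_j)
  ok <- !is.na(gt_i) & !is.na(gt_j)
  a <- gt_i[ok]; b <- gt_j[ok]
  n_shared <- length(a)
  if (n_shared == 0) stop("no shared called sites between ", id_i, " and ", id_j)
  n_het_i <- sum(a == 1L); n_het_j <- sum(b == 1L)
  m <- min(n_het_i, n_het_j)
  if (m == 0)
    stop("KING-robust is undefined without heterozygotes in both individuals")
  n_both_het <- sum(a == 1L & b == 1L)
  n_opp_hom <- sum(abs(a - b) == 2L)
  phi <- (n_both_het - 2 * n_opp_hom) / (2 * m) + 0.5 -
    (n_het_i + n_het_j) / (4 * m)
  structure(list(id_i = id_i, id_j = id_j, n_shared = n_shared,
                 n_het_i = n_het_i, n_het_j = n_het_j,
                 n_both_het = n_both_het, n_opp_hom = n_opp_hom, phi = phi),
            class = "KinshipResult")
}

#' @export
print.KinshipResult <- function(x, ...) {
  cat(sprintf("KinshipResult %s ~ %s: phi = %.4f over %d shared sites\n",
              x$id_i, x$id_j, x$phi, x$n_shared))
  invisible(x)
}

#' Pairwise kinship matrix
#'
#' KING-robust estimates for every unordered pair of individuals. Pairs
#' sharing fewer than `min_sites` called sites (or lacking heterozygotes)
#' are reported with `phi = NA`.
#'
#' @param geno genotype matrix, sites x individuals — character
#'   (AA/AB/BB/NC) or dosage codes; column names are the individual IDs.
#' @param min_sites minimum shared called sites for an estimate (default
#'   100).
#' @return a data.frame with one row per pair: `id_i`, `id_j`,
#'   `n_shared`, `n_het_i`, `n_het_j`, `n_both_het`, `n_opp_hom`, `phi`.
#' @export
kinshipMatrix <- function(geno, min_sites = 100) {
  if (is.character(geno)) geno <- genoToDosage(geno)
  ids <- colnames(geno)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(geno)))
  if (ncol(geno) < 2) stop("need at least 2 individuals")
  pairs <- utils::combn(seq_len(ncol(geno)), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    res <- tryCatch(kingRobust(geno[, i], geno[, j], ids[i], ids[j]),
                    error = function(e) NULL)
    if (is.null(res) || res$n_shared < min_sites)
      return(data.frame(id_i = ids[i], id_j = ids[j],
                        n_shared = if (is.null(res)) 0L else res$n_shared,
                        n_het_i = NA_integer_, n_het_j = NA_integer_,
                        n_both_het = NA_integer_, n_opp_hom = NA_integer_,
                        phi = NA_real_))
    data.frame(id_i = res$id_i, id_j = res$id_j, n_shared = res$n_shared,
               n_het_i = res$n_het_i, n_het_j = res$n_het_j,
               n_both_het = res$n_both_het, n_opp_hom = res$n_opp_hom,
               phi = res$phi)
  })
  do.call(rbind, rows)
}
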