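#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (ties resolved with a small relative tolerance).
#'
#' @param a,b,c,d non-negative integer cells (rows are groups, columns are
#'   allele or genotype classes), or a 2x2 matrix as \code{a}.
#' @return numeric(1) p-value.
#' @examples
#' fisherExactTwoSided(2, 0, 0, 2)  # 1/3
#' @export
fisherExactTwoSided <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), nrow = 2L)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (sum(tab) == 0L) stop("undefined input: all-zero table")
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: \code{q(i) = min over j >= i of p(j) * n / j} in
#' rank order, capped at 1, returned in input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as input.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Per-SNP allele-frequency association between phenotype groups
#'
#' For each SNP, alternative- vs reference-allele counts by group (alleles =
#' 2 x accessions) form a 2x2 table tested with the two-sided Fisher exact
#' test; q-values control the FDR across all SNPs. SNPs monomorphic in both
#' groups combined are assigned p = 1 and flagged.
#'
#' @param panel a list as returned by \code{\link{simulateSnpPanel}}:
#'   \code{positions}, \code{genotypes} (accessions x SNPs dosages 0/1/2),
#'   \code{group} (\code{"flat"}/\code{"round"} per accession).
#' @return A data.frame with columns \code{position}, \code{alt_freq_flat},
#'   \code{alt_freq_round}, \code{p}, \code{q}, \code{monomorphic}.
#' @export
snpAssociation <- function(panel) {
  geno <- panel$genotypes
  grp <- panel$group
  if (!all(grp %in% c("flat", "round")) ||
      !any(grp == "flat") || !any(grp == "round"))
    stop("both groups must be non-empty")
  if (nrow(geno) != length(grp)) stop("genotype/group dimension mismatch")
  flat <- geno[grp == "flat", , drop = FALSE]
  rnd <- geno[grp == "round", , drop = FALSE]
  nF <- 2L * nrow(flat); nR <- 2L * nrow(rnd)
  altF <- colSums(flat); altR <- colSums(rnd)
  mono <- (altF + altR) == 0L | (altF + altR) == (nF + nR)
  p <- vapply(seq_len(ncol(geno)), function(j) {
    if (mono[j]) return(1)
    fisherExactTwoSided(altF[j], nF - altF[j], altR[j], nR - altR[j])
  }, numeric(1))
  data.frame(position = panel$positions,
             alt_freq_flat = altF / nF,
             alt_freq_round = altR / nR,
             p = p, q = bhAdjust(p), monomorphic = mono)
}

#' Chi-square goodness-of-fit test of Mendelian segregation
#'
#' Tests observed genotype-class counts against an expected ratio (e.g. 1:1
#' or 1:2:1), with expected counts proportional to the ratio and
#' \code{df = k - 1}.
#'
#' @param observed integer counts per class (length >= 2, total > 0).
#' @param expectedRatio positive reals, same length.
#' @return A list with \code{observed}, \code{expected}, \code{chi2},
#'   \code{df}, \code{p}.
#' @examples
#' segregationChisq(c(71, 58), c(1, 1))      # chi2 ~ 1.31, p ~ 0.25
#' segregationChisq(c(3, 13, 8), c(1, 2, 1)) # chi2 = 2.25, p ~ 0.32
#' @export
segregationChisq <- function(observed, expectedRatio) {
  if (length(observed) != length(expectedRatio) || length(observed) < 2L)
    stop("'observed' and 'expectedRatio' must have equal length >= 2")
  if (any(expectedRatio <= 0)) stop("expected ratio classes must be positive")
  if (sum(observed) <= 0) stop("total observed count must be positive")
  expected <- sum(observed) * expectedRatio / sum(expectedRatio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(observed = observed, expected = expected, chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Check genotype-phenotype co-segregation
#'
#' Perfect co-segregation means every flat accession is H1H2, every round
#' accession H1H1, and every fruit-aborting accession H2H2. No-calls are
#' listed separately and do not count as discordant.
#'
#' @param calls data.frame with columns \code{id} and \code{genotype}
#'   (values H1H1/H1H2/H2H2/no_call).
#' @param phenotypes data.frame with columns \code{id} and \code{phenotype}
#'   (values flat/round/aborted); ids must match \code{calls$id}.
#' @return A list with \code{perfect} (logical), \code{discordant}
#'   (character ids) and \code{no_calls} (character ids).
#' @export
cosegregationCheck <- function(calls, phenotypes) {
  if (!setequal(calls$id, phenotypes$id) ||
      length(calls$id) != length(phenotypes$id))
    stop("id mismatch between calls and phenotypes")
  ph <- phenotypes$phenotype[match(calls$id, phenotypes$id)]
  expected <- c(flat = "H1H2", round = "H1H1", aborted = "H2H2")[ph]
  noCall <- calls$genotype == "no_call"
  disc <- !noCall & calls$genotype != expected
  list(perfect = !any(disc),
       discordant = calls$id[disc],
       no_calls = calls$id[noCall])
}
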