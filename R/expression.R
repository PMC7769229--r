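#' Transcripts-per-million normalization
#'
#' Per sample, counts are divided by gene length to per-base rates, and
#' rates are scaled to sum to one million. Columns of all-zero counts stay
#' all zero, with a warning.
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @param geneLengths gene lengths in bp (>= 1), one per row.
#' @return A matrix of TPM values, same shape and dimnames as \code{counts}.
#' @export
tpmNormalize <- function(counts, geneLengths) {
  counts <- as.matrix(counts)
  if (length(geneLengths) != nrow(counts))
    stop("'geneLengths' must have one entry per gene")
  if (any(geneLengths < 1)) stop("gene lengths must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / geneLengths
  total <- colSums(rate)
  if (any(total == 0))
    warning("all-zero sample(s): ",
            paste(colnames(counts)[total == 0], collapse = ", "))
  tpm <- sweep(rate, 2L, ifelse(total > 0, total, 1), "/") * 1e6
  tpm[, total == 0] <- 0
  tpm
}

.groupMeans <- function(tpm, groups) {
  if (!any(groups == "FP") || !any(groups == "RP"))
    stop("both FP and RP groups must be non-empty")
  list(fp = rowMeans(tpm[, groups == "FP", drop = FALSE]),
       rp = rowMeans(tpm[, groups == "RP", drop = FALSE]))
}

#' Per-gene log2 fold change of group mean TPM
#'
#' \code{log2((mean FP + pseudocount) / (mean RP + pseudocount))}.
#'
#' @param tpm genes x samples TPM matrix.
#' @param groups per-sample labels \code{"FP"} / \code{"RP"}.
#' @param pseudocount positive stabilizer added to both means (default 1).
#' @return numeric vector of per-gene log2 fold changes (FP over RP).
#' @export
log2FoldChange <- function(tpm, groups, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  m <- .groupMeans(as.matrix(tpm), groups)
  log2((m$fp + pseudocount) / (m$rp + pseudocount))
}

#' Screen for differentially expressed genes
#'
#' TPM-normalizes, computes per-gene log2 fold changes of group means, and
#' tests each gene with a two-sample unequal-variance (Welch) t statistic on
#' \code{log2(TPM + pseudocount)}; q-values are Benjamini-Hochberg across
#' genes. A gene passes when \code{|log2FC| > lfcThreshold} and
#' \code{q < fdrThreshold}. This is a deliberately simple mean/variance
#' screen, not a count-model fit; it is validated by recovery of planted
#' effects in simulation.
#'
#' @param counts genes x samples count matrix.
#' @param geneLengths per-gene lengths in bp.
#' @param groups per-sample labels \code{"FP"} / \code{"RP"}, >= 2 each.
#' @param lfcThreshold log2 fold-change threshold (default 2).
#' @param fdrThreshold FDR threshold (default 0.1).
#' @param pseudocount added before log transforms (default 1).
#' @return A data.frame sorted by \code{q} then decreasing \code{|log2fc|}:
#'   \code{gene_id}, \code{log2fc}, \code{p}, \code{q}, \code{direction},
#'   \code{passes}.
#' @export
degScreen <- function(counts, geneLengths, groups, lfcThreshold = 2,
                      fdrThreshold = 0.1, pseudocount = 1) {
  groups <- as.character(groups)
  if (sum(groups == "FP") < 2L || sum(groups == "RP") < 2L)
    stop("need at least two samples per group")
  counts <- as.matrix(counts)
  tpm <- tpmNormalize(counts, geneLengths)
  lfc <- log2FoldChange(tpm, groups, pseudocount)
  x <- log2(tpm[, groups == "FP", drop = FALSE] + pseudocount)
  y <- log2(tpm[, groups == "RP", drop = FALSE] + pseudocount)
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1L, stats::var); vy <- apply(y, 1L, stats::var)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(tstat) | se2 == 0] <- 1  # zero-variance identical groups
  q <- bhAdjust(p)
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_len(nrow(counts)))
  out <- data.frame(gene_id = ids, log2fc = lfc, p = p, q = q,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    passes = abs(lfc) > lfcThreshold & q < fdrThreshold)
  out <- out[order(out$q, -abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' \code{dCt = ctTarget - ctReference}; \code{ddCt = dCt -
#' calibratorDeltaCt}; relative expression is \code{2^-ddCt}.
#'
#' @param ctTarget,ctReference threshold cycles of target and reference
#'   genes in the sample of interest (vectorized).
#' @param calibratorDeltaCt dCt of the calibrator sample.
#' @return numeric relative expression.
#' @examples
#' deltaDeltaCt(20, 18, 5)  # 8
#' @export
deltaDeltaCt <- function(ctTarget, ctReference, calibratorDeltaCt) {
  if (any(!is.finite(c(ctTarget, ctReference, calibratorDeltaCt))))
    stop("cycle values must be finite")
  2^-((ctTarget - ctReference) - calibratorDeltaCt)
}
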