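# Shared fixtures and independent reference implementations (oracles).

## The worked toy locus: 16-bp H1 with the ACA/GA signature at pb=7, db=12.
toyH1 <- function() GenomeSegment("toy", "TTTTACAATGCCGGGG")
toyPair <- function() buildInvertedHaplotype(toyH1(), InversionSpec(7, 12))
toyJunctions <- function(flank = 4L) buildJunctionSet(toyPair(), flank)

## A desk-scale locus: 30-kb segment with a 20-kb inversion [5000, 25000).
smallLocus <- function(seed = 101L, length = 30000L, pb = 5000L,
                       db = 25000L) {
  ref <- generateReference(length, gc = 0.4, seed = seed, id = "locus")
  planted <- plantInversionSite(ref, pb, db)
  pair <- buildInvertedHaplotype(planted$segment, planted$spec)
  list(pair = pair, junctions = buildJunctionSet(pair, 300L),
       pb = pb, db = db)
}

## Naive character-level reverse complement (oracle for revComp).
naiveRevComp <- function(s) {
  if (!nzchar(s)) return("")
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

## Brute-force IUPAC motif scan, position by position.
iupacTab <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
              S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
              H = "ACT", V = "ACG", N = "ACGT")
bruteMotifScan <- function(seq, motif, bothStrands = FALSE) {
  matchAt <- function(s, m) {
    sc <- strsplit(s, "")[[1]]; mc <- strsplit(m, "")[[1]]
    hits <- integer()
    for (p in seq_len(length(sc) - length(mc) + 1L)) {
      ok <- all(mapply(function(b, code) grepl(b, iupacTab[[code]], fixed = TRUE),
                       sc[p:(p + length(mc) - 1L)], mc))
      if (ok) hits <- c(hits, p - 1L)
    }
    hits
  }
  out <- data.frame(motif = character(), pos = integer(), strand = character())
  fw <- matchAt(seq, motif)
  if (length(fw)) out <- rbind(out, data.frame(motif = motif, pos = fw,
                                               strand = "+"))
  if (bothStrands) {
    rc <- matchAt(naiveRevComp(seq), motif)
    if (length(rc))
      out <- rbind(out, data.frame(motif = motif,
                                   pos = nchar(seq) - rc - nchar(motif),
                                   strand = "-"))
  }
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Exhaustive ungapped alignment: maximal match count of 'read' against
## 'ref' over every offset and both strands (full-overlap counting).
bruteBestMatches <- function(read, ref) {
  one <- function(rd) {
    rc <- strsplit(rd, "")[[1]]; fc <- strsplit(ref, "")[[1]]
    L <- length(rc); N <- length(fc)
    best <- 0L
    for (d in (-L + 1L):(N - 1L)) {
      i <- seq_len(L)
      j <- i + d
      ok <- j >= 1L & j <= N
      if (!any(ok)) next
      best <- max(best, sum(rc[i[ok]] == fc[j[ok]]))
    }
    best
  }
  max(one(read), one(naiveRevComp(read)))
}

## Two-sided Fisher p by direct hypergeometric enumeration.
bruteFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0L, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Naive two-pass Benjamini-Hochberg step-up.
naiveBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- n / seq_len(n) * p[o]
  for (i in (n - 1L):1L) if (n > 1L) q[i] <- min(q[i], q[i + 1L])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

## Brute-force split-read alignment mirroring the refinement objective:
## maximize explained read bases of read[0:s] + read[s:] over both junction
## cases and both read orientations, with per-part feasibility (>= minPart
## matches, mismatch fraction <= maxMM over compared positions). A distal
## split may additionally consume the insertion motif from the read,
## scoring its bases as explained. Small inputs only.
bruteSplit <- function(read, h1, pbWin, dbWin, minPart = 20L, maxMM = 0.1,
                       insMotif = "GA") {
  N <- nchar(h1)
  h1rc <- naiveRevComp(h1)
  partMatches <- function(part, ref, from) {
    # align 'part' starting at 0-based 'from' on ref; count matches over
    # the in-bounds overlap
    pc <- strsplit(part, "")[[1]]; fc <- strsplit(ref, "")[[1]]
    if (!length(pc)) return(c(m = 0L, cmp = 0L))
    j <- from + seq_along(pc)
    ok <- j >= 1L & j <= N
    c(m = sum(pc[ok] == fc[j[ok]]), cmp = sum(ok))
  }
  feasible <- function(mc) mc[["m"]] >= minPart &&
    (mc[["cmp"]] - mc[["m"]]) <= maxMM * mc[["cmp"]]
  best <- list(total = -1L)
  for (rd in c(read, naiveRevComp(read))) {
    L <- nchar(rd)
    for (s in 0:L) {
      pre <- substr(rd, 1, s); suf <- substr(rd, s + 1, L)
      ## case PB: prefix fwd ends at u; suffix on rc(h1) starts at N - v
      for (u in pbWin[1]:pbWin[2]) {
        f <- partMatches(pre, h1, u - s)
        if (!feasible(f)) next
        for (v in dbWin[1]:dbWin[2]) {
          r <- partMatches(suf, h1rc, N - v)
          if (!feasible(r)) next
          tot <- f[["m"]] + r[["m"]]
          if (tot > best$total)
            best <- list(total = tot, junction = "PB", u = u, v = v)
        }
      }
      ## case DB: prefix on rc(h1) ends at N - u; suffix fwd starts at v;
      ## optionally the insertion motif is consumed at the split
      ilen <- nchar(insMotif)
      consumed <- ilen > 0 && s + ilen <= L &&
        substr(rd, s + 1, s + ilen) == insMotif
      for (u in pbWin[1]:pbWin[2]) {
        f <- partMatches(pre, h1rc, (N - u) - s)
        if (!feasible(f)) next
        for (v in dbWin[1]:dbWin[2]) {
          r <- partMatches(suf, h1, v)
          if (feasible(r)) {
            tot <- f[["m"]] + r[["m"]]
            if (tot > best$total)
              best <- list(total = tot, junction = "DB", u = u, v = v)
          }
          if (consumed) {
            sufI <- substr(rd, s + ilen + 1, L)
            rI <- partMatches(sufI, h1, v)
            if (feasible(rI)) {
              tot <- f[["m"]] + ilen + rI[["m"]]
              if (tot > best$total)
                best <- list(total = tot, junction = "DB", u = u, v = v)
            }
          }
        }
      }
    }
  }
  if (best$total < 0) NULL else best
}
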