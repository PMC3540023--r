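# Sensitivity/specificity, ROC/AUC, paired t-tests, decoy discrimination,
# native base-pair recovery and benchmark-style summary tables.

#' Sensitivity and specificity of a confusion count
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TP/(TP+FP)` (the positive
#' predictive value convention used for site prediction benchmarks). A zero
#' denominator yields 0 with a `degenerate` attribute.
#'
#' @param counts list with `tp`, `fn`, `fp` (e.g. from
#'   [classifyPredictions()])
#' @return fraction in `[0, 1]`
#' @export
sensitivity <- function(counts) {
  den <- counts$tp + counts$fn
  if (den <= 0) return(structure(0, degenerate = TRUE))
  counts$tp / den
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  den <- counts$tp + counts$fp
  if (den <= 0) return(structure(0, degenerate = TRUE))
  counts$tp / den
}

#' ROC curve and AUC for energy scores
#'
#' Lower energy means predicted positive. The threshold sweep visits every
#' distinct energy (ties are one threshold); the area under the curve is the
#' trapezoidal area, which equals the Mann-Whitney probability that a random
#' positive scores below a random negative (ties counted half).
#'
#' @param scores numeric window energies
#' @param labels logical (or 0/1) site-overlap truth per window
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC needs at least one positive and one negative")
  ord <- order(scores)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tpByGrp <- tapply(l, grp, sum)
  fpByGrp <- tapply(!l, grp, sum)
  tpr <- c(0, cumsum(tpByGrp) / nPos)
  fpr <- c(0, cumsum(fpByGrp) / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Paired t-test
#'
#' Classic paired t on the per-item differences (df = n - 1, two-tailed).
#'
#' @param a,b paired numeric vectors
#' @return named vector with `t` and `p`
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired t-test needs two equal-length vectors of length >= 2")
  if (all(a - b == 0)) return(c(t = 0, p = 1))
  tt <- stats::t.test(a, b, paired = TRUE)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Threading-decoy discrimination of a potential
#'
#' Threads `nDecoys` uniformly random sequences of the template's TFBS
#' length onto the fixed backbone (by base-pair substitution, which under
#' the base-atom energy restriction is additive over positions) and compares
#' their binding energies with the native sequence. The success ratio is
#' the fraction of decoys with energy above the native; the Z-score is
#' `(E_native - mean(E_decoy)) / sd(E_decoy)` (lower is better).
#'
#' @param potential a [Potential-class]
#' @param structure the template [ComplexStructure-class]
#' @param nDecoys number of random sequences
#' @param seed RNG seed
#' @return list with `ratio`, `z`, `nativeEnergy`, `decoyEnergies`
#' @export
threadingDecoyTest <- function(potential, structure, nDecoys = 500L,
                               seed = 1L) {
  if (nDecoys < 1L) stop("nDecoys must be at least 1")
  pem <- buildPem(potential, structure)
  L <- pemLength(pem)
  native <- pem@nativeBases
  eNative <- sum(pem@energies[cbind(native, seq_len(L))])
  decoys <- makeThreadingDecoys(L, nDecoys, seed)
  eDecoy <- vapply(decoys, function(s) {
    b <- strsplit(s, "")[[1L]]
    sum(pem@energies[cbind(b, seq_len(L))])
  }, 0)
  sdd <- stats::sd(eDecoy)
  if (!is.finite(sdd) || sdd == 0)
    stop("decoy energies are degenerate (zero spread)")
  list(ratio = mean(eDecoy > eNative),
       z = (eNative - mean(eDecoy)) / sdd,
       nativeEnergy = eNative, decoyEnergies = unname(eDecoy))
}

#' Native base-pair recovery rate
#'
#' Fraction of TFBS positions at which the native pair attains the strict
#' minimum of the position energy matrix.
#'
#' @param potential a [Potential-class]
#' @param structure the template [ComplexStructure-class]
#' @param pem optionally a precomputed [PEM-class]
#' @return fraction in `[0, 1]`
#' @export
basepairRecovery <- function(potential, structure, pem = NULL) {
  if (is.null(pem)) pem <- buildPem(potential, structure)
  m <- pem@energies
  native <- pem@nativeBases
  hits <- vapply(seq_len(ncol(m)), function(j) {
    e <- m[, j]
    e[native[j]] < min(e[DNA_BASES != native[j]]) - 1e-12
  }, NA)
  mean(hits)
}

.round2 <- function(x) round(x, 2)

#' Benchmark summary table
#'
#' One row per factor with TP/FN/FP, SE, SP, SE+SP, AUC and site/ORF
#' bookkeeping, plus unweighted `Average` and sample (n-1) `Standard
#' Deviation` rows, rounded to two decimals. `nTopSites` counts sites whose
#' best overlapping window is rank 1 in its promoter.
#'
#' @param perTf list of per-factor results; each element is a list with
#'   `tfId`, `counts` (tp/fn/fp), `auc`, `nTopSites`, `nSites`, `nTopOrfs`,
#'   `nOrfs`
#' @return data.frame in benchmark column order
#' @export
summarizeTfResults <- function(perTf) {
  rows <- lapply(perTf, function(r) {
    se <- sensitivity(r$counts); sp <- specificity(r$counts)
    data.frame(tf = r$tfId, tp = r$counts$tp, fn = r$counts$fn,
               fp = r$counts$fp, se = .round2(se), sp = .round2(sp),
               seSp = .round2(se + sp), auc = .round2(r$auc),
               nTopSites = r$nTopSites, nSites = r$nSites,
               nTopOrfs = r$nTopOrfs, nOrfs = r$nOrfs,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- names(df)[-1L]
  avg <- c(tf = "Average", lapply(df[num], function(v) .round2(mean(v))))
  if (nrow(df) > 1L) {
    sdr <- c(tf = "Standard Deviation",
             lapply(df[num], function(v) .round2(stats::sd(v))))
    out <- rbind(df, as.data.frame(avg, stringsAsFactors = FALSE),
                 as.data.frame(sdr, stringsAsFactors = FALSE))
  } else {
    out <- rbind(df, as.data.frame(avg, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Count top-ranked sites and promoters
#'
#' A site is "top-ranked" when some window overlapping it (under the >50%
#' rule) has rank 1 within its promoter; a promoter is top-ranked when it
#' contains such a site.
#'
#' @param scored window table from [scanPromoters()]
#' @param sites merged sites (0-based half-open)
#' @param Ln template TFBS length
#' @param config a [scanConfig()]
#' @return list with `nTopSites`, `nTopOrfs`
#' @export
topRankedSites <- function(scored, sites, Ln, config = scanConfig()) {
  sites <- mergeSites(sites)
  top <- scored[scored$rank == 1L, , drop = FALSE]
  hit <- logical(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    same <- top$orf == sites$orf[k]
    if (!any(same)) next
    hit[k] <- any(.hits(top$offset[same], top$offset[same] + top$length[same],
                        sites$start[k], sites$end[k], Ln,
                        config$overlapFraction))
  }
  list(nTopSites = sum(hit), nTopOrfs = length(unique(sites$orf[hit])))
}
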