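# Threading promoter sequences through a position energy matrix, merging
# annotated sites, the >50% overlap classification rule and the threshold
# that maximizes sensitivity + specificity.
#
# Coordinates are 0-based half-open internally; reading/writing site tables
# supports 1-based inclusive input (the style of curated site databases).

#' Scan configuration
#'
#' @param keepK number of lowest-energy windows kept per promoter
#' @param overlapFraction overlap threshold of the classification rule
#'   (strictly greater than)
#' @param scanReverse also scan the reverse complement
#' @return a list with class `ScanConfig`
#' @export
scanConfig <- function(keepK = 200L, overlapFraction = 0.5,
                       scanReverse = FALSE) {
  if (keepK < 1) stop("keepK must be at least 1")
  if (overlapFraction <= 0 || overlapFraction >= 1)
    stop("overlapFraction must be in (0,1)")
  structure(list(keepK = as.integer(keepK),
                 overlapFraction = overlapFraction,
                 scanReverse = isTRUE(scanReverse)),
            class = "ScanConfig")
}

.windowEnergies <- function(pemMat, sequence) {
  L <- ncol(pemMat)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(chars)
  if (n < L) return(numeric(0))
  idx <- match(chars, DNA_BASES)           # N and friends -> NA
  nw <- n - L + 1L
  e <- numeric(nw)
  bad <- logical(nw)
  for (j in seq_len(L)) {
    v <- pemMat[cbind(idx[j:(j + nw - 1L)], j)]
    nav <- is.na(v)
    bad <- bad | nav
    v[nav] <- 0
    e <- e + v
  }
  e[bad] <- Inf                             # windows containing N: never predicted
  e
}

#' Thread a promoter through a PEM
#'
#' One window per offset `0 .. len - L`; the window energy is the sum of the
#' PEM entries of its bases. Windows containing an ambiguous base get
#' energy `Inf` (counted, never predicted). Ranks are 1 for the lowest
#' energy within the promoter, ties broken by smaller offset.
#'
#' @param pem a [PEM-class]
#' @param sequence promoter DNA string
#' @param orfId promoter identifier
#' @param strand strand label stored with the windows
#' @return data.frame with columns `orf`, `offset`, `length`, `strand`,
#'   `energy`, `rank` (empty, with a warning, if the promoter is shorter
#'   than the motif)
#' @export
scoreWindows <- function(pem, sequence, orfId = "promoter", strand = "+") {
  pm <- pem@energies
  seqq <- if (strand == "-") reverseComplement(sequence) else sequence
  e <- .windowEnergies(pm, seqq)
  if (!length(e)) {
    warning("promoter '", orfId, "' shorter than the motif; no windows")
    return(data.frame(orf = character(0), offset = integer(0),
                      length = integer(0), strand = character(0),
                      energy = numeric(0), rank = integer(0)))
  }
  off <- seq_along(e) - 1L
  if (strand == "-") off <- rev(off)  # report on forward coordinates
  ord <- order(e, off)
  rk <- integer(length(e))
  rk[ord] <- seq_along(e)
  data.frame(orf = orfId, offset = off, length = ncol(pm), strand = strand,
             energy = e, rank = rk, stringsAsFactors = FALSE)
}

#' Scan a set of promoters
#'
#' Applies [scoreWindows()] to every promoter (both strands when requested)
#' and marks the `keepK` lowest-energy finite windows per promoter.
#'
#' @param pem a [PEM-class]
#' @param promoters named character vector (or `DNAStringSet`) of promoter
#'   sequences; names are ORF identifiers
#' @param config a [scanConfig()]
#' @return data.frame of windows with an added logical `kept` column
#' @export
scanPromoters <- function(pem, promoters, config = scanConfig()) {
  if (is(promoters, "DNAStringSet"))
    promoters <- setNames(as.character(promoters), names(promoters))
  if (is.null(names(promoters)) || any(!nzchar(names(promoters))))
    stop("promoters must be named by ORF id")
  res <- lapply(names(promoters), function(id) {
    out <- scoreWindows(pem, promoters[[id]], orfId = id)
    if (config$scanReverse)
      out <- rbind(out, scoreWindows(pem, promoters[[id]], orfId = id,
                                     strand = "-"))
    out
  })
  df <- do.call(rbind, res)
  df$kept <- FALSE
  for (id in unique(df$orf)) {
    sel <- which(df$orf == id & is.finite(df$energy))
    ord <- sel[order(df$energy[sel], df$offset[sel])]
    df$kept[utils::head(ord, config$keepK)] <- TRUE
  }
  df
}

#' Reverse complement of a DNA string
#' @param sequence DNA string
#' @return reverse-complemented string
#' @export
reverseComplement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Merge overlapping site annotations
#'
#' Overlapping or bookended intervals on the same promoter are replaced by
#' their union (so two curated sites `1984-2007` and `1988-2012`, 1-based
#' inclusive, merge to `1984-2012`). Output is sorted and disjoint.
#'
#' @param sites data.frame with columns `orf`, `start`, `end` (0-based
#'   half-open)
#' @return merged data.frame in the same coordinates
#' @export
mergeSites <- function(sites) {
  if (!nrow(sites)) return(sites)
  out <- lapply(split(sites, sites$orf), function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L,
                                           end = df$end))
    data.frame(orf = df$orf[1L], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$orf, df$start), , drop = FALSE]
}

# overlap length of a window [ws, we) with a site [ss, se)
.overlapLen <- function(ws, we, ss, se) pmax(0L, pmin(we, se) - pmax(ws, ss))

# does window w hit site s under the >50% rule?
.hits <- function(ws, we, ss, se, Ln, frac) {
  lo <- .overlapLen(ws, we, ss, se)
  ld <- se - ss
  (lo > frac * ld) | (ld > Ln & lo > frac * Ln)
}

#' Classify predicted windows against annotated sites
#'
#' A site (merged, length Ld) counts as a true positive if at least one
#' predicted window overlaps it by more than `overlapFraction` of Ld - or,
#' when the curated site is longer than the template site length Ln, by more
#' than `overlapFraction` of Ln. Unhit sites are false negatives; predicted
#' windows hitting no site are false positives (several windows on one site
#' count a single TP and no FP).
#'
#' @param predictions data.frame of predicted windows (`orf`, `offset`,
#'   `length`)
#' @param sites merged annotation data.frame (`orf`, `start`, `end`),
#'   0-based half-open
#' @param Ln template TFBS length
#' @param config a [scanConfig()]
#' @return list with `tp`, `fn`, `fp` (and `tn = NA`)
#' @export
classifyPredictions <- function(predictions, sites, Ln,
                                config = scanConfig()) {
  if (Ln <= 0) stop("Ln must be positive")
  frac <- config$overlapFraction
  tp <- 0L; fp <- 0L
  siteHit <- logical(nrow(sites))
  if (nrow(predictions)) {
    winHit <- logical(nrow(predictions))
    for (k in seq_len(nrow(sites))) {
      same <- predictions$orf == sites$orf[k]
      if (!any(same)) next
      h <- .hits(predictions$offset[same],
                 predictions$offset[same] + predictions$length[same],
                 sites$start[k], sites$end[k], Ln, frac)
      if (any(h)) siteHit[k] <- TRUE
      winHit[which(same)[h]] <- TRUE
    }
    tp <- sum(siteHit)
    fp <- sum(!winHit)
  }
  list(tp = as.integer(tp), fn = as.integer(nrow(sites) - sum(siteHit)),
       fp = as.integer(fp), tn = NA_integer_)
}

#' Choose the energy threshold maximizing sensitivity + specificity
#'
#' Candidate thresholds are the distinct energies of the kept windows; a
#' window is predicted when its energy is at or below the cutoff. The
#' returned cutoff maximizes SE + SP, ties broken toward the more stringent
#' (lower) threshold.
#'
#' @param scored window table from [scanPromoters()] (uses kept windows)
#' @param sites annotated sites (merged or not; merged internally)
#' @param Ln template TFBS length
#' @param config a [scanConfig()]
#' @return list with `cutoff`, `counts`, `se`, `sp`, `seSp`
#' @export
chooseThreshold <- function(scored, sites, Ln, config = scanConfig()) {
  if (!nrow(sites)) stop("no annotated sites: cannot choose a threshold")
  sites <- mergeSites(sites)
  kept <- scored[scored$kept & is.finite(scored$energy), , drop = FALSE]
  if (!nrow(kept)) stop("no kept windows to threshold")
  frac <- config$overlapFraction
  # precompute which sites each window hits
  nS <- nrow(sites)
  hitList <- vector("list", nrow(kept))
  for (k in seq_len(nS)) {
    same <- which(kept$orf == sites$orf[k])
    if (!length(same)) next
    h <- .hits(kept$offset[same], kept$offset[same] + kept$length[same],
               sites$start[k], sites$end[k], Ln, frac)
    for (w in same[h]) hitList[[w]] <- c(hitList[[w]], k)
  }
  ord <- order(kept$energy, kept$offset)
  siteCover <- integer(nS)
  tp <- 0L; fp <- 0L
  bestSeSp <- -Inf; bestCut <- NA_real_; bestCounts <- NULL
  i <- 1L
  n <- length(ord)
  while (i <= n) {
    e <- kept$energy[ord[i]]
    # admit the whole tie group at this energy
    while (i <= n && kept$energy[ord[i]] == e) {
      w <- ord[i]
      hs <- hitList[[w]]
      if (is.null(hs)) {
        fp <- fp + 1L
      } else {
        tp <- tp + sum(siteCover[hs] == 0L)
        siteCover[hs] <- siteCover[hs] + 1L
      }
      i <- i + 1L
    }
    se <- tp / nS
    sp <- if (tp + fp > 0) tp / (tp + fp) else 0
    if (se + sp > bestSeSp + 1e-12) {
      bestSeSp <- se + sp
      bestCut <- e
      bestCounts <- list(tp = tp, fn = nS - tp, fp = fp, tn = NA_integer_)
    }
  }
  list(cutoff = bestCut, counts = bestCounts,
       se = bestCounts$tp / nS,
       sp = bestCounts$tp / (bestCounts$tp + bestCounts$fp),
       seSp = bestSeSp)
}
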