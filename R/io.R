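# Plain-text serialization: PEM/PWM TSV (rows A,C,G,T; columns 1..L), PWM in
# JASPAR text format, the potential as TSV with a config header, site tables
# (BED-like, with 1-based inclusive input support) and promoter FASTA.

#' Write / read a PEM as TSV
#'
#' Rows A, C, G, T; one column per position; a `#tf=` header line carries
#' the identifier and `#native=` the template bases when known.
#'
#' @param pem a [PEM-class]
#' @param file path
#' @return `file` (write) or a [PEM-class] (read)
#' @export
writePem <- function(pem, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#tf=", pem@tfId), con)
  if (length(pem@nativeBases))
    writeLines(paste0("#native=", paste(pem@nativeBases, collapse = "")), con)
  utils::write.table(pem@energies, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname writePem
#' @export
readPem <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  tf <- sub("^#tf=", "", grep("^#tf=", hdr, value = TRUE))
  native <- sub("^#native=", "", grep("^#native=", hdr, value = TRUE))
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            row.names = 1L)
  m <- as.matrix(body)
  dimnames(m) <- list(DNA_BASES, NULL)
  new("PEM", energies = m,
      tfId = if (length(tf)) tf else "pem",
      nativeBases = if (length(native)) strsplit(native, "")[[1L]]
                    else character(0))
}

#' Write / read a PWM as TSV
#'
#' @param pwm a [PWM-class]
#' @param file path
#' @return `file` (write) or a [PWM-class] (read)
#' @export
writePwm <- function(pwm, file) {
  utils::write.table(pwm@probs, file, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname writePwm
#' @export
readPwm <- function(file) {
  m <- as.matrix(utils::read.table(file, sep = "\t", row.names = 1L))
  dimnames(m) <- list(DNA_BASES, NULL)
  new("PWM", probs = sweep(m, 2, colSums(m), "/"))
}

#' Write / read a PWM in JASPAR text format
#'
#' Writes the `>ID` header followed by four `A [ ... ]` rows. Reading
#' accepts both that dialect and a bare 4-line matrix; counts are normalized
#' to column-stochastic probabilities.
#'
#' @param pwm a [PWM-class]
#' @param file path
#' @param id motif identifier for the header
#' @return `file` (write) or a [PWM-class] (read)
#' @export
writeJaspar <- function(pwm, file, id = "motif") {
  p <- pwm@probs
  rows <- vapply(DNA_BASES, function(b)
    sprintf("%s  [ %s ]", b, paste(formatC(p[b, ], format = "f", digits = 6),
                                   collapse = " ")), "")
  writeLines(c(paste0(">", id), rows), file)
  invisible(file)
}

#' @rdname writeJaspar
#' @export
readJaspar <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  if (length(lines) < 4L) stop("JASPAR matrix needs 4 rows")
  parseRow <- function(ln) {
    ln <- gsub("^[ACGTacgt]", "", ln)
    ln <- gsub("[][]", " ", ln)
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1L]])
  }
  m <- do.call(rbind, lapply(lines[1:4], parseRow))
  rownames(m) <- DNA_BASES
  new("PWM", probs = sweep(m, 2, colSums(m), "/"))
}

#' Write / read a potential as TSV
#'
#' Columns `res_i atom_i res_j atom_j bin_low bin_high energy` preceded by
#' `#key=value` config header lines; the pseudo-count-only fallback curve is
#' stored under the reserved type `* *`.
#'
#' @param potential a [Potential-class]
#' @param file path
#' @return `file` (write) or a [Potential-class] (read)
#' @export
writePotential <- function(potential, file) {
  cfg <- potential@config
  hdr <- c(rCut = format(cfg@rCut), deltaR = format(cfg@deltaR),
           alpha = format(cfg@alpha), etaRT = format(cfg@etaRT),
           pseudoCount = format(cfg@pseudoCount),
           useReweight = as.character(cfg@useReweight),
           useSmoothing = as.character(cfg@useSmoothing),
           useDipolar = as.character(cfg@useDipolar),
           useVolumeFraction = as.character(cfg@useVolumeFraction),
           seed = format(cfg@seed))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#", names(hdr), "=", unlist(hdr)), con)
  writeLines(paste0("#training=", paste(potential@trainingIds,
                                        collapse = ",")), con)
  nb <- nBins(cfg)
  lows <- (seq_len(nb) - 1L) * cfg@deltaR
  emit <- function(key, v) {
    parts <- strsplit(key, "||", fixed = TRUE)[[1L]]
    pi <- strsplit(parts[1L], " ", fixed = TRUE)[[1L]]
    pj <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
    data.frame(res_i = pi[1L], atom_i = pi[2L], res_j = pj[1L],
               atom_j = pj[2L], bin_low = lows, bin_high = lows + cfg@deltaR,
               energy = v, stringsAsFactors = FALSE)
  }
  rows <- lapply(names(potential@energies), function(k)
    emit(k, potential@energies[[k]]))
  rows <- c(rows, list(emit("* *||* *", potential@nullEnergy)))
  df <- do.call(rbind, rows)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePotential
#' @export
readPotential <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(k) sub(paste0("^#", k, "="), "",
                          grep(paste0("^#", k, "="), hdr, value = TRUE))
  cfg <- new("PotentialConfig",
             rCut = as.numeric(getv("rCut")),
             deltaR = as.numeric(getv("deltaR")),
             alpha = as.numeric(getv("alpha")),
             etaRT = as.numeric(getv("etaRT")),
             pseudoCount = as.numeric(getv("pseudoCount")),
             useReweight = as.logical(getv("useReweight")),
             useSmoothing = as.logical(getv("useSmoothing")),
             useDipolar = as.logical(getv("useDipolar")),
             useVolumeFraction = as.logical(getv("useVolumeFraction")),
             seed = as.integer(getv("seed")))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  key <- .pairKey(paste(df$res_i, df$atom_i), paste(df$res_j, df$atom_j))
  ord <- order(df$bin_low)
  energies <- lapply(split(seq_len(nrow(df))[ord], key[ord]),
                     function(i) df$energy[i])
  nullE <- energies[["* *||* *"]]
  energies[["* *||* *"]] <- NULL
  new("Potential", energies = energies, nullEnergy = nullE, config = cfg,
      trainingIds = strsplit(getv("training"), ",")[[1L]])
}

#' Write / read promoter FASTA
#'
#' @param promoters named character vector of sequences
#' @param file path
#' @return `file` (write) or a named character vector (read)
#' @export
writePromoterFasta <- function(promoters, file) {
  x <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname writePromoterFasta
#' @export
readPromoterFasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write / read site annotations
#'
#' BED-like TSV with columns `orf`, `start`, `end`. Internal coordinates are
#' 0-based half-open; set `oneBased = TRUE` to read or write curated-style
#' 1-based inclusive intervals.
#'
#' @param sites data.frame (`orf`, `start`, `end`)
#' @param file path
#' @param oneBased use 1-based inclusive coordinates in the file
#' @return `file` (write) or a data.frame (read)
#' @export
writeSites <- function(sites, file, oneBased = FALSE) {
  out <- sites
  if (oneBased) out$start <- out$start + 1L
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSites
#' @export
readSites <- function(file, oneBased = FALSE) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("orf", "start", "end")
  if (oneBased) df$start <- df$start - 1L
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}
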