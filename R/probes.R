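#' smiFISH secondary-hybridization overhang
#'
#' The shared 28-nt overhang appended to every primary probe; a
#' fluorophore-conjugated secondary oligo anneals to it, so the primary
#' pool itself is unlabeled.
#' @export
smifish_overhang <- "TTACACTCGGACCTCGTCGACATGCATT"

#' GC fraction of a nucleotide sequence
#'
#' @param sequence single string over A, C, G, T, U, N (case-insensitive);
#'   N counts as non-GC.
#' @return (#G + #C) / length.
#' @export
gc_fraction <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(bad) > 0)
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Enumerate candidate probe windows under length and GC constraints
#'
#' Every window of every allowed length whose GC content lies within
#' `gc_range` (inclusive), the standard smiFISH primary-probe rule of
#' 26-32 nt at 40-60% GC.
#'
#' @param transcript sequence string (sense strand).
#' @param len_range inclusive (min, max) probe length in nt.
#' @param gc_range inclusive (min, max) GC fraction.
#' @return tibble ordered by `start` then `length`: `start` (0-based
#'   position on the transcript), `length`, `sequence`, `gc`.
#' @export
enumerate_candidates <- function(transcript, len_range = c(26L, 32L),
                                 gc_range = c(0.40, 0.60)) {
  tx <- toupper(transcript)
  n <- nchar(tx)
  if (n < len_range[1])
    return(tibble::tibble(start = integer(), length = integer(),
                          sequence = character(), gc = numeric()))
  chars <- strsplit(tx, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(bad) > 0)
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  cum_gc <- c(0, cumsum(chars %in% c("G", "C")))
  out <- purrr::map_dfr(seq(len_range[1], len_range[2]), function(L) {
    if (n < L) return(NULL)
    starts <- 0:(n - L)
    gc <- (cum_gc[starts + L + 1] - cum_gc[starts + 1]) / L
    keep <- gc >= gc_range[1] & gc <= gc_range[2]
    if (!any(keep)) return(NULL)
    tibble::tibble(start = starts[keep], length = L,
                   sequence = substring(tx, starts[keep] + 1,
                                        starts[keep] + L),
                   gc = gc[keep])
  })
  if (nrow(out) == 0)
    return(tibble::tibble(start = integer(), length = integer(),
                          sequence = character(), gc = numeric()))
  dplyr::arrange(out, .data$start, .data$length)
}

revcomp <- function(sequence) {
  chartr("ACGTUN", "TGCAAN",
         paste(rev(strsplit(toupper(sequence), "")[[1]]), collapse = ""))
}

#' Greedily select a non-overlapping probe set
#'
#' Left-to-right greedy tiling: the first candidate position is accepted,
#' then each subsequent position whose start is at least `min_spacing` nt
#' past the previous probe's end.  Where several window lengths share a
#' start, the one with GC closest to 0.50 wins (ties: shorter, then
#' earlier).  Selection stops at `max_n` probes and is deterministic;
#' duplicate candidate rows are ignored.
#'
#' @param candidates tibble from [enumerate_candidates()], sorted by start.
#' @param max_n maximum number of probes (default 48, a typical smiFISH
#'   pool size).
#' @param min_spacing minimum gap between consecutive probes, nt.
#' @param hybridizing if `TRUE`, probe portions of the emitted oligos are
#'   reverse-complemented (the strand that anneals to the transcript);
#'   default reports sense-strand sequence.
#' @param overhang sequence appended to every probe to form the ordered
#'   oligo.
#' @return tibble of class `probe_set`: `probe_id`, `start`, `length`,
#'   `gc`, `sequence`, `oligo` (probe + overhang); attributes `overhang`,
#'   `max_n`, `min_spacing`.
#' @export
select_probes <- function(candidates, max_n = 48L, min_spacing = 2L,
                          hybridizing = FALSE,
                          overhang = smifish_overhang) {
  cand <- dplyr::distinct(candidates)
  cand <- dplyr::arrange(cand, .data$start, .data$length)
  sel <- list()
  next_allowed <- -Inf
  for (s in unique(cand$start)) {
    if (length(sel) >= max_n) break
    if (s < next_allowed) next
    here <- cand[cand$start == s, ]
    here <- here[order(abs(here$gc - 0.5), here$length), ]
    pick <- here[1, ]
    sel[[length(sel) + 1L]] <- pick
    next_allowed <- pick$start + pick$length + min_spacing
  }
  probes <- if (length(sel)) dplyr::bind_rows(sel) else
    tibble::tibble(start = integer(), length = integer(),
                   sequence = character(), gc = numeric())
  probe_seq <- if (hybridizing)
    vapply(probes$sequence, revcomp, character(1), USE.NAMES = FALSE)
  else probes$sequence
  out <- tibble::tibble(probe_id = seq_len(nrow(probes)),
                        start = probes$start, length = probes$length,
                        gc = probes$gc, sequence = probe_seq,
                        oligo = paste0(probe_seq, overhang))
  if (nrow(out) == 0) out$oligo <- character(0)
  structure(out, class = c("probe_set", class(out)),
            overhang = overhang, max_n = max_n, min_spacing = min_spacing,
            hybridizing = hybridizing)
}

#' Design a smiFISH probe pool for a transcript
#'
#' Convenience wrapper: [enumerate_candidates()] then [select_probes()].
#'
#' @param transcript sequence string, or a path to a FASTA file (first
#'   record used) when `from_fasta = TRUE`.
#' @param from_fasta read `transcript` as a FASTA path via Biostrings.
#' @inheritParams enumerate_candidates
#' @inheritParams select_probes
#' @return a `probe_set` tibble (see [select_probes()]).
#' @export
design_probes <- function(transcript, max_n = 48L, min_spacing = 2L,
                          len_range = c(26L, 32L),
                          gc_range = c(0.40, 0.60),
                          hybridizing = FALSE, from_fasta = FALSE,
                          overhang = smifish_overhang) {
  if (from_fasta) {
    seqs <- Biostrings::readDNAStringSet(transcript)
    transcript <- as.character(seqs[[1]])
  }
  select_probes(enumerate_candidates(transcript, len_range, gc_range),
                max_n = max_n, min_spacing = min_spacing,
                hybridizing = hybridizing, overhang = overhang)
}

#' Write a probe set to TSV and FASTA
#'
#' @param probes a `probe_set`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the two paths written.
#' @export
write_probes <- function(probes, dir, prefix = "probes") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(as.data.frame(probes), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  writeLines(as.vector(rbind(sprintf(">probe_%02d start=%d gc=%.3f",
                                     probes$probe_id, probes$start,
                                     probes$gc),
                             probes$oligo)), fa)
  invisible(c(tsv = tsv, fasta = fa))
}

#' Secondary-probe concentration at a molar excess
#'
#' The fluorescent secondary oligo is annealed to the primary pool at a
#' molar excess (20% by default) over the total primary concentration.
#'
#' @param primary_total_conc total primary probe concentration, uM (> 0).
#' @param excess fractional molar excess (>= 0; default 0.20).
#' @return secondary concentration in uM.
#' @export
#' @examples
#' secondary_mix(20)   # 24 uM
secondary_mix <- function(primary_total_conc, excess = 0.20) {
  if (!is.numeric(primary_total_conc) || primary_total_conc <= 0)
    stop("primary_total_conc must be > 0", call. = FALSE)
  if (excess < 0) stop("excess must be >= 0", call. = FALSE)
  primary_total_conc * (1 + excess)
}
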