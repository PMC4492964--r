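#' Find perfect tandem repeats in a DNA sequence
#'
#' Scans one sequence for maximal perfect runs of 3- and 4-base motifs, the
#' unit lengths used for tri-/tetranucleotide microsatellite marker design.
#' `N` breaks runs. A maximal periodic region whose length is not an exact
#' multiple of the unit is reported left-anchored (earliest start, partial
#' trailing unit trimmed), and hits of the same unit length never overlap:
#' where two motif blocks abut (e.g. a compound repeat), the second hit
#' starts where the first ends. Motifs that are themselves repetitions of a
#' shorter motif (homopolymers, dinucleotide squares) are not repeats at
#' these unit lengths and are skipped.
#'
#' @param sequence a single DNA string over `A C G T N` (case-insensitive)
#' @param unit_lengths repeat unit sizes to scan (subset of 3:4)
#' @param min_units minimum number of perfect units to report (default 4;
#'   candidate selection applies stricter thresholds, see
#'   [select_candidates()])
#' @param seq_id id stored in the output rows
#' @return data.frame: seq_id, start (1-based), end (inclusive), motif,
#'   unit_length, n_units; zero rows if nothing found
#' @export
find_tandem_repeats <- function(sequence, unit_lengths = c(3L, 4L),
                                min_units = 4L, seq_id = "seq") {
  stopifnot(length(sequence) == 1L)
  s <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]*$", s)) stop("sequence must be over A, C, G, T, N")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  out <- list()
  for (u in sort(as.integer(unit_lengths))) {
    if (!u %in% c(3L, 4L)) stop("unit lengths restricted to 3 and 4")
    if (n < 2L * u) next
    m <- ch[seq_len(n - u)] == ch[seq_len(n - u) + u] &
         ch[seq_len(n - u)] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    prev_end <- 0L
    for (i in which(r$values & r$lengths >= u * (min_units - 1L))) {
      reg_start <- max(starts[i], prev_end + 1L)
      reg_end <- ends[i] + u          # periodic region, inclusive
      k <- (reg_end - reg_start + 1L) %/% u
      if (k < min_units) next
      motif <- paste(ch[reg_start:(reg_start + u - 1L)], collapse = "")
      if (is_motif_power(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, start = reg_start, end = reg_start + k * u - 1L,
        motif = motif, unit_length = u, n_units = k,
        stringsAsFactors = FALSE)
      prev_end <- reg_start + k * u - 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      unit_length = integer(0), n_units = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

# TRUE when the motif has a period shorter than its own length
is_motif_power <- function(motif) {
  u <- nchar(motif)
  ch <- strsplit(motif, "", fixed = TRUE)[[1L]]
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (all(ch == rep_len(ch[seq_len(d)], u))) return(TRUE)
  }
  FALSE
}

#' Canonical motif: lexicographic minimum over rotations
#'
#' Used to group hits of the same repeat family regardless of the phase in
#' which the run was observed; the reported motif stays strand- and
#' phase-as-observed.
#'
#' @param motif DNA string
#' @return canonical rotation
#' @export
canonical_motif <- function(motif) {
  u <- nchar(motif)
  rot <- vapply(seq_len(u), function(i)
    paste0(substr(motif, i, u), substr(motif, 1, i - 1L)), character(1))
  min(rot)
}

#' Select candidate marker loci from repeat hits
#'
#' Keeps the long repeat stretches worth designing primers around:
#' trinucleotide runs of at least `min_units_3` units and tetranucleotide
#' runs of at least `min_units_4` units (defaults 10 and 8). Idempotent.
#'
#' @param hits data.frame from [find_tandem_repeats()]
#' @param min_units_3 threshold for 3-base motifs (default 10)
#' @param min_units_4 threshold for 4-base motifs (default 8)
#' @return the qualifying rows of `hits`
#' @export
select_candidates <- function(hits, min_units_3 = 10L, min_units_4 = 8L) {
  keep <- (hits$unit_length == 3L & hits$n_units >= min_units_3) |
          (hits$unit_length == 4L & hits$n_units >= min_units_4)
  hits[keep, , drop = FALSE]
}

#' Scan a FASTA file for candidate microsatellite loci
#'
#' Reads sequences (via Biostrings when available, else a minimal plain
#' FASTA reader), runs [find_tandem_repeats()] on each, and marks the rows
#' passing [select_candidates()].
#'
#' @param fasta path to a FASTA file
#' @param min_units_3,min_units_4 selection thresholds
#' @param min_units detection floor passed to [find_tandem_repeats()]
#' @return data.frame of hits with a logical `selected` column
#' @export
discover_ssr <- function(fasta, min_units_3 = 10L, min_units_4 = 8L,
                         min_units = 4L) {
  seqs <- read_fasta(fasta)
  hits <- lapply(names(seqs), function(id)
    find_tandem_repeats(seqs[[id]], min_units = min_units, seq_id = id))
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      unit_length = integer(0), n_units = integer(0),
                      selected = logical(0)))
  sel <- select_candidates(hits, min_units_3, min_units_4)
  hits$selected <- paste(hits$seq_id, hits$start, hits$unit_length) %in%
    paste(sel$seq_id, sel$start, sel$unit_length)
  hits
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- as.list(as.character(x))
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0L) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[idx])
  ids <- sub("\\s.*$", "", ids)
  starts <- idx + 1L
  ends <- c(idx[-1L] - 1L, length(lines))
  out <- lapply(seq_along(idx), function(i)
    paste(lines[starts[i]:ends[i]], collapse = ""))
  names(out) <- ids
  out
}

write_fasta <- function(seqs, path, width = 70L) {
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), width),
                pmin(seq(1, nchar(s), width) + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}
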