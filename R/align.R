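# Semi-global read alignment against the amplicon reference.
#
# Stage 1 is an ungapped scan: every candidate offset that keeps the read
# fully inside the reference is scored by Hamming distance, in both
# orientations, vectorised across reads of equal length. This is exact
# for the substitution-only errors that dominate amplicon data. Reads
# that fail the identity threshold ungapped are rescued by a gapped
# semi-global alignment (Biostrings::pairwiseAlignment, read global /
# reference local), which handles indels.

hamming_offsets <- function(seqs, ref_raw) {
  # seqs: character vector, all the same length; ref_raw: the reference
  # as a raw byte vector. Returns the best 0-based offset per read, its
  # mismatch count, and whether the best score is attained at multiple
  # offsets. Byte-wise comparison on a column-per-read raw matrix keeps
  # this fast at depth in the thousands.
  L <- length(ref_raw)
  l <- nchar(seqs[1])
  n_off <- L - l + 1L
  mat <- matrix(unlist(lapply(seqs, charToRaw), use.names = FALSE), nrow = l)
  mm <- matrix(NA_integer_, nrow = length(seqs), ncol = n_off)
  for (o in seq_len(n_off)) {
    win <- ref_raw[o:(o + l - 1L)]
    mm[, o] <- as.integer(colSums(mat != win))
  }
  best <- max.col(-mm, ties.method = "first")
  best_mm <- mm[cbind(seq_len(nrow(mm)), best)]
  multi <- rowSums(mm == best_mm) > 1L
  list(offset = best - 1L, mismatches = best_mm, ambiguous = multi)
}

reverse_strings <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# Gapped rescue for one read; returns NULL if below min_identity.
gapped_align <- function(seq, qual, ref, min_identity) {
  subj <- Biostrings::DNAString(ref$sequence)
  best <- NULL
  for (ori in c("fwd", "rev")) {
    s <- if (ori == "fwd") seq else revcomp(seq)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), subj, type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 2, gapExtension = 1)
    if (is.null(best) || Biostrings::score(pa) > best$score) {
      best <- list(score = Biostrings::score(pa), orientation = ori,
                   identity = Biostrings::nmatch(pa) / Biostrings::nchar(pa),
                   offset = Biostrings::start(Biostrings::subject(pa)) - 1L,
                   pattern_gapped = as.character(Biostrings::alignedPattern(pa)),
                   subject_gapped = as.character(Biostrings::alignedSubject(pa)),
                   oriented_seq = s,
                   oriented_qual = if (ori == "fwd") qual else
                     reverse_strings(qual))
    }
  }
  if (best$identity < min_identity) return(NULL)
  best
}

#' Align amplicon reads to the reference
#'
#' Each read is aligned semi-globally (read fully contained in the
#' reference, end-gap free) in both orientations and the higher-scoring
#' orientation is kept; orientation ties break toward forward.
#' Equal-best multi-offset ungapped hits are discarded as ambiguous, and
#' reads whose final identity falls below `min_identity` are discarded
#' and counted.
#'
#' @param reads A FASTQ data frame (`id`, `sequence`, `quality`), e.g.
#'   the `r1` element of [simulate_reads()] or the result of
#'   [read_fastq()].
#' @param ref An [amplicon_reference()].
#' @param min_identity Minimum fraction of matching bases (default 0.9).
#'
#' @return A data frame of class `amplicon_alignments`, one row per
#'   mapped read: `read_id`, `offset` (0-based), `orientation`
#'   ("fwd"/"rev"), `identity`, `gapped`, `oriented_seq`/`oriented_qual`
#'   (read expressed on the forward strand) and, for gapped rescues,
#'   `pattern_gapped`/`subject_gapped`. Attribute `discarded` holds the
#'   counts of reads dropped for low identity or ambiguity.
#' @export
align_reads <- function(reads, ref, min_identity = 0.9) {
  stopifnot(inherits(ref, "amplicon_reference"))
  if (nchar(ref$sequence) == 0L) stopf("empty reference")
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(grepl("[^ACGTN]", reads$sequence))) {
    stopf("reads must be over the {A,C,G,T,N} alphabet")
  }
  empty <- data.frame(read_id = character(0), offset = integer(0),
                      orientation = character(0), identity = numeric(0),
                      gapped = logical(0), oriented_seq = character(0),
                      oriented_qual = character(0),
                      pattern_gapped = character(0),
                      subject_gapped = character(0),
                      stringsAsFactors = FALSE)
  discarded <- c(low_identity = 0L, ambiguous = 0L, too_long = 0L)
  ref_raw <- charToRaw(ref$sequence)
  L <- length(ref_raw)
  chunks <- list()
  lens <- nchar(reads$sequence)
  for (l in sort(unique(lens))) {
    sel <- which(lens == l)
    if (l > L) {
      discarded[["too_long"]] <- discarded[["too_long"]] + length(sel)
      next
    }
    fwd <- hamming_offsets(reads$sequence[sel], ref_raw)
    rc <- revcomp(reads$sequence[sel])
    rev_ <- hamming_offsets(rc, ref_raw)
    use_rev <- rev_$mismatches < fwd$mismatches  # ties break toward forward
    mm <- ifelse(use_rev, rev_$mismatches, fwd$mismatches)
    offset <- as.integer(ifelse(use_rev, rev_$offset, fwd$offset))
    amb <- ifelse(use_rev, rev_$ambiguous, fwd$ambiguous)
    ident <- 1 - mm / l

    keep <- ident >= min_identity & !amb
    discarded[["ambiguous"]] <- discarded[["ambiguous"]] +
      sum(ident >= min_identity & amb)
    if (any(keep)) {
      oq <- reads$quality[sel]
      oq[use_rev & keep] <- reverse_strings(oq[use_rev & keep])
      chunks[[length(chunks) + 1L]] <- data.frame(
        read_id = reads$id[sel][keep], offset = offset[keep],
        orientation = ifelse(use_rev[keep], "rev", "fwd"),
        identity = ident[keep], gapped = FALSE,
        oriented_seq = ifelse(use_rev, rc, reads$sequence[sel])[keep],
        oriented_qual = oq[keep],
        pattern_gapped = NA_character_, subject_gapped = NA_character_,
        stringsAsFactors = FALSE)
    }
    for (i in sel[ident < min_identity]) {
      ga <- gapped_align(reads$sequence[i], reads$quality[i], ref,
                         min_identity)
      if (is.null(ga)) {
        discarded[["low_identity"]] <- discarded[["low_identity"]] + 1L
      } else {
        chunks[[length(chunks) + 1L]] <- data.frame(
          read_id = reads$id[i], offset = ga$offset,
          orientation = ga$orientation, identity = ga$identity,
          gapped = TRUE, oriented_seq = ga$oriented_seq,
          oriented_qual = ga$oriented_qual,
          pattern_gapped = ga$pattern_gapped,
          subject_gapped = ga$subject_gapped,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(chunks)) do.call(rbind, chunks) else empty
  attr(res, "discarded") <- discarded
  class(res) <- c("amplicon_alignments", class(res))
  res
}
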