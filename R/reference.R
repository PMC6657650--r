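#' Amplicon reference with a single interrogated SNP
#'
#' Constructs the reference object the aligner and pileup work against: a
#' nucleotide sequence carrying one biallelic SNP at a known offset. By
#' default the alleles are those of rs179247 in *TSHR* intron 1 — A
#' (disease-predisposing, reference here) and G (protective, alternate).
#'
#' @param sequence Nucleotide string over {A,C,G,T}.
#' @param snp_pos 0-based offset of the SNP within `sequence`.
#' @param allele_ref,allele_alt The two SNP alleles; single distinct bases.
#'   `sequence[snp_pos]` must equal one of them.
#' @param name Reference name, used in FASTA headers and reports.
#'
#' @return An object of class `amplicon_reference`: a list with fields
#'   `name`, `sequence`, `snp_pos`, `allele_ref`, `allele_alt`.
#' @seealso [make_amplicon_reference()] to generate a synthetic reference.
#' @export
amplicon_reference <- function(sequence, snp_pos, allele_ref = "A",
                               allele_alt = "G",
                               name = "amplicon") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stopf("`sequence` must be a non-empty nucleotide string")
  }
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stopf("`sequence` may only contain A, C, G, T")
  }
  len <- nchar(sequence)
  if (!is_scalar_number(snp_pos) || snp_pos != as.integer(snp_pos) ||
      snp_pos < 0 || snp_pos >= len) {
    stopf("`snp_pos` must be a 0-based offset in [0, %d)", len)
  }
  for (a in list(c("allele_ref", allele_ref), c("allele_alt", allele_alt))) {
    if (!is.character(a[2]) || nchar(a[2]) != 1L || !a[2] %in% c("A", "C", "G", "T")) {
      stopf("`%s` must be a single base in {A,C,G,T}", a[1])
    }
  }
  if (allele_ref == allele_alt) stopf("SNP alleles must differ")
  base_at_snp <- substr(sequence, snp_pos + 1L, snp_pos + 1L)
  if (!base_at_snp %in% c(allele_ref, allele_alt)) {
    stopf("sequence base at snp_pos (%s) is neither allele", base_at_snp)
  }
  structure(
    list(name = name, sequence = sequence, snp_pos = as.integer(snp_pos),
         allele_ref = allele_ref, allele_alt = allele_alt),
    class = "amplicon_reference"
  )
}

#' Generate a synthetic amplicon reference
#'
#' Draws a random sequence of the requested length and GC composition and
#' places the SNP reference allele at the requested offset. The true
#' amplimer sequence around rs179247 is not public, and only the locus
#' structure (length, a mid-amplicon biallelic site) matters to the
#' computation, so a seeded synthetic sequence is used throughout.
#'
#' @param length Amplicon length in bases (default 233, the rs179247
#'   amplimer length).
#' @param snp_offset 0-based SNP offset; default places it mid-amplicon.
#' @param gc_content Expected GC fraction in (0, 1).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @inheritParams amplicon_reference
#'
#' @return An `amplicon_reference`.
#' @examples
#' ref <- make_amplicon_reference(seed = 1)
#' substr(ref$sequence, ref$snp_pos + 1, ref$snp_pos + 1)  # "A"
#' @export
make_amplicon_reference <- function(length = 233L, snp_offset = 116L,
                                    gc_content = 0.4, seed = 1L,
                                    allele_ref = "A", allele_alt = "G",
                                    name = "TSHR_intron1_rs179247_synthetic") {
  if (!is_scalar_number(length) || length < 1) stopf("`length` must be >= 1")
  length <- as.integer(length)
  if (!is_scalar_number(snp_offset) || snp_offset < 0 || snp_offset >= length) {
    stopf("`snp_offset` must lie in [0, %d)", length)
  }
  if (!is_scalar_number(gc_content) || gc_content <= 0 || gc_content >= 1) {
    stopf("`gc_content` must lie strictly between 0 and 1")
  }
  seq <- with_seed(seed, sample(
    c("A", "C", "G", "T"), length, replace = TRUE,
    prob = c((1 - gc_content) / 2, gc_content / 2,
             gc_content / 2, (1 - gc_content) / 2)
  ))
  seq[snp_offset + 1L] <- allele_ref
  amplicon_reference(paste(seq, collapse = ""), snp_offset,
                     allele_ref = allele_ref, allele_alt = allele_alt,
                     name = name)
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("Amplicon reference '%s': %d bp, SNP %s/%s at offset %d (0-based)\n",
              x$name, nchar(x$sequence), x$allele_ref, x$allele_alt, x$snp_pos))
  invisible(x)
}
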