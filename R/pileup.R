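#' Per-sample allele counts at the SNP
#'
#' Container for the pileup result at the interrogated position.
#' Bookkeeping invariants (`count_alt + count_ref + count_other = depth`,
#' `fwd_reads + rev_reads = depth`) are enforced at construction.
#'
#' @param depth Total reads interrogating the SNP position.
#' @param count_alt,count_ref,count_other Reads classified as the
#'   alternate (G, protective) allele, reference (A, predisposing)
#'   allele, or other (non-SNP base or sub-threshold quality).
#' @param fwd_reads,rev_reads Reads by sequencing orientation.
#' @return An object of class `allele_count`. `balance` is
#'   `fwd_reads / depth` (NA at depth 0): 0.5 means no strand bias.
#' @export
allele_count <- function(depth, count_alt, count_ref, count_other = 0L,
                         fwd_reads = NA_integer_, rev_reads = NA_integer_) {
  vals <- c(depth, count_alt, count_ref, count_other)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != as.integer(vals))) {
    stopf("counts must be non-negative integers")
  }
  if (count_alt + count_ref + count_other != depth) {
    stopf("count_alt + count_ref + count_other must equal depth")
  }
  if (is.na(fwd_reads) || is.na(rev_reads)) {
    fwd_reads <- NA_integer_; rev_reads <- NA_integer_
  } else if (fwd_reads + rev_reads != depth) {
    stopf("fwd_reads + rev_reads must equal depth")
  }
  structure(
    list(depth = as.integer(depth), count_alt = as.integer(count_alt),
         count_ref = as.integer(count_ref), count_other = as.integer(count_other),
         fwd_reads = as.integer(fwd_reads), rev_reads = as.integer(rev_reads),
         balance = if (!is.na(fwd_reads) && depth > 0) fwd_reads / depth
                   else NA_real_),
    class = "allele_count"
  )
}

#' @export
print.allele_count <- function(x, ...) {
  cat(sprintf("Allele count: depth %d (alt %d / ref %d / other %d), balance %s\n",
              x$depth, x$count_alt, x$count_ref, x$count_other,
              ifelse(is.na(x$balance), "NA", sprintf("%.2f", x$balance))))
  invisible(x)
}

# Read base (and quality char) at a 0-based reference position, handling
# gapped alignments by walking the aligned columns.
base_at_ref_pos <- function(aln_row, pos0) {
  if (!isTRUE(aln_row$gapped)) {
    idx <- pos0 - aln_row$offset + 1L
    if (idx < 1L || idx > nchar(aln_row$oriented_seq)) return(NULL)
    return(list(base = substr(aln_row$oriented_seq, idx, idx),
                qual = substr(aln_row$oriented_qual, idx, idx)))
  }
  subj <- strsplit(aln_row$subject_gapped, "", fixed = TRUE)[[1]]
  patt <- strsplit(aln_row$pattern_gapped, "", fixed = TRUE)[[1]]
  ref_pos <- aln_row$offset - 1L  # last consumed 0-based ref position
  read_pos <- 0L
  for (col in seq_along(subj)) {
    if (subj[col] != "-") ref_pos <- ref_pos + 1L
    if (patt[col] != "-") read_pos <- read_pos + 1L
    if (subj[col] != "-" && ref_pos == pos0) {
      if (patt[col] == "-") return(NULL)  # deletion spans the SNP
      return(list(base = patt[col],
                  qual = substr(aln_row$oriented_qual, read_pos, read_pos)))
    }
  }
  NULL
}

#' Pile up alleles at the SNP position
#'
#' Classifies, for every aligned read covering the SNP, the read base as
#' alternate (G), reference (A), or other. Bases below `min_base_quality`
#' are absorbed into `count_other` regardless of identity, the standard
#' pileup guard against miscalls. Strand counts and balance come from
#' the alignment orientations.
#'
#' @param alignments An `amplicon_alignments` data frame from
#'   [align_reads()], produced against the same reference.
#' @param ref The [amplicon_reference()] used for alignment.
#' @param min_base_quality Minimum Phred base quality (default 20).
#' @return An [allele_count()]. If no read covers the SNP the depth is 0
#'   (not an error); downstream statistics must guard.
#' @export
pileup_alleles <- function(alignments, ref, min_base_quality = 20L) {
  stopifnot(inherits(ref, "amplicon_reference"), is.data.frame(alignments))
  pos0 <- ref$snp_pos
  n <- nrow(alignments)
  if (n == 0L) return(allele_count(0L, 0L, 0L, 0L, 0L, 0L))

  ungapped <- !alignments$gapped
  covers <- rep(FALSE, n)
  base <- character(n); qual <- character(n)

  idx <- pos0 - alignments$offset + 1L
  ok <- ungapped & idx >= 1L & idx <= nchar(alignments$oriented_seq)
  covers[ok] <- TRUE
  base[ok] <- substr(alignments$oriented_seq[ok], idx[ok], idx[ok])
  qual[ok] <- substr(alignments$oriented_qual[ok], idx[ok], idx[ok])

  for (i in which(!ungapped)) {
    hit <- base_at_ref_pos(alignments[i, ], pos0)
    if (!is.null(hit)) {
      covers[i] <- TRUE
      base[i] <- hit$base
      qual[i] <- hit$qual
    }
  }

  cov <- which(covers)
  if (!length(cov)) return(allele_count(0L, 0L, 0L, 0L, 0L, 0L))
  phred <- utf8ToInt(paste(qual[cov], collapse = "")) - 33L
  b <- base[cov]
  good <- phred >= min_base_quality
  n_alt <- sum(good & b == ref$allele_alt)
  n_ref <- sum(good & b == ref$allele_ref)
  depth <- length(cov)
  fwd <- sum(alignments$orientation[cov] == "fwd")
  allele_count(depth, n_alt, n_ref, depth - n_alt - n_ref,
               fwd, depth - fwd)
}

#' Allele frequency and G/A ratio for one sample
#'
#' The reported frequency uses total depth as the denominator
#' (`100 * count_alt / depth`), matching the assay's per-sample report;
#' the allelic ratio uses the informative reads only
#' (`count_alt / count_ref`). With error-free data the two coincide.
#'
#' @param ac An [allele_count()] with depth > 0.
#' @return A list: `frequency_alt` (percent of all reads carrying the
#'   alternate allele), `ratio_ga` (alt/ref read ratio; `Inf` with a
#'   `ratio_undefined` flag when `count_ref` is 0), `flags`.
#' @export
allele_stats <- function(ac) {
  stopifnot(inherits(ac, "allele_count"))
  if (ac$depth == 0L) stopf("allele statistics are undefined at depth 0")
  flags <- character(0)
  ratio <- if (ac$count_ref > 0L) ac$count_alt / ac$count_ref else {
    flags <- "ratio_undefined"
    Inf
  }
  list(frequency_alt = 100 * ac$count_alt / ac$depth,
       ratio_ga = ratio, flags = flags)
}

#' Call a genotype from gDNA allele counts
#'
#' Genomic DNA carries one copy of each allele, so the informative-read
#' alternate fraction `f = count_alt / (count_alt + count_ref)` is ~0.5
#' for heterozygotes. `f` inside the closed heterozygote band is called
#' het; below it hom_ref; above it hom_alt.
#'
#' @param ac An [allele_count()] from gDNA.
#' @param het_band Closed interval of `f` called heterozygous
#'   (default `c(0.35, 0.65)`).
#' @param min_depth Minimum depth for a call (default 500); below it the
#'   genotype is "unknown" with a QC reason attribute.
#' @return One of "hom_ref", "het", "hom_alt", "unknown" (the latter
#'   carries attribute `reason`).
#' @export
call_genotype <- function(ac, het_band = c(0.35, 0.65), min_depth = 500L) {
  stopifnot(inherits(ac, "allele_count"))
  if (ac$depth < min_depth) {
    return(structure("unknown",
                     reason = sprintf("depth %d below minimum %d",
                                      ac$depth, as.integer(min_depth))))
  }
  inf <- ac$count_alt + ac$count_ref
  if (inf == 0L) return(structure("unknown", reason = "no informative reads"))
  f <- ac$count_alt / inf
  if (f < het_band[1]) "hom_ref"
  else if (f > het_band[2]) "hom_alt"
  else "het"
}

#' Per-sample sequencing QC
#'
#' Fails a sample on insufficient depth or strand bias (balance outside
#' the accepted band). Balance 0.5 means half the reads come from each
#' primer.
#'
#' @param ac An [allele_count()].
#' @param balance_band Accepted closed balance interval
#'   (default `c(0.4, 0.6)`).
#' @param min_depth Minimum accepted depth (default 100).
#' @return A list: `qc_pass` (logical) and `reasons` (character vector
#'   enumerating the failures, empty on pass).
#' @export
qc_sample <- function(ac, balance_band = c(0.4, 0.6), min_depth = 100L) {
  stopifnot(inherits(ac, "allele_count"))
  reasons <- character(0)
  if (ac$depth < min_depth) {
    reasons <- c(reasons, sprintf("low depth (%d < %d)", ac$depth,
                                  as.integer(min_depth)))
  }
  if (!is.na(ac$balance) &&
      (ac$balance < balance_band[1] || ac$balance > balance_band[2])) {
    reasons <- c(reasons, "strand bias")
  }
  list(qc_pass = length(reasons) == 0L, reasons = reasons)
}
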