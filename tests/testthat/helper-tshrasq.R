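# Shared test fixtures, all built in code.

tiny_ref <- function(seed = 1L) make_amplicon_reference(seed = seed)

# Truth-oracle allele counts by direct inspection of the emitted FASTQ:
# picks each fragment's forward-strand read (r1 for forward fragments,
# r2 for reverse ones) and reads the base at the SNP offset. Independent
# of the alignment/pileup path.
brute_force_counts <- function(rs) {
  pos <- rs$ref$snp_pos + 1L
  fwd_read <- ifelse(rs$truth$orientation == "fwd",
                     rs$r1$sequence, rs$r2$sequence)
  base <- substr(fwd_read, pos, pos)
  c(alt = sum(base == rs$ref$allele_alt),
    ref = sum(base == rs$ref$allele_ref),
    other = sum(!base %in% c(rs$ref$allele_alt, rs$ref$allele_ref)))
}

# Build an allele_count directly from read counts (error-free layout).
ac_of <- function(alt, ref, other = 0L, fwd = NULL) {
  depth <- alt + ref + other
  if (is.null(fwd)) fwd <- floor(depth / 2)
  allele_count(depth, alt, ref, other, fwd, depth - fwd)
}

# A minimal hand-built read data frame.
reads_df <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("F", nchar(seqs))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

# Zero-dispersion, zero-noise qPCR configuration for round-trip tests.
noiseless_qpcr_config <- function(n_thyroid = 3L, n_thymus = 3L, seed = 1L) {
  qpcr_cohort_config(
    n_thyroid = n_thyroid, n_thymus = n_thymus,
    iqrs = list(thyroid = c(flTSHR = 0, ST4 = 0, ST5 = 0),
                thymus = c(flTSHR = 0, ST4 = 0, ST5 = 0)),
    ct_noise_sd = 0, seed = seed)
}
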