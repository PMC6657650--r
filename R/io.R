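# Readers and writers for the pipeline's file formats. FASTA goes
# through Biostrings; FASTQ is read/written as strict 4-line records so
# malformed input can be reported with its line number.

#' Read a FASTQ file
#'
#' Strict 4-line-record parser (Phred+33). Malformed records are
#' reported with the offending line number; a file whose length is not a
#' multiple of four is treated as truncated.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data frame with columns `id` (without the leading `@`),
#'   `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stopf("truncated FASTQ: %d lines is not a multiple of 4 (near line %d)",
          n, n)
  }
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  hdr <- seq(1L, n, by = 4L)
  plus <- hdr + 2L
  bad_hdr <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad_hdr)) {
    stopf("FASTQ parse error at line %d: header must start with '@'",
          bad_hdr[1])
  }
  bad_plus <- plus[!startsWith(lines[plus], "+")]
  if (length(bad_plus)) {
    stopf("FASTQ parse error at line %d: separator must start with '+'",
          bad_plus[1])
  }
  seqs <- lines[hdr + 1L]
  quals <- lines[hdr + 3L]
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len)) {
    stopf("FASTQ parse error at line %d: sequence and quality lengths differ",
          hdr[bad_len[1]] + 3L)
  }
  data.frame(id = sub("^@", "", lines[hdr]), sequence = seqs,
             quality = quals, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stopf("sequence and quality lengths differ")
  }
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
    out[seq(2L, length(out), 4L)] <- reads$sequence
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- reads$quality
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an amplicon reference as FASTA
#'
#' The SNP annotation (0-based offset and alleles) is carried in the
#' FASTA description so [read_reference_fasta()] can restore the object.
#'
#' @param ref An [amplicon_reference()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "amplicon_reference"))
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- sprintf("%s snp_pos=%d allele_ref=%s allele_alt=%s",
                      ref$name, ref$snp_pos, ref$allele_ref, ref$allele_alt)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an amplicon reference from FASTA
#'
#' @param path Path to a single-record FASTA file. If the header does
#'   not carry the `snp_pos=`/`allele_ref=`/`allele_alt=` annotation
#'   written by [write_reference_fasta()], the `snp_pos`, `allele_ref`
#'   and `allele_alt` arguments must be supplied.
#' @param snp_pos,allele_ref,allele_alt Optional overrides for the SNP
#'   annotation.
#' @return An [amplicon_reference()].
#' @export
read_reference_fasta <- function(path, snp_pos = NULL, allele_ref = NULL,
                                 allele_alt = NULL) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stopf("expected exactly one reference record, got %d",
                             length(x))
  hdr <- names(x)[1]
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (length(m)) sub(paste0(key, "="), "", m) else NULL
  }
  if (is.null(snp_pos)) snp_pos <- as.integer(grab("snp_pos"))
  if (is.null(allele_ref)) allele_ref <- grab("allele_ref")
  if (is.null(allele_alt)) allele_alt <- grab("allele_alt")
  if (is.null(snp_pos) || length(snp_pos) == 0L || is.na(snp_pos) ||
      is.null(allele_ref) || is.null(allele_alt)) {
    stopf("FASTA header lacks SNP annotation; supply snp_pos and alleles")
  }
  amplicon_reference(as.character(x[[1]]), snp_pos,
                     allele_ref = allele_ref, allele_alt = allele_alt,
                     name = sub(" .*", "", hdr))
}

#' Read the sample sheet
#'
#' @param path CSV with header; required columns `sample_id`, `tissue`
#'   (thymus/thyroid), `material` (gDNA/cDNA); optional `age`, `sex`,
#'   `genotype_*`, `gdna_contamination_free`.
#' @return A validated data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue", "material")
  miss <- setdiff(req, names(d))
  if (length(miss)) stopf("sample sheet lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$tissue), c("thymus", "thyroid"))
  if (length(bad)) stopf("unknown tissue value(s): %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(unique(d$material), c("gDNA", "cDNA"))
  if (length(bad)) stopf("unknown material value(s): %s",
                         paste(bad, collapse = ", "))
  d
}

#' Read a Ct triplicate table
#'
#' @param path CSV with header; columns `sample_id`, `gene` (flTSHR,
#'   ST4, ST5, GAPDH), `ct1`, `ct2`, `ct3` (finite, positive).
#' @return A validated data frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stopf("Ct table not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "gene", "ct1", "ct2", "ct3")
  miss <- setdiff(req, names(d))
  if (length(miss)) stopf("Ct table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$gene), c("flTSHR", "ST4", "ST5", "GAPDH"))
  if (length(bad)) stopf("unknown gene value(s): %s",
                         paste(bad, collapse = ", "))
  cts <- as.matrix(d[, c("ct1", "ct2", "ct3")])
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stopf("Ct values must be finite and positive")
  }
  d
}

#' Load the packaged per-sample allele-count table
#'
#' The study's published per-sample allele-specific quantification table
#' (27 heterozygous donors: 8 thyroid, 19 thymus; one gDNA and one cDNA
#' row each) ships as a plain-text fixture. On load the internal
#' consistency invariant is enforced: for every row the printed G-allele
#' frequency must equal `100 * count_g / depth` at 2 decimal places.
#'
#' @param path Fixture path; defaults to the copy installed with the
#'   package.
#' @return A data frame of class `table1_fixture` with columns
#'   `sample_id`, `tissue`, `material`, `depth`, `balance`, `count_g`,
#'   `frequency_pct`.
#' @export
load_table1_fixture <- function(path = system.file("extdata",
                                                   "table1_asq.csv",
                                                   package = "tshrasq")) {
  if (!nzchar(path) || !file.exists(path)) stopf("fixture file not found")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sample_id = "character"))
  req <- c("sample_id", "tissue", "material", "depth", "balance",
           "count_g", "frequency_pct")
  miss <- setdiff(req, names(d))
  if (length(miss)) stopf("fixture corruption: missing column(s) %s",
                          paste(miss, collapse = ", "))
  if (nrow(d) != 54L) stopf("fixture corruption: expected 54 rows, got %d",
                            nrow(d))
  donors <- unique(d$sample_id)
  if (length(donors) != 27L ||
      length(unique(d$sample_id[d$tissue == "thyroid"])) != 8L ||
      length(unique(d$sample_id[d$tissue == "thymus"])) != 19L) {
    stopf("fixture corruption: expected 8 thyroid + 19 thymus donors")
  }
  per <- table(d$sample_id, d$material)
  if (!all(per == 1L)) {
    stopf("fixture corruption: each donor needs one gDNA and one cDNA row")
  }
  recomputed <- round(100 * d$count_g / d$depth, 2)
  bad <- which(abs(recomputed - d$frequency_pct) > 0.005)
  if (length(bad)) {
    stopf("fixture corruption: row %d frequency %.2f != 100*G/depth = %.2f",
          bad[1], d$frequency_pct[bad[1]], recomputed[bad[1]])
  }
  class(d) <- c("table1_fixture", class(d))
  d
}

#' Per-sample ASQ results from the packaged fixture
#'
#' Rebuilds [asq_results()]-shaped rows from the published counts. The
#' table prints the G count and the total depth, so the A count is taken
#' as `depth - count_g` (the published frequencies are consistent with a
#' total-depth denominator).
#'
#' @param fixture A `table1_fixture`, by default loaded from the
#'   package.
#' @return A data frame as returned by [asq_results()].
#' @export
fixture_asq_results <- function(fixture = load_table1_fixture()) {
  stopifnot(inherits(fixture, "table1_fixture"))
  counts <- lapply(seq_len(nrow(fixture)), function(i) {
    depth <- fixture$depth[i]
    g <- fixture$count_g[i]
    fwd <- as.integer(round(fixture$balance[i] * depth))
    allele_count(depth, g, depth - g, 0L, fwd, depth - fwd)
  })
  asq_results(counts, fixture$sample_id, fixture$tissue, fixture$material)
}
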