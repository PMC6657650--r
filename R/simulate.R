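#' Configuration for the paired-end amplicon read simulator
#'
#' @param allele_fraction True fraction of template fragments carrying the
#'   alternate (G, protective) allele at the SNP. 0.5 emulates gDNA from a
#'   heterozygote; values above 0.5 emulate cis-regulatory overexpression
#'   of the protective allele in cDNA.
#' @param depth Number of template fragments to emit (each yields one
#'   read pair).
#' @param error_rate Per-base substitution probability applied once per
#'   fragment; both mates then read the mutated fragment.
#' @param fwd_fraction Probability a fragment is sequenced from the
#'   forward primer (read 1 in forward orientation). Drives the
#'   strand-balance QC statistic.
#' @param read_length Read length; the default 233 covers the full
#'   amplimer so the pair overlaps completely (MiSeq v2 500-cycle design).
#' @param indel_rate Per-base probability of a 1-bp indel event
#'   (insertion or deletion with equal probability). Off by default:
#'   substitution errors dominate amplicon allele-miscall risk.
#' @param base_quality Constant Phred quality written to FASTQ.
#' @param seed Integer seed; simulation is deterministic given the seed.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(allele_fraction = 0.5, depth = 1000L,
                              error_rate = 0, fwd_fraction = 0.5,
                              read_length = 233L, indel_rate = 0,
                              base_quality = 37L, seed = 1L) {
  check_prob(allele_fraction, "allele_fraction")
  check_prob(error_rate, "error_rate", upper_open = TRUE)
  check_prob(fwd_fraction, "fwd_fraction")
  check_prob(indel_rate, "indel_rate", upper_open = TRUE)
  if (!is_scalar_number(depth) || depth < 0 || depth != as.integer(depth)) {
    stopf("`depth` must be a non-negative integer")
  }
  if (!is_scalar_number(read_length) || read_length < 1) {
    stopf("`read_length` must be >= 1")
  }
  if (!is_scalar_number(base_quality) || base_quality < 2 || base_quality > 41) {
    stopf("`base_quality` must be a Phred score in [2, 41]")
  }
  structure(
    list(allele_fraction = allele_fraction, depth = as.integer(depth),
         error_rate = error_rate, fwd_fraction = fwd_fraction,
         read_length = as.integer(read_length), indel_rate = indel_rate,
         base_quality = as.integer(base_quality), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Substitute each base independently with probability `rate`, to a
# uniformly random different base. Equivalent to per-base Bernoulli
# draws: a Binomial(len, rate) error count per fragment, error positions
# sampled without replacement, each substituted by a uniform shift to
# one of the three other bases. Vectorised round-by-round over the k-th
# error of every affected fragment.
mutate_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) {
    return(list(seqs = seqs, n_errors = integer(length(seqs))))
  }
  len <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), len, rate)
  hit <- which(n_err > 0L)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    pos_list <- lapply(hit, function(i) sample.int(len[i], n_err[i]))
    for (k in seq_len(max(n_err))) {
      sub <- which(n_err[hit] >= k)
      frags <- hit[sub]
      p <- vapply(pos_list[sub], `[`, integer(1), k)
      tmp <- seqs[frags]
      cur <- substr(tmp, p, p)
      shift <- sample.int(3L, length(frags), replace = TRUE)
      new <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
      substr(tmp, p, p) <- new
      seqs[frags] <- tmp
    }
  }
  list(seqs = seqs, n_errors = n_err)
}

# Apply 1-bp indels at random positions (insertion/deletion 50:50).
mutate_indels <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- nchar(seqs)
  n_ev <- stats::rbinom(length(seqs), len, rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_ev > 0L)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (k in seq_len(n_ev[i])) {
      p <- sample.int(length(chars), 1L)
      if (stats::runif(1) < 0.5 && length(chars) > 1L) {
        chars <- chars[-p]
      } else {
        chars <- append(chars, sample(bases, 1L), after = p)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate a paired-end amplicon read set with known truth
#'
#' Emits `depth` template fragments from the amplicon. Each fragment
#' carries the alternate allele at the SNP with probability
#' `allele_fraction`, is assigned forward-primer orientation with
#' probability `fwd_fraction`, and is then mutated base-by-base at
#' `error_rate`. Read 1 reads the fragment from the orientation's primer,
#' read 2 from the opposite end (reverse complement); with the default
#' full-amplimer read length the pair overlaps completely. The true
#' per-fragment allele and orientation are returned alongside the reads
#' so tests can use them as an oracle.
#'
#' @param ref An [amplicon_reference()].
#' @param cfg A [simulation_config()].
#'
#' @return A list of class `amplicon_read_set` with elements
#'   `r1`, `r2` (data frames with columns `id`, `sequence`, `quality`)
#'   and `truth` (data frame: `fragment_id`, `true_allele` in
#'   {"ref","alt"}, `orientation` in {"fwd","rev"}, `n_errors`).
#' @export
simulate_reads <- function(ref, cfg) {
  stopifnot(inherits(ref, "amplicon_reference"),
            inherits(cfg, "simulation_config"))
  n <- cfg$depth
  empty_fq <- data.frame(id = character(0), sequence = character(0),
                         quality = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(
      r1 = empty_fq, r2 = empty_fq,
      truth = data.frame(fragment_id = character(0), true_allele = character(0),
                         orientation = character(0), n_errors = integer(0),
                         stringsAsFactors = FALSE),
      ref = ref, config = cfg), class = "amplicon_read_set"))
  }

  tmpl_ref <- ref$sequence
  substr(tmpl_ref, ref$snp_pos + 1L, ref$snp_pos + 1L) <- ref$allele_ref
  tmpl_alt <- ref$sequence
  substr(tmpl_alt, ref$snp_pos + 1L, ref$snp_pos + 1L) <- ref$allele_alt

  sim <- with_seed(cfg$seed, {
    is_alt <- stats::runif(n) < cfg$allele_fraction
    is_fwd <- stats::runif(n) < cfg$fwd_fraction
    frags <- ifelse(is_alt, tmpl_alt, tmpl_ref)
    mut <- mutate_substitutions(frags, cfg$error_rate)
    frags <- mutate_indels(mut$seqs, cfg$indel_rate)
    list(is_alt = is_alt, is_fwd = is_fwd, frags = frags,
         n_errors = mut$n_errors)
  })

  rl <- cfg$read_length
  fwd_read <- substr(sim$frags, 1L, rl)
  rev_read <- substr(revcomp(sim$frags), 1L, rl)
  r1_seq <- ifelse(sim$is_fwd, fwd_read, rev_read)
  r2_seq <- ifelse(sim$is_fwd, rev_read, fwd_read)
  qchar <- intToUtf8(33L + cfg$base_quality)
  qual1 <- strrep(qchar, nchar(r1_seq))
  qual2 <- strrep(qchar, nchar(r2_seq))
  ids <- sprintf("frag%06d", seq_len(n))

  structure(list(
    r1 = data.frame(id = paste0(ids, "/1"), sequence = r1_seq,
                    quality = qual1, stringsAsFactors = FALSE),
    r2 = data.frame(id = paste0(ids, "/2"), sequence = r2_seq,
                    quality = qual2, stringsAsFactors = FALSE),
    truth = data.frame(
      fragment_id = ids,
      true_allele = ifelse(sim$is_alt, "alt", "ref"),
      orientation = ifelse(sim$is_fwd, "fwd", "rev"),
      n_errors = sim$n_errors,
      stringsAsFactors = FALSE),
    ref = ref, config = cfg), class = "amplicon_read_set")
}

#' @export
print.amplicon_read_set <- function(x, ...) {
  cat(sprintf("Simulated amplicon read set: %d fragments (%d alt / %d ref), ref '%s'\n",
              nrow(x$truth), sum(x$truth$true_allele == "alt"),
              sum(x$truth$true_allele == "ref"), x$ref$name))
  invisible(x)
}

#' Write a simulated read set to disk
#'
#' Writes R1/R2 FASTQ files (Phred+33), the reference FASTA, the truth
#' table as CSV, and the simulation configuration as JSON.
#'
#' @param rs An `amplicon_read_set` from [simulate_reads()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_read_set <- function(rs, dir, prefix = "sim") {
  stopifnot(inherits(rs, "amplicon_read_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    r1 = file.path(dir, paste0(prefix, "_R1.fastq")),
    r2 = file.path(dir, paste0(prefix, "_R2.fastq")),
    reference = file.path(dir, paste0(prefix, "_reference.fasta")),
    truth = file.path(dir, paste0(prefix, "_truth.csv")),
    config = file.path(dir, paste0(prefix, "_config.json"))
  )
  write_fastq(rs$r1, paths[["r1"]])
  write_fastq(rs$r2, paths[["r2"]])
  write_reference_fasta(rs$ref, paths[["reference"]])
  utils::write.csv(rs$truth, paths[["truth"]], row.names = FALSE)
  cfg <- rs$config
  jsonlite::write_json(c(unclass(cfg),
                         list(snp_pos = rs$ref$snp_pos,
                              allele_ref = rs$ref$allele_ref,
                              allele_alt = rs$ref$allele_alt)),
                       paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
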