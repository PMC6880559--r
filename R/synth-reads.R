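#' Read-simulation parameters
#'
#' @param coverage fold coverage per haploid genome (>= 0).
#' @param read_len read length in bases.
#' @param frag_mean,frag_sd fragment (insert) size mean and sd in bases;
#'   `frag_mean` must exceed `read_len`.
#' @param err_rate per-base substitution probability (no indel errors are
#'   simulated, which keeps flank mapping an exact-identity contract).
#' @param seed optional integer seed.
#' @return A list of class `alu_readsim_params`.
#' @export
read_sim_params <- function(coverage = 30, read_len = 100L, frag_mean = 450,
                            frag_sd = 50, err_rate = 0.001, seed = NULL) {
  if (coverage < 0) stop("coverage must be >= 0")
  if (read_len <= 0) stop("read_len must be positive")
  if (frag_mean <= read_len) stop("frag_mean must exceed read_len")
  if (err_rate < 0 || err_rate > 1) stop("err_rate must lie in [0, 1]")
  structure(list(coverage = coverage, read_len = as.integer(read_len),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 err_rate = err_rate, seed = seed),
            class = "alu_readsim_params")
}

# Substitution errors on a character vector of reads (vectorized per read).
.add_errors <- function(reads, err_rate) {
  if (err_rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads)
  n_err <- rbinom(length(reads), rl, err_rate)
  for (i in which(n_err > 0L)) {
    p <- sample.int(rl[i], n_err[i])
    for (j in p) {
      old <- substr(reads[i], j, j)
      substr(reads[i], j, j) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  reads
}

.revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Simulate paired-end reads from a diploid donor genome
#'
#' Fragments are sampled uniformly along each haplotype (half of the total
#' pairs per haplotype), fragment lengths are normal
#' (`frag_mean`, `frag_sd`) truncated below at `read_len`, and mates are
#' emitted in FR orientation with the forward/reverse role of mate 1 chosen at
#' random. The total number of pairs is
#' `round(coverage * haploid_length / (2 * read_len))`, so summed base yield
#' equals `coverage` per haploid position in expectation. Base-call errors are
#' i.i.d. substitutions at `err_rate`.
#'
#' @param donor a list of two `DNAStringSet`s (`hapA`, `hapB`) as from
#'   [build_donor_genomes()], or a single `DNAStringSet` treated as haploid.
#' @param params an `alu_readsim_params`.
#' @param id_prefix read-name prefix (conventionally the individual id).
#' @return A list with `DNAStringSet`s `r1` and `r2` (same names, `/1`, `/2`
#'   suffixes stripped).
#' @export
simulate_reads <- function(donor, params = read_sim_params(),
                           id_prefix = "ind") {
  stopifnot(inherits(params, "alu_readsim_params"))
  .set_seed(params$seed)
  if (is(donor, "DNAStringSet")) donor <- list(hapA = donor)
  rl <- params$read_len
  hap_len <- mean(vapply(donor, function(h) sum(width(h)), numeric(1)))
  n_pairs_total <- round(params$coverage * hap_len / (2 * rl))
  r1 <- r2 <- character(0)
  nm <- character(0)
  for (h in seq_along(donor)) {
    hap <- donor[[h]]
    chr_chr <- as.character(hap)
    lens <- nchar(chr_chr)
    n_h <- round(n_pairs_total / length(donor))
    if (n_h == 0L) next
    ## chromosomes drawn proportionally to length
    ci <- sample.int(length(lens), n_h, replace = TRUE, prob = lens / sum(lens))
    flen <- pmax(rl, pmin(round(rnorm(n_h, params$frag_mean, params$frag_sd)),
                          lens[ci]))
    start <- floor(runif(n_h, 1, lens[ci] - flen + 1 + 1))  # 1-based
    fwd_first <- runif(n_h) < 0.5
    frag <- substring(chr_chr[ci], start, start + flen - 1L)
    left <- substring(frag, 1L, rl)
    right <- .revcomp_chr(substring(frag, flen - rl + 1L, flen))
    a <- ifelse(fwd_first, left, right)
    b <- ifelse(fwd_first, right, left)
    r1 <- c(r1, a)
    r2 <- c(r2, b)
    nm <- c(nm, sprintf("%s:h%d:%06d", id_prefix, h, seq_len(n_h)))
  }
  r1 <- .add_errors(r1, params$err_rate)
  r2 <- .add_errors(r2, params$err_rate)
  r1 <- DNAStringSet(r1); names(r1) <- nm
  r2 <- DNAStringSet(r2); names(r2) <- nm
  list(r1 = r1, r2 = r2)
}

#' Write a read pair as FASTQ
#'
#' Emits `<prefix>_1.fastq` / `<prefix>_2.fastq` with constant base quality
#' (quality modeling is out of scope).
#'
#' @param reads list with `r1`, `r2` from [simulate_reads()].
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (i in 1:2) {
    x <- reads[[i]]
    q <- BStringSet(vapply(width(x), function(w) strrep("I", w), character(1)))
    writeXStringSet(x, paths[i], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Read a FASTQ pair back into memory
#'
#' @param prefix path prefix used by [write_fastq_pair()].
#' @return A list with `r1` and `r2` `DNAStringSet`s.
#' @export
read_fastq_pair <- function(prefix) {
  list(r1 = readDNAStringSet(paste0(prefix, "_1.fastq"), format = "fastq"),
       r2 = readDNAStringSet(paste0(prefix, "_2.fastq"), format = "fastq"))
}
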