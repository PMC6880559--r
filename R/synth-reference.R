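#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. at the requested GC content. The sequence is the
#' neutral, repeat-free background into which insertions are planted; it is
#' deliberately simpler than a real primate genome (no repeats, no N runs),
#' which is what makes unique flank mapping a clean, testable contract.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of each chromosome in bases (>= 10000).
#' @param gc GC fraction in (0, 1); the two extremes 0 and 1 are allowed for
#'   degenerate test genomes.
#' @param seed optional integer seed; identical seeds give identical sequences.
#' @return A named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
generate_reference <- function(n_chroms = 1L, chrom_len = 1e5, gc = 0.40,
                               seed = NULL) {
  if (n_chroms < 1L || chrom_len <= 0)
    stop("n_chroms and chrom_len must be positive")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  .set_seed(seed)
  seqs <- vapply(seq_len(n_chroms), function(i) .random_dna(chrom_len, gc),
                 character(1))
  out <- DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(n_chroms))
  out
}

#' The built-in Alu consensus
#'
#' A fixed 300 bp synthetic AluY-like consensus (280 bp GC-rich body with a
#' central A-rich linker, plus a 20 bp 3' A-tail). It plays the role a
#' repeat-database AluY consensus plays in a real pipeline: the sequence that
#' split reads are screened against, and the base from which subfamily
#' consensus sequences are derived by diagnostic substitutions. It is
#' synthetic: no third-party repeat-library sequence is shipped.
#'
#' @return A `DNAString` of length 300.
#' @export
alu_consensus <- function() {
  DNAString(paste0(
    "GAGCTTGCTTCTCGCGAGCGTCTCCTTTCGTGCGCTGCCGGCCGTCAGGGCGGTACCGTA",
    "CTGCCACTGTGGACTTAGCAGCGGCCGTGACGCGCGGGAACGCATGCGGCTCTGCCACAT",
    "CAAACGCGGCAAAAATACAAAATGGAAACGCCCCGCCAGTAGGGAGACCTTAGCCGCGTA",
    "GCGGTGAGATCGGTCACCTTTAATGTCCCCGGCAGCGCGGTCATGGGCATGGTACCCTGC",
    "GCTCGAAGACCGCTATAGGCCTCCTGAGTCGCTAACGGACAAAAAAAAAAAAAAAAAAAA"))
}

#' Build a subfamily consensus library
#'
#' Each subfamily is the base consensus with a small set of diagnostic
#' substitutions. The substitution list is recorded in the FASTA-style name
#' (`Sub1 diag=17:T,88:C,...`, positions 1-based in the consensus) so a
#' library round-trips through FASTA without any external repeat library.
#' Diagnostic positions avoid the A-tail.
#'
#' @param consensus a `DNAString`; defaults to [alu_consensus()].
#' @param n_subfamilies number of subfamilies.
#' @param n_diagnostic diagnostic substitutions per subfamily (>= 5 keeps
#'   subfamilies reliably distinguishable).
#' @param seed optional integer seed.
#' @return A named `DNAStringSet`, one consensus per subfamily.
#' @export
make_subfamily_library <- function(consensus = alu_consensus(),
                                   n_subfamilies = 4L, n_diagnostic = 6L,
                                   seed = NULL) {
  stopifnot(n_subfamilies >= 1L, n_diagnostic >= 1L)
  .set_seed(seed)
  base <- strsplit(as.character(consensus), "")[[1]]
  tail_a <- match(TRUE, rev(base) != "A", nomatch = length(base) + 1L) - 1L
  body_len <- length(base) - tail_a  # diagnostics avoid the 3' A-tail
  seqs <- character(n_subfamilies)
  nms <- character(n_subfamilies)
  for (i in seq_len(n_subfamilies)) {
    pos <- sort(sample.int(body_len, n_diagnostic))
    s <- base
    sub <- vapply(pos, function(p) sample(setdiff(c("A", "C", "G", "T"), s[p]), 1),
                  character(1))
    s[pos] <- sub
    seqs[i] <- paste(s, collapse = "")
    nms[i] <- paste0("Sub", i, " diag=", paste0(pos, ":", sub, collapse = ","))
  }
  out <- DNAStringSet(seqs)
  names(out) <- nms
  out
}

#' Short subfamily names of a library
#'
#' @param library a named `DNAStringSet` as from [make_subfamily_library()].
#' @return Character vector of names with any `diag=` annotation stripped.
#' @export
subfamily_names <- function(library) {
  vapply(strsplit(names(library), " "), `[[`, character(1), 1L)
}
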