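#' Assign an Alu sequence to its closest subfamily consensus
#'
#' Global alignment with cost-free terminal gaps (match +1, mismatch -1,
#' interior affine gaps: open 5, extend 1) against every consensus in the
#' library. Divergence is the percentage of mismatch plus interior-indel
#' columns over the aligned consensus columns; terminal gaps are excluded
#' (elements may be 5'-truncated, so a missing head is not evidence of
#' divergence). The best subfamily
#' minimizes divergence, ties broken by library order; elements at <= 2%
#' divergence are flagged young (recently integrated). CpG positions are not
#' down-weighted, a divergence-inflating simplification relative to
#' RepeatMasker-style scoring.
#'
#' @param alu_seq a `DNAString` or character string (>= 100 bases).
#' @param library named `DNAStringSet` of subfamily consensus sequences.
#' @param young_max divergence threshold (percent) for the young flag.
#' @return A one-row data.frame: `best_subfamily`, `divergence` (percent),
#'   `young`, `runner_up_margin` (percent; NA for a single-entry library).
#' @export
assign_subfamily <- function(alu_seq, library, young_max = 2.0) {
  if (is.character(alu_seq)) alu_seq <- DNAString(alu_seq)
  if (length(library) == 0L) stop("empty subfamily library")
  if (length(alu_seq) < 100L) stop("alu_seq must be at least 100 bases")
  div <- vapply(seq_along(library), function(i)
    .alignment_divergence(alu_seq, library[[i]]), numeric(1))
  best <- which.min(div)  # ties -> first in library order
  ord <- sort(div)
  data.frame(
    best_subfamily = subfamily_names(library)[best],
    divergence = div[best],
    young = div[best] <= young_max,
    runner_up_margin = if (length(div) > 1L) ord[2] - ord[1] else NA_real_,
    stringsAsFactors = FALSE)
}

# Percent divergence of `seq` from consensus: global alignment with
# cost-free terminal gaps (type "overlap"; interior affine gaps open 5,
# extend 1), then (mismatch + indel columns) / (aligned consensus columns)
# over the aligned region. Ends-free alignment is what makes a 5'-truncated
# element score as a clean suffix match: a strictly global alignment admits
# co-optimal tracebacks that anchor a stray terminal base before the long
# truncation gap, which a trim-the-ends rule then miscounts as divergence.
.alignment_divergence <- function(seq, consensus) {
  al <- pairwiseAlignment(DNAStringSet(list(seq)), consensus, type = "overlap",
                          substitutionMatrix = .submat(),
                          gapOpening = 5, gapExtension = 1)
  p <- strsplit(as.character(alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(alignedSubject(al)), "")[[1]]
  gap <- p == "-" | s == "-"
  inner <- which(!gap)
  if (!length(inner)) return(100)
  keep <- min(inner):max(inner)       # trim terminal gap runs
  p <- p[keep]; s <- s[keep]
  cons_cols <- sum(s != "-")
  bad <- sum(p != s)                  # mismatches plus interior indel columns
  100 * bad / cons_cols
}

#' Summarize subfamily calls
#'
#' @param calls data.frame of rows from [assign_subfamily()], optionally with
#'   a `locus_id` column.
#' @return data.frame ordered by count (descending): `subfamily`, `n`,
#'   `mean_divergence`, `min_divergence`, `max_divergence`, `n_young`,
#'   `young_fraction`.
#' @export
summarize_subfamilies <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  sp <- split(calls, calls$best_subfamily)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    subfamily = d$best_subfamily[1],
    n = nrow(d),
    mean_divergence = mean(d$divergence),
    min_divergence = min(d$divergence),
    max_divergence = max(d$divergence),
    n_young = sum(d$young),
    young_fraction = mean(d$young),
    stringsAsFactors = FALSE)))
  out <- out[order(-out$n, out$subfamily), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign subfamilies for every locus of a truth table
#'
#' Convenience wrapper over [assign_subfamily()] for planted loci whose
#' (possibly truncated) element sequence is at least 100 bases.
#'
#' @param truth an `alu_truth` table.
#' @param library subfamily `DNAStringSet`.
#' @return data.frame with `locus_id`, `true_subfamily` and the
#'   [assign_subfamily()] columns.
#' @export
assign_subfamilies_truth <- function(truth, library) {
  ok <- nchar(truth$alu_seq) >= 100L
  rows <- lapply(which(ok), function(i)
    cbind(locus_id = truth$locus_id[i], true_subfamily = truth$subfamily[i],
          assign_subfamily(truth$alu_seq[i], library),
          stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
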