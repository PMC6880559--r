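# Local alignment scoring used throughout: match +1, mismatch -1, linear gap -2.
.submat <- function() nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

# Vectorized local alignment of reads against the consensus.
# `orient` selects which orientation(s) to try per read: a list with integer
# vectors `fwd` and `rev` of read indices (a read may appear in both; the
# better-scoring orientation wins). Returns a data.frame (one row per
# qualifying read): strand ("+" = read as given matches consensus forward),
# astart/aend = the consensus-matching span in oriented-read coordinates,
# nmatch, identity.
.scan_reads <- function(reads, consensus, min_alu_bases, min_identity,
                        orient = NULL) {
  empty <- data.frame(idx = integer(0), strand = character(0),
                      astart = integer(0), aend = integer(0),
                      sstart = integer(0), send = integer(0),
                      ngaps = integer(0), nmatch = integer(0),
                      identity = numeric(0), score = numeric(0))
  if (!length(reads)) return(empty)
  orient <- orient %||% list(fwd = seq_along(reads), rev = seq_along(reads))
  align <- function(x) pairwiseAlignment(x, consensus, type = "local",
                                         substitutionMatrix = .submat(),
                                         gapOpening = 0, gapExtension = 2)
  aligned_cols <- function(al) {
    ni <- nindel(al)
    nmatch(al) + nmismatch(al) +
      insertion(ni)[, "WidthSum"] + deletion(ni)[, "WidthSum"]
  }
  rows <- list()
  one_strand <- function(oriented, idx, strand) {
    al <- align(oriented)
    pat <- pattern(al); sub <- pattern_subject(al)
    ni <- nindel(al)
    data.frame(idx = idx, strand = strand,
               astart = start(pat), aend = end(pat),
               sstart = sub[, 1], send = sub[, 2],
               ngaps = insertion(ni)[, "WidthSum"] + deletion(ni)[, "WidthSum"],
               nmatch = nmatch(al),
               identity = nmatch(al) / pmax(1L, aligned_cols(al)),
               score = score(al), stringsAsFactors = FALSE)
  }
  rows <- list()
  if (length(orient$fwd))
    rows$f <- one_strand(reads[orient$fwd], orient$fwd, "+")
  if (length(orient$rev))
    rows$r <- one_strand(reverseComplement(reads[orient$rev]),
                         orient$rev, "-")
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) return(empty)
  ## better orientation per read (ties go to the forward orientation)
  out <- out[order(out$idx, -out$score, out$strand), , drop = FALSE]
  out <- out[!duplicated(out$idx), , drop = FALSE]
  rownames(out) <- NULL
  out <- .polish_spans(out, reads, consensus)
  out[out$nmatch >= min_alu_bases & out$identity >= min_identity, , drop = FALSE]
}

pattern_subject <- function(al) {
  s <- subject(al)
  cbind(start(s), end(s))
}

# The DP traceback may include net-zero-score extensions at either end of a
# local alignment (a chance match absorbing an adjacent mismatch), which
# drags the cleave point into the flank at truncated-element junctions.
# Canonicalize gapless alignments to the shortest optimal form: trim the
# longest terminal run with a non-positive partial score from each end.
.polish_spans <- function(out, reads, consensus) {
  if (!nrow(out)) return(out)
  cons <- strsplit(as.character(consensus), "")[[1]]
  read_chr <- as.character(reads)
  for (r in seq_len(nrow(out))) {
    if (out$ngaps[r] > 0L) next  # gapped alignment: leave as is
    rd <- read_chr[[out$idx[r]]]
    if (out$strand[r] == "-") rd <- .revcomp_chr(rd)
    seg <- strsplit(substr(rd, out$astart[r], out$aend[r]), "")[[1]]
    sc <- ifelse(seg == cons[out$sstart[r]:out$send[r]], 1L, -1L)
    n <- length(sc)
    cum <- cumsum(sc)
    lead <- which(cum <= 0L)
    k_l <- if (length(lead)) max(lead) else 0L
    cum_r <- cumsum(rev(sc))
    trail <- which(cum_r <= 0L)
    k_r <- if (length(trail)) max(trail) else 0L
    if (k_l + k_r >= n || (k_l == 0L && k_r == 0L)) next
    keep <- sc[(k_l + 1L):(n - k_r)]
    out$astart[r] <- out$astart[r] + k_l
    out$aend[r] <- out$aend[r] - k_r
    out$sstart[r] <- out$sstart[r] + k_l
    out$send[r] <- out$send[r] - k_r
    out$nmatch[r] <- sum(keep == 1L)
    out$identity[r] <- out$nmatch[r] / length(keep)
    out$score[r] <- sum(keep)
  }
  out
}

#' Scan a read for an Alu-matching segment
#'
#' Best local alignment of the read (either orientation) against the
#' consensus under the default scoring scheme (match +1, mismatch -1,
#' gap -2). The read is a candidate split read when the alignment has at
#' least `min_alu_bases` matching bases at identity >= `min_identity`.
#'
#' @param read a `DNAString` or single character string.
#' @param consensus the Alu consensus (`DNAString`).
#' @param min_alu_bases minimum matched bases.
#' @param min_identity minimum alignment identity (matches / aligned columns).
#' @return `NULL` if no qualifying match, else a list with `span` (start, end
#'   of the Alu segment in oriented-read coordinates, 1-based closed),
#'   `identity`, `nmatch`, `strand` (`"-"` means the reverse complement of
#'   the read matched the consensus) and the alignment `score`.
#' @export
scan_read_for_alu <- function(read, consensus = alu_consensus(),
                              min_alu_bases = 20L, min_identity = 0.90) {
  if (is.character(read)) read <- DNAString(read)
  if (length(read) == 0L) stop("empty read")
  hit <- .scan_reads(DNAStringSet(list(read)), consensus,
                     min_alu_bases, min_identity)
  if (!nrow(hit)) return(NULL)
  list(span = c(hit$astart, hit$aend), identity = hit$identity,
       nmatch = hit$nmatch, strand = hit$strand, score = hit$score)
}

# Map one flank sequence to the reference. Placements are exact-ish matches
# (substitutions only, mismatch budget from min_identity); score = len - 2*mm.
# Returns list(chrom, start0, end0, strand, mm, margin) or
# list(reject = reason).
.map_flank <- function(flank, reference, min_identity = 0.95,
                       uniqueness_margin = 4L) {
  len <- nchar(as.character(flank))
  budget <- floor((1 - min_identity) * len)
  hits <- list()
  for (ci in seq_along(reference)) {
    subj <- reference[[ci]]
    for (str in c("+", "-")) {
      pat <- if (str == "+") flank else reverseComplement(flank)
      m <- matchPattern(pat, subj, max.mismatch = budget)
      if (length(m)) {
        mm <- neditStartingAt(pat, subj, starting.at = start(m))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = names(reference)[ci], start0 = start(m) - 1L,
          end0 = end(m), strand = str, mm = mm)
      }
    }
  }
  if (!length(hits)) return(list(reject = "unmapped"))
  h <- do.call(rbind, hits)
  h$score <- len - 2L * h$mm
  h <- h[order(-h$score), , drop = FALSE]
  margin <- if (nrow(h) >= 2L) h$score[1] - h$score[2] else len
  if (nrow(h) >= 2L && margin < uniqueness_margin)
    return(list(reject = "non_unique"))
  list(chrom = h$chrom[1], start0 = h$start0[1], end0 = h$end0[1],
       strand = h$strand[1], mm = h$mm[1], margin = margin)
}

#' Cleave the Alu segment of a split read and map the residual flank
#'
#' The non-Alu residue(s) of the read are aligned to the reference and
#' accepted when (a) at least `min_flank` bases long, (b) placed uniquely
#' (best placement beats the second best by >= `uniqueness_margin` score
#' units), and (c) at >= `min_flank_identity` identity. The junction is the
#' reference coordinate abutting the cleaved end; the flank side (5' or 3' of
#' the element) and the element strand follow from the geometry. A read whose
#' Alu segment is internal yields up to two evidence records, one per flank.
#'
#' @param read a `DNAString` or character string (as sequenced).
#' @param alu_scan result of [scan_read_for_alu()] for this read.
#' @param reference reference `DNAStringSet`.
#' @param min_flank minimum flank length in bases.
#' @param uniqueness_margin minimum score gap between best and second-best
#'   placement for the mapping to count as unique.
#' @param min_flank_identity minimum flank alignment identity.
#' @param read_id,individual_id identifiers copied into the evidence rows.
#' @return A data.frame of accepted evidence rows (possibly 0 rows) with an
#'   attribute `rejected` (data.frame of flank rejection reasons). Columns:
#'   `read_id`, `individual_id`, `chrom`, `pos` (0-based junction),
#'   `flank_side` (`5p`/`3p`), `flank_len`, `flank_seq`, `strand` (element
#'   strand on the reference), `alu_identity`, `alu_len`, `margin`,
#'   `junction_kmer` (up to 30 bases either side of the cleave point, oriented
#'   5'->3' along the element; used for the second-reference screen).
#' @export
cleave_and_map_flank <- function(read, alu_scan, reference,
                                 min_flank = 20L, uniqueness_margin = 4L,
                                 min_flank_identity = 0.95,
                                 read_id = "read", individual_id = "ind") {
  if (is.character(read)) read <- DNAString(read)
  if (is.null(alu_scan)) stop("alu_scan is NULL; run scan_read_for_alu first")
  oriented <- if (alu_scan$strand == "-") reverseComplement(read) else read
  rl <- length(oriented)
  s <- alu_scan$span[1]; e <- alu_scan$span[2]
  ev <- list(); rej <- list()
  sides <- list()
  if (s - 1L > 0L) sides$`5p` <- c(1L, s - 1L)      # flank left of element head
  if (rl - e > 0L) sides$`3p` <- c(e + 1L, rl)      # flank right of element tail
  for (side in names(sides)) {
    rng <- sides[[side]]
    flen <- rng[2] - rng[1] + 1L
    if (flen < min_flank) {
      rej[[length(rej) + 1L]] <- data.frame(read_id = read_id, side = side,
                                            reason = "flank_too_short")
      next
    }
    flank <- subseq(oriented, rng[1], rng[2])
    pl <- .map_flank(flank, reference, min_flank_identity, uniqueness_margin)
    if (!is.null(pl$reject)) {
      rej[[length(rej) + 1L]] <- data.frame(read_id = read_id, side = side,
                                            reason = pl$reject)
      next
    }
    ## geometry: oriented read has the element on the + of its own axis;
    ## flank placement strand gives the element strand on the reference.
    if (side == "5p") {
      pos <- if (pl$strand == "+") pl$end0 else pl$start0
      elt_strand <- pl$strand
    } else {
      pos <- if (pl$strand == "+") pl$start0 else pl$end0
      elt_strand <- pl$strand
    }
    km_l <- subseq(oriented, max(1L, ifelse(side == "5p", s - 30L, e - 29L)),
                   ifelse(side == "5p", s - 1L, e))
    km_r <- subseq(oriented, ifelse(side == "5p", s, e + 1L),
                   min(rl, ifelse(side == "5p", s + 29L, e + 30L)))
    ev[[length(ev) + 1L]] <- data.frame(
      read_id = read_id, individual_id = individual_id,
      chrom = pl$chrom, pos = pos, flank_side = side, flank_len = flen,
      flank_seq = as.character(flank), strand = elt_strand,
      alu_identity = alu_scan$identity, alu_len = e - s + 1L,
      margin = pl$margin,
      junction_kmer = paste0(as.character(km_l), as.character(km_r)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(ev)) do.call(rbind, ev) else .empty_evidence()
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(read_id = character(0), side = character(0),
               reason = character(0))
  out
}

.empty_evidence <- function() {
  data.frame(read_id = character(0), individual_id = character(0),
             chrom = character(0), pos = integer(0), flank_side = character(0),
             flank_len = integer(0), flank_seq = character(0),
             strand = character(0), alu_identity = numeric(0),
             alu_len = integer(0), margin = numeric(0),
             junction_kmer = character(0), stringsAsFactors = FALSE)
}
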