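#' Detection parameters
#'
#' Defaults follow the package's calling contract: a candidate split read
#' needs >= 20 matched Alu bases at >= 0.90 identity; the residual flank must
#' be >= 20 bp and uniquely placed; junctions within 25 bp are merged (target
#' site duplications and clipped-base jitter motivate a window larger than
#' 10 bp); a single supporting read suffices to call.
#'
#' @param min_alu_bases minimum matched bases against the consensus.
#' @param min_identity minimum Alu alignment identity.
#' @param min_flank minimum flank length (bases) to attempt mapping.
#' @param merge_window junction merge window (bases).
#' @param min_support minimum supporting reads per call.
#' @param uniqueness_margin score gap required between best and second-best
#'   flank placement.
#' @param seed_len k-mer length of the candidate-read prefilter.
#' @return A list of class `alu_detect_params`.
#' @export
detect_params <- function(min_alu_bases = 20L, min_identity = 0.90,
                          min_flank = 20L, merge_window = 25L,
                          min_support = 1L, uniqueness_margin = 4L,
                          seed_len = 11L) {
  structure(list(min_alu_bases = as.integer(min_alu_bases),
                 min_identity = min_identity,
                 min_flank = as.integer(min_flank),
                 merge_window = as.integer(merge_window),
                 min_support = as.integer(min_support),
                 uniqueness_margin = as.integer(uniqueness_margin),
                 seed_len = as.integer(seed_len)),
            class = "alu_detect_params")
}

# k-mer prefilter: for each strand of the consensus, the indices of reads
# sharing a seed k-mer with it, plus per-read seed-hit counts. Cuts the
# alignment workload to junction/element reads plus a small random
# background, and settles the orientation cheaply for most reads.
.candidate_reads <- function(reads, consensus, seed_len) {
  if (!length(reads)) return(list(fwd = integer(0), rev = integer(0)))
  kmerize <- function(s) {
    n <- nchar(s) - seed_len + 1L
    unique(substring(s, seq_len(n), seq_len(n) + seed_len - 1L))
  }
  cons <- as.character(consensus)
  rcons <- as.character(reverseComplement(DNAString(cons)))
  ## a read whose reverse complement matches the forward consensus shares
  ## k-mers with the reverse-complemented consensus
  n_f <- lengths(vwhichPDict(PDict(DNAStringSet(kmerize(cons))), reads))
  n_r <- lengths(vwhichPDict(PDict(DNAStringSet(kmerize(rcons))), reads))
  list(fwd = which(n_f > 0L & n_f >= n_r),
       rev = which(n_r > 0L & n_r >= n_f),
       n_seed = pmax(n_f, n_r))
}

# Reads provably internal to an element need no alignment: each distinct
# matched seed k-mer requires a distinct read start position inside the
# element segment, so a read retaining a clean flank of at least min_flank
# bases can match at most read_len - seed_len + 1 - min_flank distinct
# consensus k-mers. Reads at or above that bound have no usable flank.
.internal_by_seeds <- function(n_seed, read_len, seed_len, min_flank) {
  n_seed >= pmax(1L, read_len - seed_len + 2L - min_flank)
}

#' Call Alu insertions for one individual from its reads
#'
#' The split-read caller: every read sharing a seed k-mer with the consensus
#' is locally aligned to it ([scan_read_for_alu()]); qualifying reads have
#' their Alu segment cleaved and their residual flank(s) uniquely mapped to
#' the reference ([cleave_and_map_flank()]); accepted evidence is merged into
#' calls by single-linkage clustering of junctions within `merge_window`.
#' Mate-pair information is not used for calling (split reads only).
#'
#' The call coordinate is the 5' (element head side) cleave point when any 5'
#' evidence exists -- the modal 5' junction, ties broken to the smaller
#' coordinate -- otherwise the modal 3' junction.
#'
#' @param reads a `DNAStringSet`, or a list with `r1`/`r2` as returned by
#'   [simulate_reads()] (mates are pooled).
#' @param consensus Alu consensus `DNAString`.
#' @param reference reference `DNAStringSet`.
#' @param individual_id id recorded in the output.
#' @param params an `alu_detect_params`.
#' @return An object of class `alu_calls`: a data.frame of calls
#'   (`individual_id`, `chrom`, `pos`, `support`, `n_5p`, `max_5p_flank`,
#'   `strand`) with attributes `evidence` (read-level evidence rows, each
#'   tagged with its `call_id`) and `rejected` (flank rejection reasons).
#' @export
call_insertions <- function(reads, consensus = alu_consensus(), reference,
                            individual_id = "ind", params = detect_params()) {
  stopifnot(inherits(params, "alu_detect_params"))
  if (is.list(reads) && !is(reads, "DNAStringSet")) {
    nm <- c(paste0(names(reads$r1), "/1"), paste0(names(reads$r2), "/2"))
    reads <- c(reads$r1, reads$r2)
    names(reads) <- nm
  }
  if (!length(reads)) {
    warning("no reads for individual ", individual_id)
    return(.finalize_calls(.empty_evidence(), NULL, individual_id, params))
  }
  orient <- .candidate_reads(reads, consensus, params$seed_len)
  skip <- which(.internal_by_seeds(orient$n_seed, width(reads),
                                   params$seed_len, params$min_flank))
  orient$fwd <- setdiff(orient$fwd, skip)
  orient$rev <- setdiff(orient$rev, skip)
  hits <- .scan_reads(reads, consensus,
                      params$min_alu_bases, params$min_identity,
                      orient = orient)
  ## only reads with a mappable residue can become evidence; reads internal
  ## to an element (no flank of min_flank bases on either side) are skipped
  ## wholesale rather than recorded read by read
  if (nrow(hits)) {
    rl <- width(reads)[hits$idx]
    has_flank <- (hits$astart - 1L >= params$min_flank) |
      (rl - hits$aend >= params$min_flank)
    n_internal <- sum(!has_flank) + length(skip)
    hits <- hits[has_flank, , drop = FALSE]
  } else n_internal <- length(skip)
  ev <- list(); rej <- list()
  for (i in seq_len(nrow(hits))) {
    ri <- hits$idx[i]
    scan <- list(span = c(hits$astart[i], hits$aend[i]),
                 identity = hits$identity[i], nmatch = hits$nmatch[i],
                 strand = hits$strand[i])
    res <- cleave_and_map_flank(reads[[ri]], scan, reference,
                                min_flank = params$min_flank,
                                uniqueness_margin = params$uniqueness_margin,
                                read_id = names(reads)[ri] %||% as.character(ri),
                                individual_id = individual_id)
    if (nrow(res)) ev[[length(ev) + 1L]] <- res
    r <- attr(res, "rejected")
    if (nrow(r)) rej[[length(rej) + 1L]] <- r
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else .empty_evidence()
  rejected <- if (length(rej)) do.call(rbind, rej) else NULL
  out <- .finalize_calls(evidence, rejected, individual_id, params)
  attr(out, "n_internal") <- n_internal  # element-internal reads, no flank
  out
}

# Merge evidence junctions into calls (single linkage along the coordinate).
.finalize_calls <- function(evidence, rejected, individual_id, params) {
  calls <- list()
  if (nrow(evidence)) {
    evidence <- evidence[order(evidence$chrom, evidence$pos), , drop = FALSE]
    evidence$call_id <- NA_character_
    k <- 0L
    for (chrom in unique(evidence$chrom)) {
      rows <- which(evidence$chrom == chrom)
      grp <- cumsum(c(1L, diff(evidence$pos[rows]) > params$merge_window))
      for (g in unique(grp)) {
        k <- k + 1L
        id <- sprintf("%s_c%04d", individual_id, k)
        idx <- rows[grp == g]
        evidence$call_id[idx] <- id
        sub <- evidence[idx, , drop = FALSE]
        pos <- .call_junction(sub)
        is5 <- sub$flank_side == "5p"
        calls[[k]] <- data.frame(
          call_id = id, individual_id = individual_id, chrom = chrom,
          pos = pos, support = nrow(sub), n_5p = sum(is5),
          max_5p_flank = if (any(is5)) max(sub$flank_len[is5]) else 0L,
          strand = names(which.max(table(sub$strand))),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(call_id = character(0), individual_id = character(0),
               chrom = character(0), pos = integer(0), support = integer(0),
               n_5p = integer(0), max_5p_flank = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  out <- out[out$support >= params$min_support, , drop = FALSE]
  if (nrow(out)) out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            evidence = evidence,
            rejected = rejected %||% data.frame(read_id = character(0),
                                                side = character(0),
                                                reason = character(0)),
            params = params,
            class = c("alu_calls", "data.frame"))
}

# Representative junction of one evidence cluster: modal 5' position when 5'
# evidence exists (ties to the smaller coordinate), else modal 3' position.
.call_junction <- function(ev) {
  side <- if (any(ev$flank_side == "5p")) "5p" else "3p"
  p <- ev$pos[ev$flank_side == side]
  tab <- table(p)
  as.integer(names(tab)[which.max(tab)])  # table names sorted: ties -> smaller
}

#' Evidence and rejection accessors for calls
#'
#' @param calls an `alu_calls` object (or a list of them).
#' @return The read-level evidence (or rejection) data.frame.
#' @export
call_evidence <- function(calls) attr(calls, "evidence")

#' @rdname call_evidence
#' @export
call_rejections <- function(calls) attr(calls, "rejected")

#' Run the caller across a cohort
#'
#' @param reads_by_individual named list (individual id -> reads as accepted
#'   by [call_insertions()]).
#' @param consensus,reference,params as in [call_insertions()].
#' @return Named list of `alu_calls`, one per individual.
#' @export
detect_cohort <- function(reads_by_individual, consensus = alu_consensus(),
                          reference, params = detect_params()) {
  ids <- names(reads_by_individual)
  stopifnot(!is.null(ids))
  out <- lapply(ids, function(id)
    call_insertions(reads_by_individual[[id]], consensus, reference,
                    individual_id = id, params = params))
  names(out) <- ids
  out
}
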