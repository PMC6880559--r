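#' Apply the 5'-flank-length read filter to a set of calls
#'
#' A locus call for an individual survives iff it retains at least one
#' supporting split read whose flank is on the 5' (element head) side and at
#' least `min_5p_flank` bases long. Surviving calls keep all their evidence;
#' the filter is therefore idempotent, and raising the threshold can only
#' shrink each individual's call set.
#'
#' @param calls an `alu_calls` object or a list of them (one per individual).
#' @param min_5p_flank bases; 0 is the identity transform.
#' @return The same shape as the input, filtered; each `alu_calls` keeps a
#'   `removed` attribute listing the dropped calls.
#' @export
apply_flank_filter <- function(calls, min_5p_flank = 30L) {
  if (!inherits(calls, "alu_calls") && is.list(calls))
    return(lapply(calls, apply_flank_filter, min_5p_flank = min_5p_flank))
  stopifnot(inherits(calls, "alu_calls"))
  keep <- calls$max_5p_flank >= min_5p_flank
  ev <- attr(calls, "evidence")
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(ev) && nrow(ev))
    ev <- ev[ev$call_id %in% out$call_id | is.na(ev$call_id), , drop = FALSE]
  structure(out, evidence = ev, rejected = attr(calls, "rejected"),
            params = attr(calls, "params"),
            removed = calls[!keep, , drop = FALSE],
            class = c("alu_calls", "data.frame"))
}

#' Re-cluster filtered calls and compare with the original run
#'
#' Re-runs locus clustering, matrix construction, classification and binning
#' on the post-filter calls, then reports the shifts: total and per-bin locus
#' deltas, per-individual calls removed, and the loci that enter or leave
#' each species-indicative set. The latter captures a documented pathology of
#' post-hoc read filtering: removing another individual's call can promote a
#' locus into a species-indicative set it did not originally belong to.
#'
#' @param filtered_calls list of filtered `alu_calls` (from
#'   [apply_flank_filter()]).
#' @param original_matrix the pre-filter `alu_matrix`.
#' @param cohort an `alu_cohort`.
#' @param min_5p_flank the threshold used (recorded in the report).
#' @param cluster_window bases, as in [cluster_calls()].
#' @param second_reference,evidence optional, as in [build_matrix()].
#' @return A list of class `alu_filter_report`: `report` (scalars), `bins_before`,
#'   `bins_after`, `per_bin` (data.frame bin/before/after/delta),
#'   `individuals_affected`, `indicative_gained`, `indicative_lost`,
#'   `matrix` (post-filter `alu_matrix`), `loci` (post-filter `alu_loci`).
#' @export
rebuild_and_compare <- function(filtered_calls, original_matrix, cohort,
                                min_5p_flank = 30L, cluster_window = 25L,
                                second_reference = NULL, evidence = NULL) {
  stopifnot(inherits(original_matrix, "alu_matrix"))
  loci2 <- cluster_calls(filtered_calls, cluster_window)
  ev2 <- evidence %||% do.call(rbind, lapply(filtered_calls, call_evidence))
  mat2 <- build_matrix(loci2, cohort, second_reference = second_reference,
                       evidence = ev2)
  cls1 <- classify_loci(original_matrix)
  cls2 <- classify_loci(mat2)
  bins1 <- bin_shared_insertions(original_matrix)
  bins2 <- bin_shared_insertions(mat2)
  per_bin <- data.frame(bin = as.integer(rownames(bins1$counts)),
                        before = bins1$totals, after = bins2$totals)
  per_bin$delta <- per_bin$after - per_bin$before
  removed <- lapply(filtered_calls, function(cl) attr(cl, "removed"))
  affected <- vapply(removed, function(r) if (is.null(r)) 0L else nrow(r),
                     integer(1))
  sets1 <- species_indicative(original_matrix)
  sets2 <- species_indicative(mat2)
  gained <- lost <- list()
  for (s in names(sets1)) {
    pos1 <- original_matrix$loci$pos[match(sets1[[s]],
                                           original_matrix$loci$locus_id)]
    pos2 <- mat2$loci$pos[match(sets2[[s]], mat2$loci$locus_id)]
    chr1 <- original_matrix$loci$chrom[match(sets1[[s]],
                                             original_matrix$loci$locus_id)]
    chr2 <- mat2$loci$chrom[match(sets2[[s]], mat2$loci$locus_id)]
    in_orig <- .match_positions(chr2, pos2, chr1, pos1, cluster_window)
    in_post <- .match_positions(chr1, pos1, chr2, pos2, cluster_window)
    gained[[s]] <- sets2[[s]][!in_orig]
    lost[[s]] <- sets1[[s]][!in_post]
  }
  structure(list(
    report = list(min_5p_flank = min_5p_flank,
                  loci_before = nrow(original_matrix$loci),
                  loci_after = nrow(mat2$loci),
                  ascertained_before = cls1$counts[["ascertained_shared"]],
                  ascertained_after = cls2$counts[["ascertained_shared"]],
                  fixed_pct_before = cls1$fixed_pct,
                  fixed_pct_after = cls2$fixed_pct,
                  polymorphic_pct_before = cls1$polymorphic_pct,
                  polymorphic_pct_after = cls2$polymorphic_pct),
    per_bin = per_bin, bins_before = bins1, bins_after = bins2,
    individuals_affected = affected,
    indicative_gained = gained, indicative_lost = lost,
    matrix = mat2, loci = loci2),
    class = "alu_filter_report")
}

# For each query locus (chrom, pos), is there a subject locus on the same
# chromosome within `window` bases?
.match_positions <- function(qchr, qpos, schr, spos, window) {
  if (!length(qpos)) return(logical(0))
  vapply(seq_along(qpos), function(i)
    any(schr == qchr[i] & abs(spos - qpos[i]) <= window), logical(1))
}

#' @export
print.alu_filter_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "5'-flank filter (>= %d bp): loci %d -> %d; fixed %.1f%% -> %.1f%%; polymorphic %.1f%% -> %.1f%%\n",
    r$min_5p_flank, r$loci_before, r$loci_after, r$fixed_pct_before,
    r$fixed_pct_after, r$polymorphic_pct_before, r$polymorphic_pct_after))
  cat("calls removed per individual:",
      paste(names(x$individuals_affected), x$individuals_affected,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' High-confidence species-indicative sets after filtering
#'
#' The intersection rule: keep a post-filter locus iff it is also present in
#' the original (pre-filter) species-indicative set for the same species and
#' is not flagged as present in the second reference. Loci are matched across
#' the two runs by junction proximity (same chromosome, within `window`).
#'
#' @param post_sets,orig_sets named lists from [species_indicative()] on the
#'   post- and pre-filter matrices.
#' @param post_matrix,orig_matrix the corresponding `alu_matrix` objects
#'   (used for coordinates and the `in_second_reference` flag of the
#'   post-filter loci).
#' @param window locus-matching window in bases.
#' @return Named list, species -> character vector of retained post-filter
#'   locus ids.
#' @export
high_confidence_set <- function(post_sets, orig_sets, post_matrix,
                                orig_matrix, window = 25L) {
  out <- list()
  for (s in names(post_sets)) {
    ids <- post_sets[[s]]
    i2 <- match(ids, post_matrix$loci$locus_id)
    i1 <- match(orig_sets[[s]] %||% character(0), orig_matrix$loci$locus_id)
    in_orig <- .match_positions(post_matrix$loci$chrom[i2],
                                post_matrix$loci$pos[i2],
                                orig_matrix$loci$chrom[i1],
                                orig_matrix$loci$pos[i1], window)
    flagged <- post_matrix$loci$in_second_reference[i2]
    out[[s]] <- ids[in_orig & !flagged]
  }
  out
}
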