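#' Cluster per-individual calls into cohort-level loci
#'
#' Single-linkage clustering along each chromosome: calls are processed in
#' coordinate order and a call joins the open cluster iff its junction lies
#' within `cluster_window` of the cluster representative (the median junction
#' of the members so far); otherwise a new cluster is opened. The construction
#' is deterministic and independent of the input order of individuals.
#'
#' @param calls_list list of `alu_calls` (one per individual), or a single
#'   data.frame of pooled calls with `individual_id`, `chrom`, `pos`.
#' @param cluster_window bases.
#' @return A list of class `alu_loci`: `loci` (data.frame `locus_id`, `chrom`,
#'   `pos` = median junction, `n_individuals`) and `members` (pooled calls
#'   annotated with `locus_id`).
#' @export
cluster_calls <- function(calls_list, cluster_window = 25L) {
  pooled <- if (is.data.frame(calls_list)) calls_list
            else do.call(rbind, lapply(calls_list, as.data.frame))
  if (is.null(pooled) || !nrow(pooled)) {
    return(structure(list(
      loci = data.frame(locus_id = character(0), chrom = character(0),
                        pos = integer(0), n_individuals = integer(0)),
      members = data.frame()), class = "alu_loci"))
  }
  pooled <- pooled[order(pooled$chrom, pooled$pos), , drop = FALSE]
  rownames(pooled) <- NULL
  pooled$locus_id <- NA_character_
  loci <- list()
  k <- 0L
  for (chrom in unique(pooled$chrom)) {
    rows <- which(pooled$chrom == chrom)
    members <- integer(0)
    flush <- function() {
      if (!length(members)) return()
      k <<- k + 1L
      id <- sprintf("L%04d", k)
      pooled$locus_id[members] <<- id
      loci[[k]] <<- data.frame(
        locus_id = id, chrom = chrom,
        pos = as.integer(round(median(pooled$pos[members]))),
        n_individuals = length(unique(pooled$individual_id[members])),
        stringsAsFactors = FALSE)
    }
    for (r in rows) {
      if (length(members) &&
          abs(pooled$pos[r] - median(pooled$pos[members])) <= cluster_window) {
        members <- c(members, r)
      } else {
        flush()
        members <- r
      }
    }
    flush()
  }
  structure(list(loci = do.call(rbind, loci), members = pooled),
            class = "alu_loci")
}

#' @export
print.alu_loci <- function(x, ...) {
  cat("Clustered", nrow(x$members), "calls into", nrow(x$loci), "loci\n")
  invisible(x)
}

#' Build the cohort detection matrix
#'
#' State is `detected` (1) iff the individual contributed at least one call to
#' the locus, else `not_detected` (0). `not_detected` is a single state: the
#' absence of a call reflects a lack of acceptable supporting reads, not a
#' predicted absence -- the per-cell support counts are therefore carried
#' alongside so downstream users can distinguish 0-support from low-support.
#' Loci detected in the outgroup are flagged `in_outgroup` and excluded from
#' all downstream statistics (candidate insertions must be absent from the
#' outgroup). If `second_reference` is supplied, loci whose filled-junction
#' 60-mer is found in it are flagged `in_second_reference` (a stand-in for
#' screening candidates against a second assembled genome).
#'
#' @param loci an `alu_loci` from [cluster_calls()].
#' @param cohort an `alu_cohort`.
#' @param second_reference optional `DNAStringSet` to screen junctions against.
#' @param evidence optional pooled evidence data.frame (with `junction_kmer`);
#'   required for the second-reference screen.
#' @return An object of class `alu_matrix`: list with `detected` and `support`
#'   (loci x individuals integer matrices), `loci` (data.frame with flags),
#'   `cohort`.
#' @export
build_matrix <- function(loci, cohort, second_reference = NULL,
                         evidence = NULL) {
  stopifnot(inherits(loci, "alu_loci"), inherits(cohort, "alu_cohort"))
  ids <- cohort$individuals$id
  ldf <- loci$loci
  n <- nrow(ldf)
  det <- sup <- matrix(0L, nrow = n, ncol = length(ids),
                       dimnames = list(ldf$locus_id, ids))
  mem <- loci$members
  if (n && nrow(mem)) {
    if (!all(mem$individual_id %in% ids))
      stop("calls contain unknown individual(s): ",
           paste(setdiff(unique(mem$individual_id), ids), collapse = ", "))
    for (r in seq_len(nrow(mem))) {
      li <- mem$locus_id[r]
      det[li, mem$individual_id[r]] <- 1L
      sup[li, mem$individual_id[r]] <- sup[li, mem$individual_id[r]] +
        mem$support[r]
    }
  }
  og <- outgroup_id(cohort)
  ldf$in_outgroup <- if (n) det[, og] > 0L else logical(0)
  ldf$in_second_reference <- rep(FALSE, n)
  if (!is.null(second_reference) && n) {
    if (is.null(evidence) || is.null(evidence$junction_kmer))
      stop("second-reference screen needs evidence with junction_kmer")
    for (i in seq_len(n)) {
      km <- evidence$junction_kmer[
        !is.na(evidence$call_id) &
          evidence$call_id %in% mem$call_id[mem$locus_id == ldf$locus_id[i]]]
      km <- km[nchar(km) >= 40L]
      if (!length(km)) next
      km <- DNAString(km[which.max(nchar(km))])
      found <- any(vapply(seq_along(second_reference), function(ci)
        length(matchPattern(km, second_reference[[ci]])) > 0L ||
          length(matchPattern(reverseComplement(km),
                              second_reference[[ci]])) > 0L,
        logical(1)))
      ldf$in_second_reference[i] <- found
    }
  }
  structure(list(detected = det, support = sup, loci = ldf, cohort = cohort),
            class = "alu_matrix")
}

#' @export
print.alu_matrix <- function(x, ...) {
  cat("Detection matrix:", nrow(x$loci), "loci x", ncol(x$detected),
      "individuals;", sum(x$loci$in_outgroup), "flagged in outgroup;",
      sum(x$loci$in_second_reference), "in second reference\n")
  invisible(x)
}

# Loci retained for statistics: not outgroup-detected.
.screened_rows <- function(matrix) which(!matrix$loci$in_outgroup)

#' Classify screened loci by ingroup carrier count
#'
#' Among loci absent from the outgroup and detected in the intergeneric
#' individual, the ingroup carrier count k determines the class: k equal to
#' the full ingroup size is `fixed`; 2 <= k <= n-1 is `polymorphic` (retained
#' for the sharing bins); k = 1 is a `singleton` (reported but excluded from
#' the bins, which start at 2); k = 0 is private to the intergeneric
#' individual. The ascertained total counts loci with k >= 2 (fixed +
#' polymorphic), matching the convention that candidates are "shared by two
#' to twelve" ingroup individuals.
#'
#' @param matrix an `alu_matrix`.
#' @param intergeneric_id defaults to the cohort's intergeneric individual.
#' @return An object of class `alu_classification`: list with `per_locus`
#'   (data.frame `locus_id`, `k`, `class`), `counts` (named: ascertained_shared,
#'   fixed_ingroup, polymorphic_ingroup, singleton, intergeneric_private),
#'   `bins` (named vector, loci per carrier-count bin 2..n-1), `fixed_pct`
#'   and `polymorphic_pct` (percent of the ascertained total).
#' @export
classify_loci <- function(matrix, intergeneric_id = NULL) {
  stopifnot(inherits(matrix, "alu_matrix"))
  ig <- intergeneric_id %||% intergeneric_id(matrix$cohort)
  ing <- ingroup_ids(matrix$cohort)
  rows <- .screened_rows(matrix)
  det <- matrix$detected[rows, , drop = FALSE]
  shared <- det[, ig] > 0L
  k <- as.integer(det[shared, ing, drop = FALSE] %*% rep(1L, length(ing)))
  ids <- rownames(det)[shared]
  n <- length(ing)
  cls <- ifelse(k == n, "fixed", ifelse(k >= 2L, "polymorphic",
                ifelse(k == 1L, "singleton", "intergeneric_private")))
  bins <- table(factor(k[cls == "polymorphic"], levels = 2:(n - 1L)))
  counts <- c(ascertained_shared = sum(cls %in% c("fixed", "polymorphic")),
              fixed_ingroup = sum(cls == "fixed"),
              polymorphic_ingroup = sum(cls == "polymorphic"),
              singleton = sum(cls == "singleton"),
              intergeneric_private = sum(cls == "intergeneric_private"))
  .classification(counts, bins,
                  per_locus = data.frame(locus_id = ids, k = k, class = cls,
                                         stringsAsFactors = FALSE))
}

.classification <- function(counts, bins = NULL, per_locus = NULL) {
  asc <- counts[["ascertained_shared"]]
  structure(list(
    per_locus = per_locus, counts = counts, bins = bins,
    fixed_pct = if (asc > 0) 100 * counts[["fixed_ingroup"]] / asc else NA_real_,
    polymorphic_pct = if (asc > 0)
      100 * counts[["polymorphic_ingroup"]] / asc else NA_real_),
    class = "alu_classification")
}

#' Classification summary from bare ascertainment totals
#'
#' Builds the same summary object as [classify_loci()] from published or
#' otherwise precomputed totals, so fixed/polymorphic percentages are always
#' produced by the one code path.
#'
#' @param n_fixed,n_polymorphic,n_singleton,n_private locus counts.
#' @return An `alu_classification`.
#' @export
classification_from_counts <- function(n_fixed, n_polymorphic,
                                       n_singleton = 0L, n_private = 0L) {
  .classification(c(ascertained_shared = n_fixed + n_polymorphic,
                    fixed_ingroup = n_fixed,
                    polymorphic_ingroup = n_polymorphic,
                    singleton = n_singleton,
                    intergeneric_private = n_private))
}

#' @export
print.alu_classification <- function(x, ...) {
  cat(sprintf(
    "Ascertained shared loci: %d (fixed %d = %.1f%%, polymorphic %d = %.1f%%); singletons %d\n",
    x$counts[["ascertained_shared"]], x$counts[["fixed_ingroup"]],
    x$fixed_pct, x$counts[["polymorphic_ingroup"]], x$polymorphic_pct,
    x$counts[["singleton"]]))
  invisible(x)
}

#' Write a detection matrix as TSV
#'
#' One row per locus: `locus_id chrom pos flag_outgroup flag_ref2` then a
#' `detected(support)` cell per individual.
#'
#' @param matrix an `alu_matrix`.
#' @param path file path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  ids <- colnames(matrix$detected)
  cells <- matrix(sprintf("%d(%d)", matrix$detected, matrix$support),
                  nrow = nrow(matrix$detected))
  df <- cbind(matrix$loci[, c("locus_id", "chrom", "pos")],
              flag_outgroup = as.integer(matrix$loci$in_outgroup),
              flag_ref2 = as.integer(matrix$loci$in_second_reference),
              as.data.frame(cells, stringsAsFactors = FALSE))
  names(df)[6:(5 + length(ids))] <- ids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
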