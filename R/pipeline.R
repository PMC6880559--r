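#' Configuration for an end-to-end pipeline run
#'
#' The default preset is the package's standing study design: a 14-individual
#' cohort (6 ingroup species x 2, one intergeneric, one outgroup), a 100 kb
#' single-chromosome reference, 30x coverage, and a planting design spanning
#' fixed, polymorphic, species-indicative, intergenerically shared and
#' intergeneric-private loci.
#'
#' @param cohort an `alu_cohort`.
#' @param chrom_len,n_chroms,gc reference parameters
#'   ([generate_reference()]).
#' @param design planting design ([plant_insertions()]).
#' @param shared_bins optional ingroup carrier counts for the
#'   `intergeneric_shared` loci.
#' @param readsim an `alu_readsim_params` (its `seed` field is ignored; the
#'   pipeline seed is fanned out per stage).
#' @param detect an `alu_detect_params`.
#' @param min_5p_flank 5'-flank filter threshold (bases).
#' @param cluster_window cohort clustering window (bases).
#' @param with_second_reference if `TRUE`, a second reference carrying a
#'   subset of the planted insertions is built and screened against.
#' @param seed integer master seed, fanned out into per-stage substreams.
#' @param out_dir optional directory; when given, FASTA/FASTQ/TSV artifacts
#'   are written there.
#' @return A list of class `alu_run_config`.
#' @export
alu_run_config <- function(cohort = papio_gelada_cohort(),
                           chrom_len = 1e5, n_chroms = 1L, gc = 0.40,
                           design = c(fixed_ingroup = 8,
                                      polymorphic_ingroup = 8,
                                      species_indicative = 12,
                                      intergeneric_shared = 30,
                                      intergeneric_private = 4),
                           shared_bins = NULL,
                           readsim = read_sim_params(),
                           detect = detect_params(),
                           min_5p_flank = 30L, cluster_window = 25L,
                           with_second_reference = FALSE,
                           seed = 1L, out_dir = NULL) {
  structure(list(cohort = cohort, chrom_len = chrom_len, n_chroms = n_chroms,
                 gc = gc, design = design, shared_bins = shared_bins,
                 readsim = readsim, detect = detect,
                 min_5p_flank = as.integer(min_5p_flank),
                 cluster_window = as.integer(cluster_window),
                 with_second_reference = with_second_reference,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "alu_run_config")
}

#' Run the full pipeline: simulate, detect, genotype, analyse
#'
#' Chains the stages on a synthetic cohort: reference generation, insertion
#' planting, read simulation, split-read calling, locus clustering, matrix
#' construction with outgroup (and optional second-reference) screening,
#' classification, sharing bins with per-bin ANOVA, species-indicative sets
#' with intergeneric cross-reference and z-test, the 5'-flank filter with
#' rebuild/compare and high-confidence sets, truth-based validation, and
#' subfamily assignment of the planted elements.
#'
#' @param config an `alu_run_config`.
#' @param verbose print per-stage progress.
#' @return A list of class `alu_pipeline_run` with all stage products
#'   (`truth`, `reference`, `calls`, `loci`, `matrix`, `classification`,
#'   `bins`, `anova_species`, `anova_clade`, `indicative`, `cross_ref`,
#'   `ztest`, `filter_report`, `high_confidence`, `validation`,
#'   `subfamilies`, `recovery`, `summary`).
#' @export
run_alu_pipeline <- function(config = alu_run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "alu_run_config"))
  say <- function(...) if (verbose) message(...)
  seeds <- .stage_seeds(config$seed,
                        c("reference", "plant", "reads", "library", "ref2"))
  cohort <- config$cohort
  say("reference: ", config$n_chroms, " x ", config$chrom_len, " bp")
  reference <- generate_reference(config$n_chroms, config$chrom_len,
                                  config$gc, seed = seeds[["reference"]])
  library <- make_subfamily_library(seed = seeds[["library"]])
  truth <- plant_insertions(reference, cohort, design = config$design,
                            library = library, seed = seeds[["plant"]],
                            guard = max(900L, 2L * config$readsim$frag_mean),
                            shared_bins = config$shared_bins)
  say("planted ", nrow(truth), " loci")
  donors <- build_donor_genomes(reference, truth)
  ids <- cohort$individuals$id
  .set_seed(seeds[["reads"]])
  read_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  reads <- lapply(seq_along(ids), function(i) {
    p <- config$readsim
    p$seed <- read_seeds[i]
    simulate_reads(donors[[ids[i]]], p, id_prefix = ids[i])
  })
  names(reads) <- ids
  say("simulated reads for ", length(ids), " individuals")
  calls <- detect_cohort(reads, alu_consensus(), reference,
                         params = config$detect)
  say("called ", sum(vapply(calls, nrow, integer(1))), " per-individual calls")
  loci <- cluster_calls(calls, config$cluster_window)
  evidence <- do.call(rbind, lapply(calls, call_evidence))
  ref2 <- NULL
  if (config$with_second_reference) {
    ## a second assembly carrying every other planted insertion
    sub <- truth[seq(1, nrow(truth), by = 2L), , drop = FALSE]
    attr(sub, "cohort") <- cohort
    ref2 <- .filled_reference(reference, sub)
  }
  mat <- build_matrix(loci, cohort, second_reference = ref2,
                      evidence = evidence)
  cls <- classify_loci(mat)
  bins <- bin_shared_insertions(mat)
  an_sp <- anova_bins(bins, "species")
  an_cl <- anova_bins(bins, "clade")
  sets <- species_indicative(mat)
  xref <- cross_reference_intergeneric(sets, mat)
  zt <- if (sum(xref$n_shared) > 0 && sd(xref$n_shared) > 0)
    ztest_counts(structure(xref$n_shared, names = xref$species)) else NULL
  filtered <- apply_flank_filter(calls, config$min_5p_flank)
  frep <- rebuild_and_compare(filtered, mat, cohort,
                              min_5p_flank = config$min_5p_flank,
                              cluster_window = config$cluster_window,
                              second_reference = ref2)
  hc <- high_confidence_set(species_indicative(frep$matrix), sets,
                            frep$matrix, mat,
                            window = config$cluster_window)
  val <- compare_predictions(mat, .truth_matched_to(mat, truth, cohort),
                             panel = ingroup_ids(cohort))
  subfam <- assign_subfamilies_truth(truth, library)
  recovery <- evaluate_detection(calls, truth, cohort,
                                 tol = 5L, window = config$cluster_window)
  summary <- list(
    n_planted = nrow(truth),
    n_loci_called = nrow(mat$loci),
    ascertained = cls$counts[["ascertained_shared"]],
    fixed = cls$counts[["fixed_ingroup"]],
    fixed_pct = cls$fixed_pct,
    polymorphic = cls$counts[["polymorphic_ingroup"]],
    sensitivity = recovery$sensitivity,
    mean_junction_error = recovery$mean_junction_error,
    false_calls = recovery$false_calls,
    bin_agreement = recovery$bin_agreement)
  run <- structure(list(
    config = config, truth = truth, reference = reference, library = library,
    calls = calls, loci = loci, matrix = mat, classification = cls,
    bins = bins, anova_species = an_sp, anova_clade = an_cl,
    indicative = sets, cross_ref = xref, ztest = zt,
    filter_report = frep, high_confidence = hc, validation = val,
    subfamilies = subfam, recovery = recovery, summary = summary),
    class = "alu_pipeline_run")
  if (!is.null(config$out_dir)) .write_run(run, config$out_dir)
  run
}

# Reference with a subset of insertions filled in (one haplotype, all loci of
# `truth` at copy >= 1 regardless of carriers).
.filled_reference <- function(reference, truth) {
  chrs <- as.character(reference)
  ord <- order(truth$pos, decreasing = TRUE)
  for (i in ord) {
    chr <- truth$chrom[i]; p <- truth$pos[i]; t <- truth$tsd_len[i]
    s <- chrs[[chr]]
    chrs[[chr]] <- paste0(substr(s, 1L, p + t), truth$alu_seq[i],
                          substr(s, p + 1L, nchar(s)))
  }
  DNAStringSet(chrs)
}

# Detection matrix rows matched to planted loci by junction proximity, so the
# truth table can serve as the validation genotype source.
.truth_matched_to <- function(mat, truth, cohort, window = 25L) {
  g <- truth_genotypes(truth)
  j5 <- truth_junction5p(truth)
  idx <- vapply(seq_len(nrow(mat$loci)), function(i) {
    hit <- which(truth$chrom == mat$loci$chrom[i] &
                   abs(j5 - mat$loci$pos[i]) <= window)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  g2 <- g[idx[keep], , drop = FALSE]
  rownames(g2) <- mat$loci$locus_id[keep]
  pcr_genotype_table(g2)
}

#' Score called insertions against the planted truth
#'
#' For every (locus, carrier individual) pair in the truth table, the call is
#' recovered iff that individual has a call on the same chromosome within
#' `window` bases of the planted junction. Sensitivity is the recovered
#' fraction. The junction error of a recovered pair is the distance from the
#' call coordinate to the duplicated target site `[pos, pos + tsd_len]`
#' (0 when the call lies inside it): a TPRT insertion's cleave point is only
#' defined up to the TSD -- when the duplicated bases happen to extend the
#' element-consensus match, any coordinate within the TSD is an equally
#' valid, score-optimal description of the same insertion event. False calls
#' are calls (in any individual) farther than `window` from every planted
#' junction, plus calls at planted junctions in individuals the truth says
#' are non-carriers. Bin agreement compares, per intergenerically shared
#' polymorphic truth locus, the planted ingroup carrier count with the
#' detected one.
#'
#' @param calls list of `alu_calls` (or pooled data.frame).
#' @param truth an `alu_truth` table.
#' @param cohort an `alu_cohort`.
#' @param tol junction-error tolerance (bases) counted in
#'   `junction_within_tol`.
#' @param window matching window (bases).
#' @return list with `sensitivity`, `mean_junction_error`,
#'   `junction_within_tol`, `false_calls`, `bin_agreement`, `per_pair`
#'   (data.frame of truth carrier pairs and their outcome).
#' @export
evaluate_detection <- function(calls, truth, cohort, tol = 5L, window = 25L) {
  pooled <- if (is.data.frame(calls)) calls
            else do.call(rbind, lapply(calls, as.data.frame))
  g <- truth_genotypes(truth)
  j5 <- truth_junction5p(truth)
  ids <- cohort$individuals$id
  ## distance from a call to the duplicated target site [pos, pos + tsd]
  tsd_dist <- function(p, i) pmax(0L, pmax(truth$pos[i] - p, p - j5[i]))
  pairs <- list()
  for (i in seq_len(nrow(truth))) {
    carriers <- ids[g[truth$locus_id[i], ] > 0L]
    for (id in carriers) {
      cand <- pooled[pooled$individual_id == id &
                       pooled$chrom == truth$chrom[i], , drop = FALSE]
      d <- tsd_dist(cand$pos, i)
      hit <- length(d) && min(d) <= window
      pairs[[length(pairs) + 1L]] <- data.frame(
        locus_id = truth$locus_id[i], individual_id = id,
        recovered = hit,
        junction_error = if (hit) min(d) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  per_pair <- do.call(rbind, pairs)
  ## calls not explained by any planted carrier junction
  false_calls <- 0L
  if (nrow(pooled)) {
    for (r in seq_len(nrow(pooled))) {
      near <- which(truth$chrom == pooled$chrom[r] &
                      abs(j5 - pooled$pos[r]) <= window)
      carrier_near <- length(near) &&
        any(g[truth$locus_id[near], pooled$individual_id[r]] > 0L)
      if (!carrier_near) false_calls <- false_calls + 1L
    }
  }
  ## bin agreement over intergenerically shared polymorphic truth loci
  ing <- ingroup_ids(cohort)
  shared_rows <- which(truth$class == "intergeneric_shared")
  agree <- NA_real_
  if (length(shared_rows)) {
    planted_k <- rowSums(g[shared_rows, ing, drop = FALSE] > 0L)
    detected_k <- vapply(shared_rows, function(i) {
      sum(vapply(ing, function(id) {
        cand <- pooled[pooled$individual_id == id &
                         pooled$chrom == truth$chrom[i], , drop = FALSE]
        nrow(cand) && min(abs(cand$pos - j5[i])) <= window
      }, logical(1)))
    }, numeric(1))
    agree <- mean(planted_k == detected_k)
  }
  list(sensitivity = mean(per_pair$recovered),
       mean_junction_error = mean(per_pair$junction_error, na.rm = TRUE),
       junction_within_tol = mean(per_pair$junction_error <= tol, na.rm = TRUE),
       false_calls = false_calls,
       bin_agreement = agree,
       per_pair = per_pair)
}

#' @export
print.alu_pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("Pipeline run: %d planted loci, %d called; ascertained %d ",
           "(fixed %.1f%%); sensitivity %.3f, mean junction error %.2f bp, ",
           "%d false calls, bin agreement %.2f\n"),
    s$n_planted, s$n_loci_called, s$ascertained, s$fixed_pct, s$sensitivity,
    s$mean_junction_error, s$false_calls, s$bin_agreement))
  invisible(x)
}

# Persist the main artifacts of a run as plain-text files.
.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(run$reference, file.path(out_dir, "reference.fa"))
  writeXStringSet(run$library, file.path(out_dir, "subfamilies.fa"))
  write_truth_table(run$truth, file.path(out_dir, "truth.tsv"))
  write_matrix_tsv(run$matrix, file.path(out_dir, "matrix.tsv"))
  pooled <- do.call(rbind, lapply(run$calls, as.data.frame))
  write.table(pooled, file.path(out_dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$cross_ref, file.path(out_dir, "species_indicative.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- run$summary
  writeLines(paste(names(s), vapply(s, format, character(1)), sep = "\t"),
             file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
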