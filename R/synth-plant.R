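#' Plant Alu insertions into a reference under a sharing design
#'
#' Chooses non-overlapping insertion points (pairwise separated by at least
#' `guard` bases), assigns each locus a subfamily sequence from `library`, a
#' target-site duplication (TSD) length, an optional 5' truncation, and a
#' carrier set drawn to satisfy the requested sharing class. Each realized
#' insertion in a carrier haplotype has the canonical TPRT structure
#' `[TSD][possibly 5'-truncated Alu][TSD]`: the reference bases
#' `[pos, pos + tsd_len)` are duplicated on both sides of the element.
#'
#' The design is a named count vector over the sharing classes
#' (`fixed_ingroup`, `polymorphic_ingroup`, `species_indicative`,
#' `intergeneric_shared`, `intergeneric_private`); see
#' [classify_sharing_class()] for their definitions. For
#' `intergeneric_shared` loci the ingroup carrier count k is drawn uniformly
#' from 2..11 unless `shared_bins` pins it; `species_indicative` loci rotate
#' through the ingroup species. The outgroup never carries an insertion.
#'
#' @param reference a `DNAStringSet` from [generate_reference()].
#' @param cohort an `alu_cohort`.
#' @param design named integer vector of locus counts per sharing class.
#' @param library subfamily `DNAStringSet`; defaults to a 4-subfamily library
#'   derived from the built-in consensus.
#' @param seed optional integer seed.
#' @param tsd_range integer length-2: uniform range of TSD lengths in bases.
#' @param guard minimum distance between insertion points (use at least twice
#'   the intended fragment length so read pairs never straddle two loci).
#' @param trunc_prob probability that a locus is 5'-truncated.
#' @param max_trunc maximum 5' truncation in bases (element length after
#'   truncation is kept >= 50).
#' @param p_hom probability that a carrier is homozygous (2 copies);
#'   heterozygous carriers get the insertion on haplotype A only.
#' @return An object of class `alu_truth`: a data.frame with one row per locus
#'   (`locus_id`, `chrom`, `pos` [0-based insertion point], `subfamily`,
#'   `tsd_len`, `trunc5p`, `class`, `alu_seq`, then one genotype column of
#'   copy numbers per individual), with the cohort attached as an attribute.
#' @export
plant_insertions <- function(reference, cohort,
                             design = c(fixed_ingroup = 8, polymorphic_ingroup = 8,
                                        species_indicative = 12,
                                        intergeneric_shared = 30,
                                        intergeneric_private = 4),
                             library = NULL, seed = NULL,
                             tsd_range = c(6L, 20L), guard = 900L,
                             trunc_prob = 0.25, max_trunc = 150L,
                             p_hom = 0.35, shared_bins = NULL) {
  stopifnot(is(reference, "DNAStringSet"), inherits(cohort, "alu_cohort"))
  design <- design[design > 0]
  bad <- setdiff(names(design), c("fixed_ingroup", "polymorphic_ingroup",
                                  "species_indicative", "intergeneric_shared",
                                  "intergeneric_private"))
  if (length(bad)) stop("unknown sharing class(es) in design: ",
                        paste(bad, collapse = ", "))
  .set_seed(seed)
  lib <- library %||% make_subfamily_library(seed = NULL)
  n_loci <- sum(design)

  ## positions: spread across chromosomes, pairwise >= guard apart, away from
  ## the ends; slots of width guard + jmax with a jitter in [0, jmax] keep the
  ## pairwise spacing at >= guard
  lens <- width(reference)
  margin <- guard
  jmax <- 200L
  capacity <- pmax(0L, floor((lens - 2 * margin) / (guard + jmax)))
  if (n_loci > sum(capacity))
    stop("design infeasible: ", n_loci, " loci exceed genome capacity of ",
         sum(capacity), " at guard distance ", guard)
  chrom_idx <- rep(seq_along(lens), capacity)[seq_len(n_loci)]
  pos <- integer(n_loci)
  for (ci in unique(chrom_idx)) {
    k <- sum(chrom_idx == ci)
    slot0 <- margin + (guard + jmax) * (seq_len(k) - 1L)
    pos[chrom_idx == ci] <- as.integer(slot0 + floor(runif(k, 0, jmax)))
  }

  classes <- rep(names(design), design)
  classes <- sample(classes)  # interleave classes along the genome

  ing <- ingroup_ids(cohort)
  ig <- intergeneric_id(cohort)
  og <- outgroup_id(cohort)
  all_ids <- cohort$individuals$id
  species <- ingroup_species(cohort)
  sp_rotor <- 0L
  if (!is.null(shared_bins))
    shared_bins <- rep_len(as.integer(shared_bins), sum(classes == "intergeneric_shared"))
  shared_i <- 0L

  geno <- matrix(0L, nrow = n_loci, ncol = length(all_ids),
                 dimnames = list(NULL, all_ids))
  draw_copies <- function(ids) {
    g <- 1L + rbinom(length(ids), 1L, p_hom)
    names(g) <- ids
    g
  }
  for (i in seq_len(n_loci)) {
    cl <- classes[i]
    carriers <- switch(cl,
      fixed_ingroup = c(draw_copies(ing), draw_copies(ig)),
      intergeneric_private = draw_copies(ig),
      intergeneric_shared = {
        shared_i <- shared_i + 1L
        k <- if (!is.null(shared_bins)) shared_bins[shared_i]
             else sample(2:(length(ing) - 1L), 1L)
        c(draw_copies(sample(ing, k)), draw_copies(ig))
      },
      species_indicative = {
        sp_rotor <- sp_rotor %% length(species) + 1L
        sp <- species[sp_rotor]
        draw_copies(ing[species_of(cohort, ing) == sp])
      },
      polymorphic_ingroup = {
        repeat {
          k <- sample(2:(length(ing) - 1L), 1L)
          ids <- sample(ing, k)
          g <- draw_copies(ids)
          full <- structure(integer(length(all_ids)), names = all_ids)
          full[ids] <- g
          if (classify_sharing_class(full, cohort) == "polymorphic_ingroup") break
        }
        g
      })
    geno[i, names(carriers)] <- carriers
    ## the stored class must be recomputable from the carriers alone
    stopifnot(classify_sharing_class(geno[i, ], cohort) == cl)
  }
  stopifnot(all(geno[, og] == 0L))

  sub_i <- sample.int(length(lib), n_loci, replace = TRUE)
  tsd <- as.integer(floor(runif(n_loci, tsd_range[1], tsd_range[2] + 1)))
  trunc <- ifelse(runif(n_loci) < trunc_prob,
                  pmin(as.integer(floor(runif(n_loci, 1, max_trunc + 1))),
                       width(lib)[sub_i] - 50L),
                  0L)
  trunc <- pmax(trunc, 0L)
  alu_seq <- vapply(seq_len(n_loci), function(i)
    as.character(subseq(lib[[sub_i[i]]], start = trunc[i] + 1L)), character(1))

  truth <- data.frame(
    locus_id = sprintf("L%04d", seq_len(n_loci)),
    chrom = names(reference)[chrom_idx],
    pos = pos,
    subfamily = subfamily_names(lib)[sub_i],
    tsd_len = tsd,
    trunc5p = trunc,
    class = classes,
    alu_seq = alu_seq,
    stringsAsFactors = FALSE
  )
  truth <- cbind(truth, as.data.frame(geno))
  ## sort by coordinate so locus ids are stable and coordinate-ordered
  truth <- truth[order(truth$chrom, truth$pos), ]
  truth$locus_id <- sprintf("L%04d", seq_len(n_loci))
  rownames(truth) <- NULL
  structure(truth, cohort = cohort, class = c("alu_truth", "data.frame"))
}

#' The 5'-junction coordinate of planted loci
#'
#' The split-read caller reports the 5' (element head side) cleave point,
#' which for a +-strand element sits at `pos + tsd_len` on the reference
#' (the duplicated target site lies between the insertion point and the
#' element head). Recovery of planted loci is therefore scored against this
#' coordinate, not the raw insertion point.
#'
#' @param truth an `alu_truth` table.
#' @return Integer vector of 0-based junction coordinates.
#' @export
truth_junction5p <- function(truth) truth$pos + truth$tsd_len

#' Genotype columns of a truth table
#'
#' @param truth an `alu_truth` table.
#' @return Integer matrix loci x individuals of planted copy numbers.
#' @export
truth_genotypes <- function(truth) {
  cohort <- attr(truth, "cohort")
  g <- as.matrix(truth[, cohort$individuals$id, drop = FALSE])
  rownames(g) <- truth$locus_id
  storage.mode(g) <- "integer"
  g
}

#' Build diploid donor genomes from a truth table
#'
#' Applies each individual's planted insertions to the reference to produce two
#' haplotype sequences. Heterozygous carriers (1 copy) get the insertion on
#' haplotype A only; homozygous carriers on both.
#'
#' @param reference the reference `DNAStringSet`.
#' @param truth an `alu_truth` table from [plant_insertions()].
#' @param ids individuals to build (default: whole cohort).
#' @return Named list; per individual a list of two `DNAStringSet`s (`hapA`,
#'   `hapB`).
#' @export
build_donor_genomes <- function(reference, truth, ids = NULL) {
  cohort <- attr(truth, "cohort")
  ids <- ids %||% cohort$individuals$id
  geno <- truth_genotypes(truth)
  ref_chr <- as.character(reference)
  out <- lapply(ids, function(id) {
    haps <- lapply(c(1L, 2L), function(h) {
      rows <- which(geno[, id] >= h)  # h=1: any carrier; h=2: homozygous only
      chrs <- ref_chr
      if (length(rows)) {
        ## insert right-to-left so earlier coordinates stay valid
        for (i in rev(rows[order(truth$pos[rows])])) {
          chr <- truth$chrom[i]
          p <- truth$pos[i]
          t <- truth$tsd_len[i]
          s <- chrs[[chr]]
          chrs[[chr]] <- paste0(substr(s, 1L, p + t), truth$alu_seq[i],
                                substr(s, p + 1L, nchar(s)))
        }
      }
      DNAStringSet(chrs)
    })
    names(haps) <- c("hapA", "hapB")
    haps
  })
  names(out) <- ids
  out
}

#' Write / read a truth table as TSV
#'
#' The on-disk format is a BED-like TSV with a `#`-prefixed header: one row per
#' locus with `locus_id chrom pos subfamily tsd_len trunc5p class alu_seq`
#' followed by one copy-number column per individual.
#'
#' @param truth an `alu_truth` table.
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(truth), collapse = "\t")), con)
  write.table(truth, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @param cohort the `alu_cohort` the genotype columns refer to.
#' @export
read_truth_table <- function(path, cohort) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t")[[1]]
  df <- read.delim(path, header = FALSE, skip = 1L, col.names = cols,
                   stringsAsFactors = FALSE, check.names = FALSE)
  structure(df, cohort = cohort, class = c("alu_truth", "data.frame"))
}
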