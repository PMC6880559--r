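#' Per-bin sharing counts across individuals
#'
#' For every screened locus detected in the intergeneric individual with
#' ingroup carrier count k in 2..(n-1), the locus is assigned to bin k, and
#' every carrier individual's tally in that bin is incremented. By
#' construction, for each bin b the tallies over individuals sum to
#' b x total(b) -- each locus contributes one unit per carrier.
#'
#' @param matrix an `alu_matrix`.
#' @param intergeneric_id defaults to the cohort's intergeneric individual.
#' @return An object of class `alu_sharing_bins`: list with `counts` (bins x
#'   ingroup-individuals integer matrix), `totals` (loci per bin), `species`
#'   and `clade` (per ingroup column).
#' @export
bin_shared_insertions <- function(matrix, intergeneric_id = NULL) {
  stopifnot(inherits(matrix, "alu_matrix"))
  cohort <- matrix$cohort
  ig <- intergeneric_id %||% intergeneric_id(cohort)
  ing <- ingroup_ids(cohort)
  cls <- classify_loci(matrix, ig)
  poly <- cls$per_locus[cls$per_locus$class == "polymorphic", , drop = FALSE]
  n <- length(ing)
  bins <- 2:(n - 1L)
  counts <- matrix(0L, nrow = length(bins), ncol = n,
                   dimnames = list(bins, ing))
  det <- matrix$detected
  for (r in seq_len(nrow(poly))) {
    b <- as.character(poly$k[r])
    carriers <- ing[det[poly$locus_id[r], ing] > 0L]
    counts[b, carriers] <- counts[b, carriers] + 1L
  }
  totals <- table(factor(poly$k, levels = bins))
  sharing_bins(counts, as.integer(totals),
               species = species_of(cohort, ing),
               clade = clade_of(cohort, ing))
}

#' Construct a sharing-bin table directly
#'
#' Used both by [bin_shared_insertions()] and to load published tables as
#' fixtures.
#'
#' @param counts integer matrix, bins x individuals; rownames are the bins.
#' @param totals integer vector of loci per bin.
#' @param species,clade character vectors labelling the individual columns.
#' @return An `alu_sharing_bins`.
#' @export
sharing_bins <- function(counts, totals, species, clade) {
  stopifnot(nrow(counts) == length(totals), ncol(counts) == length(species),
            length(species) == length(clade))
  structure(list(counts = counts, totals = totals,
                 species = species, clade = clade),
            class = "alu_sharing_bins")
}

#' @export
print.alu_sharing_bins <- function(x, ...) {
  cat("Sharing-bin table:", nrow(x$counts), "bins x", ncol(x$counts),
      "individuals;", sum(x$totals), "polymorphic shared loci\n")
  invisible(x)
}

#' Per-species bin means and standard deviations
#'
#' The numeric content of the customary bar plot: for every bin, the mean and
#' sd of the per-individual tallies within each species.
#'
#' @param bins an `alu_sharing_bins`.
#' @return data.frame with `bin`, `species`, `mean`, `sd`.
#' @export
bin_species_summary <- function(bins) {
  sp <- unique(bins$species)
  out <- expand.grid(bin = as.integer(rownames(bins$counts)), species = sp,
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(b, s)
    mean(bins$counts[as.character(b), bins$species == s]),
    out$bin, out$species)
  out$sd <- mapply(function(b, s)
    sd(bins$counts[as.character(b), bins$species == s]),
    out$bin, out$species)
  out
}

#' Plot a sharing-bin table
#'
#' Grouped bar plot of the per-species mean tallies per bin with +/- 1 sd
#' error bars (base graphics).
#'
#' @param x an `alu_sharing_bins`.
#' @param ... passed to [graphics::barplot()].
#' @method plot alu_sharing_bins
#' @export
plot.alu_sharing_bins <- function(x, ...) {
  s <- bin_species_summary(x)
  sp <- unique(x$species)
  m <- matrix(s$mean, nrow = length(sp), byrow = FALSE,
              dimnames = list(sp, unique(s$bin)))
  e <- matrix(s$sd, nrow = length(sp), byrow = FALSE)
  bp <- graphics::barplot(m, beside = TRUE, legend.text = sp,
                          xlab = "ingroup carriers (bin)",
                          ylab = "shared insertions per individual (mean)",
                          ...)
  graphics::arrows(bp, m - e, bp, m + e, angle = 90, code = 3, length = 0.02)
  invisible(bp)
}

#' Per-bin one-way ANOVA with Bonferroni post-hoc t-tests
#'
#' For each bin, a classical fixed-effects one-way ANOVA of the 12 individual
#' tallies grouped by species (6 groups of 2) or clade (2 groups of 6). When
#' the ANOVA p-value is <= `alpha`, all pairwise two-tailed pooled-variance
#' t-tests are run and flagged significant under a Bonferroni threshold of
#' `alpha / n_pairs`. Zero within-group variance in every group leaves F
#' undefined (reported as NA).
#'
#' @param bins an `alu_sharing_bins`.
#' @param grouping `"species"` or `"clade"`.
#' @param alpha significance level.
#' @return data.frame with one row per bin (`bin`, `F`, `p`, `significant`)
#'   and an attribute `pairwise`: named list of data.frames
#'   (`group_a`, `group_b`, `t`, `p_raw`, `significant_after_bonferroni`)
#'   for bins with p <= alpha.
#' @export
anova_bins <- function(bins, grouping = c("species", "clade"), alpha = 0.05) {
  grouping <- match.arg(grouping)
  g <- factor(bins[[grouping]], levels = unique(bins[[grouping]]))
  pairs <- combn(levels(g), 2)
  m <- ncol(pairs)
  res <- list(); pw <- list()
  for (i in seq_len(nrow(bins$counts))) {
    b <- rownames(bins$counts)[i]
    y <- as.numeric(bins$counts[i, ])
    ## degenerate fits warn here and are overridden by the explicit branches
    tab <- suppressWarnings(anova(lm(y ~ g)))
    ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
    tol <- 1e-9 * max(1, sum(y^2))
    if (ssb <= tol) {               # no between-group signal at all
      Fv <- 0; p <- 1
    } else if (ssw <= tol) {        # perfect separation: zero within-group var
      Fv <- Inf; p <- 0
    } else {
      Fv <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
    }
    sig <- !is.na(p) && p <= alpha
    res[[i]] <- data.frame(bin = as.integer(b), F = Fv, p = p,
                           significant = sig)
    if (sig) {
      rows <- lapply(seq_len(m), function(j) {
        a <- pairs[1, j]; bgrp <- pairs[2, j]
        ya <- y[g == a]; yb <- y[g == bgrp]
        tp <- tryCatch({
          tt <- t.test(ya, yb, var.equal = TRUE)
          c(unname(tt$statistic), tt$p.value)
        }, error = function(e) {
          # degenerate pooled variance 0: infinite t if means differ, else 0
          if (mean(ya) != mean(yb)) c(sign(mean(ya) - mean(yb)) * Inf, 0)
          else c(0, 1)
        })
        data.frame(group_a = a, group_b = bgrp,
                   t = tp[1], p_raw = tp[2],
                   significant_after_bonferroni = tp[2] <= alpha / m,
                   stringsAsFactors = FALSE)
      })
      pw[[b]] <- do.call(rbind, rows)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "pairwise") <- pw
  attr(out, "grouping") <- grouping
  attr(out, "alpha") <- alpha
  out
}

#' Species-indicative locus sets
#'
#' A locus is indicative of species S iff it is detected in both sampled
#' individuals of S and in none of the other ingroup individuals. The
#' intergeneric and outgroup states are not consulted here (the outgroup
#' screen has already been applied to the matrix rows considered).
#'
#' @param matrix an `alu_matrix`.
#' @return Named list, species -> character vector of locus ids.
#' @export
species_indicative <- function(matrix) {
  stopifnot(inherits(matrix, "alu_matrix"))
  cohort <- matrix$cohort
  ing <- ingroup_ids(matrix$cohort)
  sp <- species_of(cohort, ing)
  tab <- table(sp)
  if (any(tab != 2L))
    stop("species_indicative requires exactly 2 individuals per species; got: ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  rows <- .screened_rows(matrix)
  det <- matrix$detected[rows, ing, drop = FALSE] > 0L
  out <- lapply(unique(sp), function(s) {
    inside <- det[, sp == s, drop = FALSE]
    outside <- det[, sp != s, drop = FALSE]
    rownames(det)[rowSums(inside) == 2L & rowSums(outside) == 0L]
  })
  names(out) <- unique(sp)
  out
}

#' Cross-reference species-indicative sets with the intergeneric individual
#'
#' @param sets named list from [species_indicative()].
#' @param matrix the `alu_matrix` the sets came from.
#' @param intergeneric_id defaults to the cohort's intergeneric individual.
#' @return data.frame with `species`, `n_indicative`, `n_shared`,
#'   `pct_shared` (100 x n_shared / n_indicative; NA when the set is empty).
#' @export
cross_reference_intergeneric <- function(sets, matrix,
                                         intergeneric_id = NULL) {
  ig <- intergeneric_id %||% intergeneric_id(matrix$cohort)
  shared <- rownames(matrix$detected)[matrix$detected[, ig] > 0L]
  out <- data.frame(
    species = names(sets),
    n_indicative = lengths(sets),
    n_shared = vapply(sets, function(s) sum(s %in% shared), integer(1)),
    stringsAsFactors = FALSE)
  out$pct_shared <- ifelse(out$n_indicative > 0,
                           100 * out$n_shared / out$n_indicative, NA_real_)
  rownames(out) <- NULL
  out
}

#' z-test of per-species shared counts
#'
#' Standardizes each species' shared count against the mean and the sample
#' (n-1 denominator) standard deviation of the counts: z = (count - mean)/sd.
#' The one-tailed p-value is the standard-normal tail beyond the observed
#' deviation, p = 1 - Phi(|z|) -- the upper tail for above-average counts and
#' the lower tail for below-average ones. Both the sample sd and the
#' by-deviation tail are the conventions the published statistic follows
#' (they are what reproduce its printed values for every sign of z).
#' sd = 0 leaves z undefined (NA).
#'
#' @param counts named integer vector of per-species shared counts.
#' @return An object of class `alu_ztest`: data.frame (`species`, `count`,
#'   `z`, `p_one_tailed`) with attributes `mean` and `sd`.
#' @export
ztest_counts <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) >= 2L)
  mu <- mean(counts)
  s <- sd(counts)
  z <- if (s > 0) (counts - mu) / s else rep(NA_real_, length(counts))
  out <- data.frame(
    species = names(counts) %||% paste0("group", seq_along(counts)),
    count = as.integer(counts),
    z = as.numeric(z),
    p_one_tailed = if (s > 0) pnorm(abs(z), lower.tail = FALSE)
                   else rep(NA_real_, length(counts)),
    stringsAsFactors = FALSE)
  structure(out, mean = mu, sd = s, class = c("alu_ztest", "data.frame"))
}

#' @export
print.alu_ztest <- function(x, ...) {
  cat(sprintf("z-test of %d counts (mean %.4g, sample sd %.4g)\n",
              nrow(x), attr(x, "mean"), attr(x, "sd")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' PCR-style genotype table
#'
#' Validates and encodes a genotype table whose cells use the band-presence
#' coding `(1,1)` homozygous present, `(1,0)` heterozygous, `(0,0)`
#' homozygous absent, `(-9,-9)` missing (no amplification). Cells may be
#' given as strings (`"1,1"`, `"1,0"`, `"0,0"`, `"-9,-9"`) or as insertion
#' allele counts (2, 1, 0, NA).
#'
#' @param x matrix or data.frame, loci x individuals.
#' @return Integer matrix of insertion-allele counts (0, 1, 2) with NA for
#'   missing cells, of class `alu_pcr_table`.
#' @export
pcr_genotype_table <- function(x) {
  m <- as.matrix(x)
  if (is.character(m)) {
    key <- gsub("[ ()]", "", m)
    allele <- c("1,1" = 2L, "1,0" = 1L, "0,1" = 1L, "0,0" = 0L, "-9,-9" = NA_integer_)
    if (!all(key %in% names(allele)))
      stop("invalid genotype code(s): ",
           paste(unique(key[!key %in% names(allele)]), collapse = ", "))
    g <- matrix(allele[key], nrow = nrow(m), dimnames = dimnames(m))
  } else {
    g <- m
    storage.mode(g) <- "integer"
    if (any(g[!is.na(g)] < 0L | g[!is.na(g)] > 2L))
      stop("allele counts must be 0, 1, 2 or NA")
  }
  structure(g, class = c("alu_pcr_table", class(g)))
}

#' Per-individual insertion-allele frequencies from a PCR genotype table
#'
#' frequency = (number of insertion alleles) / (2 x loci with a non-missing
#' genotype); missing cells contribute to neither numerator nor denominator.
#' An all-missing individual gets NA.
#'
#' @param pcr an [pcr_genotype_table()] (or anything it accepts).
#' @return Named numeric vector of frequencies per individual.
#' @export
allele_frequencies <- function(pcr) {
  g <- pcr_genotype_table(unclass(pcr))
  n_typed <- colSums(!is.na(g))
  freq <- colSums(g, na.rm = TRUE) / (2 * n_typed)
  freq[n_typed == 0L] <- NA_real_
  freq
}
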