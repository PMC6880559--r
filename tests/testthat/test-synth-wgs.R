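test_that("generated reference has the requested length, GC and determinism", {
  ref <- generate_reference(1, 1e5, gc = 0.40, seed = 7)
  expect_named(ref, "chr1")
  expect_equal(width(ref), 1e5)
  ## binomial oracle: observed GC within 3 sd of np
  s <- as.character(ref[[1]])
  n_gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(n_gc - 0.40 * 1e5), 3 * sqrt(1e5 * 0.40 * 0.60))

  ## degenerate GC = 0: A/T only
  at <- generate_reference(1, 1e4, gc = 0, seed = 1)
  expect_false(grepl("[GC]", as.character(at[[1]])))

  ## identical seed, identical bytes; different seed differs
  expect_identical(as.character(generate_reference(1, 1e4, 0.4, seed = 7)),
                   as.character(generate_reference(1, 1e4, 0.4, seed = 7)))
  expect_false(identical(as.character(generate_reference(1, 1e4, 0.4, seed = 7)),
                         as.character(generate_reference(1, 1e4, 0.4, seed = 8))))
  expect_error(generate_reference(1, -5), "positive")
})

test_that("planted insertions realize the design and the TSD structure", {
  cohort <- papio_gelada_cohort()
  ref <- generate_reference(1, 6e4, 0.4, seed = 3)
  design <- c(fixed_ingroup = 5, species_indicative = 6,
              intergeneric_shared = 10)
  truth <- plant_insertions(ref, cohort, design = design, seed = 4)
  expect_equal(unname(table(truth$class)[names(design)]),
               unname(design), ignore_attr = TRUE)

  ## sharing class is recomputable from the carriers for every row
  g <- truth_genotypes(truth)
  rec <- apply(g, 1, classify_sharing_class, cohort = cohort)
  expect_equal(unname(rec), truth$class)

  ## outgroup never carries
  expect_true(all(g[, outgroup_id(cohort)] == 0))

  ## species-indicative rows: both individuals of exactly one species
  si <- which(truth$class == "species_indicative")
  ing <- ingroup_ids(cohort)
  for (i in si) {
    carriers <- ing[g[i, ing] > 0]
    expect_length(carriers, 2L)
    expect_length(unique(species_of(cohort, carriers)), 1L)
  }

  ## donor haplotype realizes [TSD][element][TSD] at the insertion point
  row <- truth[truth$class == "fixed_ingroup", ][1, ]
  id <- ing[1]
  don <- build_donor_genomes(ref, truth, id)[[id]]
  hap <- as.character(don$hapA[[row$chrom]])
  refs <- as.character(ref[[row$chrom]])
  tsd <- substr(refs, row$pos + 1, row$pos + row$tsd_len)
  expect_identical(substr(hap, row$pos + row$tsd_len + 1,
                          row$pos + row$tsd_len + nchar(row$alu_seq)),
                   row$alu_seq)
  ## the duplicated target site flanks the element on both sides
  expect_identical(substr(hap, row$pos + 1, row$pos + row$tsd_len), tsd)
  expect_identical(substr(hap, row$pos + row$tsd_len + nchar(row$alu_seq) + 1,
                          row$pos + 2 * row$tsd_len + nchar(row$alu_seq)), tsd)

  ## infeasible design errors out
  expect_error(plant_insertions(generate_reference(1, 1e4, 0.4, seed = 1),
                                cohort, design = c(fixed_ingroup = 50)),
               "infeasible")
})

test_that("truth tables round-trip through TSV", {
  cohort <- papio_gelada_cohort()
  ref <- generate_reference(1, 3e4, 0.4, seed = 5)
  truth <- plant_insertions(ref, cohort,
                            design = c(intergeneric_shared = 5), seed = 6)
  f <- tempfile(fileext = ".tsv")
  write_truth_table(truth, f)
  back <- read_truth_table(f, cohort)
  expect_equal(as.data.frame(back), as.data.frame(truth))
})

test_that("read simulation matches its coverage contract", {
  ref <- generate_reference(1, 1e5, 0.4, seed = 2)
  don <- list(hapA = ref, hapB = ref)

  ## coverage 0 -> no reads
  r0 <- simulate_reads(don, read_sim_params(coverage = 0, seed = 1))
  expect_length(r0$r1, 0)

  ## 100 kb, 30x, read length 100 -> ~15,000 pairs (Poisson-scale tolerance)
  rs <- simulate_reads(don, read_sim_params(coverage = 30, seed = 1))
  expect_lt(abs(length(rs$r1) - 15000), 4 * sqrt(15000))
  expect_equal(length(rs$r1), length(rs$r2))
  expect_equal(unique(width(rs$r1)), 100L)

  ## err_rate 0: every read is an exact substring of the donor (either strand)
  rs0 <- simulate_reads(list(hapA = ref),
                        read_sim_params(coverage = 0.5, err_rate = 0, seed = 9))
  s <- as.character(ref[[1]])
  ok <- vapply(as.character(rs0$r1), function(r)
    grepl(r, s, fixed = TRUE) || grepl(revcomp_chr(r), s, fixed = TRUE),
    logical(1))
  expect_true(all(ok))

  ## determinism: same seed, identical FASTQ bytes
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq_pair(simulate_reads(don, read_sim_params(coverage = 2, seed = 5)), f1)
  write_fastq_pair(simulate_reads(don, read_sim_params(coverage = 2, seed = 5)), f2)
  expect_identical(readLines(paste0(f1, "_1.fastq")),
                   readLines(paste0(f2, "_1.fastq")))
  expect_identical(readLines(paste0(f1, "_2.fastq")),
                   readLines(paste0(f2, "_2.fastq")))

  ## parameter validation
  expect_error(read_sim_params(frag_mean = 80, read_len = 100), "frag_mean")
  expect_error(read_sim_params(coverage = -1), "coverage")
})

test_that("junctions are spanned by flanked reads at planted loci", {
  ## round-trip property: at 30x nearly every carrier junction is spanned by
  ## at least one read with >= 30 bases on each side
  cohort <- papio_gelada_cohort()
  ref <- generate_reference(1, 3e4, 0.4, seed = 21)
  truth <- plant_insertions(ref, cohort,
                            design = c(fixed_ingroup = 4,
                                       intergeneric_shared = 6), seed = 22)
  g <- truth_genotypes(truth)
  j5 <- truth_junction5p(truth)
  ids <- c(ingroup_ids(cohort)[1:4], intergeneric_id(cohort))
  donors <- build_donor_genomes(ref, truth, ids)
  hits <- misses <- 0L
  for (id in ids) {
    reads <- simulate_reads(donors[[id]],
                            read_sim_params(coverage = 30, err_rate = 0,
                                            seed = 100 + match(id, ids)),
                            id_prefix = id)
    ## one big haystack; a junction is spanned with >= 30 bp on each side iff
    ## some read contains the 60-mer centered on the 5' cleave point
    pool <- paste(as.character(c(reads$r1, reads$r2)), collapse = "N")
    for (i in which(g[, id] > 0)) {
      left30 <- substr(as.character(ref[[1]]), j5[i] - 29, j5[i])
      target <- paste0(left30, substr(truth$alu_seq[i], 1, 30))
      spanned <- grepl(target, pool, fixed = TRUE) ||
        grepl(revcomp_chr(target), pool, fixed = TRUE)
      if (spanned) hits <- hits + 1L else misses <- misses + 1L
    }
  }
  expect_gt(hits / (hits + misses), 0.95)
})
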