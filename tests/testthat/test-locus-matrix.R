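make_calls <- function(id, pos, chrom = "chr1") {
  data.frame(call_id = paste0(id, "_", seq_along(pos)), individual_id = id,
             chrom = chrom, pos = as.integer(pos), support = 1L, n_5p = 1L,
             max_5p_flank = 50L, strand = "+", stringsAsFactors = FALSE)
}

test_that("junction clustering respects the window", {
  ## two individuals 4 bp apart -> one locus
  one <- cluster_calls(rbind(make_calls("a", 1000), make_calls("b", 1004)), 25)
  expect_equal(nrow(one$loci), 1L)
  expect_equal(one$loci$n_individuals, 2L)

  ## 60 bp apart -> two loci
  two <- cluster_calls(rbind(make_calls("a", 1000), make_calls("b", 1060)), 25)
  expect_equal(nrow(two$loci), 2L)

  ## chromosomes never merge
  cc <- cluster_calls(rbind(make_calls("a", 1000, "chr1"),
                            make_calls("b", 1000, "chr2")), 25)
  expect_equal(nrow(cc$loci), 2L)

  ## empty input -> empty output
  expect_equal(nrow(cluster_calls(list())$loci), 0L)

  ## growing the window never increases the locus count (monotone property)
  set.seed(3)
  pos <- sort(sample(1e5, 60))
  pooled <- rbind(make_calls("a", pos), make_calls("b", pos + sample(0:30, 60, TRUE)))
  n_prev <- Inf
  for (w in c(5, 15, 25, 50, 100)) {
    n <- nrow(cluster_calls(pooled, w)$loci)
    expect_lte(n, n_prev)
    n_prev <- n
  }

  ## planted cohort: one locus per planted insertion detected anywhere
  run <- tiny_run()
  expect_equal(nrow(run$loci$loci), nrow(run$truth))
})

test_that("matrix construction flags and excludes outgroup loci", {
  cohort <- papio_gelada_cohort()
  og <- outgroup_id(cohort)
  ig <- intergeneric_id(cohort)
  ing <- ingroup_ids(cohort)

  ## locus 1: gelada + 5 ingroup; locus 2: also in outgroup; locus 3: fixed
  m <- manual_matrix(list(
    c(ig, ing[1:5]),
    c(ig, og, ing[1:6]),
    c(ig, ing)))
  expect_equal(m$loci$in_outgroup, c(FALSE, TRUE, FALSE))
  cls <- classify_loci(m)
  ## outgroup locus is gone from every downstream count
  expect_equal(cls$counts[["ascertained_shared"]], 2L)
  expect_equal(cls$counts[["fixed_ingroup"]], 1L)
  expect_equal(cls$counts[["polymorphic_ingroup"]], 1L)

  ## unknown individual errors
  bad <- make_calls("nobody", 500)
  expect_error(build_matrix(cluster_calls(bad, 25), cohort), "unknown")

  ## empty evidence -> zero loci
  expect_equal(nrow(build_matrix(cluster_calls(list()), cohort)$loci), 0L)
})

test_that("carrier-count classification follows the k rules", {
  cohort <- papio_gelada_cohort()
  ig <- intergeneric_id(cohort)
  ing <- ingroup_ids(cohort)
  ## ingroup carrier counts 12, 12, 5, 1 -> fixed 2, polymorphic 1 (bin 5),
  ## singleton 1
  m <- manual_matrix(list(
    c(ig, ing), c(ig, ing), c(ig, ing[1:5]), c(ig, ing[7])))
  cls <- classify_loci(m)
  expect_equal(cls$counts[["fixed_ingroup"]], 2L)
  expect_equal(cls$counts[["polymorphic_ingroup"]], 1L)
  expect_equal(unname(cls$bins[["5"]]), 1L)
  expect_equal(cls$counts[["singleton"]], 1L)
  ## conservation: polymorphic = ascertained - fixed (singletons not counted)
  expect_equal(cls$counts[["polymorphic_ingroup"]],
               cls$counts[["ascertained_shared"]] - cls$counts[["fixed_ingroup"]])

  ## permuting individual columns never changes the classification
  set.seed(9)
  sets <- replicate(12, sample(c(ing, ig), sample(3:13, 1)), simplify = FALSE)
  m1 <- manual_matrix(sets)
  perm <- sample(length(cohort$individuals$id))
  cohort2 <- cohort_spec(cohort$individuals[perm, ])
  m2 <- manual_matrix(sets, cohort2)
  c1 <- classify_loci(m1); c2 <- classify_loci(m2)
  expect_equal(c1$counts, c2$counts)
  expect_equal(c1$bins, c2$bins)
})

test_that("published ascertainment totals give the published percentages", {
  asc <- load_fixture_tables("ascertainment")
  pre <- asc[asc$run == "prefilter", ]
  cls <- classification_from_counts(pre$n_fixed, pre$n_polymorphic)
  expect_equal(cls$counts[["ascertained_shared"]], 27700L)
  expect_equal(round(cls$fixed_pct), 53)
})

test_that("second-reference screen flags loci whose junction k-mer is present", {
  run <- tiny_run()
  ## rebuild the matrix against a second reference carrying every other locus
  truth <- run$truth
  sub <- truth[seq(1, nrow(truth), by = 2), ]
  attr(sub, "cohort") <- attr(truth, "cohort")
  ref2 <- alushare:::.filled_reference(run$reference, sub)
  ev <- do.call(rbind, lapply(run$calls, call_evidence))
  m2 <- build_matrix(run$loci, attr(truth, "cohort"),
                     second_reference = ref2, evidence = ev)
  flagged <- m2$loci$in_second_reference
  ## loci planted into ref2 must be flagged, the others not
  j5 <- truth_junction5p(truth)
  planted2 <- vapply(m2$loci$pos, function(p)
    any(abs(truth_junction5p(sub) - p) <= 25), logical(1))
  expect_equal(flagged, planted2)
})
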