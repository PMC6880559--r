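cons <- alu_consensus()
cons_chr <- as.character(cons)

test_that("scan_read_for_alu finds exact and mutated consensus segments", {
  set.seed(42)
  uniq <- random_dna(40)
  read <- paste0(substr(cons_chr, 1, 60), uniq)
  hit <- scan_read_for_alu(read, cons)
  expect_equal(hit$span, c(1L, 60L))
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$strand, "+")

  ## reverse-complement read is found on the other strand, same span length
  hit_rc <- scan_read_for_alu(revcomp_chr(read), cons)
  expect_equal(hit_rc$strand, "-")
  expect_equal(hit_rc$span[2] - hit_rc$span[1], 59L)

  ## a read with no consensus content yields nothing
  expect_null(scan_read_for_alu(random_dna(100), cons))

  ## 5% substitutions: identity close to 0.95
  seg <- strsplit(substr(cons_chr, 11, 110), "")[[1]]
  idx <- seq(5, 100, by = 20)  # 5 substitutions in 100 bases
  for (i in idx) seg[i] <- setdiff(c("A", "C", "G", "T"), seg[i])[1]
  hit2 <- scan_read_for_alu(paste(seg, collapse = ""), cons)
  expect_lt(abs(hit2$identity - 0.95), 0.02)

  expect_error(scan_read_for_alu("", cons), "empty")
})

test_that("scan agrees with a brute-force Smith-Waterman oracle", {
  set.seed(7)
  n_checked <- 0L
  for (i in 1:100) {
    ## random short reads, some seeded with consensus fragments
    if (i %% 2 == 0) {
      start <- sample(200, 1)
      len <- sample(20:50, 1)
      read <- paste0(random_dna(sample(0:10, 1)),
                     substr(cons_chr, start, start + len - 1),
                     random_dna(sample(0:10, 1)))
    } else {
      read <- random_dna(sample(30:60, 1))
    }
    hit <- scan_read_for_alu(read, cons, min_alu_bases = 1, min_identity = 0)
    ## oracle: best local score over both orientations, computed by an
    ## independent dynamic-programming implementation
    s_or <- max(sw_oracle_score(read, cons_chr),
                sw_oracle_score(revcomp_chr(read), cons_chr))
    expect_false(is.null(hit))
    expect_equal(hit$score, s_or)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 100L)
})

test_that("cleave_and_map_flank enforces flank length, uniqueness and geometry", {
  set.seed(13)
  ref <- generate_reference(1, 2e4, 0.4, seed = 31)
  refs <- as.character(ref[[1]])

  ## construct a junction read: 40 bp reference flank + 60 bp element head
  jpos <- 5000L  # 0-based junction
  flank <- substr(refs, jpos - 39, jpos)
  read <- paste0(flank, substr(cons_chr, 1, 60))
  scan <- scan_read_for_alu(read, cons)
  ev <- cleave_and_map_flank(read, scan, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$flank_side, "5p")
  expect_equal(ev$pos, jpos)
  expect_equal(ev$strand, "+")
  expect_equal(ev$flank_len, 40L)

  ## same read reverse-complemented: same junction, element on minus strand
  ev_rc <- cleave_and_map_flank(revcomp_chr(read),
                                scan_read_for_alu(revcomp_chr(read), cons), ref)
  expect_equal(ev_rc$pos, jpos)

  ## a 3' junction read: element tail + reference flank
  read3 <- paste0(substr(cons_chr, 201, 300), substr(refs, jpos + 1, jpos + 40))
  ev3 <- cleave_and_map_flank(read3, scan_read_for_alu(read3, cons), ref)
  expect_equal(ev3$flank_side, "3p")
  expect_equal(ev3$pos, jpos)

  ## short flank is rejected with a reason, not an error
  read_short <- paste0(substr(refs, jpos - 24, jpos), substr(cons_chr, 1, 75))
  evs <- cleave_and_map_flank(read_short, scan_read_for_alu(read_short, cons),
                              ref, min_flank = 30)
  expect_equal(nrow(evs), 0L)
  expect_equal(attr(evs, "rejected")$reason, "flank_too_short")

  ## duplicated flank in the reference -> non_unique rejection
  dup <- substr(refs, 1001, 1040)
  ref_dup <- Biostrings::DNAStringSet(paste0(refs, dup))
  names(ref_dup) <- "chr1"
  read_dup <- paste0(dup, substr(cons_chr, 1, 60))
  evd <- cleave_and_map_flank(read_dup, scan_read_for_alu(read_dup, cons),
                              ref_dup)
  expect_equal(nrow(evd), 0L)
  expect_equal(attr(evd, "rejected")$reason, "non_unique")

  ## internal element: flanks on both sides give two evidence records
  read_int <- paste0(substr(refs, 3001, 3040), substr(cons_chr, 1, 80),
                     substr(refs, 7001, 7040))
  evi <- cleave_and_map_flank(read_int, scan_read_for_alu(read_int, cons), ref)
  expect_equal(nrow(evi), 2L)
  expect_setequal(evi$flank_side, c("5p", "3p"))
})

test_that("planted junctions are recovered to within a few bases", {
  run <- tiny_run()
  expect_gte(run$recovery$sensitivity, 0.95)
  expect_lte(run$recovery$mean_junction_error, 5)
  ## clean reads: no spurious junctions anywhere in the cohort
  expect_equal(run$recovery$false_calls, 0L)
  ## non-carriers get no calls at planted loci (checked inside recovery via
  ## false_calls); additionally every call belongs to a planted junction
  pooled <- do.call(rbind, lapply(run$calls, as.data.frame))
  j5 <- truth_junction5p(run$truth)
  near <- vapply(pooled$pos, function(p) min(abs(j5 - p)) <= 25, logical(1))
  expect_true(all(near))
})

test_that("raising min_flank never enlarges the call set and revcomp is symmetric", {
  run <- tiny_run()
  ref <- run$reference
  id <- "kindae_1"
  donors <- build_donor_genomes(ref, run$truth, id)
  reads <- simulate_reads(donors[[id]],
                          read_sim_params(coverage = 12, err_rate = 0, seed = 5),
                          id_prefix = id)
  key <- function(calls) paste(calls$chrom, calls$pos)
  base <- call_insertions(reads, alu_consensus(), ref, id,
                          detect_params(min_flank = 20))
  stricter <- call_insertions(reads, alu_consensus(), ref, id,
                              detect_params(min_flank = 40))
  expect_true(all(key(stricter) %in% key(base)))

  ## reverse-complementing every read leaves the junction set unchanged
  rc_reads <- list(r1 = Biostrings::reverseComplement(reads$r1),
                   r2 = Biostrings::reverseComplement(reads$r2))
  names(rc_reads$r1) <- names(reads$r1)
  names(rc_reads$r2) <- names(reads$r2)
  rc <- call_insertions(rc_reads, alu_consensus(), ref, id,
                        detect_params(min_flank = 20))
  expect_setequal(key(rc), key(base))
})
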