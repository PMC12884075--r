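# hit classification: rejection rules, occupancy inference, refinement,
# binning and ranking

test_that("filter_hits applies rules (i)-(iv)", {
  # single clean full hit: kept
  fh <- filter_hits(make_hit())
  expect_identical(nrow(fh$kept), 1L)
  # 3 mismatches in a 40-column alignment: identity 92.5, rejected
  h3 <- make_hit(mismatches = 3L)
  expect_equal(h3$identity_pct, 92.5)
  fh3 <- filter_hits(h3)
  expect_identical(nrow(fh3$rejected), 1L)
  expect_identical(nrow(fh3$kept), 0L)
  # L and R halves at distant loci: routed to the occupancy pool
  hp <- rbind(make_hit("a1_L", part = "L", start = 10000L, aln_len = 30L),
              make_hit("a1_R", part = "R", start = 50000L, aln_len = 30L))
  fhp <- filter_hits(hp)
  expect_identical(nrow(fhp$occupancy_pool), 2L)
  expect_identical(nrow(fhp$kept), 0L)
  # full hit with both halves nested at the same locus: one locus, kept
  nest <- rbind(make_hit(),
                make_hit("a1_L", part = "L", start = 100L, aln_len = 30L),
                make_hit("a1_R", part = "R", start = 110L, aln_len = 30L))
  fhn <- filter_hits(nest)
  expect_identical(nrow(fhn$kept), 3L)
  expect_identical(nrow(fhn$occupancy_pool), 0L)
})

occ_setup <- function(actual, expected = 40000L, contig_len = 100000L) {
  attbs <- mini_attb("a1", strrep("ACGTG", 8), 11L, 30L)
  gis <- mini_gi(length = expected)
  db <- mini_db(attbs, gis)
  pool <- rbind(
    make_hit("a1_L", part = "L", start = 1000L, aln_len = 30L),
    make_hit("a1_R", part = "R",
             start = 1000L + actual - 30L, aln_len = 30L))
  infer_occupancy(pool, db, c(c1 = contig_len))
}

test_that("infer_occupancy applies the normalized-difference rule", {
  # exact length: nd = 0, occupied
  r <- occ_setup(40000L)
  expect_identical(nrow(r$occupied), 1L)
  expect_equal(r$occupied$normalized_difference, 0)
  expect_equal(r$occupied$actual, 40000)
  # 36 kb vs 40 kb: nd = 0.0526, not occupied
  expect_identical(nrow(occ_setup(36000L)$occupied), 0L)
  expect_equal(abs(normalized_difference(40000, 36000)), 4000 / 76000)
  # 9.1 kb vs 10 kb: nd = 0.0471, occupied
  r3 <- occ_setup(9100L, expected = 10000L)
  expect_identical(nrow(r3$occupied), 1L)
  expect_equal(r3$occupied$normalized_difference, 900 / 19100)
})

test_that("normalized difference is antisymmetric with nd(x, x) = 0", {
  set.seed(101)
  e <- runif(50, 1e3, 1e5); a <- runif(50, 1e3, 1e5)
  expect_equal(normalized_difference(e, a), -normalized_difference(a, e))
  expect_equal(normalized_difference(e, e), rep(0, 50))
})

test_that("occupancy evidence picks the best-fitting island and handles
           minus-strand and cross-contig pairs", {
  attbs <- mini_attb("a1", strrep("ACGTG", 8), 11L, 30L,
                     gi_refs = c("G|g1", "G|g2"))
  gis <- rbind(mini_gi("G|g1", length = 40000L, support = 2),
               mini_gi("G|g2", length = 39950L, support = 9))
  db <- mini_db(attbs, gis)
  pool <- rbind(
    make_hit("a1_L", part = "L", start = 1000L, aln_len = 30L),
    make_hit("a1_R", part = "R", start = 40970L, aln_len = 30L))
  r <- infer_occupancy(pool, db, c(c1 = 100000L))
  # actual = 40000; both islands within 5 %; minimal |nd| wins
  expect_identical(nrow(r$evidence), 2L)
  expect_identical(r$occupied$gi_ref, "G|g1")

  # minus-strand pair: R before L in genome coordinates
  pool_m <- rbind(
    make_hit("a1_R", part = "R", start = 1000L, aln_len = 30L,
             strand = "-"),
    make_hit("a1_L", part = "L", start = 40970L, aln_len = 30L,
             strand = "-"))
  rm <- infer_occupancy(pool_m, db, c(c1 = 100000L))
  expect_equal(rm$occupied$actual, 40000)

  # cross-contig: + strand L near the end of c1, + strand R on c2
  pool_x <- rbind(
    make_hit("a1_L", part = "L", contig = "c1", start = 95001L,
             aln_len = 30L),
    make_hit("a1_R", part = "R", contig = "c2", start = 34971L,
             aln_len = 30L))
  rx <- infer_occupancy(pool_x, db, c(c1 = 100000L, c2 = 50000L))
  expect_true(rx$occupied$cross_contig)
  expect_equal(rx$occupied$actual, 5000 + 35000)
})

test_that("refine_candidates flags occupied overlap, multi-ID-block and
           homopolymer ID blocks", {
  set.seed(103)
  flank <- attbscout:::random_dna(10)
  idb <- attbscout:::random_dna(20)
  seq <- paste0(flank, idb, attbscout:::random_dna(10))
  attbs <- rbind(
    mini_attb("a1", seq, 11L, 30L),
    mini_attb("a2", paste0(flank, "C", strrep("A", 12), "G",
                           attbscout:::random_dna(16)), 12L, 23L))
  genome <- random_genome(20000L, seed = 104L)
  genome <- plant_attb(genome, list(sequence = seq, attb_id = "a1"),
                       "contig_1", 5000L)
  cand <- candidates <- data.frame(
    attb_ref = "a1", contig = "contig_1", start = 5000L,
    end = 5000L + nchar(seq) - 1L, strand = "+", status = "candidate",
    reason = "ok", best_hit_score = 80, ref_gi = "G|g1",
    ref_gi_support = 5, stringsAsFactors = FALSE)
  no_occ <- attbscout:::empty_df(list(
    contig = "character", start = "integer", end = "integer",
    contig2 = "character", start2 = "integer", end2 = "integer",
    cross_contig = "logical"))

  # clean candidate passes
  r0 <- refine_candidates(cand, no_occ, genome, attbs)
  expect_identical(nrow(r0$final_pool), 1L)

  # containment in an occupied interval
  occ <- data.frame(contig = "contig_1", start = 4000L, end = 44000L,
                    contig2 = NA_character_, start2 = NA_integer_,
                    end2 = NA_integer_, cross_contig = FALSE,
                    stringsAsFactors = FALSE)
  r1 <- refine_candidates(cand, occ, genome, attbs)
  expect_identical(r1$questionable$reason, "in_occupied")

  # second exact ID-block copy elsewhere
  g2 <- attbscout:::splice_seq(genome, "contig_1", 12000L, idb)
  r2 <- refine_candidates(cand, no_occ, g2, attbs)
  expect_identical(r2$questionable$reason, "multi_idblock")

  # 12-nt homopolymer ID block
  g3 <- plant_attb(genome, list(sequence = attbs$sequence[2],
                                attb_id = "a2"), "contig_1", 9000L)
  cand2 <- cand; cand2$attb_ref <- "a2"
  cand2$start <- 9000L; cand2$end <- 9000L + nchar(attbs$sequence[2]) - 1L
  r3 <- refine_candidates(cand2, no_occ, g3, attbs)
  expect_identical(r3$questionable$reason, "homopolymer_idblock")
})

test_that("bin_and_select picks per-bin winners and ranks by island
           support", {
  base <- data.frame(
    attb_ref = c("a1", "a2", "a3", "a4", "a5"),
    contig = "c1",
    start = c(100L, 120L, 1000L, 1020L, 5000L),
    end = c(160L, 180L, 1060L, 1080L, 5060L),
    strand = "+", status = "candidate", reason = "ok",
    best_hit_score = c(80, 70, 90, 90, 60),
    ref_gi = paste0("G|g", 1:5),
    ref_gi_support = c(5, 9, 7.2, 9.5, 9.9),
    stringsAsFactors = FALSE)
  r <- bin_and_select(base)
  # bin 1: 80 beats 70; bin 2: equal hit scores, support 9.5 wins
  expect_identical(sort(r$ranked_candidates$attb_ref),
                   c("a1", "a4", "a5"))
  expect_identical(sort(r$duplicates$attb_ref), c("a2", "a3"))
  expect_true(all(r$duplicates$reason == "overlap_loser"))
  # ranks descend by island support: a5 (9.9), a4 (9.5), a1 (5)
  expect_identical(r$ranked_candidates$attb_ref[
    order(r$ranked_candidates$rank)], c("a5", "a4", "a1"))
  expect_identical(r$ranked_candidates$rank[
    order(r$ranked_candidates$rank)], 1:3)
})

test_that("planted islands of 5-100 kb are recovered as occupied and a
           mismatched span never is", {
  lens <- c(5000L, 10000L, 40000L, 100000L)
  ref <- synth_reference_db(n_species = 1L, attbs_per_species = 5L,
                            seed = 111L, gi_lengths = c(lens, 30000L),
                            backbone_len = 5000L)
  tr <- ref$attb_truth
  genome <- random_genome(190000L, seed = 112L, prefix = "t")
  cursor <- 1000L
  for (i in 1:4) {
    a <- list(sequence = tr$sequence[i],
              idblock_start = tr$idblock_start[i],
              idblock_end = tr$idblock_end[i])
    genome <- plant_occupied(genome, a, lens[i], "t_1", cursor,
                             flank = attbscout:::flank_for_family(
                               tr$family[i]),
                             filler_seed = 113L + i)
    cursor <- cursor + lens[i] + 500L
  }
  # attB 5: planted span misses its 30 kb reference by |nd| >= 0.06
  a5 <- list(sequence = tr$sequence[5],
             idblock_start = tr$idblock_start[5],
             idblock_end = tr$idblock_end[5])
  span5 <- 26400L  # nd = 3600/56400 = 0.0638
  genome <- plant_occupied(genome, a5, span5, "t_1", cursor,
                           flank = attbscout:::flank_for_family(
                             tr$family[5]),
                           filler_seed = 118L)
  hits <- find_hits(build_query_set(ref$db$attbs), genome)
  cls <- classify_hits(hits, ref$db, genome)
  occ_ids <- cls$occupied$attb_ref
  for (i in 1:4)
    expect_true(attbscout:::attb_id_for(ref$db, tr$sequence[i]) %in%
                occ_ids)
  expect_false(attbscout:::attb_id_for(ref$db, tr$sequence[5]) %in%
               occ_ids)
  expect_equal(sort(cls$occupied$expected), sort(as.numeric(lens)))
  expect_equal(max(abs(cls$occupied$normalized_difference)), 0)
})

test_that("classification is invariant to hit order", {
  fx <- standard_fixture(seed = 7L)
  qs <- build_query_set(fx$db$attbs)
  hits <- find_hits(qs, fx$genome)
  cls1 <- classify_hits(hits, fx$db, fx$genome)
  set.seed(120)
  shuffled <- hits[sample(nrow(hits)), , drop = FALSE]
  rownames(shuffled) <- NULL
  cls2 <- classify_hits(shuffled, fx$db, fx$genome)
  for (part in c("ranked_candidates", "duplicates", "occupied")) {
    a <- cls1[[part]]; b <- cls2[[part]]
    expect_identical(a[order(a$attb_ref), , drop = FALSE]$attb_ref,
                     b[order(b$attb_ref), , drop = FALSE]$attb_ref)
  }
  expect_identical(cls1$ranked_candidates$rank, cls2$ranked_candidates$rank)
})
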