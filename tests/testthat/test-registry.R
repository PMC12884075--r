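# reference-database construction: ddha metric, family filters, attB
# deduplication, IO round trips

test_that("compute_ddha matches the definition and its worked examples", {
  full <- list(hmm_from = 1, hmm_to = 300, hmm_length = 300,
               ali_from = 1, ali_to = 300)
  expect_identical(compute_ddha(full, 300)$ddha, 0L)

  h <- compute_ddha(list(hmm_from = 101, hmm_to = 300, hmm_length = 300,
                         ali_from = 1, ali_to = 200), 200)
  expect_identical(c(h$delta_h, h$delta_a, h$ddha), c(100L, 0L, 100L))

  h2 <- compute_ddha(list(hmm_from = 1, hmm_to = 300, hmm_length = 300,
                          ali_from = 51, ali_to = 350), 400)
  expect_identical(c(h2$delta_h, h2$delta_a, h2$ddha), c(0L, 100L, -100L))

  expect_error(compute_ddha(list(hmm_from = 10, hmm_to = 5,
                                 hmm_length = 300, ali_from = 1,
                                 ali_to = 100), 100), "invalid HMM")
  expect_error(compute_ddha(full, 250), "exceeds protein length")
})

test_that("compute_ddha is translation-covariant under N-terminal padding", {
  set.seed(11)
  for (i in 1:25) {
    plen <- sample(200:500, 1)
    hl <- sample(100:300, 1)
    hf <- sample(1:20, 1); ht <- sample(hl - 20, 1) + 20L
    af <- sample(1:30, 1); at <- sample(af:plen, 1)
    base <- compute_ddha(list(hmm_from = hf, hmm_to = ht, hmm_length = hl,
                              ali_from = af, ali_to = at), plen)
    t <- sample(1:50, 1)
    pad <- compute_ddha(list(hmm_from = hf, hmm_to = ht, hmm_length = hl,
                             ali_from = af + t, ali_to = at + t),
                        plen + t)
    expect_identical(pad$delta_a, base$delta_a + t)
    expect_identical(pad$ddha, base$ddha - t)
  }
})

test_that("tyrosine filter applies its rules in order, with boundaries", {
  # pass: medium protein, panel hit, small ddha
  r <- filter_tyrosine(tyr_rec(393), tyr_hit(ddha = 5L))
  expect_identical(r$verdict, "pass")
  # no panel hit
  r <- filter_tyrosine(tyr_rec(), tyr_hit(hmm = "NotInPanel"))
  expect_identical(r$reject_reason, "no_hmm")
  # best hit excluded subfamily (beats a weaker panel hit)
  hits <- rbind(tyr_hit(ddha = 5L, score = 100),
                tyr_hit(ddha = 5L, hmm = "Xer", score = 300))
  r <- filter_tyrosine(tyr_rec(), hits)
  expect_identical(r$reject_reason, "xer_or_integron")
  # length boundary: 800 passes, 801+ rejects
  expect_identical(
    filter_tyrosine(tyr_rec(800), tyr_hit(len = 800L))$verdict, "pass")
  expect_identical(
    filter_tyrosine(tyr_rec(850), tyr_hit(len = 850L))$reject_reason,
    "too_long")
  # ddha boundary: 100 passes (cutoff is strict >), 120 rejects
  expect_identical(
    filter_tyrosine(tyr_rec(200), tyr_hit(ddha = 100L, len = 200L))$verdict,
    "pass")
  expect_identical(
    filter_tyrosine(tyr_rec(200),
                    tyr_hit(ddha = 120L, len = 200L))$reject_reason,
    "truncated")
  expect_error(filter_tyrosine(tyr_rec(0), tyr_hit()), "empty")
})

ser_hits <- function(id = "p1", len = 500L, ddha = -10L, swap = FALSE) {
  rbind(attbscout:::make_domhit(id, "Resolvase", 120L, len, -200L, 100,
                                lead = if (swap) 150L else 4L),
        attbscout:::make_domhit(id, "Recombinase", 180L, len, ddha, 300,
                                lead = if (swap) 4L else 140L))
}

test_that("serine filter handles architecture, IS607 branch, boundaries", {
  expect_identical(filter_serine(ser_rec(500), ser_hits())$verdict, "pass")
  expect_identical(
    filter_serine(ser_rec(500), ser_hits(swap = TRUE))$reject_reason,
    "bad_architecture")
  # IS607 branch: 250 aa, ddha = 0 passes (<= 0 allowed)
  is607 <- attbscout:::make_domhit("p1", "S-Core_IS607", 150L, 250L, 0L,
                                   200)
  expect_identical(
    filter_serine(ser_rec(250, class = "s_core_is607"), is607)$verdict,
    "pass")
  expect_identical(
    filter_serine(ser_rec(301, class = "s_core_is607"),
                  attbscout:::make_domhit("p1", "S-Core_IS607", 150L,
                                          301L, 0L, 200))$reject_reason,
    "too_long")
  # length boundary 800 passes; ddha > 0 is truncated
  expect_identical(filter_serine(ser_rec(800),
                                 ser_hits(len = 800L))$verdict, "pass")
  expect_identical(
    filter_serine(ser_rec(500),
                  ser_hits(ddha = 10L))$reject_reason, "truncated")
  expect_identical(filter_serine(ser_rec(500),
                                 ser_hits()[0, ])$reject_reason, "no_hmm")
})

test_that("family filters partition every constructed record", {
  tyr_cases <- list(
    list(rec = tyr_rec(393), hits = tyr_hit(ddha = 5L)),
    list(rec = tyr_rec(850), hits = tyr_hit(len = 850L)),
    list(rec = tyr_rec(200), hits = tyr_hit(ddha = 120L, len = 200L)),
    list(rec = tyr_rec(), hits = tyr_hit(hmm = "Xer")),
    list(rec = tyr_rec(), hits = tyr_hit(hmm = "NotInPanel")))
  verdicts <- vapply(tyr_cases, function(cs)
    filter_tyrosine(cs$rec, cs$hits)$verdict, character(1))
  expect_identical(sum(verdicts == "pass") + sum(verdicts == "reject"),
                   length(tyr_cases))
  reasons <- vapply(tyr_cases, function(cs)
    filter_tyrosine(cs$rec, cs$hits)$reject_reason, character(1))
  expect_identical(all(xor(verdicts == "pass", reasons != "none")), TRUE)
})

test_that("dedupe_attbs collapses identical sequences and drops short", {
  set.seed(3)
  s40 <- attbscout:::random_dna(40)
  gis <- simple_gi_table(c(s40, s40), support = c(2, 7),
                         ints = c("iA", "iB"))
  dd <- dedupe_attbs(gis)
  expect_identical(nrow(dd$attbs), 1L)
  expect_identical(dd$attbs$gi_refs[[1]], sort(gis$gi_id))
  expect_identical(dd$attbs$integrase_refs[[1]], c("iA", "iB"))

  gis3 <- simple_gi_table(vapply(1:3, function(i)
    attbscout:::random_dna(40), character(1)))
  expect_identical(nrow(dedupe_attbs(gis3)$attbs), 3L)

  short <- simple_gi_table(attbscout:::random_dna(20))
  dd2 <- dedupe_attbs(short, min_len = 22L)
  expect_identical(nrow(dd2$attbs), 0L)
  expect_identical(dd2$n_dropped_seqs, 1L)
})

test_that("dedupe_attbs is idempotent, conserving, and resolves ID-block
           disagreement by support", {
  set.seed(4)
  seqs <- c(replicate(5, attbscout:::random_dna(40)))
  gis <- simple_gi_table(c(seqs, seqs[2], seqs[3]))
  dd <- dedupe_attbs(gis)
  # conservation: every GI in exactly one record (none dropped here)
  expect_identical(sort(unlist(dd$attbs$gi_refs)), sort(gis$gi_id))
  expect_identical(nrow(dd$attbs) + dd$n_dropped_seqs,
                   length(unique(gis$attb_seq)))
  # idempotence: re-deduping the deduped sequences changes nothing
  gis2 <- simple_gi_table(dd$attbs$sequence)
  expect_identical(dedupe_attbs(gis2)$attbs$sequence, dd$attbs$sequence)
  # ID-block disagreement: highest support wins, with warning
  g <- simple_gi_table(c(seqs[1], seqs[1]), support = c(2, 9))
  g$idblock_start <- c(11L, 13L)
  expect_warning(dd3 <- dedupe_attbs(g), "disagree")
  expect_identical(dd3$attbs$idblock_start, 13L)
})

test_that("build_reference_db filters integrases and drops orphan attBs", {
  # 10 GIs, 12 integrases, 2 failing on ddha
  set.seed(5)
  seqs <- vapply(1:10, function(i) attbscout:::random_dna(45),
                 character(1))
  gis <- simple_gi_table(seqs)
  gis$integrase_ids[[1]] <- c("i01", "iX1")   # extra failing integrase
  gis$integrase_ids[[2]] <- "iX2"             # sole integrase fails
  ids <- c(sprintf("i%02d", 1:10), "iX1", "iX2")
  prots <- setNames(vapply(seq_along(ids), function(i)
    paste(sample(attbscout:::AA20, 350, replace = TRUE), collapse = ""),
    character(1)), ids)
  hits <- do.call(rbind, lapply(ids, function(id)
    attbscout:::make_domhit(id, "Int_P2", 300L, 350L,
                            if (startsWith(id, "iX")) 150L else -5L,
                            200)))
  db <- build_reference_db(gis, prots, hits,
                           data.frame(genome_accession = "GCA_T001",
                                      species = "s", genus = "g"))
  # i02 is never referenced by a GI (GI 2 carries only iX2), so eleven
  # integrases enter filtering and nine pass
  expect_identical(sum(db$verdicts$verdict == "pass"), 9L)
  expect_identical(sort(db$verdicts$protein_id[
    db$verdicts$verdict == "reject"]), c("iX1", "iX2"))
  # attB of GI 2 lost (only integrase rejected); attB of GI 1 kept
  expect_identical(nrow(db$attbs), 9L)
  expect_false(seqs[2] %in% db$attbs$sequence)
  # no queryable attB references only rejected integrases
  passing <- db$verdicts$protein_id[db$verdicts$verdict == "pass"]
  expect_true(all(vapply(db$attbs$integrase_refs,
                         function(x) any(x %in% passing), logical(1))))
})

test_that("build_reference_db contracts: empty table, dangling reference", {
  tax <- data.frame(genome_accession = character(0),
                    species = character(0), genus = character(0))
  expect_warning(db <- build_reference_db(attbscout:::empty_gi_table(),
                                          character(0),
                                          tyr_hit()[0, ], tax),
                 "empty GI table")
  expect_identical(nrow(db$attbs), 0L)

  gis <- simple_gi_table(strrep("ACGT", 10), ints = "missing_prot")
  expect_error(build_reference_db(gis, c(iA = "MMMM"),
                                  tyr_hit(id = "iA", len = 4L), tax),
               "missing_prot")
})

test_that("GI table, domtblout and ReferenceDB round-trip through files", {
  ref <- synth_reference_db(n_species = 2L, attbs_per_species = 4L,
                            seed = 21L, backbone_len = 4000L)
  td <- withr::local_tempdir()
  p <- file.path(td, "gi.tsv")
  write_gi_table(ref$gi_table, p)
  back <- read_gi_table(p)
  expect_equal(back$attb_seq, ref$gi_table$attb_seq)
  expect_identical(lapply(back$integrase_ids, identity),
                   lapply(ref$gi_table$integrase_ids, identity))

  dp <- file.path(td, "hits.tbl")
  write_domtblout(ref$domtblout, dp)
  hits <- read_domtblout(dp)
  expect_equal(hits$ali_from,  ref$domtblout$ali_from)
  expect_equal(hits$hmm_length, ref$domtblout$hmm_length)

  dbp <- file.path(td, "db.json")
  write_reference_db(ref$db, dbp)
  db2 <- read_reference_db(dbp)
  expect_equal(db2$attbs$sequence, ref$db$attbs$sequence)
  expect_equal(db2$gis$length, ref$db$gis$length)
  expect_identical(sort(names(db2$integrases)),
                   sort(names(ref$db$integrases)))
})
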