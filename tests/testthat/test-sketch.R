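# MinHash sketching, distance, neighbour ranking, taxonomic collection

test_that("sketch_genome is deterministic and bounded by s", {
  g <- random_genome(10000L, seed = 1L)
  a <- sketch_genome(g, genome_id = "a")
  b <- sketch_genome(g, genome_id = "b")
  expect_identical(a$hashes, b$hashes)
  expect_identical(length(a$hashes), 1000L)   # >= 1000 distinct 21-mers
  expect_identical(a$hashes, sort(a$hashes))  # ascending

  # genome of length k: exactly one k-mer, one hash
  one <- sketch_genome(setNames(substr(strrep("ACGTG", 5), 1, 21), "c"),
                       k = 21L)
  expect_identical(length(one$hashes), 1L)
  expect_error(sketch_genome(setNames("ACGT", "c"), k = 21L), "shorter")
})

fake_sketch <- function(id, hashes, k = 21L, s = 3L) {
  structure(list(genome_id = id, k = k, s = s,
                 hashes = sprintf("%016x", as.integer(hashes)),
                 genome_length = 1000L),
            class = "Sketch")
}

test_that("mash_distance matches the closed form and its boundaries", {
  a <- fake_sketch("a", c(1, 2, 3))
  expect_equal(mash_distance(a, a)$distance, 0)
  expect_equal(mash_distance(a, a)$jaccard, 1)
  b <- fake_sketch("b", c(4, 5, 6))
  expect_equal(mash_distance(a, b)$jaccard, 0)
  expect_equal(mash_distance(a, b)$distance, 1.0)
  # shared bottom-3 of the union {1..5} is {1,2,3}; only 1 is in both
  cc <- fake_sketch("c", c(1, 4, 5))
  m <- mash_distance(a, cc)
  expect_equal(m$jaccard, 1 / 3)
  expect_equal(m$distance, -(1 / 21) * log(0.5), tolerance = 1e-5)
  expect_equal(m$distance, 0.03301, tolerance = 1e-3)
  bad <- fake_sketch("d", c(1, 2, 3), k = 19L)
  expect_error(mash_distance(a, bad), "different k")
})

test_that("mash_distance is symmetric and monotone in shared hashes", {
  set.seed(8)
  for (i in 1:10) {
    g1 <- random_genome(5000L, seed = 100 + i)
    g2 <- random_genome(5000L, seed = 200 + i)
    s1 <- sketch_genome(g1, s = 200L, genome_id = "x")
    s2 <- sketch_genome(g2, s = 200L, genome_id = "y")
    expect_identical(mash_distance(s1, s2)$distance,
                     mash_distance(s2, s1)$distance)
  }
  # monotone: more shared values in a fixed-size merged sketch, smaller d
  base <- 1:6
  dists <- vapply(0:6, function(sh) {
    a <- fake_sketch("a", base, s = 6L)
    b <- fake_sketch("b", c(head(base, sh),
                            if (sh < 6) 100 + seq_len(6 - sh)), s = 6L)
    mash_distance(a, b)$distance
  }, numeric(1))
  expect_true(all(diff(dists) <= 0))
})

test_that("sketch Jaccard converges to the true k-mer Jaccard", {
  # two related 15 kb genomes: true canonical-k-mer Jaccard by brute force
  k <- 21L
  g1 <- random_genome(15000L, seed = 31L)[[1]]
  chars <- strsplit(g1, "")[[1]]
  set.seed(32)
  mut <- sample(length(chars), 120L)
  chars[mut] <- vapply(chars[mut], function(c)
    sample(setdiff(c("A", "C", "G", "T"), c), 1L), character(1))
  g2 <- paste(chars, collapse = "")

  canon_set <- function(g) {
    kmers <- substring(g, 1:(nchar(g) - k + 1L), k:nchar(g))
    rc <- revcomp(kmers)
    unique(pmin(kmers, rc))
  }
  k1 <- canon_set(g1); k2 <- canon_set(g2)
  j_true <- length(intersect(k1, k2)) / length(union(k1, k2))

  s1 <- sketch_genome(setNames(g1, "c"), s = 1000L, genome_id = "1")
  s2 <- sketch_genome(setNames(g2, "c"), s = 1000L, genome_id = "2")
  m <- mash_distance(s1, s2)
  sigma <- sqrt(j_true * (1 - j_true) / 1000)
  expect_lt(abs(m$jaccard - j_true), 3 * sigma + 1e-9)
})

test_that("rank_neighbors sorts by distance with lexicographic ties", {
  g <- random_genome(8000L, seed = 41L)
  t <- sketch_genome(g, s = 300L, genome_id = "target")
  self <- sketch_genome(g, s = 300L, genome_id = "self")
  far1 <- sketch_genome(random_genome(8000L, seed = 42L), s = 300L,
                        genome_id = "zzz")
  far2 <- sketch_genome(random_genome(8000L, seed = 43L), s = 300L,
                        genome_id = "aaa")
  r <- rank_neighbors(t, list(far1, self, far2))
  expect_identical(r$genome_id[1], "self")
  expect_equal(r$distance[1], 0)
  # unrelated genomes both capped at d = 1: tie broken lexicographically
  expect_identical(r$genome_id[2:3], c("aaa", "zzz"))
  expect_error(rank_neighbors(t, list()), "no reference")
})

collect_db <- function(per_species, n_attb_len = 40L) {
  # species named by letter; one genome per species; one GI per attB
  rows <- list(); gis <- list(); k <- 0L
  set.seed(55)
  for (si in seq_along(per_species)) {
    for (ai in seq_len(per_species[si])) {
      k <- k + 1L
      seq <- attbscout:::random_dna(n_attb_len)
      acc <- sprintf("GCA_%s", LETTERS[si])
      gis[[k]] <- mini_gi(gi_id = sprintf("%s|g%03d", acc, k),
                          attb_seq = seq)
      rows[[k]] <- mini_attb(attb_id = sprintf("attb_%03d", k),
                             sequence = seq, idblock_start = 11L,
                             idblock_end = 30L,
                             gi_refs = sprintf("%s|g%03d", acc, k))
    }
  }
  db <- mini_db(do.call(rbind, rows), do.call(rbind, gis))
  db$taxonomy <- data.frame(
    genome_accession = sprintf("GCA_%s", LETTERS[seq_along(per_species)]),
    species = sprintf("sp_%s", LETTERS[seq_along(per_species)]),
    genus = c("gen_1", "gen_1", "gen_2")[seq_along(per_species)],
    stringsAsFactors = FALSE)
  db
}

test_that("collect_attbs adds whole species blocks until n_min", {
  db <- collect_db(c(30, 25, 10))
  ranked <- data.frame(genome_id = c("GCA_A", "GCA_B", "GCA_C"),
                       jaccard = c(.5, .3, .1),
                       distance = c(.01, .05, .2),
                       species = c("sp_A", "sp_B", "sp_C"),
                       genus = c("gen_1", "gen_1", "gen_2"),
                       stringsAsFactors = FALSE)
  # atomic addition: 30 < 50 so the whole of sp_B joins -> 55
  expect_identical(nrow(collect_attbs(ranked, db, n_min = 50L)), 55L)
  # fewer than n_min available: everything returned, tolerated
  expect_identical(nrow(collect_attbs(ranked, db, n_min = 500L)), 65L)
  # n_min = 0: the best species block only
  expect_identical(nrow(collect_attbs(ranked, db, n_min = 0L)), 30L)
  # unranked species of an included genus precede foreign genera
  ranked1 <- ranked[1, , drop = FALSE]
  got <- collect_attbs(ranked1, db, n_min = 40L)
  sp_of <- function(df) unique(unlist(lapply(df$gi_refs, function(r)
    substr(r, 5, 5))))
  expect_identical(sort(sp_of(got)), c("A", "B"))  # gen_1 before gen_2
})

test_that("sketch cache round-trips", {
  sk <- lapply(1:3, function(i)
    sketch_genome(random_genome(3000L, seed = 60 + i), s = 100L,
                  genome_id = paste0("g", i)))
  p <- withr::local_tempfile()
  write_sketch_cache(sk, p)
  back <- read_sketch_cache(p)
  expect_identical(lapply(back, `[[`, "hashes"),
                   lapply(sk, `[[`, "hashes"))
  expect_identical(vapply(back, `[[`, character(1), "genome_id"),
                   c("g1", "g2", "g3"))
})
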