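# Synthetic genomes, reference databases and planted-truth fixtures.
# Everything regenerates byte-identically from (parameters, seed); no
# downloads, no bundled data.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random DNA under the current RNG state
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Random genome with i.i.d. bases at a given GC content
#'
#' @param length total length in nt.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed; regeneration is byte-identical.
#' @param n_contigs split the sequence into this many contigs.
#' @param prefix contig name prefix.
#' @return named character vector of contigs with an empty `plants`
#'   bookkeeping attribute.
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L, n_contigs = 1L,
                          prefix = "contig") {
  stopifnot(length > 0, gc > 0, gc < 1, n_contigs >= 1)
  with_seed(seed, {
    cuts <- floor(length * seq(0, 1, length.out = n_contigs + 1L))
    seqs <- vapply(seq_len(n_contigs), function(i)
      random_dna(cuts[i + 1L] - cuts[i], gc), character(1))
    names(seqs) <- sprintf("%s_%d", prefix, seq_len(n_contigs))
    attr(seqs, "plants") <- empty_plants()
    seqs
  })
}

empty_plants <- function() {
  empty_df(list(contig = "character", start = "integer", end = "integer",
                kind = "character", label = "character"))
}

plants_of <- function(genome) {
  p <- attr(genome, "plants")
  if (is.null(p)) empty_plants() else p
}

record_plant <- function(genome, contig, start, end, kind, label) {
  p <- plants_of(genome)
  prev <- p[p$contig == contig, , drop = FALSE]
  if (overlaps_any(start, end, prev$start, prev$end))
    stop("plant [", start, ", ", end, "] on ", contig,
         " overlaps an existing plant")
  if (end > nchar(genome[[contig]]) || start < 1L)
    stop("plant [", start, ", ", end, "] does not fit in ", contig)
  attr(genome, "plants") <- rbind(p, data.frame(
    contig = contig, start = as.integer(start), end = as.integer(end),
    kind = kind, label = label, stringsAsFactors = FALSE))
  genome
}

# replace genome bases at [start, start+nchar(repl)-1]
splice_seq <- function(genome, contig, start, repl) {
  s <- genome[[contig]]
  end <- start + nchar(repl) - 1L
  genome[contig] <- paste0(substr(s, 1L, start - 1L), repl,
                           substr(s, end + 1L, nchar(s)))
  genome
}

# exactly n_mismatch substitutions and n_gap (0/1) indels
mutate_seq <- function(seq, n_mismatch = 0L, n_gap = 0L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n_mismatch > 0L) {
    pos <- sample(length(chars), n_mismatch)
    for (p in pos)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  if (n_gap > 0L) {
    stopifnot(n_gap == 1L)
    if (runif(1) < 0.5) {
      chars <- chars[-sample(length(chars), 1L)]           # deletion
    } else {
      at <- sample(length(chars) + 1L, 1L)                 # insertion
      chars <- append(chars, sample(c("A", "C", "G", "T"), 1L),
                      after = at - 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Plant an attB sequence into a genome
#'
#' Replaces genome bases at the locus with the attB sequence, optionally
#' mutated with exactly the stated numbers of substitutions and indels.
#'
#' @param genome genome from [random_genome()].
#' @param attb list or one-row data.frame with `sequence` (and optionally
#'   `attb_id`).
#' @param contig,start target locus (1-based).
#' @param edits integer pair `(n_mismatch, n_gap)`.
#' @param seed seed for edit placement.
#' @return the modified genome; the plant is recorded in the `plants`
#'   attribute and the planted sequence in the `last_plant` attribute.
#' @export
plant_attb <- function(genome, attb, contig, start, edits = c(0L, 0L),
                       seed = 1L) {
  seq <- toupper(attb$sequence)
  planted <- with_seed(seed, mutate_seq(seq, edits[1], edits[2]))
  end <- start + nchar(planted) - 1L
  genome <- record_plant(genome, contig, start, end, "attb",
                         if (!is.null(attb$attb_id)) attb$attb_id else "")
  genome <- splice_seq(genome, contig, start, planted)
  attr(genome, "last_plant") <- list(contig = contig, start = start,
                                     end = end, sequence = planted)
  genome
}

# query half sites of an attB at a given flank length
half_sites <- function(attb, flank) {
  len <- nchar(attb$sequence)
  list(L = substr(attb$sequence, max(1L, attb$idblock_start - flank),
                  attb$idblock_end),
       R = substr(attb$sequence, attb$idblock_start,
                  min(len, attb$idblock_end + flank)))
}

# GC-matched filler screened against exact ID-block copies (either strand)
screened_filler <- function(n, gc, idblock) {
  if (n <= 0L) return("")
  repeat {
    f <- random_dna(n, gc)
    if (!grepl(idblock, f, fixed = TRUE) &&
        !grepl(revcomp(idblock), f, fixed = TRUE)) return(f)
  }
}

#' Plant an island-occupied attB site
#'
#' Inserts `left half site ... filler ... right half site` such that the
#' outer span (left-hit start to right-hit end) equals `gi_length`.  The
#' half sites are exactly the query half sites at flank length `flank`, so
#' downstream occupancy inference observes `actual == gi_length`.
#'
#' @param genome genome from [random_genome()].
#' @param attb list/one-row data.frame with `sequence`, `idblock_start`,
#'   `idblock_end`.
#' @param gi_length outer span in nt.
#' @param contig,start locus of the left-hit start.
#' @param flank half-site flank length (16 serine / 10 tyrosine).
#' @param gc filler GC content.
#' @param filler_seed seed for the filler sequence.
#' @return the modified genome.
#' @export
plant_occupied <- function(genome, attb, gi_length, contig, start,
                           flank = 10L, gc = 0.5, filler_seed = 1L) {
  hs <- half_sites(attb, flank)
  idblock <- substr(attb$sequence, attb$idblock_start, attb$idblock_end)
  mid <- gi_length - nchar(hs$L) - nchar(hs$R)
  if (mid < 0L)
    stop("gi_length ", gi_length, " too short for the two half sites")
  filler <- with_seed(filler_seed, screened_filler(mid, gc, idblock))
  block <- paste0(hs$L, filler, hs$R)
  end <- start + gi_length - 1L
  genome <- record_plant(genome, contig, start, end, "occupied",
                         if (!is.null(attb$attb_id)) attb$attb_id else "")
  splice_seq(genome, contig, start, block)
}

#' Plant an island-occupied site split across two contigs
#'
#' The left half site sits `d_left` nt from the right terminus of
#' `contig_left` (measured from the left-hit start) and the right half
#' site ends `d_right = gi_length - d_left` nt into `contig_right`, so the
#' cross-contig occupancy geometry reconstructs `actual == gi_length`.
#'
#' @inheritParams plant_occupied
#' @param contig_left,contig_right the two contigs.
#' @param d_left distance from the left-hit start to the end of
#'   `contig_left`.
#' @return the modified genome.
#' @export
plant_occupied_split <- function(genome, attb, gi_length, contig_left,
                                 contig_right, d_left, flank = 10L,
                                 gc = 0.5, filler_seed = 1L) {
  hs <- half_sites(attb, flank)
  idblock <- substr(attb$sequence, attb$idblock_start, attb$idblock_end)
  d_right <- gi_length - d_left
  if (d_left < nchar(hs$L) || d_right < nchar(hs$R))
    stop("split distances too short for the half sites")
  len_l <- nchar(genome[[contig_left]])
  s1 <- len_l - d_left + 1L
  fill1 <- with_seed(filler_seed,
                     screened_filler(d_left - nchar(hs$L), gc, idblock))
  fill2 <- with_seed(filler_seed + 1L,
                     screened_filler(d_right - nchar(hs$R), gc, idblock))
  genome <- record_plant(genome, contig_left, s1, len_l, "occupied_L",
                         if (!is.null(attb$attb_id)) attb$attb_id else "")
  genome <- splice_seq(genome, contig_left, s1, paste0(hs$L, fill1))
  genome <- record_plant(genome, contig_right, 1L, d_right, "occupied_R",
                         if (!is.null(attb$attb_id)) attb$attb_id else "")
  genome <- splice_seq(genome, contig_right, 1L, paste0(fill2, hs$R))
  genome
}

# one synthetic attB: random flanks around a random identity block,
# screened against long homopolymer runs
gen_attb <- function(idblock = NULL, gc = 0.5) {
  repeat {
    ib_len <- sample(14:22, 1L)
    fl_l <- sample(12:20, 1L)
    fl_r <- sample(12:20, 1L)
    ib <- if (is.null(idblock)) random_dna(ib_len, gc) else idblock
    seq <- paste0(random_dna(fl_l, gc), ib, random_dna(fl_r, gc))
    if (is.null(idblock) && max_homopolymer_run(seq) >= 8L) next
    return(list(sequence = seq, idblock_start = fl_l + 1L,
                idblock_end = fl_l + nchar(ib)))
  }
}

# Fabricate a domtblout row realizing a requested ddha on a protein.
# `lead` fixes ali_from - 1 (protein residues before the hit), so domain
# order can be controlled independently of the truncation metric:
# dA = lead + trail, dH = ddha + dA, missing HMM positions at the C end.
make_domhit <- function(protein_id, hmm_name, hmm_length, protein_len,
                        ddha, score, lead = 0L) {
  ddha <- as.integer(ddha); lead <- as.integer(lead)
  trail <- max(0L, -ddha - lead)
  d_a <- lead + trail
  d_h <- ddha + d_a
  if (d_h < 0L) stop("lead too small for ddha ", ddha)
  hmm_from <- 1L; hmm_to <- hmm_length - d_h
  if (hmm_to < 1L) stop("ddha ", ddha, " exceeds hmm_length")
  ali_from <- 1L + lead; ali_to <- protein_len - trail
  if (ali_from > ali_to) stop("protein too short for ddha ", ddha)
  data.frame(protein_id = protein_id, hmm_name = hmm_name,
             hmm_length = hmm_length, score = score,
             hmm_from = hmm_from, hmm_to = hmm_to,
             ali_from = ali_from, ali_to = ali_to,
             stringsAsFactors = FALSE)
}

#' Write domain hits in the HMMER3 domtblout dialect
#' @param hits data.frame as produced by [read_domtblout()] plus a
#'   `protein_len` column (tlen).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  header <- paste("#", "target name accession tlen query name accession",
                  "qlen E-value score bias # of c-Evalue i-Evalue score",
                  "bias from to from to from to acc description")
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(h$protein_id, "-", h$protein_len, h$hmm_name, "-", h$hmm_length,
          "1e-50", h$score, "0.1", "1", "1", "1e-50", "1e-50", h$score,
          "0.1", h$hmm_from, h$hmm_to, h$ali_from, h$ali_to,
          h$ali_from, h$ali_to, "0.99", "-")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Generate a synthetic reference database with reference genomes
#'
#' Emits (in memory, optionally to files) a GI table, integrase protein
#' FASTA, fabricated domtblout rows, a taxonomy table and per-species
#' reference genomes with the attBs embedded, then builds the
#' `ReferenceDB`.  The fabricated proteins are random sequences: the
#' integrity filters read coordinates and scores, not residues.
#'
#' @param n_species number of reference species (one genome each).
#' @param attbs_per_species attBs per species (recycled).
#' @param seed integer seed; output is byte-identical per seed.
#' @param attb_list optional list (one element per species) of lists of
#'   attB definitions (`sequence`, `idblock_start`, `idblock_end`)
#'   overriding random generation.
#' @param gi_lengths optional integer vector of primary-GI lengths indexed
#'   by global attB order (species-major); `NA` entries fall back to
#'   random lengths.
#' @param integrase_ddha optional numeric vector (global attB order) of
#'   fabricated ddha values for each primary integrase.
#' @param swap_serine_domains optional logical vector (global attB order):
#'   fabricate Recombinase-before-Resolvase architecture.
#' @param second_gi_every every n-th attB gains a second reference GI and
#'   integrase (default 9; 0 disables).
#' @param backbone_len reference-genome backbone length in nt.
#' @param gc GC content.
#' @param out_dir optional directory: writes `gi_table.tsv`,
#'   `integrases.faa`, `domhits.tbl`, `taxonomy.tsv`,
#'   `genomes/<accession>.fna`.
#' @return list with `db` (a `ReferenceDB`), the input tables, the
#'   reference genomes, and `attb_truth` (generation ground truth with
#'   per-attB family, primary GI and its length).
#' @export
synth_reference_db <- function(n_species = 3L, attbs_per_species = 17L,
                               seed = 1L, attb_list = NULL,
                               gi_lengths = NULL, integrase_ddha = NULL,
                               swap_serine_domains = NULL,
                               second_gi_every = 9L,
                               backbone_len = 20000L, gc = 0.5,
                               out_dir = NULL) {
  stopifnot(n_species >= 1L)
  counts <- rep_len(attbs_per_species, n_species)
  with_seed(seed, {
    acc <- sprintf("GCA_SIM%03d", seq_len(n_species))
    species <- sprintf("Species_%02d", seq_len(n_species))
    genus <- sprintf("Genus_%02d", ceiling(seq_len(n_species) / 2))
    taxonomy <- data.frame(genome_accession = acc, species = species,
                           genus = genus, stringsAsFactors = FALSE)
    gi_rows <- list(); dom_rows <- list(); prots <- character(0)
    truth_rows <- list()
    ref_genomes <- list()
    k <- 0L
    for (si in seq_len(n_species)) {
      backbone <- random_dna(backbone_len, gc)
      for (ai in seq_len(counts[si])) {
        k <- k + 1L
        ab <- if (!is.null(attb_list)) attb_list[[si]][[ai]]
              else gen_attb(gc = gc)
        family <- if (k %% 3L == 0L) "serine" else "tyrosine"
        gi_len <- if (!is.null(gi_lengths) && k <= length(gi_lengths) &&
                      !is.na(gi_lengths[k])) as.integer(gi_lengths[k])
                  else sample(5000:50000, 1L)
        gi_start <- sample(1000:100000, 1L)
        pid <- sprintf("int%04d", k)
        plen <- sample(320:420, 1L)
        prots[pid] <- paste(sample(AA20, plen, replace = TRUE),
                            collapse = "")
        ddha <- if (!is.null(integrase_ddha) && k <= length(integrase_ddha)
                    && !is.na(integrase_ddha[k])) integrase_ddha[k]
                else if (family == "tyrosine") -10L else -20L
        swap <- !is.null(swap_serine_domains) &&
          k <= length(swap_serine_domains) &&
          isTRUE(swap_serine_domains[k])
        if (family == "tyrosine") {
          dh <- make_domhit(pid, "Int_P2", 300L, plen, ddha,
                            round(runif(1, 150, 400), 1))
        } else {
          # Resolvase then Recombinase along the protein (reversed when
          # fabricating a bad_architecture case); the best-scoring
          # Recombinase hit carries the requested ddha
          res_hit <- make_domhit(pid, "Resolvase", 120L, plen, -200L,
                                 round(runif(1, 50, 150), 1),
                                 lead = if (swap) 150L else 4L)
          rec_hit <- make_domhit(pid, "Recombinase", 180L, plen, ddha,
                                 round(runif(1, 200, 400), 1),
                                 lead = if (swap) 4L else 140L)
          dh <- rbind(res_hit, rec_hit)
        }
        dh$protein_len <- plen
        dom_rows[[length(dom_rows) + 1L]] <- dh
        gi_id <- sprintf("%s|gene%04d", acc[si], k)
        ints <- pid
        gi_rows[[length(gi_rows) + 1L]] <- data.frame(
          gi_id = gi_id, contig_accession = paste0(acc[si], "_ctg1"),
          start = gi_start, end = gi_start + gi_len - 1L, length = gi_len,
          support_score = round(runif(1, 1, 10), 2),
          attb_seq = ab$sequence, idblock_start = ab$idblock_start,
          idblock_end = ab$idblock_end,
          target_class = sample(c("tRNA", "tmRNA", "intergenic",
                                  "protein_coding"), 1L),
          stringsAsFactors = FALSE)
        gi_rows[[length(gi_rows)]]$integrase_ids <- I(list(ints))
        if (second_gi_every > 0L && k %% second_gi_every == 0L) {
          pid2 <- sprintf("int%04d_b", k)
          plen2 <- sample(320:420, 1L)
          prots[pid2] <- paste(sample(AA20, plen2, replace = TRUE),
                               collapse = "")
          dh2 <- make_domhit(pid2, "Int_SXT", 300L, plen2, -15L,
                             round(runif(1, 150, 400), 1))
          dh2$protein_len <- plen2
          dom_rows[[length(dom_rows) + 1L]] <- dh2
          gi2_len <- sample(5000:50000, 1L)
          gi2_start <- sample(1000:100000, 1L)
          g2 <- data.frame(
            gi_id = sprintf("%s|gene%04d_b", acc[si], k),
            contig_accession = paste0(acc[si], "_ctg1"),
            start = gi2_start, end = gi2_start + gi2_len - 1L,
            length = gi2_len,
            support_score = round(runif(1, 1, 10), 2),
            attb_seq = ab$sequence, idblock_start = ab$idblock_start,
            idblock_end = ab$idblock_end, target_class = "intergenic",
            stringsAsFactors = FALSE)
          g2$integrase_ids <- I(list(pid2))
          gi_rows[[length(gi_rows) + 1L]] <- g2
        }
        # embed the attB in the species reference genome
        pos <- 200L + (ai - 1L) * 700L
        backbone <- paste0(substr(backbone, 1L, pos - 1L), ab$sequence,
                           substr(backbone, pos + nchar(ab$sequence),
                                  nchar(backbone)))
        truth_rows[[k]] <- data.frame(
          species = species[si], genome_accession = acc[si],
          global_index = k, sequence = ab$sequence,
          idblock_start = ab$idblock_start, idblock_end = ab$idblock_end,
          family = family, gi_id = gi_id, gi_length = gi_len,
          protein_id = pid, stringsAsFactors = FALSE)
      }
      ref_genomes[[acc[si]]] <- setNames(backbone,
                                         paste0(acc[si], "_ctg1"))
    }
    gi_table <- do.call(rbind, gi_rows)
    domtbl <- do.call(rbind, dom_rows)
    attb_truth <- do.call(rbind, truth_rows)
    db <- build_reference_db(gi_table, prots,
                             domtbl[setdiff(names(domtbl), "protein_len")],
                             taxonomy)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      dir.create(file.path(out_dir, "genomes"), showWarnings = FALSE)
      write_gi_table(gi_table, file.path(out_dir, "gi_table.tsv"))
      write_fasta(prots, file.path(out_dir, "integrases.faa"), type = "AA")
      write_domtblout(domtbl, file.path(out_dir, "domhits.tbl"))
      write_tsv(taxonomy, file.path(out_dir, "taxonomy.tsv"))
      for (a in names(ref_genomes))
        write_fasta(ref_genomes[[a]],
                    file.path(out_dir, "genomes", paste0(a, ".fna")))
      write_reference_db(db, file.path(out_dir, "reference_db.json"))
    }
    list(db = db, gi_table = gi_table, proteins = prots,
         domtblout = domtbl, taxonomy = taxonomy,
         ref_genomes = ref_genomes, attb_truth = attb_truth)
  })
}

# attb_id in the built DB for a generated sequence
attb_id_for <- function(db, sequence) {
  id <- db$attbs$attb_id[db$attbs$sequence == toupper(sequence)]
  if (length(id) != 1L) stop("attB sequence not uniquely in DB")
  id
}

flank_for_family <- function(family, sl = 16L, yl = 10L) {
  ifelse(family == "serine", sl, yl)
}

#' Standard planted-truth fixture
#'
#' Builds a 3-species, 50-attB reference database and a single-contig
#' target genome whose first 20 kb are the backbone of the top-ranked
#' species (so taxonomic neighbour selection finds it), followed by a
#' planted region containing: 5 unoccupied attBs (0 edits), 2
#' island-occupied sites whose spans equal their reference island lengths
#' (5 kb and 8 kb), a near-length occupied decoy (reference island 40 kb,
#' planted span 36 kb, |nd| = 0.0526), a multi-ID-block decoy (attB
#' planted once plus a second ID-block copy elsewhere) and a homopolymer
#' decoy (attB whose 12-nt ID block is a single-nucleotide run).
#'
#' @param seed integer seed.
#' @param out_dir optional directory: writes the database files, the
#'   target genome (`genome.fna`), a reference sketch cache
#'   (`sketches.jsonl`) and `truth.json`.
#' @return list with `db`, `genome`, `ref` (the [synth_reference_db()]
#'   output), `sketches` and `truth` (planted loci and expected calls by
#'   attB id).
#' @export
standard_fixture <- function(seed = 1L, out_dir = NULL) {
  base <- as.integer(seed)
  # attB definitions for species 1 need custom entries (homopolymer decoy)
  attb_list <- with_seed(base + 1L, {
    lapply(seq_len(3L), function(si) {
      n <- c(17L, 17L, 16L)[si]
      lapply(seq_len(n), function(ai) {
        if (si == 1L && ai == 10L) {
          # 12-nt single-nucleotide-run ID block; non-A flanking bases
          # keep the run at exactly 12
          ab <- gen_attb(idblock = strrep("A", 12L))
          sq <- strsplit(ab$sequence, "")[[1]]
          sq[ab$idblock_start - 1L] <- "C"
          sq[ab$idblock_end + 1L] <- "G"
          ab$sequence <- paste(sq, collapse = "")
          ab
        } else gen_attb()
      })
    })
  })
  gi_lengths <- rep(NA_integer_, 50L)
  gi_lengths[6L] <- 5000L; gi_lengths[7L] <- 8000L
  gi_lengths[8L] <- 40000L
  ref <- synth_reference_db(n_species = 3L,
                            attbs_per_species = c(17L, 17L, 16L),
                            seed = base + 2L, attb_list = attb_list,
                            gi_lengths = gi_lengths)
  db <- ref$db
  tr <- ref$attb_truth
  sp1 <- tr[tr$species == "Species_01", ]
  ab <- function(i) {
    a <- attb_list[[1L]][[i]]
    a$attb_id <- attb_id_for(db, a$sequence)
    a$family <- sp1$family[i]
    a
  }
  # target genome: species-1 backbone (no attBs) + random tail
  backbone <- with_seed(base + 2L, {
    # regenerate the same species-1 backbone the reference genome used:
    # first draw of synth_reference_db's stream
    random_dna(20000L, 0.5)
  })
  tail_seq <- with_seed(base + 3L, random_dna(58000L, 0.5))
  genome <- setNames(paste0(backbone, tail_seq), "target_1")
  attr(genome, "plants") <- empty_plants()

  cand_idx <- 1:5
  cand_pos <- c(21000L, 21500L, 22000L, 22500L, 23000L)
  for (i in seq_along(cand_idx)) {
    genome <- plant_attb(genome, ab(cand_idx[i]), "target_1",
                         cand_pos[i], edits = c(0L, 0L),
                         seed = base + 10L + i)
  }
  a9 <- ab(9L)                               # multi-ID-block decoy
  genome <- plant_attb(genome, a9, "target_1", 23500L, seed = base + 20L)
  idb9 <- substr(a9$sequence, a9$idblock_start, a9$idblock_end)
  genome <- record_plant(genome, "target_1", 24000L,
                         24000L + nchar(idb9) - 1L, "idblock_copy",
                         a9$attb_id)
  genome <- splice_seq(genome, "target_1", 24000L, idb9)
  a10 <- ab(10L)                             # homopolymer decoy
  genome <- plant_attb(genome, a10, "target_1", 24500L, seed = base + 21L)
  a6 <- ab(6L); a7 <- ab(7L); a8 <- ab(8L)
  genome <- plant_occupied(genome, a6, 5000L, "target_1", 25000L,
                           flank = flank_for_family(a6$family),
                           filler_seed = base + 30L)
  genome <- plant_occupied(genome, a7, 8000L, "target_1", 30500L,
                           flank = flank_for_family(a7$family),
                           filler_seed = base + 31L)
  genome <- plant_occupied(genome, a8, 36000L, "target_1", 39000L,
                           flank = flank_for_family(a8$family),
                           filler_seed = base + 32L)
  truth <- list(
    seed = base,
    planted_candidates = data.frame(
      attb_id = vapply(cand_idx, function(i) ab(i)$attb_id, character(1)),
      contig = "target_1", start = cand_pos,
      end = cand_pos + vapply(cand_idx, function(i)
        nchar(ab(i)$sequence), integer(1)) - 1L,
      stringsAsFactors = FALSE),
    planted_occupied = data.frame(
      attb_id = c(a6$attb_id, a7$attb_id),
      gi_length = c(5000L, 8000L), start = c(25000L, 30500L),
      stringsAsFactors = FALSE),
    decoys = data.frame(
      kind = c("near_length_gi", "multi_idblock", "homopolymer"),
      attb_id = c(a8$attb_id, a9$attb_id, a10$attb_id),
      stringsAsFactors = FALSE))
  sketches <- lapply(names(ref$ref_genomes), function(a)
    sketch_genome(ref$ref_genomes[[a]], genome_id = a))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    synth_reference_db(n_species = 3L,
                       attbs_per_species = c(17L, 17L, 16L),
                       seed = base + 2L, attb_list = attb_list,
                       gi_lengths = gi_lengths, out_dir = out_dir)
    write_fasta(genome, file.path(out_dir, "genome.fna"))
    write_sketch_cache(sketches, file.path(out_dir, "sketches.jsonl"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(db = db, genome = genome, ref = ref, sketches = sketches,
       truth = truth)
}

#' Small randomized fixture for conservation audits
#'
#' Two species, twelve attBs, a ~15 kb target with a random mix of planted
#' unoccupied attBs (0-2 substitutions), one occupied site (3 kb), one
#' two-copy attB and one lone half site.
#'
#' @param seed integer seed.
#' @return list with `db`, `genome` and the planted attB ids.
#' @export
random_fixture <- function(seed = 1L) {
  base <- as.integer(seed)
  gi_lengths <- rep(NA_integer_, 12L); gi_lengths[4L] <- 3000L
  ref <- synth_reference_db(n_species = 2L, attbs_per_species = 6L,
                            seed = base + 1L, gi_lengths = gi_lengths,
                            second_gi_every = 5L, backbone_len = 6000L)
  db <- ref$db
  tr <- ref$attb_truth
  genome <- random_genome(15000L, gc = 0.5, seed = base + 2L,
                          prefix = "tgt")
  pick <- function(i) {
    a <- list(sequence = tr$sequence[i],
              idblock_start = tr$idblock_start[i],
              idblock_end = tr$idblock_end[i],
              family = tr$family[i])
    a$attb_id <- attb_id_for(db, a$sequence)
    a
  }
  edits <- with_seed(base + 3L, sample(0:2, 2L, replace = TRUE))
  genome <- plant_attb(genome, pick(1L), "tgt_1", 500L,
                       edits = c(edits[1], 0L), seed = base + 4L)
  genome <- plant_attb(genome, pick(2L), "tgt_1", 1000L,
                       edits = c(edits[2], 0L), seed = base + 5L)
  a4 <- pick(4L)
  genome <- plant_occupied(genome, a4, 3000L, "tgt_1", 1500L,
                           flank = flank_for_family(a4$family),
                           filler_seed = base + 6L)
  a5 <- pick(5L)                        # two-copy attB
  genome <- plant_attb(genome, a5, "tgt_1", 5000L, seed = base + 7L)
  genome <- plant_attb(genome, a5, "tgt_1", 6000L, seed = base + 8L)
  a6 <- pick(6L)                        # lone half site
  hsl <- half_sites(a6, flank_for_family(a6$family))$L
  genome <- record_plant(genome, "tgt_1", 7000L,
                         7000L + nchar(hsl) - 1L, "half", a6$attb_id)
  genome <- splice_seq(genome, "tgt_1", 7000L, hsl)
  list(db = db, genome = genome,
       planted_ids = vapply(c(1L, 2L, 4L, 5L, 6L),
                            function(i) pick(i)$attb_id, character(1)))
}
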