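# shared helpers: tiny constructed records and hit-set comparison keys

# canonical key for raw-hit set comparison
hit_key <- function(d) {
  sort(paste(d$query_id, d$contig, d$start, d$end, d$strand,
             d$gap_columns, d$mismatches))
}

# one-row MatchHit constructor with consistent derived fields
make_hit <- function(query_id = "a1_full", attb_ref = "a1", part = "full",
                     contig = "c1", start = 100L, aln_len = 40L,
                     mismatches = 0L, gap_columns = 0L, strand = "+") {
  identities <- aln_len - gap_columns - mismatches
  end <- start + aln_len - gap_columns - 1L  # genome span approximation
  df <- data.frame(query_id = query_id, attb_ref = attb_ref, part = part,
                   contig = contig, start = start, end = end,
                   strand = strand, aln_len = aln_len,
                   identities = identities, mismatches = mismatches,
                   gap_columns = gap_columns,
                   identity_pct = 100 * identities / aln_len,
                   stringsAsFactors = FALSE)
  df$score <- score_hit(df)
  df
}

# integrase record + single fabricated hit at a chosen ddha
tyr_rec <- function(len = 393L, id = "p1") {
  attbscout:::new_integrase_record(id, strrep("M", len), "tyrosine")
}
ser_rec <- function(len = 500L, id = "p1", class = "none") {
  attbscout:::new_integrase_record(id, strrep("M", len), "serine",
                                   serine_class = class)
}
tyr_hit <- function(id = "p1", ddha = 5L, len = 393L, hmm = "Int_P2",
                    score = 200) {
  attbscout:::make_domhit(id, hmm, 300L, len, ddha, score)
}

# minimal ReferenceDB around explicit attB/GI tables (for classify tests)
mini_db <- function(attbs, gis) {
  structure(list(attbs = attbs, gis = gis, integrases = character(0),
                 verdicts = attbscout:::empty_verdicts(),
                 taxonomy = data.frame(genome_accession = character(0),
                                       species = character(0),
                                       genus = character(0)),
                 provenance = list(schema_version = 1L)),
            class = "ReferenceDB")
}

mini_attb <- function(attb_id = "a1", sequence, idblock_start,
                      idblock_end, family = "tyrosine",
                      gi_refs = "G|g1", integrase_refs = "i1") {
  df <- data.frame(attb_id = attb_id, sequence = sequence,
                   idblock_start = idblock_start,
                   idblock_end = idblock_end, family = family,
                   stringsAsFactors = FALSE)
  df$gi_refs <- I(list(gi_refs))
  df$integrase_refs <- I(list(integrase_refs))
  df
}

mini_gi <- function(gi_id = "G|g1", length = 40000L, support = 5,
                    attb_seq = strrep("A", 40L), idblock_start = 11L,
                    idblock_end = 30L, integrase_ids = "i1") {
  df <- data.frame(gi_id = gi_id, contig_accession = "G_ctg1",
                   start = 1000L, end = 1000L + length - 1L,
                   length = length, support_score = support,
                   attb_seq = attb_seq, idblock_start = idblock_start,
                   idblock_end = idblock_end, target_class = "tRNA",
                   stringsAsFactors = FALSE)
  df$integrase_ids <- I(list(integrase_ids))
  df
}

# a GI row set around generated attBs, for registry tests
simple_gi_table <- function(seqs, support = NULL, ints = NULL) {
  n <- length(seqs)
  if (is.null(support)) support <- rep(5, n)
  if (is.null(ints)) ints <- sprintf("i%02d", seq_len(n))
  df <- data.frame(
    gi_id = sprintf("GCA_T%03d|gene%02d", seq_len(n), seq_len(n)),
    contig_accession = "ctg", start = 1L, end = 10000L, length = 10000L,
    support_score = support, attb_seq = seqs,
    idblock_start = 11L,
    idblock_end = pmin(nchar(seqs), 30L),
    target_class = "tRNA", stringsAsFactors = FALSE)
  df$integrase_ids <- I(as.list(ints))
  df
}
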