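# Query-set construction and edit-bounded matching against the target
# genome.  The matcher is an internal seed-and-extend scan (exact
# pigeonhole seeds, banded verification in C++); a brute-force per-offset
# scanner with independent evaluation code is exported as the reference
# oracle.

#' Build the query set from attB records
#'
#' Each attB yields three queries: the full site, the left half site
#' (left flank + identity block) and the right half site (identity block +
#' right flank).  The flank length is `sl` for serine-family attBs and
#' `yl` for tyrosine-family attBs, truncated to the available sequence.
#'
#' @param attbs attB data.frame (from a `ReferenceDB` or
#'   [dedupe_attbs()]); needs `attb_id`, `sequence`, `idblock_start`,
#'   `idblock_end`, `family`.
#' @param sl serine flank length in nt (default 16).
#' @param yl tyrosine flank length in nt (default 10).
#' @param min_query_len queries shorter than this are dropped with a
#'   warning (default 22, the database attB floor).
#' @return data.frame of queries: `query_id`, `attb_ref`, `part`
#'   (full/L/R), `sequence`, `flank_len`.
#' @export
build_query_set <- function(attbs, sl = 16L, yl = 10L, min_query_len = 22L) {
  out_cols <- list(query_id = "character", attb_ref = "character",
                   part = "character", sequence = "character",
                   flank_len = "integer")
  if (nrow(attbs) == 0L) return(empty_df(out_cols))
  bad <- attbs$idblock_start < 1L | attbs$idblock_end < attbs$idblock_start |
    attbs$idblock_end > nchar(attbs$sequence)
  if (any(bad))
    stop("ID block outside attB sequence for: ",
         paste(attbs$attb_id[bad], collapse = ", "))
  rows <- lapply(seq_len(nrow(attbs)), function(i) {
    a <- attbs[i, ]
    fl <- if (identical(a$family, "serine")) sl else yl
    len <- nchar(a$sequence)
    l_from <- max(1L, a$idblock_start - fl)
    r_to <- min(len, a$idblock_end + fl)
    data.frame(
      query_id = paste0(a$attb_id, c("_full", "_L", "_R")),
      attb_ref = a$attb_id,
      part = c("full", "L", "R"),
      sequence = c(a$sequence,
                   substr(a$sequence, l_from, a$idblock_end),
                   substr(a$sequence, a$idblock_start, r_to)),
      flank_len = c(len - (a$idblock_end - a$idblock_start + 1L),
                    a$idblock_start - l_from, r_to - a$idblock_end),
      stringsAsFactors = FALSE)
  })
  q <- do.call(rbind, rows)
  short <- nchar(q$sequence) < min_query_len
  if (any(short)) {
    warning(sum(short), " query(ies) shorter than ", min_query_len,
            " nt dropped", call. = FALSE)
    q <- q[!short, , drop = FALSE]
  }
  rownames(q) <- NULL
  q
}

# convert a raw per-offset scan data.frame to MatchHit columns
raw_to_hits <- function(raw, query_id, attb_ref, part, qlen) {
  if (nrow(raw) == 0L) {
    return(empty_df(list(query_id = "character", attb_ref = "character",
                         part = "character", contig = "character",
                         start = "integer", end = "integer",
                         strand = "character", aln_len = "integer",
                         identities = "integer", mismatches = "integer",
                         gap_columns = "integer", identity_pct = "numeric",
                         score = "numeric")))
  }
  aln_len <- ifelse(raw$span >= qlen, raw$span, qlen)  # L or L+1 columns
  aligned <- aln_len - raw$gap_columns
  identities <- aligned - raw$mismatches
  df <- data.frame(
    query_id = query_id, attb_ref = attb_ref, part = part,
    contig = raw$contig, start = raw$start, end = raw$end,
    strand = raw$strand, aln_len = as.integer(aln_len),
    identities = as.integer(identities), mismatches = raw$mismatches,
    gap_columns = raw$gap_columns,
    identity_pct = 100 * identities / aln_len,
    stringsAsFactors = FALSE)
  df$score <- score_hit(df)
  df
}

# merge overlapping raw alignments of one query/strand into one reported
# hit per locus: best by (gap columns, mismatches, leftmost start)
reduce_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)),
                              paste(hits$query_id, hits$strand, sep = "\r")),
                        function(idx) {
    sub <- hits[idx, , drop = FALSE]
    grp <- overlap_groups(sub)
    vapply(split(seq_along(idx), grp), function(j) {
      s <- sub[j, , drop = FALSE]
      idx[j][order(s$gap_columns, s$mismatches, s$start)[1]]
    }, integer(1))
  }))
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_queries <- function(queries, genome, max_mismatch, max_gapcols,
                         scanner) {
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    raw <- scanner(toupper(q$sequence), genome,
                   as.integer(max_mismatch), as.integer(max_gapcols))
    raw_to_hits(raw, q$query_id, q$attb_ref, q$part, nchar(q$sequence))
  })
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$contig, hits$start, hits$query_id, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Locate edit-bounded occurrences of queries in a genome
#'
#' Finds every full-query-span alignment on either strand with at most
#' `max_mismatch` substitutions and `max_gapcols` gap columns (end gaps
#' count as gap columns), then merges overlapping per-offset alignments of
#' the same query and strand into one hit per locus.  Coordinates are
#' 1-based inclusive on the forward strand.
#'
#' @param queries data.frame from [build_query_set()] (columns `query_id`,
#'   `attb_ref`, `part`, `sequence`); a character vector is also accepted.
#' @param genome named character vector of contigs, or FASTA path.
#' @param max_mismatch maximum substitutions per hit (default 2).
#' @param max_gapcols maximum gap columns per hit (default 1).
#' @param threads accepted for interface compatibility; the scan is serial
#'   and its output is order-normalised, so results never depend on it.
#' @return MatchHit data.frame: `query_id`, `attb_ref`, `part`, `contig`,
#'   `start`, `end`, `strand`, `aln_len`, `identities`, `mismatches`,
#'   `gap_columns`, `identity_pct`, `score`.
#' @export
find_hits <- function(queries, genome, max_mismatch = 2L, max_gapcols = 1L,
                      threads = 1L) {
  genome <- normalize_genome(genome)
  queries <- normalize_queries(queries)
  if (nrow(queries) == 0L)
    return(raw_to_hits(empty_raw(), character(0), character(0),
                       character(0), 0L))
  hits <- scan_queries(queries, genome, max_mismatch, max_gapcols,
                       cpp_scan_hits)
  reduce_hits(hits)
}

#' Brute-force reference scan (oracle for [find_hits()])
#'
#' Evaluates every genome offset with independent per-gap-placement
#' mismatch counting; same raw-alignment contract as the seeded scan.
#' Returns raw per-offset alignments (no locus merging) unless
#' `reduce = TRUE`.
#'
#' @inheritParams find_hits
#' @param reduce merge overlapping per-offset alignments as [find_hits()]
#'   does (default `FALSE`: raw set, for exact-equivalence checks).
#' @return MatchHit data.frame (raw, one row per admissible offset).
#' @export
find_hits_brute <- function(queries, genome, max_mismatch = 2L,
                            max_gapcols = 1L, reduce = FALSE) {
  genome <- normalize_genome(genome)
  queries <- normalize_queries(queries)
  if (nrow(queries) == 0L)
    return(raw_to_hits(empty_raw(), character(0), character(0),
                       character(0), 0L))
  hits <- scan_queries(queries, genome, max_mismatch, max_gapcols,
                       cpp_scan_hits_brute)
  if (reduce) hits <- reduce_hits(hits)
  hits
}

# raw (unmerged) alignments from the seeded route, for oracle comparison
find_hits_raw <- function(queries, genome, max_mismatch = 2L,
                          max_gapcols = 1L) {
  genome <- normalize_genome(genome)
  queries <- normalize_queries(queries)
  scan_queries(queries, genome, max_mismatch, max_gapcols, cpp_scan_hits)
}

empty_raw <- function() {
  empty_df(list(contig = "character", start = "integer", end = "integer",
                strand = "character", gap_columns = "integer",
                mismatches = "integer", span = "integer"))
}

normalize_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))
      && file.exists(genome))
    genome <- read_genome(genome)
  if (length(genome) == 0L) stop("empty genome")
  if (is.null(names(genome))) names(genome) <- paste0("contig_",
                                                      seq_along(genome))
  toupper(genome)
}

normalize_queries <- function(queries) {
  if (is.character(queries)) {
    ids <- names(queries)
    if (is.null(ids)) ids <- paste0("query_", seq_along(queries))
    queries <- data.frame(query_id = ids, attb_ref = ids,
                          part = "full", sequence = unname(queries),
                          flank_len = 0L, stringsAsFactors = FALSE)
  }
  queries
}

#' Support score of a hit
#'
#' A fixed short-query score with BLASTN-like rewards and penalties:
#' `2 * identities - 3 * mismatches - 5 * gap_columns`.
#'
#' @param hit MatchHit data.frame (vectorised) or one-row list.
#' @return numeric score(s).
#' @export
score_hit <- function(hit) {
  2 * hit$identities - 3 * hit$mismatches - 5 * hit$gap_columns
}
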