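# Hit classification: rejection rules, island-occupancy inference
# (including cross-contig geometry), refining filters, overlap binning and
# ranking.

#' Normalized difference between expected and observed island spans
#'
#' `(expected - actual) / (expected + actual)`; an occupied call requires
#' the absolute value to be below the acceptance threshold (default 0.05),
#' equivalent to `actual/expected` within (19/21, 21/19).
#'
#' @param expected reference island length in nt.
#' @param actual observed separation in nt.
#' @return numeric normalized difference (vectorised).
#' @export
normalized_difference <- function(expected, actual) {
  (expected - actual) / (expected + actual)
}

#' Apply hit rejection rules and split off the occupancy pool
#'
#' Individual hits are rejected for identity below `min_identity_pct`,
#' more than `max_gapcols` gap columns, or more than `max_mismatch`
#' substitutions.  Surviving hits are then grouped per attB and their loci
#' merged by coordinate overlap: an attB whose hits form two or more
#' distinct loci (or a single locus with no full-site hit) becomes a
#' possible island-occupied site and is routed to the occupancy pool; an
#' attB with one coherent locus containing a full-site hit is kept.
#'
#' @param hits MatchHit data.frame from [find_hits()].
#' @param min_identity_pct identity threshold (default 95).
#' @param max_mismatch,max_gapcols per-hit caps (defaults 2 and 1).
#' @return list of MatchHit data.frames: `kept`, `occupancy_pool`,
#'   `rejected`.
#' @export
filter_hits <- function(hits, min_identity_pct = 95, max_mismatch = 2L,
                        max_gapcols = 1L) {
  if (nrow(hits) == 0L)
    return(list(kept = hits, occupancy_pool = hits, rejected = hits))
  bad <- hits$identity_pct < min_identity_pct |
    hits$gap_columns > max_gapcols | hits$mismatches > max_mismatch
  rejected <- hits[bad, , drop = FALSE]
  surv <- hits[!bad, , drop = FALSE]
  to_pool <- logical(nrow(surv))
  for (ab in unique(surv$attb_ref)) {
    idx <- which(surv$attb_ref == ab)
    sub <- surv[idx, , drop = FALSE]
    grp <- overlap_groups(sub)
    n_loci <- length(unique(grp))
    has_full <- "full" %in% sub$part
    if (n_loci >= 2L || !has_full) to_pool[idx] <- TRUE
  }
  kept <- surv[!to_pool, , drop = FALSE]
  pool <- surv[to_pool, , drop = FALSE]
  rownames(kept) <- rownames(pool) <- rownames(rejected) <- NULL
  log_stage("filter_hits", nrow(hits), nrow(kept))
  list(kept = kept, occupancy_pool = pool, rejected = rejected)
}

# per-hit distance to the island-ward terminus of its contig, for
# cross-contig occupancy geometry (hit direction chooses the terminus)
terminus_distance <- function(hit, contig_len, side) {
  if (side == "L") {
    if (hit$strand == "+") contig_len - hit$start + 1L else hit$end
  } else {
    if (hit$strand == "+") hit$end else contig_len - hit$start + 1L
  }
}

#' Infer island-occupied sites from pooled half-site hits
#'
#' For each attB in the occupancy pool, every admissible pairing of a
#' left-half and right-half hit yields an observed separation: on one
#' contig and strand, the outer span from the left hit's start to the
#' right hit's end (order reversed on the minus strand); across contigs,
#' the sum of the two distances to the island-ward contig termini chosen
#' by hit orientation.  Each reference island length for the attB is then
#' tested with the normalized difference; evidence is emitted when
#' `|nd| < nd_threshold`.
#'
#' @param pool MatchHit data.frame (`occupancy_pool` from
#'   [filter_hits()]).
#' @param db a `ReferenceDB` (source of reference island lengths and
#'   support scores).
#' @param contig_lengths named integer vector of target contig lengths.
#' @param nd_threshold acceptance threshold on `|nd|` (default 0.05).
#' @param span which same-contig separation to use: `"outer"` (default,
#'   left start to right end) or `"inner"` (between the facing hit ends).
#' @return list with `evidence` (all emitted rows) and `occupied` (best
#'   evidence per attB: minimum `|nd|`, ties to higher island support).
#' @export
infer_occupancy <- function(pool, db, contig_lengths, nd_threshold = 0.05,
                            span = c("outer", "inner")) {
  span <- match.arg(span)
  ev_cols <- list(attb_ref = "character", contig = "character",
                  start = "integer", end = "integer",
                  contig2 = "character", start2 = "integer",
                  end2 = "integer", gi_ref = "character",
                  expected = "numeric", actual = "numeric",
                  normalized_difference = "numeric",
                  cross_contig = "logical")
  evidence <- empty_df(ev_cols)
  gis <- db$gis
  gi_support <- setNames(gis$support_score, gis$gi_id)
  for (ab in unique(pool$attb_ref)) {
    sub <- pool[pool$attb_ref == ab, , drop = FALSE]
    arow <- db$attbs[db$attbs$attb_id == ab, , drop = FALSE]
    if (nrow(arow) == 0L) next
    gi_refs <- arow$gi_refs[[1]]
    gi_len <- gis$length[match(gi_refs, gis$gi_id)]
    known <- !is.na(gi_len)
    if (!any(known)) {
      warning("attB ", ab, " has no reference island length; skipped",
              call. = FALSE)
      next
    }
    gi_refs <- gi_refs[known]; gi_len <- gi_len[known]
    lh <- sub[sub$part == "L", , drop = FALSE]
    rh <- sub[sub$part == "R", , drop = FALSE]
    if (nrow(lh) == 0L || nrow(rh) == 0L) next
    for (i in seq_len(nrow(lh))) for (j in seq_len(nrow(rh))) {
      L <- lh[i, ]; R <- rh[j, ]
      if (L$contig == R$contig) {
        if (L$strand != R$strand) next
        if (L$strand == "+") {
          if (L$start > R$start) next
          actual <- if (span == "outer") R$end - L$start + 1L
                    else max(0L, R$start - L$end - 1L)
          loc <- c(L$start, R$end)
        } else {
          if (R$start > L$start) next
          actual <- if (span == "outer") L$end - R$start + 1L
                    else max(0L, L$start - R$end - 1L)
          loc <- c(R$start, L$end)
        }
        seg2 <- list(contig = NA_character_, start = NA_integer_,
                     end = NA_integer_)
        cross <- FALSE
      } else {
        dl <- terminus_distance(L, contig_lengths[[L$contig]], "L")
        dr <- terminus_distance(R, contig_lengths[[R$contig]], "R")
        actual <- dl + dr
        loc <- if (L$strand == "+")
          c(L$start, contig_lengths[[L$contig]]) else c(1L, L$end)
        seg2 <- if (R$strand == "+")
          list(contig = R$contig, start = 1L, end = R$end)
        else
          list(contig = R$contig, start = R$start,
               end = contig_lengths[[R$contig]])
        cross <- TRUE
      }
      nd <- normalized_difference(gi_len, actual)
      hit_ok <- abs(nd) < nd_threshold
      if (any(hit_ok)) {
        evidence <- rbind(evidence, data.frame(
          attb_ref = ab, contig = L$contig,
          start = as.integer(loc[1]), end = as.integer(loc[2]),
          contig2 = seg2$contig, start2 = seg2$start, end2 = seg2$end,
          gi_ref = gi_refs[hit_ok], expected = gi_len[hit_ok],
          actual = actual,
          normalized_difference = nd[hit_ok],
          cross_contig = cross, stringsAsFactors = FALSE))
      }
    }
  }
  occupied <- empty_df(ev_cols)
  if (nrow(evidence) > 0L) {
    best_rows <- vapply(split(seq_len(nrow(evidence)), evidence$attb_ref),
                        function(idx) {
      e <- evidence[idx, , drop = FALSE]
      sup <- unname(gi_support[e$gi_ref])
      idx[order(abs(e$normalized_difference), -sup, e$gi_ref)[1]]
    }, integer(1))
    occupied <- evidence[sort(unname(best_rows)), , drop = FALSE]
    rownames(occupied) <- NULL
  }
  log_stage("infer_occupancy", length(unique(pool$attb_ref)),
            nrow(occupied))
  list(evidence = evidence, occupied = occupied)
}

# SiteCall construction for kept attBs: one call per attB at its single
# coherent locus, anchored on the best full-site hit.
candidate_calls <- function(kept, db) {
  cols <- list(attb_ref = "character", contig = "character",
               start = "integer", end = "integer", strand = "character",
               status = "character", reason = "character",
               best_hit_score = "numeric", ref_gi = "character",
               ref_gi_support = "numeric")
  if (nrow(kept) == 0L) return(empty_df(cols))
  gis <- db$gis
  rows <- lapply(split(seq_len(nrow(kept)), kept$attb_ref), function(idx) {
    sub <- kept[idx, , drop = FALSE]
    full <- sub[sub$part == "full", , drop = FALSE]
    best <- full[order(-full$score, full$start)[1], ]
    arow <- db$attbs[db$attbs$attb_id == best$attb_ref, , drop = FALSE]
    refs <- arow$gi_refs[[1]]
    sup <- gis$support_score[match(refs, gis$gi_id)]
    pick <- order(-sup, refs)[1]
    data.frame(attb_ref = best$attb_ref, contig = best$contig,
               start = best$start, end = best$end, strand = best$strand,
               status = "candidate", reason = "ok",
               best_hit_score = best$score, ref_gi = refs[pick],
               ref_gi_support = sup[pick], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$attb_ref), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# count distinct genomic loci carrying an exact copy of the ID block, on
# either strand; overlapping matches merge into one locus
count_idblock_loci <- function(idblock, genome) {
  pats <- unique(c(idblock, revcomp(idblock)))
  locs <- list()
  for (cname in names(genome)) {
    subj <- Biostrings::DNAString(genome[[cname]])
    for (p in pats) {
      m <- Biostrings::matchPattern(p, subj)
      if (length(m))
        locs[[length(locs) + 1L]] <- data.frame(
          contig = cname, start = Biostrings::start(m),
          end = Biostrings::end(m), stringsAsFactors = FALSE)
    }
  }
  if (length(locs) == 0L) return(0L)
  all <- unique(do.call(rbind, locs))
  length(unique(overlap_groups(all)))
}

#' Refining filter for candidate attB sites
#'
#' A candidate becomes questionable when its interval overlaps an occupied
#' site (`in_occupied`), when its ID-block sequence occurs at more than
#' one genomic locus on either strand (`multi_idblock`), or when the
#' ID block contains a single-nucleotide run of at least
#' `homopolymer_min` (`homopolymer_idblock`).  Checks apply in that order;
#' the first failing reason is recorded.
#'
#' @param candidates SiteCall data.frame from candidate construction.
#' @param occupied occupied-evidence data.frame (from
#'   [infer_occupancy()]), whose one or two interval segments are tested
#'   for overlap.
#' @param genome named character vector of target contigs.
#' @param attbs attB data.frame (source of ID-block sequences).
#' @param homopolymer_min minimum run length flagged (default 10).
#' @return list of SiteCall data.frames: `final_pool`, `questionable`.
#' @export
refine_candidates <- function(candidates, occupied, genome, attbs,
                              homopolymer_min = 10L) {
  if (nrow(candidates) == 0L)
    return(list(final_pool = candidates, questionable = candidates))
  occ_iv <- occupied[c("contig", "start", "end")]
  if (nrow(occupied) > 0L && any(occupied$cross_contig)) {
    seg2 <- occupied[occupied$cross_contig,
                     c("contig2", "start2", "end2")]
    names(seg2) <- c("contig", "start", "end")
    occ_iv <- rbind(occ_iv, seg2[!is.na(seg2$contig), , drop = FALSE])
  }
  reason <- rep("ok", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    same <- occ_iv[occ_iv$contig == cand$contig, , drop = FALSE]
    if (overlaps_any(cand$start, cand$end, same$start, same$end)) {
      reason[i] <- "in_occupied"; next
    }
    arow <- attbs[attbs$attb_id == cand$attb_ref, , drop = FALSE]
    idblock <- substr(arow$sequence, arow$idblock_start, arow$idblock_end)
    if (count_idblock_loci(idblock, genome) > 1L) {
      reason[i] <- "multi_idblock"; next
    }
    if (max_homopolymer_run(idblock) >= homopolymer_min)
      reason[i] <- "homopolymer_idblock"
  }
  questionable <- candidates[reason != "ok", , drop = FALSE]
  if (nrow(questionable) > 0L) {
    questionable$status <- "questionable"
    questionable$reason <- reason[reason != "ok"]
  }
  final_pool <- candidates[reason == "ok", , drop = FALSE]
  rownames(final_pool) <- rownames(questionable) <- NULL
  log_stage("refine", nrow(candidates), nrow(final_pool))
  list(final_pool = final_pool, questionable = questionable)
}

#' Bin overlapping candidates and rank the winners
#'
#' Candidates are grouped by single-linkage coordinate overlap on each
#' contig.  Within a bin the winner has the highest hit support score;
#' ties go to the higher reference-island support, then to the leftmost
#' start, then to the lexicographically smallest attB id.  Losers become
#' duplicates (`overlap_loser`).  Winners are ranked 1..N in decreasing
#' order of reference-island support.
#'
#' @param final_pool SiteCall data.frame from [refine_candidates()].
#' @return list with `ranked_candidates` (with `rank` column) and
#'   `duplicates`.
#' @export
bin_and_select <- function(final_pool) {
  if (nrow(final_pool) == 0L) {
    ranked <- final_pool; ranked$rank <- integer(0)
    return(list(ranked_candidates = ranked, duplicates = final_pool))
  }
  grp <- overlap_groups(final_pool)
  win <- vapply(split(seq_len(nrow(final_pool)), grp), function(idx) {
    s <- final_pool[idx, , drop = FALSE]
    idx[order(-s$best_hit_score, -s$ref_gi_support, s$start, s$attb_ref)[1]]
  }, integer(1))
  winners <- final_pool[sort(unname(win)), , drop = FALSE]
  losers <- final_pool[setdiff(seq_len(nrow(final_pool)), win), ,
                       drop = FALSE]
  if (nrow(losers) > 0L) {
    losers$status <- "duplicate"
    losers$reason <- "overlap_loser"
  }
  winners <- winners[order(-winners$ref_gi_support, winners$attb_ref), ,
                     drop = FALSE]
  winners$rank <- seq_len(nrow(winners))
  rownames(winners) <- rownames(losers) <- NULL
  log_stage("bin_and_select", nrow(final_pool), nrow(winners))
  list(ranked_candidates = winners, duplicates = losers)
}

#' Full classification of a hit set
#'
#' Chains [filter_hits()], [infer_occupancy()], candidate construction,
#' [refine_candidates()] and [bin_and_select()].  Pool attBs with no
#' confirmable occupancy evidence become questionable (`multi_hit`).
#'
#' @param hits MatchHit data.frame.
#' @param db a `ReferenceDB`.
#' @param genome named character vector of target contigs.
#' @param nd_threshold occupancy acceptance threshold (default 0.05).
#' @param homopolymer_min refining-filter run length (default 10).
#' @param min_identity_pct,max_mismatch,max_gapcols hit rejection rules.
#' @return list with `ranked_candidates`, `duplicates`, `questionable`,
#'   `occupied`, `evidence`, `rejected`, `kept`, `pool`.
#' @export
classify_hits <- function(hits, db, genome, nd_threshold = 0.05,
                          homopolymer_min = 10L, min_identity_pct = 95,
                          max_mismatch = 2L, max_gapcols = 1L) {
  genome <- normalize_genome(genome)
  fh <- filter_hits(hits, min_identity_pct, max_mismatch, max_gapcols)
  occ <- infer_occupancy(fh$occupancy_pool, db,
                         setNames(nchar(genome), names(genome)),
                         nd_threshold)
  cands <- candidate_calls(fh$kept, db)
  rf <- refine_candidates(cands, occ$occupied, genome, db$attbs,
                          homopolymer_min)
  bs <- bin_and_select(rf$final_pool)
  # pool attBs without occupancy evidence: questionable, multi_hit
  unconfirmed <- setdiff(unique(fh$occupancy_pool$attb_ref),
                         occ$occupied$attb_ref)
  q_extra <- empty_df(list(attb_ref = "character", contig = "character",
                           start = "integer", end = "integer",
                           strand = "character", status = "character",
                           reason = "character",
                           best_hit_score = "numeric",
                           ref_gi = "character",
                           ref_gi_support = "numeric"))
  gis <- db$gis
  for (ab in sort(unconfirmed)) {
    sub <- fh$occupancy_pool[fh$occupancy_pool$attb_ref == ab, ,
                             drop = FALSE]
    lead <- sub[order(sub$contig, sub$start)[1], ]
    arow <- db$attbs[db$attbs$attb_id == ab, , drop = FALSE]
    refs <- arow$gi_refs[[1]]
    sup <- gis$support_score[match(refs, gis$gi_id)]
    pick <- order(-sup, refs)[1]
    q_extra <- rbind(q_extra, data.frame(
      attb_ref = ab, contig = lead$contig, start = lead$start,
      end = lead$end, strand = lead$strand, status = "questionable",
      reason = "multi_hit", best_hit_score = max(sub$score),
      ref_gi = refs[pick], ref_gi_support = sup[pick],
      stringsAsFactors = FALSE))
  }
  questionable <- rbind(rf$questionable, q_extra)
  rownames(questionable) <- NULL
  list(ranked_candidates = bs$ranked_candidates,
       duplicates = bs$duplicates, questionable = questionable,
       occupied = occ$occupied, evidence = occ$evidence,
       rejected = fh$rejected, kept = fh$kept, pool = fh$occupancy_pool)
}
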