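# Run configuration, the two run modes, report writing, and the k-mer
# discovery-rate model.

#' Run configuration
#'
#' @param mode `"taxonomic"` or `"search"`.
#' @param genome path to the target genome FASTA.
#' @param db path to the reference database JSON (or a `ReferenceDB`).
#' @param out output directory.
#' @param sketches path to a reference sketch cache (taxonomic mode).
#' @param n_min minimum attBs to collect in taxonomic mode (default 500).
#' @param sl,yl serine / tyrosine flank lengths (defaults 16, 10).
#' @param threads accepted for interface compatibility (results are
#'   thread-count invariant).
#' @param min_attb_len database attB length floor (default 22 nt).
#' @param homopolymer_min refining-filter run length (default 10).
#' @param nd_threshold occupancy acceptance threshold (default 0.05).
#' @param min_identity_pct,max_mismatch,max_gapcols hit rejection rules.
#' @param seed integer seed recorded in the run log.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(mode = c("taxonomic", "search"), genome, db, out,
                       sketches = NULL, n_min = 500L, sl = 16L, yl = 10L,
                       threads = 1L, min_attb_len = 22L,
                       homopolymer_min = 10L, nd_threshold = 0.05,
                       min_identity_pct = 95, max_mismatch = 2L,
                       max_gapcols = 1L, seed = 42L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, genome = genome, db = db, out = out,
              sketches = sketches, n_min = as.integer(n_min),
              sl = as.integer(sl), yl = as.integer(yl),
              threads = as.integer(threads),
              min_attb_len = as.integer(min_attb_len),
              homopolymer_min = as.integer(homopolymer_min),
              nd_threshold = as.numeric(nd_threshold),
              min_identity_pct = as.numeric(min_identity_pct),
              max_mismatch = as.integer(max_mismatch),
              max_gapcols = as.integer(max_gapcols),
              seed = as.integer(seed))
  for (f in c("n_min", "sl", "yl", "threads", "min_attb_len",
              "homopolymer_min", "nd_threshold", "min_identity_pct"))
    if (cfg[[f]] < 0) stop("negative config value: ", f)
  if (cfg$nd_threshold <= 0 || cfg$homopolymer_min <= 0)
    stop("thresholds must be positive")
  structure(cfg, class = "RunConfig")
}

#' Write a run configuration to JSON
#' @param config a `RunConfig`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path JSON path.
#' @return a `RunConfig` (round-trips losslessly).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

load_db <- function(db) {
  if (inherits(db, "ReferenceDB")) return(db)
  if (!file.exists(db)) stop("reference database not found: ", db)
  read_reference_db(db)
}

#' Run the pipeline in taxonomic mode
#'
#' Sketch the target genome, rank the reference sketches, collect the
#' query attBs from the nearest species, match, classify and write the
#' four report files.
#'
#' @param config a `RunConfig` with `mode = "taxonomic"`.
#' @return invisibly, the full classification (see [classify_hits()])
#'   plus `queries` and `query_attbs`.
#' @export
run_taxonomic <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (!file.exists(config$genome))
    stop("genome FASTA not found: ", config$genome)
  if (is.character(config$db) && !file.exists(config$db))
    stop("reference database not found: ", config$db)
  if (is.null(config$sketches) || !file.exists(config$sketches))
    stop("sketch cache not found: ", config$sketches)
  db <- load_db(config$db)
  genome <- read_genome(config$genome)
  refs <- read_sketch_cache(config$sketches)
  target <- sketch_genome(genome, k = refs[[1]]$k, s = refs[[1]]$s,
                          genome_id = "target")
  ranked <- rank_neighbors(target, refs, db$taxonomy)
  query_attbs <- collect_attbs(ranked, db, n_min = config$n_min)
  run_pipeline(query_attbs, genome, db, config)
}

#' Run the pipeline in search mode
#'
#' Queries either a user-supplied attB list or the entire de-duplicated
#' database against the target genome (no sketching).
#'
#' @param config a `RunConfig` with `mode = "search"`.
#' @param query_attbs optional query set: an attB data.frame (columns as
#'   `db$attbs`), a character vector of attB ids selecting from the
#'   database, or a named character vector of raw sequences (the ID block
#'   is then taken to be the whole sequence).
#' @return invisibly, as [run_taxonomic()].
#' @export
run_search <- function(config, query_attbs = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (!file.exists(config$genome))
    stop("genome FASTA not found: ", config$genome)
  if (is.character(config$db) && !file.exists(config$db))
    stop("reference database not found: ", config$db)
  db <- load_db(config$db)
  genome <- read_genome(config$genome)
  qa <- if (is.null(query_attbs)) {
    db$attbs
  } else if (is.data.frame(query_attbs)) {
    query_attbs
  } else if (is.character(query_attbs) &&
             all(query_attbs %in% db$attbs$attb_id)) {
    db$attbs[match(query_attbs, db$attbs$attb_id), , drop = FALSE]
  } else if (is.character(query_attbs)) {
    ids <- names(query_attbs)
    if (is.null(ids)) ids <- paste0("user_attb_", seq_along(query_attbs))
    df <- data.frame(attb_id = ids, sequence = toupper(query_attbs),
                     idblock_start = 1L,
                     idblock_end = nchar(query_attbs),
                     family = "tyrosine", stringsAsFactors = FALSE)
    df$gi_refs <- I(rep(list(character(0)), nrow(df)))
    df$integrase_refs <- I(rep(list(character(0)), nrow(df)))
    df
  } else stop("unsupported query_attbs")
  run_pipeline(qa, genome, db, config)
}

run_pipeline <- function(query_attbs, genome, db, config) {
  queries <- build_query_set(query_attbs, sl = config$sl, yl = config$yl,
                             min_query_len = config$min_attb_len)
  log_stage("build_queries", nrow(query_attbs), nrow(queries))
  hits <- find_hits(queries, genome, max_mismatch = config$max_mismatch,
                    max_gapcols = config$max_gapcols,
                    threads = config$threads)
  log_stage("find_hits", nrow(queries), nrow(hits))
  cls <- classify_hits(hits, db, genome,
                       nd_threshold = config$nd_threshold,
                       homopolymer_min = config$homopolymer_min,
                       min_identity_pct = config$min_identity_pct,
                       max_mismatch = config$max_mismatch,
                       max_gapcols = config$max_gapcols)
  write_reports(cls$ranked_candidates, cls$duplicates, cls$questionable,
                cls$occupied, db, query_attbs, config$out)
  invisible(c(cls, list(queries = queries, query_attbs = query_attbs)))
}

site_report_rows <- function(calls, db, ranked = FALSE) {
  cols <- c("rank", "attb_id", "contig", "start", "end", "strand",
            "attb_seq", "idblock_seq", "family", "best_hit_score",
            "ref_gi_id", "ref_gi_support", "integrase_ids", "all_refs")
  if (nrow(calls) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE)
    return(out)
  }
  gis <- db$gis
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    s <- calls[i, ]
    a <- db$attbs[db$attbs$attb_id == s$attb_ref, , drop = FALSE]
    attb_seq <- if (nrow(a)) a$sequence else NA_character_
    idblock <- if (nrow(a))
      substr(a$sequence, a$idblock_start, a$idblock_end) else NA_character_
    ints <- if (nrow(a)) paste(a$integrase_refs[[1]], collapse = ",")
            else ""
    refs <- if (nrow(a)) a$gi_refs[[1]] else character(0)
    all_refs <- if (length(refs) > 1L) {
      paste(vapply(refs, function(g) {
        gints <- gis$integrase_ids[[match(g, gis$gi_id)]]
        paste0(g, "|", paste(gints, collapse = ","))
      }, character(1)), collapse = ";")
    } else ""
    data.frame(rank = if (ranked) s$rank else NA_integer_,
               attb_id = s$attb_ref, contig = s$contig, start = s$start,
               end = s$end, strand = s$strand, attb_seq = attb_seq,
               idblock_seq = idblock,
               family = if (nrow(a)) a$family else NA_character_,
               best_hit_score = s$best_hit_score, ref_gi_id = s$ref_gi,
               ref_gi_support = s$ref_gi_support, integrase_ids = ints,
               all_refs = all_refs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the four standard report files
#'
#' `final_candidates.tsv` (ranked candidates), `attb_dupes.tsv` (overlap
#' losers and questionable sites, with a `reason` column),
#' `occupied.tsv` (island-occupied loci with the best-fitting reference
#' island) and `isles.json` (every queried attB with its full reference
#' GI records).
#'
#' @param ranked,duplicates,questionable SiteCall data.frames.
#' @param occupied occupied-evidence data.frame from [infer_occupancy()].
#' @param db a `ReferenceDB`.
#' @param query_attbs the attB data.frame that entered matching.
#' @param outdir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_reports <- function(ranked, duplicates, questionable, occupied, db,
                          query_attbs, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  final_path <- file.path(outdir, "final_candidates.tsv")
  dupes_path <- file.path(outdir, "attb_dupes.tsv")
  occ_path <- file.path(outdir, "occupied.tsv")
  isles_path <- file.path(outdir, "isles.json")

  write_tsv(site_report_rows(ranked, db, ranked = TRUE), final_path)

  dupes <- rbind(duplicates, questionable)
  drows <- site_report_rows(dupes, db)
  drows$reason <- if (nrow(dupes)) dupes$reason else character(0)
  write_tsv(drows, dupes_path)

  occ <- occupied[c("contig", "start", "end", "attb_ref", "gi_ref",
                    "expected", "actual", "normalized_difference",
                    "cross_contig")]
  names(occ)[4] <- "attb_id"
  if (nrow(occ))
    occ <- occ[order(occ$contig, occ$start, occ$attb_id), , drop = FALSE]
  write_tsv(occ, occ_path)

  gis <- db$gis
  isles <- lapply(seq_len(nrow(query_attbs)), function(i) {
    refs <- query_attbs$gi_refs[[i]]
    lapply(refs, function(g) {
      gr <- gis[gis$gi_id == g, , drop = FALSE]
      if (nrow(gr) == 0L) return(NULL)
      list(gi_id = gr$gi_id, contig_accession = gr$contig_accession,
           start = gr$start, end = gr$end, length = gr$length,
           support_score = gr$support_score,
           target_class = gr$target_class,
           integrase_ids = gr$integrase_ids[[1]])
    })
  })
  names(isles) <- query_attbs$attb_id
  jsonlite::write_json(isles, isles_path, auto_unbox = TRUE, digits = NA)
  invisible(c(final_candidates = final_path, attb_dupes = dupes_path,
              occupied = occ_path, isles = isles_path))
}

#' Random k-mer discovery-rate model
#'
#' The probability of finding a random k-mer in a genome of length `L`
#' (both strands) is `p = 2 * L * 4^-k`; for `n` independent queries the
#' union-bound rate is `n * p`.  Either supply `genome_length` and
#' `kmer_length` or a precomputed `p`.
#'
#' @param genome_length genome length `L` in nt.
#' @param kmer_length k-mer length.
#' @param n_queries number of query k-mers (default 1).
#' @param p optional precomputed per-k-mer rate (overrides `L`, `k`).
#' @return list with `per_kmer_rate` and `any_of_n`, both also logged to
#'   3 significant figures.
#' @export
discovery_rate <- function(genome_length = NULL, kmer_length = NULL,
                           n_queries = 1L, p = NULL) {
  if (is.null(p)) {
    stopifnot(genome_length > 0, kmer_length > 0)
    p <- 2 * genome_length * 4^(-kmer_length)
  }
  stopifnot(n_queries > 0)
  any_n <- n_queries * p
  message(sprintf("[attbscout] discovery rate: p = %.3g, any-of-%d = %.3g",
                  signif(p, 3), n_queries, signif(any_n, 3)))
  list(per_kmer_rate = p, any_of_n = any_n)
}
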