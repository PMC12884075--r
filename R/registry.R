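# Reference-database construction: genomic-island (GI) table ingest,
# HMMER domtblout ingest, integrase integrity filtering (tyrosine and
# serine families), attB deduplication, and DB (de)serialization.

#' Default HMM panel for tyrosine-integrase integrity checks
#'
#' The tyrosine-recombinase HMM collection is an external resource; the
#' panel is therefore configuration, not code.  The default names cover the
#' common subfamilies plus the two excluded non-integrase subfamilies
#' (`Xer`, `Integron`).
#'
#' @return character vector of HMM names.
#' @export
default_tyrosine_panel <- function() {
  c("Int_P2", "Int_SXT", "Int_BPP1", "Int_Phage", "Int_Tn916", "Int_Des",
    "Int_CTnDOT", "Int_Brujita", "Int_Primase", "Int_Myoviridae",
    "Int_Siphoviridae", "Int_ICE", "Int_Okika", "Int_Pox", "Int_Rci",
    "Int_Telomere", "Int_TnpA", "Int_Cre", "Xer", "Integron")
}

serine_domain_resolvase   <- "Resolvase"
serine_domain_recombinase <- "Recombinase"
serine_is607_flag         <- "S-Core_IS607"

# ---- input readers -------------------------------------------------------

#' Read a GI (genomic island) table
#'
#' Tab-separated with header; columns `gi_id, contig_accession, start, end,
#' length, support_score, attb_seq, idblock_start, idblock_end,
#' target_class, integrase_ids` (comma-joined).  Coordinates are 1-based
#' inclusive.  `gi_id` is `<genome_accession>|<gene_id>`.
#'
#' @param path path to the TSV file.
#' @return data.frame with `integrase_ids` as a list-column.
#' @export
read_gi_table <- function(path) {
  if (!file.exists(path)) stop("GI table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  required <- c("gi_id", "contig_accession", "start", "end", "length",
                "support_score", "attb_seq", "idblock_start", "idblock_end",
                "target_class", "integrase_ids")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("GI table lacks columns: ", paste(missing, collapse = ", "))
  df <- df[required]
  for (col in c("start", "end", "length", "idblock_start", "idblock_end"))
    df[[col]] <- as.integer(df[[col]])
  df$support_score <- as.numeric(df$support_score)
  df$attb_seq <- toupper(df$attb_seq)
  df$integrase_ids <- I(strsplit(df$integrase_ids, ",", fixed = TRUE))
  validate_gi_table(df)
  df
}

validate_gi_table <- function(gis) {
  if (nrow(gis) == 0L) return(invisible(gis))
  bad <- !(gis$idblock_start >= 1L &
           gis$idblock_start <= gis$idblock_end &
           gis$idblock_end <= nchar(gis$attb_seq))
  if (any(bad))
    stop("invalid ID-block coordinates for GI(s): ",
         paste(gis$gi_id[bad], collapse = ", "))
  if (any(gis$length <= 0L))
    stop("non-positive GI length for: ",
         paste(gis$gi_id[gis$length <= 0L], collapse = ", "))
  n_int <- lengths(gis$integrase_ids)
  if (any(n_int == 0L))
    stop("GI without integrase: ",
         paste(gis$gi_id[n_int == 0L], collapse = ", "))
  invisible(gis)
}

#' Write a GI table (inverse of [read_gi_table()])
#' @param gis GI data.frame with `integrase_ids` list-column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gi_table <- function(gis, path) {
  out <- gis
  out$integrase_ids <- vapply(gis$integrase_ids, paste, character(1),
                              collapse = ",")
  write_tsv(out, path)
}

# genome accession from a gi_id of the form <genome>|<gene>
gi_genome_accession <- function(gi_id) sub("\\|.*$", "", gi_id)

#' Read HMMER3 per-domain hits (domtblout dialect)
#'
#' Whitespace-delimited with `#` comment lines.  Fields used: target name
#' (protein), query name (HMM), qlen (HMM length), full-sequence score, and
#' the hmm/ali from/to coordinates.
#'
#' @param path path to a domtblout file.
#' @return data.frame of domain hits.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("domtblout not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(empty_df(list(protein_id = "character", hmm_name = "character",
                         hmm_length = "integer", score = "numeric",
                         hmm_from = "integer", hmm_to = "integer",
                         ali_from = "integer", ali_to = "integer")))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  short <- lengths(fields) < 19L
  if (any(short)) stop("malformed domtblout line(s): ",
                       paste(which(short), collapse = ", "))
  g <- function(i, f = identity) f(vapply(fields, `[`, character(1), i))
  data.frame(
    protein_id = g(1),
    hmm_name   = g(4),
    hmm_length = g(6, as.integer),
    score      = g(8, as.numeric),
    hmm_from   = g(16, as.integer),
    hmm_to     = g(17, as.integer),
    ali_from   = g(18, as.integer),
    ali_to     = g(19, as.integer),
    stringsAsFactors = FALSE)
}

#' Read a taxonomy table (`genome_accession`, `species`, `genus`)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  required <- c("genome_accession", "species", "genus")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("taxonomy table lacks columns: ", paste(missing, collapse = ", "))
  df[required]
}

# ---- ddha ----------------------------------------------------------------

#' Truncation metric for an HMM domain hit
#'
#' `delta_h` counts HMM positions missing at the protein termini,
#' `delta_a` counts protein residues extending beyond the HMM hit at the
#' termini, and `ddha = delta_h - delta_a`.  Large positive values flag
#' truncated proteins.
#'
#' @param hit one domain hit: a list or one-row data.frame with
#'   `hmm_from`, `hmm_to`, `hmm_length`, `ali_from`, `ali_to`.
#' @param protein_length protein length in amino acids.
#' @return the hit with `delta_h`, `delta_a` and `ddha` set.
#' @examples
#' h <- list(hmm_from = 101, hmm_to = 300, hmm_length = 300,
#'           ali_from = 1, ali_to = 200)
#' compute_ddha(h, 200)$ddha  # 100
#' @export
compute_ddha <- function(hit, protein_length) {
  hit <- as.list(hit)
  ok <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (f in c("hmm_from", "hmm_to", "hmm_length", "ali_from", "ali_to"))
    if (!ok(hit[[f]])) stop("domain hit lacks valid field: ", f)
  if (hit$hmm_from > hit$hmm_to || hit$hmm_to > hit$hmm_length)
    stop("invalid HMM coordinates (from ", hit$hmm_from, ", to ",
         hit$hmm_to, ", length ", hit$hmm_length, ")")
  if (hit$ali_from > hit$ali_to)
    stop("invalid alignment coordinates (from ", hit$ali_from, " > to ",
         hit$ali_to, ")")
  if (hit$ali_to > protein_length)
    stop("alignment end ", hit$ali_to, " exceeds protein length ",
         protein_length)
  hit$delta_h <- as.integer((hit$hmm_from - 1) + (hit$hmm_length -
                                                  hit$hmm_to))
  hit$delta_a <- as.integer((hit$ali_from - 1) + (protein_length -
                                                  hit$ali_to))
  hit$ddha <- hit$delta_h - hit$delta_a
  hit
}

# vectorized over a domain-hit data.frame; protein_lengths named by id
add_ddha <- function(hits, protein_lengths) {
  if (nrow(hits) == 0L) {
    hits$delta_h <- integer(0); hits$delta_a <- integer(0)
    hits$ddha <- integer(0)
    return(hits)
  }
  plen <- unname(protein_lengths[hits$protein_id])
  if (anyNA(plen))
    stop("domain hits reference unknown protein(s): ",
         paste(unique(hits$protein_id[is.na(plen)]), collapse = ", "))
  if (any(hits$ali_to > plen))
    stop("domain hit alignment exceeds protein length for: ",
         paste(unique(hits$protein_id[hits$ali_to > plen]), collapse = ", "))
  hits$delta_h <- (hits$hmm_from - 1L) + (hits$hmm_length - hits$hmm_to)
  hits$delta_a <- (hits$ali_from - 1L) + as.integer(plen - hits$ali_to)
  hits$ddha <- hits$delta_h - hits$delta_a
  hits
}

# best-scoring hit row (ties: hmm_name, then ali_from, for determinism)
best_hit_row <- function(hits) {
  hits[order(-hits$score, hits$hmm_name, hits$ali_from), ][1, ]
}

# ---- family filters ------------------------------------------------------

new_integrase_record <- function(protein_id, sequence, family,
                                 serine_class = "none") {
  structure(list(protein_id = protein_id, sequence = sequence,
                 family = family, length_aa = nchar(sequence),
                 serine_class = serine_class, best_hit = NULL,
                 verdict = NA_character_, reject_reason = "none"),
            class = "integrase_record")
}

finish_verdict <- function(rec, reason) {
  rec$verdict <- if (identical(reason, "none")) "pass" else "reject"
  rec$reject_reason <- reason
  rec
}

#' Integrity filter for tyrosine-family integrases
#'
#' Rejects proteins with no hit to the tyrosine HMM panel (`no_hmm`), a
#' best hit to an excluded non-integrase subfamily (`xer_or_integron`),
#' length over `max_len` amino acids (`too_long`), or a best-hit truncation
#' metric `ddha` over `ddha_cutoff` (`truncated`).
#'
#' @param rec integrase record from `new_integrase_record()` with
#'   `family == "tyrosine"`.
#' @param hits data.frame of this protein's domain hits (ddha columns are
#'   computed here if absent).
#' @param panel character vector of panel HMM names.
#' @param excluded subfamily names whose best hit rejects the protein.
#' @param max_len maximum length in aa (default 800).
#' @param ddha_cutoff reject when best-hit ddha exceeds this (default 100).
#' @return the record with `verdict`, `reject_reason` and `best_hit` set.
#' @export
filter_tyrosine <- function(rec, hits, panel = default_tyrosine_panel(),
                            excluded = c("Xer", "Integron"),
                            max_len = 800L, ddha_cutoff = 100L) {
  stopifnot(identical(rec$family, "tyrosine"))
  if (!nzchar(rec$sequence)) stop("empty protein sequence: ", rec$protein_id)
  hits <- hits[hits$protein_id == rec$protein_id & hits$hmm_name %in% panel,
               , drop = FALSE]
  if (nrow(hits) == 0L) return(finish_verdict(rec, "no_hmm"))
  if (is.null(hits$ddha)) {
    hits <- add_ddha(hits, setNames(rec$length_aa, rec$protein_id))
  }
  best <- best_hit_row(hits)
  rec$best_hit <- as.list(best)
  if (best$hmm_name %in% excluded)
    return(finish_verdict(rec, "xer_or_integron"))
  if (rec$length_aa > max_len) return(finish_verdict(rec, "too_long"))
  if (best$ddha > ddha_cutoff) return(finish_verdict(rec, "truncated"))
  finish_verdict(rec, "none")
}

#' Integrity filter for serine-family integrases
#'
#' Passes a protein when either (i) a Resolvase domain hit precedes a
#' Recombinase domain hit along the protein, length is at most `max_len`
#' (default 800 aa) and best-hit `ddha <= 0`; or (ii) it carries the
#' S-Core_IS607 classification, length is at most `is607_max_len` (default
#' 300 aa) and best-hit `ddha <= 0`.  Otherwise the first failing rule sets
#' the reject reason.
#'
#' @param rec integrase record with `family == "serine"`; the IS607
#'   classification is taken from `rec$serine_class` or from a domtblout
#'   row with HMM name `S-Core_IS607`.
#' @param hits data.frame of this protein's domain hits.
#' @param max_len,is607_max_len length caps for the two branches.
#' @return the record with verdict fields set.
#' @export
filter_serine <- function(rec, hits, max_len = 800L, is607_max_len = 300L) {
  stopifnot(identical(rec$family, "serine"))
  if (!nzchar(rec$sequence)) stop("empty protein sequence: ", rec$protein_id)
  hits <- hits[hits$protein_id == rec$protein_id, , drop = FALSE]
  if (nrow(hits) > 0L && is.null(hits$ddha))
    hits <- add_ddha(hits, setNames(rec$length_aa, rec$protein_id))
  is607 <- identical(rec$serine_class, "s_core_is607") ||
    serine_is607_flag %in% hits$hmm_name
  if (is607) rec$serine_class <- "s_core_is607"
  dom_hits <- hits[hits$hmm_name != serine_is607_flag, , drop = FALSE]
  best_ddha <- 0L  # absent hits carry no truncation evidence
  if (nrow(hits) > 0L) {
    best <- best_hit_row(hits)
    rec$best_hit <- as.list(best)
    best_ddha <- best$ddha
  }
  if (is607) {
    if (rec$length_aa > is607_max_len) return(finish_verdict(rec, "too_long"))
    if (best_ddha > 0L) return(finish_verdict(rec, "truncated"))
    return(finish_verdict(rec, "none"))
  }
  if (nrow(dom_hits) == 0L) return(finish_verdict(rec, "no_hmm"))
  res <- dom_hits[dom_hits$hmm_name == serine_domain_resolvase, , drop = FALSE]
  rec_dom <- dom_hits[dom_hits$hmm_name == serine_domain_recombinase, ,
                      drop = FALSE]
  arch_ok <- nrow(res) > 0L && nrow(rec_dom) > 0L &&
    min(res$ali_from) < min(rec_dom$ali_from)
  if (!arch_ok) return(finish_verdict(rec, "bad_architecture"))
  if (rec$length_aa > max_len) return(finish_verdict(rec, "too_long"))
  if (best_ddha > 0L) return(finish_verdict(rec, "truncated"))
  finish_verdict(rec, "none")
}

# family inference from domain evidence (override via `families` argument
# of build_reference_db): serine when the protein shows serine-type
# domains or the IS607 classification, tyrosine otherwise.
infer_family <- function(protein_id, hits) {
  h <- hits[hits$protein_id == protein_id, , drop = FALSE]
  serine_names <- c(serine_domain_resolvase, serine_domain_recombinase,
                    serine_is607_flag)
  if (any(h$hmm_name %in% serine_names)) "serine" else "tyrosine"
}

# ---- attB deduplication --------------------------------------------------

#' Deduplicate attB sequences across GIs
#'
#' Collapses GIs sharing an identical (uppercase, given-strand) attB
#' sequence into one attB record; `gi_refs` and `integrase_refs` are the
#' unions over contributing GIs.  Sequences shorter than `min_len` are
#' dropped and counted.  When contributing GIs disagree on ID-block
#' coordinates, the highest-support GI wins, with a warning.
#'
#' @param gis GI data.frame (see [read_gi_table()]).
#' @param min_len minimum attB length in nt (default 22).
#' @return list with `attbs` (data.frame; `gi_refs`/`integrase_refs` are
#'   list-columns, `family` is `NA` until integrase families are known),
#'   `dropped` (data.frame of dropped GIs) and `n_dropped_seqs`.
#' @export
dedupe_attbs <- function(gis, min_len = 22L) {
  empty_attbs <- data.frame(attb_id = character(0), sequence = character(0),
                            idblock_start = integer(0),
                            idblock_end = integer(0),
                            family = character(0), stringsAsFactors = FALSE)
  empty_attbs$gi_refs <- I(list()); empty_attbs$integrase_refs <- I(list())
  if (nrow(gis) == 0L)
    return(list(attbs = empty_attbs, dropped = gis, n_dropped_seqs = 0L))
  seqs <- toupper(gis$attb_seq)
  short <- nchar(seqs) < min_len
  dropped <- gis[short, , drop = FALSE]
  n_dropped_seqs <- length(unique(seqs[short]))
  keep <- gis[!short, , drop = FALSE]
  keep_seqs <- seqs[!short]
  if (nrow(keep) == 0L)
    return(list(attbs = empty_attbs, dropped = dropped,
                n_dropped_seqs = n_dropped_seqs))
  useq <- sort(unique(keep_seqs))
  rows <- lapply(seq_along(useq), function(i) {
    s <- useq[i]
    grp <- keep[keep_seqs == s, , drop = FALSE]
    best <- grp[order(-grp$support_score, grp$gi_id), ][1, ]
    disagree <- length(unique(grp$idblock_start)) > 1L ||
      length(unique(grp$idblock_end)) > 1L
    if (disagree)
      warning("GIs sharing attB sequence disagree on ID-block ",
              "coordinates; keeping those of ", best$gi_id, call. = FALSE)
    list(attb_id = sprintf("attb_%05d", i), sequence = s,
         idblock_start = best$idblock_start,
         idblock_end = best$idblock_end,
         gi_refs = sort(grp$gi_id),
         integrase_refs = sort(unique(unlist(grp$integrase_ids))))
  })
  attbs <- data.frame(
    attb_id = vapply(rows, `[[`, character(1), "attb_id"),
    sequence = vapply(rows, `[[`, character(1), "sequence"),
    idblock_start = vapply(rows, `[[`, integer(1), "idblock_start"),
    idblock_end = vapply(rows, `[[`, integer(1), "idblock_end"),
    family = NA_character_, stringsAsFactors = FALSE)
  attbs$gi_refs <- I(lapply(rows, `[[`, "gi_refs"))
  attbs$integrase_refs <- I(lapply(rows, `[[`, "integrase_refs"))
  list(attbs = attbs, dropped = dropped, n_dropped_seqs = n_dropped_seqs)
}

# ---- database build ------------------------------------------------------

#' Build the searchable reference database
#'
#' Loads the GI table, integrase FASTA, HMMER domtblout and taxonomy
#' table; applies the family integrity filters; deduplicates attB
#' sequences; and excludes attBs whose every cognate integrase was
#' rejected.
#'
#' @param gi_table path or data.frame (see [read_gi_table()]).
#' @param integrase_fasta path or named character vector of protein
#'   sequences.
#' @param domtblout path or data.frame (see [read_domtblout()]).
#' @param taxonomy_table path or data.frame (see [read_taxonomy()]).
#' @param panel tyrosine HMM panel (see [default_tyrosine_panel()]).
#' @param families optional named character vector protein_id -> family
#'   ("tyrosine"/"serine") overriding domain-based family inference.
#' @param is607_ids optional protein ids pre-classified as S-Core_IS607.
#' @param min_attb_len minimum attB length in nt (default 22).
#' @return object of class `ReferenceDB`: list with `attbs` (queryable
#'   set), `gis`, `integrases` (passing records), `verdicts` (all
#'   pass/reject calls), `taxonomy`, `provenance`.
#' @export
build_reference_db <- function(gi_table, integrase_fasta, domtblout,
                               taxonomy_table,
                               panel = default_tyrosine_panel(),
                               families = NULL, is607_ids = character(0),
                               min_attb_len = 22L) {
  gis <- if (is.character(gi_table)) read_gi_table(gi_table) else gi_table
  prots <- if (is.character(integrase_fasta) &&
               length(integrase_fasta) == 1L && file.exists(integrase_fasta))
    read_protein_fasta(integrase_fasta) else integrase_fasta
  hits <- if (is.character(domtblout)) read_domtblout(domtblout) else domtblout
  taxonomy <- if (is.character(taxonomy_table)) read_taxonomy(taxonomy_table)
              else taxonomy_table
  validate_gi_table(gis)
  if (nrow(gis) == 0L) {
    warning("empty GI table: building an empty reference database",
            call. = FALSE)
    dd <- dedupe_attbs(gis, min_attb_len)
    return(new_reference_db(dd$attbs, gis, verdicts = empty_verdicts(),
                            prots = character(0), taxonomy = taxonomy,
                            params = list(min_attb_len = min_attb_len),
                            n_dropped_seqs = 0L))
  }
  needed <- sort(unique(unlist(gis$integrase_ids)))
  dangling <- setdiff(needed, names(prots))
  if (length(dangling))
    stop("GI table references integrase id(s) missing from the protein ",
         "FASTA: ", paste(dangling, collapse = ", "))
  hits <- add_ddha(hits, setNames(nchar(prots), names(prots)))

  verdicts <- lapply(needed, function(pid) {
    fam <- if (!is.null(families) && pid %in% names(families))
      unname(families[[pid]]) else infer_family(pid, hits)
    rec <- new_integrase_record(pid, prots[[pid]], fam,
                                serine_class = if (pid %in% is607_ids)
                                  "s_core_is607" else "none")
    if (fam == "tyrosine") filter_tyrosine(rec, hits, panel = panel)
    else filter_serine(rec, hits)
  })
  names(verdicts) <- needed
  vdf <- data.frame(
    protein_id = needed,
    family = vapply(verdicts, `[[`, character(1), "family"),
    length_aa = vapply(verdicts, `[[`, integer(1), "length_aa"),
    verdict = vapply(verdicts, `[[`, character(1), "verdict"),
    reject_reason = vapply(verdicts, `[[`, character(1), "reject_reason"),
    stringsAsFactors = FALSE, row.names = NULL)
  passing <- vdf$protein_id[vdf$verdict == "pass"]

  dd <- dedupe_attbs(gis, min_attb_len)
  attbs <- dd$attbs
  if (nrow(attbs) > 0L) {
    fam_of <- setNames(vdf$family, vdf$protein_id)
    attbs$family <- vapply(seq_len(nrow(attbs)), function(i) {
      ints <- intersect(attbs$integrase_refs[[i]], passing)
      if (length(ints) == 0L) ints <- attbs$integrase_refs[[i]]
      fams <- fam_of[ints]
      names(sort(table(fams), decreasing = TRUE))[1]
    }, character(1))
    queryable <- vapply(attbs$integrase_refs,
                        function(x) any(x %in% passing), logical(1))
    attbs <- attbs[queryable, , drop = FALSE]
    rownames(attbs) <- NULL
  }
  log_stage("build_db.attbs", nrow(dd$attbs), nrow(attbs))
  new_reference_db(attbs, gis, vdf, prots[passing], taxonomy,
                   params = list(min_attb_len = min_attb_len),
                   n_dropped_seqs = dd$n_dropped_seqs)
}

empty_verdicts <- function() {
  empty_df(list(protein_id = "character", family = "character",
                length_aa = "integer", verdict = "character",
                reject_reason = "character"))
}

new_reference_db <- function(attbs, gis, verdicts, prots, taxonomy, params,
                             n_dropped_seqs) {
  reasons <- table(verdicts$reject_reason[verdicts$verdict == "reject"])
  structure(list(
    attbs = attbs, gis = gis,
    integrases = prots, verdicts = verdicts,
    taxonomy = taxonomy,
    provenance = list(
      schema_version = 1L,
      n_attbs = nrow(attbs), n_gis = nrow(gis),
      n_integrases_pass = length(prots),
      n_integrases_total = nrow(verdicts),
      n_attb_seqs_dropped_short = n_dropped_seqs,
      reject_counts = as.list(reasons),
      params = params)),
    class = "ReferenceDB")
}

#' @export
print.ReferenceDB <- function(x, ...) {
  p <- x$provenance
  cat("ReferenceDB:", p$n_attbs, "attBs,", p$n_gis, "GIs,",
      p$n_integrases_pass, "/", p$n_integrases_total,
      "integrases passing\n")
  invisible(x)
}

#' Serialize a ReferenceDB to JSON plus a FASTA sidecar
#'
#' @param db a `ReferenceDB`.
#' @param path output path for the JSON document; the passing integrase
#'   proteins go to `<path>.faa`.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path) {
  gis <- db$gis
  gis$integrase_ids <- lapply(gis$integrase_ids, identity)
  doc <- list(
    schema_version = 1L,
    attbs = lapply(seq_len(nrow(db$attbs)), function(i) {
      a <- db$attbs[i, ]
      list(attb_id = a$attb_id, sequence = a$sequence,
           idblock_start = a$idblock_start, idblock_end = a$idblock_end,
           family = a$family, gi_refs = a$gi_refs[[1]],
           integrase_refs = a$integrase_refs[[1]])
    }),
    gis = gis,
    verdicts = db$verdicts,
    taxonomy = db$taxonomy,
    provenance = db$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (length(db$integrases))
    write_fasta(db$integrases, paste0(path, ".faa"), type = "AA")
  invisible(path)
}

#' Read a ReferenceDB serialized by [write_reference_db()]
#' @param path JSON path.
#' @return a `ReferenceDB`.
#' @export
read_reference_db <- function(path) {
  if (!file.exists(path)) stop("reference DB not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L)
    stop("unsupported reference DB schema_version")
  attbs <- if (length(doc$attbs)) {
    a <- doc$attbs
    df <- data.frame(attb_id = a$attb_id, sequence = a$sequence,
                     idblock_start = as.integer(a$idblock_start),
                     idblock_end = as.integer(a$idblock_end),
                     family = a$family, stringsAsFactors = FALSE)
    df$gi_refs <- I(lapply(a$gi_refs, as.character))
    df$integrase_refs <- I(lapply(a$integrase_refs, as.character))
    df
  } else dedupe_attbs(empty_gi_table())$attbs
  gis <- doc$gis
  if (is.null(gis) || length(gis) == 0L || nrow(as.data.frame(gis)) == 0L) {
    gis <- empty_gi_table()
  } else {
    gis <- as.data.frame(gis, stringsAsFactors = FALSE)
    gis$integrase_ids <- I(lapply(gis$integrase_ids, as.character))
    for (col in c("start", "end", "length", "idblock_start", "idblock_end"))
      gis[[col]] <- as.integer(gis[[col]])
    gis$support_score <- as.numeric(gis$support_score)
  }
  prots <- character(0)
  sidecar <- paste0(path, ".faa")
  if (file.exists(sidecar)) prots <- read_protein_fasta(sidecar)
  verdicts <- if (length(doc$verdicts)) as.data.frame(doc$verdicts)
              else empty_verdicts()
  structure(list(attbs = attbs, gis = gis, integrases = prots,
                 verdicts = verdicts,
                 taxonomy = as.data.frame(doc$taxonomy),
                 provenance = doc$provenance),
            class = "ReferenceDB")
}

empty_gi_table <- function() {
  df <- empty_df(list(gi_id = "character", contig_accession = "character",
                      start = "integer", end = "integer",
                      length = "integer", support_score = "numeric",
                      attb_seq = "character", idblock_start = "integer",
                      idblock_end = "integer", target_class = "character"))
  df$integrase_ids <- I(list())
  df
}
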