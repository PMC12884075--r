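# Genome sketching and taxonomic neighbour selection.
#
# Bottom-s MinHash over canonical k-mers; hash values are MurmurHash3
# x64-128 low words, carried as fixed-width 16-hex-digit strings so that
# 64-bit values stay exact in R (lexicographic order == numeric order).

#' MinHash sketch of a genome
#'
#' Hashes every canonical k-mer (lexicographic minimum of the k-mer and its
#' reverse complement; windows containing non-ACGT are skipped) and keeps
#' the `s` smallest distinct 64-bit values.
#'
#' @param seqs named character vector of contig sequences, or a FASTA path.
#' @param k k-mer length (default 21).
#' @param s sketch size (default 1000).
#' @param seed hash seed (default 42; fixed, not drawn from R's RNG).
#' @param genome_id identifier stored on the sketch.
#' @return object of class `Sketch`: list with `genome_id`, `k`, `s`,
#'   `hashes` (ascending hex strings) and `genome_length`.
#' @export
sketch_genome <- function(seqs, k = 21L, s = 1000L, seed = 42L,
                          genome_id = "genome") {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_genome(seqs)
  if (sum(nchar(seqs)) < k)
    stop("total sequence length ", sum(nchar(seqs)),
         " is shorter than k = ", k)
  res <- cpp_sketch_kmers(toupper(seqs), as.integer(k), as.integer(s),
                          as.integer(seed))
  structure(list(genome_id = genome_id, k = as.integer(k),
                 s = as.integer(s), hashes = res$hashes,
                 genome_length = sum(nchar(seqs)),
                 n_distinct_kmers = res$n_distinct_kmers),
            class = "Sketch")
}

#' @export
print.Sketch <- function(x, ...) {
  cat("Sketch", x$genome_id, ": k =", x$k, ", |hashes| =", length(x$hashes),
      "/", x$s, "\n")
  invisible(x)
}

#' MinHash distance between two sketches
#'
#' The Jaccard index `j` is estimated as the fraction of shared values
#' within the merged bottom-`s'` sketch, and converted to a distance
#' `d = -(1/k) * log(2j / (1 + j))`; `j = 0` is capped at `d = 1`.
#'
#' @param a,b `Sketch` objects with equal `k` and `s`.
#' @return list with `jaccard` and `distance`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "Sketch"), inherits(b, "Sketch"))
  if (a$k != b$k) stop("sketches have different k: ", a$k, " vs ", b$k)
  if (a$s != b$s) stop("sketches have different s: ", a$s, " vs ", b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  sprime <- min(a$s, length(merged))
  merged <- merged[seq_len(sprime)]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- if (sprime > 0L) shared / sprime else 0
  d <- if (j <= 0) 1.0 else min(1.0, -(1 / a$k) * log(2 * j / (1 + j)))
  list(jaccard = j, distance = d)
}

#' Rank reference sketches by distance to a target sketch
#'
#' @param target `Sketch` of the target genome.
#' @param refs list of reference `Sketch` objects.
#' @param taxonomy optional taxonomy data.frame (`genome_accession`,
#'   `species`, `genus`) used to annotate the ranking.
#' @return data.frame sorted ascending by distance (ties broken by
#'   `genome_id`) with columns `genome_id`, `jaccard`, `distance`,
#'   `species`, `genus`.
#' @export
rank_neighbors <- function(target, refs, taxonomy = NULL) {
  if (length(refs) == 0L) stop("no reference sketches supplied")
  rows <- lapply(refs, function(r) {
    m <- mash_distance(target, r)
    data.frame(genome_id = r$genome_id, jaccard = m$jaccard,
               distance = m$distance, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$distance, df$genome_id), , drop = FALSE]
  rownames(df) <- NULL
  df$species <- NA_character_
  df$genus <- NA_character_
  if (!is.null(taxonomy) && nrow(taxonomy) > 0L) {
    idx <- match(df$genome_id, taxonomy$genome_accession)
    df$species <- taxonomy$species[idx]
    df$genus <- taxonomy$genus[idx]
  }
  df
}

#' Collect the taxonomic-mode query set of attBs
#'
#' attBs are accumulated species-by-species: first the species of the
#' ranked neighbours in rank order (each species' whole attB set added
#' atomically), then remaining database species belonging to
#' already-included genera, then remaining genera.  Accumulation stops at
#' the first point where at least `n_min` distinct attBs are collected (at
#' least one species block is always taken).
#'
#' @param ranked neighbour ranking from [rank_neighbors()] (must carry
#'   species/genus annotation).
#' @param db a `ReferenceDB`.
#' @param n_min minimum number of attBs to collect (default 500).
#' @return data.frame of attB records (subset of `db$attbs`).
#' @export
collect_attbs <- function(ranked, db, n_min = 500L) {
  attbs <- db$attbs
  if (nrow(attbs) == 0L) {
    warning("reference database has no queryable attBs", call. = FALSE)
    return(attbs)
  }
  tax <- db$taxonomy
  # species of each attB: species of the genomes of its contributing GIs
  gi_genome <- gi_genome_accession(db$gis$gi_id)
  genome_species <- setNames(tax$species, tax$genome_accession)
  genome_of_gi <- setNames(gi_genome, db$gis$gi_id)
  attb_species <- lapply(attbs$gi_refs, function(refs)
    sort(unique(unname(genome_species[genome_of_gi[refs]]))))
  species_genus <- setNames(tax$genus, tax$species)

  ranked_species <- unique(ranked$species[!is.na(ranked$species)])
  all_species <- sort(unique(unlist(attb_species)))
  all_species <- all_species[!is.na(all_species)]
  phase1 <- ranked_species[ranked_species %in% all_species]
  included_genera <- unique(unname(species_genus[phase1]))
  rest <- setdiff(all_species, phase1)
  phase2 <- sort(rest[species_genus[rest] %in% included_genera])
  phase3 <- sort(setdiff(rest, phase2))
  order_species <- c(phase1, phase2, phase3)

  chosen <- logical(nrow(attbs))
  taken <- 0L
  for (sp in order_species) {
    block <- vapply(attb_species, function(x) sp %in% x, logical(1))
    chosen <- chosen | block
    taken <- taken + 1L
    if (sum(chosen) >= n_min && taken >= 1L) break
  }
  out <- attbs[chosen, , drop = FALSE]
  rownames(out) <- NULL
  log_stage("collect_attbs", nrow(attbs), nrow(out))
  out
}

# ---- sketch cache --------------------------------------------------------

#' Write sketches to a JSON-lines cache (one sketch per line)
#' @param sketches list of `Sketch` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sketch_cache <- function(sketches, path) {
  lines <- vapply(sketches, function(sk)
    jsonlite::toJSON(list(genome_id = sk$genome_id, k = sk$k, s = sk$s,
                          genome_length = sk$genome_length,
                          hashes = sk$hashes),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sketch cache written by [write_sketch_cache()]
#' @param path JSON-lines path.
#' @return list of `Sketch` objects.
#' @export
read_sketch_cache <- function(path) {
  if (!file.exists(path)) stop("sketch cache not found: ", path)
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l) {
    x <- jsonlite::fromJSON(l)
    structure(list(genome_id = x$genome_id, k = as.integer(x$k),
                   s = as.integer(x$s), hashes = as.character(x$hashes),
                   genome_length = x$genome_length,
                   n_distinct_kmers = NA_real_),
              class = "Sketch")
  })
}
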