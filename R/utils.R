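# shared helpers: seeded RNG scoping, FASTA IO, intervals, small seq utils

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator functions do
#' not perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read a (possibly gzip-compressed, multi-contig) genome FASTA
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase contig sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  # FASTA descriptions may carry comments after the id
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector (DNA or protein).
#' @param path output path.
#' @param type "DNA" or "AA".
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
        else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Read a protein FASTA as a named character vector
#' @param path path to a FASTA file.
#' @return named character vector of uppercase protein sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("protein FASTA not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(x)

# Longest single-nucleotide run in a sequence.
max_homopolymer_run <- function(seq) {
  if (!nzchar(seq)) return(0L)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

# Single-linkage grouping of intervals by overlap, within contig.
# df needs columns contig, start, end; returns integer group ids.
overlap_groups <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  grp <- integer(n)
  ord <- order(df$contig, df$start, df$end)
  gid <- 0L
  cur_contig <- ""
  cur_end <- -Inf
  for (i in ord) {
    if (!identical(df$contig[i], cur_contig) || df$start[i] > cur_end) {
      gid <- gid + 1L
      cur_contig <- df$contig[i]
      cur_end <- df$end[i]
    } else {
      cur_end <- max(cur_end, df$end[i])
    }
    grp[i] <- gid
  }
  grp
}

# TRUE where interval [s1,e1] overlaps any interval in (s2,e2) vectors.
overlaps_any <- function(s1, e1, s2, e2) {
  if (length(s2) == 0L) return(FALSE)
  any(s1 <= e2 & e1 >= s2)
}

# deterministic TSV writer (no quoting surprises, fixed eol)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

# stage logging: fixed format so conservation audits are greppable
log_stage <- function(stage, n_in, n_out) {
  message(sprintf("[attbscout] %-18s in=%d out=%d", stage, n_in, n_out))
}

# empty data.frame with given character/numeric/integer/logical columns
empty_df <- function(col_types) {
  cols <- lapply(col_types, function(t) switch(t,
    character = character(0), numeric = numeric(0),
    integer = integer(0), logical = logical(0)))
  as.data.frame(cols, stringsAsFactors = FALSE)
}
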