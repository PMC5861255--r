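#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a data frame
#' of records. Sequence lines belonging to one header are concatenated and
#' all whitespace is stripped; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `id` (header token before the first
#'   whitespace), `description` (remainder of the header, possibly empty) and
#'   `sequence` (raw concatenated sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) stop("not FASTA: text before the first '>' header in ", path)
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(headers))),
                 function(x) gsub("\\s+", "", paste(x, collapse = "")), character(1L))
  if (any(!nzchar(id))) stop("FASTA record with empty identifier in ", path)
  if (any(!nzchar(seqs))) stop("FASTA record with empty sequence in ", path)
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records data frame with columns `id` and `sequence` (and optionally
#'   `description`), as returned by [read_fasta()].
#' @param path output file path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i]))
      hdr <- paste(hdr, records$description[i])
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Validate a protein sequence
#'
#' Uppercases the input, strips all whitespace, and checks that every
#' character is one of the 20 canonical amino acids. Returns the sequence
#' length on success and 0 otherwise (ambiguity codes such as B, Z, X, U, O,
#' gaps and the empty string all give 0); it never throws for ordinary
#' strings.
#'
#' @param raw a character string.
#' @return Integer: the validated length, or 0.
#' @export
#' @examples
#' validate_protein("MKV")  # 3
#' validate_protein("MKB1") # 0
validate_protein <- function(raw) {
  s <- clean_seq(raw)
  if (is.na(s) || !nzchar(s)) return(0L)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s)) return(0L)
  nchar(s)
}

#' Validate a DNA sequence
#'
#' Same contract as [validate_protein()] over the alphabet {A, C, G, T}.
#' RNA input ('U') is rejected, not transliterated.
#'
#' @param raw a character string.
#' @return Integer: the validated length, or 0.
#' @export
validate_dna <- function(raw) {
  s <- clean_seq(raw)
  if (is.na(s) || !nzchar(s)) return(0L)
  if (grepl("[^ACGT]", s)) return(0L)
  nchar(s)
}

clean_seq <- function(raw) {
  if (length(raw) != 1L || !is.character(raw)) return(NA_character_)
  toupper(gsub("\\s+", "", raw))
}

# validate-or-stop wrappers used by descriptor code
as_protein <- function(seq) {
  n <- validate_protein(seq)
  if (n == 0L) stop("not a valid protein sequence (20 canonical residues): ",
                    substr(as.character(seq)[1L], 1L, 30L))
  clean_seq(seq)
}

as_dna <- function(seq) {
  n <- validate_dna(seq)
  if (n == 0L) stop("not a valid DNA sequence over {A,C,G,T}: ",
                    substr(as.character(seq)[1L], 1L, 30L))
  clean_seq(seq)
}

#' Generate random sequences
#'
#' Seeded fixture generator: i.i.d. uniform letters over the protein or DNA
#' alphabet. Deterministic given `seed`; every output passes its validator.
#'
#' @param kind `"protein"` or `"dna"`.
#' @param n number of sequences.
#' @param length length of each sequence.
#' @param seed integer random seed.
#' @return Character vector of `n` sequences.
#' @export
random_sequences <- function(kind = c("protein", "dna"), n, length, seed) {
  kind <- match.arg(kind)
  if (n < 1L || length < 1L) stop("n and length must be >= 1")
  alphabet <- if (kind == "protein") AA_ALPHABET else DNA_ALPHABET
  withr_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(alphabet, length, replace = TRUE), collapse = ""),
      character(1L))
  })
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
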