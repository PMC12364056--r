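#' Read a multi-record FASTA file
#'
#' Reads a standard FASTA file (wrapped or unwrapped sequence lines),
#' concatenates wrapped lines, strips whitespace and normalizes every
#' sequence with [normalize_sequence()] (uppercase, U -> T).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of normalized sequences; names are
#'   the record identifiers (the header word up to the first whitespace),
#'   in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "TT", "GG"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .stopf("FASTA file is empty: %s", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) .stopf("Not a FASTA file (first line lacks '>'): %s", path)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) .stopf("FASTA record with empty identifier")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    .stopf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  seqs <- vapply(seq_along(ids), function(i) {
    body <- lines[rec == i & !hdr]
    paste(gsub("\\s+", "", body), collapse = "")
  }, character(1))
  empty <- ids[!nzchar(seqs)]
  if (length(empty) > 0L)
    .stopf("empty sequence for FASTA record(s): %s",
           paste(empty, collapse = ", "))
  setNames(vapply(seqs, normalize_sequence, character(1), USE.NAMES = FALSE),
           ids)
}

#' Normalize a raw nucleotide sequence
#'
#' Uppercases the sequence and transcribes RNA to its DNA equivalent
#' (U -> T).  All other symbols, including IUPAC ambiguity codes, are
#' preserved verbatim; ambiguous windows are excluded later, at k-mer
#' matching.
#'
#' @param raw A non-empty character scalar.
#' @return The normalized sequence.
#' @export
#' @examples
#' normalize_sequence("acgu")   # "ACGT"
#' normalize_sequence("ACNNT")  # unchanged
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) .stopf("cannot normalize an empty sequence")
  chartr("U", "T", toupper(raw))
}

#' Occurrence positions of one k-mer in a sequence
#'
#' Returns every 1-based start position i in `[1, N - k + 1]` with
#' `substr(seq, i, i + k - 1) == kmer`.  Overlapping occurrences are all
#' reported; a window longer than the sequence yields an empty set.
#'
#' @param seq Normalized sequence string.
#' @param kmer The k-mer word; its length defines k.
#' @return Sorted integer vector of 1-based positions (possibly empty).
#' @export
#' @examples
#' kmer_positions("ACGACGT", "ACG")  # 1, 4
#' kmer_positions("AAAA", "AA")      # 1, 2, 3 (overlaps counted)
kmer_positions <- function(seq, kmer) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(kmer), length(kmer) == 1L, nzchar(kmer))
  k <- nchar(kmer)
  n <- nchar(seq)
  if (k > n) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  kc <- strsplit(kmer, "", fixed = TRUE)[[1]]
  hit <- chars[seq_len(n - k + 1L)] == kc[1L]
  if (k > 1L) for (j in 2L:k)
    hit <- hit & chars[j:(n - k + j)] == kc[j]
  which(hit)
}

#' Enumerate all k-mers over an alphabet
#'
#' All `|alphabet|^k` words in lexicographic order of the alphabet as
#' given.  This order is the fixed layout of every feature vector, so it
#' must be identical across sequences compared under one configuration.
#'
#' @param k Word length (positive integer).
#' @param alphabet Ordered character vector of distinct symbols.
#' @return Character vector of length `length(alphabet)^k`.
#' @export
#' @examples
#' enumerate_kmers(1)                      # "A" "C" "G" "T"
#' enumerate_kmers(3, c("0", "1"))         # "000" ... "111"
enumerate_kmers <- function(k, alphabet = c("A", "C", "G", "T")) {
  stopifnot(k >= 1, length(alphabet) >= 1, !anyDuplicated(alphabet))
  words <- alphabet
  if (k > 1L) for (i in 2L:k)
    words <- as.vector(t(outer(words, alphabet, paste0)))
  words
}

# Position sets of every k-mer actually present in seq, in one pass.
# Returns a named list (kmer -> integer positions); k-mers absent from
# seq (or whose enumerated positions fall on ambiguous windows) are not
# listed.  Windows containing symbols outside the alphabet match nothing.
.all_kmer_positions <- function(seq, k, alphabet = c("A", "C", "G", "T")) {
  n <- nchar(seq)
  if (k > n) return(list())
  starts <- seq_len(n - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  canonical <- !grepl(paste0("[^", paste(alphabet, collapse = ""), "]"), words)
  split(starts[canonical], words[canonical])
}

#' Read a two-column sequence label table
#'
#' TSV with sequence id in the first column and class label in the
#' second; no header by default.
#'
#' @param path Path to the TSV file.
#' @param header Whether the file carries a header row.
#' @return Named character vector mapping id to label.
#' @export
read_labels <- function(path, header = FALSE) {
  if (!file.exists(path)) .stopf("label file not found: %s", path)
  tab <- read.table(path, sep = "\t", header = header,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 2L) .stopf("label table needs two columns (id, label)")
  dup <- tab[[1]][duplicated(tab[[1]])]
  if (length(dup) > 0L)
    .stopf("duplicate id(s) in label table: %s",
           paste(unique(dup), collapse = ", "))
  setNames(tab[[2]], tab[[1]])
}

#' Write a two-column label table
#'
#' @param labels Named character vector (names are sequence ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(id = names(labels), label = unname(labels)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
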