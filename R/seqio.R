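# Token vocabulary: 20 canonical amino acids (alphabetical one-letter code),
# 'X' for any non-canonical residue, then the three special tokens. Integer
# ids are fixed and 1-based.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Token vocabulary for the sequence encoder
#'
#' Returns the fixed integer vocabulary used by [tokenize()]: the 20 canonical
#' amino-acid letters, `X` for unknown residues, and the `BEGIN` (`<cls>`),
#' `END` (`<eos>`) and `PAD` special tokens.
#'
#' @return Named integer vector mapping token string to id.
#' @export
aa_vocab <- function() {
  toks <- c(.AA20, "X", "<cls>", "<eos>", "<pad>")
  stats::setNames(seq_along(toks), toks)
}

.VOCAB <- local({
  toks <- c(.AA20, "X", "<cls>", "<eos>", "<pad>")
  stats::setNames(seq_along(toks), toks)
})
.ID_BEGIN <- .VOCAB[["<cls>"]]
.ID_END   <- .VOCAB[["<eos>"]]
.ID_PAD   <- .VOCAB[["<pad>"]]

#' Construct a protein record
#'
#' One protein: an identifier, its amino-acid sequence, and optionally its
#' C-alpha coordinates (in Angstrom, one row per residue) and a family label.
#'
#' @param id Character scalar.
#' @param sequence Character scalar over the 20 canonical letters plus `X`.
#' @param coords Optional numeric matrix with 3 columns (x, y, z) and one row
#'   per residue; must be finite and match the sequence length.
#' @param family Optional scalar label.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, coords = NULL, family = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("protein_record: sequence must be non-empty")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(.AA20, "X"))
  if (length(bad) > 0L)
    stop("protein_record: invalid residue letter(s): ",
         paste(unique(bad), collapse = ", "))
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (ncol(coords) != 3L)
      stop("protein_record: coords must have 3 columns")
    if (nrow(coords) != nchar(sequence))
      stop("protein_record: coords rows (", nrow(coords),
           ") must equal sequence length (", nchar(sequence), ")")
    if (!all(is.finite(coords)))
      stop("protein_record: coords must be finite")
    storage.mode(coords) <- "double"
    dimnames(coords) <- list(NULL, c("x", "y", "z"))
  }
  structure(list(id = id, sequence = sequence, coords = coords,
                 family = family),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", nchar(x$sequence), " residues",
      if (!is.null(x$coords)) ", with C-alpha coords" else "",
      if (!is.null(x$family)) paste0(", family ", x$family) else "",
      "\n", sep = "")
  invisible(x)
}

# Uppercase, strip '*' stop characters (warn), map non-canonical letters to
# 'X' (warn). Returns the cleaned sequence string.
clean_sequence <- function(seq, id = "?") {
  seq <- toupper(seq)
  if (grepl("*", seq, fixed = TRUE)) {
    warning("sequence ", id, ": '*' stop character(s) stripped")
    seq <- gsub("*", "", seq, fixed = TRUE)
  }
  ch <- strsplit(seq, "")[[1]]
  bad <- !(ch %in% c(.AA20, "X"))
  if (any(bad)) {
    warning("sequence ", id, ": non-canonical letter(s) ",
            paste(unique(ch[bad]), collapse = ", "), " mapped to 'X'")
    ch[bad] <- "X"
  }
  paste(ch, collapse = "")
}

#' Read a FASTA file into protein records
#'
#' Parses a (multi-record, wrapped or unwrapped) FASTA file. Letters are
#' uppercased; `*` stop characters are stripped and any letter outside the
#' 20-canonical + `X` alphabet is mapped to `X`, both with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("read_fasta: malformed FASTA at line ", nonblank[1],
         ": expected '>' header, got: ", lines[nonblank[1]])
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- clean_sequence(as.character(set[[i]]), id = ids[i])
    out[[i]] <- protein_record(ids[i], s)
  }
  out
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Tokenize a protein sequence
#'
#' Truncates the sequence to its first `max_len` residues, then wraps it in
#' `BEGIN`/`END` tokens. The mask marks real-residue positions only (special
#' tokens and padding are `FALSE`), which is the validity mask used by masked
#' mean pooling downstream.
#'
#' @param rec A [protein_record()] or a plain character sequence.
#' @param max_len Maximum number of residues kept (N-terminal prefix);
#'   default 512.
#' @return A `token_seq`: list with integer `token_ids`, logical `mask`, and
#'   `original_length` (pre-truncation residue count).
#' @export
tokenize <- function(rec, max_len = 512L) {
  if (inherits(rec, "protein_record")) rec <- rec$sequence
  stopifnot(is.character(rec), length(rec) == 1L, max_len >= 1L)
  n0 <- nchar(rec)
  keep <- substr(rec, 1L, max_len)
  ch <- strsplit(keep, "")[[1]]
  ids <- unname(.VOCAB[ch])
  if (anyNA(ids)) stop("tokenize: letter outside vocabulary: ",
                       paste(unique(ch[is.na(ids)]), collapse = ", "))
  structure(list(
    token_ids = c(.ID_BEGIN, ids, .ID_END),
    mask = c(FALSE, rep(TRUE, length(ids)), FALSE),
    original_length = n0
  ), class = "token_seq")
}

#' Recover the (possibly truncated) sequence from a token sequence
#'
#' @param ts A `token_seq` from [tokenize()].
#' @return Character sequence of the real-residue tokens.
#' @export
detokenize <- function(ts) {
  stopifnot(inherits(ts, "token_seq"))
  rev_vocab <- names(.VOCAB)
  paste(rev_vocab[ts$token_ids[ts$mask]], collapse = "")
}

#' Pad a list of token sequences to a common width
#'
#' Appends `PAD` tokens (mask `FALSE`) so every member has the width of the
#' longest one; used to form rectangular batches.
#'
#' @param tss List of `token_seq`.
#' @return List of `token_seq`, all the same length.
#' @export
pad_batch <- function(tss) {
  w <- max(vapply(tss, function(t) length(t$token_ids), 1L))
  lapply(tss, function(t) {
    k <- w - length(t$token_ids)
    if (k > 0L) {
      t$token_ids <- c(t$token_ids, rep(.ID_PAD, k))
      t$mask <- c(t$mask, rep(FALSE, k))
    }
    t
  })
}
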