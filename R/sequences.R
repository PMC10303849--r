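#' One-hot encode a DNA sequence
#'
#' Converts a DNA string into an L x 4 binary matrix with columns in the
#' fixed order A, C, G, T. Sequences containing `N` are not encoded: they
#' are rejected (returning `NULL`) so that callers can keep a discard log,
#' mirroring the training convention that ambiguous sequences are dropped
#' rather than imputed.
#'
#' @param sequence A single DNA string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @param id Optional sequence identifier used in error messages.
#'
#' @return An L x 4 integer matrix (columns `A`, `C`, `G`, `T`) in which
#'   every row sums to 1, or `NULL` if the sequence contains `N`.
#' @examples
#' one_hot_encode("ACGT")
#' is.null(one_hot_encode("ACNT"))
#' @export
one_hot_encode <- function(sequence, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  code <- seq_codes(s, id = id)
  if (anyNA(code)) {
    return(NULL)
  }
  L <- length(code)
  m <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_len(L), code)] <- 1L
  m
}

DNA_BASES <- c("A", "C", "G", "T")

# Integer codes 1..4 for A,C,G,T; NA for N; error on anything else.
seq_codes <- function(s, id = NULL) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(chars, DNA_BASES)
  bad <- which(is.na(code) & chars != "N")
  if (length(bad) > 0L) {
    who <- if (is.null(id)) "sequence" else paste0("sequence '", id, "'")
    abort(sprintf(
      "invalid character '%s' at position %d in %s (alphabet is A/C/G/T/N)",
      chars[bad[1]], bad[1], who
    ))
  }
  code[chars == "N"] <- NA_integer_
  code
}

#' Reverse complement DNA strings
#'
#' Standard Watson-Crick reverse complement; an involution
#' (`reverse_complement(reverse_complement(x))` is `x`).
#'
#' @param sequences Character vector of DNA strings over `A`, `C`, `G`, `T`
#'   (optionally `N`).
#' @return Character vector of reverse complements, same length.
#' @examples
#' reverse_complement("AACG")
#' @export
reverse_complement <- function(sequences) {
  stopifnot(is.character(sequences))
  if (length(sequences) == 0L) {
    return(character(0))
  }
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(sequences))
  ))
}

#' GC content of DNA strings
#'
#' @param sequences Character vector of DNA strings.
#' @return Numeric vector of G+C fractions.
#' @export
gc_content <- function(sequences) {
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(toupper(sequences)),
    letters = c("GC"), as.prob = TRUE
  )
  as.numeric(freq)
}

# Encode a batch of equal-length N-free sequences into an n x (4L) matrix.
# Column layout is position-major: columns 4(p-1)+1 .. 4p hold the A,C,G,T
# indicator for position p, so a filter window of width W is a contiguous
# block of 4W columns.
encode_batch <- function(sequences, ids = NULL) {
  n <- length(sequences)
  stopifnot(n > 0L)
  seqs <- toupper(sequences)
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) {
    off <- which(nchar(seqs) != L)[1]
    who <- if (is.null(ids)) off else ids[off]
    abort(sprintf(
      "sequence '%s' has length %d; expected %d", who, nchar(seqs[off]), L
    ))
  }
  codes <- lapply(seq_len(n), function(i) {
    code <- seq_codes(seqs[i], id = if (is.null(ids)) i else ids[i])
    if (anyNA(code)) {
      abort(sprintf(
        "sequence '%s' contains N and cannot be encoded; filter with discard_n()",
        if (is.null(ids)) i else ids[i]
      ))
    }
    code
  })
  code_mat <- do.call(rbind, codes) # n x L, values 1..4
  X <- matrix(0, nrow = n, ncol = 4L * L)
  pos <- rep(seq_len(L), each = n)
  row <- rep(seq_len(n), times = L)
  col <- 4L * (pos - 1L) + as.vector(code_mat)
  X[cbind(row, col)] <- 1
  X
}

#' Drop sequences containing N
#'
#' Splits a set of sequences into encodable records and a discard log, the
#' convention used before training or interpretation.
#'
#' @param data A data frame with columns `id` and `sequence`.
#' @return A list with `kept` (tibble) and `discarded` (tibble of ids with a
#'   reason column).
#' @export
discard_n <- function(data) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  has_n <- stringr::str_detect(toupper(data$sequence), "N")
  list(
    kept = as_tibble(data[!has_n, , drop = FALSE]),
    discarded = tibble(
      id = data$id[has_n],
      reason = rep("contains N", sum(has_n))
    )
  )
}
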