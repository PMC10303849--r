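#' Read and write FASTA
#'
#' Thin wrappers over Biostrings. Record ids are taken up to the first
#' whitespace; duplicate ids are rejected.
#'
#' @param path File path.
#' @return `read_fasta` returns a tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- stringr::str_split_i(names(set), "\\s+", 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id '%s' in %s",
                  ids[anyDuplicated(ids)], path))
  }
  tibble(id = ids, sequence = as.character(set))
}

#' @rdname read_fasta
#' @param data Data frame with columns `id` and `sequence` (or a named
#'   character vector).
#' @param width Line-wrap width.
#' @export
write_fasta <- function(data, path, width = 60L) {
  if (is.character(data)) {
    data <- tibble(id = names(data) %||% as.character(seq_along(data)),
                   sequence = unname(data))
  }
  set <- Biostrings::DNAStringSet(setNames(data$sequence, data$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read and write a label table
#'
#' Tab-separated with a header line `id<TAB>task1..taskT`; one row per
#' sequence; duplicate ids are rejected.
#'
#' @param path File path.
#' @return A tibble with an `id` column and one numeric column per task.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(tab)) abort("label table must have an 'id' column")
  if (anyDuplicated(tab$id)) {
    abort(sprintf("duplicate id '%s' in label table %s",
                  tab$id[anyDuplicated(tab$id)], path))
  }
  tab
}

#' @rdname read_labels
#' @param data Data frame with `id` plus label columns.
#' @export
write_labels <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read BED6 intervals
#'
#' 0-based, half-open coordinates; six columns (chrom, start, end, name,
#' score, strand). Malformed records raise line-numbered errors.
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed6 <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  bad <- which(lengths(parts) < 6L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d of %s has %d fields; BED6 needs 6", bad[1], path,
                  lengths(parts)[bad[1]]))
  }
  f <- function(i) vapply(parts, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("non-integer coordinate at line %d of %s",
                  which(is.na(start) | is.na(end))[1], path))
  }
  strand <- f(6)
  if (!all(strand %in% c("+", "-", "."))) {
    abort(sprintf("invalid strand at line %d of %s",
                  which(!strand %in% c("+", "-", "."))[1], path))
  }
  tibble(
    chrom = f(1), start = start, end = end,
    name = f(4), score = f(5), strand = strand
  )
}

#' Extract sequences for BED6 intervals
#'
#' Half-open, 0-based extraction; minus-strand records return the reverse
#' complement of the plus-strand slice.
#'
#' @param bed A tibble as from [read_bed6()].
#' @param genome A named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @return The `bed` tibble with an added `sequence` column (and `id` from
#'   `name`).
#' @export
extract_bed_sequences <- function(bed, genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  missing_chrom <- setdiff(unique(bed$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    abort(sprintf("chromosome '%s' not present in the genome",
                  missing_chrom[1]))
  }
  seqs <- vapply(seq_len(nrow(bed)), function(i) {
    chrom_seq <- genome[[bed$chrom[i]]]
    if (bed$end[i] > nchar(chrom_seq) || bed$start[i] < 0L) {
      abort(sprintf("interval %s:%d-%d out of chromosome bounds",
                    bed$chrom[i], bed$start[i], bed$end[i]))
    }
    s <- substr(chrom_seq, bed$start[i] + 1L, bed$end[i])
    if (bed$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
  dplyr::mutate(bed, id = .data$name, sequence = seqs)
}

#' Read and write JASPAR-format motif files
#'
#' Supports both flat dialects: bracketed rows (`A  [ 1 2 3 ]`) and plain
#' 4-line count rows, with `>ID name` headers. Writing uses the bracketed
#' dialect and round-trips bit-exactly modulo trailing whitespace.
#'
#' @param path File path.
#' @return `read_jaspar` returns a list of [pfm()]s.
#' @export
read_jaspar <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  hdr <- which(stringr::str_starts(lines, ">"))
  if (length(hdr) == 0L) abort(sprintf("no '>' headers found in %s", path))
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L) {
      abort(sprintf("motif block after line %d of %s has %d rows; expected 4",
                    hdr[i], path, length(block)))
    }
    toks <- stringr::str_split(stringr::str_trim(lines[hdr[i]]), "\\s+")[[1]]
    id <- sub("^>", "", toks[1])
    name <- if (length(toks) > 1L) toks[2] else id
    rows <- lapply(seq_len(4L), function(j) {
      row <- stringr::str_replace_all(block[j], "[\\[\\]]", " ")
      row <- stringr::str_trim(row)
      vals <- stringr::str_split(row, "\\s+")[[1]]
      if (vals[1] %in% DNA_BASES) {
        base <- vals[1]
        vals <- vals[-1]
      } else {
        base <- DNA_BASES[j]
      }
      num <- suppressWarnings(as.numeric(vals))
      if (anyNA(num)) {
        abort(sprintf("non-numeric count in motif '%s' row %s of %s", id,
                      base, path))
      }
      setNames(list(num), base)
    })
    rows <- unlist(rows, recursive = FALSE)
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      abort(sprintf("ragged motif '%s' in %s: row widths %s", id, path,
                    paste(widths, collapse = "/")))
    }
    counts <- do.call(rbind, rows[DNA_BASES])
    out[[i]] <- pfm(counts, id = id, name = name)
  }
  setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' @rdname read_jaspar
#' @param profiles A list of [pfm()]s (or a single one).
#' @export
write_jaspar <- function(profiles, path) {
  if (inherits(profiles, "pfm")) profiles <- list(profiles)
  lines <- unlist(lapply(profiles, function(p) {
    rows <- vapply(seq_len(4L), function(j) {
      sprintf("%s  [ %s ]", DNA_BASES[j],
              paste(format_count(p$counts[j, ]), collapse = " "))
    }, character(1))
    c(sprintf(">%s %s", p$id, p$name), rows)
  }))
  writeLines(lines, path)
  invisible(path)
}

format_count <- function(x) {
  ifelse(x == round(x), format(round(x), scientific = FALSE, trim = TRUE),
         format(x, scientific = FALSE, trim = TRUE))
}

#' Read and write MEME minimal motif format
#'
#' Probability matrices under a `MOTIF` header with a
#' `letter-probability matrix` line; uniform background.
#'
#' @param path File path.
#' @return `read_meme` returns a list of `pwm` objects (with `n_sites`
#'   from `nsites=` when present).
#' @export
read_meme <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  starts <- which(stringr::str_starts(lines, "MOTIF"))
  if (length(starts) == 0L) abort(sprintf("no MOTIF entries in %s", path))
  out <- list()
  for (s in starts) {
    toks <- stringr::str_split(stringr::str_trim(lines[s]), "\\s+")[[1]]
    id <- toks[2]
    name <- if (length(toks) > 2L) toks[3] else id
    mline <- s + which(stringr::str_starts(
      lines[(s + 1L):length(lines)], "letter-probability matrix"
    ))[1]
    if (is.na(mline)) {
      abort(sprintf("MOTIF %s in %s has no letter-probability matrix", id,
                    path))
    }
    w <- as.integer(stringr::str_match(lines[mline], "w=\\s*(\\d+)")[, 2])
    nsites <- suppressWarnings(as.numeric(
      stringr::str_match(lines[mline], "nsites=\\s*([0-9.]+)")[, 2]
    ))
    rows <- lines[(mline + 1L):(mline + w)]
    probs <- t(vapply(rows, function(r) {
      as.numeric(stringr::str_split(stringr::str_trim(r), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    p <- pwm_from_probs(t(probs), id = id, name = name)
    p$n_sites <- if (is.na(nsites)) NA_real_ else nsites
    out[[id]] <- p
  }
  out
}

#' @rdname read_meme
#' @param motifs A list of `pwm` (or `pfm`) objects.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "pwm") || inherits(motifs, "pfm")) {
    motifs <- list(motifs)
  }
  header <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", ""
  )
  body <- unlist(lapply(motifs, function(m) {
    if (inherits(m, "pfm")) m <- pfm_to_pwm(m)
    w <- ncol(m$probs)
    ns <- if (is.na(m$n_sites)) 20 else m$n_sites
    c(
      sprintf("MOTIF %s %s", m$id, m$name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
              w, format(ns, scientific = FALSE, trim = TRUE)),
      vapply(seq_len(w), function(j) {
        paste(sprintf("%.6f", m$probs[, j]), collapse = " ")
      }, character(1)),
      ""
    )
  }))
  writeLines(c(header, body), path)
  invisible(path)
}
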