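#' Read sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the first non-empty character (`>` FASTA,
#' `@` FASTQ) unless given. Multi-line (wrapped) FASTA records are
#' concatenated. Qualities are returned for FASTQ and `NA` otherwise.
#'
#' @param path File path.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Tibble with `id`, `sequence`, `quality`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (!length(first)) stop("empty sequence file: ", path)
    format <- if (startsWith(first, "@")) "fastq" else if (startsWith(first, ">")) "fasta"
    else stop("cannot detect format of ", path, " (expected '>' or '@' on line 1)")
  }
  if (format == "fastq") {
    n_lines <- length(readLines(path))
    if (n_lines %% 4L != 0L) {
      stop("truncated FASTQ record in ", path, ": ", n_lines,
           " lines (around line ", 4L * (n_lines %/% 4L) + 1L, ")")
    }
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    tibble(
      id = names(x),
      sequence = unname(as.character(x)),
      quality = unname(as.character(S4Vectors::mcols(x)$qualities))
    )
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    tibble(id = names(x), sequence = unname(as.character(x)), quality = NA_character_)
  }
}

#' Read paired sequencing reads
#'
#' Two layouts are supported: two files (`r1`, `r2`, record-matched by
#' order, ids validated up to a trailing `/1` `/2`) or one interleaved file.
#'
#' @param r1,r2 Paths to the two mate files, or with `r2 = NULL` and
#'   `interleaved = TRUE` a single interleaved file in `r1`.
#' @param interleaved Set when `r1` holds interleaved pairs.
#' @return Tibble with one row per read in interleaved order (mate 1 of
#'   pair 1, mate 2 of pair 1, ...): `id`, `sequence`, `quality`, `pair`,
#'   `mate`.
#' @export
read_paired <- function(r1, r2 = NULL, interleaved = FALSE) {
  if (interleaved) {
    x <- read_sequences(r1)
    if (nrow(x) %% 2L != 0L) stop("interleaved file has an odd number of records")
    x$pair <- rep(seq_len(nrow(x) / 2L), each = 2L)
    x$mate <- rep(c(1L, 2L), nrow(x) / 2L)
    return(x)
  }
  if (is.null(r2)) stop("r2 is required unless interleaved = TRUE")
  a <- read_sequences(r1)
  b <- read_sequences(r2)
  if (nrow(a) != nrow(b)) {
    stop("pair-count mismatch: ", nrow(a), " reads in r1, ", nrow(b), " in r2")
  }
  strip <- function(id) sub("/[12]$", "", sub("\\s.*$", "", id))
  bad <- which(strip(a$id) != strip(b$id))
  if (length(bad)) {
    stop("read id mismatch at record ", bad[1], ": '", a$id[bad[1]],
         "' vs '", b$id[bad[1]], "'")
  }
  n <- nrow(a)
  out <- dplyr::bind_rows(a, b)[rep(seq_len(n), each = 2L) + c(0L, n), ]
  out$pair <- rep(seq_len(n), each = 2L)
  out$mate <- rep(c(1L, 2L), n)
  out
}

#' Write sequences as FASTA
#'
#' @param x Named character vector, or a tibble with `id`/`name` and
#'   `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (is.data.frame(x)) {
    nm <- if ("id" %in% names(x)) x$id else x$name
    x <- setNames(as.character(x$sequence), nm)
  }
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param x Tibble with `id` and `sequence` (and optional `quality`;
#'   constant quality `"I"` is used when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  qual <- if ("quality" %in% names(x) && !anyNA(x$quality)) x$quality
  else vapply(nchar(x$sequence), function(n) strrep("I", n), character(1))
  set <- Biostrings::DNAStringSet(setNames(as.character(x$sequence), x$id))
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Write a tab-separated table with a '#'-prefixed header
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_hash <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a tab-separated table with a '#'-prefixed header
#' @param path File path.
#' @return Tibble.
#' @export
read_tsv_hash <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  readr::read_tsv(path, skip = 1L, col_names = cols, show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a manifest of output files with checksums
#'
#' @param paths Character vector of files.
#' @param path Manifest destination (JSON).
#' @param extra Named list merged into the manifest (seeds, parameters).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(paths, path, extra = list()) {
  files <- lapply(paths, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)), bytes = file.size(p))
  })
  jsonlite::write_json(c(list(files = files), extra), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
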