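# Standard-format I/O. Sequence parsing is delegated to Biostrings; the thin
# wrappers normalise case, return tibbles, and attach line/record context to
# parse errors.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (verbatim header) and `sequence`
#'   (uppercased). Zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0L) {
    return(tibble(id = character(), sequence = character()))
  }
  check_fasta_lines(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("FASTA parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  tibble(id = names(set), sequence = unname(toupper(as.character(set))))
}

# Biostrings is forgiving about headerless leading sequence; report the line
check_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(lines[nonblank[1]], ">")) {
    abort(paste0("FASTA parse error in ", path, ": line ", nonblank[1],
                 " is not a header."))
  }
  invisible(TRUE)
}

#' Write a FASTA file
#'
#' @param x A data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` (default) keeps one line per sequence
#'   so that `write_fasta(read_fasta(f))` round-trips byte-identically for
#'   normalized input.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = Inf) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  seqs <- x$sequence
  if (is.finite(width)) {
    seqs <- map_chr(seqs, function(s) {
      paste(substring(s, seq(1L, nchar(s), width),
                      pmin(seq(width, nchar(s) + width - 1L, width), nchar(s))),
            collapse = "\n")
    })
  }
  writeLines(paste0(">", x$id, "\n", seqs), path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Plain or gzip-compressed 4-line-record FASTQ. Qualities are parsed and
#' carried along but not used by any default analysis.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A tibble with columns `id`, `sequence` (uppercased), `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble(id = character(), sequence = character(), quality = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(paste0("FASTQ parse error in ", path,
                 ": truncated record near line ", length(lines)))
  }
  id_raw <- lines[seq(1L, length(lines), 4L)]
  if (!all(startsWith(id_raw, "@"))) {
    first_bad <- which(!startsWith(id_raw, "@"))[1]
    abort(paste0("FASTQ parse error in ", path, ": record ", first_bad,
                 " does not start with '@'."))
  }
  out <- tibble(
    id = sub("^@", "", id_raw),
    sequence = toupper(lines[seq(2L, length(lines), 4L)]),
    quality = lines[seq(4L, length(lines), 4L)]
  )
  mismatch <- nchar(out$sequence) != nchar(out$quality)
  if (any(mismatch)) {
    abort(paste0("FASTQ parse error in ", path,
                 ": sequence/quality length mismatch for record '",
                 out$id[which(mismatch)[1]], "'"))
  }
  out
}

#' Write a FASTQ file
#'
#' @param x A data frame with columns `id`, `sequence` and optionally
#'   `quality` (default: constant 'I').
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  quality <- x$quality %||% strrep("I", nchar(x$sequence))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", x$id, "\n", x$sequence, "\n+\n", quality), con)
  invisible(path)
}

#' Write a TSV with '#'-prefixed metadata header
#'
#' All primary tabular outputs carry their provenance (tool, seed, config
#' hash) as comment lines so that byte-identity across reruns is meaningful.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list of metadata scalars written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# ", names(meta), ": ",
                      map_chr(meta, ~ paste(format(.x, scientific = FALSE),
                                            collapse = " "))), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x)) {
    body <- do.call(paste, c(map(x, ~ format_tsv_col(.x)), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

format_tsv_col <- function(col) {
  if (is.numeric(col) && !is.integer(col)) {
    formatC(col, digits = 15, format = "g")
  } else {
    as.character(col)
  }
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path Input path.
#' @return A tibble; metadata lines are returned in the `meta` attribute as a
#'   named character vector.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "# ")
  meta_lines <- lines[is_meta & seq_along(lines) <= rle(is_meta)$lengths[1] *
                        as.integer(is_meta[1])]
  meta <- character()
  if (length(meta_lines)) {
    kv <- regmatches(meta_lines, regexec("^# ([^:]+): (.*)$", meta_lines))
    meta <- setNames(map_chr(kv, 3), map_chr(kv, 2))
  }
  body <- lines[!startsWith(lines, "# ")]
  out <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  attr(out, "meta") <- meta
  out
}
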