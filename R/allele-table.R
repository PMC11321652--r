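#' Allele table of edit combinations
#'
#' The central quantification object: read counts per combination of
#' substitutions observed inside the quantification window, on the
#' protospacer strand. The wild-type (empty) combo is always present as the
#' `""` key, so outcome fractions can use total passing reads as the
#' denominator.
#'
#' @param combos Either a character vector of combo strings (see
#'   [format_combo()]) or a data frame with columns `combo`, `count`.
#' @param counts Integer read counts, parallel to `combos` (ignored when
#'   `combos` is a data frame).
#' @param spec Optional [protospacer_spec()] the table was quantified against.
#' @param window Quantification window `c(lo, hi)` in protospacer
#'   coordinates; every combo position must lie inside it.
#' @param discards Named integer vector of discarded-read counters
#'   (`indel`, `mismatch`, `short`).
#' @return A tibble of class `allele_tbl` with columns `combo`, `count`, and
#'   attributes `spec`, `window`, `discards`.
#' @examples
#' at <- allele_table(c("", "6A>G", "6A>G;7A>G"), c(50, 30, 20))
#' tidy(at)
#' @export
allele_table <- function(combos, counts = NULL, spec = NULL,
                         window = c(-3L, 12L),
                         discards = c(indel = 0L, mismatch = 0L, short = 0L)) {
  if (is.data.frame(combos)) {
    df <- as_tibble(combos)
    stopifnot(all(c("combo", "count") %in% names(df)))
  } else {
    df <- tibble(combo = as.character(combos), count = counts)
  }
  df$combo[is.na(df$combo)] <- ""
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    abort("counts must be non-negative integers.")
  }
  df$count <- as.integer(round(df$count))
  agg <- rowsum(df$count, df$combo)   # base aggregation: this constructor is hot
  df <- tibble(combo = rownames(agg), count = as.integer(agg[, 1L]))
  wpos <- window_positions(window)
  pos_used <- unique(unlist(map(df$combo, combo_positions)))
  if (length(pos_used) && !all(pos_used %in% wpos)) {
    abort("combo position(s) outside the quantification window.")
  }
  if (!"" %in% df$combo) {
    df <- bind_rows(tibble(combo = "", count = 0L), df)
  }
  df <- df[order(df$combo != "", df$combo), ]
  for (nm in c("indel", "mismatch", "short")) {
    if (is.na(discards[nm])) discards[nm] <- 0L
  }
  structure(df,
            spec = spec, window = as.integer(window),
            discards = as.integer(discards[c("indel", "mismatch", "short")]) |>
              setNames(c("indel", "mismatch", "short")),
            class = c("allele_tbl", class(df)))
}

#' @rdname allele_table
#' @param x An `allele_tbl`.
#' @export
n_total <- function(x) {
  stopifnot(inherits(x, "allele_tbl"))
  sum(x$count)
}

at_spec   <- function(x) attr(x, "spec", exact = TRUE)
at_window <- function(x) attr(x, "window", exact = TRUE)

#' @rdname allele_table
#' @export
discard_counts <- function(x) attr(x, "discards", exact = TRUE)

#' @export
print.allele_tbl <- function(x, ...) {
  cat("<allele_tbl> ", n_total(x), " reads, ",
      sum(x$count > 0 | x$combo == ""), " combos, window [",
      paste(at_window(x), collapse = ", "), "]; discarded: ",
      paste(names(discard_counts(x)), discard_counts(x),
            sep = "=", collapse = " "), "\n", sep = "")
  NextMethod()
}

#' Write / read an allele table as TSV
#'
#' The quantification window, discard counters and any extra metadata are
#' stored as `#`-prefixed header lines so the table round-trips.
#'
#' @param x An [allele_table()].
#' @param path File path.
#' @param meta Extra metadata for the header.
#' @return `path` / an `allele_tbl`.
#' @export
write_allele_table <- function(x, path, meta = list()) {
  stopifnot(inherits(x, "allele_tbl"))
  d <- discard_counts(x)
  meta <- c(list(window = paste(at_window(x), collapse = " "),
                 discarded_indel = d[["indel"]],
                 discarded_mismatch = d[["mismatch"]],
                 discarded_short = d[["short"]]),
            meta)
  write_tsv_meta(as_tibble(x)[, c("combo", "count")], path, meta)
}

#' @rdname write_allele_table
#' @param spec Optional [protospacer_spec()] to re-attach on read.
#' @export
read_allele_table <- function(path, spec = NULL) {
  df <- read_tsv_meta(path)
  meta <- attr(df, "meta")
  window <- as.integer(strsplit(meta[["window"]], " ")[[1]])
  df$combo[is.na(df$combo)] <- ""
  allele_table(df, spec = spec, window = window,
               discards = c(indel = as.integer(meta[["discarded_indel"]]),
                            mismatch = as.integer(meta[["discarded_mismatch"]]),
                            short = as.integer(meta[["discarded_short"]])))
}

#' @exportS3Method generics::tidy
tidy.allele_tbl <- function(x, ...) {
  nt <- n_total(x)
  as_tibble(x) |>
    mutate(fraction = if (nt > 0) .data$count / nt else NA_real_,
           n_edits = map_int(.data$combo, ~ length(combo_positions(.x)))) |>
    arrange(desc(.data$count))
}

#' @exportS3Method generics::glance
glance.allele_tbl <- function(x, ...) {
  d <- discard_counts(x)
  tibble(
    n_total = n_total(x),
    n_combos = sum(x$count > 0),
    wild_type_fraction = if (n_total(x) > 0)
      x$count[x$combo == ""] / n_total(x) else NA_real_,
    n_discarded_indel = d[["indel"]],
    n_discarded_mismatch = d[["mismatch"]],
    n_discarded_short = d[["short"]]
  )
}
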