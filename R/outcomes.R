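# Outcome classification: product-purity combinatorics, codon consequences,
# and the precise / bystander-missense / wild-type trichotomy used to judge
# therapeutic base edits.

#' Consequence of a codon change
#'
#' Standard-genetic-code comparison of a reference and an edited codon.
#' `"corrective"` is assigned only when the caller marks the codon as the
#' designated therapeutic target; the genetic code alone cannot know intent.
#'
#' @param ref_codon,alt_codon DNA triplets (vectorised).
#' @param is_target Logical; is this the designated target position?
#' @return `"corrective"`, `"synonymous"`, `"missense"`, `"nonsense"`, or
#'   `"stop_loss"`.
#' @examples
#' codon_consequence("ACG", "GCG")  # Thr -> Ala, missense
#' codon_consequence("TGA", "TGG")  # stop -> Trp, stop_loss
#' @export
codon_consequence <- function(ref_codon, alt_codon, is_target = FALSE) {
  ref_codon <- toupper(ref_codon); alt_codon <- toupper(alt_codon)
  n <- max(length(ref_codon), length(alt_codon))
  ref_codon <- rep_len(ref_codon, n); alt_codon <- rep_len(alt_codon, n)
  is_target <- rep_len(is_target, n)
  ok <- grepl("^[ACGT]{3}$", ref_codon) & grepl("^[ACGT]{3}$", alt_codon)
  if (!all(ok)) abort("codons must be ACGT triplets.")
  if (any(ref_codon == alt_codon)) {
    abort("ref_codon and alt_codon must differ at >= 1 base.")
  }
  aa_ref <- unname(Biostrings::GENETIC_CODE[ref_codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
  out <- ifelse(aa_ref == aa_alt, "synonymous",
         ifelse(aa_alt == "*", "nonsense",
         ifelse(aa_ref == "*", "stop_loss", "missense")))
  ifelse(is_target, "corrective", out)
}

#' Target specification for outcome classification
#'
#' Declares which protospacer positions carry editable adenines, which one is
#' the therapeutic target, and the codon context of each, from which the
#' consequence of editing each position is derived.
#'
#' @param name Locus name.
#' @param editable_positions Integer protospacer positions bearing the
#'   editable base.
#' @param target_position The designated therapeutic position (must be one of
#'   `editable_positions`).
#' @param consequences A data frame with columns `position`, `ref_codon`,
#'   `edited_codon` covering every editable position; each edited codon must
#'   differ from its reference codon at exactly one base. An optional
#'   `consequence` column overrides the genetic-code call (e.g. for
#'   non-coding context).
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(name, editable_positions, target_position,
                        consequences) {
  editable_positions <- sort(as.integer(editable_positions))
  target_position <- as.integer(target_position)
  if (!target_position %in% editable_positions) {
    abort("`target_position` must be one of `editable_positions`.")
  }
  cons <- as_tibble(consequences)
  stopifnot(all(c("position", "ref_codon", "edited_codon") %in% names(cons)))
  cons$position <- as.integer(cons$position)
  missing <- setdiff(editable_positions, cons$position)
  if (length(missing)) {
    abort(paste0("consequences missing for position(s): ",
                 paste(missing, collapse = ", ")))
  }
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, toupper(cons$ref_codon), toupper(cons$edited_codon))
  if (any(ndiff != 1L)) {
    abort("each edited_codon must differ from ref_codon at exactly one base.")
  }
  if (!"consequence" %in% names(cons)) {
    cons$consequence <- codon_consequence(cons$ref_codon, cons$edited_codon,
                                          cons$position == target_position)
  }
  structure(list(name = name, editable_positions = editable_positions,
                 target_position = target_position,
                 consequences = cons[order(cons$position), ]),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat("<target_spec> ", x$name, ": target +", x$target_position,
      ", editable {", paste(x$editable_positions, collapse = ", "), "}\n",
      sep = "")
  print(x$consequences)
  invisible(x)
}

#' Distribution of editing products over a position set
#'
#' Projects every read's combo onto the given positions (edits elsewhere are
#' ignored) and reports the fraction of reads per projected combo, labelled
#' by multiplicity (none / single / dual / triple / ...). This is the
#' product-purity view: a narrow-window editor concentrates mass on a single
#' position, a promiscuous one spreads it over dual and triple products.
#'
#' @param table An [allele_table()].
#' @param positions Integer protospacer positions to project onto.
#' @return A tibble with columns `combo` (projected), `n_edits`,
#'   `multiplicity`, `count`, `fraction`; fractions sum to 1 over all reads.
#' @export
combo_distribution <- function(table, positions) {
  stopifnot(inherits(table, "allele_tbl"))
  nt <- n_total(table)
  if (nt == 0L) abort("empty allele table.")
  positions <- as.integer(positions)
  projected <- map_chr(table$combo, function(cm) {
    e <- parse_combo(cm)
    format_combo(e[e$position %in% positions, , drop = FALSE])
  })
  agg <- rowsum(table$count, projected)
  out <- tibble(combo = rownames(agg), count = as.integer(agg[, 1L])) |>
    filter(.data$count > 0L) |>
    mutate(n_edits = map_int(.data$combo, ~ length(combo_positions(.x))),
           multiplicity = multiplicity_label(.data$n_edits),
           fraction = .data$count / nt) |>
    select("combo", "n_edits", "multiplicity", "count", "fraction")
  out[order(out$n_edits, out$combo), ]
}

multiplicity_label <- function(n) {
  lab <- c("none", "single", "dual", "triple", "quadruple")
  ifelse(n < length(lab), lab[n + 1L], paste0(n, "-fold"))
}

#' Product-purity ratio between two combos
#'
#' `focal / (focal + competing)` over combo fractions matched by position
#' set, e.g. single editing at +5 versus dual editing at +5 and +8. Returns
#' `NA` (not defined) when both fractions are zero.
#'
#' @param dist A [combo_distribution()] tibble.
#' @param focal,competing Integer position vectors identifying the two
#'   combos by their position sets.
#' @return A single fraction in `[0, 1]`, or `NA_real_`.
#' @export
purity_ratio <- function(dist, focal, competing) {
  keys <- map_chr(dist$combo, ~ position_key(combo_positions(.x)))
  f <- sum(dist$fraction[keys == position_key(focal)])
  k <- sum(dist$fraction[keys == position_key(competing)])
  if (f + k == 0) return(NA_real_)
  f / (f + k)
}

#' Classify editing outcomes at a therapeutic locus
#'
#' Partitions all passing reads into four exhaustive, mutually exclusive
#' categories:
#' \describe{
#'   \item{precise}{edited at the target position and nowhere else}
#'   \item{bystander_missense}{any combo containing at least one position
#'     whose consequence is missense or nonsense}
#'   \item{wild_type}{the unedited (empty) combo}
#'   \item{other_edited}{everything else, e.g. combos whose only bystanders
#'     are synonymous}
#' }
#' The three-way precise / missense / wild-type chart common for loci whose
#' bystanders are all missense is recovered with `fold_other = TRUE`, which
#' folds `other_edited` into `bystander_missense`.
#'
#' @param table An [allele_table()].
#' @param spec A [target_spec()]. Combos containing positions outside the
#'   spec's editable set (residual sequencing error, incidental edits) fall
#'   into `other_edited` unless they also contain a missense/nonsense
#'   editable position; categories are decided by position sets.
#' @param fold_other Fold `other_edited` into `bystander_missense`
#'   (default `FALSE`).
#' @return An object of class `outcome_summary`; see [tidy()] / [glance()].
#' @export
classify_outcomes <- function(table, spec, fold_other = FALSE) {
  stopifnot(inherits(table, "allele_tbl"), inherits(spec, "target_spec"))
  nt <- n_total(table)
  if (nt == 0L) abort("empty allele table.")
  cons <- setNames(spec$consequences$consequence, spec$consequences$position)
  category <- map_chr(table$combo, function(cm) {
    pos <- combo_positions(cm)
    if (length(pos) == 0L) return("wild_type")
    if (identical(pos, spec$target_position)) return("precise")
    covered <- pos[pos %in% as.integer(names(cons))]
    if (any(cons[as.character(covered)] %in% c("missense", "nonsense"))) {
      return("bystander_missense")
    }
    # combos whose only extra edits are synonymous bystanders or lie outside
    # the spec's editable positions (e.g. residual sequencing error)
    "other_edited"
  })
  if (fold_other) {
    category[category == "other_edited"] <- "bystander_missense"
  }
  lev <- c("precise", "bystander_missense", "other_edited", "wild_type")
  counts_by <- unname(vapply(lev, function(l) sum(table$count[category == l]),
                             numeric(1)))
  fractions <- tibble(category = lev, count = as.integer(counts_by),
                      fraction = counts_by / nt)
  structure(list(fractions = fractions,
                 combo_distribution = combo_distribution(
                   table, spec$editable_positions),
                 n_total = nt, locus = spec$name,
                 target_position = spec$target_position,
                 fold_other = fold_other),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary> ", x$locus, " (target +", x$target_position, ", ",
      x$n_total, " reads)\n", sep = "")
  print(x$fractions)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.outcome_summary <- function(x, ...) x$fractions

#' @exportS3Method generics::glance
glance.outcome_summary <- function(x, ...) {
  wide <- setNames(as.list(x$fractions$fraction), x$fractions$category)
  as_tibble(c(list(locus = x$locus, n_total = x$n_total), wide))
}

#' @exportS3Method ggplot2::autoplot
autoplot.outcome_summary <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = object$locus, y = .data$fraction,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu") +
    ggplot2::labs(x = NULL, y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' Bystander editing report
#'
#' Frequency and consequence label for every editable non-target position.
#' Frequencies share the all-passing-reads denominator of
#' [per_position_frequencies()].
#'
#' @param table An [allele_table()].
#' @param spec A [target_spec()].
#' @return A tibble with columns `position`, `frequency`, `consequence`.
#' @export
bystander_report <- function(table, spec) {
  stopifnot(inherits(table, "allele_tbl"), inherits(spec, "target_spec"))
  nt <- n_total(table)
  if (nt == 0L) abort("empty allele table.")
  bys <- setdiff(spec$editable_positions, spec$target_position)
  edited <- combos_long(table$combo) |>
    left_join(as_tibble(table)[, c("combo", "count")], by = "combo") |>
    filter(.data$position %in% bys) |>
    group_by(.data$position) |> summarise(n_edited = sum(.data$count))
  tibble(position = bys) |>
    left_join(edited, by = "position") |>
    mutate(frequency = ifelse(is.na(.data$n_edited), 0, .data$n_edited) / nt) |>
    left_join(spec$consequences[, c("position", "consequence")],
              by = "position") |>
    select("position", "frequency", "consequence")
}
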