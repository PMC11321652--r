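# Shared fixtures and independent oracles. Oracles deliberately use a
# different route than the implementation (Biostrings::translate, explicit
# loops over expanded combos) so agreement is informative.

# generic test amplicon: adenines at protospacer +6 and +7
test_spec <- function() {
  up <- "GATCCTGGGCTACGTCCAGGAGCTCGGCTC"
  protospacer_spec(paste0(up, "GTCGTAACGGCGTGCGTGCG", "CGG",
                          "TGGAGGATACCTCACCCTGGAGCACCTGGC"),
                   protospacer_offset = nchar(up))
}

# amplicon with adenines at the six even protospacer positions 2,4,...,12
six_a_spec <- function() {
  up <- "GATCCTGGGCTACGTCCAGGAGCTCGGCTC"
  protospacer_spec(paste0(up, "CACATAGACATACGTGCGTG", "CGG",
                          "TGGAGGATACCTCACCCTGGAGCACCTGGC"),
                   protospacer_offset = nchar(up))
}

SIX_A_POSITIONS <- c(2L, 4L, 6L, 8L, 10L, 12L)

# random allele table over a subset of the six A positions (A>G combos)
random_allele_table <- function(spec = six_a_spec(),
                                positions = SIX_A_POSITIONS,
                                max_combos = 12L) {
  k <- sample(2:max_combos, 1L)
  subsets <- unique(c(list(integer()), replicate(k, {
    sort(sample(positions, sample.int(length(positions), 1L)))
  }, simplify = FALSE)))
  combos <- vapply(subsets, function(ps) {
    if (length(ps) == 0L) return("")
    paste0(ps, "A>G", collapse = ";")
  }, character(1))
  allele_table(combos, sample.int(500L, length(combos), replace = TRUE),
               spec = spec, window = c(-3L, 12L))
}

# brute-force marginalisation: expand every combo, count indicator per position
oracle_marginal_freq <- function(table, positions, from = "A", to = "G") {
  nt <- sum(table$count)
  vapply(positions, function(p) {
    needle <- paste0(p, from, ">", to)
    hit <- vapply(table$combo, function(cm) {
      needle %in% strsplit(cm, ";", fixed = TRUE)[[1]]
    }, logical(1))
    sum(table$count[hit]) / nt
  }, double(1))
}

# translate-and-scan EGFP oracle, via Biostrings::translate
oracle_egfp <- function(insert) {
  if (nchar(insert) %% 3L != 0L) return("off")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(insert)))
  if (grepl("*", aa, fixed = TRUE)) "off" else "on"
}

# exhaustive outcome-rule oracle over explicit A>G combos
oracle_classify <- function(combo, target, consequence_by_pos) {
  pos <- if (combo == "") integer() else
    as.integer(sub("A>G$", "", strsplit(combo, ";", fixed = TRUE)[[1]]))
  if (length(pos) == 0L) return("wild_type")
  if (identical(sort(pos), as.integer(target))) return("precise")
  lab <- consequence_by_pos[as.character(pos)]
  if (any(lab %in% c("missense", "nonsense"), na.rm = TRUE)) {
    return("bystander_missense")
  }
  "other_edited"
}
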