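# Bundled deaminase sequences and codon preference table.

# Synthetic stand-in TadA pair: a fixed pseudorandom 167-aa background,
# identical between the two sequences except at the eight modern-vs-ancestral
# divergence positions (109, 111, 119, 122, 147, 149, 166, 167). The modern
# sequence carries S109/R111/N119/N122/D147/Y149/I166/N167 — the residues the
# charge-swap sub-library rules name — and the ancestral sequence the
# corresponding A/T/D/H/Y/F/T/D states. These are NOT the natural TadA
# sequences; only the divergence layout matters to the enumeration rules.
TADA8E_SYNTHETIC <- paste0(
  "MHMYAIKKDKTAHFYDALPWASCGAMWGGFLTSIKLHEWVRTCTMAIHTRPWYVHTCPSF",
  "NVLFDTSTEWDPWNGTASQWGVSGWCSSETRLCIRWIRAIWKVLGFHFSDRVWYDSRCND",
  "GNMVARRTGLCILHWNTVDAWYICKYDWYDLFVGYCDPVIFPHKMIN")

TADA710_SYNTHETIC <- paste0(
  "MHMYAIKKDKTAHFYDALPWASCGAMWGGFLTSIKLHEWVRTCTMAIHTRPWYVHTCPSF",
  "NVLFDTSTEWDPWNGTASQWGVSGWCSSETRLCIRWIRAIWKVLGFHFADTVWYDSRCDD",
  "GHMVARRTGLCILHWNTVDAWYICKYYWFDLFVGYCDPVIFPHKMTD")

#' Bundled synthetic deaminase sequence pair
#'
#' A synthetic modern (highly active, TadA-8e-like) and ancestral
#' (TadA-7.10-like) deaminase pair for exercising the library rules: equal
#' length, differing exactly at the eight canonical modern-vs-ancestral
#' positions (109, 111, 119, 122, 147, 149, 166, 167), with the modern
#' residues at the six charge-swap positions being 109S, 111R, 119N, 122N,
#' 147D, 149Y. The same pair ships as `inst/extdata/tada_synthetic.fasta`.
#'
#' @return A tibble with columns `id` (`tada8e_synthetic`,
#'   `tada710_synthetic`) and `sequence`.
#' @export
tada_sequences <- function() {
  tibble(id = c("tada8e_synthetic", "tada710_synthetic"),
         sequence = c(TADA8E_SYNTHETIC, TADA710_SYNTHETIC))
}

#' Human-preference codon ranking
#'
#' Codons per amino acid ordered by human codon-usage preference; the first
#' entry is the default choice when reverse-translating a designed variant,
#' later entries are fallbacks when the preferred codon would create a
#' forbidden restriction site in context.
#'
#' @return A named list (one-letter amino-acid code -> character vector of
#'   codons, most preferred first).
#' @export
human_codon_ranks <- function() {
  list(
    A = c("GCC", "GCT", "GCA", "GCG"),
    C = c("TGC", "TGT"),
    D = c("GAC", "GAT"),
    E = c("GAG", "GAA"),
    F = c("TTC", "TTT"),
    G = c("GGC", "GGA", "GGG", "GGT"),
    H = c("CAC", "CAT"),
    I = c("ATC", "ATT", "ATA"),
    K = c("AAG", "AAA"),
    L = c("CTG", "CTC", "TTG", "CTT", "CTA", "TTA"),
    M = "ATG",
    N = c("AAC", "AAT"),
    P = c("CCC", "CCT", "CCA", "CCG"),
    Q = c("CAG", "CAA"),
    R = c("CGG", "AGA", "AGG", "CGC", "CGA", "CGT"),
    S = c("AGC", "TCC", "TCT", "AGT", "TCA", "TCG"),
    T = c("ACC", "ACA", "ACT", "ACG"),
    V = c("GTG", "GTC", "GTT", "GTA"),
    W = "TGG",
    Y = c("TAC", "TAT")
  )
}

#' Default charge classes for the charge-swap sub-library
#'
#' Positive, negative, polar-uncharged and nonpolar partitions of the 20
#' canonical amino acids. "Same charge" is only unambiguous for charged
#' residues; the uncharged classes are a configurable convention.
#'
#' @return A named list of character vectors partitioning the 20 amino acids.
#' @export
default_charge_classes <- function() {
  list(
    positive = c("K", "R", "H"),
    negative = c("D", "E"),
    polar    = c("S", "T", "N", "Q", "C", "Y"),
    nonpolar = c("A", "V", "L", "I", "P", "F", "M", "W", "G")
  )
}

#' Reverse-translate a protein with a codon ranking
#'
#' @param protein One-letter amino-acid string.
#' @param codon_ranks A ranking as from [human_codon_ranks()].
#' @return A DNA string using each amino acid's top-ranked codon.
#' @export
reverse_translate <- function(protein, codon_ranks = human_codon_ranks()) {
  aa <- strsplit(toupper(protein), "")[[1]]
  missing <- setdiff(aa, names(codon_ranks))
  if (length(missing)) {
    abort(paste0("codon ranking missing amino acid(s): ",
                 paste(missing, collapse = ", ")))
  }
  paste(map_chr(aa, ~ codon_ranks[[.x]][1]), collapse = "")
}
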