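# Synthetic data: amplicon reads with joint (co-occurring) edit structure
# plus uniform substitution sequencing error, and FACS-gated screen pools
# where sort probability increases monotonically with a variant's true
# editing activity. Both generators are deterministic given their seed.

#' Simulation profile for amplicon reads
#'
#' @param spec A [protospacer_spec()].
#' @param combo_dist Named numeric vector or two-column data frame
#'   (`combo`, `prob`) giving the generating probability of each edit
#'   combination (combo strings as in [format_combo()]; `""` = unedited).
#'   Probabilities must sum to 1.
#' @param error_rate Per-base substitution error probability in `[0, 0.1]`
#'   (default 0.001).
#' @param n_reads Number of reads (default 20000).
#' @param read_length Read length; default the full amplicon, which is also
#'   what [align_and_call()] expects.
#' @param seed Integer seed; the generator is byte-deterministic given it.
#' @return An object of class `sim_profile`.
#' @export
sim_profile <- function(spec, combo_dist, error_rate = 0.001,
                        n_reads = 20000L, read_length = NULL, seed = 1L) {
  stopifnot(inherits(spec, "protospacer_spec"))
  if (is.data.frame(combo_dist)) {
    combo_dist <- setNames(combo_dist$prob, combo_dist$combo)
  }
  if (is.null(names(combo_dist))) abort("`combo_dist` must be named by combo.")
  names(combo_dist)[is.na(names(combo_dist))] <- ""
  if (abs(sum(combo_dist) - 1) > 1e-9) {
    abort("combo probabilities must sum to 1.")
  }
  if (error_rate < 0 || error_rate > 0.1) {
    abort("`error_rate` must lie in [0, 0.1].")
  }
  # validate combos against the reference now, not at generation time
  for (cm in names(combo_dist)) {
    e <- parse_combo(cm)
    if (nrow(e)) {
      refb <- proto_base(spec, e$position)
      if (any(refb != e$ref)) {
        abort(paste0("combo '", cm, "' ref base(s) disagree with the reference."))
      }
    }
  }
  structure(list(spec = spec, combo_dist = combo_dist,
                 error_rate = error_rate, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length %||% nchar(spec$reference)),
                 seed = as.integer(seed)),
            class = "sim_profile")
}

#' Simulate amplicon sequencing reads
#'
#' Each read draws a combo from the generating distribution, applies its
#' substitutions to the reference, then applies i.i.d. uniform substitution
#' errors at `error_rate` (each erroneous base is replaced by one of the
#' three other bases uniformly). Qualities are a constant 'I'.
#'
#' @param profile A [sim_profile()].
#' @param path Optional output path; a FASTQ file (gzip if `.gz`) is written
#'   and the tibble returned invisibly.
#' @return A tibble with columns `id`, `sequence`, `quality`, plus a
#'   `true_combo` column recording the generating combo of each read.
#' @export
simulate_amplicon_reads <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "sim_profile"))
  spec <- profile$spec
  L <- nchar(spec$reference)
  if (profile$read_length > L) abort("read_length exceeds the reference.")
  n <- profile$n_reads
  combos <- names(profile$combo_dist)

  reads <- withr::with_seed(profile$seed, {
    idx <- sample.int(length(combos), n, replace = TRUE,
                      prob = profile$combo_dist)
    ref_chars <- strsplit(spec$reference, "")[[1]]
    mat <- matrix(ref_chars, nrow = L, ncol = n)
    for (j in seq_along(combos)) {
      cols <- which(idx == j)
      if (length(cols) == 0L) next
      e <- parse_combo(combos[j])
      if (nrow(e) == 0L) next
      sidx <- position_index(spec, e$position)
      ridx <- if (spec$strand == "forward") sidx else L - sidx + 1L
      alt <- if (spec$strand == "forward") e$alt else complement_base(e$alt)
      for (k in seq_along(ridx)) mat[ridx[k], cols] <- alt[k]
    }
    if (profile$error_rate > 0) {
      hit <- which(runif(L * n) < profile$error_rate)
      if (length(hit)) {
        # replace by one of the three other bases, uniformly
        others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                        G = c("A", "C", "T"), T = c("A", "C", "G"))
        cur <- mat[hit]
        pick <- sample.int(3L, length(hit), replace = TRUE)
        mat[hit] <- others[cbind(match(cur, rownames(others)), pick)]
      }
    }
    seqs <- do.call(paste0, map(seq_len(L), ~ mat[.x, ]))
    if (profile$read_length < L) seqs <- substr(seqs, 1L, profile$read_length)
    tibble(id = paste0("read_", seq_len(n)), sequence = seqs,
           quality = strrep("I", nchar(seqs)), true_combo = combos[idx])
  })
  if (!is.null(path)) {
    write_fastq(reads, path)
    return(invisible(reads))
  }
  reads
}

#' Screen pool simulation parameters
#'
#' @param variants A tibble with columns `variant_id`, `activity` (true
#'   editing activity in `[0, 1]`) and `input_frequency` (must sum to 1).
#' @param n_cells Number of cells infected (default 1e6).
#' @param gate_fraction Fraction of cells sorted from the top of the
#'   fluorescence distribution (default 0.05, the top-5% EGFP gate).
#' @param reporter_noise_sd Gaussian sd of the fluorescence readout around
#'   the true activity (default 0.1).
#' @param seed Integer seed.
#' @return An object of class `screen_sim_spec`.
#' @export
screen_sim_spec <- function(variants, n_cells = 1e6, gate_fraction = 0.05,
                            reporter_noise_sd = 0.1, seed = 1L) {
  variants <- as_tibble(variants)
  stopifnot(all(c("variant_id", "activity", "input_frequency") %in%
                  names(variants)))
  if (abs(sum(variants$input_frequency) - 1) > 1e-9) {
    abort("input frequencies must sum to 1.")
  }
  if (gate_fraction <= 0 || gate_fraction >= 1) {
    abort("`gate_fraction` must lie in (0, 1).")
  }
  if (reporter_noise_sd < 0) abort("`reporter_noise_sd` must be >= 0.")
  n_sorted <- round(gate_fraction * n_cells)
  if (n_sorted < 1) abort("gate is degenerate: it contains no cells.")
  structure(list(variants = variants, n_cells = as.integer(n_cells),
                 gate_fraction = gate_fraction,
                 reporter_noise_sd = reporter_noise_sd,
                 seed = as.integer(seed)),
            class = "screen_sim_spec")
}

#' Simulate FACS-gated screen pools
#'
#' Cells are assigned variants multinomially by input frequency; each cell's
#' fluorescence is its variant's true activity plus Gaussian noise; the top
#' `gate_fraction` of cells by fluorescence form the sorted pool.
#'
#' @param sim A [screen_sim_spec()].
#' @param replicate Replicate label attached to the output (default 1);
#'   the effective seed is `seed + replicate - 1`.
#' @return A long tibble with columns `replicate`, `pool`
#'   (`"input"`/`"sorted"`), `variant_id`, `count` — directly consumable by
#'   [enrichment_scores()]. Input counts sum to `n_cells`, sorted counts to
#'   `round(gate_fraction * n_cells)`.
#' @export
simulate_screen_pools <- function(sim, replicate = 1L) {
  stopifnot(inherits(sim, "screen_sim_spec"))
  v <- sim$variants
  k <- nrow(v)
  n <- sim$n_cells
  n_sorted <- round(sim$gate_fraction * n)
  out <- withr::with_seed(sim$seed + as.integer(replicate) - 1L, {
    input_counts <- as.integer(rmultinom(1L, n, v$input_frequency))
    cell_variant <- rep.int(seq_len(k), input_counts)
    fluor <- v$activity[cell_variant] +
      rnorm(n, sd = sim$reporter_noise_sd)
    gate <- order(fluor, decreasing = TRUE)[seq_len(n_sorted)]
    sorted_counts <- tabulate(cell_variant[gate], nbins = k)
    bind_rows(
      tibble(pool = "input", variant_id = v$variant_id, count = input_counts),
      tibble(pool = "sorted", variant_id = v$variant_id, count = sorted_counts)
    )
  })
  mutate(out, replicate = as.integer(replicate), .before = 1L)
}

#' Bundled synthetic locus fixtures
#'
#' Synthetic amplicons whose protospacer layout reproduces the positional
#' logic of the package's worked loci. The sequences are synthetic
#' stand-ins honouring the codon/position constraints, not genomic sequence.
#'
#' \describe{
#'   \item{hfe_c282y}{Hereditary-hemochromatosis correction model: editable
#'     adenines at +1/+5/+8, therapeutic target +5 (TAC -> TGC restores the
#'     wild-type cysteine codon), missense-risk bystanders at +1
#'     (ACG -> GCG) and +8 (CAG -> CGG).}
#'   \item{hbb_s}{Sickle-allele model: target adenine +7, bystander adenines
#'     +9 and +12 whose edits are synonymous (ACA -> ACG, CCA -> CCG).}
#'   \item{pcsk9_intron1}{Splice-donor disruption model: target +6, bystander
#'     adenine at -1. The -1 context is intronic in the real locus; the
#'     synthetic fixture gives it a codon context whose edit is missense so
#'     deleterious-bystander bookkeeping is exercised.}
#'   \item{stop_egfp_reporter}{The screen's reporter: 27-nt insert between
#'     the ATG and the EGFP CDS with an in-frame TGA rescued by +7 A-to-G.}
#' }
#'
#' @param name One of `"hfe_c282y"`, `"hbb_s"`, `"pcsk9_intron1"`,
#'   `"stop_egfp_reporter"`.
#' @return A list with `$spec` ([protospacer_spec()]) and either `$target`
#'   ([target_spec()]) or `$construct` ([reporter_construct()]).
#' @examples
#' fx <- make_locus_fixture("hfe_c282y")
#' fx$target$consequences
#' @export
make_locus_fixture <- function(name = c("hfe_c282y", "hbb_s",
                                        "pcsk9_intron1",
                                        "stop_egfp_reporter")) {
  name <- match.arg(name)
  switch(
    name,
    hfe_c282y = {
      up <- "GATCCTGGGCTACGTCCAGGAGCTCGGCTC"
      proto <- "ACGTACCAGCTGCTGCTGCT"
      down <- "TGGAGGATACCTCACCCTGGAGCACCTGGC"
      spec <- protospacer_spec(paste0(up, proto, "CGG", down),
                               protospacer_offset = nchar(up))
      target <- target_spec(
        name = "hfe_c282y",
        editable_positions = c(1L, 5L, 8L), target_position = 5L,
        consequences = tibble(
          position = c(1L, 5L, 8L),
          ref_codon = c("ACG", "TAC", "CAG"),
          edited_codon = c("GCG", "TGC", "CGG")))
      list(spec = spec, target = target)
    },
    hbb_s = {
      up <- "CCGTTACTGCCCTGTGGGGCAAGGTGGGCT"
      proto <- "GTGCTGACACCATGGTGCTG"
      down <- "TGGTGGTGAGGCCCTGGGCAGGTTGGTATC"
      spec <- protospacer_spec(paste0(up, proto, "CAC", down),
                               protospacer_offset = nchar(up))
      target <- target_spec(
        name = "hbb_s",
        editable_positions = c(7L, 9L, 12L), target_position = 7L,
        consequences = tibble(
          position = c(7L, 9L, 12L),
          ref_codon = c("ACA", "ACA", "CCA"),
          edited_codon = c("GCA", "ACG", "CCG")))
      list(spec = spec, target = target)
    },
    pcsk9_intron1 = {
      up <- "CTGGGCTCCTGGTGCGTGTGGGCGTGGGCA"  # ends in the -1 adenine
      proto <- "GTCGTACGGCGTGCGTGCGT"
      down <- "CGGTGCTGGGCGTGTGGCTGGGCGTCTTGC"
      spec <- protospacer_spec(paste0(up, proto, "TGG", down),
                               protospacer_offset = nchar(up))
      target <- target_spec(
        name = "pcsk9_intron1",
        editable_positions = c(-1L, 6L), target_position = 6L,
        consequences = tibble(
          position = c(-1L, 6L),
          ref_codon = c("AGT", "ACG"),
          edited_codon = c("GGT", "GCG")))
      list(spec = spec, target = target)
    },
    stop_egfp_reporter = {
      construct <- reporter_construct()
      list(spec = construct$spec, construct = construct)
    }
  )
}

#' Read a target specification from YAML
#'
#' The YAML mirrors [target_spec()]: `name`, `editable_positions`,
#' `target_position`, and a `consequences` list of
#' `{position, ref_codon, edited_codon}` records. The bundled fixtures
#' (`hfe_c282y.yaml`, `hbb_s.yaml`, `pcsk9_intron1.yaml`) live in
#' `system.file("extdata", package = "bescreen")`.
#'
#' @param path Path to a YAML file, or a bare fixture name.
#' @return A [target_spec()].
#' @export
read_target_spec <- function(path) {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", paste0(path, ".yaml"),
                           package = "bescreen")
    if (nzchar(bundled)) path <- bundled else {
      abort(paste0("no such file or bundled fixture: ", path))
    }
  }
  y <- yaml::read_yaml(path)
  target_spec(name = y$name,
              editable_positions = as.integer(y$editable_positions),
              target_position = as.integer(y$target_position),
              consequences = bind_rows(map(y$consequences, as_tibble)))
}
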