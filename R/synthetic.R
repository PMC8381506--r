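# Synthetic genomes with planted repeats of the four structural
# archetypes plus ground-truth annotation.  The generator emulates
# structure, not phylogeny: a uniform-ACGT background into which tandem
# satellite arrays (noisy ATTCC pentamers; mutated 171 bp alphoid
# monomers), dispersed ~300 bp Alu-like copies and ~6 kb LINE-like
# copies (optionally 5'-truncated) are written, each derived from a
# shared consensus library so that separate genomes simulate the same
# repeat families.

#' Simulation parameters
#'
#' Densities are target fractions of genome bp per class; planted copies
#' are mutated by per-base substitutions (`mutation_rate`) and, for the
#' dispersed classes, indels (`indel_rate`).  `library_seed` controls
#' the consensus library only, so train/validation/test genomes built
#' with different `seed`s but one `library_seed` share repeat families.
#'
#' @param genome_length Genome length in bp.
#' @param densities Named numeric vector of per-class bp fractions with
#'   names `HSAT23`, `ALPHOID`, `ALU`, `LINE1`; must sum to < 1.
#' @param mutation_rate Per-base substitution probability in planted
#'   copies.
#' @param indel_rate Per-base indel probability in Alu/LINE copies.
#' @param seed Seed for background, placement and mutation.
#' @param library_seed Seed for the consensus library (default: `seed`).
#' @param hsat_motif Satellite pentamer motif (default `ATTCC`).
#' @param alphoid_monomer_length Alphoid monomer length (default 171).
#' @param alu_length Alu consensus length (default 300).
#' @param line_length LINE-1 consensus length (default 6000).
#' @param line_truncation_prob Probability that a LINE copy is
#'   5'-truncated at a uniform point (default 0.5).
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L,
                       densities = c(HSAT23 = 0.02, ALPHOID = 0.02,
                                     ALU = 0.05, LINE1 = 0.08),
                       mutation_rate = 0.05, indel_rate = 0.005,
                       seed = 0L, library_seed = NULL,
                       hsat_motif = "ATTCC",
                       alphoid_monomer_length = 171L,
                       alu_length = 300L, line_length = 6000L,
                       line_truncation_prob = 0.5) {
  stopifnot(all(names(densities) %in% names(REPEAT_CLASSES)[2:5]),
            all(densities >= 0), sum(densities) < 1,
            mutation_rate >= 0, mutation_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            line_truncation_prob >= 0, line_truncation_prob <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 densities = densities,
                 mutation_rate = mutation_rate, indel_rate = indel_rate,
                 seed = as.integer(seed),
                 library_seed = if (is.null(library_seed))
                   as.integer(seed) else as.integer(library_seed),
                 hsat_motif = toupper(hsat_motif),
                 alphoid_monomer_length = as.integer(alphoid_monomer_length),
                 alu_length = as.integer(alu_length),
                 line_length = as.integer(line_length),
                 line_truncation_prob = line_truncation_prob),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitutions: each base flips to a different base with prob `rate`.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

# Indels: each base independently deleted or followed by a random
# insertion, with prob `rate` each way.
indel_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  keep <- stats::runif(length(chars)) >= rate
  ins <- stats::runif(length(chars)) < rate
  out <- character(0)
  for (i in seq_along(chars)) {
    if (keep[i]) out <- c(out, chars[i])
    if (ins[i]) out <- c(out, sample(c("A", "C", "G", "T"), 1L))
  }
  paste(out, collapse = "")
}

#' Build the consensus library for a simulation
#'
#' @param config A [sim_config()].
#' @return List with `hsat_motif`, `alphoid_monomer`, `alu_consensus`,
#'   `line_consensus` (character sequences).
#' @export
make_repeat_library <- function(config) {
  set.seed(config$library_seed)
  list(hsat_motif = config$hsat_motif,
       alphoid_monomer = random_dna(config$alphoid_monomer_length),
       alu_consensus = random_dna(config$alu_length),
       line_consensus = random_dna(config$line_length))
}

# One planted element: returns list(seq, source).  `budget` caps tandem
# array / LINE length so a class never overshoots its density target by
# more than one monomer-scale unit.
propose_element <- function(class_name, config, lib, budget) {
  mu <- config$mutation_rate
  switch(class_name,
    HSAT23 = {
      motif_len <- nchar(lib$hsat_motif)
      n_copies <- sample(60:240, 1L)                     # 300-1200 bp arrays
      n_copies <- max(3L, min(n_copies, budget %/% motif_len))
      copies <- vapply(seq_len(n_copies),
                       function(i) mutate_seq(lib$hsat_motif, mu), "")
      list(seq = paste(copies, collapse = ""), source = "HSAT23_motif")
    },
    ALPHOID = {
      mono_len <- nchar(lib$alphoid_monomer)
      n_copies <- sample(3:8, 1L)
      n_copies <- max(3L, min(n_copies, budget %/% mono_len))
      copies <- vapply(seq_len(n_copies),
                       function(i) mutate_seq(lib$alphoid_monomer, mu), "")
      list(seq = paste(copies, collapse = ""), source = "ALPHOID_monomer")
    },
    ALU = {
      s <- indel_seq(mutate_seq(lib$alu_consensus, mu), config$indel_rate)
      list(seq = s, source = "ALU_consensus")
    },
    LINE1 = {
      s <- lib$line_consensus
      if (stats::runif(1L) < config$line_truncation_prob) {
        # 5' truncation at a uniform point; keep at least 500 bp
        cut <- sample.int(nchar(s) - 500L, 1L)
        s <- substr(s, cut + 1L, nchar(s))
      }
      if (nchar(s) > budget && budget >= 500L)
        s <- substr(s, nchar(s) - budget + 1L, nchar(s))  # truncate 5' more
      s <- indel_seq(mutate_seq(s, mu), config$indel_rate)
      list(seq = s, source = "LINE1_consensus")
    },
    stop("unknown archetype ", class_name))
}

#' Simulate a genome with planted repeats
#'
#' Elements are planted by overwriting stretches of the uniform
#' background at uniformly drawn non-overlapping loci (rejection
#' sampling), so the genome length stays fixed and truth intervals are
#' exact and unnested.  Per class, elements are added until the planted
#' bp reach the configured density; achieved densities land within
#' +/- 20% of the target.  Fully determined by `seed`/`library_seed`.
#'
#' @param config A [sim_config()].
#' @param sequence_name Name for the simulated record.
#' @return A `sim_result`: list with `sequence` (string), `truth`
#'   (annotation records data frame, sorted by start), `provenance`
#'   (per-element archetype/source/placement table), `library` and
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config(), sequence_name = "sim") {
  lib <- make_repeat_library(config)
  glen <- config$genome_length
  # feasibility: each requested class must fit at least one minimal element
  min_len <- c(HSAT23 = 3L * nchar(lib$hsat_motif),
               ALPHOID = 3L * config$alphoid_monomer_length,
               ALU = config$alu_length, LINE1 = 500L)
  for (nm in names(config$densities)) {
    target <- config$densities[[nm]] * glen
    if (target > 0 && target < min_len[[nm]] * 0.8)
      stop("density for ", nm, " infeasible for genome_length ", glen,
           ": target ", round(target), " bp < minimal element")
  }
  set.seed(config$seed)
  genome <- strsplit(random_dna(glen), "", fixed = TRUE)[[1L]]
  placed_start <- integer(0); placed_end <- integer(0)
  truth <- list(); prov <- list()
  for (nm in c("LINE1", "ALPHOID", "HSAT23", "ALU")) {  # large first
    target <- round(config$densities[[nm]] * glen)
    if (is.null(config$densities[[nm]]) || target <= 0) next
    planted <- 0L
    # stop once the shortfall is smaller than half a minimal element, so
    # achieved bp stay within +/-20% of the target on both sides
    while (planted < target &&
           (target - planted) >= 0.5 * min_len[[nm]]) {
      el <- propose_element(nm, config, lib, budget = target - planted +
                              as.integer(min_len[[nm]]))
      len <- nchar(el$seq)
      # rejection-sample a locus keeping >= 20 bp between elements
      pos <- NA_integer_
      for (try in 1:200) {
        cand <- sample.int(glen - len + 1L, 1L) - 1L
        if (!any(cand < placed_end + 20L &
                 cand + len + 20L > placed_start)) {
          pos <- cand; break
        }
      }
      if (is.na(pos))
        stop("could not place ", nm, " element: genome too dense")
      genome[(pos + 1L):(pos + len)] <- strsplit(el$seq, "", fixed = TRUE)[[1L]]
      placed_start <- c(placed_start, pos)
      placed_end <- c(placed_end, pos + len)
      truth[[length(truth) + 1L]] <- data.frame(
        sequence_name = sequence_name, start = pos, end = pos + len,
        class_id = repeat_class_id(nm), class_name = nm,
        source_id = el$source, stringsAsFactors = FALSE)
      prov[[length(prov) + 1L]] <- data.frame(
        archetype = nm, source = el$source, start = pos, end = pos + len,
        length = len, stringsAsFactors = FALSE)
      planted <- planted + len
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sequence_name = character(0), start = integer(0),
               end = integer(0), class_id = integer(0),
               class_name = character(0), source_id = character(0),
               stringsAsFactors = FALSE)
  ord <- order(truth$start)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  prov <- if (length(prov)) do.call(rbind, prov)[ord, , drop = FALSE] else
    data.frame(archetype = character(0), source = character(0),
               start = integer(0), end = integer(0), length = integer(0))
  rownames(prov) <- NULL
  structure(list(sequence = paste(genome, collapse = ""),
                 sequence_name = sequence_name,
                 truth = truth, provenance = prov,
                 library = lib, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  bp <- tapply(x$truth$end - x$truth$start, x$truth$class_name, sum)
  cat(sprintf("<sim_result> %s: %d bp, %d planted elements\n",
              x$sequence_name, nchar(x$sequence), nrow(x$truth)))
  for (nm in names(bp))
    cat(sprintf("  %-8s %6d bp (%.2f%%)\n", nm, bp[[nm]],
                100 * bp[[nm]] / nchar(x$sequence)))
  invisible(x)
}

#' Write a simulated genome as a test fixture
#'
#' Emits `genome.fa` (FASTA), `truth.bed` (BED5, score 0) and
#' `provenance.tsv` into `dir`; all round-trip through the package's
#' own readers.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(stats::setNames(sim$sequence,
                                                  sim$sequence_name))
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  truth <- sim$truth
  truth$score <- 0
  write_bed(truth, sim$sequence_name, file.path(dir, "truth.bed"))
  utils::write.table(sim$provenance, file.path(dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
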