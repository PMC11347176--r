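# Packaged study presets. The structure composition (three stems; 12
# canonical plus 4 G-T/T-G wobble pairs; 8-pair Stem 3; conserved core at
# positions 1-8 and 34-64) and the kinetic scale (catalytic efficiency about
# 200 M^-1 min^-1, non-saturable below 1.5 mM substrate, a 10-fold weaker
# parent isolate) follow the published characterization of the Apollon
# deoxyribozyme. Exact pair coordinates and the 85-nt reference sequence are
# NOT published; the ones packaged here are a synthetic reconstruction built
# to satisfy the printed composition, and every analysis treating them should
# be read as operating on a stand-in, not the real isolate.

# synthetic 85-nt reference; paired positions are complementary by design
apollon_synthetic_ref <-
  "CGGCATGCGACTTTCGTGATGCTCGGCTCAGTCGGACGGTGTTAGCTAGAATAACTTGTTGTCCTCGTCCCTGTCGATCGAATTC"

#' Synthetic reference sequence for the packaged deoxyribozyme model
#'
#' An 85-nt stand-in for the mutagenized region of the selection library,
#' constructed so that every pair of [apollon_structure()] is complementary
#' (Watson-Crick, or G-T at the wobble positions). The true isolate sequence
#' is not bundled; this synthetic reference exists so simulations and
#' worked examples are fully reproducible.
#'
#' @return An 85-character A/C/G/T string.
#' @export
apollon_reference <- function() apollon_synthetic_ref

#' Packaged secondary-structure model (synthetic coordinates)
#'
#' Three stems over the 85-nt synthetic reference: Stem 1 (4 canonical
#' pairs, including the 3-22 pair probed by mutant cycles), Stem 2 (4
#' canonical pairs, deletable), and Stem 3 (8 pairs: 4 canonical + 4 G-T/T-G
#' wobbles in a G-rich stretch). Composition matches the published model
#' (12 canonical + 4 wobble pairs, hence 20 expected imino signals);
#' coordinates are reconstructed, not published.
#'
#' @return A [structure_model()].
#' @export
apollon_structure <- function() {
  pairs <- tibble(
    i = c(3L, 4L, 5L, 6L,
          9L, 10L, 11L, 12L,
          34L, 35L, 36L, 37L, 38L, 39L, 40L, 41L),
    j = c(22L, 21L, 20L, 19L,
          33L, 32L, 31L, 30L,
          64L, 63L, 62L, 61L, 60L, 59L, 58L, 57L),
    type = rep(c("canonical", "wobble"), c(12L, 4L)),
    stem = rep(c("Stem1", "Stem2", "Stem3"), c(4L, 4L, 8L))
  )
  structure_model(pairs, nchar(apollon_synthetic_ref))
}

#' Packaged fitness model for reselection simulations
#'
#' Encodes, generatively, what the comparative analysis of the selected pool
#' reads out: a conserved catalytic core (positions 1-8 and 34-64, a few
#' mismatches tolerated) and the requirement to form most of Stem 3 (at
#' least 7 of its 8 pairs) plus most of Stem 1. Qualifying variants are
#' fully active; everything else retains 1% background activity.
#'
#' @param active_level,background_level Activity levels in `[0, 1]`.
#' @param graded Use the graded fitness variant (see [fitness_model()]).
#' @return A [fitness_model()].
#' @export
apollon_fitness <- function(active_level = 1.0, background_level = 0.01,
                            graded = FALSE) {
  fitness_model(core_positions = c(1:8, 34:64), core_tolerance = 3L,
                stems = list(Stem1 = 3L, Stem3 = 7L),
                active_level = active_level,
                background_level = background_level, graded = graded)
}

#' Kinetic parameter presets
#'
#' Michaelis-Menten presets for the optimized deoxyribozyme (`"apollon2"`)
#' and the parent isolate (`"apollon1"`), at 1 uM enzyme. The substrate
#' cannot be saturated below 1.5 mM, so Km lies far above the tested range;
#' the well-identified quantity is the catalytic efficiency kcat/Km, set to
#' 200 M^-1 min^-1 for the optimized variant and 10-fold lower for the
#' parent. With Km = 50 mM this puts kobs at 1.5 mM substrate at ~0.29
#' min^-1 for the optimized variant.
#'
#' @param which `"apollon2"` or `"apollon1"`.
#' @return A list with `vmax` (M/min), `km` (M), `enzyme_conc` (M), and the
#'   implied `kcat` (1/min).
#' @export
apollon_kinetic_preset <- function(which = c("apollon2", "apollon1")) {
  which <- match.arg(which)
  enzyme <- 1e-6                      # 1 uM deoxyribozyme
  km <- 0.05                          # far above the 1.5 mM tested maximum
  kcat <- switch(which, apollon2 = 200 * km, apollon1 = 20 * km)
  list(vmax = kcat * enzyme, km = km, enzyme_conc = enzyme, kcat = kcat)
}
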