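# Shared fixtures: sequences of the two lead peptides and the albumin
# Cys34-containing tryptic fragment, plus small helpers.

WSC02 <- "IVRWSKKVPCVS"
JM21 <- "ILRWSRKLPCVS"
ALB_21_41 <- "ALVLIAFAQYLQQCPFEDHVK"

# independent residue monoisotopic mass table (Unimod values, frozen here
# as an oracle that bypasses the package's elemental-composition route)
RESIDUE_MASS_ORACLE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

oracle_peptide_mass <- function(sequence) {
  sum(RESIDUE_MASS_ORACLE[strsplit(sequence, "")[[1]]]) + 18.010565
}

random_sequence <- function(n) {
  paste(sample(names(RESIDUE_MASS_ORACLE), n, replace = TRUE),
        collapse = "")
}

# small scenario used by round-trip tests (fast: few species, short grid)
small_scenario <- function(seed, noise_cv = 0, decoy_density = 0,
                           mz_jitter_ppm = 0, times = c(0, 2, 5, 10, 20),
                           ...) {
  simulation_scenario(
    analyte_seq = JM21, carrier_seq = ALB_21_41,
    free_half_life = 1.7, formation_half_time = 2.5,
    bound_species = data.frame(
      name = c("Cys-adduct", "HSA-crosslink"),
      kind = c("Cys", "crosslink"), branching = c(0.4, 0.6),
      half_life = c(Inf, Inf), stringsAsFactors = FALSE),
    times = times, charges_free = c(2, 3), charges_bound = c(3, 4),
    noise_cv = noise_cv, mz_jitter_ppm = mz_jitter_ppm,
    decoy_density = decoy_density, seed = seed, ...)
}
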