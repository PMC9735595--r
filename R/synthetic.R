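# Synthetic-data generator: plasma incubation time courses (centroided
# peak lists with known species composition and a ground-truth manifest)
# and antibody-competition activity tables. Every stochastic element is
# driven by the scenario's mandatory seed; identical (scenario, seed)
# pairs give identical output.

#' Define a plasma-incubation simulation scenario
#'
#' Describes a spiked-plasma experiment: a free analyte peptide that is
#' degraded by proteases and simultaneously converted (first order) into
#' longer-lived disulfide-bound pools (LMW thiol adducts, homodimer,
#' albumin-fragment crosslink), sampled as centroided LC-MS peak lists at
#' the given incubation times.
#'
#' @param analyte_seq Analyte peptide sequence.
#' @param carrier_seq Carrier (albumin) fragment used for crosslink
#'   species.
#' @param free_half_life Degradation half-life of the free pool (min).
#' @param formation_half_time Half-time of free-to-bound conversion (min);
#'   `Inf` disables conversion.
#' @param bound_species data.frame with columns `name`, `kind` (an adduct
#'   name from [delta_library()], `"dimer"`, or `"crosslink"`),
#'   `branching` (fractions of the conversion flux, summing to 1) and
#'   `half_life` (degradation half-life of the bound pool, min; `Inf` =
#'   stable).
#' @param initial_fractions Named numeric vector of initial pool
#'   fractions; must sum to at most 1 (default: all free). Names are
#'   `"free"` plus `bound_species$name`.
#' @param times Sampling times in minutes.
#' @param charges_free,charges_bound Charge states simulated for the free
#'   peptide and the bound species.
#' @param noise_cv Multiplicative log-normal coefficient of variation on
#'   peak intensities.
#' @param mz_jitter_ppm Standard deviation of m/z scatter in ppm.
#' @param decoy_density Expected number of decoy peaks per scan (Poisson).
#' @param intensity_scale Peak height corresponding to abundance 1.
#' @param rt_sigma_min Gaussian elution peak width (SD, minutes).
#' @param rt_step_min Scan spacing (minutes).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(
    analyte_seq = "ILRWSRKLPCVS",
    carrier_seq = "ALVLIAFAQYLQQCPFEDHVK",
    free_half_life = 1.7,
    formation_half_time = 2.5,
    bound_species = data.frame(
      name = c("Cys-adduct", "HSA-crosslink"),
      kind = c("Cys", "crosslink"),
      branching = c(0.4, 0.6),
      half_life = c(Inf, Inf),
      stringsAsFactors = FALSE),
    initial_fractions = NULL,
    times = c(0, 5, 10, 20, 30, 45, 60, 90, 120),
    charges_free = c(1, 2, 3),
    charges_bound = c(3, 4),
    noise_cv = 0.1,
    mz_jitter_ppm = 3,
    decoy_density = 5,
    intensity_scale = 1e6,
    rt_sigma_min = 0.06,
    rt_step_min = 0.02,
    seed) {
  if (missing(seed)) stop("a seed is mandatory (no hidden random state)")
  .check_sequence(analyte_seq)
  .check_sequence(carrier_seq)
  stopifnot(free_half_life > 0, formation_half_time > 0,
            is.data.frame(bound_species),
            all(c("name", "kind", "branching", "half_life") %in%
                  names(bound_species)),
            all(bound_species$half_life > 0),
            noise_cv >= 0, mz_jitter_ppm >= 0, decoy_density >= 0)
  if (nrow(bound_species) &&
      abs(sum(bound_species$branching) - 1) > 1e-9) {
    stop("bound_species$branching must sum to 1")
  }
  pools <- c("free", bound_species$name)
  if (is.null(initial_fractions)) {
    initial_fractions <- stats::setNames(c(1, rep(0, nrow(bound_species))),
                                         pools)
  }
  if (!all(names(initial_fractions) %in% pools) ||
      sum(initial_fractions) > 1 + 1e-9) {
    stop("initial_fractions must be named after the pools and sum to <= 1")
  }
  structure(list(
    analyte_seq = analyte_seq, carrier_seq = carrier_seq,
    free_half_life = free_half_life,
    formation_half_time = formation_half_time,
    bound_species = bound_species,
    initial_fractions = initial_fractions, times = sort(unique(times)),
    charges_free = charges_free, charges_bound = charges_bound,
    noise_cv = noise_cv, mz_jitter_ppm = mz_jitter_ppm,
    decoy_density = decoy_density, intensity_scale = intensity_scale,
    rt_sigma_min = rt_sigma_min, rt_step_min = rt_step_min,
    seed = as.integer(seed)), class = "simulation_scenario")
}

# formula of one simulated species
.species_formula <- function(scenario, name) {
  pf <- peptide_formula(scenario$analyte_seq)
  if (name == "free") return(pf)
  row <- scenario$bound_species[scenario$bound_species$name == name, ]
  stopifnot(nrow(row) == 1)
  switch(row$kind,
    dimer = formula_subtract(formula_add(pf, pf), c(H = 2)),
    crosslink = formula_subtract(
      formula_add(pf, peptide_formula(scenario$carrier_seq)), c(H = 2)),
    formula_add(pf, parse_formula(adduct_delta(row$kind)$formula)))
}

#' Species candidate table for a scenario
#'
#' The simulated species in the candidate-table format the quantification
#' module consumes.
#'
#' @param scenario A [simulation_scenario()].
#' @return A data.frame with `label`, `class`, `mass`, `formula`.
#' @export
scenario_species <- function(scenario) {
  pools <- c("free", scenario$bound_species$name)
  cls <- c("free", vapply(scenario$bound_species$kind, function(k)
    switch(k, dimer = "dimer", crosslink = "crosslink", "adduct"), ""))
  do.call(rbind, lapply(seq_along(pools), function(i) {
    f <- .species_formula(scenario, pools[i])
    data.frame(label = pools[i], class = cls[i], mass = formula_mass(f),
               formula = format_formula(f), stringsAsFactors = FALSE)
  }))
}

#' Closed-form two-compartment species kinetics
#'
#' The free pool decays with total rate `a = k_deg + k_conv` (degradation
#' plus conversion); each bound pool `i` receives flux
#' `branching_i * k_conv * F(t)` and degrades with its own rate `k_i`:
#' \deqn{F(t) = F0 e^{-a t}}
#' \deqn{B_i(t) = B_{i0} e^{-k_i t} + \frac{c_i F_0}{k_i - a}
#'   (e^{-a t} - e^{-k_i t})}
#' (with the `k_i = a` limit `c_i F_0 t e^{-a t}`). No ODE solver is
#' needed; the solution is exact and deterministic.
#'
#' @param scenario A [simulation_scenario()].
#' @param times Optional override of the scenario sampling times.
#' @return A data.frame with columns `time_min`, `species`, `abundance`.
#' @export
simulate_species_kinetics <- function(scenario, times = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  t <- times %||% scenario$times
  kd <- log(2) / scenario$free_half_life
  kc <- if (is.finite(scenario$formation_half_time))
    log(2) / scenario$formation_half_time else 0
  a <- kd + kc
  f0 <- scenario$initial_fractions[["free"]]
  rows <- list(data.frame(time_min = t, species = "free",
                          abundance = f0 * exp(-a * t),
                          stringsAsFactors = FALSE))
  bs <- scenario$bound_species
  for (i in seq_len(nrow(bs))) {
    ki <- log(2) / bs$half_life[i]       # 0 when half_life is Inf
    ci <- bs$branching[i] * kc
    b0 <- scenario$initial_fractions[bs$name[i]]
    b0 <- if (is.na(b0)) 0 else unname(b0)
    inflow <- if (abs(ki - a) > 1e-12) {
      ci * f0 * (exp(-a * t) - exp(-ki * t)) / (ki - a)
    } else {
      ci * f0 * t * exp(-a * t)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      time_min = t, species = bs$name[i],
      abundance = b0 * exp(-ki * t) + inflow, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emit centroided peak lists for a simulated time course
#'
#' For each sampling time, builds a centroided peak list: every species
#' elutes as a Gaussian profile (height proportional to its current
#' abundance) whose isotope-cluster m/z values and relative intensities
#' come from [isotope_pattern()], with log-normal intensity noise and ppm
#' m/z jitter per the scenario. Decoy peaks are placed at least 50 ppm
#' away from any true species isotopologue.
#'
#' @param scenario A [simulation_scenario()].
#' @param abundances Optional precomputed [simulate_species_kinetics()]
#'   table.
#' @return A list of runs `list(time, peaks, replicate)` with attribute
#'   `manifest`: the ground-truth data.frame of per (time, species) true
#'   abundance and true top-isotopologue XIC area (summed over the
#'   configured charges).
#' @export
emit_peaklists <- function(scenario, abundances = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  ab <- abundances %||% simulate_species_kinetics(scenario)
  species <- scenario_species(scenario)
  nsp <- nrow(species)
  # per-species elution apex, spaced along the gradient
  apex <- 8 + 1.5 * (seq_len(nsp) - 1)
  sig <- scenario$rt_sigma_min
  rt_grid <- seq(min(apex) - 4 * sig, max(apex) + 4 * sig,
                 by = scenario$rt_step_min)
  # theoretical isotope clusters per species x charge
  clusters <- list()
  for (i in seq_len(nsp)) {
    charges <- if (species$class[i] == "free") scenario$charges_free else
      scenario$charges_bound
    clusters[[i]] <- lapply(charges, function(z)
      isotope_pattern(species$formula[i], z))
  }
  true_mzs <- unlist(lapply(clusters, function(cl)
    unlist(lapply(cl, function(p) p$mz))))
  sdlog <- if (scenario$noise_cv > 0)
    sqrt(log(1 + scenario$noise_cv^2)) else 0

  gauss_area <- sig * sqrt(2 * pi)
  runs <- list()
  manifest <- list()
  for (tm in scenario$times) {
    rows <- list()
    for (i in seq_len(nsp)) {
      abund <- ab$abundance[ab$time_min == tm & ab$species == species$label[i]]
      charges <- if (species$class[i] == "free") scenario$charges_free else
        scenario$charges_bound
      zw <- 1 / length(charges)   # split signal evenly across charges
      top_rel <- max(clusters[[i]][[1]]$abundance)
      manifest[[length(manifest) + 1L]] <- data.frame(
        time_min = tm, species = species$label[i], abundance = abund,
        true_area = abund * scenario$intensity_scale * top_rel * gauss_area,
        stringsAsFactors = FALSE)
      if (abund <= 0) next
      prof <- exp(-(rt_grid - apex[i])^2 / (2 * sig^2))
      keep_rt <- which(prof > 1e-6)
      for (j in seq_along(charges)) {
        pat <- clusters[[i]][[j]]
        for (k in seq_len(nrow(pat))) {
          h <- abund * scenario$intensity_scale * zw * pat$abundance[k]
          inten <- h * prof[keep_rt]
          if (sdlog > 0) inten <- inten * exp(stats::rnorm(length(inten),
                                                           0, sdlog))
          mzv <- pat$mz[k] *
            (1 + stats::rnorm(length(inten), 0,
                              scenario$mz_jitter_ppm) * 1e-6)
          rows[[length(rows) + 1L]] <- data.frame(
            rt_min = rt_grid[keep_rt], mz = mzv, intensity = inten)
        }
      }
    }
    # decoys: uniform m/z, rejected within 50 ppm of any true signal
    if (scenario$decoy_density > 0) {
      nd <- stats::rpois(length(rt_grid), scenario$decoy_density)
      for (s in which(nd > 0)) {
        mzd <- stats::runif(nd[s], 300, 1400)
        ok <- vapply(mzd, function(m)
          all(abs(m - true_mzs) / true_mzs * 1e6 >= 50), TRUE)
        if (!any(ok)) next
        rows[[length(rows) + 1L]] <- data.frame(
          rt_min = rt_grid[s], mz = mzd[ok],
          intensity = stats::rlnorm(sum(ok), log(1e3), 1))
      }
    }
    peaks <- if (length(rows)) do.call(rbind, rows) else
      data.frame(rt_min = numeric(), mz = numeric(), intensity = numeric())
    peaks <- peaks[order(peaks$rt_min, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    runs[[length(runs) + 1L]] <- list(time = tm, peaks = peaks,
                                      replicate = 1L)
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  attr(runs, "manifest") <- manifest
  attr(runs, "species") <- species
  runs
}

#' Simulate antibody-competition activity tables over incubation time
#'
#' Generates 4PL competition responses for a serial dilution at each
#' timepoint, with the true IC50 following the supplied trajectory and
#' optional multiplicative log-normal noise.
#'
#' @param ic50_trajectory data.frame with columns `time_min` and `ic50`
#'   (same concentration unit as `concentrations`; all `> 0`).
#' @param concentrations Dilution-series concentrations (default an
#'   8-point 3-fold series from 10000 nM).
#' @param hill,top,bottom True 4PL parameters (hill negative for
#'   inhibition).
#' @param noise_cv Multiplicative CV on responses (0 = noise-free).
#' @param seed Mandatory integer seed.
#' @return A data.frame with columns `time_min`, `conc_nM`,
#'   `response_pct`, `replicate`.
#' @export
simulate_activity_tables <- function(ic50_trajectory,
                                     concentrations = 10000 / 3^(0:7),
                                     hill = -1, top = 100, bottom = 0,
                                     noise_cv = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory (no hidden random state)")
  stopifnot(is.data.frame(ic50_trajectory),
            all(c("time_min", "ic50") %in% names(ic50_trajectory)),
            all(ic50_trajectory$ic50 > 0), all(concentrations > 0))
  set.seed(as.integer(seed))
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  rows <- lapply(seq_len(nrow(ic50_trajectory)), function(i) {
    l50 <- log10(ic50_trajectory$ic50[i])
    y <- bottom + (top - bottom) /
      (1 + 10^((l50 - log10(concentrations)) * hill))
    if (sdlog > 0) y <- y * exp(stats::rnorm(length(y), 0, sdlog))
    data.frame(time_min = ic50_trajectory$time_min[i],
               conc_nM = concentrations, response_pct = y,
               replicate = 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a noisy exponential-decay series
#'
#' Convenience generator for parameter-recovery experiments: values on the
#' decay curve `(y0 - plateau) exp(-log(2) t / half_life) + plateau`
#' multiplied by log-normal noise with the given CV.
#'
#' @param times Sampling times (minutes).
#' @param half_life Generating half-life (minutes).
#' @param y0,plateau Curve parameters.
#' @param cv Multiplicative coefficient of variation (0 = noise-free).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (for batch replicate generation under one outer seed).
#' @return Numeric vector of simulated values.
#' @export
simulate_exponential_series <- function(times, half_life, y0 = 100,
                                        plateau = 0, cv = 0.1,
                                        seed = NULL) {
  stopifnot(half_life > 0, cv >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- (y0 - plateau) * exp(-log(2) * times / half_life) + plateau
  if (cv > 0) {
    y <- y * exp(stats::rnorm(length(times), 0, sqrt(log(1 + cv^2))))
  }
  y
}
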