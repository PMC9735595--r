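# Isotope-pattern prediction (nominal-offset aggregation), extracted-ion
# chromatograms at the most intense isotopologue, and trapezoidal peak-area
# integration per timepoint per species.

# natural isotope abundances per element, indexed by nominal mass offset
# from the monoisotopic isotope (offset 0)
.ISOTOPE_DIST <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# averaged spacing between adjacent nominal isotopologues of a peptide
.ISO_SPACING <- 1.00336

.conv <- function(a, b, cap = 64L) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  if (length(out) > cap) out <- out[seq_len(cap)]
  out
}

.dist_power <- function(d, n, cap = 64L) {
  # exponentiation by squaring of the per-atom offset distribution
  out <- 1
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) out <- .conv(out, base, cap)
    base <- .conv(base, base, cap)
    n <- n %/% 2
  }
  out
}

#' Theoretical isotope pattern of an elemental formula
#'
#' Aggregated (nominal-offset) isotopologue distribution obtained by
#' convolving each element's natural-abundance distribution over its atom
#' count. Offset-k peaks sit at `mz(M, z) + k * 1.00336 / z`, where `M` is
#' the monoisotopic mass; fine structure within a nominal offset is not
#' resolved (irrelevant at the +/- 20 ppm windows used downstream).
#'
#' @param formula Elemental formula (named count vector or string).
#' @param charge Positive integer charge state.
#' @param prune_below Relative abundance (fraction of total) below which
#'   peaks are dropped after normalization bookkeeping.
#' @return A data.frame of class `isotope_pattern` with columns `offset`,
#'   `mz`, `abundance` (normalized to the full, pre-pruning distribution).
#'   Attributes: `most_intense` (row index), `retained` (abundance mass
#'   kept after pruning), `mono_mass`, `charge`.
#' @examples
#' isotope_pattern(peptide_formula("G"), charge = 1)
#' @export
isotope_pattern <- function(formula, charge = 1, prune_below = 1e-4) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!length(formula) || all(formula == 0)) stop("empty elemental formula")
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer")
  }
  dist <- 1
  for (el in names(formula)) {
    d <- .ISOTOPE_DIST[[el]]
    if (is.null(d)) stop("no isotope data for element ", el)
    if (formula[[el]] > 0) dist <- .conv(dist, .dist_power(d, formula[[el]]))
  }
  dist <- dist / sum(dist)
  mono <- formula_mass(formula)
  keep <- which(dist >= prune_below)
  out <- data.frame(
    offset = keep - 1L,
    mz = mz(mono, charge) + (keep - 1L) * .ISO_SPACING / charge,
    abundance = dist[keep])
  class(out) <- c("isotope_pattern", "data.frame")
  attr(out, "most_intense") <- which.max(out$abundance)
  attr(out, "retained") <- sum(out$abundance)
  attr(out, "mono_mass") <- mono
  attr(out, "charge") <- charge
  out
}

#' m/z of the most intense isotopologue
#'
#' @param formula Elemental formula (vector or string).
#' @param charge Charge state.
#' @return The m/z value at which an XIC for this species should be
#'   extracted.
#' @export
most_intense_mz <- function(formula, charge) {
  p <- isotope_pattern(formula, charge)
  p$mz[attr(p, "most_intense")]
}

#' Build an extracted-ion chromatogram from a centroided peak list
#'
#' For each retention-time scan, sums the intensities of peaks whose m/z
#' lies within `tolerance` ppm of `target_mz`; scans with no matching peak
#' contribute zero, so the trace covers every scan in the input.
#'
#' @param peaks A data.frame with columns `rt_min`, `mz`, `intensity`.
#' @param target_mz Target m/z.
#' @param tolerance Window half-width in ppm (`> 0`), default 20.
#' @param label Optional species label stored on the trace.
#' @return A data.frame of class `xic_trace` with columns `rt_min`,
#'   `intensity`, one row per scan, sorted by retention time.
#' @export
build_xic <- function(peaks, target_mz, tolerance = 20, label = NULL) {
  stopifnot(is.data.frame(peaks), tolerance > 0, target_mz > 0)
  if (!nrow(peaks)) {
    out <- data.frame(rt_min = numeric(), intensity = numeric())
  } else {
    stopifnot(all(c("rt_min", "mz", "intensity") %in% names(peaks)))
    scans <- sort(unique(peaks$rt_min))
    inwin <- abs(peaks$mz - target_mz) / target_mz * 1e6 <= tolerance
    sums <- numeric(length(scans))
    if (any(inwin)) {
      idx <- match(peaks$rt_min[inwin], scans)
      agg <- rowsum(peaks$intensity[inwin], idx)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    out <- data.frame(rt_min = scans, intensity = sums)
  }
  class(out) <- c("xic_trace", "data.frame")
  attr(out, "target_mz") <- target_mz
  attr(out, "tolerance") <- tolerance
  attr(out, "label") <- label
  out
}

#' Trapezoidal peak-area integration of an XIC
#'
#' @param trace An [build_xic()] trace (or any data.frame with `rt_min`,
#'   `intensity`).
#' @param window Optional `c(start, end)` retention-time interval in
#'   minutes; default integrates the full trace. The window is clipped to
#'   the trace span; an inverted window is an error.
#' @return The non-negative integrated area (intensity x minutes).
#' @export
integrate_area <- function(trace, window = NULL) {
  stopifnot(is.data.frame(trace),
            all(c("rt_min", "intensity") %in% names(trace)))
  if (nrow(trace) < 2) return(0)
  t <- trace$rt_min
  y <- trace$intensity
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    if (window[2] < window[1]) {
      stop("inverted integration window: [", window[1], ", ", window[2], "]")
    }
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]
    y <- y[keep]
    if (length(t) < 2) return(0)
  }
  pracma::trapz(t, y)
}

#' Automatic apex integration window
#'
#' The contiguous region around the trace apex where intensity stays above
#' `frac` of the maximum (a reproducible stand-in for interactive
#' peak-boundary picking).
#'
#' @param trace An XIC trace.
#' @param frac Fraction of the apex intensity defining the boundaries.
#' @return `c(start, end)` in minutes, or `NULL` for an all-zero trace.
#' @export
apex_window <- function(trace, frac = 0.05) {
  if (!nrow(trace) || max(trace$intensity) <= 0) return(NULL)
  apex <- which.max(trace$intensity)
  thr <- frac * trace$intensity[apex]
  lo <- apex
  while (lo > 1 && trace$intensity[lo - 1] > thr) lo <- lo - 1
  hi <- apex
  while (hi < nrow(trace) && trace$intensity[hi + 1] > thr) hi <- hi + 1
  c(trace$rt_min[lo], trace$rt_min[hi])
}

#' Per-timepoint, per-species XIC areas over an incubation time course
#'
#' For every run in the manifest and every candidate species, extracts an
#' XIC at the most intense theoretical isotopologue for each charge state
#' and integrates its area.
#'
#' @param run_manifest A list of runs, each a list with elements `time`
#'   (incubation time, minutes), `peaks` (a peak-list data.frame) and
#'   optionally `replicate`.
#' @param species A candidate table with columns `label` and `formula`
#'   (from [enumerate_adducts()] / [enumerate_conjugates()]).
#' @param charges Integer charge states to extract; areas are summed over
#'   charges when `aggregate_charges` is `TRUE`.
#' @param tolerance XIC window half-width in ppm.
#' @param aggregate_charges Sum areas across charge states (default) or
#'   report one row per charge.
#' @return A data.frame with columns `time_min`, `species`, `charge`
#'   (`NA` when aggregated), `area`, `replicate`.
#' @export
timecourse <- function(run_manifest, species, charges = c(3, 4),
                       tolerance = 20, aggregate_charges = TRUE) {
  stopifnot(is.list(run_manifest), is.data.frame(species),
            all(c("label", "formula") %in% names(species)))
  key <- vapply(run_manifest, function(r)
    paste(r$time, r$replicate %||% 1L), "")
  if (anyDuplicated(key)) {
    stop("duplicate (time, replicate) entries in run manifest: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  targets <- lapply(seq_len(nrow(species)), function(i)
    vapply(charges, function(z)
      most_intense_mz(species$formula[i], z), 0))
  rows <- list()
  for (run in run_manifest) {
    rep_id <- run$replicate %||% 1L
    for (i in seq_len(nrow(species))) {
      areas <- vapply(seq_along(charges), function(j) {
        tr <- build_xic(run$peaks, targets[[i]][j], tolerance,
                        label = species$label[i])
        integrate_area(tr)
      }, 0)
      if (aggregate_charges) {
        rows[[length(rows) + 1L]] <- data.frame(
          time_min = run$time, species = species$label[i],
          charge = NA_integer_, area = sum(areas), replicate = rep_id,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          time_min = run$time, species = species$label[i],
          charge = charges, area = areas, replicate = rep_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a centroided peak list from delimited text
#'
#' Expects a header line with columns `rt_min`, `mz`, `intensity`;
#' leading `#` comment lines are skipped.
#'
#' @param path File path.
#' @return A peak-list data.frame.
#' @export
read_peaklist <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  stopifnot(all(c("rt_min", "mz", "intensity") %in% names(df)))
  df
}
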