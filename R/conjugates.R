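# Candidate-species enumeration (disulfide crosslinks, LMW thiol adducts,
# dimers, oxidation forms, alkylated controls) and ppm-tolerance matching
# of observed masses, including the reduction/alkylation consistency check.

.candidate_row <- function(label, class, mass, formula, provenance) {
  data.frame(label = label, class = class, mass = mass,
             formula = format_formula(formula), provenance = provenance,
             stringsAsFactors = FALSE)
}

.frag_sequences <- function(x) {
  if (is.data.frame(x)) x$sequence else as.character(x)
}

#' Enumerate disulfide-linked crosslink candidates
#'
#' Builds the Cartesian product of carrier and analyte cysteine-containing
#' fragments as disulfide-linked candidates (each pairing loses 2 H),
#' deduplicated and ordered by theoretical mass.
#'
#' @param carrier_fragments,analyte_fragments Fragment tables from
#'   [digest()]/[cysteine_fragments()] or plain character vectors of
#'   sequences. All sequences must contain a cysteine.
#' @return A candidate data.frame with columns `label`, `class`
#'   (`"crosslink"`), `mass`, `formula`, `provenance`.
#' @examples
#' enumerate_conjugates("ALVLIAFAQYLQQCPFEDHVK", c("VPCVS", "KVPCVS"))
#' @export
enumerate_conjugates <- function(carrier_fragments, analyte_fragments) {
  ca <- .frag_sequences(carrier_fragments)
  an <- .frag_sequences(analyte_fragments)
  if (!length(ca) || !length(an)) {
    return(data.frame(label = character(), class = character(),
                      mass = numeric(), formula = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  }
  bad <- c(ca, an)[!grepl("C", c(ca, an), fixed = TRUE)]
  if (length(bad)) {
    stop("fragment(s) without cysteine supplied to enumerate_conjugates: ",
         paste(unique(bad), collapse = ", "))
  }
  rows <- list()
  for (cs in unique(ca)) {
    for (as_ in unique(an)) {
      f <- formula_subtract(
        formula_add(peptide_formula(cs), peptide_formula(as_)), c(H = 2))
      rows[[paste(cs, as_)]] <- .candidate_row(
        label = paste0(cs, "-SS-", as_), class = "crosslink",
        mass = formula_mass(f), formula = f,
        provenance = paste0("carrier:", cs, "+analyte:", as_))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$label), , drop = FALSE]
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate free, adduct, dimer, oxidized and alkylated candidates
#'
#' For an analyte peptide with a free cysteine, generates one candidate per
#' applicable mass delta: the free peptide, each requested thiol adduct,
#' the disulfide homodimer, oxidized forms of the free peptide, and the
#' carbamidomethylated (alkylation-control) form.
#'
#' @param analyte Analyte sequence or [peptide_species()].
#' @param adducts Character vector of adduct names from [delta_library()];
#'   default is the four plasma low-molecular-weight thiols and their
#'   symmetric dimers.
#' @param include_dimer Include the disulfide-linked homodimer.
#' @param include_oxidation Include `+O2`/`+O3` oxidized free peptide.
#' @param include_alkylated Include the carbamidomethylated form.
#' @return A candidate data.frame as in [enumerate_conjugates()].
#' @export
enumerate_adducts <- function(analyte,
                              adducts = c("Cys", "homoCys", "CysGly", "GSH",
                                          "Cys-dimer", "homoCys-dimer",
                                          "CysGly-dimer", "GSH-dimer"),
                              include_dimer = TRUE,
                              include_oxidation = TRUE,
                              include_alkylated = TRUE) {
  seqx <- if (inherits(analyte, "peptide_species")) analyte$sequence else analyte
  .check_sequence(seqx)
  has_cys <- grepl("C", seqx, fixed = TRUE)
  pf <- peptide_formula(seqx)
  rows <- list(.candidate_row(seqx, "free", formula_mass(pf), pf, "free peptide"))
  for (nm in adducts) {
    e <- adduct_delta(nm)
    if (!has_cys) {
      stop("disulfide adduct '", nm, "' requires a free cysteine in '",
           seqx, "'")
    }
    f <- formula_add(pf, parse_formula(e$formula))
    rows[[length(rows) + 1L]] <- .candidate_row(
      paste0(seqx, "+", nm), "adduct", formula_mass(f), f,
      paste0("analyte:", seqx, "+delta:", nm))
  }
  if (include_dimer) {
    if (!has_cys) stop("a disulfide homodimer requires a cysteine in '",
                       seqx, "'")
    f <- formula_subtract(formula_add(pf, pf), c(H = 2))
    rows[[length(rows) + 1L]] <- .candidate_row(
      paste0(seqx, "-SS-", seqx), "dimer", formula_mass(f), f,
      paste0("homodimer of ", seqx))
  }
  if (include_oxidation) {
    for (k in c(2L, 3L)) {
      f <- formula_add(pf, c(O = k))
      rows[[length(rows) + 1L]] <- .candidate_row(
        paste0(seqx, "+O", k), "oxidized", formula_mass(f), f,
        paste0("analyte:", seqx, "+", k, "O"))
    }
  }
  if (include_alkylated && has_cys) {
    e <- adduct_delta("carbamidomethyl")
    f <- formula_add(pf, parse_formula(e$formula))
    rows[[length(rows) + 1L]] <- .candidate_row(
      paste0(seqx, "+CAM"), "alkylated", formula_mass(f), f,
      paste0("analyte:", seqx, "+carbamidomethyl"))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$label), , drop = FALSE]
  out <- out[order(out$mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match observed masses to candidate species within a ppm tolerance
#'
#' Every (observed, candidate) pair within tolerance is reported; for each
#' observed mass, matches are ranked by absolute ppm error. No silent
#' best-hit selection: ties are all kept.
#'
#' @param observed Numeric vector of observed neutral monoisotopic masses
#'   (Da).
#' @param candidates Candidate table from [enumerate_conjugates()] /
#'   [enumerate_adducts()] (needs `label`, `mass`; other columns carried).
#' @param tolerance Mass tolerance in ppm (`> 0`), default 20.
#' @return A data.frame with columns `observed`, `label`, `class`,
#'   `theoretical`, `ppm`, ordered by observed mass then `|ppm|`.
#'   Unmatched observed masses are available in `attr(, "unmatched")`.
#' @export
match_masses <- function(observed, candidates, tolerance = 20) {
  stopifnot(is.numeric(observed), tolerance > 0,
            is.data.frame(candidates))
  rows <- list()
  unmatched <- numeric()
  cls <- if ("class" %in% names(candidates)) candidates$class else
    rep(NA_character_, nrow(candidates))
  for (obs in observed) {
    ppm <- ppm_error(obs, candidates$mass)
    hit <- which(abs(ppm) <= tolerance)
    if (!length(hit)) {
      unmatched <- c(unmatched, obs)
      next
    }
    hit <- hit[order(abs(ppm[hit]))]
    rows[[length(rows) + 1L]] <- data.frame(
      observed = obs, label = candidates$label[hit], class = cls[hit],
      theoretical = candidates$mass[hit], ppm = ppm[hit],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observed = numeric(), label = character(),
               class = character(), theoretical = numeric(),
               ppm = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  attr(out, "tolerance") <- tolerance
  out
}

#' Reduction + alkylation consistency control for crosslink assignments
#'
#' A genuine disulfide crosslink must disappear after reduction and
#' carbamidomethylation, and the carbamidomethylated carrier fragment must
#' appear instead. For each crosslink match this asserts (a) its mass is
#' absent from the reduced/alkylated observed list and (b) the CAM carrier
#' fragment mass is present.
#'
#' @param matches A match table from [match_masses()] (crosslink rows are
#'   evaluated; other classes are ignored).
#' @param reduced_observed Observed masses from the reduced + alkylated
#'   condition, or `NULL` if that condition was not measured.
#' @param carrier_fragments Carrier fragment sequences (character vector or
#'   fragment table); each must contain the cysteine that is alkylated.
#' @param tolerance Mass tolerance in ppm.
#' @return A data.frame with one row per crosslink match: `label`,
#'   `crosslink_absent`, `cam_fragment_present`, `status` (`"pass"`,
#'   `"fail"`, or `"not evaluated"`).
#' @export
reduction_control <- function(matches, reduced_observed, carrier_fragments,
                              tolerance = 20) {
  xl <- matches[!is.na(matches$class) & matches$class == "crosslink", ,
                drop = FALSE]
  if (!nrow(xl)) {
    return(data.frame(label = character(), crosslink_absent = logical(),
                      cam_fragment_present = logical(), status = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(reduced_observed)) {
    return(data.frame(label = xl$label, crosslink_absent = NA,
                      cam_fragment_present = NA,
                      status = "not evaluated", stringsAsFactors = FALSE))
  }
  carrier <- .frag_sequences(carrier_fragments)
  cam_masses <- vapply(carrier, function(s)
    peptide_mono_mass(s, "carbamidomethyl"), 0)
  cam_present <- any(vapply(cam_masses, function(m)
    any(abs(ppm_error(reduced_observed, m)) <= tolerance), TRUE))
  out <- do.call(rbind, lapply(seq_len(nrow(xl)), function(i) {
    absent <- !any(abs(ppm_error(reduced_observed, xl$theoretical[i])) <=
                     tolerance)
    data.frame(label = xl$label[i], crosslink_absent = absent,
               cam_fragment_present = cam_present,
               status = if (absent && cam_present) "pass" else "fail",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Component arithmetic report for a printed crosslink mass
#'
#' Recomputes the theoretical mass of a carrier-analyte disulfide pairing
#' and reports the signed discrepancy against an observed (or printed)
#' mass, both in Da and ppm. Used to document observed masses that are
#' inconsistent with their stated components rather than forcing a match.
#'
#' @param observed Observed/printed mass (Da).
#' @param carrier_fragment,analyte_fragment Component sequences.
#' @return A one-row data.frame with the component masses, theoretical sum,
#'   and `discrepancy_da` / `discrepancy_ppm`.
#' @export
crosslink_components <- function(observed, carrier_fragment,
                                 analyte_fragment) {
  mc <- peptide_mono_mass(carrier_fragment)
  ma <- peptide_mono_mass(analyte_fragment)
  theo <- disulfide_mass(carrier_fragment, analyte_fragment)
  data.frame(observed = observed, carrier = carrier_fragment,
             carrier_mass = mc, analyte = analyte_fragment,
             analyte_mass = ma, link_delta = ma - 2 * ELEMENT_MASS[["H"]],
             theoretical = theo, discrepancy_da = observed - theo,
             discrepancy_ppm = ppm_error(observed, theo),
             stringsAsFactors = FALSE)
}
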