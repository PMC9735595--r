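# Monoisotopic mass and elemental-composition arithmetic for peptides,
# disulfide links and thiol adducts. All printed masses in downstream
# modules derive from the single constant table below (IUPAC monoisotopic
# element masses at >= 6 decimals); no duplicated mass literals elsewhere.

#' Monoisotopic element masses (Da)
#'
#' Named numeric vector of monoisotopic masses for the elements occurring in
#' canonical peptides and the built-in modification library.
#' @export
ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' @rdname ELEMENT_MASS
#' @export
PROTON_MASS <- 1.0072765

.WATER <- c(H = 2, O = 1)

# residue (not free amino acid) compositions of the 20 canonical codes
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.canon_formula <- function(x) {
  x <- x[x != 0]
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  x[ord]
}

#' Elemental formula constructors and arithmetic
#'
#' An elemental formula is a named numeric vector of integer element counts
#' (e.g. `c(C = 3, H = 7, N = 1, O = 2, S = 1)` for free cysteine). Counts
#' must be non-negative after any algebra; `formula_subtract()` enforces this.
#'
#' @param text A formula string such as `"C3H7NO2S"`.
#' @return A named numeric vector of element counts.
#' @examples
#' parse_formula("C10H17N3O6S")
#' formula_mass(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(text)) {
    stop("cannot parse elemental formula: '", text, "'")
  }
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(cnt, els, sum)
  unknown <- setdiff(names(out), names(ELEMENT_MASS))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  .canon_formula(stats::setNames(as.numeric(out), names(out)))
}

#' @rdname parse_formula
#' @param f,a,b Elemental formulas (named count vectors).
#' @export
format_formula <- function(f) {
  f <- .canon_formula(f)
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

#' @rdname parse_formula
#' @export
formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  .canon_formula(out)
}

#' @rdname parse_formula
#' @export
formula_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    stop("negative element count after subtraction: ",
         paste(names(out)[out < 0], collapse = ", "))
  }
  .canon_formula(out)
}

#' @rdname parse_formula
#' @export
formula_mass <- function(f) {
  if (!length(f)) return(0)
  unknown <- setdiff(names(f), names(ELEMENT_MASS))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(ELEMENT_MASS[names(f)] * f)
}

#' Residue and peptide elemental composition
#'
#' `residue_formula()` returns the composition of an amino-acid *residue*
#' (the free amino acid minus water); `peptide_formula()` sums residue
#' formulas and adds back one water for the termini.
#'
#' @param residue A single one-letter canonical amino-acid code.
#' @param sequence A peptide as a one-letter-code string.
#' @return A named element-count vector.
#' @examples
#' residue_formula("G")   # C2H3NO
#' peptide_formula("VPCVS")
#' @export
residue_formula <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L)
  f <- .RESIDUE_FORMULA[[residue]]
  if (is.null(f)) {
    stop("unknown amino-acid code: '", residue, "'")
  }
  .canon_formula(f)
}

#' @rdname residue_formula
#' @export
peptide_formula <- function(sequence) {
  .check_sequence(sequence)
  aas <- strsplit(sequence, "")[[1]]
  out <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (aa in aas) {
    f <- .RESIDUE_FORMULA[[aa]]
    out[names(f)] <- out[names(f)] + f
  }
  out[names(.WATER)] <- out[names(.WATER)] + .WATER
  .canon_formula(out)
}

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty character string")
  }
  aas <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aas, names(.RESIDUE_FORMULA))
  if (length(bad)) {
    stop("unknown amino-acid code(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Modification / adduct library
#
# Thiol adducts attach by disulfide exchange, so each delta is the free
# compound's composition minus H2 (the two hydrogens lost on S-S formation).
# Symmetric dimer adducts (e.g. cystine on the peptide thiol) lose H2 twice:
# once for the internal S-S of the dimer and once for the attachment.

.delta_entry <- function(name, formula_change, site, note) {
  f <- parse_formula(formula_change)
  list(name = name, delta = formula_mass(f), formula = format_formula(f),
       site = site, note = note)
}

.DELTA_LIBRARY <- local({
  h2 <- c(H = 2)
  free <- list(
    Cys     = parse_formula("C3H7NO2S"),
    homoCys = parse_formula("C4H9NO2S"),
    CysGly  = parse_formula("C5H10N2O3S"),
    GSH     = parse_formula("C10H17N3O6S")
  )
  entries <- list()
  for (nm in names(free)) {
    entries[[nm]] <- .delta_entry(
      nm, format_formula(formula_subtract(free[[nm]], h2)), "C",
      sprintf("disulfide-linked %s (free compound - H2)", nm))
    dimer <- formula_subtract(
      formula_subtract(formula_add(free[[nm]], free[[nm]]), h2), h2)
    entries[[paste0(nm, "-dimer")]] <- .delta_entry(
      paste0(nm, "-dimer"), format_formula(dimer), "C",
      sprintf("disulfide-linked symmetric %s dimer", nm))
  }
  entries$dioxidation <- .delta_entry("dioxidation", "O2", "CMW",
                                      "double oxidation of the thiol")
  entries$trioxidation <- .delta_entry("trioxidation", "O3", "C",
                                       "cysteine trioxidation (sulfonic acid)")
  entries$carbamidomethyl <- .delta_entry("carbamidomethyl", "C2H3NO", "C",
                                          "iodoacetamide alkylation (CAM)")
  entries
})

#' The built-in modification and thiol-adduct library
#'
#' Each entry carries the delta name, its mass shift in Da, the elemental
#' formula change, and the residue letters the delta may attach to.
#' Disulfide-type adduct deltas equal the free compound's monoisotopic mass
#' minus 2.015650 Da (two hydrogens lost on disulfide formation).
#'
#' @return A data.frame with columns `name`, `delta`, `formula`, `site`,
#'   `note`, one row per library entry.
#' @examples
#' delta_library()
#' @export
delta_library <- function() {
  do.call(rbind, lapply(.DELTA_LIBRARY, function(e) {
    data.frame(name = e$name, delta = e$delta, formula = e$formula,
               site = e$site, note = e$note, stringsAsFactors = FALSE)
  })) -> df
  rownames(df) <- NULL
  df
}

#' Look up a mass delta by name
#'
#' @param name One of the library names (see [delta_library()]); thiol
#'   adducts are `"Cys"`, `"homoCys"`, `"CysGly"`, `"GSH"` and their
#'   `"-dimer"` forms; also `"dioxidation"`, `"trioxidation"`,
#'   `"carbamidomethyl"`.
#' @return A list with `name`, `delta` (Da), `formula` (change string) and
#'   `site` (allowed residue letters).
#' @examples
#' adduct_delta("Cys")$delta   # +119.0041 Da
#' @export
adduct_delta <- function(name) {
  e <- .DELTA_LIBRARY[[name]]
  if (is.null(e)) {
    stop("unknown adduct/modification '", name, "'; library: ",
         paste(names(.DELTA_LIBRARY), collapse = ", "))
  }
  e
}

#' Write the modification library to a delimited text file
#'
#' @param path Output file path.
#' @export
write_delta_library <- function(path) {
  utils::write.table(delta_library(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------

.resolve_modifications <- function(sequence, modifications) {
  if (is.null(modifications) || (is.data.frame(modifications) && !nrow(modifications))) {
    return(data.frame(name = character(), pos = integer()))
  }
  if (is.character(modifications)) {
    modifications <- data.frame(name = modifications, pos = NA_integer_,
                                stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(modifications), "name" %in% names(modifications))
  if (!"pos" %in% names(modifications)) modifications$pos <- NA_integer_
  aas <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(modifications))) {
    e <- adduct_delta(modifications$name[i])
    sites <- strsplit(e$site, "")[[1]]
    pos <- modifications$pos[i]
    if (is.na(pos)) {
      hit <- which(aas %in% sites)
      if (!length(hit)) {
        stop("modification '", e$name, "' requires a residue in [", e$site,
             "] but none is present in '", sequence, "'")
      }
      modifications$pos[i] <- hit[1]
    } else {
      if (pos < 1 || pos > length(aas) || !(aas[pos] %in% sites)) {
        stop("modification '", e$name, "' not allowed at position ", pos,
             " ('", aas[min(max(pos, 1), length(aas))], "'); allowed sites: ",
             e$site)
      }
    }
  }
  modifications
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus any modification deltas.
#'
#' @param sequence Peptide as a one-letter-code string.
#' @param modifications Either `NULL`, a character vector of delta names
#'   (attached to the first allowed residue), or a data.frame with columns
#'   `name` and `pos` (1-based). Site constraints are enforced.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("VPCVS")                          # 503.2414
#' peptide_mono_mass("ALVLIAFAQYLQQCPFEDHVK", "carbamidomethyl")
#' @export
peptide_mono_mass <- function(sequence, modifications = NULL) {
  .check_sequence(sequence)
  mods <- .resolve_modifications(sequence, modifications)
  m <- formula_mass(peptide_formula(sequence))
  if (nrow(mods)) {
    m <- m + sum(vapply(mods$name, function(n) adduct_delta(n)$delta, 0))
  }
  m
}

#' Mass of a disulfide-linked peptide pair
#'
#' Two peptides joined by one S-S bridge lose two hydrogen atoms:
#' `mass(a) + mass(b) - 2 * 1.0078250`. Both partners must contain a
#' cysteine. Symmetric in its arguments.
#'
#' @param peptide_a,peptide_b Sequences (strings) or [peptide_species()]
#'   objects.
#' @return Monoisotopic mass of the crosslinked species in Da.
#' @examples
#' disulfide_mass("ALVLIAFAQYLQQCPFEDHVK", "VPCVS")  # 2933.482
#' @export
disulfide_mass <- function(peptide_a, peptide_b) {
  ma <- .species_mass_cys(peptide_a, "first")
  mb <- .species_mass_cys(peptide_b, "second")
  ma + mb - 2 * ELEMENT_MASS[["H"]]
}

.species_mass_cys <- function(x, which_arg) {
  seqx <- if (inherits(x, "peptide_species")) x$sequence else x
  .check_sequence(seqx)
  if (!grepl("C", seqx, fixed = TRUE)) {
    stop("no cysteine in the ", which_arg, " partner ('", seqx,
         "'); a disulfide link requires one in both")
  }
  if (inherits(x, "peptide_species")) x$mono_mass else peptide_mono_mass(seqx)
}

#' Mass-to-charge ratio of a protonated species
#'
#' @param mass Neutral monoisotopic mass (Da), `> 0`.
#' @param charge Positive integer charge state.
#' @return `(mass + charge * 1.0072765) / charge`.
#' @examples
#' mz(2933.482, 3)
#' @export
mz <- function(mass, charge) {
  stopifnot(is.numeric(mass), all(mass > 0))
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("charge must be a positive integer")
  }
  (mass + charge * PROTON_MASS) / charge
}

#' A peptide species with modifications and an optional link
#'
#' Lightweight container pairing a sequence with positioned modifications
#' and a link (none, a disulfide partner, or a named adduct), carrying the
#' recomputable theoretical monoisotopic mass and a human-readable label.
#'
#' @param sequence Peptide one-letter string.
#' @param modifications As in [peptide_mono_mass()].
#' @param link `NULL`, a sequence/`peptide_species` to disulfide-link to, or
#'   a single adduct name from [delta_library()].
#' @param label Optional label; a default is derived from the parts.
#' @return An object of class `peptide_species` with elements `sequence`,
#'   `modifications`, `link`, `mono_mass`, `formula`, `label`.
#' @export
peptide_species <- function(sequence, modifications = NULL, link = NULL,
                            label = NULL) {
  .check_sequence(sequence)
  mods <- .resolve_modifications(sequence, modifications)
  f <- peptide_formula(sequence)
  for (n in mods$name) f <- formula_add(f, parse_formula(adduct_delta(n)$formula))
  mass <- formula_mass(f)
  link_desc <- "none"
  if (!is.null(link)) {
    if (is.character(link) && link %in% names(.DELTA_LIBRARY)) {
      e <- adduct_delta(link)
      if (!grepl("C", sequence, fixed = TRUE)) {
        stop("adduct link '", link, "' requires a cysteine in '", sequence, "'")
      }
      f <- formula_add(f, parse_formula(e$formula))
      link_desc <- paste0("+", e$name)
    } else {
      partner_seq <- if (inherits(link, "peptide_species")) link$sequence else link
      mass_partner <- .species_mass_cys(link, "link partner")
      if (!grepl("C", sequence, fixed = TRUE)) {
        stop("a disulfide link requires a cysteine in '", sequence, "'")
      }
      pf <- if (inherits(link, "peptide_species")) link$formula else
        peptide_formula(partner_seq)
      f <- formula_subtract(formula_add(f, pf), c(H = 2))
      link_desc <- paste0("-SS-", partner_seq)
    }
    mass <- formula_mass(f)
  }
  if (is.null(label)) {
    modtag <- if (nrow(mods)) {
      paste0("(", paste(mods$name, "@", mods$pos, sep = "", collapse = ","), ")")
    } else ""
    label <- paste0(sequence, modtag,
                    if (link_desc != "none") link_desc else "")
  }
  structure(list(sequence = sequence, modifications = mods, link = link,
                 mono_mass = mass, formula = f, label = label),
            class = "peptide_species")
}

#' @export
print.peptide_species <- function(x, ...) {
  cat(sprintf("<peptide_species> %s  %.4f Da  [%s]\n",
              x$label, x$mono_mass, format_formula(x$formula)))
  invisible(x)
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical Masses in Da.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
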