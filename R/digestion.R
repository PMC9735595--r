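# In-silico proteolysis with missed cleavages. Positions are 1-based
# inclusive on the parent, matching the "residues 21-41" convention used
# for the albumin mature chain.

.PROTEASES <- list(
  # cleave C-terminal to K/R, except when the next residue is P
  trypsin = function(aas) {
    n <- length(aas)
    if (n < 2) return(integer())
    i <- which(aas[-n] %in% c("K", "R"))
    i[aas[i + 1] != "P"]
  }
)

#' In-silico proteolytic digestion
#'
#' Cleaves a sequence with the named protease and returns every fragment
#' spanning `0..max_missed_cleavages` internal cleavage sites, with 1-based
#' inclusive positions on the parent. For trypsin the rule is: cleave
#' C-terminal to K or R unless the following residue is P.
#'
#' @param sequence Parent sequence (one-letter codes).
#' @param protease Protease token; currently `"trypsin"`.
#' @param max_missed_cleavages Maximum number of internal sites a fragment
#'   may span (`>= 0`).
#' @param parent_id Identifier copied into the output table.
#' @return A data.frame of class `digest_fragments` with columns `parent`,
#'   `start`, `end`, `sequence`, `mc`, ordered by `start` then fragment
#'   length.
#' @examples
#' digest("ILRWSRKLPCVS", "trypsin", 1)   # includes LPCVS and KLPCVS
#' @export
digest <- function(sequence, protease = "trypsin", max_missed_cleavages = 2,
                   parent_id = sequence) {
  .check_sequence(sequence)
  stopifnot(max_missed_cleavages >= 0)
  rule <- .PROTEASES[[protease]]
  if (is.null(rule)) {
    stop("unknown protease '", protease, "'; available: ",
         paste(names(.PROTEASES), collapse = ", "))
  }
  aas <- strsplit(sequence, "")[[1]]
  sites <- rule(aas)                      # cleavage after these positions
  bounds <- c(0L, sites, length(aas))     # fragment boundaries
  nb <- length(bounds)
  rows <- list()
  for (i in seq_len(nb - 1L)) {
    for (mc in 0:max_missed_cleavages) {
      j <- i + 1L + mc
      if (j > nb) break
      start <- bounds[i] + 1L
      end <- bounds[j]
      rows[[length(rows) + 1L]] <- data.frame(
        parent = parent_id, start = start, end = end,
        sequence = substr(sequence, start, end), mc = mc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end - out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("digest_fragments", "data.frame")
  out
}

#' Filter digest fragments to those containing cysteine
#'
#' @param fragments A fragment table from [digest()] (or any data.frame
#'   with a `sequence` column).
#' @return The subset of rows whose sequence contains at least one `C`,
#'   input order preserved.
#' @export
cysteine_fragments <- function(fragments) {
  stopifnot(is.data.frame(fragments), "sequence" %in% names(fragments))
  out <- fragments[grepl("C", fragments$sequence, fixed = TRUE), ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read protein/peptide sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    if (!length(set)) stop("empty FASTA file: ", path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    return(seqs)
  }
  # minimal fallback parser (header lines start with '>')
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA header ('>') found in ", path,
                      " (line 1: '", lines[1], "')")
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  names(seqs) <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (!all(nzchar(seqs))) stop("empty sequence record in ", path)
  seqs
}

#' Write a fragment table as tab-delimited text
#'
#' @param fragments A fragment table from [digest()].
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines.
#' @export
write_fragments <- function(fragments, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(fragments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
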