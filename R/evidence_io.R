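#' Evidence-table dialect configuration
#'
#' An evidence dialect maps the column names of a peptide-evidence table onto
#' the internal field names, and records how the SILAC ratio is oriented and
#' how strict parsing should be. The default dialect matches MaxQuant
#' \code{evidence.txt} exports, so those tables load unchanged; the
#' \code{"canonical"} dialect matches the TSV written by
#' \code{\link{write_evidence}}.
#'
#' @param name dialect preset, \code{"maxquant"} or \code{"canonical"}.
#' @param columns named character vector mapping internal field names
#'   (\code{peptide_sequence}, \code{modifications}, \code{protein_id},
#'   \code{ratio_hl}, \code{intensity}, \code{condition_id},
#'   \code{replicate_id}, and optionally \code{fraction}, \code{charge}) to
#'   the file's column headers. Entries override the preset.
#' @param ratio_orientation \code{"heavy_over_light"} (internal convention:
#'   heavy reference / light sample) or \code{"light_over_heavy"}, in which
#'   case ratios are inverted on load.
#' @param error_tolerance maximum tolerated fraction of malformed rows before
#'   \code{\link{read_evidence}} aborts.
#'
#' @return A list of class \code{"evidence_dialect"}.
#' @export
evidence_dialect <- function(name = c("maxquant", "canonical"),
                             columns = NULL,
                             ratio_orientation = c("heavy_over_light",
                                                   "light_over_heavy"),
                             error_tolerance = 0.01) {
  name <- match.arg(name)
  ratio_orientation <- match.arg(ratio_orientation)
  base_cols <- switch(name,
    maxquant = c(peptide_sequence = "Sequence",
                 modifications    = "Modifications",
                 protein_id       = "Leading razor protein",
                 ratio_hl         = "Ratio H/L",
                 intensity        = "Intensity",
                 condition_id     = "Condition",
                 replicate_id     = "Replicate",
                 fraction         = "Fraction",
                 charge           = "Charge"),
    canonical = c(peptide_sequence = "peptide_sequence",
                  modifications    = "modifications",
                  protein_id       = "protein_id",
                  ratio_hl         = "ratio_hl",
                  intensity        = "intensity",
                  condition_id     = "condition_id",
                  replicate_id     = "replicate_id",
                  fraction         = "fraction",
                  charge           = "charge"))
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), names(base_cols))
    if (length(bad))
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    base_cols[names(columns)] <- columns
  }
  stopifnot(is.numeric(error_tolerance), error_tolerance >= 0,
            error_tolerance <= 1)
  structure(list(name = name, columns = base_cols,
                 ratio_orientation = ratio_orientation,
                 error_tolerance = error_tolerance),
            class = "evidence_dialect")
}

.EV_REQUIRED <- c("peptide_sequence", "modifications", "protein_id",
                  "ratio_hl", "intensity", "condition_id", "replicate_id")
.EV_FRACTIONS <- c("UNBOUND", "DTT", "GUANIDINE", "NONE")

#' Read a peptide-evidence table
#'
#' Loads a tab-separated evidence table (one row per quantified peptide
#' feature), maps its columns through an \code{\link{evidence_dialect}},
#' validates each row, and canonicalizes it into the internal model. Rows
#' whose SILAC ratio is missing are retained with the ratio flagged absent
#' (\code{NA}); malformed rows (bad sequence, unparseable modification cell,
#' non-positive ratio, invalid replicate) are rejected, counted, and reported
#' in the object's attributes. Rows quantified in multiple charge states stay
#' separate; merging happens downstream by median aggregation.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect an \code{\link{evidence_dialect}}.
#' @return A data frame of class \code{"redox_evidence"} with columns
#'   \code{peptide_sequence}, \code{modifications} (canonical
#'   \code{"Name (X) pos"} entries, semicolon-separated), \code{protein_id},
#'   \code{ratio_hl}, \code{intensity}, \code{condition_id},
#'   \code{replicate_id}, \code{fraction}, \code{charge}; attributes
#'   \code{n_input}, \code{n_rejected}, \code{rejected} (a data frame of row
#'   number + reason).
#' @export
read_evidence <- function(path, dialect = evidence_dialect()) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  as_redox_evidence(raw, dialect)
}

#' Canonicalize an in-memory evidence table
#'
#' Same validation and canonicalization as \code{\link{read_evidence}} applied
#' to a data frame already in memory.
#'
#' @param x data frame in the dialect's column layout.
#' @inheritParams read_evidence
#' @return A \code{"redox_evidence"} data frame (see
#'   \code{\link{read_evidence}}).
#' @export
as_redox_evidence <- function(x, dialect = evidence_dialect()) {
  if (inherits(x, "redox_evidence")) return(x)
  cols <- dialect$columns
  missing_req <- .EV_REQUIRED[!cols[.EV_REQUIRED] %in% names(x)]
  if (length(missing_req))
    stop("evidence table lacks required column(s): ",
         paste(sprintf("'%s' (field %s)", cols[missing_req], missing_req),
               collapse = ", "))

  n <- nrow(x)
  get <- function(field) x[[cols[[field]]]]
  opt <- function(field, default) {
    if (cols[[field]] %in% names(x)) x[[cols[[field]]]] else rep(default, n)
  }

  ev <- data.frame(
    peptide_sequence = toupper(trimws(as.character(get("peptide_sequence")))),
    modifications    = as.character(get("modifications")),
    protein_id       = as.character(get("protein_id")),
    ratio_hl         = suppressWarnings(as.numeric(get("ratio_hl"))),
    intensity        = suppressWarnings(as.numeric(get("intensity"))),
    condition_id     = as.character(get("condition_id")),
    replicate_id     = suppressWarnings(as.integer(opt("replicate_id", NA))),
    fraction         = toupper(as.character(opt("fraction", "NONE"))),
    charge           = suppressWarnings(as.integer(opt("charge", 2L))),
    stringsAsFactors = FALSE
  )
  ev$modifications[is.na(ev$modifications)] <- ""
  ev$fraction[is.na(ev$fraction) | ev$fraction == ""] <- "NONE"
  ev$charge[is.na(ev$charge)] <- 2L
  ev$intensity[is.na(ev$intensity)] <- 0

  # shared peptides: keep the leading accession only
  ev$protein_id <- sub(";.*$", "", ev$protein_id)

  reasons <- character(0); rows <- integer(0)
  reject <- function(i, why) {
    rows <<- c(rows, i); reasons <<- c(reasons, why)
  }
  canon <- character(n)
  for (i in seq_len(n)) {
    if (is.na(ev$peptide_sequence[i]) ||
        !grepl("^[A-Z]+$", ev$peptide_sequence[i])) {
      reject(i, "invalid peptide sequence"); next
    }
    if (!is.na(ev$ratio_hl[i]) && ev$ratio_hl[i] <= 0) {
      reject(i, "non-positive ratio"); next
    }
    if (is.na(ev$replicate_id[i]) || ev$replicate_id[i] < 1L) {
      reject(i, "invalid replicate id"); next
    }
    if (!ev$fraction[i] %in% .EV_FRACTIONS) {
      reject(i, paste0("unknown fraction '", ev$fraction[i], "'")); next
    }
    m <- tryCatch(parse_modifications(ev$modifications[i],
                                      ev$peptide_sequence[i]),
                  error = function(e) conditionMessage(e))
    if (is.character(m) && length(m) == 1L && !grepl("^OKMODS:", m)) {
      reject(i, m); next
    }
    canon[i] <- sub("^OKMODS:", "", m)
  }
  ev$modifications <- canon
  if (!is.na(dialect$ratio_orientation) &&
      dialect$ratio_orientation == "light_over_heavy")
    ev$ratio_hl <- 1 / ev$ratio_hl

  keep <- setdiff(seq_len(n), rows)
  rejected <- data.frame(row = rows, reason = reasons,
                         stringsAsFactors = FALSE)
  frac_bad <- length(rows) / max(1L, n)
  if (frac_bad > dialect$error_tolerance)
    stop(sprintf(
      "%d of %d evidence rows malformed (%.1f%% > tolerance %.1f%%); first: %s",
      length(rows), n, 100 * frac_bad, 100 * dialect$error_tolerance,
      if (length(reasons)) reasons[1] else ""))
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_input = n, n_rejected = length(rows), rejected = rejected,
            class = c("redox_evidence", "data.frame"))
}

# Parse one modification cell against its peptide. Grammar (semicolon
# separated): each entry is [count] Name [(target)] [pos] where Name may
# itself contain spaces/hyphens, target is a residue letter (or *-term), and
# pos is 1-based within the peptide. Entries with an explicit position are
# checked against the residue when the target is a single letter; entries
# with only a target letter are expanded to the matching residue positions.
# "Unmodified" or an empty cell means no modifications. Returns the canonical
# string prefixed "OKMODS:" or raises an error describing the entry.
parse_modifications <- function(cell, peptide) {
  cell <- trimws(cell)
  if (cell == "" || toupper(cell) == "UNMODIFIED") return("OKMODS:")
  entries <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  entries <- entries[entries != ""]
  plen <- nchar(peptide)
  res <- strsplit(peptide, "")[[1]]
  out_name <- character(0); out_pos <- integer(0)
  pat <- "^(?:(\\d+)\\s+)?([A-Za-z][A-Za-z0-9_+\\-]*(?:\\s[A-Za-z0-9_+\\-]+)*?)\\s*(?:\\(([A-Za-z][A-Za-z\\-]*)\\))?\\s*(\\d+)?$"
  for (e in entries) {
    m <- regmatches(e, regexec(pat, e))[[1]]
    if (length(m) == 0L)
      stop("unparseable modification entry '", e, "'")
    count <- if (m[2] != "") as.integer(m[2]) else NA_integer_
    nm <- m[3]; target <- m[4]; pos <- if (m[5] != "") as.integer(m[5]) else NA
    if (!is.na(pos)) {
      if (pos < 1L || pos > plen)
        stop("modification position ", pos, " outside peptide for '", e, "'")
      if (nchar(target) == 1L && res[pos] != toupper(target))
        stop("modification '", e, "' targets ", target,
             " but residue at ", pos, " is ", res[pos])
      out_name <- c(out_name, nm); out_pos <- c(out_pos, pos)
    } else if (nchar(target) == 1L) {
      hits <- which(res == toupper(target))
      if (!length(hits))
        stop("modification '", e, "' targets ", target,
             " absent from peptide")
      if (!is.na(count)) {
        if (count > length(hits))
          stop("modification '", e, "' count exceeds ", target, " residues")
        hits <- hits[seq_len(count)]
      }
      out_name <- c(out_name, rep(nm, length(hits)))
      out_pos <- c(out_pos, hits)
    } else if (grepl("term$", target, ignore.case = TRUE)) {
      out_name <- c(out_name, nm)
      out_pos <- c(out_pos,
                   if (grepl("^N", target, ignore.case = TRUE)) 1L else plen)
    } else {
      stop("modification entry '", e, "' has neither position nor residue target")
    }
  }
  canon <- paste(sprintf("%s (%s) %d", out_name, res[out_pos], out_pos),
                 collapse = ";")
  paste0("OKMODS:", canon)
}

#' Extract parsed modifications from canonical evidence
#'
#' @param modifications canonical modification strings as stored in a
#'   \code{"redox_evidence"} data frame.
#' @return A list (one element per input string) of data frames with columns
#'   \code{name}, \code{target}, \code{position}.
#' @export
modification_list <- function(modifications) {
  lapply(modifications, function(s) {
    if (is.na(s) || s == "")
      return(data.frame(name = character(0), target = character(0),
                        position = integer(0), stringsAsFactors = FALSE))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^(.*) \\((.)\\) (\\d+)$", parts))
    data.frame(name = vapply(m, `[`, "", 2),
               target = vapply(m, `[`, "", 3),
               position = as.integer(vapply(m, `[`, "", 4)),
               stringsAsFactors = FALSE)
  })
}

#' Write canonical evidence to TSV
#'
#' Writes the validated table in the canonical dialect; re-reading with
#' \code{evidence_dialect("canonical")} reproduces the parse field-for-field.
#'
#' @param ev a \code{"redox_evidence"} data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_evidence <- function(ev, path) {
  stopifnot(inherits(ev, "redox_evidence"))
  utils::write.table(as.data.frame(ev), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a JSON run report of rejected evidence rows
#'
#' @param ev a \code{"redox_evidence"} data frame.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_evidence_report <- function(ev, path) {
  stopifnot(inherits(ev, "redox_evidence"))
  rep <- list(n_input = attr(ev, "n_input"),
              n_parsed = nrow(ev),
              n_rejected = attr(ev, "n_rejected"),
              rejected = attr(ev, "rejected"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a protein FASTA into a protein database
#'
#' @param path FASTA file of protein sequences.
#' @param accession_pattern regex whose first match in each header is the
#'   accession (default: first whitespace-delimited token).
#' @return Named character vector of class \code{"protein_db"}
#'   (accession -> amino-acid sequence).
#' @export
read_fasta <- function(path, accession_pattern = "^\\S+") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # BStringSet keeps the record text verbatim (AAStringSet silently drops
  # invalid one-letter codes), so alphabet validation can be strict
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("FASTA file is empty: ", path)
  acc <- regmatches(names(aa), regexpr(accession_pattern, names(aa)))
  if (length(acc) != length(aa))
    stop("FASTA header without accession match in ", path)
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- as.character(aa)
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYBXZJUO]+$", seqs)
  if (any(bad))
    stop("sequence with illegal characters or empty in record(s): ",
         paste(acc[bad], collapse = ", "))
  names(seqs) <- acc
  structure(seqs, class = "protein_db")
}

#' Write a protein database to FASTA
#'
#' @param db a \code{"protein_db"} named character vector.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(unclass(db))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
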