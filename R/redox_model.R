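#' Cysteine chemistry label map
#'
#' The biotin-switch workflow converts cysteine redox states into chemical
#' labels: free thiols are blocked with iodoacetamide (carbamidomethylation),
#' S-nitrosylated thiols are selectively reduced by ascorbate and labeled with
#' iodoacetyl-PEG2-biotin, and reversibly oxidized thiols come through
#' unlabeled at the cysteine (reduced by DTT after enrichment). The label map
#' records which search-engine modification names correspond to the reduced
#' and S-NO labels; a single cysteine carrying neither maps to S-OX.
#'
#' @param reduced modification names denoting the reduced (S-H) label.
#' @param sno modification names denoting the S-NO label.
#' @return A list of class \code{"redox_label_map"}.
#' @export
redox_label_map <- function(reduced = c("Carbamidomethyl"),
                            sno = c("IAM-biotin", "Iodoacetyl-PEG2-biotin",
                                    "Biotin-HPDP")) {
  if (length(intersect(reduced, sno)))
    stop("a modification name cannot map to both REDUCED and SNO")
  structure(list(reduced = reduced, sno = sno), class = "redox_label_map")
}

.REDOX_STATES <- c("REDUCED", "SNO", "SOX")
.STATE_FRACTION <- c(REDUCED = "UNBOUND", SNO = "GUANIDINE", SOX = "DTT")

#' Count cysteine residues in peptide sequences
#'
#' @param peptide_sequence character vector of amino-acid sequences.
#' @return Integer vector of cysteine counts.
#' @export
count_cysteines <- function(peptide_sequence) {
  nchar(peptide_sequence) - nchar(gsub("C", "", peptide_sequence, fixed = TRUE))
}

#' Classify a peptide into a redox category
#'
#' Peptides without cysteine are \code{NON_CYS} (they feed protein-level
#' quantification); peptides with two or more cysteines are
#' \code{EXCLUDED_MULTI_CYS} (single-cysteine peptides only enter site
#' analysis); a single-cysteine peptide takes the state implied by the
#' modification on its cysteine: a reduced-label modification gives
#' \code{REDUCED}, an S-NO-label modification gives \code{SNO}, and an
#' unmodified cysteine gives \code{SOX}. Modifications on other residues
#' (e.g. methionine oxidation) never affect the state.
#'
#' @param peptide_sequence peptide sequence.
#' @param modifications canonical modification string (as stored by
#'   \code{\link{read_evidence}}).
#' @param labels a \code{\link{redox_label_map}}.
#' @return One of \code{"NON_CYS"}, \code{"EXCLUDED_MULTI_CYS"},
#'   \code{"REDUCED"}, \code{"SNO"}, \code{"SOX"}.
#' @export
classify_peptide <- function(peptide_sequence, modifications = "",
                             labels = redox_label_map()) {
  ncys <- count_cysteines(peptide_sequence)
  if (ncys == 0L) return("NON_CYS")
  if (ncys >= 2L) return("EXCLUDED_MULTI_CYS")
  cpos <- regexpr("C", peptide_sequence, fixed = TRUE)
  mods <- modification_list(modifications)[[1]]
  at_c <- mods[mods$position == as.integer(cpos), , drop = FALSE]
  if (nrow(at_c) == 0L) return("SOX")
  nm <- at_c$name
  if (any(nm %in% labels$reduced)) return("REDUCED")
  if (any(nm %in% labels$sno)) return("SNO")
  stop("unknown cysteine-targeted modification: ",
       paste(setdiff(nm, c(labels$reduced, labels$sno)), collapse = ", "))
}

#' Classify every evidence row
#'
#' Adds a \code{redox_state} column (the partition
#' \{NON_CYS, EXCLUDED_MULTI_CYS, REDUCED, SNO, SOX\}) and, when requested,
#' warns about rows whose enrichment fraction disagrees with the state their
#' chemistry labels imply (classification always follows the labels; the
#' fraction is protocol metadata).
#'
#' @param ev a \code{"redox_evidence"} data frame.
#' @param labels a \code{\link{redox_label_map}}.
#' @param check_fractions warn when label-implied state and fraction disagree.
#' @return \code{ev} with a \code{redox_state} column.
#' @export
classify_evidence <- function(ev, labels = redox_label_map(),
                              check_fractions = TRUE) {
  stopifnot(inherits(ev, "redox_evidence"))
  ev$redox_state <- vapply(seq_len(nrow(ev)), function(i) {
    classify_peptide(ev$peptide_sequence[i], ev$modifications[i], labels)
  }, character(1))
  if (check_fractions) {
    st <- ev$redox_state
    cys <- st %in% .REDOX_STATES & ev$fraction != "NONE"
    bad <- cys & ev$fraction != .STATE_FRACTION[st]
    if (any(bad))
      warning(sum(bad), " cysteine peptide row(s) have an enrichment ",
              "fraction inconsistent with their chemistry label ",
              "(classification follows the label)")
  }
  ev
}

#' Localize a peptide's cysteine within its protein
#'
#' The site position is the 1-based start of the peptide's unique exact
#' occurrence in the protein plus the cysteine's offset within the peptide.
#'
#' @param peptide_sequence single-cysteine peptide.
#' @param protein_sequence full protein sequence.
#' @return 1-based protein position of the cysteine.
#' @export
locate_site <- function(peptide_sequence, protein_sequence) {
  hits <- gregexpr(peptide_sequence, protein_sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("peptide '", peptide_sequence, "' not found in protein")
  if (length(hits) > 1L)
    stop("peptide '", peptide_sequence, "' occurs at multiple positions (",
         paste(hits, collapse = ", "), "); site ambiguous")
  cpos <- as.integer(regexpr("C", peptide_sequence, fixed = TRUE))
  if (cpos < 1L) stop("peptide has no cysteine")
  as.integer(hits[1]) + cpos - 1L
}

#' Localize all classified cysteine peptides
#'
#' Adds a \code{site_position} column for rows whose \code{redox_state} is a
#' cysteine state; rows that cannot be localized (peptide absent from the
#' protein, ambiguous occurrence, or accession missing from the database) get
#' \code{NA} and are reported via attributes.
#'
#' @param ev classified evidence (see \code{\link{classify_evidence}}).
#' @param db a \code{"protein_db"}.
#' @return \code{ev} with \code{site_position}; attribute
#'   \code{localization_failures} is a data frame of distinct
#'   (protein, peptide, reason).
#' @export
locate_sites <- function(ev, db) {
  stopifnot(inherits(ev, "redox_evidence"), !is.null(ev$redox_state))
  ev$site_position <- NA_integer_
  cysrows <- which(ev$redox_state %in% .REDOX_STATES)
  fails <- list()
  cache <- new.env(parent = emptyenv())
  for (i in cysrows) {
    k <- paste(ev$protein_id[i], ev$peptide_sequence[i])
    if (!is.null(cache[[k]])) {
      v <- cache[[k]]
    } else {
      v <- if (!ev$protein_id[i] %in% names(db)) {
        list(pos = NA_integer_, why = "accession not in protein database")
      } else {
        tryCatch(list(pos = locate_site(ev$peptide_sequence[i],
                                        db[[ev$protein_id[i]]]), why = NA),
                 error = function(e) list(pos = NA_integer_,
                                          why = conditionMessage(e)))
      }
      cache[[k]] <- v
      if (is.na(v$pos))
        fails[[k]] <- data.frame(protein_id = ev$protein_id[i],
                                 peptide_sequence = ev$peptide_sequence[i],
                                 reason = v$why, stringsAsFactors = FALSE)
    }
    ev$site_position[i] <- v$pos
  }
  attr(ev, "localization_failures") <-
    if (length(fails)) do.call(rbind, unname(fails)) else
      data.frame(protein_id = character(0), peptide_sequence = character(0),
                 reason = character(0), stringsAsFactors = FALSE)
  ev
}
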