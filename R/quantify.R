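#' Median aggregation of ratios by feature
#'
#' Distinct peptide forms of the same feature (missed-cleavage variants,
#' oxidized-methionine variants, charge states) are collapsed to a single
#' value per group using the median of their ratios.
#'
#' @param values positive numeric ratios.
#' @param grouping feature key, one per value (vector or list of vectors).
#' @return Named numeric vector of per-group medians; empty groups are
#'   omitted.
#' @export
aggregate_median <- function(values, grouping) {
  keep <- !is.na(values)
  g <- if (is.list(grouping)) {
    do.call(paste, c(lapply(grouping, `[`, keep), sep = "\r"))
  } else as.character(grouping)[keep]
  vapply(split(values[keep], g), stats::median, numeric(1))
}

#' Signed fold-change convention
#'
#' Fold changes below 1 are reported as the negated reciprocal, so a ratio of
#' 0.5 reads \code{-2.0} and the magnitude is always at least 1; the sign
#' encodes direction.
#'
#' @param x positive numeric fold changes.
#' @return Numeric vector with \code{signed(x) = x} for \code{x >= 1} and
#'   \code{-1/x} otherwise.
#' @export
signed_fc <- function(x) {
  if (any(!is.na(x) & x <= 0)) stop("fold changes must be positive")
  ifelse(x >= 1, x, -1 / x)
}

#' Invert the signed fold-change convention
#'
#' @param s signed fold changes (|s| >= 1).
#' @return The underlying positive ratio.
#' @export
unsigned_fc <- function(s) ifelse(s >= 0, s, -1 / s)

#' Protein fold changes from cysteine-free peptides
#'
#' Protein expression profiles are estimated from cysteine-free
#' (\code{NON_CYS}) peptides only: per protein, condition and replicate the
#' median heavy/light ratio over quantified peptide forms; the per-condition
#' fold change is the median over detected replicates. Proteins with no
#' quantified cysteine-free peptide anywhere are absent from the result (their
#' sites are unquantifiable and flagged downstream).
#'
#' @param ev classified evidence (see \code{\link{classify_evidence}}).
#' @return A list of class \code{"protein_quant"}: \code{replicates} (long
#'   data frame \code{protein_id}, \code{condition_id}, \code{replicate_id},
#'   \code{ratio}) and \code{conditions} (\code{protein_id},
#'   \code{condition_id}, \code{fc}, \code{n_detected}).
#' @export
protein_fold_changes <- function(ev) {
  stopifnot(inherits(ev, "redox_evidence"), !is.null(ev$redox_state))
  x <- ev[ev$redox_state == "NON_CYS" & !is.na(ev$ratio_hl), , drop = FALSE]
  key <- interaction(x$protein_id, x$condition_id, x$replicate_id,
                     drop = TRUE, sep = "\r")
  med <- vapply(split(x$ratio_hl, key), stats::median, numeric(1))
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  reps <- data.frame(protein_id = parts[, 1], condition_id = parts[, 2],
                     replicate_id = as.integer(parts[, 3]), ratio = unname(med),
                     stringsAsFactors = FALSE)
  reps <- reps[order(reps$protein_id, reps$condition_id, reps$replicate_id), ]
  rownames(reps) <- NULL
  ckey <- interaction(reps$protein_id, reps$condition_id, drop = TRUE,
                      sep = "\r")
  fc <- vapply(split(reps$ratio, ckey), stats::median, numeric(1))
  nd <- vapply(split(reps$ratio, ckey), length, integer(1))
  cparts <- do.call(rbind, strsplit(names(fc), "\r", fixed = TRUE))
  conds <- data.frame(protein_id = cparts[, 1], condition_id = cparts[, 2],
                      fc = unname(fc), n_detected = unname(nd),
                      stringsAsFactors = FALSE)
  rownames(conds) <- NULL
  structure(list(replicates = reps, conditions = conds),
            class = "protein_quant")
}

#' Site fold changes normalized to protein fold changes
#'
#' For every localized single-cysteine peptide: per (site, state, condition,
#' replicate) the raw ratio is the median over peptide forms; the normalized
#' ratio is \code{z = raw / protein ratio} of the same condition and
#' replicate, removing differential protein expression from the modification
#' signal. Per (site, state, condition) the normalized fold change is the
#' median z over replicates, with the variance of \code{log2(z)} when at
#' least two replicates are defined. Replicates where the protein ratio is
#' missing have undefined z (dropped, not imputed); \code{n_detected} counts
#' replicates with a quantified site ratio regardless of protein coverage
#' (used by presence/absence calling).
#'
#' @param ev classified, localized evidence (see \code{\link{locate_sites}}).
#' @param proteins a \code{"protein_quant"} from
#'   \code{\link{protein_fold_changes}}.
#' @return A list of class \code{"site_quant"}: \code{replicates} (long data
#'   frame with \code{raw_ratio}, \code{protein_ratio}, \code{z}) and
#'   \code{conditions} (\code{norm_fc}, \code{var_log2},
#'   \code{n_detected}, \code{n_quantified}); attribute \code{unquantifiable}
#'   lists sites whose protein has no quantification at all.
#' @export
site_fold_changes <- function(ev, proteins) {
  stopifnot(inherits(ev, "redox_evidence"), !is.null(ev$site_position),
            inherits(proteins, "protein_quant"))
  x <- ev[ev$redox_state %in% .REDOX_STATES & !is.na(ev$ratio_hl) &
            !is.na(ev$site_position), , drop = FALSE]
  key <- interaction(x$protein_id, x$site_position, x$redox_state,
                     x$condition_id, x$replicate_id, drop = TRUE, sep = "\r")
  med <- vapply(split(x$ratio_hl, key), stats::median, numeric(1))
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  reps <- data.frame(protein_id = parts[, 1],
                     position = as.integer(parts[, 2]),
                     state = parts[, 3], condition_id = parts[, 4],
                     replicate_id = as.integer(parts[, 5]),
                     raw_ratio = unname(med), stringsAsFactors = FALSE)
  pk <- paste(proteins$replicates$protein_id,
              proteins$replicates$condition_id,
              proteins$replicates$replicate_id, sep = "\r")
  idx <- match(paste(reps$protein_id, reps$condition_id, reps$replicate_id,
                     sep = "\r"), pk)
  reps$protein_ratio <- proteins$replicates$ratio[idx]
  reps$z <- reps$raw_ratio / reps$protein_ratio
  reps <- reps[order(reps$protein_id, reps$position, reps$state,
                     reps$condition_id, reps$replicate_id), ]
  rownames(reps) <- NULL

  ckey <- interaction(reps$protein_id, reps$position, reps$state,
                      reps$condition_id, drop = TRUE, sep = "\r")
  agg <- function(f) vapply(split(seq_len(nrow(reps)), ckey), f, numeric(1))
  norm_fc <- agg(function(i) {
    z <- reps$z[i]; z <- z[!is.na(z)]
    if (length(z)) stats::median(z) else NA_real_
  })
  var_log2 <- agg(function(i) {
    z <- reps$z[i]; z <- z[!is.na(z)]
    if (length(z) >= 2L) stats::var(log2(z)) else NA_real_
  })
  n_det <- agg(function(i) sum(!is.na(reps$raw_ratio[i])))
  n_quant <- agg(function(i) sum(!is.na(reps$z[i])))
  cparts <- do.call(rbind, strsplit(names(norm_fc), "\r", fixed = TRUE))
  conds <- data.frame(protein_id = cparts[, 1],
                      position = as.integer(cparts[, 2]),
                      state = cparts[, 3], condition_id = cparts[, 4],
                      norm_fc = unname(norm_fc), var_log2 = unname(var_log2),
                      n_detected = as.integer(unname(n_det)),
                      n_quantified = as.integer(unname(n_quant)),
                      stringsAsFactors = FALSE)
  rownames(conds) <- NULL
  unq <- unique(reps[is.na(reps$protein_ratio) &
                       !reps$protein_id %in% proteins$conditions$protein_id,
                     c("protein_id", "position", "state")])
  rownames(unq) <- NULL
  structure(list(replicates = reps, conditions = conds),
            unquantifiable = unq, class = "site_quant")
}

#' Compare two conditions on normalized replicate ratios
#'
#' Ratios are oriented heavy-reference over light-sample, so the
#' sample-abundance fold change of condition A relative to condition B is
#' \code{median(z_B) / median(z_A)} (ratio of medians; the reference cancels).
#' A median-of-ratios mode pairing replicates is available. The result is
#' returned in the signed convention together with the per-replicate log2
#' vectors consumed by the statistical tests.
#'
#' @param z_a,z_b normalized replicate ratios for conditions A and B
#'   (heavy/light orientation).
#' @param mode \code{"ratio_of_medians"} (default) or
#'   \code{"median_of_ratios"} (pairs replicates positionally).
#' @return List with \code{signed_fc} (abundance in A relative to B),
#'   \code{log2_a}, \code{log2_b}. \code{signed_fc} is \code{NA} when either
#'   side has no defined value.
#' @export
compare_conditions <- function(z_a, z_b,
                               mode = c("ratio_of_medians",
                                        "median_of_ratios")) {
  mode <- match.arg(mode)
  z_a <- z_a[!is.na(z_a)]; z_b <- z_b[!is.na(z_b)]
  if (!length(z_a) || !length(z_b))
    return(list(signed_fc = NA_real_, log2_a = log2(z_a), log2_b = log2(z_b)))
  fc <- if (mode == "ratio_of_medians") {
    stats::median(z_b) / stats::median(z_a)
  } else {
    m <- min(length(z_a), length(z_b))
    stats::median(z_b[seq_len(m)] / z_a[seq_len(m)])
  }
  list(signed_fc = signed_fc(fc), log2_a = log2(z_a), log2_b = log2(z_b))
}
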