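#' Differential cysteine redox analysis
#'
#' Runs the full quantification and testing pipeline on a peptide-evidence
#' table: classify peptides by their cysteine chemistry labels, localize
#' cysteines to protein sites, estimate protein fold changes from
#' cysteine-free peptides, normalize site ratios to protein ratios, test
#' biofilm against planktonic per oxygen regime (Student's test,
#' Benjamini-Hochberg FDR, fold-change threshold, presence/absence rules),
#' and label oxidation/reduction events.
#'
#' @param evidence a \code{"redox_evidence"} data frame, a data frame in the
#'   dialect's layout, or a path to an evidence TSV.
#' @param proteins a \code{"protein_db"} or a path to a protein FASTA.
#' @param thresholds a \code{\link{redox_thresholds}}.
#' @param label_map a \code{\link{redox_label_map}}.
#' @param dialect an \code{\link{evidence_dialect}} (used when
#'   \code{evidence} is a path or plain data frame).
#' @param t_variant \code{"student"} (default) or \code{"welch"}.
#' @param fc_mode \code{"ratio_of_medians"} (default) or
#'   \code{"median_of_ratios"}.
#' @param check_fractions warn on label/fraction inconsistencies.
#' @return An object of class \code{"redox_analysis"}: list with
#'   \code{calls} (site-level \code{"redox_calls"} with event labels),
#'   \code{protein_calls}, \code{site_quant}, \code{protein_quant},
#'   \code{summary_counts}, \code{runs_qc}, \code{thresholds},
#'   \code{config}, \code{stage_counts}.
#' @export
redox_analysis <- function(evidence, proteins,
                           thresholds = redox_thresholds(),
                           label_map = redox_label_map(),
                           dialect = evidence_dialect(),
                           t_variant = c("student", "welch"),
                           fc_mode = c("ratio_of_medians",
                                       "median_of_ratios"),
                           check_fractions = TRUE) {
  t_variant <- match.arg(t_variant); fc_mode <- match.arg(fc_mode)
  ev <- if (is.character(evidence)) read_evidence(evidence, dialect)
        else as_redox_evidence(evidence, dialect)
  db <- if (inherits(proteins, "protein_db")) proteins
        else if (is.character(proteins) && length(proteins) == 1L)
          read_fasta(proteins)
        else stop("'proteins' must be a protein_db or a FASTA path")

  ev <- classify_evidence(ev, label_map, check_fractions = check_fractions)
  ev <- locate_sites(ev, db)
  pq <- protein_fold_changes(ev)
  sq <- site_fold_changes(ev, pq)
  site_calls <- call_differential(sq, pq, thresholds, variant = t_variant,
                                  fc_mode = fc_mode)
  site_calls <- classify_redox_events(site_calls)
  prot_calls <- call_differential_proteins(pq, thresholds,
                                           variant = t_variant,
                                           fc_mode = fc_mode)
  qc <- runs_qc(sq, thresholds)
  counts <- summary_counts(site_calls, prot_calls)

  stage_counts <- c(evidence_in = attr(ev, "n_input"),
                    evidence_parsed = nrow(ev),
                    evidence_rejected = attr(ev, "n_rejected"),
                    localization_failures =
                      nrow(attr(ev, "localization_failures")),
                    proteins_quantified = length(unique(
                      pq$conditions$protein_id)),
                    sites_quantified = nrow(unique(
                      sq$conditions[, c("protein_id", "position", "state")])),
                    site_calls = nrow(site_calls),
                    protein_calls = nrow(prot_calls))

  structure(list(calls = site_calls, protein_calls = prot_calls,
                 site_quant = sq, protein_quant = pq,
                 summary_counts = counts, runs_qc = qc,
                 thresholds = thresholds,
                 config = list(t_variant = t_variant, fc_mode = fc_mode,
                               label_map = label_map, dialect = dialect$name),
                 stage_counts = stage_counts),
            class = "redox_analysis")
}

#' Summary counts per feature class and regime
#'
#' Tabulates, per oxygen regime and per feature class (PROTEIN, SNO, SOX,
#' REDUCED): unique features tested or called, up in planktonic, up in
#' biofilm, planktonic-only and biofilm-only, with internal consistency
#' checks (up + only never exceeds uniques).
#'
#' @param site_calls,protein_calls \code{"redox_calls"} data frames.
#' @return Data frame of class \code{"redox_summary"}.
#' @export
summary_counts <- function(site_calls, protein_calls) {
  all_calls <- rbind(
    site_calls[, c("state", "regime", "category")],
    protein_calls[, c("state", "regime", "category")])
  classes <- c("PROTEIN", "SNO", "SOX", "REDUCED")
  rows <- list()
  for (rg in unique(all_calls$regime)) for (cl in classes) {
    x <- all_calls[all_calls$regime == rg & all_calls$state == cl, ]
    if (!nrow(x)) next
    rows[[paste(rg, cl)]] <- data.frame(
      regime = rg, class = cl, uniques = nrow(x),
      up_pk = sum(x$category == "UP_PK"),
      up_bf = sum(x$category == "UP_BF"),
      only_pk = sum(x$category == "PK_ONLY"),
      only_bf = sum(x$category == "BF_ONLY"),
      ns = sum(x$category == "NS"),
      untestable = sum(x$category == "UNTESTABLE"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  with(out, stopifnot(up_pk + up_bf + only_pk + only_bf <= uniques,
                      uniques == up_pk + up_bf + only_pk + only_bf + ns +
                        untestable))
  class(out) <- c("redox_summary", "data.frame")
  out
}

#' @export
print.redox_analysis <- function(x, ...) {
  cat("Differential cysteine redox analysis\n")
  sc <- x$stage_counts
  cat(sprintf("  evidence rows: %d parsed (%d rejected)\n",
              sc[["evidence_parsed"]], sc[["evidence_rejected"]]))
  cat(sprintf("  proteins quantified: %d; site-states quantified: %d\n",
              sc[["proteins_quantified"]], sc[["sites_quantified"]]))
  cat(sprintf("  thresholds: adj p < %g, |FC| > %g, only-rule %d/%d\n",
              x$thresholds$alpha, x$thresholds$fc_threshold,
              x$thresholds$only_min_detect, x$thresholds$n_replicates))
  cat("\nSummary counts:\n")
  print.data.frame(x$summary_counts)
  invisible(x)
}

#' @export
summary.redox_analysis <- function(object, ...) object$summary_counts

#' @export
print.redox_summary <- function(x, ...) {
  cat("Redox proteomics summary (uniques / up-PK / up-BF / only-PK / only-BF)\n")
  print.data.frame(x)
  invisible(x)
}

#' Volcano export of differential calls
#'
#' One row per tested feature: log2 of the normalized fold change,
#' -log10 adjusted p-value, and category, per redox state and regime.
#' Condition-specific ("only") features have no finite p-value and are
#' returned in a separate \code{sidecar} attribute.
#'
#' @param calls a \code{"redox_calls"} data frame.
#' @return Data frame (\code{log2_fc}, \code{neg_log10_adj_p},
#'   \code{category}, \code{state}, \code{regime}, feature ids); attribute
#'   \code{sidecar} holds the only/untestable features.
#' @export
export_volcano <- function(calls) {
  stopifnot(inherits(calls, "redox_calls"))
  tested <- !is.na(calls$p_value)
  main <- calls[tested, , drop = FALSE]
  out <- data.frame(protein_id = main$protein_id, position = main$position,
                    state = main$state, regime = main$regime,
                    log2_fc = log2(unsigned_fc(main$signed_fc)),
                    neg_log10_adj_p = -log10(main$adj_p),
                    category = main$category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  side <- calls[!tested, c("protein_id", "position", "state", "regime",
                           "n_detected_bf", "n_detected_pk", "category")]
  rownames(side) <- NULL
  structure(out, sidecar = side)
}

#' Plot volcano panels of the site calls
#'
#' @param x a \code{"redox_analysis"}.
#' @param states redox states to plot.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.redox_analysis <- function(x, states = c("REDUCED", "SNO", "SOX"), ...) {
  v <- export_volcano(x$calls)
  v <- v[v$state %in% states, , drop = FALSE]
  if (!nrow(v)) {
    warning("no tested sites to plot")
    return(invisible(x))
  }
  panels <- unique(v[, c("state", "regime")])
  old <- graphics::par(mfrow = c(length(unique(panels$regime)),
                                 length(unique(panels$state))),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (rg in unique(panels$regime)) for (st in unique(panels$state)) {
    s <- v[v$state == st & v$regime == rg, ]
    if (!nrow(s)) next
    cols <- ifelse(s$category == "UP_BF", "firebrick",
                   ifelse(s$category == "UP_PK", "royalblue", "grey50"))
    graphics::plot(s$log2_fc, s$neg_log10_adj_p, col = cols, pch = 19,
                   xlab = "log2 normalized FC (BF vs PK)",
                   ylab = "-log10 adj p", main = paste(st, rg), ...)
    graphics::abline(h = -log10(x$thresholds$alpha), lty = 2, col = "grey70")
    graphics::abline(v = c(-1, 1) * log2(x$thresholds$fc_threshold),
                     lty = 2, col = "grey70")
  }
  invisible(x)
}

#' Annotate calls with functional category codes
#'
#' Left join of a user-supplied accession-to-category mapping (e.g. COG
#' letter codes) onto a calls table; unmapped features keep an empty code.
#'
#' @param calls a \code{"redox_calls"} data frame.
#' @param mapping a data frame with columns \code{protein_id},
#'   \code{category_code}, or a path to a two-column TSV (no header
#'   required if named \code{protein_id}/\code{category_code}; otherwise the
#'   first two columns are used).
#' @return \code{calls} with a \code{category_code} column.
#' @export
annotate_categories <- function(calls, mapping) {
  stopifnot(inherits(calls, "redox_calls"))
  if (is.character(mapping)) {
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE,
                                 check.names = FALSE)
  }
  if (ncol(mapping) < 2) stop("mapping needs accession and code columns")
  if (!all(c("protein_id", "category_code") %in% names(mapping)))
    names(mapping)[1:2] <- c("protein_id", "category_code")
  bad <- is.na(mapping$protein_id) | mapping$protein_id == ""
  if (any(bad)) {
    warning(sum(bad), " malformed mapping row(s) skipped")
    mapping <- mapping[!bad, , drop = FALSE]
  }
  idx <- match(calls$protein_id, mapping$protein_id)
  calls$category_code <- ifelse(is.na(idx), "",
                                as.character(mapping$category_code[idx]))
  calls
}

#' Write all analysis outputs to a directory
#'
#' Writes site and protein differential calls, per-site quantification,
#' summary counts, volcano tables (main + sidecar), runs-test QC, and a JSON
#' provenance record (configuration, thresholds, stage row counts, package
#' version).
#'
#' @param x a \code{"redox_analysis"}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "redox_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    as.data.frame(df), file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(x$calls, "site_calls.tsv")
  wt(x$protein_calls, "protein_calls.tsv")
  wt(x$site_quant$conditions, "site_quant.tsv")
  wt(x$protein_quant$conditions, "protein_quant.tsv")
  wt(x$summary_counts, "summary_counts.tsv")
  v <- export_volcano(x$calls)
  wt(v, "volcano.tsv")
  wt(attr(v, "sidecar"), "volcano_only_sidecar.tsv")
  wt(x$runs_qc, "runs_qc.tsv")
  prov <- list(package = "cysredox",
               version = as.character(utils::packageVersion("cysredox")),
               thresholds = unclass(x$thresholds),
               config = list(t_variant = x$config$t_variant,
                             fc_mode = x$config$fc_mode,
                             dialect = x$config$dialect,
                             label_map = unclass(x$config$label_map)),
               stage_counts = as.list(x$stage_counts))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Run the pipeline from a configuration list or file
#'
#' Thin orchestration over \code{\link{redox_analysis}} +
#' \code{\link{write_results}} for scripted use: reads inputs, runs the
#' analysis, writes every output table plus provenance.
#'
#' @param config list (or path to a JSON file) with \code{evidence},
#'   \code{fasta}, \code{out_dir}, and optional \code{alpha},
#'   \code{fc_threshold}, \code{n_replicates}, \code{t_variant},
#'   \code{fc_mode}, \code{category_mapping}.
#' @return The \code{"redox_analysis"}, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  for (f in c("evidence", "fasta", "out_dir"))
    if (is.null(config[[f]])) stop("config lacks required field '", f, "'")
  for (f in c("evidence", "fasta"))
    if (!file.exists(config[[f]]))
      stop("input file not found: ", config[[f]])
  th <- redox_thresholds(
    alpha = config$alpha %||% 0.05,
    fc_threshold = config$fc_threshold %||% 1.75,
    n_replicates = config$n_replicates %||% 5L)
  res <- redox_analysis(config$evidence, config$fasta, thresholds = th,
                        t_variant = config$t_variant %||% "student",
                        fc_mode = config$fc_mode %||% "ratio_of_medians")
  if (!is.null(config$category_mapping))
    res$calls <- annotate_categories(res$calls, config$category_mapping)
  write_results(res, config$out_dir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
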