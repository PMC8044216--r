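#' Significance thresholds and detection rules
#'
#' @param alpha BH-adjusted p-value threshold (default 0.05).
#' @param fc_threshold minimum signed fold-change magnitude, strictly
#'   exceeded, for a significant call (default 1.75).
#' @param n_replicates biological replicates per condition (default 5).
#' @param only_min_detect minimum detected replicates in one condition for an
#'   "only" call (default \code{n_replicates - 1}, i.e. 4 of 5).
#' @param only_max_other maximum detected replicates allowed in the other
#'   condition (default 0, i.e. absent).
#' @param runs_alpha p-value threshold for the dataset randomness QC
#'   (default 0.05).
#' @return A list of class \code{"redox_thresholds"}.
#' @export
redox_thresholds <- function(alpha = 0.05, fc_threshold = 1.75,
                             n_replicates = 5L,
                             only_min_detect = n_replicates - 1L,
                             only_max_other = 0L, runs_alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold >= 1, n_replicates >= 1,
            only_max_other >= 0, only_max_other < only_min_detect,
            only_min_detect <= n_replicates, runs_alpha > 0, runs_alpha < 1)
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 n_replicates = as.integer(n_replicates),
                 only_min_detect = as.integer(only_min_detect),
                 only_max_other = as.integer(only_max_other),
                 runs_alpha = runs_alpha),
            class = "redox_thresholds")
}

#' Exact distribution of the number of runs
#'
#' Probability mass of the run count R in a random arrangement of
#' \code{n_pos} symbols of one kind and \code{n_neg} of the other, from the
#' classical closed form: for even R = 2k,
#' P = 2 C(n1-1,k-1) C(n2-1,k-1) / C(n,n1); for odd R = 2k+1,
#' P = [C(n1-1,k-1) C(n2-1,k) + C(n1-1,k) C(n2-1,k-1)] / C(n,n1).
#'
#' @param n_pos,n_neg symbol counts (both >= 1).
#' @return Named numeric vector of probabilities over R = 2..n_pos+n_neg.
#' @export
runs_distribution <- function(n_pos, n_neg) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  n <- n_pos + n_neg
  denom <- choose(n, n_pos)
  r <- 2:n
  p <- vapply(r, function(ri) {
    if (ri %% 2 == 0) {
      k <- ri %/% 2
      2 * choose(n_pos - 1, k - 1) * choose(n_neg - 1, k - 1) / denom
    } else {
      k <- (ri - 1) %/% 2
      (choose(n_pos - 1, k - 1) * choose(n_neg - 1, k) +
         choose(n_pos - 1, k) * choose(n_neg - 1, k - 1)) / denom
    }
  }, numeric(1))
  names(p) <- r
  p
}

#' Wald-Wolfowitz runs test
#'
#' Tests the randomness of a two-symbol sequence via its number of maximal
#' same-symbol runs. For sequences of at most \code{exact_max} symbols the
#' two-sided p-value is computed from the exact runs distribution
#' (\code{p = min(1, 2 min(P(R <= r), P(R >= r)))}); longer sequences use the
#' normal approximation with continuity correction.
#'
#' @param signs character (\code{"+"}/\code{"-"}) or numeric (sign) sequence.
#' @param exact_max largest n for the exact distribution (default 30).
#' @return List with \code{runs} (observed R), \code{n_pos}, \code{n_neg},
#'   \code{p_value} (NA when fewer than 2 symbols or only one symbol kind is
#'   present) and \code{method}.
#' @export
runs_test <- function(signs, exact_max = 30L) {
  if (is.numeric(signs)) signs <- ifelse(signs >= 0, "+", "-")
  signs <- signs[signs %in% c("+", "-")]
  n_pos <- sum(signs == "+"); n_neg <- sum(signs == "-")
  n <- n_pos + n_neg
  if (n < 2L || n_pos == 0L || n_neg == 0L)
    return(list(runs = if (n) length(rle(signs)$lengths) else NA_integer_,
                n_pos = n_pos, n_neg = n_neg, p_value = NA_real_,
                method = "undefined (one-sided or too short)"))
  r_obs <- length(rle(signs)$lengths)
  if (n <= exact_max) {
    pm <- runs_distribution(n_pos, n_neg)
    r <- as.integer(names(pm))
    lower <- sum(pm[r <= r_obs]); upper <- sum(pm[r >= r_obs])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- 1 + 2 * n_pos * n_neg / n
    sigma <- sqrt(2 * n_pos * n_neg * (2 * n_pos * n_neg - n) /
                    (n^2 * (n - 1)))
    z <- (abs(r_obs - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(runs = r_obs, n_pos = n_pos, n_neg = n_neg, p_value = p,
       method = method)
}

#' Deviation signs of a site's ratios from its protein's ratios
#'
#' Per replicate, in input order, the sign of
#' \code{log2(site ratio / protein ratio)}; exact zeros (and undefined pairs)
#' are dropped. These sequences feed the dataset-level runs-test QC.
#'
#' @param site_ratios,protein_ratios positive replicate ratios, aligned.
#' @return Character vector over \{"+", "-"\}.
#' @export
deviation_signs <- function(site_ratios, protein_ratios) {
  d <- log2(site_ratios / protein_ratios)
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) return(character(0))
  ifelse(d > 0, "+", "-")
}

#' Two-sample t-test on log2 normalized ratios
#'
#' Student's (pooled-variance) two-sided t-test by default; Welch available.
#' Groups with fewer than two values are untestable (\code{NA}); constant
#' groups with zero pooled variance return p = 1 when the means are equal and
#' p = 0 otherwise, so noiseless data flow through the caller.
#'
#' @param a,b numeric vectors (log2 normalized ratios per replicate).
#' @param variant \code{"student"} or \code{"welch"}.
#' @return Two-sided p-value, or \code{NA_real_} if untestable.
#' @export
site_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  tryCatch(stats::t.test(a, b, var.equal = variant == "student")$p.value,
           error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (each the minimum over higher ranks of
#' m p/rank, capped at 1). NAs are preserved and excluded from m.
#'
#' @param p_values numeric p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Presence/absence ("only") calling
#'
#' A feature detected in at least \code{only_min_detect} replicates of one
#' condition and at most \code{only_max_other} of the other (defaults: 4 of 5
#' and absent) is condition-specific. Cysteine-site features are eligible
#' only when their parent protein is detected in both conditions, so a
#' missing protein cannot masquerade as a modification change.
#'
#' @param detect_a,detect_b detected replicate counts in conditions A and B.
#' @param protein_in_both is the parent protein detected in both conditions?
#'   (ignored for \code{feature_kind = "protein"}).
#' @param th a \code{\link{redox_thresholds}}.
#' @param feature_kind \code{"site"} or \code{"protein"}.
#' @return \code{"A_ONLY"}, \code{"B_ONLY"} or \code{"NONE"}.
#' @export
presence_absence_call <- function(detect_a, detect_b, protein_in_both = TRUE,
                                  th = redox_thresholds(),
                                  feature_kind = c("site", "protein")) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(detect_a >= 0, detect_b >= 0,
            detect_a <= th$n_replicates, detect_b <= th$n_replicates)
  if (feature_kind == "site" && !isTRUE(protein_in_both)) return("NONE")
  if (detect_a >= th$only_min_detect && detect_b <= th$only_max_other)
    return("A_ONLY")
  if (detect_b >= th$only_min_detect && detect_a <= th$only_max_other)
    return("B_ONLY")
  "NONE"
}

# Derive BF/PK condition pairs per oxygen regime from condition ids of the
# form <lifestyle>_<regime> with lifestyles BF and PK.
condition_pairs <- function(conditions) {
  m <- regmatches(conditions, regexec("^(BF|PK)_(.+)$", conditions))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("condition ids must look like BF_<regime> / PK_<regime>; got: ",
         paste(conditions[!ok], collapse = ", "))
  life <- vapply(m, `[`, "", 2); regime <- vapply(m, `[`, "", 3)
  pairs <- list()
  for (rg in unique(regime)) {
    bf <- conditions[life == "BF" & regime == rg]
    pk <- conditions[life == "PK" & regime == rg]
    if (length(bf) == 1L && length(pk) == 1L)
      pairs[[rg]] <- c(BF = bf, PK = pk)
  }
  if (!length(pairs)) stop("no complete BF/PK condition pair found")
  pairs
}

#' Differential calls for cysteine sites
#'
#' Per oxygen regime and per (site, state): sites with at least two
#' quantified normalized ratios on each side get a Student's t-test on
#' log2(z); p-values are BH-adjusted within one family per redox state per
#' regime (the four LC-MS/MS series are independent). A site is \code{UP_BF}
#' or \code{UP_PK} when adjusted p < alpha and |signed FC| strictly exceeds
#' the fold-change threshold, the sign giving the direction (positive =
#' higher in biofilm). Untestable sites are routed to
#' \code{\link{presence_absence_call}} (\code{BF_ONLY} / \code{PK_ONLY}),
#' requiring the parent protein in both conditions; those failing that rule
#' too are kept as \code{UNTESTABLE} for audit. Every call records the
#' thresholds used.
#'
#' @param sites a \code{"site_quant"} from \code{\link{site_fold_changes}}.
#' @param proteins the matching \code{"protein_quant"}.
#' @param th a \code{\link{redox_thresholds}}.
#' @param variant t-test variant, \code{"student"} or \code{"welch"}.
#' @param fc_mode fold-change aggregation across replicates (see
#'   \code{\link{compare_conditions}}).
#' @return Data frame of class \code{"redox_calls"}: one row per
#'   (protein, position, state, regime) with \code{signed_fc},
#'   \code{p_value}, \code{adj_p}, \code{category} in \{UP_BF, UP_PK,
#'   BF_ONLY, PK_ONLY, NS, UNTESTABLE\}, detection counts and thresholds.
#' @export
call_differential <- function(sites, proteins, th = redox_thresholds(),
                              variant = c("student", "welch"),
                              fc_mode = c("ratio_of_medians",
                                          "median_of_ratios")) {
  variant <- match.arg(variant); fc_mode <- match.arg(fc_mode)
  sc <- sites$conditions; sr <- sites$replicates
  pairs <- condition_pairs(unique(sc$condition_id))
  pc <- proteins$conditions
  out <- list()
  for (rg in names(pairs)) {
    bf <- pairs[[rg]][["BF"]]; pk <- pairs[[rg]][["PK"]]
    sub <- sc[sc$condition_id %in% c(bf, pk), , drop = FALSE]
    feats <- unique(sub[, c("protein_id", "position", "state")])
    if (!nrow(feats)) next
    rows <- lapply(seq_len(nrow(feats)), function(i) {
      f <- feats[i, ]
      sel <- sr$protein_id == f$protein_id & sr$position == f$position &
        sr$state == f$state
      z_bf <- sr$z[sel & sr$condition_id == bf]
      z_pk <- sr$z[sel & sr$condition_id == pk]
      det_bf <- sum(sel & sr$condition_id == bf & !is.na(sr$raw_ratio))
      det_pk <- sum(sel & sr$condition_id == pk & !is.na(sr$raw_ratio))
      cmp <- compare_conditions(z_bf, z_pk, mode = fc_mode)
      p <- site_ttest(cmp$log2_a, cmp$log2_b, variant = variant)
      data.frame(protein_id = f$protein_id, position = f$position,
                 state = f$state, regime = rg, signed_fc = cmp$signed_fc,
                 p_value = p, n_detected_bf = det_bf, n_detected_pk = det_pk,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    # one BH family per redox state within this regime
    df$adj_p <- NA_real_
    for (st in unique(df$state)) {
      i <- df$state == st
      df$adj_p[i] <- bh_adjust(df$p_value[i])
    }
    prot_both <- with(pc, tapply(n_detected > 0, list(protein_id, condition_id),
                                 any))
    in_both <- function(pid) {
      pid %in% rownames(prot_both) &&
        isTRUE(prot_both[pid, bf]) && isTRUE(prot_both[pid, pk])
    }
    df$category <- vapply(seq_len(nrow(df)), function(i) {
      if (!is.na(df$p_value[i])) {
        sig <- df$adj_p[i] < th$alpha & abs(df$signed_fc[i]) > th$fc_threshold
        if (isTRUE(sig)) {
          if (df$signed_fc[i] > 0) "UP_BF" else "UP_PK"
        } else "NS"
      } else {
        pa <- presence_absence_call(df$n_detected_bf[i], df$n_detected_pk[i],
                                    in_both(df$protein_id[i]), th, "site")
        switch(pa, A_ONLY = "BF_ONLY", B_ONLY = "PK_ONLY", "UNTESTABLE")
      }
    }, character(1))
    out[[rg]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$alpha <- th$alpha
  res$fc_threshold <- th$fc_threshold
  class(res) <- c("redox_calls", "data.frame")
  res
}

#' Differential calls for protein expression
#'
#' Same machinery as \code{\link{call_differential}} applied to protein-level
#' replicate ratios from cysteine-free peptides; one BH family per regime.
#'
#' @inheritParams call_differential
#' @return Data frame of class \code{"redox_calls"} with \code{state =
#'   "PROTEIN"}.
#' @export
call_differential_proteins <- function(proteins, th = redox_thresholds(),
                                       variant = c("student", "welch"),
                                       fc_mode = c("ratio_of_medians",
                                                   "median_of_ratios")) {
  variant <- match.arg(variant); fc_mode <- match.arg(fc_mode)
  pr <- proteins$replicates
  pairs <- condition_pairs(unique(pr$condition_id))
  out <- list()
  for (rg in names(pairs)) {
    bf <- pairs[[rg]][["BF"]]; pk <- pairs[[rg]][["PK"]]
    pids <- unique(pr$protein_id[pr$condition_id %in% c(bf, pk)])
    rows <- lapply(pids, function(pid) {
      r_bf <- pr$ratio[pr$protein_id == pid & pr$condition_id == bf]
      r_pk <- pr$ratio[pr$protein_id == pid & pr$condition_id == pk]
      cmp <- compare_conditions(r_bf, r_pk, mode = fc_mode)
      data.frame(protein_id = pid, position = NA_integer_, state = "PROTEIN",
                 regime = rg, signed_fc = cmp$signed_fc,
                 p_value = site_ttest(cmp$log2_a, cmp$log2_b, variant),
                 n_detected_bf = length(r_bf), n_detected_pk = length(r_pk),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$adj_p <- bh_adjust(df$p_value)
    df$category <- vapply(seq_len(nrow(df)), function(i) {
      if (!is.na(df$p_value[i])) {
        sig <- df$adj_p[i] < th$alpha & abs(df$signed_fc[i]) > th$fc_threshold
        if (isTRUE(sig)) {
          if (df$signed_fc[i] > 0) "UP_BF" else "UP_PK"
        } else "NS"
      } else {
        pa <- presence_absence_call(df$n_detected_bf[i], df$n_detected_pk[i],
                                    TRUE, th, "protein")
        switch(pa, A_ONLY = "BF_ONLY", B_ONLY = "PK_ONLY", "UNTESTABLE")
      }
    }, character(1))
    out[[rg]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$alpha <- th$alpha
  res$fc_threshold <- th$fc_threshold
  class(res) <- c("redox_calls", "data.frame")
  res
}

#' Label significant calls as oxidation or reduction events
#'
#' An increase in S-NO or S-OX is an oxidation event in the condition where
#' it rises; an increase in the reduced (S-H) fraction is a reduction event.
#' Condition-specific ("only") calls count as increases in that condition.
#'
#' @param calls a \code{"redox_calls"} data frame of site calls.
#' @return \code{calls} with \code{event} (\code{"oxidation"},
#'   \code{"reduction"} or \code{NA}) and \code{event_condition}
#'   (\code{"BF"}, \code{"PK"} or \code{NA}) columns.
#' @export
classify_redox_events <- function(calls) {
  stopifnot(inherits(calls, "redox_calls"))
  up_in <- ifelse(calls$category %in% c("UP_BF", "BF_ONLY"), "BF",
                  ifelse(calls$category %in% c("UP_PK", "PK_ONLY"), "PK",
                         NA_character_))
  ev <- ifelse(is.na(up_in) | calls$state == "PROTEIN", NA_character_,
               ifelse(calls$state %in% c("SNO", "SOX"),
                      "oxidation", "reduction"))
  calls$event <- ev
  calls$event_condition <- ifelse(is.na(ev), NA_character_, up_in)
  calls
}

#' Dataset-level randomness QC via the runs test
#'
#' Concatenates, per condition, the deviation-sign sequences of every site
#' (sign of log2(site ratio / protein ratio), replicate input order) and runs
#' the Wald-Wolfowitz runs test on each, as a quality check on the
#' randomness of the dataset. Reported, never used to filter sites.
#'
#' @param sites a \code{"site_quant"}.
#' @param th a \code{\link{redox_thresholds}} (supplies \code{runs_alpha}).
#' @return Data frame: condition, n signs, runs, p-value, pass flag.
#' @export
runs_qc <- function(sites, th = redox_thresholds()) {
  sr <- sites$replicates
  conds <- unique(sr$condition_id)
  rows <- lapply(conds, function(cc) {
    sub <- sr[sr$condition_id == cc & !is.na(sr$z), , drop = FALSE]
    sub <- sub[order(sub$protein_id, sub$position, sub$state,
                     sub$replicate_id), ]
    signs <- deviation_signs(sub$raw_ratio, sub$protein_ratio)
    rt <- runs_test(signs)
    data.frame(condition_id = cc, n_signs = length(signs), runs = rt$runs,
               p_value = rt$p_value,
               random = is.na(rt$p_value) | rt$p_value >= th$runs_alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
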