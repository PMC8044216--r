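#' Simulation parameters for synthetic biotin-switch SILAC evidence
#'
#' Describes a virtual experiment with the structure the analysis assumes:
#' two lifestyles (biofilm BF, planktonic PK) by two oxygen regimes, five
#' biological replicates each, every sample mixed with a common heavy
#' reference that is a 5:5:1 blend of three planktonic redox states
#' (non-, mildly and strongly S-nitrosylating). Each cysteine site carries an
#' occupancy vector over \{REDUCED, SNO, SOX\}; per condition and replicate,
#' protein abundance is baseline times \code{2^log2fc}, state-specific site
#' abundance is protein abundance times occupancy, and the emitted
#' heavy/light ratio is reference/sample with multiplicative lognormal noise
#' (\code{2^N(0, noise_sigma^2)}). Effects are planted by overriding
#' occupancies (differential and condition-specific "only" sites) or protein
#' log2 fold changes.
#'
#' By default the sample baseline occupancy equals the reference-mixture
#' composition, so an effect-free noiseless dataset has every normalized
#' ratio exactly 1.
#'
#' @param n_proteins number of proteins.
#' @param n_cys_free_peptides cysteine-free peptides per protein (protein
#'   quantification).
#' @param n_cys_sites single-cysteine sites (= peptides) per protein.
#' @param n_replicates biological replicates per condition.
#' @param regimes oxygen regimes; condition ids are
#'   \code{<BF|PK>_<regime>}.
#' @param reference_weights mixture weights of the three reference states.
#' @param reference_occupancies 3 x 3 matrix (rows: reference states,
#'   columns REDUCED/SNO/SOX), each row summing to 1.
#' @param occupancy_base baseline site occupancy vector; default: the
#'   weighted reference-mixture composition.
#' @param noise_sigma sd of the log2 multiplicative ratio noise.
#' @param dropout_prob per-(feature, replicate) missing probability.
#' @param dropout_mode \code{"uniform"} or \code{"intensity"} (logistic,
#'   low-abundance features drop out more).
#' @param dup_fraction probability a feature also yields an
#'   oxidized-methionine peptide form (exercises median aggregation).
#' @param fraction_swap_rate probability a cysteine row is tagged with a
#'   wrong enrichment fraction (exercises the consistency warning).
#' @param protein_log2fc \code{NULL} or data frame
#'   (\code{protein_id}, \code{condition_id}, \code{log2fc}).
#' @param planted_diff_sites \code{NULL} or data frame
#'   (\code{protein_id}, \code{site_index}, \code{state},
#'   \code{condition_id}, \code{occupancy}): sets that state's occupancy in
#'   that condition, rescaling the other states.
#' @param planted_only_sites \code{NULL} or data frame
#'   (\code{protein_id}, \code{site_index}, \code{state},
#'   \code{absent_condition}): occupancy 0 in that condition.
#' @param peptide_length residues per generated tryptic peptide.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return A list of class \code{"sim_params"}.
#' @export
sim_params <- function(n_proteins = 40L, n_cys_free_peptides = 3L,
                       n_cys_sites = 2L, n_replicates = 5L,
                       regimes = c("O2", "anoxic"),
                       reference_weights = c(non_sno = 5, mild = 5,
                                             strong = 1),
                       reference_occupancies = rbind(
                         non_sno = c(REDUCED = 0.90, SNO = 0.02, SOX = 0.08),
                         mild    = c(REDUCED = 0.80, SNO = 0.10, SOX = 0.10),
                         strong  = c(REDUCED = 0.55, SNO = 0.30, SOX = 0.15)),
                       occupancy_base = NULL,
                       noise_sigma = 0.3, dropout_prob = 0.1,
                       dropout_mode = c("uniform", "intensity"),
                       dup_fraction = 0.2, fraction_swap_rate = 0,
                       protein_log2fc = NULL, planted_diff_sites = NULL,
                       planted_only_sites = NULL, peptide_length = 12L,
                       seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  stopifnot(n_proteins >= 1, n_cys_free_peptides >= 1, n_cys_sites >= 0,
            n_replicates >= 1, length(regimes) >= 1,
            all(reference_weights > 0), noise_sigma >= 0,
            dropout_prob >= 0, dropout_prob < 1,
            dup_fraction >= 0, dup_fraction <= 1,
            fraction_swap_rate >= 0, fraction_swap_rate <= 1,
            peptide_length >= 6)
  refocc <- reference_occupancies[, c("REDUCED", "SNO", "SOX"), drop = FALSE]
  if (any(refocc < 0) || any(abs(rowSums(refocc) - 1) > 1e-9))
    stop("reference occupancy rows must be nonnegative and sum to 1")
  w <- reference_weights / sum(reference_weights)
  mix <- drop(w %*% refocc)
  if (is.null(occupancy_base)) occupancy_base <- mix
  occupancy_base <- occupancy_base[c("REDUCED", "SNO", "SOX")]
  if (any(occupancy_base < 0) || abs(sum(occupancy_base) - 1) > 1e-9)
    stop("occupancy_base must be nonnegative and sum to 1")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_cys_free_peptides = as.integer(n_cys_free_peptides),
                 n_cys_sites = as.integer(n_cys_sites),
                 n_replicates = as.integer(n_replicates),
                 regimes = regimes,
                 reference_weights = reference_weights,
                 reference_occupancies = refocc,
                 reference_mixture = mix,
                 occupancy_base = occupancy_base,
                 noise_sigma = noise_sigma, dropout_prob = dropout_prob,
                 dropout_mode = dropout_mode, dup_fraction = dup_fraction,
                 fraction_swap_rate = fraction_swap_rate,
                 protein_log2fc = protein_log2fc,
                 planted_diff_sites = planted_diff_sites,
                 planted_only_sites = planted_only_sites,
                 peptide_length = as.integer(peptide_length),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# amino acids available for random peptides: no C (inserted deliberately),
# no K/R inside (tryptic), no M except the fixed one at position 2
.PEP_ALPHABET <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "P",
                   "Q", "S", "T", "V", "W", "Y")

# one tryptic peptide: X M X...X K/R, optionally with a single C inside
.random_peptide <- function(len, with_cys) {
  body <- sample(.PEP_ALPHABET, len - 1L, replace = TRUE)
  body[2] <- "M"
  if (with_cys) {
    cpos <- sample(3:(len - 2L), 1L)
    body[cpos] <- "C"
  }
  paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
}

# peptides for one protein; each must occur exactly once in the concatenated
# sequence so site localization is unambiguous
.protein_peptides <- function(n_free, n_cys, len) {
  for (attempt in 1:200) {
    peps <- c(vapply(seq_len(n_free), function(i) .random_peptide(len, FALSE),
                     ""),
              vapply(seq_len(n_cys), function(i) .random_peptide(len, TRUE),
                     ""))
    seqn <- paste(peps, collapse = "")
    counts <- vapply(peps, function(p)
      length(gregexpr(p, seqn, fixed = TRUE)[[1]]), integer(1))
    hit0 <- vapply(peps, function(p)
      gregexpr(p, seqn, fixed = TRUE)[[1]][1] != -1L, logical(1))
    if (all(counts == 1L & hit0) && !anyDuplicated(peps))
      return(list(peptides = peps, sequence = seqn))
  }
  stop("could not generate substring-unique peptides; increase peptide_length")
}

#' Generate a synthetic biotin-switch SILAC dataset
#'
#' Produces an evidence table (MaxQuant-style columns, loadable by
#' \code{\link{read_evidence}} with the default dialect), the matching
#' protein database, and the planted ground truth. Deterministic given
#' \code{params$seed}.
#'
#' @param params a \code{\link{sim_params}}.
#' @return A list of class \code{"redox_sim"}: \code{evidence} (data frame),
#'   \code{proteins} (a \code{"protein_db"}), \code{ground_truth} (list:
#'   site table, occupancy table, protein log2 fold changes, expected
#'   normalized site fold changes per regime, planted effect lists),
#'   \code{params}.
#' @export
simulate_redox_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  states <- c("REDUCED", "SNO", "SOX")
  conditions <- as.vector(t(outer(c("BF", "PK"), params$regimes, paste,
                                  sep = "_")))
  nrep <- params$n_replicates

  # proteins and peptides
  pids <- sprintf("P%03d", seq_len(params$n_proteins))
  prot <- lapply(pids, function(p)
    .protein_peptides(params$n_cys_free_peptides, params$n_cys_sites,
                      params$peptide_length))
  names(prot) <- pids
  db <- structure(vapply(prot, `[[`, "", "sequence"), class = "protein_db")

  sites <- do.call(rbind, lapply(pids, function(p) {
    peps <- prot[[p]]$peptides
    cys <- peps[count_cysteines(peps) == 1L]
    if (!length(cys)) return(NULL)
    data.frame(protein_id = p, site_index = seq_along(cys),
               peptide = cys,
               position = vapply(cys, function(pe)
                 locate_site(pe, prot[[p]]$sequence), integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL

  # occupancy array: site x condition x state
  ns <- nrow(sites)
  occ <- array(rep(params$occupancy_base, each = ns * length(conditions)),
               dim = c(ns, length(conditions), 3L),
               dimnames = list(NULL, conditions, states))
  site_row <- function(p, si) which(sites$protein_id == p &
                                      sites$site_index == si)
  set_occ <- function(i, cond, state, value) {
    old <- occ[i, cond, ]
    others <- setdiff(states, state)
    rest <- sum(old[others])
    occ[i, cond, state] <<- value
    occ[i, cond, others] <<- if (rest > 0) {
      old[others] * ((1 - value) / rest)
    } else rep((1 - value) / length(others), length(others))
  }
  pd <- params$planted_diff_sites
  if (!is.null(pd)) for (j in seq_len(nrow(pd))) {
    i <- site_row(pd$protein_id[j], pd$site_index[j])
    if (!length(i)) stop("planted site not found: ", pd$protein_id[j])
    set_occ(i, pd$condition_id[j], pd$state[j], pd$occupancy[j])
  }
  po <- params$planted_only_sites
  if (!is.null(po)) for (j in seq_len(nrow(po))) {
    i <- site_row(po$protein_id[j], po$site_index[j])
    if (!length(i)) stop("planted site not found: ", po$protein_id[j])
    set_occ(i, po$absent_condition[j], po$state[j], 0)
  }

  # protein log2 fold changes (default 0)
  lfc <- matrix(0, params$n_proteins, length(conditions),
                dimnames = list(pids, conditions))
  pl <- params$protein_log2fc
  if (!is.null(pl)) for (j in seq_len(nrow(pl)))
    lfc[pl$protein_id[j], pl$condition_id[j]] <- pl$log2fc[j]

  ref_occ <- params$reference_mixture  # reference protein abundance is 1

  # accumulate evidence rows
  acc <- list(seq = character(0), mods = character(0), prot = character(0),
              ratio = numeric(0), inten = numeric(0), cond = character(0),
              rep = integer(0), frac = character(0), charge = integer(0))
  emit <- function(seqn, mods, p, ratio, inten, cond, k, frac) {
    acc$seq <<- c(acc$seq, seqn); acc$mods <<- c(acc$mods, mods)
    acc$prot <<- c(acc$prot, p); acc$ratio <<- c(acc$ratio, ratio)
    acc$inten <<- c(acc$inten, inten); acc$cond <<- c(acc$cond, cond)
    acc$rep <<- c(acc$rep, k); acc$frac <<- c(acc$frac, frac)
    acc$charge <<- c(acc$charge, sample(2:3, 1L))
  }
  noise <- function() 2^stats::rnorm(1L, 0, params$noise_sigma)
  dropped <- function(ab) {
    p <- if (params$dropout_mode == "uniform") params$dropout_prob else
      stats::plogis(stats::qlogis(min(params$dropout_prob + 1e-12, 1 - 1e-12)) -
                      2 * log2(ab))
    stats::runif(1L) < p
  }
  maybe_swap <- function(frac) {
    if (params$fraction_swap_rate > 0 &&
        stats::runif(1L) < params$fraction_swap_rate)
      sample(setdiff(c("UNBOUND", "DTT", "GUANIDINE"), frac), 1L)
    else frac
  }
  state_frac <- c(REDUCED = "UNBOUND", SNO = "GUANIDINE", SOX = "DTT")
  state_mod <- function(state, cpos) switch(state,
    REDUCED = sprintf("Carbamidomethyl (C) %d", cpos),
    SNO = sprintf("IAM-biotin (C) %d", cpos),
    SOX = "")

  for (p in pids) {
    peps <- prot[[p]]$peptides
    free <- peps[count_cysteines(peps) == 0L]
    psites <- sites[sites$protein_id == p, , drop = FALSE]
    for (cond in conditions) {
      A <- 2^lfc[p, cond]
      for (k in seq_len(nrep)) {
        for (pe in free) {
          if (dropped(A)) next
          r <- (1 / A) * noise()
          emit(pe, "", p, r, A * 1e8, cond, k, "UNBOUND")
          if (stats::runif(1L) < params$dup_fraction)
            emit(pe, "Oxidation (M) 2", p, (1 / A) * noise(),
                 A * 4e7, cond, k, "UNBOUND")
        }
        for (si in seq_len(nrow(psites))) {
          i <- which(sites$protein_id == p &
                       sites$site_index == psites$site_index[si])
          pe <- psites$peptide[si]
          cpos <- as.integer(regexpr("C", pe, fixed = TRUE))
          for (st in states) {
            ocs <- occ[i, cond, st]
            if (ocs <= 0) next
            ab <- A * ocs
            if (dropped(ab)) next
            r <- (ref_occ[[st]] / ab) * noise()
            fr <- maybe_swap(state_frac[[st]])
            emit(pe, state_mod(st, cpos), p, r, ab * 1e8, cond, k, fr)
            if (stats::runif(1L) < params$dup_fraction)
              emit(pe, paste0(sub("^$", "", state_mod(st, cpos)),
                              if (st == "SOX") "Oxidation (M) 2" else
                                ";Oxidation (M) 2"),
                   p, (ref_occ[[st]] / ab) * noise(), ab * 4e7, cond, k, fr)
          }
        }
      }
    }
  }

  evidence <- data.frame(
    Sequence = acc$seq, Modifications = acc$mods,
    `Leading razor protein` = acc$prot, `Ratio H/L` = acc$ratio,
    Intensity = acc$inten, Condition = acc$cond, Replicate = acc$rep,
    Fraction = acc$frac, Charge = acc$charge,
    check.names = FALSE, stringsAsFactors = FALSE)

  # expected normalized site fold changes (BF vs PK) per regime
  exp_rows <- list()
  for (rg in params$regimes) {
    bf <- paste0("BF_", rg); pk <- paste0("PK_", rg)
    for (i in seq_len(ns)) for (st in states) {
      obf <- occ[i, bf, st]; opk <- occ[i, pk, st]
      fc <- if (obf > 0 && opk > 0) obf / opk else NA_real_
      exp_rows[[length(exp_rows) + 1L]] <- data.frame(
        protein_id = sites$protein_id[i], position = sites$position[i],
        state = st, regime = rg, occupancy_bf = obf, occupancy_pk = opk,
        true_fc = fc,
        true_signed_fc = if (is.na(fc)) NA_real_ else signed_fc(fc),
        stringsAsFactors = FALSE)
    }
  }
  ground_truth <- list(
    sites = sites,
    occupancy = occ,
    protein_log2fc = lfc,
    expected_site_fc = do.call(rbind, exp_rows),
    reference_occupancy = ref_occ,
    planted_diff_sites = pd,
    planted_only_sites = po)

  structure(list(evidence = evidence, proteins = db,
                 ground_truth = ground_truth, params = params),
            class = "redox_sim")
}

#' Synthetic dataset with zero planted effects
#'
#' @param params a \code{\link{sim_params}}; any planted effects are removed.
#' @param seed optional seed override.
#' @return A \code{"redox_sim"} whose ground truth lists no effects.
#' @export
null_dataset <- function(params = sim_params(), seed = NULL) {
  params$planted_diff_sites <- NULL
  params$planted_only_sites <- NULL
  params$protein_log2fc <- NULL
  if (!is.null(seed)) params$seed <- as.integer(seed)
  simulate_redox_dataset(params)
}

#' Write a synthetic dataset to disk
#'
#' Writes \code{evidence.tsv} (default evidence dialect),
#' \code{proteins.fasta}, \code{ground_truth.json} and \code{params.json}
#' into a directory.
#'
#' @param sim a \code{"redox_sim"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "redox_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  gt <- sim$ground_truth
  gt$occupancy <- as.data.frame.table(gt$occupancy,
                                      responseName = "occupancy")
  gt$protein_log2fc <- as.data.frame.table(gt$protein_log2fc,
                                           responseName = "log2fc")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pj <- sim$params
  pj$reference_occupancies <- as.data.frame(pj$reference_occupancies)
  jsonlite::write_json(unclass(pj), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
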