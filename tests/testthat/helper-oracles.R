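# Independent oracles and tiny fixture builders used across the suite.

# Brute-force runs distribution: enumerate every arrangement of n_pos "+"
# and n_neg "-" symbols and tally the run counts.
brute_runs_distribution <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  placements <- utils::combn(n, n_pos)
  tab <- numeric(n - 1)
  names(tab) <- 2:n
  ones <- if (n_pos == n || n_neg == n) 1 else NULL
  for (j in seq_len(ncol(placements))) {
    s <- rep("-", n)
    s[placements[, j]] <- "+"
    r <- length(rle(s)$lengths)
    tab[as.character(r)] <- tab[as.character(r)] + 1
  }
  tab / ncol(placements)
}

# Same two-sided tail rule as the implementation, applied to the
# brute-force distribution.
brute_runs_pvalue <- function(signs) {
  n_pos <- sum(signs == "+"); n_neg <- sum(signs == "-")
  r_obs <- length(rle(signs)$lengths)
  pm <- brute_runs_distribution(n_pos, n_neg)
  r <- as.integer(names(pm))
  min(1, 2 * min(sum(pm[r <= r_obs]), sum(pm[r >= r_obs])))
}

# Benjamini-Hochberg step-up by its definition:
# adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Build a small evidence data frame in the default (MaxQuant-style) dialect.
mk_evidence <- function(seq, mods = "", prot = "P1", ratio = 1,
                        intensity = 1e6, cond = "BF_O2", rep = 1L,
                        frac = "NONE", charge = 2L) {
  data.frame(Sequence = seq, Modifications = mods,
             `Leading razor protein` = prot, `Ratio H/L` = ratio,
             Intensity = intensity, Condition = cond, Replicate = rep,
             Fraction = frac, Charge = charge,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# Hand-built site_quant / protein_quant pair: one protein, one site, the
# given normalized ratios per condition (protein ratios all 1, so z = raw).
mk_quant <- function(z_by_cond, state = "SNO", position = 5L,
                     protein_id = "P1") {
  conds <- names(z_by_cond)
  sr <- do.call(rbind, lapply(conds, function(cc) {
    z <- z_by_cond[[cc]]
    if (!length(z)) return(NULL)
    data.frame(protein_id = protein_id, position = position, state = state,
               condition_id = cc, replicate_id = seq_along(z),
               raw_ratio = z, protein_ratio = 1, z = z,
               stringsAsFactors = FALSE)
  }))
  sc <- do.call(rbind, lapply(conds, function(cc) {
    z <- z_by_cond[[cc]]
    data.frame(protein_id = protein_id, position = position, state = state,
               condition_id = cc,
               norm_fc = if (length(z)) stats::median(z) else NA_real_,
               var_log2 = if (length(z) >= 2) stats::var(log2(z)) else
                 NA_real_,
               n_detected = length(z), n_quantified = length(z),
               stringsAsFactors = FALSE)
  }))
  pr <- do.call(rbind, lapply(conds, function(cc)
    data.frame(protein_id = protein_id, condition_id = cc,
               replicate_id = 1:5, ratio = 1, stringsAsFactors = FALSE)))
  pc <- do.call(rbind, lapply(conds, function(cc)
    data.frame(protein_id = protein_id, condition_id = cc, fc = 1,
               n_detected = 5L, stringsAsFactors = FALSE)))
  list(sites = structure(list(replicates = sr, conditions = sc),
                         class = "site_quant"),
       proteins = structure(list(replicates = pr, conditions = pc),
                            class = "protein_quant"))
}
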