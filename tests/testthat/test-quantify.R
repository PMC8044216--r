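test_that("median aggregation follows the even-count mean-of-middle convention and is permutation-invariant and idempotent", {
  expect_equal(unname(aggregate_median(c(1, 2, 4), rep("a", 3))), 2)
  expect_equal(unname(aggregate_median(3, "a")), 3)
  expect_equal(unname(aggregate_median(c(1, 2, 3, 100), rep("a", 4))), 2.5)
  set.seed(42)
  for (i in 1:20) {
    v <- runif(sample(1:9, 1)) * 10
    g <- sample(letters[1:3], length(v), replace = TRUE)
    a <- aggregate_median(v, g)
    p <- sample(length(v))
    expect_equal(aggregate_median(v[p], g[p]), a)
    expect_equal(aggregate_median(a, names(a)), a)
  }
})

test_that("signed fold changes negate under reciprocals and keep magnitude >= 1", {
  expect_equal(signed_fc(2), 2)
  expect_equal(signed_fc(0.5), -2)
  expect_equal(signed_fc(1), 1)
  expect_error(signed_fc(0), "positive")
  x <- c(0.1, 0.37, 0.99, 1.01, 2.5, 7)
  expect_equal(signed_fc(1 / x), -signed_fc(x))
  expect_true(all(abs(signed_fc(x)) >= 1))
  expect_equal(unsigned_fc(signed_fc(x)), x)
})

test_that("protein fold changes use cysteine-free peptides and replicate medians", {
  df <- rbind(
    mk_evidence("AMTLK", ratio = 2), mk_evidence("AMTLK", ratio = 2,
                                                 charge = 3L),
    mk_evidence("GMSWK", ratio = 2),
    do.call(rbind, lapply(1:5, function(k)
      mk_evidence("AMTLK", ratio = c(1.0, 1.1, 0.9, 1.2, 1.0)[k],
                  cond = "PK_O2", rep = k))),
    mk_evidence("ASCDK", "Carbamidomethyl (C) 3", ratio = 50))
  ev <- classify_evidence(as_redox_evidence(df))
  pq <- protein_fold_changes(ev)
  bf <- pq$conditions[pq$conditions$condition_id == "BF_O2", ]
  expect_equal(bf$fc, 2)           # cysteine peptide ratio 50 ignored
  pk <- pq$conditions[pq$conditions$condition_id == "PK_O2", ]
  expect_equal(pk$fc, 1.0)         # median over 5 replicates
  expect_equal(pk$n_detected, 5L)
})

test_that("a protein with only cysteine peptides has no quantification and its sites are flagged", {
  df <- rbind(mk_evidence("ASCDK", "Carbamidomethyl (C) 3", ratio = 2),
              mk_evidence("AMTLK", prot = "P2", ratio = 1))
  ev <- locate_sites(classify_evidence(as_redox_evidence(df)),
                     structure(c(P1 = "MASCDKW", P2 = "MAMTLKW"),
                               class = "protein_db"))
  pq <- protein_fold_changes(ev)
  expect_false("P1" %in% pq$conditions$protein_id)
  sq <- site_fold_changes(ev, pq)
  expect_true(all(is.na(sq$replicates$z[sq$replicates$protein_id == "P1"])))
  expect_equal(attr(sq, "unquantifiable")$protein_id, "P1")
})

test_that("site ratios are normalized per replicate to the protein ratio", {
  df <- rbind(
    do.call(rbind, lapply(1:5, function(k) rbind(
      mk_evidence("AMTLK", ratio = 2, rep = k),
      mk_evidence("ASCDK", "Carbamidomethyl (C) 3", ratio = 4, rep = k)))))
  ev <- locate_sites(classify_evidence(as_redox_evidence(df)),
                     structure(c(P1 = "MASCDKAMTLKW"),
                               class = "protein_db"))
  sq <- site_fold_changes(ev, protein_fold_changes(ev))
  expect_equal(sq$replicates$z, rep(2, 5))
  expect_equal(sq$conditions$norm_fc, 2)
  expect_equal(sq$conditions$var_log2, 0)
  expect_equal(sq$conditions$n_detected, 5L)
})

test_that("normalization is neutral to per-replicate scaling of all of a protein's ratios", {
  sim <- simulate_redox_dataset(sim_params(n_proteins = 4, seed = 21,
                                           dropout_prob = 0))
  ev <- locate_sites(classify_evidence(as_redox_evidence(sim$evidence)),
                     sim$proteins)
  sq1 <- site_fold_changes(ev, protein_fold_changes(ev))
  ev2 <- ev
  scale_fac <- 1 + (ev2$replicate_id %% 3)  # per-replicate constants
  ev2$ratio_hl <- ev2$ratio_hl * scale_fac
  sq2 <- site_fold_changes(ev2, protein_fold_changes(ev2))
  expect_equal(sq2$replicates$z, sq1$replicates$z, tolerance = 1e-12)
})

test_that("condition comparison is a ratio of medians with antisymmetric sign", {
  cmp <- compare_conditions(z_a = c(2, 2, 2), z_b = c(3.5, 3.5, 3.5))
  expect_equal(cmp$signed_fc, 1.75)
  expect_equal(compare_conditions(c(2, 2), c(2, 2))$signed_fc, 1)
  expect_equal(compare_conditions(c(1, 1), c(0.5, 0.5))$signed_fc, -2)
  set.seed(7)
  for (i in 1:20) {
    a <- exp(rnorm(5)); b <- exp(rnorm(5))
    v <- compare_conditions(a, b)$signed_fc
    w <- compare_conditions(b, a)$signed_fc
    if (abs(v) != 1) expect_equal(w, -v)
  }
  expect_true(is.na(compare_conditions(numeric(0), c(1, 2))$signed_fc))
})
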