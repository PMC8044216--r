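test_that("generation is deterministic given the seed and varies across seeds", {
  a <- simulate_redox_dataset(sim_params(n_proteins = 4, seed = 13))
  b <- simulate_redox_dataset(sim_params(n_proteins = 4, seed = 13))
  expect_identical(a$evidence, b$evidence)
  expect_identical(unclass(a$proteins), unclass(b$proteins))
  c2 <- simulate_redox_dataset(sim_params(n_proteins = 4, seed = 14))
  expect_false(identical(a$evidence$`Ratio H/L`, c2$evidence$`Ratio H/L`))
  expect_identical(names(a$evidence), names(c2$evidence))
})

test_that("generated tables pass evidence validation with zero rejected rows", {
  sim <- simulate_redox_dataset(sim_params(n_proteins = 6, seed = 2,
                                           dup_fraction = 0.5))
  ev <- as_redox_evidence(sim$evidence)
  expect_equal(attr(ev, "n_rejected"), 0L)
  expect_equal(nrow(ev), nrow(sim$evidence))
  expect_true(all(ev$ratio_hl > 0))
  # each feature appears in at most n_replicates replicates per condition
  key <- paste(ev$peptide_sequence, ev$modifications, ev$condition_id)
  reps <- tapply(ev$replicate_id, key, function(x) length(unique(x)))
  expect_true(all(reps <= 5))
})

test_that("occupancy vectors stay valid after planting effects", {
  p <- sim_params(
    n_proteins = 4, seed = 1,
    planted_diff_sites = data.frame(protein_id = "P001", site_index = 1L,
                                    state = "SNO", condition_id = "BF_O2",
                                    occupancy = 0.4),
    planted_only_sites = data.frame(protein_id = "P002", site_index = 1L,
                                    state = "SNO",
                                    absent_condition = "PK_O2"))
  sim <- simulate_redox_dataset(p)
  occ <- sim$ground_truth$occupancy
  expect_true(all(occ >= 0))
  expect_equal(max(abs(apply(occ, c(1, 2), sum) - 1)), 0, tolerance = 1e-9)
  s1 <- sim$ground_truth$sites
  i1 <- which(s1$protein_id == "P001" & s1$site_index == 1)
  expect_equal(occ[i1, "BF_O2", "SNO"], 0.4)
  i2 <- which(s1$protein_id == "P002" & s1$site_index == 1)
  expect_equal(occ[i2, "PK_O2", "SNO"], 0)
  expect_error(sim_params(occupancy_base = c(REDUCED = 0.5, SNO = 0.1,
                                             SOX = 0.1)),
               "sum to 1")
})

test_that("an effect-free noiseless dataset yields normalized ratios of exactly 1", {
  p <- sim_params(n_proteins = 4, noise_sigma = 0, dropout_prob = 0,
                  dup_fraction = 0, seed = 6)
  sim <- null_dataset(p)
  ev <- locate_sites(classify_evidence(as_redox_evidence(sim$evidence)),
                     sim$proteins)
  sq <- site_fold_changes(ev, protein_fold_changes(ev))
  expect_equal(max(abs(sq$replicates$z - 1)), 0)
})

test_that("a planted protein-expression shift moves raw ratios but leaves normalized ratios at 1", {
  p <- sim_params(n_proteins = 3, noise_sigma = 0, dropout_prob = 0,
                  dup_fraction = 0, seed = 6,
                  protein_log2fc = data.frame(protein_id = "P001",
                                              condition_id = "BF_O2",
                                              log2fc = 1))
  sim <- simulate_redox_dataset(p)
  ev <- locate_sites(classify_evidence(as_redox_evidence(sim$evidence)),
                     sim$proteins)
  pq <- protein_fold_changes(ev)
  fc <- pq$conditions
  expect_equal(fc$fc[fc$protein_id == "P001" & fc$condition_id == "BF_O2"],
               0.5)  # heavy/light halves when the sample doubles
  sq <- site_fold_changes(ev, pq)
  expect_equal(max(abs(sq$replicates$z - 1)), 0)
})

test_that("written datasets load back and the null wrapper removes all effects", {
  p <- sim_params(n_proteins = 3, seed = 4,
                  planted_diff_sites = data.frame(
                    protein_id = "P001", site_index = 1L, state = "SNO",
                    condition_id = "BF_O2", occupancy = 0.4))
  dir <- withr::local_tempdir()
  write_dataset(simulate_redox_dataset(p), dir)
  expect_true(all(file.exists(file.path(dir,
    c("evidence.tsv", "proteins.fasta", "ground_truth.json",
      "params.json")))))
  ev <- read_evidence(file.path(dir, "evidence.tsv"))
  expect_equal(attr(ev, "n_rejected"), 0L)
  db <- read_fasta(file.path(dir, "proteins.fasta"))
  expect_equal(length(db), 3L)
  nd <- null_dataset(p, seed = 4)
  expect_null(nd$ground_truth$planted_diff_sites)
  expect_equal(max(abs(nd$ground_truth$occupancy[, , "SNO"] -
                         nd$params$occupancy_base[["SNO"]])), 0)
})

test_that("fraction cross-contamination triggers the consistency warning", {
  p <- sim_params(n_proteins = 4, seed = 5, fraction_swap_rate = 0.3)
  sim <- simulate_redox_dataset(p)
  expect_warning(classify_evidence(as_redox_evidence(sim$evidence)),
                 "inconsistent")
})
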