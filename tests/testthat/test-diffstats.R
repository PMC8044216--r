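test_that("the exact runs distribution matches brute-force enumeration for all n <= 12", {
  for (n in 2:12) for (n_pos in 1:(n - 1)) {
    n_neg <- n - n_pos
    exact <- runs_distribution(n_pos, n_neg)
    brute <- brute_runs_distribution(n_pos, n_neg)
    expect_equal(unname(exact), unname(brute[names(exact)]),
                 tolerance = 1e-12,
                 info = sprintf("n_pos=%d n_neg=%d", n_pos, n_neg))
    expect_equal(sum(exact), 1, tolerance = 1e-12)
  }
})

test_that("runs-test p-values agree with the enumeration oracle on concrete sequences", {
  seqs <- list(
    strsplit("+-+-+-", "")[[1]],                 # maximal runs, n=3+3
    c(rep("+", 5), rep("-", 5)),                 # R = 2, n=5+5
    strsplit("++--++--+-", "")[[1]],
    strsplit("+++----", "")[[1]],
    strsplit("+-++-", "")[[1]])
  for (s in seqs) {
    rt <- runs_test(s)
    expect_equal(rt$p_value, brute_runs_pvalue(s), tolerance = 1e-12)
  }
  # R = 2 with n_pos = n_neg = 5: exactly 2 of C(10,5)=252 arrangements
  pm <- runs_distribution(5, 5)
  expect_equal(unname(pm["2"]), 2 / 252)
  # all-same-sign input is undefined and flagged
  expect_true(is.na(runs_test(c("+", "+", "+", "+"))$p_value))
  expect_true(is.na(runs_test("+")$p_value))
})

test_that("the normal approximation is close to exact at moderate n", {
  set.seed(3)
  s <- sample(c("+", "-"), 28, replace = TRUE)
  p_exact <- runs_test(s, exact_max = 30)$p_value
  p_norm <- runs_test(s, exact_max = 10)$p_value
  expect_lt(abs(p_exact - p_norm), 0.05)
})

test_that("deviation signs compare site to protein ratios and drop zeros", {
  expect_equal(deviation_signs(c(4, 1, 4), c(2, 2, 2)), c("+", "-", "+"))
  expect_equal(deviation_signs(c(2, 2), c(2, 2)), character(0))
  expect_equal(deviation_signs(c(2, 8), c(2, 2)), "+")
})

test_that("Student's test behaves at its degenerate and symmetric corners", {
  expect_equal(site_ttest(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(site_ttest(c(-1, 1), c(-1, 1)), 1)
  set.seed(1)
  a <- rnorm(5, 0, 0.01); b <- rnorm(5, 1, 0.01)
  expect_lt(site_ttest(a, b), 1e-6)
  expect_true(is.na(site_ttest(1, c(1, 2))))
  # constant groups: exact 0/1 rather than an error
  expect_equal(site_ttest(c(0, 0, 0), c(0, 0, 0)), 1)
  expect_equal(site_ttest(c(0, 0, 0), c(2, 2, 2)), 0)
  # agreement with stats::t.test where defined
  expect_equal(site_ttest(a, b),
               t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(site_ttest(a, b, "welch"), t.test(a, b)$p.value)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("presence/absence calling implements the 4-of-5/absent rule with the protein-in-both restriction", {
  th <- redox_thresholds()
  expect_equal(presence_absence_call(5, 0, TRUE, th, "site"), "A_ONLY")
  expect_equal(presence_absence_call(4, 0, TRUE, th, "site"), "A_ONLY")
  expect_equal(presence_absence_call(4, 1, TRUE, th, "site"), "NONE")
  expect_equal(presence_absence_call(5, 0, FALSE, th, "site"), "NONE")
  expect_equal(presence_absence_call(5, 0, FALSE, th, "protein"), "A_ONLY")
  # symmetry under swapping conditions
  for (a in 0:5) for (b in 0:5) {
    ab <- presence_absence_call(a, b, TRUE, th, "site")
    ba <- presence_absence_call(b, a, TRUE, th, "site")
    expect_equal(ba, switch(ab, A_ONLY = "B_ONLY", B_ONLY = "A_ONLY", "NONE"))
  }
})

test_that("differential calling applies alpha and the strict fold-change threshold with per-state BH families", {
  th <- redox_thresholds()
  q <- mk_quant(list(BF_O2 = c(1, 1, 1, 1, 1),
                     PK_O2 = c(3.5, 3.5, 3.5, 3.5, 3.5)))
  calls <- call_differential(q$sites, q$proteins, th)
  expect_equal(calls$signed_fc, 3.5)
  expect_equal(calls$category, "UP_BF")
  # |FC| exactly at the threshold is not significant (strictly greater)
  q2 <- mk_quant(list(BF_O2 = rep(1, 5), PK_O2 = rep(1.75, 5)))
  expect_equal(call_differential(q2$sites, q2$proteins, th)$category, "NS")
  # direction: sample abundance lower in BF -> UP_PK with negative sign
  q3 <- mk_quant(list(BF_O2 = rep(3, 5), PK_O2 = rep(1, 5)))
  c3 <- call_differential(q3$sites, q3$proteins, th)
  expect_equal(c3$signed_fc, -3)
  expect_equal(c3$category, "UP_PK")
  # small fold change stays NS no matter how small p is
  q4 <- mk_quant(list(BF_O2 = rep(1, 5), PK_O2 = rep(1.5, 5)))
  expect_equal(call_differential(q4$sites, q4$proteins, th)$category, "NS")
})

test_that("raising the fold threshold or lowering alpha never creates new significant calls", {
  set.seed(8)
  sim <- simulate_redox_dataset(sim_params(
    n_proteins = 8, seed = 8,
    planted_diff_sites = data.frame(
      protein_id = c("P001", "P002"), site_index = 1L, state = "SNO",
      condition_id = "BF_O2", occupancy = c(0.5, 0.35))))
  ev <- locate_sites(classify_evidence(as_redox_evidence(sim$evidence)),
                     sim$proteins)
  pq <- protein_fold_changes(ev)
  sq <- site_fold_changes(ev, pq)
  loose <- call_differential(sq, pq, redox_thresholds(alpha = 0.05,
                                                      fc_threshold = 1.5))
  strict <- call_differential(sq, pq, redox_thresholds(alpha = 0.01,
                                                       fc_threshold = 2.5))
  key <- function(d) paste(d$protein_id, d$position, d$state, d$regime)
  sig_loose <- key(loose)[loose$category %in% c("UP_BF", "UP_PK")]
  sig_strict <- key(strict)[strict$category %in% c("UP_BF", "UP_PK")]
  expect_true(all(sig_strict %in% sig_loose))
})

test_that("untestable sites route to only-calls and otherwise stay auditable", {
  th <- redox_thresholds()
  q <- mk_quant(list(BF_O2 = rep(2, 5), PK_O2 = numeric(0)))
  calls <- call_differential(q$sites, q$proteins, th)
  expect_equal(calls$category, "BF_ONLY")
  q2 <- mk_quant(list(BF_O2 = rep(2, 3), PK_O2 = numeric(0)))
  expect_equal(call_differential(q2$sites, q2$proteins, th)$category,
               "UNTESTABLE")
})

test_that("significant calls map to oxidation and reduction events per state", {
  th <- redox_thresholds()
  mk_call <- function(state, cat) {
    structure(data.frame(protein_id = "P1", position = 5L, state = state,
                         regime = "O2", signed_fc = 3, p_value = 0.001,
                         n_detected_bf = 5L, n_detected_pk = 5L,
                         adj_p = 0.001, category = cat, alpha = 0.05,
                         fc_threshold = 1.75, stringsAsFactors = FALSE),
              class = c("redox_calls", "data.frame"))
  }
  ev1 <- classify_redox_events(mk_call("SNO", "UP_PK"))
  expect_equal(ev1$event, "oxidation")
  expect_equal(ev1$event_condition, "PK")
  ev2 <- classify_redox_events(mk_call("REDUCED", "UP_BF"))
  expect_equal(ev2$event, "reduction")
  expect_equal(ev2$event_condition, "BF")
  ev3 <- classify_redox_events(mk_call("SOX", "NS"))
  expect_true(is.na(ev3$event))
  ev4 <- classify_redox_events(mk_call("SOX", "BF_ONLY"))
  expect_equal(ev4$event, "oxidation")
})
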