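# A small two-TF dataset where leave-one-out scores are easy to reason about.
eval_dataset <- function() {
  species_dataset("sp", list(
    site_set("TFa", "sp", c("a1", "a2", "a3"),
             c("ACGTACGT", "ACGTACGT", "ACGTTCGT")),
    site_set("TFb", "sp", c("b1", "b2", "b3"),
             c("TTGGCCAA", "TTGGCCAA", "TTGGCGAA"))))
}

test_that("false positives require strictly higher scores than the positive", {
  tf <- site_set("TFa", "sp", c("a1", "a2", "a3"),
                 c("ACGTACGT", "ACGTACGT", "ACGTTCGT"))
  # leave out a3: training on two identical sites gives consensus ACGTACGT,
  # so the positive scores 7 (one mismatch)
  negs <- c("AACGTACGTA",  # contains the full consensus: scores 8 -> FP
            "ACGTACGA",    # scores 7: ties the positive, not an FP
            "GGGGGGGG")    # scores low
  ex <- loo_experiment(tf, 3, negs, scoring_config())
  expect_equal(ex$pos_score, 7)
  expect_equal(ex$fp, 1)
  expect_equal(ex$n_neg, 3)
  expect_equal(ex$fpr, 1 / 3)
})

test_that("negatives identical to the TF's own sites leave the denominator", {
  tf <- site_set("TFa", "sp", c("a1", "a2", "a3"),
                 c("ACGTACGT", "ACGTACGT", "ACGTTCGT"))
  negs <- c("ACGTACGT",   # identical to a site of this TF: excluded
            "ACGTTCGT",   # identical to the held-out site: excluded too
            "TTTTTTTT")
  ex <- loo_experiment(tf, 1, negs, scoring_config())
  expect_equal(ex$n_neg, 1)
  expect_equal(ex$fp, 0)
  expect_equal(ex$fpr, 0)
})

test_that("degenerate leave-one-out inputs are rejected", {
  small <- site_set("TFs", "sp", c("x", "y"), c("ACGT", "ACGG"))
  expect_error(loo_experiment(small, 1, "AAAA", scoring_config()), "at least 3")
  tf <- eval_dataset()$site_sets[["TFa"]]
  expect_error(loo_experiment(tf, 9, "AAAA", scoring_config()), "out of range")
})

test_that("run_configuration yields one experiment per (TF, site), paired across configs", {
  ds <- eval_dataset()
  r1 <- run_configuration(ds, scoring_config())
  expect_equal(nrow(r1), 6)
  expect_equal(r1$tf_id, rep(c("TFa", "TFb"), each = 3))
  r2 <- run_configuration(ds, scoring_config(ps_scope = 2))
  expect_equal(r1$site_id, r2$site_id)  # pairing contract
  # FPR bounded
  expect_true(all(r1$fpr >= 0 & r1$fpr <= 1))
})

test_that("TFs below the admission rule are excluded with a warning", {
  ds <- species_dataset("sp", c(eval_dataset()$site_sets,
                                list(site_set("TFc", "sp", "c1", "ACGTACGA"))))
  expect_warning(res <- run_configuration(ds, scoring_config()), "TFc")
  expect_equal(sort(unique(res$tf_id)), c("TFa", "TFb"))
})

test_that("imported-alignment training drops the held-out row", {
  ds <- eval_dataset()
  imports <- lapply(ds$site_sets, function(s) sorted_align(s))
  cfg <- scoring_config(alignment_strategy = "imported")
  res <- run_configuration(ds, cfg, imported_alignments = imports)
  expect_equal(nrow(res), 6)
  # a missing registration is reported with the TF's name
  expect_error(run_configuration(ds, cfg, imported_alignments = imports["TFa"]),
               "TFb")
  # dropping a row strips columns that become all gaps
  aln <- tfbs_alignment(c(a1 = "ACGT--", a2 = "ACGT--", a3 = "--GTAC"))
  dropped <- mlconsensus:::drop_alignment_row(aln, "a3")
  expect_equal(unname(dropped$rows), c("ACGT", "ACGT"))
})

test_that("slot-based ROC averaging follows the three-step construction", {
  # one TF, two experiments at FPR 0.0 and 0.3: only the first is ever
  # recovered, so every slot sees TPR 0.5 and the area is half the slot count
  ex <- data.frame(tf_id = "t1", site_id = c("s1", "s2"), fpr = c(0.0, 0.3))
  roc <- build_roc(ex, fpr_max = 0.2, n_slots = 20)
  expect_equal(roc$tpr, rep(0.5, 20))
  expect_equal(roc$auc, 10.0)

  # bounds
  all0 <- data.frame(tf_id = rep(c("a", "b"), 2), site_id = 1:4, fpr = 0)
  expect_equal(build_roc(all0)$auc, 20)
  high <- data.frame(tf_id = "a", site_id = 1:3, fpr = c(0.5, 0.3, 0.9))
  expect_equal(build_roc(high)$auc, 0)

  # TF-then-species averaging differs from pooling: check against the
  # independent three-step oracle on random inputs
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    ex <- data.frame(tf_id = sample(letters[1:4], n, replace = TRUE),
                     site_id = seq_len(n), fpr = round(runif(n, 0, 0.4), 3))
    roc <- build_roc(ex)
    expect_equal(roc$auc, oracle_roc_auc(ex$tf_id, ex$fpr))
    expect_true(all(diff(roc$tpr) >= 0))  # monotone in the slot index
  }
})

test_that("wilcoxon comparison reproduces the worked signed-rank example", {
  a <- data.frame(tf_id = "t", site_id = 1:5, fp = c(3, 5, 7, 9, 0))
  b <- data.frame(tf_id = "t", site_id = 1:5, fp = c(1, 1, 1, 1, 1))
  w <- wilcoxon_compare(a, b)
  expect_equal(w$n, 5)
  expect_equal(w$w_plus, 14)
  expect_equal(w$w_minus, 1)
  expect_equal(w$z, (14 - 7.5) / sqrt(5 * 6 * 11 / 24), tolerance = 1e-12)
  expect_equal(round(w$z, 3), 1.753)
  expect_equal(w$p_value, oracle_exact_wilcoxon_p(c(2, 4, 6, 8, -1)))
})

test_that("wilcoxon handles degenerate and one-sided inputs", {
  a <- data.frame(tf_id = "t", site_id = 1:4, fp = c(2, 2, 2, 2))
  w0 <- wilcoxon_compare(a, a)
  expect_equal(w0$n, 0)
  expect_equal(w0$p_bound, "ns")
  expect_equal(w0$z, 0)

  b <- data.frame(tf_id = "t", site_id = 1:8, fp = 0)
  a8 <- data.frame(tf_id = "t", site_id = 1:8, fp = 1:8)
  w1 <- wilcoxon_compare(a8, b)
  expect_equal(w1$w_minus, 0)
  expect_equal(w1$w_plus, 36)
  expect_equal(w1$direction, "b")   # b has fewer false positives
  expect_equal(w1$p_value, 2 / 256) # the two extreme sign assignments

  expect_error(wilcoxon_compare(a, b), "not paired")
})

test_that("exact signed-rank p agrees with enumeration and wilcox.test", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(-6:6, n, replace = TRUE)
    a <- data.frame(tf_id = "t", site_id = seq_len(n), fp = pmax(d, 0) + 3)
    b <- data.frame(tf_id = "t", site_id = seq_len(n), fp = a$fp - d)
    w <- wilcoxon_compare(a, b)
    expect_equal(w$p_value, oracle_exact_wilcoxon_p(d))
    # cross-check against the reference implementation when assumptions
    # coincide (no zeros, no ties in |d|)
    dd <- d[d != 0]
    if (length(dd) >= 1 && !any(duplicated(abs(dd)))) {
      ref <- stats::wilcox.test(dd, exact = TRUE)$p.value
      expect_equal(w$p_value, ref)
    }
  }
})

test_that("large-sample wilcoxon uses the tie-corrected normal approximation", {
  set.seed(5)
  n <- 40
  d <- sample(c(-2, -1, 1, 2, 3), n, replace = TRUE)
  a <- data.frame(tf_id = "t", site_id = 1:n, fp = pmax(d, 0) + 1)
  b <- data.frame(tf_id = "t", site_id = 1:n, fp = a$fp - d)
  w <- wilcoxon_compare(a, b)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value
  expect_equal(w$p_value, ref, tolerance = 1e-10)
})

# Build a per-scope experiment list whose scope-to-scope verdicts are forced
# by constant FP differences across 20 paired experiments.
scope_track <- function(fps, n_neg = 100) {
  lapply(fps, function(fp) {
    data.frame(tf_id = rep(c("t1", "t2"), each = 10), site_id = rep(1:10, 2),
               fp = fp, n_neg = n_neg, fpr = fp / n_neg)
  })
}

test_that("plateau detection follows the literal start-and-extend rule", {
  # verdicts: better, ns, ns, worse over five scopes -> plateau scopes 2..4
  track <- scope_track(c(5, 1, 1, 1, 6))
  names(track) <- paste0("s", 1:5)
  p <- detect_plateau(track)
  expect_equal(p$verdicts, c("better", "ns", "ns", "worse"))
  expect_equal(p$plateau_scopes, c("s2", "s3", "s4"))
  expect_equal(p$peak_scope, "s2")
  expect_true(p$peak_in_plateau)

  # all flat: empty plateau
  flat <- scope_track(c(2, 2, 2))
  names(flat) <- paste0("s", 1:3)
  expect_length(detect_plateau(flat)$plateau_scopes, 0)

  # better, better, ns: the literal rule opens at the first better-then-ns
  twostep <- scope_track(c(9, 5, 1, 1))
  names(twostep) <- paste0("s", 1:4)
  p2 <- detect_plateau(twostep)
  expect_equal(p2$verdicts, c("better", "better", "ns"))
  expect_equal(p2$plateau_scopes, c("s3", "s4"))
  # the alternative rule opens at the first significant improvement
  p3 <- detect_plateau(twostep, rule = "first_better")
  expect_equal(p3$plateau_scopes, "s2")

  expect_error(detect_plateau(scope_track(c(1, 2))), "at least 3")
})
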