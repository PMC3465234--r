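test_that("positional match covers bases, ambiguity codes and gaps", {
  model <- consensus_from_alignment(tfbs_alignment(c("AA", "AC", "-C", "-C")))
  # column 1: f(A)=0.5 -> '-'; column 2: f(C)=0.75 -> 'C'
  expect_equal(model$consensus, "-C")
  w <- overlap("AC", model, 1)
  expect_equal(match_site(w, 1), 0)  # consensus gap never matches
  expect_equal(match_site(w, 2), 1)

  amb <- consensus_from_alignment(tfbs_alignment(c("A", "A", "C", "C")))
  expect_equal(match_site(overlap("C", amb, 1), 1), 1)  # I covers C
  expect_equal(match_site(overlap("A", amb, 1), 1), 1)  # and A
  expect_equal(match_site(overlap("G", amb, 1), 1), 0)  # but not G
})

test_that("pair match is 2 when both ends match, else 0", {
  model <- consensus_from_alignment(tfbs_alignment(c(x = "ACG")))
  w <- overlap("ACG", model, 1)
  expect_equal(match_pair(w, 1, 1), 2)
  expect_equal(match_pair(w, 1, 2), 2)
  w2 <- overlap("ACT", model, 1)   # position 3 mismatches
  expect_equal(match_pair(w2, 2, 1), 0)
  w3 <- overlap("TTT", model, 1)
  expect_equal(match_pair(w3, 1, 2), 0)
})

test_that("per-overlap scores match hand-checked and oracle values", {
  model <- consensus_from_alignment(tfbs_alignment(c(x = "ACCTAAGCTG")))
  expect_equal(score_overlap_basic(overlap("ACCTAAGCTG", model, 1)), 10)
  expect_equal(score_overlap_basic(overlap("ACACCAAGTA", model, 1)), 4)

  # IC weighting: fully conserved columns are worth 2 bits each
  m3 <- consensus_from_alignment(tfbs_alignment(c("ACG", "ACG")))
  expect_equal(score_overlap_ic(overlap("ACG", m3, 1)), 6.0)
  expect_equal(score_overlap_ic(overlap("TTT", m3, 1)), 0.0)
  # additivity over a mixed-conservation model
  m4 <- consensus_from_alignment(tfbs_alignment(c("AAC", "AGC", "ATC", "ACC")))
  expect_equal(m4$col_ic[c(1, 3)], c(2, 2))
  expect_equal(score_overlap_ic(overlap("ATA", m4, 1)), 2.0)

  # PS: literal triple sum (oracle-computed expectations)
  w3 <- overlap("ACG", m3, 1)      # all three positions match
  expect_equal(score_overlap_ps(w3, 1), 4)    # pairs (1,2),(2,3)
  expect_equal(score_overlap_ps(w3, 2), 8)    # s=2 adds (1,2),(1,3)
  expect_equal(score_overlap_ps(w3, "full"), 8)
  expect_equal(score_overlap_ps(overlap("TTT", m3, 1), 5), 0)

  # ICPS: pair-IC weighting, fully conserved pairs are worth 4 bits
  m2 <- consensus_from_alignment(tfbs_alignment(c("AC", "AC")))
  expect_equal(score_overlap_icps(overlap("AC", m2, 1), 1), 8.0)
  expect_equal(score_overlap_icps(overlap("ACG", m3, 1), 2), 32.0)
})

test_that("per-overlap scores equal the literal-loop oracle on random cases", {
  set.seed(23)
  for (rep in 1:30) {
    model <- random_model()
    t <- random_site_set(1, min_len = 3, max_len = 10)$sequence
    off <- sample((2 - nchar(t)):model$width, 1)
    w <- overlap(t, model, off)
    tvec <- strsplit(t, "")[[1]]
    K <- sample(1:5, 1)
    expect_equal(score_overlap_basic(w),
                 oracle_score(tvec, model$symbols, off, "basic"))
    expect_equal(score_overlap_ic(w),
                 oracle_score(tvec, model$symbols, off, "ic",
                              col_ic = model$col_ic))
    expect_equal(score_overlap_ps(w, K),
                 oracle_score(tvec, model$symbols, off, "ps", K))
    expect_equal(score_overlap_icps(w, K),
                 oracle_score(tvec, model$symbols, off, "icps", K,
                              pair_ic = model$pair_ic))
  }
})

test_that("scan maximises over offsets for all four variants", {
  # identity scan of a gap-free consensus scores its length
  m <- consensus_from_alignment(tfbs_alignment(c(x = "ACGTACGTAC")))
  expect_equal(scan_sequence("ACGTACGTAC", m), 10)
  # a length-1 sequence has no pairs at any scope
  expect_equal(scan_sequence("A", m, scoring_config(ps_scope = 3)), 0)
  expect_equal(scan_sequence("A", m, scoring_config(ps_scope = "full")), 0)

  set.seed(31)
  for (rep in 1:40) {
    model <- random_model()
    t <- random_site_set(1, min_len = 1, max_len = 12)$sequence
    expect_equal(scan_sequence(t, model, scoring_config()),
                 oracle_scan(t, model, "basic"))
    expect_equal(scan_sequence(t, model, scoring_config(use_ic = TRUE)),
                 oracle_scan(t, model, "ic"))
    K <- sample(1:6, 1)
    expect_equal(scan_sequence(t, model, scoring_config(ps_scope = K)),
                 oracle_scan(t, model, "ps", K))
    expect_equal(scan_sequence(t, model, scoring_config(use_ic = TRUE, ps_scope = K)),
                 oracle_scan(t, model, "icps", K))
    expect_equal(scan_sequence(t, model, scoring_config(ps_scope = "full")),
                 oracle_scan(t, model, "ps", "full"))
  }
})

test_that("scores are non-negative and basic scores respect their ceiling", {
  set.seed(5)
  for (rep in 1:25) {
    model <- random_model()
    t <- random_site_set(1)$sequence
    s <- scan_sequence(t, model)
    expect_gte(s, 0)
    expect_lte(s, min(nchar(t), sum(model$symbols != "-")))
  }
})

test_that("a minimum overlap can forbid short overhangs", {
  m <- consensus_from_alignment(tfbs_alignment(c(x = "AAAA")))
  # with min_overlap = 2 the single-column overhangs are not scored
  expect_equal(scan_sequence("AA", m, scoring_config(), min_overlap = 2), 2)
  # an unreachable minimum overlap is reported, not silently ignored
  expect_error(scan_sequence("AA", m, scoring_config(), min_overlap = 3),
               "minimum overlap")
})

test_that("scoring configurations validate their scope", {
  expect_error(scoring_config(ps_scope = 0), "ps_scope")
  expect_error(scoring_config(ps_scope = 11), "ps_scope")
  expect_equal(scoring_config(ps_scope = "7")$ps_scope, 7L)
  expect_equal(scoring_config(ps_scope = "full")$ps_scope, "full")
})
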