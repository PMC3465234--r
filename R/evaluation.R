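#' One leave-one-out experiment
#'
#' Holds out one site of a TF, trains the model (alignment, consensus,
#' information content) on the remaining sites, then scores the held-out
#' positive and every negative example. A negative counts as a false
#' positive iff its score is strictly greater than the positive's score
#' (ties favour the positive). Any negative whose sequence is identical to
#' one of this TF's own sites is removed before scoring.
#'
#' @param tf A [site_set()] with at least 3 sites.
#' @param left_out_index Index of the held-out site within `tf`.
#' @param negatives Negative examples: a list of [site_set()]s (sites of the
#'   other TFs of the same species), a single `site_set`, or a character
#'   vector of sequences.
#' @param config A [scoring_config()].
#' @param imported_alignment For the `"imported"` strategy: a
#'   [tfbs_alignment()] of all of this TF's sites, rows named by site id.
#'   The held-out row is dropped and all-gap columns are stripped before
#'   training.
#' @param tie_rule,min_overlap Passed to the aligner and scanner.
#' @return An object of class `loo_experiment`: a list with `tf_id`,
#'   `site_id`, `pos_score`, `neg_scores`, `fp`, `n_neg`, `fpr`.
#' @export
loo_experiment <- function(tf, left_out_index, negatives, config,
                           imported_alignment = NULL,
                           tie_rule = "last_best", min_overlap = 1L) {
  stopifnot(inherits(tf, "site_set"))
  n <- length(tf)
  if (n < 3) stop(sprintf("tf '%s' has %d sites; at least 3 are required", tf$tf_id, n))
  if (left_out_index < 1 || left_out_index > n) stop("left_out_index out of range")

  neg_seqs <- negative_sequences(negatives)
  keep <- !(neg_seqs %in% tf$sequence)
  neg_seqs <- neg_seqs[keep]

  model <- train_loo_model(tf, left_out_index, config$alignment_strategy,
                           imported_alignment, tie_rule)
  positive <- tf$sequence[left_out_index]
  pos_score <- scan_sequence(positive, model, config, min_overlap)
  neg_scores <- if (length(neg_seqs)) {
    scan_batch(lapply(neg_seqs, encode_dna), model, config, min_overlap)
  } else numeric(0)
  fp <- sum(neg_scores > pos_score)
  structure(list(tf_id = tf$tf_id, site_id = tf$site_id[left_out_index],
                 pos_score = pos_score, neg_scores = neg_scores,
                 fp = fp, n_neg = length(neg_seqs),
                 fpr = if (length(neg_seqs)) fp / length(neg_seqs) else 0),
            class = "loo_experiment")
}

negative_sequences <- function(negatives) {
  if (inherits(negatives, "site_set")) return(negatives$sequence)
  if (is.character(negatives)) return(toupper(negatives))
  if (is.list(negatives)) {
    return(unlist(lapply(negatives, function(s) {
      if (inherits(s, "site_set")) s$sequence else toupper(as.character(s))
    }), use.names = FALSE))
  }
  stop("negatives must be a site_set, a list of site_sets, or a character vector")
}

# Train the consensus model for one leave-one-out fold.
train_loo_model <- function(tf, left_out_index, strategy, imported_alignment,
                            tie_rule) {
  keep <- setdiff(seq_len(length(tf)), left_out_index)
  if (length(keep) < 2) stop("fewer than 2 training sites after leave-out")
  if (strategy == "sorted") {
    training <- site_set(tf$tf_id, tf$species, tf$site_id[keep], tf$sequence[keep])
    aln <- sorted_align(training, tie_rule = tie_rule)
  } else {
    if (is.null(imported_alignment)) {
      stop(sprintf("no imported alignment registered for tf '%s'", tf$tf_id))
    }
    aln <- drop_alignment_row(imported_alignment, tf$site_id[left_out_index])
  }
  consensus_from_alignment(aln)
}

# Drop one row (by site id) from an alignment and strip all-gap columns.
drop_alignment_row <- function(alignment, site_id) {
  rows <- alignment$rows
  if (!site_id %in% names(rows)) {
    stop(sprintf("site '%s' not found among alignment rows", site_id))
  }
  rows <- rows[names(rows) != site_id]
  m <- do.call(rbind, strsplit(rows, ""))
  keep_cols <- colSums(m != GAP) > 0
  tfbs_alignment(stats::setNames(apply(m[, keep_cols, drop = FALSE], 1,
                                       paste, collapse = ""), names(rows)))
}

#' Run all leave-one-out experiments for one configuration
#'
#' One experiment per (TF, site) pair, iterated in deterministic order
#' (TF id, then site order). TFs with fewer than `min_sites` sites are
#' excluded from cross-validation (with a warning). Negatives for a TF are
#' all sites of the other TFs of the species, minus exact duplicates of the
#' TF's own sites.
#'
#' @param dataset A [species_dataset()].
#' @param config A [scoring_config()].
#' @param imported_alignments Named list (by TF id) of [tfbs_alignment()]s;
#'   required when `config$alignment_strategy == "imported"`.
#' @param min_sites Admission rule: TFs need at least this many sites
#'   (default 3).
#' @inheritParams loo_experiment
#' @return A data frame of class `loo_results` with one row per experiment:
#'   `tf_id`, `site_id`, `pos_score`, `fp`, `n_neg`, `fpr`.
#' @export
run_configuration <- function(dataset, config, imported_alignments = NULL,
                              min_sites = 3L, tie_rule = "last_best",
                              min_overlap = 1L) {
  stopifnot(inherits(dataset, "species_dataset"))
  sets <- dataset$site_sets[order(names(dataset$site_sets))]
  small <- vapply(sets, length, integer(1)) < min_sites
  if (any(small)) {
    warning("excluding TFs with fewer than ", min_sites, " sites: ",
            paste(names(sets)[small], collapse = ", "))
    sets <- sets[!small]
  }
  if (length(sets) == 0) stop("no TFs admitted to cross-validation")
  out <- list()
  for (tf_id in names(sets)) {
    tf <- sets[[tf_id]]
    negatives <- sets[names(sets) != tf_id]
    imp <- NULL
    if (config$alignment_strategy == "imported") {
      imp <- imported_alignments[[tf_id]]
      if (is.null(imp)) stop(sprintf("no imported alignment registered for tf '%s'", tf_id))
    }
    for (j in seq_len(length(tf))) {
      ex <- loo_experiment(tf, j, negatives, config, imp, tie_rule, min_overlap)
      out[[length(out) + 1L]] <- data.frame(tf_id = ex$tf_id, site_id = ex$site_id,
                                            pos_score = ex$pos_score, fp = ex$fp,
                                            n_neg = ex$n_neg, fpr = ex$fpr,
                                            stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("loo_results", "data.frame")
  attr(res, "config") <- config
  res
}

#' Slot-based ROC curve and sum-of-TPR area
#'
#' The allowable false-positive-rate range `[0, fpr_max]` is discretised
#' into `n_slots` equal slots with upper bounds `FPR_k = fpr_max * k /
#' n_slots`. Averaging proceeds in three steps: a per-experiment indicator
#' (the observed FPR is within the k-th allowable FPR), the mean over a
#' TF's sites, and the mean over TFs. The area is the sum of the per-slot
#' true-positive rates (so its maximum is `n_slots`); reports should always
#' state `n_slots`, since the area scales with it.
#'
#' @param experiments A `loo_results` data frame (see [run_configuration()]),
#'   or any data frame with columns `tf_id` and `fpr`.
#' @param fpr_max Maximal allowable false positive rate (default 0.20).
#' @param n_slots Number of slots (default 20).
#' @return An object of class `roc_curve`: list with `slot_fpr`, `tpr`,
#'   `auc`, `n_slots`, `fpr_max`.
#' @export
build_roc <- function(experiments, fpr_max = 0.20, n_slots = 20L) {
  stopifnot(is.data.frame(experiments), nrow(experiments) >= 1)
  if (length(unique(experiments$tf_id)) < 1) stop("no TFs in experiment set")
  slot_fpr <- fpr_max * seq_len(n_slots) / n_slots
  per_tf <- split(experiments$fpr, experiments$tf_id)
  tpr_tf <- vapply(slot_fpr, function(thr) {
    mean(vapply(per_tf, function(fprs) mean(fprs <= thr), numeric(1)))
  }, numeric(1))
  structure(list(slot_fpr = slot_fpr, tpr = tpr_tf, auc = sum(tpr_tf),
                 n_slots = n_slots, fpr_max = fpr_max),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d slots over FPR [0, %.2f]; sum-of-TPR area %.3f (max %d)\n",
              x$n_slots, x$fpr_max, x$auc, x$n_slots))
  invisible(x)
}

#' Wilcoxon matched-pair signed-ranks comparison of two configurations
#'
#' Pairs the per-experiment false-positive counts of two configurations run
#' on the same (TF, site) experiments in the same order, then applies the
#' signed-ranks test to the differences: zero differences are dropped,
#' absolute differences are ranked with midranks for ties, and the positive
#' and negative rank sums are compared. For `n <= 12` remaining pairs the
#' p-value comes from full enumeration of the `2^n` sign assignments;
#' otherwise from the normal approximation with tie correction (no
#' continuity correction). The test is two-sided; the reported direction is
#' the configuration with the smaller rank sum of false-positive excess
#' (i.e., fewer false positives overall).
#'
#' @param experiments_a,experiments_b `loo_results` data frames from
#'   [run_configuration()] over the same dataset (same rows, same order).
#' @return An object of class `wilcoxon_result`: `n` (pairs used), `w_plus`,
#'   `w_minus`, `z`, `p_value`, `p_bound` (one of `"<=0.01"`, `"<=0.05"`,
#'   `"ns"`), `direction` (`"a"`, `"b"` or `"none"`), `method`.
#' @export
wilcoxon_compare <- function(experiments_a, experiments_b) {
  key_a <- paste(experiments_a$tf_id, experiments_a$site_id)
  key_b <- paste(experiments_b$tf_id, experiments_b$site_id)
  if (length(key_a) != length(key_b) || !all(key_a == key_b)) {
    stop("experiment lists are not paired (same TF/site rows in the same order)")
  }
  d <- experiments_a$fp - experiments_b$fp
  signed_rank_test(d)
}

# Core signed-rank machinery, also usable on raw paired differences.
signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(n = 0L, w_plus = 0, w_minus = 0, z = 0,
                          p_value = 1, p_bound = "ns", direction = "none",
                          method = "degenerate (all differences zero)"),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else 0
  if (n <= 12) {
    p <- exact_signed_rank_p(r, w_plus, w_minus)
    method <- "exact enumeration"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  p <- min(1, p)
  bound <- if (p <= 0.01) "<=0.01" else if (p <= 0.05) "<=0.05" else "ns"
  direction <- if (bound == "ns") "none" else if (w_plus > w_minus) "b" else "a"
  structure(list(n = n, w_plus = w_plus, w_minus = w_minus, z = z,
                 p_value = p, p_bound = bound, direction = direction,
                 method = method),
            class = "wilcoxon_result")
}

# Two-sided exact p: enumerate all 2^n assignments of signs to the observed
# (mid)ranks; p = P(W+ >= max(w+, w-)) + P(W+ <= min(w+, w-)).
exact_signed_rank_p <- function(ranks, w_plus, w_minus) {
  n <- length(ranks)
  lo <- min(w_plus, w_minus)
  hi <- max(w_plus, w_minus)
  count <- 0L
  total <- 2L^n
  for (mask in 0:(total - 1L)) {
    wp <- sum(ranks[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L])
    if (wp >= hi || wp <= lo) count <- count + 1L
  }
  count / total
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> n=%d  W+=%.1f  W-=%.1f  Z=%.3f  p=%.4g (%s)  superior: %s\n",
              x$n, x$w_plus, x$w_minus, x$z, x$p_value, x$p_bound, x$direction))
  invisible(x)
}

#' Detect the significance plateau across pairwise-score scopes
#'
#' Given leave-one-out results for the same data at an ordered series of
#' scopes (none, 1..10, full), compares each scope with its predecessor by
#' [wilcoxon_compare()]. A scope opens the plateau when it is significantly
#' better than its predecessor (fewer false positives, `p <= alpha`) *and*
#' the following scope change is not significant; the plateau then extends
#' through consecutive non-significant changes. The scope of maximal
#' sum-of-TPR area is reported, along with whether it falls inside the
#' plateau. `rule = "first_better"` instead opens the plateau at the first
#' significantly-better scope regardless of what follows.
#'
#' @param per_scope_experiments Named list of `loo_results` data frames, in
#'   scope order (at least 3 scopes).
#' @param alpha Significance level for the scope-to-scope comparisons.
#' @param rule `"literal"` (default) or `"first_better"`.
#' @param fpr_max,n_slots Passed to [build_roc()] for the per-scope areas.
#' @return An object of class `scope_plateau`: `scopes`, `verdicts`
#'   (between consecutive scopes: `"better"`, `"worse"`, `"ns"`),
#'   `plateau_scopes`, `auc` (per scope), `peak_scope`, `peak_in_plateau`.
#' @export
detect_plateau <- function(per_scope_experiments, alpha = 0.05,
                           rule = c("literal", "first_better"),
                           fpr_max = 0.20, n_slots = 20L) {
  rule <- match.arg(rule)
  scopes <- names(per_scope_experiments)
  if (length(scopes) < 3) stop("plateau detection needs at least 3 scopes")
  verdicts <- character(length(scopes) - 1)
  for (i in seq_along(verdicts)) {
    # compare scope i+1 (b) against its predecessor i (a)
    w <- wilcoxon_compare(per_scope_experiments[[i]], per_scope_experiments[[i + 1]])
    verdicts[i] <- if (w$p_value <= alpha && w$direction == "b") "better"
                   else if (w$p_value <= alpha && w$direction == "a") "worse"
                   else "ns"
  }
  plateau <- plateau_from_verdicts(verdicts, rule)
  auc <- vapply(per_scope_experiments, function(e) build_roc(e, fpr_max, n_slots)$auc,
                numeric(1))
  peak <- which.max(auc)
  structure(list(scopes = scopes, verdicts = verdicts,
                 plateau_scopes = scopes[plateau],
                 auc = auc, peak_scope = scopes[peak],
                 peak_in_plateau = peak %in% plateau),
            class = "scope_plateau")
}

# verdicts[i] relates scope i+1 to scope i; returns plateau scope indices.
plateau_from_verdicts <- function(verdicts, rule = "literal") {
  n_scopes <- length(verdicts) + 1L
  start <- NA_integer_
  for (i in seq_along(verdicts)) {
    if (verdicts[i] != "better") next
    if (rule == "first_better" ||
        (i < length(verdicts) && verdicts[i + 1] == "ns")) {
      start <- i + 1L  # the scope that improved
      break
    }
  }
  if (is.na(start)) return(integer(0))
  end <- start
  while (end < n_scopes && verdicts[end] == "ns") end <- end + 1L
  start:end
}

#' @export
print.scope_plateau <- function(x, ...) {
  cat("<scope_plateau>\n  scopes: ", paste(x$scopes, collapse = " "), "\n",
      "  verdicts: ", paste(x$verdicts, collapse = " "), "\n",
      "  plateau: ", if (length(x$plateau_scopes)) paste(x$plateau_scopes, collapse = " ") else "(empty)",
      "\n  peak AUC at scope ", x$peak_scope,
      if (x$peak_in_plateau) " (inside plateau)" else " (outside plateau)", "\n", sep = "")
  invisible(x)
}
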