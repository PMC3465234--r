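#' Scoring configuration
#'
#' One cell of the experiment grid: whether information content weights the
#' score, the pairwise-score scope, and which alignment strategy trains the
#' model. The full grid (both strategies x IC on/off x scopes none, 1..10,
#' full) has exactly 48 cells.
#'
#' @param use_ic Logical; weight matches (or pair matches) by information
#'   content computed on the training alignment.
#' @param ps_scope `"none"`, an integer 1..10, or `"full"` (the scope spans
#'   the entire overlap).
#' @param alignment_strategy `"sorted"` (the built-in greedy aligner) or
#'   `"imported"` (a pre-computed alignment registered per TF).
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(use_ic = FALSE, ps_scope = "none",
                           alignment_strategy = c("sorted", "imported")) {
  alignment_strategy <- match.arg(alignment_strategy)
  ps_scope <- normalize_scope(ps_scope)
  structure(list(use_ic = isTRUE(use_ic), ps_scope = ps_scope,
                 alignment_strategy = alignment_strategy),
            class = "scoring_config")
}

normalize_scope <- function(ps_scope) {
  if (identical(ps_scope, "none") || identical(ps_scope, "full")) return(ps_scope)
  k <- suppressWarnings(as.integer(ps_scope))
  if (is.na(k) || k < 1 || k > 10) {
    stop("ps_scope must be \"none\", an integer 1..10, or \"full\"")
  }
  k
}

scope_label <- function(ps_scope) as.character(ps_scope)

config_label <- function(config) {
  sprintf("%s|%s|ps=%s", config$alignment_strategy,
          if (config$use_ic) "IC" else "noIC", scope_label(config$ps_scope))
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("<scoring_config>", config_label(x), "\n")
  invisible(x)
}

# variant code shared with the C++ kernel
config_variant <- function(config) {
  has_ps <- !identical(config$ps_scope, "none")
  if (!config$use_ic && !has_ps) 0L
  else if (config$use_ic && !has_ps) 1L
  else if (!config$use_ic && has_ps) 2L
  else 3L
}

config_K <- function(config) {
  if (identical(config$ps_scope, "none")) 0L
  else if (identical(config$ps_scope, "full")) -1L
  else as.integer(config$ps_scope)
}

#' Overlap between a test sequence and a consensus
#'
#' Places the test sequence `t` at a fixed offset against the consensus and
#' records, for each overlap position `i`, the consensus symbol, the test
#' base, and the underlying alignment column (consensus positions map 1:1 to
#' alignment columns).
#'
#' @param t A DNA string.
#' @param model A [consensus_from_alignment()] result (or consensus string).
#' @param offset Offset of `t`'s first base relative to consensus column 1
#'   (see [best_offset()]).
#' @return An object of class `tfbs_overlap` with fields `length`, `offset`,
#'   `cons_symbol`, `t_base`, `columns` (alignment columns), `positions`
#'   (positions within `t`), and the source `model`.
#' @export
overlap <- function(t, model, offset) {
  symbols <- if (inherits(model, "tfbs_consensus")) model$symbols
             else strsplit(toupper(model), "")[[1]]
  tb <- strsplit(toupper(t), "")[[1]]
  lc <- length(symbols); lt <- length(tb)
  c1 <- max(1L, offset); c2 <- min(lc, offset + lt - 1L)
  if (c2 < c1) stop("offset produces no overlap")
  cols <- c1:c2
  pos <- cols - offset + 1L
  structure(list(length = length(cols), offset = offset,
                 cons_symbol = symbols[cols], t_base = tb[pos],
                 columns = cols, positions = pos,
                 model = if (inherits(model, "tfbs_consensus")) model else NULL),
            class = "tfbs_overlap")
}

#' Positional match against the consensus
#'
#' 1 if the consensus symbol at overlap position `i` equals the test base or
#' is an ambiguity code covering it; 0 otherwise (in particular whenever the
#' consensus symbol is a gap).
#'
#' @param w A [overlap()].
#' @param i Position within the overlap (1-based).
#' @return 0 or 1.
#' @export
match_site <- function(w, i) {
  stopifnot(i >= 1, i <= w$length)
  sym <- w$cons_symbol[i]
  base <- w$t_base[i]
  .MATCH_TABLE[sym, base]
}

#' Pairwise match
#'
#' 2 if both overlap positions `i` and `i + k` match the consensus
#' ([match_site()]), else 0.
#'
#' @inheritParams match_site
#' @param k Separation, `k >= 1` and `i + k <= |w|`.
#' @return 0 or 2.
#' @export
match_pair <- function(w, i, k) {
  stopifnot(k >= 1, i + k <= w$length)
  if (match_site(w, i) == 1L && match_site(w, i + k) == 1L) 2L else 0L
}

overlap_match_vector <- function(w) {
  .MATCH_TABLE[cbind(w$cons_symbol, w$t_base)]
}

#' Per-overlap scores
#'
#' The four scoring functions evaluated on one fixed overlap:
#' * `score_overlap_basic()`: the number of matching positions.
#' * `score_overlap_ic()`: matches weighted by the information content of
#'   the underlying alignment column.
#' * `score_overlap_ps()`: the pairwise score at scope `K` — the literal
#'   triple sum over `s = 1..K`, `i = 1..|w|-s`, `k = 1..s` of
#'   [match_pair()]; a pair at separation `k` is therefore counted once for
#'   every admissible `s >= k`, so its total weight grows with the scope.
#' * `score_overlap_icps()`: the same sum with every pair-match term
#'   weighted by the pair information content of the underlying column pair.
#'
#' @param w A [overlap()].
#' @param col_ic Per-column IC; defaults to the model attached to `w`.
#' @return A numeric score (non-negative).
#' @export
score_overlap_basic <- function(w) {
  sum(overlap_match_vector(w))
}

#' @rdname score_overlap_basic
#' @export
score_overlap_ic <- function(w, col_ic = NULL) {
  if (is.null(col_ic)) {
    if (is.null(w$model)) stop("no model attached to overlap; supply col_ic")
    col_ic <- w$model$col_ic
  }
  m <- overlap_match_vector(w)
  sum(m * col_ic[w$columns])
}

#' @rdname score_overlap_basic
#' @param K Scope: a positive integer, or `"full"` for `|w| - 1`.
#' @export
score_overlap_ps <- function(w, K) {
  K <- if (identical(K, "full")) w$length - 1L else as.integer(K)
  if (K < 1) return(0)
  m <- overlap_match_vector(w)
  acc <- 0
  for (s in seq_len(K)) {
    imax <- w$length - s
    if (imax < 1) next
    for (i in seq_len(imax)) {
      for (k in seq_len(s)) {
        if (m[i] && m[i + k]) acc <- acc + 2
      }
    }
  }
  acc
}

#' @rdname score_overlap_basic
#' @param pair_ic Pair IC matrix (upper triangle, alignment columns);
#'   defaults to the model attached to `w`.
#' @export
score_overlap_icps <- function(w, K, pair_ic = NULL) {
  if (is.null(pair_ic)) {
    if (is.null(w$model)) stop("no model attached to overlap; supply pair_ic")
    pair_ic <- w$model$pair_ic
  }
  K <- if (identical(K, "full")) w$length - 1L else as.integer(K)
  if (K < 1) return(0)
  m <- overlap_match_vector(w)
  acc <- 0
  for (s in seq_len(K)) {
    imax <- w$length - s
    if (imax < 1) next
    for (i in seq_len(imax)) {
      for (k in seq_len(s)) {
        if (m[i] && m[i + k]) {
          acc <- acc + 2 * pair_ic[w$columns[i], w$columns[i + k]]
        }
      }
    }
  }
  acc
}

#' Scan a sequence against a consensus model
#'
#' Slides the test sequence along the consensus, evaluates the configured
#' per-overlap score at every offset with at least `min_overlap` overlapping
#' columns, and returns the maximum.
#'
#' @param t A DNA string.
#' @param model A [consensus_from_alignment()] result.
#' @param config A [scoring_config()] (its alignment strategy is ignored
#'   here; only `use_ic` and `ps_scope` matter).
#' @param min_overlap Minimum overlap columns (default 1).
#' @return The maximal score over all overlaps.
#' @export
scan_sequence <- function(t, model, config = scoring_config(), min_overlap = 1L) {
  stopifnot(inherits(model, "tfbs_consensus"))
  out <- scan_cpp(encode_dna(t), encode_consensus_symbols(model$symbols),
                  .MATCH_TABLE, config_variant(config), config_K(config),
                  model$col_ic, model$pair_ic, as.integer(min_overlap))
  if (!is.finite(out)) stop("no offset satisfies the minimum overlap")
  out
}

# Batch scan used by the evaluation harness: `seqs_enc` is a list of
# integer-encoded sequences (see encode_dna).
scan_batch <- function(seqs_enc, model, config, min_overlap = 1L) {
  scan_batch_cpp(seqs_enc, encode_consensus_symbols(model$symbols),
                 .MATCH_TABLE, config_variant(config), config_K(config),
                 model$col_ic, model$pair_ic, as.integer(min_overlap))
}
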