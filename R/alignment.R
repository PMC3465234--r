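#' Enumerate candidate offsets and find the best placement
#'
#' A site placed at offset `o` has its first base in consensus column `o`
#' (offset 1 = aligned with the consensus start; offsets below 1 overhang on
#' the left, offsets above 1 shift right). Every offset with at least
#' `min_overlap` overlapping columns is scored with the basic match count
#' against the consensus, and the maximum is returned. Among tied offsets,
#' `"first_best"` keeps the smallest offset met scanning left to right and
#' `"last_best"` the largest.
#'
#' @param site A DNA string.
#' @param consensus A [consensus_from_alignment()] result, or a plain
#'   consensus string over \{A,C,G,T,I,J,K,L,M,N,-\}.
#' @param tie_rule `"last_best"` (default) or `"first_best"`.
#' @param min_overlap Minimum number of overlapping columns (default 1).
#' @return A list with `offset` and `score`.
#' @export
best_offset <- function(site, consensus, tie_rule = c("last_best", "first_best"),
                        min_overlap = 1L) {
  tie_rule <- match.arg(tie_rule)
  symbols <- if (inherits(consensus, "tfbs_consensus")) consensus$symbols
             else strsplit(toupper(consensus), "")[[1]]
  t_enc <- encode_dna(site)
  c_enc <- encode_consensus_symbols(symbols)
  lt <- length(t_enc); lc <- length(c_enc)
  stopifnot(lt >= 1, lc >= 1)
  offsets <- seq.int(2L - lt, lc)
  scores <- vapply(offsets, function(o) {
    c1 <- max(1L, o); c2 <- min(lc, o + lt - 1L)
    if (c2 - c1 + 1L < min_overlap) return(NA_real_)
    sum(.MATCH_TABLE[cbind(c_enc[c1:c2] + 1L, t_enc[(c1 - o + 1L):(c2 - o + 1L)] + 1L)])
  }, numeric(1))
  if (all(is.na(scores))) stop("no offset satisfies the minimum overlap")
  best <- max(scores, na.rm = TRUE)
  idx <- which(scores == best)
  pick <- if (tie_rule == "last_best") max(idx) else min(idx)
  list(offset = offsets[pick], score = best)
}

# Profile placement score: total matches of the candidate site against all
# rows of the current alignment (equivalently sum_j n_j(t)). This is the
# default placement objective of sorted_align; it reduces to the basic
# consensus score when the alignment has a single row.
profile_offsets <- function(t_enc, counts, tie_rule, min_overlap = 1L) {
  lt <- length(t_enc); lc <- ncol(counts)
  offsets <- seq.int(2L - lt, lc)
  scores <- vapply(offsets, function(o) {
    c1 <- max(1L, o); c2 <- min(lc, o + lt - 1L)
    if (c2 - c1 + 1L < min_overlap) return(NA_real_)
    sum(counts[cbind(t_enc[(c1 - o + 1L):(c2 - o + 1L)] + 1L, c1:c2)])
  }, numeric(1))
  best <- max(scores, na.rm = TRUE)
  idx <- which(scores == best)
  pick <- if (tie_rule == "last_best") max(idx) else min(idx)
  list(offset = offsets[pick], score = best)
}

#' Greedy sorting-based multiple alignment
#'
#' Aligns a set of binding sites by the naive greedy procedure: sort sites
#' from shortest to longest, seed the alignment with the shortest, then place
#' each next site as a contiguous block at its best-scoring offset against
#' the current alignment, padding with gaps on either side so widths agree.
#' No internal gaps are ever introduced; every row degaps to its source site.
#'
#' Two placement objectives are available. `"profile"` (default) scores a
#' candidate offset by its total matches against all rows already aligned.
#' `"consensus"` recomputes the ambiguity-code consensus after every
#' addition and scores candidate offsets with the basic match count against
#' it, as in [best_offset()]. The profile objective is the default because
#' with one or two rows the thresholded consensus is nearly all gaps or
#' two-base codes, which makes mid-construction placement degenerate; the
#' profile uses the full column counts instead (see the methods vignette).
#'
#' @param sites A [site_set()].
#' @param tie_rule Offset tie rule, `"last_best"` (default) or `"first_best"`.
#' @param rng_seed Optional integer; when given, sites of equal length are
#'   ordered by a seeded random draw. Otherwise equal-length sites are taken
#'   in lexicographic sequence order (fully deterministic).
#' @param placement `"profile"` (default) or `"consensus"`.
#' @return A [tfbs_alignment()] whose rows are named by site id, with
#'   attribute `"placements"`: a data frame of per-step offsets and scores.
#' @export
sorted_align <- function(sites, tie_rule = c("last_best", "first_best"),
                         rng_seed = NULL, placement = c("profile", "consensus")) {
  tie_rule <- match.arg(tie_rule)
  placement <- match.arg(placement)
  stopifnot(inherits(sites, "site_set"), length(sites) >= 1)
  seqs <- sites$sequence
  ids <- sites$site_id
  if (is.null(rng_seed)) {
    ord <- order(nchar(seqs), seqs, ids)
  } else {
    set.seed(as.integer(rng_seed))
    ord <- order(nchar(seqs), runif(length(seqs)))
  }
  seqs <- seqs[ord]; ids <- ids[ord]

  rows <- seqs[1]
  names(rows) <- ids[1]
  placements <- data.frame(site_id = ids, offset = NA_integer_, score = NA_real_)
  placements$offset[1] <- 1L
  for (s in seq_along(seqs)[-1]) {
    t_enc <- encode_dna(seqs[s])
    if (placement == "profile") {
      aln <- tfbs_alignment(rows)
      counts <- build_profiles(aln)$counts
      bo <- profile_offsets(t_enc, counts, tie_rule)
    } else {
      cons <- consensus_from_alignment(tfbs_alignment(rows))
      bo <- best_offset(seqs[s], cons, tie_rule)
    }
    o <- bo$offset
    W <- nchar(rows[1])
    left <- max(0L, 1L - o)
    right <- max(0L, o + nchar(seqs[s]) - 1L - W)
    rows <- stats::setNames(paste0(strrep(GAP, left), rows, strrep(GAP, right)),
                            names(rows))
    start <- o + left
    newrow <- paste0(strrep(GAP, start - 1L), seqs[s],
                     strrep(GAP, W + left + right - (start - 1L) - nchar(seqs[s])))
    rows <- c(rows, stats::setNames(newrow, ids[s]))
    placements$offset[s] <- o
    placements$score[s] <- bo$score
  }
  out <- tfbs_alignment(rows)
  attr(out, "source") <- stats::setNames(seqs, ids)
  attr(out, "placements") <- placements
  attr(out, "placement") <- placement
  attr(out, "tie_rule") <- tie_rule
  out
}

#' Check that every alignment row degaps to its source site
#'
#' @param alignment A [tfbs_alignment()].
#' @param sites Optional [site_set()] to check against (matched by site id);
#'   defaults to the source sequences recorded when the alignment was built.
#' @return `TRUE` iff every row, gaps removed, equals its source sequence.
#' @export
degap_check <- function(alignment, sites = NULL) {
  stopifnot(inherits(alignment, "tfbs_alignment"))
  got <- degap(alignment)
  if (is.null(sites)) {
    src <- attr(alignment, "source")
    if (is.null(src)) stop("alignment has no recorded source; supply `sites`")
  } else {
    src <- stats::setNames(sites$sequence, sites$site_id)
  }
  if (!all(names(got) %in% names(src))) return(FALSE)
  all(got == src[names(got)])
}
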