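#' Column and pair profiles of an alignment
#'
#' Counts and frequencies of bases per column, and joint frequencies of base
#' pairs per ordered column pair. With `N` alignment rows, frequencies are
#' `n/N`: gaps contribute to the denominator but never to a count, so a
#' column with one C and three gaps has `f(C) = 0.25`.
#'
#' @param alignment A [tfbs_alignment()].
#' @return An object of class `tfbs_profiles` with fields:
#'   \describe{
#'     \item{counts}{4 x W matrix `n_j(b)` (rows A,C,G,T).}
#'     \item{freqs}{4 x W matrix `f_j(b) = n_j(b)/N`.}
#'     \item{overall_counts, overall_freqs}{`n(b)` and `f(b)` over the whole
#'       alignment (defined by the model, unused by any score).}
#'     \item{pair_freqs}{4 x 4 x W x W array `f_ij(b,d)`, filled for column
#'       pairs `i < j`.}
#'     \item{n_rows, width}{N and W.}
#'   }
#' @export
build_profiles <- function(alignment) {
  stopifnot(inherits(alignment, "tfbs_alignment"))
  m <- alignment_matrix(alignment)
  N <- nrow(m)
  W <- ncol(m)
  # one-hot indicator per base: N x W
  X <- lapply(DNA_BASES, function(b) (m == b) * 1L)
  names(X) <- DNA_BASES
  counts <- do.call(rbind, lapply(X, colSums))
  rownames(counts) <- DNA_BASES
  freqs <- counts / N
  pair <- array(0, dim = c(4, 4, W, W),
                dimnames = list(DNA_BASES, DNA_BASES, NULL, NULL))
  for (bi in 1:4) {
    for (di in 1:4) {
      # n_ij(b,d): number of rows carrying b at column i and d at column j
      cross <- crossprod(X[[bi]], X[[di]])          # W x W
      pair[bi, di, , ] <- cross
    }
  }
  # keep only ordered pairs i < j (the lower triangle mirrors by symmetry
  # f_ij(b,d) = f_ji(d,b); we zero it to make the contract explicit)
  lower <- lower.tri(matrix(0, W, W), diag = TRUE)
  for (bi in 1:4) for (di in 1:4) {
    slab <- pair[bi, di, , ]
    slab[lower] <- 0
    pair[bi, di, , ] <- slab
  }
  structure(list(counts = counts, freqs = freqs,
                 overall_counts = rowSums(counts),
                 overall_freqs = rowSums(counts) / (N * W),
                 pair_freqs = pair / N,
                 n_rows = N, width = W),
            class = "tfbs_profiles")
}

#' @export
print.tfbs_profiles <- function(x, ...) {
  cat(sprintf("<tfbs_profiles> %d rows x %d columns\n", x$n_rows, x$width))
  invisible(x)
}

# xlog2x with the 0*log(0) = 0 convention
xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Information content of an alignment column
#'
#' `IC(A,j) = 2 + sum_b f_j(b) log2 f_j(b)`, in bits. A fully conserved
#' column scores 2, a uniform column 0. Terms with `f_j(b) = 0` contribute
#' zero.
#'
#' @param profiles A [build_profiles()] result.
#' @param j Column index (1-based).
#' @return IC in bits.
#' @export
ic_column <- function(profiles, j) {
  stopifnot(j >= 1, j <= profiles$width)
  2 + sum(xlog2(profiles$freqs[, j]))
}

#' Information content of a column pair
#'
#' `ICpair(A,i,j) = 4 + sum_{b,d} f_ij(b,d) log2 f_ij(b,d)`, in bits. A fully
#' conserved pair (one joint base combination in every row) scores 4; sixteen
#' equiprobable combinations score 0.
#'
#' @inheritParams ic_column
#' @param i,j Column indices, `i < j`.
#' @return Pair IC in bits.
#' @export
ic_pair <- function(profiles, i, j) {
  stopifnot(i >= 1, j <= profiles$width, i != j)
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  4 + sum(xlog2(profiles$pair_freqs[, , i, j]))
}

# Vectorised versions used when building a consensus model.
all_column_ic <- function(profiles) {
  2 + colSums(xlog2(profiles$freqs))
}

all_pair_ic <- function(profiles) {
  W <- profiles$width
  out <- matrix(0, W, W)
  pf <- profiles$pair_freqs
  contrib <- xlog2(pf)
  # sum over the 16 base combinations for every (i, j)
  s <- matrix(colSums(matrix(contrib, nrow = 16L)), W, W)
  out[upper.tri(out)] <- 4 + s[upper.tri(s)]
  out
}

#' Ambiguity code for a base pair
#'
#' The model's two-base codes: I=A/C, J=A/G, K=A/T, L=C/G, M=C/T, N=G/T.
#' These are deliberately not IUPAC; see [consensus_to_iupac()].
#'
#' @param b,d Two distinct bases.
#' @return A single code character.
#' @export
amb_code <- function(b, d) {
  key <- paste0(sort(c(b, d)), collapse = "")
  hit <- names(AMB_CODES)[AMB_CODES == key]
  if (length(hit) != 1) stop("no ambiguity code for pair ", b, "/", d)
  hit
}

#' Map a consensus string to IUPAC codes (display helper)
#'
#' The model's own codes map to IUPAC as I→M, J→R, K→W, L→S, M→Y, N→K.
#' Bases and gaps pass through.
#'
#' @param consensus Consensus string (or `tfbs_consensus` object).
#' @return A character string over IUPAC codes.
#' @export
consensus_to_iupac <- function(consensus) {
  if (inherits(consensus, "tfbs_consensus")) consensus <- consensus$consensus
  chartr("IJKLMN", "MRWSYK", consensus)
}

consensus_symbol_for_column <- function(fj) {
  # fj: named frequency vector over A,C,G,T for one column
  if (any(fj > 0.5)) {
    cand <- which(fj > 0.5)
    return(DNA_BASES[cand[which.max(fj[cand])]])
  }
  pairs <- utils::combn(4, 2)
  sums <- fj[pairs[1, ]] + fj[pairs[2, ]]
  ok <- sums > 0.75
  if (any(ok)) {
    # highest pair sum wins; ties resolve in A<C<G<T pair enumeration order
    p <- which(ok)[which.max(sums[ok])]
    return(amb_code(DNA_BASES[pairs[1, p]], DNA_BASES[pairs[2, p]]))
  }
  GAP
}

#' Derive the ambiguity-code consensus of an alignment
#'
#' Per column `j`, in order: a base `b` with `f_j(b) > 0.5` (strict) becomes
#' the consensus symbol; otherwise a base pair with `f_j(b) + f_j(d) > 0.75`
#' (strict) becomes its ambiguity code; otherwise the column is a gap.
#' Thresholds are strict: a column at exactly 0.5, or a pair at exactly
#' 0.75, yields a gap.
#'
#' The returned model carries the column and pair profiles and the
#' precomputed per-column and per-pair information content used by the
#' scanning scores; consensus positions map 1:1 to alignment columns.
#'
#' @param alignment A [tfbs_alignment()].
#' @param profiles Optional precomputed [build_profiles()] result.
#' @return An object of class `tfbs_consensus` with fields `consensus`
#'   (string), `symbols` (character vector), `profiles`, `col_ic`, `pair_ic`,
#'   `width`, `n_rows`.
#' @export
consensus_from_alignment <- function(alignment, profiles = NULL) {
  if (is.null(profiles)) profiles <- build_profiles(alignment)
  symbols <- vapply(seq_len(profiles$width),
                    function(j) consensus_symbol_for_column(profiles$freqs[, j]),
                    character(1))
  structure(list(consensus = paste(symbols, collapse = ""),
                 symbols = symbols,
                 profiles = profiles,
                 col_ic = all_column_ic(profiles),
                 pair_ic = all_pair_ic(profiles),
                 width = profiles$width,
                 n_rows = profiles$n_rows),
            class = "tfbs_consensus")
}

#' @export
print.tfbs_consensus <- function(x, ...) {
  cat(sprintf("<tfbs_consensus> width %d (from %d sites)\n  %s\n",
              x$width, x$n_rows, x$consensus))
  invisible(x)
}

#' Export / import a consensus model as JSON
#'
#' Bundles the consensus string, per-column IC and per-pair IC so a scan can
#' run without the training alignment.
#'
#' @param model A [consensus_from_alignment()] result.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tfbs_consensus"))
  obj <- list(consensus = model$consensus,
              col_ic = model$col_ic,
              pair_ic = model$pair_ic,
              n_rows = model$n_rows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  symbols <- strsplit(obj$consensus, "")[[1]]
  pm <- obj$pair_ic
  if (!is.matrix(pm)) pm <- matrix(as.numeric(pm), nrow = length(symbols), byrow = TRUE)
  structure(list(consensus = obj$consensus,
                 symbols = symbols,
                 profiles = NULL,
                 col_ic = as.numeric(obj$col_ic),
                 pair_ic = pm,
                 width = length(symbols),
                 n_rows = obj$n_rows),
            class = "tfbs_consensus")
}
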