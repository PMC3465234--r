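# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (explicit loops, no shared code with the package
# internals) so that agreement with the package is informative.

oracle_amb <- list(I = c("A", "C"), J = c("A", "G"), K = c("A", "T"),
                   L = c("C", "G"), M = c("C", "T"), N = c("G", "T"))

oracle_match <- function(cons_char, base) {
  if (cons_char %in% c("A", "C", "G", "T")) return(as.integer(cons_char == base))
  if (cons_char == "-") return(0L)
  as.integer(base %in% oracle_amb[[cons_char]])
}

# Literal per-overlap scores. `cons` is a character vector of consensus
# symbols, `tvec` a character vector of bases; `off` places tvec[1] at
# consensus column `off`.
oracle_overlap <- function(tvec, cons, off) {
  c1 <- max(1, off); c2 <- min(length(cons), off + length(tvec) - 1)
  if (c2 < c1) return(NULL)
  cols <- c1:c2
  list(cols = cols,
       m = mapply(function(cc) oracle_match(cons[cc], tvec[cc - off + 1]), cols))
}

oracle_score <- function(tvec, cons, off, variant, K = 0,
                         col_ic = NULL, pair_ic = NULL) {
  ov <- oracle_overlap(tvec, cons, off)
  if (is.null(ov)) return(NULL)
  m <- ov$m; L <- length(m)
  if (variant == "basic") return(sum(m))
  if (variant == "ic") return(sum(m * col_ic[ov$cols]))
  # PS / ICPS: the literal triple sum
  Keff <- if (identical(K, "full")) L - 1 else K
  acc <- 0
  if (Keff >= 1) {
    for (s in 1:Keff) {
      if (L - s < 1) next
      for (i in 1:(L - s)) {
        for (k in 1:s) {
          mp <- if (m[i] == 1 && m[i + k] == 1) 2 else 0
          if (mp > 0) {
            if (variant == "ps") acc <- acc + mp
            else acc <- acc + mp * pair_ic[ov$cols[i], ov$cols[i + k]]
          }
        }
      }
    }
  }
  acc
}

# Exhaustive maximum over every offset with at least `min_overlap` columns.
oracle_scan <- function(t, model, variant, K = 0, min_overlap = 1) {
  tvec <- strsplit(t, "")[[1]]
  cons <- model$symbols
  best <- -Inf
  for (off in (2 - length(tvec)):length(cons)) {
    c1 <- max(1, off); c2 <- min(length(cons), off + length(tvec) - 1)
    if (c2 - c1 + 1 < min_overlap) next
    s <- oracle_score(tvec, cons, off, variant, K, model$col_ic, model$pair_ic)
    if (!is.null(s) && s > best) best <- s
  }
  best
}

# Exact two-sided signed-rank p by explicit enumeration of sign vectors
# (structurally different from the package's bitmask enumeration).
oracle_exact_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  wp <- sum(r[d > 0]); wm <- sum(r[d < 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wplus_all <- as.vector(signs %*% r)
  mean(wplus_all >= max(wp, wm) | wplus_all <= min(wp, wm))
}

# Direct three-step ROC construction from a table of per-experiment FPRs.
oracle_roc_auc <- function(tf_id, fpr, fpr_max = 0.2, n_slots = 20) {
  slots <- fpr_max * (1:n_slots) / n_slots
  tpr <- sapply(slots, function(thr) {
    mean(tapply(fpr <= thr, tf_id, mean))
  })
  sum(tpr)
}
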