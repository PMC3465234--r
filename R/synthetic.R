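#' Specification for a synthetic binding-site dataset
#'
#' Describes a species-like collection of TF site sets with a planted core
#' motif: every site is a left flank, a (possibly truncated and noised) copy
#' of its TF's core, and a right flank. Flank lengths per side follow a
#' truncated negative binomial distribution whose two parameters are solved
#' numerically so the site-length distribution hits both
#' `target_mean_length` and `target_sd_length`; the long right tail mimics
#' the spread seen in curated binding-site collections (target mean 12,
#' SD 6).
#'
#' @param n_tfs Number of TFs.
#' @param sites_per_tf Sites per TF (at least 3, the admission rule).
#' @param core_length Length of the planted core consensus.
#' @param core_conservation Mean per-position probability of emitting the
#'   core base (otherwise one of the three other bases, uniformly).
#' @param core_conservation_sd Spread of the per-position conservation: each
#'   TF draws one conservation value per core position from a Beta
#'   distribution with mean `core_conservation` and this standard deviation
#'   (0 = identical conservation at every position). Real motifs are
#'   strongly position-heterogeneous — some positions are near-invariant
#'   while others tolerate substitutions — and per-column information
#'   content is only informative when such heterogeneity exists.
#' @param core_truncation_prob Probability that a site carries the core only
#'   in part: a uniform-length prefix or suffix (1 .. `core_length %/% 2`)
#'   is removed.
#' @param target_mean_length,target_sd_length Targets for the site-length
#'   distribution (mean and population SD); the flank parameters are solved
#'   for both moments, net of the core-length contribution.
#' @param max_flank Truncation point of the per-side flank distribution.
#' @param background Base frequencies for flanks and core draws.
#' @param species Species label for the generated dataset.
#' @param seed Default seed used by [generate_dataset()].
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_tfs = 20L, sites_per_tf = 8L, core_length = 6L,
                       core_conservation = 0.9, core_conservation_sd = 0.1,
                       core_truncation_prob = 0.25,
                       target_mean_length = 12, target_sd_length = 6,
                       max_flank = 40L,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       species = "synthetic", seed = 1L) {
  stopifnot(n_tfs >= 1, sites_per_tf >= 3, core_length >= 1,
            core_conservation >= 0, core_conservation <= 1,
            core_conservation_sd >= 0, core_conservation_sd < 0.5,
            core_truncation_prob >= 0, core_truncation_prob <= 1,
            length(background) == 4, abs(sum(background) - 1) < 1e-8)
  max_cut <- core_length %/% 2
  # moments of the core-length contribution under truncation
  if (max_cut >= 1 && core_truncation_prob > 0) {
    cuts <- 1:max_cut
    mean_cut <- core_truncation_prob * mean(cuts)
    var_cut <- core_truncation_prob * mean(cuts^2) - mean_cut^2
  } else {
    mean_cut <- 0; var_cut <- 0
  }
  mean_core <- core_length - mean_cut
  mean_flank <- (target_mean_length - mean_core) / 2
  if (mean_flank < 0) stop("core longer than the target mean site length")
  var_flank <- max(0, (target_sd_length^2 - var_cut) / 2)
  structure(list(n_tfs = as.integer(n_tfs), sites_per_tf = as.integer(sites_per_tf),
                 core_length = as.integer(core_length),
                 core_conservation = core_conservation,
                 core_conservation_sd = core_conservation_sd,
                 core_truncation_prob = core_truncation_prob,
                 target_mean_length = target_mean_length,
                 target_sd_length = target_sd_length,
                 max_flank = as.integer(max_flank),
                 flank_pmf = solve_flank_pmf(mean_flank, var_flank, max_flank),
                 mean_flank = mean_flank,
                 background = background, species = species,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Per-side flank distribution: negative binomial on 0..max_flank
# (truncated), with (size, mu) solved numerically so the truncated mean and
# variance match the requested moments. Returns the pmf over 0..max_flank.
solve_flank_pmf <- function(mean_target, var_target, max_flank) {
  k <- 0:max_flank
  if (mean_target <= 0) {
    pmf <- c(1, rep(0, max_flank))
    return(stats::setNames(pmf, k))
  }
  moments <- function(par) {
    wt <- stats::dnbinom(k, size = exp(par[1]), mu = exp(par[2]))
    wt <- wt / sum(wt)
    m <- sum(k * wt)
    v <- sum(k^2 * wt) - m^2
    c(m, v)
  }
  # overdispersed target (var > mean): solve both moments; otherwise fall
  # back to a Poisson-like NB with large size and match the mean only
  if (var_target > mean_target) {
    obj <- function(par) {
      mv <- moments(par)
      (mv[1] - mean_target)^2 + (mv[2] - var_target)^2
    }
    r0 <- mean_target^2 / (var_target - mean_target)
    fit <- stats::optim(c(log(r0), log(mean_target)), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000))
    par <- fit$par
  } else {
    par <- c(log(1e4), log(mean_target))
  }
  wt <- stats::dnbinom(k, size = exp(par[1]), mu = exp(par[2]))
  stats::setNames(wt / sum(wt), k)
}

rflank <- function(n, pmf) {
  sample(as.integer(names(pmf)), n, replace = TRUE, prob = pmf)
}

#' Generate a synthetic species dataset with a planted core
#'
#' Fully reproducible from the seed. The truth record stores, per TF, the
#' planted core consensus and, per site, the span of the (possibly
#' truncated) core copy within the site.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return A list with `dataset` (a [species_dataset()]) and `truth` (list
#'   with per-TF cores and per-site core spans).
#' @export
generate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(as.integer(seed))
  max_cut <- spec$core_length %/% 2
  sets <- vector("list", spec$n_tfs)
  truth <- vector("list", spec$n_tfs)
  for (i in seq_len(spec$n_tfs)) {
    tf_id <- sprintf("TF%03d", i)
    core <- sample(DNA_BASES, spec$core_length, replace = TRUE, prob = spec$background)
    # position-specific conservation profile of this TF's core
    if (spec$core_conservation_sd > 0 &&
        spec$core_conservation > 0 && spec$core_conservation < 1) {
      m <- spec$core_conservation
      kappa <- max(m * (1 - m) / spec$core_conservation_sd^2 - 1, 1e-3)
      cons_profile <- stats::rbeta(spec$core_length, m * kappa, (1 - m) * kappa)
    } else {
      cons_profile <- rep(spec$core_conservation, spec$core_length)
    }
    seqs <- character(spec$sites_per_tf)
    spans <- vector("list", spec$sites_per_tf)
    for (j in seq_len(spec$sites_per_tf)) {
      core_copy <- core
      copy_cons <- cons_profile
      cut_side <- "none"; cut_len <- 0L
      if (max_cut >= 1 && runif(1) < spec$core_truncation_prob) {
        cut_len <- sample.int(max_cut, 1)
        cut_side <- if (runif(1) < 0.5) "prefix" else "suffix"
        keep <- if (cut_side == "prefix") -seq_len(cut_len)
                else seq_len(length(core) - cut_len)
        core_copy <- core[keep]
        copy_cons <- cons_profile[keep]
      }
      # per-position substitution noise
      noise <- runif(length(core_copy)) >= copy_cons
      if (any(noise)) {
        core_copy[noise] <- vapply(core_copy[noise], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
      }
      lf <- rflank(1, spec$flank_pmf)
      rf <- rflank(1, spec$flank_pmf)
      left <- sample(DNA_BASES, lf, replace = TRUE, prob = spec$background)
      right <- sample(DNA_BASES, rf, replace = TRUE, prob = spec$background)
      seqs[j] <- paste(c(left, core_copy, right), collapse = "")
      spans[[j]] <- list(core_start = lf + 1L,
                         core_end = lf + length(core_copy),
                         truncated = cut_side, cut_len = cut_len)
    }
    ids <- sprintf("%s_s%d", tf_id, seq_len(spec$sites_per_tf))
    sets[[i]] <- site_set(tf_id, spec$species, ids, seqs)
    truth[[i]] <- list(tf_id = tf_id, core = paste(core, collapse = ""),
                       conservation = cons_profile,
                       sites = stats::setNames(spans, ids))
  }
  names(truth) <- vapply(truth, function(x) x$tf_id, character(1))
  list(dataset = species_dataset(spec$species, sets), truth = truth)
}

#' Write the truth record of a synthetic dataset as JSON
#' @param truth The `truth` element of a [generate_dataset()] result.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Length-variability histogram of a dataset
#'
#' Per TF, the ratio of the population standard deviation to the mean of
#' its site lengths, binned; reports the fraction of TFs and of sites per
#' bin. TFs without sites are excluded with a warning.
#'
#' @param dataset A [species_dataset()].
#' @param breaks Bin boundaries for the SD/mean ratio (right-open bins).
#' @return A data frame with `bin_low`, `bin_high`, `n_tf`, `tf_fraction`,
#'   `n_bs`, `bs_fraction`, plus attributes `mean_length` and `sd_length`
#'   (population SD) of the whole dataset.
#' @export
variability_histogram <- function(dataset,
                                  breaks = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, Inf)) {
  stopifnot(inherits(dataset, "species_dataset"))
  sets <- dataset$site_sets
  empty <- vapply(sets, function(s) length(s$sequence) == 0, logical(1))
  if (any(empty)) {
    warning("excluding TFs without sites: ", paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  lens <- lapply(sets, function(s) nchar(s$sequence))
  ratio <- vapply(lens, function(x) population_sd(x) / mean(x), numeric(1))
  n_bs <- vapply(lens, length, integer(1))
  bin <- cut(ratio, breaks = breaks, right = FALSE, include.lowest = TRUE)
  out <- data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
                    n_tf = as.vector(table(bin)),
                    n_bs = as.vector(tapply(n_bs, bin, sum, default = 0L)))
  out$tf_fraction <- out$n_tf / sum(out$n_tf)
  out$bs_fraction <- out$n_bs / sum(out$n_bs)
  all_len <- unlist(lens)
  attr(out, "mean_length") <- mean(all_len)
  attr(out, "sd_length") <- population_sd(all_len)
  attr(out, "ratios") <- ratio
  out
}

#' Does a consensus contain the planted core?
#'
#' Slides the core along the consensus and reports whether some contiguous
#' window matches it position by position, counting a position as matched
#' when the consensus symbol is the core base or an ambiguity code covering
#' it. Used as the core-recovery check for synthetic data.
#'
#' @param consensus A [consensus_from_alignment()] result or consensus string.
#' @param core The planted core (DNA string).
#' @return `TRUE` or `FALSE`.
#' @export
consensus_contains_core <- function(consensus, core) {
  symbols <- if (inherits(consensus, "tfbs_consensus")) consensus$symbols
             else strsplit(consensus, "")[[1]]
  cb <- strsplit(toupper(core), "")[[1]]
  W <- length(symbols); L <- length(cb)
  if (L > W) return(FALSE)
  for (start in seq_len(W - L + 1)) {
    win <- symbols[start:(start + L - 1)]
    if (all(.MATCH_TABLE[cbind(win, cb)] == 1L)) return(TRUE)
  }
  FALSE
}
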