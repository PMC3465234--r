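#' Experiment grid configuration
#'
#' Describes which cells of the (alignment strategy) x (IC) x (PS scope)
#' grid to run. The default grid — both strategies, IC on and off, and the
#' twelve scopes none, 1..10, full — expands to exactly 48 configurations.
#'
#' @param strategies Character subset of `c("sorted", "imported")`.
#' @param ic Logical vector of IC settings to run (default both).
#' @param scopes Scopes to run: `"none"`, integers 1..10, `"full"`.
#' @param n_slots,fpr_max ROC construction parameters (see [build_roc()]).
#' @param tie_rule Offset tie rule for the greedy aligner.
#' @param seed Integer seed recorded in the manifest and used for any
#'   randomised step.
#' @param imported_alignments Named list (TF id -> [tfbs_alignment()]),
#'   required when `"imported"` is among the strategies.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(strategies = c("sorted", "imported"),
                        ic = c(TRUE, FALSE),
                        scopes = c("none", 1:10, "full"),
                        n_slots = 20L, fpr_max = 0.20,
                        tie_rule = "last_best", seed = 1L,
                        imported_alignments = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  scopes <- vapply(scopes, function(s) scope_label(normalize_scope(s)), character(1))
  structure(list(strategies = strategies, ic = unique(ic), scopes = unname(scopes),
                 n_slots = as.integer(n_slots), fpr_max = fpr_max,
                 tie_rule = tie_rule, seed = as.integer(seed),
                 imported_alignments = imported_alignments),
            class = "grid_config")
}

#' @rdname grid_config
#' @param path A YAML file with any of the fields `strategies`, `ic`,
#'   `scopes`, `n_slots`, `fpr_max`, `tie_rule`, `seed`; missing fields take
#'   the defaults above. `read_grid_config()` returns the parsed
#'   `grid_config`.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("strategies", "ic", "scopes", "n_slots", "fpr_max", "tie_rule", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown grid config fields: ", paste(bad, collapse = ", "))
  do.call(grid_config, cfg)
}

#' @rdname grid_config
#' @param grid A `grid_config`.
#' @return `expand_grid_config()`: a data frame with one row per cell
#'   (`strategy`, `use_ic`, `ps_scope`, `label`).
#' @export
expand_grid_config <- function(grid) {
  cells <- expand.grid(ps_scope = grid$scopes, use_ic = grid$ic,
                       strategy = grid$strategies,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("strategy", "use_ic", "ps_scope")]
  cells$label <- vapply(seq_len(nrow(cells)), function(i) {
    config_label(scoring_config(cells$use_ic[i], cells$ps_scope[i], cells$strategy[i]))
  }, character(1))
  cells
}

#' @export
print.grid_config <- function(x, ...) {
  cat(sprintf("<grid_config> %d cells: strategies {%s} x IC {%s} x scopes {%s}\n",
              nrow(expand_grid_config(x)),
              paste(x$strategies, collapse = ","),
              paste(x$ic, collapse = ","),
              paste(x$scopes, collapse = ",")))
  invisible(x)
}

#' Run the experiment grid
#'
#' Runs leave-one-out cross-validation for every cell of the grid on one
#' species dataset. Models are trained once per (strategy, TF, held-out
#' site) and shared across the IC/scope cells, then each cell scores the
#' held-out positive and the negatives under its own scoring function.
#' Produces per-cell experiment tables and ROC areas, Wilcoxon comparisons
#' along the grid axes (IC on vs off at fixed strategy and scope; strategy
#' vs strategy at fixed IC and scope), and a plateau report per
#' (strategy, IC) track.
#'
#' @param dataset A [species_dataset()].
#' @param grid A [grid_config()].
#' @param out_dir Optional directory; when given, per-cell TSVs, an AUC
#'   table, comparison JSON and a manifest are written there.
#' @param min_sites Admission rule (default 3).
#' @param verbose Log progress to stderr.
#' @return An object of class `grid_result`: `cells`, `experiments` (named
#'   list of per-cell data frames), `roc`, `auc` (data frame), `ic_effect`
#'   and `strategy_effect` (Wilcoxon comparisons), `plateaus`, `manifest`.
#' @export
run_grid <- function(dataset, grid, out_dir = NULL, min_sites = 3L,
                     verbose = FALSE) {
  stopifnot(inherits(dataset, "species_dataset"), inherits(grid, "grid_config"))
  set.seed(grid$seed)
  cells <- expand_grid_config(grid)
  say <- function(...) if (verbose) message(sprintf(...))

  sets <- dataset$site_sets[order(names(dataset$site_sets))]
  sets <- sets[vapply(sets, length, integer(1)) >= min_sites]
  if (length(sets) == 0) stop("no TFs admitted to cross-validation")

  # negatives per TF: encoded once
  say("encoding negatives for %d TFs", length(sets))
  all_seqs <- lapply(sets, function(s) s$sequence)
  neg_enc <- lapply(names(sets), function(tf_id) {
    negs <- unlist(all_seqs[names(sets) != tf_id], use.names = FALSE)
    negs <- negs[!(negs %in% all_seqs[[tf_id]])]
    lapply(negs, encode_dna)
  })
  names(neg_enc) <- names(sets)

  # shared training: one model per (strategy, tf, left-out site)
  models <- list()
  for (strategy in grid$strategies) {
    say("training models (%s strategy)", strategy)
    models[[strategy]] <- lapply(names(sets), function(tf_id) {
      tf <- sets[[tf_id]]
      imp <- grid$imported_alignments[[tf_id]]
      if (strategy == "imported" && is.null(imp)) {
        stop(sprintf("no imported alignment registered for tf '%s'", tf_id))
      }
      lapply(seq_len(length(tf)), function(j) {
        train_loo_model(tf, j, strategy, imp, grid$tie_rule)
      })
    })
    names(models[[strategy]]) <- names(sets)
  }

  experiments <- vector("list", nrow(cells))
  names(experiments) <- cells$label
  for (ci in seq_len(nrow(cells))) {
    config <- scoring_config(cells$use_ic[ci], cells$ps_scope[ci], cells$strategy[ci])
    say("scoring cell %s", cells$label[ci])
    rows <- list()
    for (tf_id in names(sets)) {
      tf <- sets[[tf_id]]
      for (j in seq_len(length(tf))) {
        model <- models[[cells$strategy[ci]]][[tf_id]][[j]]
        pos <- scan_sequence(tf$sequence[j], model, config)
        negs <- scan_batch(neg_enc[[tf_id]], model, config)
        fp <- sum(negs > pos)
        rows[[length(rows) + 1L]] <- data.frame(
          tf_id = tf_id, site_id = tf$site_id[j], pos_score = pos,
          fp = fp, n_neg = length(negs),
          fpr = if (length(negs)) fp / length(negs) else 0,
          stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, rows)
    class(res) <- c("loo_results", "data.frame")
    attr(res, "config") <- config
    experiments[[ci]] <- res
  }

  roc <- lapply(experiments, build_roc, fpr_max = grid$fpr_max, n_slots = grid$n_slots)
  auc <- data.frame(cells, auc = vapply(roc, `[[`, numeric(1), "auc"),
                    row.names = NULL)

  # IC effect: on vs off at fixed (strategy, scope)
  ic_effect <- list()
  if (all(c(TRUE, FALSE) %in% grid$ic)) {
    for (strategy in grid$strategies) {
      for (sc in grid$scopes) {
        a <- cells$label[cells$strategy == strategy & !cells$use_ic & cells$ps_scope == sc]
        b <- cells$label[cells$strategy == strategy & cells$use_ic & cells$ps_scope == sc]
        ic_effect[[sprintf("%s|ps=%s", strategy, sc)]] <-
          wilcoxon_compare(experiments[[a]], experiments[[b]])
      }
    }
  }

  # strategy effect: pairing at fixed (ic, scope)
  strategy_effect <- list()
  if (length(grid$strategies) == 2) {
    for (ic_on in grid$ic) {
      for (sc in grid$scopes) {
        a <- cells$label[cells$strategy == grid$strategies[1] &
                           cells$use_ic == ic_on & cells$ps_scope == sc]
        b <- cells$label[cells$strategy == grid$strategies[2] &
                           cells$use_ic == ic_on & cells$ps_scope == sc]
        strategy_effect[[sprintf("%s|ps=%s", if (ic_on) "IC" else "noIC", sc)]] <-
          wilcoxon_compare(experiments[[a]], experiments[[b]])
      }
    }
  }

  plateaus <- list()
  if (length(grid$scopes) >= 3) {
    for (strategy in grid$strategies) {
      for (ic_on in grid$ic) {
        labels <- cells$label[cells$strategy == strategy & cells$use_ic == ic_on]
        track <- experiments[labels]
        names(track) <- cells$ps_scope[cells$strategy == strategy & cells$use_ic == ic_on]
        plateaus[[sprintf("%s|%s", strategy, if (ic_on) "IC" else "noIC")]] <-
          detect_plateau(track, fpr_max = grid$fpr_max, n_slots = grid$n_slots)
      }
    }
  }

  manifest <- grid_manifest(grid, dataset)
  result <- structure(list(cells = cells, experiments = experiments, roc = roc,
                           auc = auc, ic_effect = ic_effect,
                           strategy_effect = strategy_effect,
                           plateaus = plateaus, manifest = manifest),
                      class = "grid_result")
  if (!is.null(out_dir)) write_grid_result(result, out_dir)
  result
}

grid_manifest <- function(grid, dataset) {
  cfg <- list(strategies = grid$strategies, ic = grid$ic, scopes = grid$scopes,
              n_slots = grid$n_slots, fpr_max = grid$fpr_max,
              tie_rule = grid$tie_rule, seed = grid$seed)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(package = "mlconsensus",
       version = as.character(utils::packageVersion("mlconsensus")),
       species = dataset$species, seed = grid$seed,
       config = cfg, config_md5 = hash,
       timestamp = format(Sys.time(), tz = "UTC"))
}

write_grid_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (label in names(result$experiments)) {
    fn <- file.path(out_dir, paste0("experiments_", gsub("[^A-Za-z0-9]+", "_", label), ".tsv"))
    write.table(result$experiments[[label]], fn, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(result$auc, file.path(out_dir, "auc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- list(ic_effect = lapply(result$ic_effect, unclass),
               strategy_effect = lapply(result$strategy_effect, unclass),
               plateaus = lapply(result$plateaus, unclass))
  jsonlite::write_json(comp, file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d cells on '%s'\n", nrow(x$cells), x$manifest$species))
  print(x$auc[, c("label", "auc")], row.names = FALSE)
  invisible(x)
}

#' Plot sum-of-TPR area against PS scope
#'
#' One line per (strategy, IC) track, with the plateau scopes and the peak
#' marked, in the style of an area-versus-scope performance chart. Requires
#' ggplot2.
#'
#' @param result A [run_grid()] result.
#' @return A ggplot object.
#' @export
plot_auc_by_scope <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_auc_by_scope requires ggplot2")
  }
  df <- result$auc
  df$scope <- factor(df$ps_scope, levels = unique(df$ps_scope))
  df$track <- sprintf("%s|%s", df$strategy, ifelse(df$use_ic, "IC", "noIC"))
  df$in_plateau <- vapply(seq_len(nrow(df)), function(i) {
    p <- result$plateaus[[df$track[i]]]
    !is.null(p) && df$ps_scope[i] %in% p$plateau_scopes
  }, logical(1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope, y = .data$auc,
                                   group = .data$track, colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_plateau), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18)) +
    ggplot2::labs(x = "PS scope", y = "sum-of-TPR area",
                  shape = "in plateau", colour = NULL)
}
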