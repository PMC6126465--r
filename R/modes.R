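#' Run configuration (keyword set)
#'
#' Collects the tunable parameters of a run with their defaults: no
#' resolution limits, RADFRAC 0.75 (retained-intensity fraction for the
#' damage cutoff), ISIGI 1.5 (signal threshold for the resolution
#' estimate), TOLERANCE 2 (cell-agreement check, percent/degrees),
#' COMPLETENESS 95 (pruning target, percent), MAXCYCLES 20 and
#' PRUNEFRAC 0.10 (pruning schedule), SEED 42 (CC1/2 half-split).
#'
#' @param resolution_high,resolution_low Resolution limits in Angstrom
#'   (`NA` = none).
#' @param radfrac Fraction in (0, 1].
#' @param isigi Positive signal threshold.
#' @param tolerance Non-negative cell tolerance; >= 100 disables the check.
#' @param completeness_target Percent in (0, 100].
#' @param max_prune_cycles,prune_fraction Pruning schedule.
#' @param seed Integer seed for seeded statistics.
#' @return List of class `keyword_set`.
#' @export
keyword_set <- function(resolution_high = NA_real_, resolution_low = NA_real_,
                        radfrac = 0.75, isigi = 1.5, tolerance = 2,
                        completeness_target = 95, max_prune_cycles = 20L,
                        prune_fraction = 0.10, seed = 42L) {
  stopifnot(radfrac > 0, radfrac <= 1, isigi > 0, tolerance >= 0,
            completeness_target > 0, completeness_target <= 100,
            max_prune_cycles >= 0, prune_fraction > 0, prune_fraction <= 1)
  structure(list(resolution_high = resolution_high,
                 resolution_low = resolution_low,
                 radfrac = radfrac, isigi = isigi, tolerance = tolerance,
                 completeness_target = completeness_target,
                 max_prune_cycles = as.integer(max_prune_cycles),
                 prune_fraction = prune_fraction, seed = as.integer(seed)),
            class = "keyword_set")
}

#' Parse a keyword stream
#'
#' Reads a keyword file (or character vector), one keyword per line, into a
#' [keyword_set()]. An empty stream yields all defaults — the equivalent of
#' accepting every default interactively. Recognised keywords:
#' `RESOLUTION HIGH x`, `RESOLUTION LOW x`, `TOLERANCE n`, `RADFRAC x`,
#' `ISIGI x`, `COMPLETENESS x`, `MAXCYCLES n`, `PRUNEFRAC x`, `SEED n`.
#' Unknown keywords are ignored with a warning.
#'
#' @param stream Character vector of lines, or a connection/file path.
#' @return A [keyword_set()].
#' @export
parse_keywords <- function(stream = character(0)) {
  lines <- if (is.character(stream) && (length(stream) != 1 || !file.exists(stream))) {
    stream
  } else {
    readLines(stream, warn = FALSE)
  }
  kw <- keyword_set()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(toupper(ln), "\\s+")[[1]]
    raw <- strsplit(ln, "\\s+")[[1]]
    num <- function(i) suppressWarnings(as.numeric(raw[i]))
    if (tok[1] == "RESOLUTION" && length(tok) >= 3 && tok[2] == "HIGH") {
      kw$resolution_high <- num(3)
    } else if (tok[1] == "RESOLUTION" && length(tok) >= 3 && tok[2] == "LOW") {
      kw$resolution_low <- num(3)
    } else if (tok[1] == "TOLERANCE") {
      kw$tolerance <- num(2)
    } else if (tok[1] == "RADFRAC") {
      kw$radfrac <- num(2)
    } else if (tok[1] == "ISIGI") {
      kw$isigi <- num(2)
    } else if (tok[1] == "COMPLETENESS") {
      kw$completeness_target <- num(2)
    } else if (tok[1] == "MAXCYCLES") {
      kw$max_prune_cycles <- as.integer(num(2))
    } else if (tok[1] == "PRUNEFRAC") {
      kw$prune_fraction <- num(2)
    } else if (tok[1] == "SEED") {
      kw$seed <- as.integer(num(2))
    } else {
      warning("unknown keyword ignored: ", ln)
    }
  }
  kw
}

#' Dendrogram-only mode: quick clustering and bookkeeping
#'
#' Gathers the inputs, assigns serials, clusters on cell parameters and
#' writes `mtz_names.dat`, `CLUSTERS.txt` and an annotated dendrogram plot.
#' No damage analysis, resolution estimation or scaling is performed.
#'
#' @param target Directory or list file of input datasets.
#' @param keywords A [keyword_set()].
#' @param run_dir Output directory (default `"."`).
#' @param plot Draw the annotated dendrogram PNG (default `TRUE`).
#' @return List of class `analysis_state` with `datasets`, `dendrogram`,
#'   `keywords`, `run_dir` (and `entries = NULL`).
#' @export
mode_dendrogram_only <- function(target, keywords = keyword_set(),
                                 run_dir = ".", plot = TRUE) {
  datasets <- gather_inputs(target, output_dir = run_dir)
  if (length(datasets) < 2) stop("clustering needs at least 2 input datasets")
  dendro <- build_dendrogram(datasets)
  write_clusters_file(dendro, file.path(run_dir, "CLUSTERS.txt"))
  if (plot) {
    try(plot_dendrogram(dendro, path = file.path(run_dir, "dendrogram.png")),
        silent = TRUE)
  }
  structure(list(datasets = datasets, dendrogram = dendro, entries = NULL,
                 keywords = keywords, run_dir = run_dir),
            class = "analysis_state")
}

#' Analysis mode: clustering plus damage and resolution screening
#'
#' Everything [mode_dendrogram_only()] does, plus the per-dataset
#' radiation-damage assessment and resolution estimate, written as the
#' six-column `FINAL_list_of_files.dat`. The returned state is the
#' prerequisite for the synthesis, combination and pruning modes.
#'
#' @inheritParams mode_dendrogram_only
#' @return An `analysis_state` with `entries` populated.
#' @export
mode_analysis <- function(target, keywords = keyword_set(), run_dir = ".",
                          plot = TRUE) {
  state <- mode_dendrogram_only(target, keywords, run_dir, plot)
  state$entries <- analysis_pass(state$datasets, keywords)
  write_final_list(state$entries, file.path(run_dir, "FINAL_list_of_files.dat"))
  state
}

#' @export
print.analysis_state <- function(x, ...) {
  cat(sprintf("analysis state: %d datasets in '%s'%s\n", length(x$datasets),
              x$run_dir,
              if (is.null(x$entries)) " (dendrogram-only)" else ""))
  print(x$dendrogram)
  invisible(x)
}

# Accepted image range per dataset, honouring analysis cutoffs.
accepted_ranges_from_state <- function(state) {
  if (is.null(state$entries)) return(NULL)
  e <- state$entries
  rng <- lapply(seq_len(nrow(e)), function(i) {
    c(e$first_image[i],
      if (is.na(e$cutoff_image[i])) e$last_image[i] else e$cutoff_image[i])
  })
  stats::setNames(rng, e$serial)
}

datasets_by_serial <- function(state, serials) {
  all_ser <- vapply(state$datasets, `[[`, integer(1), "serial")
  state$datasets[match(serials, all_ser)]
}

#' Synthesis mode: merge every selected dendrogram node
#'
#' Cuts the analysis-state dendrogram at `threshold` (by merge height or by
#' aLCV), runs the scale-and-merge engine on every selected node —
#' honouring each dataset's damage cutoff and the resolution keywords —
#' and writes per-node merged reflection files under `merged_files/` plus
#' the summary table `MERGING_STATISTICS.info`, rows sorted by descending
#' completeness.
#'
#' @param state An [mode_analysis()] state.
#' @param threshold_kind `"height"` or `"alcv"`.
#' @param threshold Positive cut value.
#' @param keywords A [keyword_set()] (defaults to the state's).
#' @return Named list of [merge_group()] results (names = node ids),
#'   invisibly carrying the statistics table as attribute `"table"`.
#' @export
mode_synthesis <- function(state, threshold_kind = c("height", "alcv"),
                           threshold, keywords = NULL) {
  threshold_kind <- match.arg(threshold_kind)
  if (is.null(state$entries)) stop("synthesis requires an analysis-mode state")
  if (is.null(keywords)) keywords <- state$keywords
  sel <- cut_tree(state$dendrogram, threshold_kind, threshold)
  out_dir <- file.path(state$run_dir, "merged_files")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!nrow(sel)) {
    warning("no dendrogram node satisfies the ", threshold_kind,
            " threshold ", threshold)
    write_stats_table(list(), file.path(state$run_dir, "MERGING_STATISTICS.info"))
    return(invisible(list()))
  }
  ranges <- accepted_ranges_from_state(state)
  results <- list()
  for (i in seq_len(nrow(sel))) {
    nid <- sel$node_id[i]
    grp <- datasets_by_serial(state, sel$members[[i]])
    res <- tryCatch(
      merge_group(grp, keywords = keywords, accepted_ranges = ranges,
                  label = as.character(nid)),
      error = function(e) {
        warning("node ", nid, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    write_merge_result(res, out_dir)
    results[[as.character(nid)]] <- res
  }
  tab <- write_stats_table(results, file.path(state$run_dir, "MERGING_STATISTICS.info"))
  attr(results, "table") <- tab
  invisible(results)
}

write_merge_result <- function(res, out_dir) {
  m <- res$merged
  lines <- c(sprintf("# merged group %s: datasets %s", res$label,
                     paste(res$members, collapse = ",")),
             paste("CELL", paste(formatC(as.numeric(res$cell), format = "f", digits = 5),
                                 collapse = " ")),
             sprintf("RESOLUTION %.3f", res$d_min),
             "H K L I SIGI NOBS",
             sprintf("%d %d %d %.6g %.6g %d", m$h, m$k, m$l, m$intensity,
                     m$sigma, m$n_obs))
  writeLines(lines, file.path(out_dir, sprintf("merged_%s.refl", res$label)))
  sc <- res$scaled
  writeLines(c(sprintf("# scaled unmerged group %s", res$label),
               "H K L I SIGI IMAGE SERIAL",
               sprintf("%d %d %d %.6g %.6g %d %d", sc$h, sc$k, sc$l,
                       sc$intensity, sc$sigma, sc$image, sc$serial)),
             file.path(out_dir, sprintf("scaled_%s.refl", res$label)))
  log <- utils::capture.output(print(res))
  writeLines(log, file.path(out_dir, sprintf("group_%s.log", res$label)))
  invisible(NULL)
}

stats_table_row <- function(res) {
  st <- res$stats
  data.frame(cluster = res$label,
             r_meas = st$r_meas, r_pim = st$r_pim,
             completeness = st$completeness, multiplicity = st$multiplicity,
             res_cc = st$res_cc, res_mnisd = st$res_mnisd, res_max = st$res_max)
}

write_stats_table <- function(results, path) {
  hdr <- sprintf("%-10s %-9s %-9s %-13s %-13s %-10s %-12s %-8s",
                 "Cluster", "Rmeas", "Rpim", "Completeness",
                 "Multiplicity", "ResCC1/2", "ResMnI/sd", "ResMax")
  if (!length(results)) {
    writeLines(hdr, path)
    return(invisible(NULL))
  }
  tab <- do.call(rbind, lapply(results, stats_table_row))
  tab <- tab[order(-tab$completeness), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  rows <- sprintf("%-10s %-9s %-9s %-13.2f %-13.2f %-10.2f %-12.2f %-8.2f",
                  tab$cluster, fmt(tab$r_meas), fmt(tab$r_pim),
                  tab$completeness, tab$multiplicity, tab$res_cc,
                  tab$res_mnisd, tab$res_max)
  writeLines(c(hdr, rows), path)
  invisible(tab)
}

#' Parse the combination-mode selection syntax
#'
#' Selections are written as one bracketed include token and an optional
#' double-bracketed exclude token, e.g. `"[49] [[41]]"`: include ids that
#' match a dendrogram cluster expand to the cluster's member serials,
#' other ids are taken as dataset serials; excluded serials are then
#' removed and duplicates collapsed.
#'
#' @param tokens Character string (or vector of tokens) of the selection.
#' @param dendro The [build_dendrogram()] result the node ids refer to.
#' @return List of class `combination_spec` with `include` (the original
#'   ids), `exclude`, and `serials` (the expanded final dataset set).
#' @export
parse_combination <- function(tokens, dendro) {
  txt <- paste(tokens, collapse = " ")
  ex_m <- regmatches(txt, gregexpr("\\[\\[[0-9, ]+\\]\\]", txt))[[1]]
  txt_wo <- gsub("\\[\\[[0-9, ]+\\]\\]", "", txt)
  in_m <- regmatches(txt_wo, gregexpr("\\[[0-9, ]+\\]", txt_wo))[[1]]
  ids <- function(ms) {
    if (!length(ms)) return(integer(0))
    as.integer(unlist(strsplit(gsub("[^0-9,]", "", ms), ",")))
  }
  include <- ids(in_m); exclude <- ids(ex_m)
  if (!length(include)) stop("combination spec has no include token: ", txt)
  serials <- unlist(lapply(include, function(id) node_members(dendro, id)))
  serials <- sort(setdiff(unique(serials), exclude))
  if (!length(serials)) stop("combination spec selects no datasets: ", txt)
  structure(list(include = include, exclude = exclude, serials = serials),
            class = "combination_spec")
}

#' Combination mode: merge an arbitrary dataset selection
#'
#' Runs the scale-and-merge engine on the datasets named by a combination
#' spec — any grouping, whether or not it corresponds to a dendrogram node
#' — and stores the outputs sequentially under `combined_files/` (run
#' numbers increase across invocations in the same run directory).
#'
#' @param state An [mode_analysis()] state.
#' @param spec A [parse_combination()] result, or a character selection
#'   string parsed against the state's dendrogram.
#' @param keywords A [keyword_set()] (defaults to the state's).
#' @return The [merge_group()] result, labelled `run<N>`.
#' @export
mode_combination <- function(state, spec, keywords = NULL) {
  if (is.null(state$entries)) stop("combination requires an analysis-mode state")
  if (is.character(spec)) spec <- parse_combination(spec, state$dendrogram)
  if (is.null(keywords)) keywords <- state$keywords
  out_dir <- file.path(state$run_dir, "combined_files")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  run_no <- length(list.files(out_dir, pattern = "^group_run[0-9]+\\.log$")) + 1L
  res <- merge_group(datasets_by_serial(state, spec$serials),
                     keywords = keywords,
                     accepted_ranges = accepted_ranges_from_state(state),
                     label = sprintf("run%d", run_no))
  write_merge_result(res, out_dir)
  stats_path <- file.path(out_dir, "COMBINED_STATISTICS.info")
  row <- stats_table_row(res)
  row$cluster <- sprintf("run%d[%s]", run_no, paste(spec$serials, collapse = ","))
  line <- sprintf("%-24s %-9.3f %-9.3f %-13.2f %-13.2f %-10.2f %-12.2f %-8.2f",
                  row$cluster, row$r_meas, row$r_pim, row$completeness,
                  row$multiplicity, row$res_cc, row$res_mnisd, row$res_max)
  cat(line, "\n", sep = "", file = stats_path, append = file.exists(stats_path))
  res
}

#' Pruning mode: trim damaged image tails to minimise R_pim
#'
#' Cycle 0 merges the selection unchanged. Each subsequent cycle finds the
#' member dataset with the highest per-dataset mean R_merge contribution
#' (its own sum of |I - <I>| over its observations of multiply-observed
#' reflections, divided by the sum of its intensities, on the current
#' scaling), removes the last `prune_fraction` of that dataset's currently
#' accepted images (at least one), and re-merges. Cycling halts when a
#' cycle's completeness falls below `completeness_target` (that cycle is
#' discarded), when `max_prune_cycles` is reached, or when a removal would
#' eliminate a dataset entirely. The cycle with the lowest R_pim — cycle 0
#' included — is selected.
#'
#' @inheritParams mode_combination
#' @return List of class `prune_result`: `best_cycle` (index), `best` (its
#'   [merge_group()] result), `cycles` (a `data.frame` log: cycle, victim
#'   serial, images removed this cycle and in total, r_merge, r_meas,
#'   r_pim, completeness, multiplicity, eligible), `ranges` (final
#'   accepted ranges) and `results` (every cycle's merge result).
#' @export
mode_pruning <- function(state, spec, keywords = NULL) {
  if (is.null(state$entries)) stop("pruning requires an analysis-mode state")
  if (is.character(spec)) spec <- parse_combination(spec, state$dendrogram)
  if (length(spec$serials) < 2) stop("pruning needs at least 2 datasets")
  if (is.null(keywords)) keywords <- state$keywords
  ranges <- accepted_ranges_from_state(state)[as.character(spec$serials)]
  group <- datasets_by_serial(state, spec$serials)
  log <- list(); results <- list()
  removed_this <- 0L; removed_total <- 0L
  cyc <- 0L
  repeat {
    res <- merge_group(group, keywords = keywords, accepted_ranges = ranges,
                       label = sprintf("cycle%d", cyc))
    st <- res$stats
    eligible <- cyc == 0L || st$completeness >= keywords$completeness_target
    victim <- per_dataset_rmerge(res)
    log[[cyc + 1L]] <- data.frame(cycle = cyc,
                                  victim = victim$serial[1],
                                  images_removed = removed_this,
                                  images_removed_total = removed_total,
                                  r_merge = st$r_merge, r_meas = st$r_meas,
                                  r_pim = st$r_pim,
                                  completeness = st$completeness,
                                  multiplicity = st$multiplicity,
                                  eligible = eligible)
    results[[cyc + 1L]] <- res
    if (cyc > 0L && st$completeness < keywords$completeness_target) break
    if (cyc >= keywords$max_prune_cycles) break
    # choose the victim and its tail cut for the next cycle
    vser <- as.character(victim$serial[1])
    rng <- ranges[[vser]]
    n_acc <- rng[2] - rng[1] + 1L
    n_cut <- max(1L, as.integer(floor(keywords$prune_fraction * n_acc)))
    if (n_cut >= n_acc) break  # would eliminate the dataset entirely
    ranges[[vser]] <- c(rng[1], rng[2] - n_cut)
    removed_this <- n_cut
    removed_total <- removed_total + n_cut
    cyc <- cyc + 1L
  }
  logdf <- do.call(rbind, log)
  elig <- which(logdf$eligible & is.finite(logdf$r_pim))
  best <- elig[which.min(logdf$r_pim[elig])]
  structure(list(best_cycle = logdf$cycle[best], best = results[[best]],
                 cycles = logdf, ranges = ranges, results = results),
            class = "prune_result")
}

# Per-dataset R_merge contribution on the current scaling: each dataset's
# own numerator/denominator restricted to its observations of reflections
# observed >= 2 times in the group. Sorted worst-first.
per_dataset_rmerge <- function(res) {
  sc <- res$scaled
  sc <- data.table::copy(sc)
  sc[, n := .N, by = key]
  sc[, mean_i := mean(intensity), by = key]
  multi <- sc[n >= 2]
  out <- multi[, .(num = sum(abs(intensity - mean_i)), den = sum(intensity)),
               by = serial]
  out$r_merge <- ifelse(out$den > 0, out$num / out$den, Inf)
  out <- as.data.frame(out[order(-out$r_merge)])
  out
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("pruning: %d cycles run, best cycle %d (R_pim %.4f, completeness %.1f %%)\n",
              nrow(x$cycles) - 1L, x$best_cycle,
              x$best$stats$r_pim, x$best$stats$completeness))
  print(x$cycles[, c("cycle", "victim", "images_removed",
                     "images_removed_total", "r_merge", "r_pim",
                     "completeness", "eligible")], row.names = FALSE)
  invisible(x)
}
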