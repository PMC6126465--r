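#' Check cell agreement within a merge group
#'
#' Before scaling, the group's cells are compared pairwise: the check fails
#' when any pair differs by more than `tolerance` percent on any edge or by
#' more than `tolerance` degrees on any angle. A tolerance of 100 or more
#' always passes — the escape hatch for deliberately merging very different
#' crystals.
#'
#' @param cells List of [unit_cell()]s (>= 2).
#' @param tolerance Non-negative; default 2.
#' @return `TRUE` (pass) or `FALSE` (fail). On failure the attribute
#'   `"worst"` names the worst pair and parameter.
#' @export
check_tolerance <- function(cells, tolerance = 2) {
  stopifnot(length(cells) >= 2, tolerance >= 0)
  if (tolerance >= 100) return(TRUE)
  M <- t(vapply(cells, function(x) as.numeric(as_unit_cell(x)), numeric(6)))
  worst <- NULL; worst_val <- -Inf
  for (i in seq_len(nrow(M) - 1)) for (j in (i + 1):nrow(M)) {
    edge_dev <- 100 * abs(M[i, 1:3] - M[j, 1:3]) / pmin(M[i, 1:3], M[j, 1:3])
    ang_dev <- abs(M[i, 4:6] - M[j, 4:6])
    dev <- c(edge_dev, ang_dev)
    k <- which.max(dev)
    if (dev[k] > worst_val) {
      worst_val <- dev[k]
      worst <- sprintf("cells %d and %d differ by %.2f%s on %s", i, j, dev[k],
                       if (k <= 3) " %" else " deg",
                       c("a", "b", "c", "alpha", "beta", "gamma")[k])
    }
  }
  ok <- worst_val <= tolerance
  if (!ok) attr(ok, "worst") <- worst
  ok
}

# Build the pooled observation table for a group: one row per observation
# with serial, canonical key, s (from the dataset's own cell), I, sigma,
# image. Keys are encoded as a single character column for fast grouping.
pool_observations <- function(group, ops) {
  dt <- data.table::rbindlist(lapply(group, function(ds) {
    obs <- ds$observations
    if (!nrow(obs)) return(NULL)
    ck <- map_to_unique(obs[, c("h", "k", "l")], ops)
    out <- data.table::data.table(serial = ds$serial,
                                  h = ck[, 1], k = ck[, 2], l = ck[, 3],
                                  s = resolution_s(obs[, c("h", "k", "l")], ds$cell),
                                  intensity = obs$intensity, sigma = obs$sigma,
                                  image = obs$image)
    out$key <- paste(out$h, out$k, out$l)
    out
  }))
  if (!nrow(dt)) stop("group contains no observations")
  dt
}

#' Scale a group of datasets to a common intensity scale
#'
#' Fits the standard two-parameter model per dataset j — corrected
#' intensity = k_j * exp(-2 * B_j * s) * I_obs — by alternating least
#' squares: (1) merged mean intensities per unique reflection under the
#' current scales; (2) per-dataset (ln k_j, B_j) from a linear regression
#' of ln(I_obs / <I>) on s over that dataset's positive-intensity,
#' multiply-observed reflections. The dataset with the lowest serial is
#' the reference (k = 1, B = 0). Iteration stops when the largest relative
#' change in any scale falls below 1e-6 (or after 100 iterations, with a
#' warning). Sigmas are multiplied by the same correction factor.
#'
#' @param group List of [unmerged_dataset()]s (tolerance-checked upstream).
#' @param ops A [symmetry_ops()].
#' @param keywords A [keyword_set()] (unused fields ignored).
#' @return List with `scales` (data.frame serial, k, B), `scaled` (a
#'   `data.table` of scaled observations with canonical keys), `iterations`
#'   and `converged`.
#' @export
scale_datasets <- function(group, ops, keywords = keyword_set()) {
  serials <- vapply(group, `[[`, integer(1), "serial")
  stopifnot(!anyNA(serials), !anyDuplicated(serials))
  dt <- pool_observations(group, ops)
  scales <- data.frame(serial = sort(serials), k = 1, B = 0)
  if (length(group) == 1L) {
    return(list(scales = scales, scaled = finish_scaled(dt, scales),
                iterations = 0L, converged = TRUE))
  }
  # connectivity: at least one unique key seen in >= 2 datasets
  nser <- dt[, data.table::uniqueN(serial), by = key]$V1
  if (!any(nser >= 2)) {
    stop("unconnected group: no unique reflection observed in two or more datasets")
  }
  multi_keys <- dt[, .(nser = data.table::uniqueN(serial)), by = key][nser >= 2, key]
  fitable <- dt[intensity > 0 & key %in% multi_keys]
  kvec <- stats::setNames(rep(1, length(scales$serial)), scales$serial)
  Bvec <- stats::setNames(rep(0, length(scales$serial)), scales$serial)
  ref <- as.character(min(serials))
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(100L)) {
    iters <- it
    fitable$fac <- kvec[as.character(fitable$serial)] *
      exp(-2 * Bvec[as.character(fitable$serial)] * fitable$s)
    fitable[, mean_i := mean(intensity * fac), by = key]
    # grouped closed-form OLS of y = ln(I_obs/<I>) on s: intercept -ln k, slope 2B
    fit <- fitable[mean_i > 0,
                   {
                     y <- log(intensity / mean_i)
                     if (.N >= 2 && stats::sd(s) > 0) {
                       b <- stats::cov(s, y) / stats::var(s)
                       a <- mean(y) - b * mean(s)
                     } else if (.N >= 1) {
                       a <- mean(y); b <- 0
                     } else {
                       a <- 0; b <- 0
                     }
                     .(lnk = -a, slope = b)
                   },
                   by = serial]
    k_new <- kvec; B_new <- Bvec
    k_new[as.character(fit$serial)] <- exp(fit$lnk)
    B_new[as.character(fit$serial)] <- fit$slope / 2
    # pin the reference dataset at identity
    B_new <- B_new - B_new[ref]
    k_new <- k_new / k_new[ref]
    delta <- max(abs(k_new - kvec) / pmax(abs(kvec), 1e-12),
                 abs(B_new - Bvec))
    kvec <- k_new; Bvec <- B_new
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  if (!converged) warning("scaling did not converge in 100 iterations; returning last iterate")
  scales$k <- unname(kvec[as.character(scales$serial)])
  scales$B <- unname(Bvec[as.character(scales$serial)])
  list(scales = scales, scaled = finish_scaled(dt, scales),
       iterations = iters, converged = converged)
}

finish_scaled <- function(dt, scales) {
  kvec <- stats::setNames(scales$k, scales$serial)
  Bvec <- stats::setNames(scales$B, scales$serial)
  fac <- kvec[as.character(dt$serial)] * exp(-2 * Bvec[as.character(dt$serial)] * dt$s)
  out <- data.table::copy(dt)
  out$intensity <- out$intensity * fac
  out$sigma <- out$sigma * fac
  out[]
}

#' Merge scaled observations into unique reflections
#'
#' Inverse-variance weighted mean per unique reflection; the merged sigma
#' is (sum 1/sigma^2)^(-1/2).
#'
#' @param scaled A scaled observation `data.table` from [scale_datasets()]
#'   (needs columns `key`, `h`, `k`, `l`, `s`, `intensity`, `sigma`).
#' @return `data.table` with one row per unique reflection: `key`, `h`,
#'   `k`, `l`, `s`, `intensity`, `sigma`, `n_obs`.
#' @export
merge_observations <- function(scaled) {
  stopifnot(nrow(scaled) > 0)
  out <- scaled[, {
    w <- 1 / sigma^2
    .(h = h[1], k = k[1], l = l[1], s = s[1],
      intensity = sum(w * intensity) / sum(w),
      sigma = 1 / sqrt(sum(w)), n_obs = .N)
  }, by = key]
  data.table::setorder(out, -s)
  out[]
}

# R-statistic sums over keys with n >= 2 observations; <I_h> is the plain
# mean, per the textbook definitions.
r_statistics <- function(scaled) {
  grp <- scaled[, .(n = .N, num = sum(abs(intensity - mean(intensity))),
                    den = sum(intensity)), by = key][n >= 2]
  if (!nrow(grp) || sum(grp$den) == 0) {
    return(c(r_merge = NA_real_, r_meas = NA_real_, r_pim = NA_real_))
  }
  den <- sum(grp$den)
  c(r_merge = sum(grp$num) / den,
    r_meas = sum(sqrt(grp$n / (grp$n - 1)) * grp$num) / den,
    r_pim = sum(sqrt(1 / (grp$n - 1)) * grp$num) / den)
}

# Seeded random half-split CC1/2: each multiply-observed reflection's
# observations are split into two halves, each half merged (unweighted
# mean), halves correlated across reflections.
cc_half_split <- function(scaled, seed) {
  grp <- scaled[, .(n = .N), by = key][n >= 2]
  if (nrow(grp) < 3) return(NA_real_)
  sub <- data.table::copy(scaled[key %in% grp$key])
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sub[, half := sample(rep(1:2, length.out = .N)), by = key]
  hm <- sub[, .(m = mean(intensity)), by = .(key, half)]
  wide <- data.table::dcast(hm, key ~ half, value.var = "m")
  wide <- wide[stats::complete.cases(wide)]
  if (nrow(wide) < 3) return(NA_real_)
  v1 <- wide[[2]]; v2 <- wide[[3]]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Merging quality statistics
#'
#' Computes the standard agreement and coverage statistics of a merged
#' group: R_merge, R_meas and R_pim over multiply-observed unique
#' reflections; completeness against a direct enumeration of the
#' theoretically measurable unique reflections of the given cell and
#' symmetry to `d_min`; multiplicity; CC1/2 by a seeded random half-split;
#' and Mean(I/sd) of the merged data. The same quantities are reported per
#' resolution shell, along with three resolution criteria: the finest
#' shell midpoint with CC1/2 > 0.3, the finest with Mean(I/sd) > 2, and
#' the applied limit `d_min` itself.
#'
#' @param scaled Scaled observations ([scale_datasets()]`$scaled`).
#' @param merged Merged table ([merge_observations()]).
#' @param cell Representative [unit_cell()] of the group (completeness
#'   denominator).
#' @param ops A [symmetry_ops()].
#' @param d_min Applied high-resolution limit in Angstrom.
#' @param n_shells Number of equal-count shells for per-shell statistics.
#' @param seed Seed for the CC1/2 half split.
#' @return Object of class `merge_stats`: list of overall scalars
#'   (`r_merge`, `r_meas`, `r_pim`, `completeness`, `multiplicity`,
#'   `cc_half`, `mn_i_sd`, `res_cc`, `res_mnisd`, `res_max`, `n_unique`,
#'   `n_obs`) plus `per_shell`, a `data.frame`.
#' @export
compute_stats <- function(scaled, merged, cell, ops, d_min, n_shells = 10,
                          seed = 42) {
  stopifnot(nrow(merged) > 0)
  rs <- r_statistics(scaled)
  n_theory <- count_unique_reflections(cell, ops, d_min)
  overall_cc <- cc_half_split(scaled, seed)
  shells <- assign_shells(merged$s, n_shells)  # shell 1 = lowest resolution
  n_shells_eff <- max(shells)
  merged_key_shell <- stats::setNames(shells, merged$key)
  scaled_shell <- merged_key_shell[scaled$key]
  # theoretical per-shell counts share the observed shell boundaries in s,
  # with the outer edges extended to 0 and 1/d_min^2
  smax_obs <- vapply(seq_len(n_shells_eff), function(i) max(merged$s[shells == i]), numeric(1))
  bounds <- c(0, utils::head(smax_obs, -1),
              max(1 / d_min^2, max(merged$s)) + 1e-12)
  uniq_all <- enumerate_unique_reflections(cell, ops, d_min)
  s_all <- resolution_s(uniq_all, cell)
  th_shell <- findInterval(s_all, bounds, rightmost.closed = TRUE,
                           left.open = TRUE)
  th_counts <- tabulate(pmin(pmax(th_shell, 1L), n_shells_eff), n_shells_eff)
  per_shell <- do.call(rbind, lapply(seq_len(n_shells_eff), function(i) {
    mk <- shells == i
    sk <- !is.na(scaled_shell) & scaled_shell == i
    sub <- scaled[sk]
    rsh <- r_statistics(sub)
    m <- merged[mk]
    data.frame(shell = i,
               d_mid = 1 / sqrt((min(m$s) + max(m$s)) / 2),
               n_unique = nrow(m), n_obs = nrow(sub),
               completeness = 100 * nrow(m) / max(th_counts[i], nrow(m)),
               multiplicity = nrow(sub) / nrow(m),
               r_merge = rsh[["r_merge"]], r_meas = rsh[["r_meas"]],
               r_pim = rsh[["r_pim"]],
               cc_half = cc_half_split(sub, seed + i),
               mn_i_sd = mean(m$intensity / m$sigma))
  }))
  finest_passing <- function(val, thr) {
    ok <- which(is.finite(val) & val > thr)
    if (length(ok)) per_shell$d_mid[max(ok)] else per_shell$d_mid[1]
  }
  structure(list(
    r_merge = unname(rs[["r_merge"]]), r_meas = unname(rs[["r_meas"]]),
    r_pim = unname(rs[["r_pim"]]),
    completeness = 100 * nrow(merged) / max(n_theory, nrow(merged)),
    multiplicity = nrow(scaled) / nrow(merged),
    cc_half = overall_cc,
    mn_i_sd = mean(merged$intensity / merged$sigma),
    res_cc = finest_passing(per_shell$cc_half, 0.3),
    res_mnisd = finest_passing(per_shell$mn_i_sd, 2),
    res_max = d_min,
    n_unique = nrow(merged), n_obs = nrow(scaled),
    per_shell = per_shell), class = "merge_stats")
}

#' @export
print.merge_stats <- function(x, ...) {
  cat(sprintf(paste0("merge stats: R_merge %.3f  R_meas %.3f  R_pim %.3f\n",
                     "  completeness %.2f %%  multiplicity %.2f  CC1/2 %.3f  Mn(I/sd) %.2f\n",
                     "  resolution: CC1/2 %.2f A  Mn(I/sd) %.2f A  max %.2f A  (%d unique / %d obs)\n"),
              x$r_merge, x$r_meas, x$r_pim, x$completeness, x$multiplicity,
              x$cc_half, x$mn_i_sd, x$res_cc, x$res_mnisd, x$res_max,
              x$n_unique, x$n_obs))
  invisible(x)
}

#' Scale, merge and score a group of datasets
#'
#' The single entry point composing the whole merge stage: tolerance check
#' on the cells, truncation of each dataset to its accepted image range and
#' the resolution limit, iterative scaling, inverse-variance merging and
#' quality statistics. Used by the synthesis, combination and pruning
#' modes.
#'
#' @param group List of [unmerged_dataset()]s.
#' @param ops A [symmetry_ops()]; defaults to the first dataset's
#'   space-group symbol.
#' @param keywords A [keyword_set()] (`tolerance`, `resolution_high`,
#'   `resolution_low`, `seed` honoured).
#' @param accepted_ranges Optional named list serial -> c(first, last)
#'   restricting each dataset's images (radiation-damage cutoffs).
#' @param label Free-form tag stored on the result (cluster node id or
#'   combination tag).
#' @param n_shells Shells for per-shell statistics.
#' @return Object of class `merge_result`: list with `label`, `members`,
#'   `cell` (average), `scales`, `scaled`, `merged`, `stats`, `d_min`.
#' @export
merge_group <- function(group, ops = NULL, keywords = keyword_set(),
                        accepted_ranges = NULL, label = "group",
                        n_shells = 10) {
  stopifnot(length(group) >= 1)
  if (is.null(ops)) ops <- symmetry_ops(group[[1]]$spacegroup)
  cells <- lapply(group, `[[`, "cell")
  if (length(group) >= 2) {
    ok <- check_tolerance(cells, keywords$tolerance)
    if (!isTRUE(ok)) {
      stop("cell tolerance check failed (TOLERANCE ", keywords$tolerance,
           "): ", attr(ok, "worst"))
    }
  }
  group <- lapply(group, function(ds) {
    rng <- accepted_ranges[[as.character(ds$serial)]]
    obs <- ds$observations
    if (!is.null(rng)) obs <- obs[obs$image >= rng[1] & obs$image <= rng[2], , drop = FALSE]
    s <- if (nrow(obs)) resolution_s(obs[, c("h", "k", "l")], ds$cell) else numeric(0)
    keep <- rep(TRUE, nrow(obs))
    if (!is.null(keywords$resolution_high) && !is.na(keywords$resolution_high)) {
      keep <- keep & s <= 1 / keywords$resolution_high^2 + 1e-12
    }
    if (!is.null(keywords$resolution_low) && !is.na(keywords$resolution_low)) {
      keep <- keep & s >= 1 / keywords$resolution_low^2 - 1e-12
    }
    ds$observations <- obs[keep, , drop = FALSE]
    ds
  })
  group <- group[vapply(group, function(d) nrow(d$observations) > 0, logical(1))]
  if (!length(group)) stop("no observations survive the image/resolution cuts")
  sc <- scale_datasets(group, ops, keywords)
  merged <- merge_observations(sc$scaled)
  avg_cell <- as_unit_cell(colMeans(t(vapply(group, function(d) as.numeric(d$cell), numeric(6)))))
  d_min <- if (!is.null(keywords$resolution_high) && !is.na(keywords$resolution_high)) {
    keywords$resolution_high
  } else 1 / sqrt(max(sc$scaled$s))
  stats <- compute_stats(sc$scaled, merged, avg_cell, ops, d_min,
                         n_shells = n_shells, seed = keywords$seed)
  structure(list(label = label,
                 members = sort(vapply(group, `[[`, integer(1), "serial")),
                 cell = avg_cell, scales = sc$scales, scaled = sc$scaled,
                 merged = merged, stats = stats, d_min = d_min,
                 converged = sc$converged),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf("merge result '%s': %d datasets (%s), %d unique reflections to %.2f A\n",
              x$label, length(x$members), paste(x$members, collapse = ","),
              nrow(x$merged), x$d_min))
  print(x$stats)
  invisible(x)
}
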