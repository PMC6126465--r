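#' Shell-averaged signal for resolution estimation
#'
#' Bins a dataset's observations into `n_shells` resolution shells of equal
#' population in s = 1/d^2 and returns the unweighted mean raw intensity,
#' mean sigma and their ratio per shell. Deliberately computed on all
#' images of the unscaled data — before any damage cutoff — so the estimate
#' reflects what was actually measured.
#'
#' @param ds An [unmerged_dataset()].
#' @param n_shells Requested number of shells (default 20); fewer are used
#'   when the dataset is small (at least 5 observations per shell are
#'   aimed for).
#' @return `data.frame` with columns `shell_index`, `s_mid` (1/A^2),
#'   `mean_intensity`, `mean_sigma`, `ratio`, `n_obs`, ordered by
#'   increasing `s_mid`.
#' @export
shell_signal <- function(ds, n_shells = 20) {
  obs <- ds$observations
  if (!nrow(obs)) stop("dataset has no observations")
  n_shells <- max(1L, min(as.integer(n_shells), nrow(obs) %/% 5L, nrow(obs)))
  s <- resolution_s(obs[, c("h", "k", "l")], ds$cell)
  shell <- assign_shells(s, n_shells)
  out <- do.call(rbind, lapply(sort(unique(shell)), function(sh) {
    in_sh <- shell == sh
    data.frame(shell_index = sh,
               s_mid = (min(s[in_sh]) + max(s[in_sh])) / 2,
               mean_intensity = mean(obs$intensity[in_sh]),
               mean_sigma = mean(obs$sigma[in_sh]),
               n_obs = sum(in_sh))
  }))
  out$ratio <- out$mean_intensity / out$mean_sigma
  out[order(out$s_mid), c("shell_index", "s_mid", "mean_intensity",
                          "mean_sigma", "ratio", "n_obs")]
}

#' Estimate the usable high-resolution limit from shell signal
#'
#' A polynomial of degree min(10, n_shells - 1) is fitted by least squares
#' to the shell-wise mean(I)/mean(sigma) ratio as a function of s = 1/d^2
#' (an exact interpolant when the degree allows). The polynomial is
#' evaluated on a 1000-point grid spanning the observed s range and the
#' first grid point (scanning from low to high resolution) at which it
#' falls below `isigi` is converted to d = 1/sqrt(s) and returned. If the
#' curve never drops below the threshold the dataset's own maximum
#' resolution is returned; if even the first shell is below it, the
#' lowest-resolution grid point is returned and a note is attached.
#'
#' @param signal A [shell_signal()] table (>= 2 shells).
#' @param isigi Signal threshold (default 1.5, a deliberately conservative
#'   value).
#' @param d_max_data The dataset's own maximum resolution in Angstrom
#'   (smallest d of any observation).
#' @return Resolution in Angstrom. Attribute `"note"` is set to
#'   `"all data below threshold"` in the degenerate low-signal case.
#' @export
estimate_resolution <- function(signal, isigi = 1.5, d_max_data) {
  stopifnot(nrow(signal) >= 2, isigi > 0, d_max_data > 0)
  degree <- min(10L, nrow(signal) - 1L)
  fit <- stats::lm(ratio ~ stats::poly(s_mid, degree, raw = FALSE),
                   data = signal)
  grid <- seq(min(signal$s_mid), max(signal$s_mid), length.out = 1000)
  yhat <- stats::predict(fit, newdata = data.frame(s_mid = grid))
  below <- which(yhat < isigi)
  if (!length(below)) return(d_max_data)
  d <- 1 / sqrt(grid[below[1]])
  if (below[1] == 1L) attr(d, "note") <- "all data below threshold"
  d
}

#' Full analysis pass: damage cutoffs and resolution estimates
#'
#' Composes the radiation-damage assessment and the resolution estimate for
#' every dataset into the six-column final list (path, serial, last
#' accepted image, first image, last image, suggested resolution). Datasets
#' with no suggested cutoff carry their last image in the cutoff column.
#'
#' @param datasets List of [unmerged_dataset()]s with serials assigned.
#' @param keywords A [keyword_set()]; `radfrac` and `isigi` are honoured.
#' @param n_shells_damage,n_shells_signal Shell counts for the two
#'   procedures.
#' @return `data.frame` of final-list entries (see [write_final_list()]),
#'   with an extra logical column `damaged`.
#' @export
analysis_pass <- function(datasets, keywords = keyword_set(),
                          n_shells_damage = 10, n_shells_signal = 20) {
  stopifnot(length(datasets) >= 1)
  rows <- lapply(datasets, function(ds) {
    dmg <- assess_dataset_damage(ds, n_shells = n_shells_damage,
                                 radfrac = keywords$radfrac)
    sig <- shell_signal(ds, n_shells = n_shells_signal)
    s <- resolution_s(ds$observations[, c("h", "k", "l")], ds$cell)
    d_max <- 1 / sqrt(max(s))
    res <- if (nrow(sig) >= 2) {
      estimate_resolution(sig, isigi = keywords$isigi, d_max_data = d_max)
    } else d_max
    data.frame(path = ds$source_path, serial = ds$serial,
               cutoff_image = if (is.na(dmg$cutoff_image)) NA_integer_ else dmg$cutoff_image,
               first_image = ds$first_image, last_image = ds$last_image,
               suggested_resolution = round(as.numeric(res), 3),
               damaged = dmg$damaged)
  })
  out <- do.call(rbind, rows)
  out[order(out$serial), , drop = FALSE]
}
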