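# Equal-count binning in s = 1/d^2. Returns an integer shell index per
# observation (1 = lowest resolution); shell populations differ by <= 1.
assign_shells <- function(s, n_shells) {
  n <- length(s)
  n_shells <- max(1L, min(as.integer(n_shells), n))
  idx <- integer(n)
  ord <- order(s)
  idx[ord] <- ceiling(seq_len(n) * n_shells / n)
  idx
}

#' Fit per-shell intensity decay against image number
#'
#' Radiation damage shows up as a loss of diffracted intensity with
#' accumulated dose, i.e. with image number, and the loss is faster at high
#' resolution. Observations are binned into `n_shells` resolution shells of
#' equal population in s = 1/d^2; within each shell the mean positive
#' intensity per image is computed and ln(mean I) is regressed on image
#' number by ordinary least squares, modelling I as a single exponential
#' exp(amplitude - decay * image). Images contributing no positive
#' intensity to a shell are skipped, and shells with fewer than 3 usable
#' images are dropped.
#'
#' @param ds An [unmerged_dataset()].
#' @param n_shells Number of resolution shells (default 10).
#' @return `data.frame` with one row per usable shell: `shell_index`,
#'   `s_mid` (1/A^2, midpoint of the shell's s range), `amplitude`, `decay`
#'   (per image; positive = fading), `decay_se`, `n_obs`, `n_images`.
#'   Zero rows when nothing is usable.
#' @export
fit_shell_decay <- function(ds, n_shells = 10) {
  obs <- ds$observations
  empty <- data.frame(shell_index = integer(), s_mid = numeric(),
                      amplitude = numeric(), decay = numeric(),
                      decay_se = numeric(), n_obs = integer(), n_images = integer())
  if (nrow(obs) < 2 || length(unique(obs$image)) < 2) return(empty)
  s <- resolution_s(obs[, c("h", "k", "l")], ds$cell)
  shell <- assign_shells(s, n_shells)
  out <- lapply(sort(unique(shell)), function(sh) {
    in_sh <- shell == sh
    pos <- in_sh & obs$intensity > 0
    if (!any(pos)) return(NULL)
    mI <- tapply(obs$intensity[pos], obs$image[pos], mean)
    img <- as.numeric(names(mI))
    if (length(img) < 3) return(NULL)
    y <- log(as.numeric(mI))
    fit <- stats::lm(y ~ img)
    se <- tryCatch(
      suppressWarnings(summary(fit))$coefficients["img", "Std. Error"],
      error = function(e) NA_real_)
    data.frame(shell_index = sh,
               s_mid = (min(s[in_sh]) + max(s[in_sh])) / 2,
               amplitude = unname(stats::coef(fit)[1]),
               decay = -unname(stats::coef(fit)[2]),
               decay_se = se,
               n_obs = sum(pos), n_images = length(img))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out[order(out$s_mid), , drop = FALSE]
}

#' Decide whether a dataset is radiation damaged
#'
#' A dataset is flagged as damaged when its per-shell decay rate increases
#' significantly with resolution: the shell decays are regressed on s_mid
#' by weighted least squares (weights 1/se^2 from the shell fits, equal
#' weights when standard errors are unavailable) and a one-sided t-test
#' asks whether the slope is positive at level `alpha`. At least 3 fitted
#' shells are required; with fewer the dataset is reported undamaged.
#'
#' @param fits Output of [fit_shell_decay()].
#' @param alpha One-sided significance level (default 0.05).
#' @param serial Dataset serial carried through to the report.
#' @return An object of class `damage_assessment`: list with `serial`,
#'   `fits`, `damaged`, `trend_slope`, `trend_pvalue`, `cutoff_image`
#'   (filled by [suggest_cutoff()], `NA` here).
#' @export
assess_damage <- function(fits, alpha = 0.05, serial = NA_integer_) {
  res <- list(serial = serial, fits = fits, damaged = FALSE,
              trend_slope = NA_real_, trend_pvalue = NA_real_,
              cutoff_image = NA_integer_)
  class(res) <- "damage_assessment"
  if (is.null(fits) || nrow(fits) < 3) return(res)
  w <- 1 / fits$decay_se^2
  if (any(!is.finite(w))) w <- rep(1, nrow(fits))
  fit <- stats::lm(decay ~ s_mid, data = fits, weights = w)
  sm <- suppressWarnings(summary(fit))$coefficients
  if (!"s_mid" %in% rownames(sm)) return(res)
  tval <- sm["s_mid", "t value"]
  p <- stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
  res$trend_slope <- unname(stats::coef(fit)["s_mid"])
  res$trend_pvalue <- p
  res$damaged <- is.finite(p) && res$trend_slope > 0 && p < alpha
  res
}

#' @export
print.damage_assessment <- function(x, ...) {
  cat(sprintf("damage assessment (serial %s): %s", ifelse(is.na(x$serial), "-", x$serial),
              if (x$damaged) "DAMAGED" else "no significant damage"))
  if (!is.na(x$trend_pvalue)) {
    cat(sprintf(" [decay-vs-s slope %.4g, one-sided p %.3g]", x$trend_slope, x$trend_pvalue))
  }
  if (!is.na(x$cutoff_image)) cat(sprintf("; suggested cutoff image %d", x$cutoff_image))
  cat("\n")
  invisible(x)
}

#' Suggest a last accepted image for a damaged dataset
#'
#' Using the decay rate B of the highest-resolution usable shell — where
#' damage bites first — the suggested last accepted image is the one at
#' which the modelled intensity has dropped to a predefined fraction
#' `radfrac` of its initial value: first_image - 1 + floor(ln(1/radfrac)/B),
#' clamped to the dataset's image range. Returns `NA` (no cutoff) when the
#' assessment is not damaged or B <= 0.
#'
#' @param assessment An [assess_damage()] result.
#' @param ds The assessed [unmerged_dataset()].
#' @param radfrac Retained-intensity fraction in (0, 1] (default 0.75).
#' @return Integer image number or `NA`.
#' @export
suggest_cutoff <- function(assessment, ds, radfrac = 0.75) {
  stopifnot(radfrac > 0, radfrac <= 1)
  if (!isTRUE(assessment$damaged)) return(NA_integer_)
  fits <- assessment$fits
  B <- fits$decay[which.max(fits$s_mid)]
  if (!is.finite(B) || B <= 0) return(NA_integer_)
  cut <- ds$first_image - 1L + as.integer(floor(log(1 / radfrac) / B))
  max(ds$first_image, min(ds$last_image, cut))
}

#' One-call damage assessment for a dataset
#'
#' Convenience wrapper running [fit_shell_decay()], [assess_damage()] and
#' [suggest_cutoff()] in sequence. Wedges of fewer than `min_images` images
#' are not assessed (reported undamaged): the decay model needs a minimal
#' dose range to be meaningful.
#'
#' @inheritParams fit_shell_decay
#' @inheritParams suggest_cutoff
#' @param alpha Trend-test significance level.
#' @param min_images Minimum sweep length for the procedure to apply.
#' @return A `damage_assessment` with `cutoff_image` populated.
#' @export
assess_dataset_damage <- function(ds, n_shells = 10, alpha = 0.05,
                                  radfrac = 0.75, min_images = 5) {
  n_img <- ds$last_image - ds$first_image + 1L
  if (n_img < min_images) {
    return(assess_damage(fit_shell_decay(ds, n_shells)[0, ], alpha, ds$serial))
  }
  a <- assess_damage(fit_shell_decay(ds, n_shells), alpha, ds$serial)
  a$cutoff_image <- suggest_cutoff(a, ds, radfrac)
  a
}
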