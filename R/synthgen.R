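#' Configuration for the synthetic multi-crystal generator
#'
#' Describes a simulated multi-crystal experiment: groups of crystals whose
#' cells differ by `group_shift` between groups and jitter by `cell_jitter`
#' within a group; contiguous rotation wedges of `wedge_images` images with
#' `obs_per_image` observations each; per-dataset true scales (k, B); a
#' radiation-damage model in which the per-image attenuation is
#' exp(-2 * damage_B * (image - first) * s) — a B-factor growing linearly
#' with dose, so the apparent decay rate in a resolution shell is
#' 2 * damage_B * s_mid, fastest at high resolution; counting-type noise
#' with sigma = sqrt((noise_frac * I)^2 + background_sigma^2); optional
#' cell-parameter outliers; and optional "rogue" datasets whose images
#' carry a log-normal per-image scale jitter that no smooth scale model can
#' absorb.
#'
#' @param base_cell Reference [unit_cell()].
#' @param spacegroup Space-group symbol (see [symmetry_ops()]).
#' @param d_min Simulation resolution limit in Angstrom.
#' @param n_groups Number of isomorphism groups.
#' @param n_per_group Datasets per group (recycled to `n_groups`).
#' @param group_shift Added to edge a per group step, Angstrom.
#' @param cell_jitter Gaussian sd of within-group edge jitter, Angstrom.
#' @param wedge_images Images per dataset (single integer or range
#'   `c(lo, hi)` sampled per dataset).
#' @param obs_per_image Observations recorded per image.
#' @param k_range,scale_B_range Ranges for true per-dataset scale factors k
#'   and B-factors (Angstrom^2).
#' @param damage_B Per-image B-factor growth (Angstrom^2/image): single
#'   value, range `c(lo, hi)`, or a vector of one value per dataset
#'   (0 = undamaged).
#' @param noise_frac Fractional intensity noise (e.g. 0.05).
#' @param background_sigma Additive noise floor in intensity units.
#' @param n_outliers Number of trailing datasets with grossly shifted cells.
#' @param outlier_shift Edge shift applied to outlier cells, Angstrom.
#' @param rogue_ids Dataset indices (1-based, in generation order) planted
#'   as rogues.
#' @param rogue_scale_error sdlog of the rogue per-image scale jitter.
#' @param mean_intensity Wilson-scale mean intensity at s = 0.
#' @param b_wilson Wilson B controlling the falloff of true intensities
#'   (Angstrom^2).
#' @param seed Integer; fixes the entire simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(base_cell = unit_cell(40, 50, 60, 90, 90, 90),
                       spacegroup = "P222", d_min = 3,
                       n_groups = 2, n_per_group = 5,
                       group_shift = 2, cell_jitter = 0.05,
                       wedge_images = 30, obs_per_image = 40,
                       k_range = c(0.5, 2), scale_B_range = c(0, 10),
                       damage_B = 0, noise_frac = 0.05,
                       background_sigma = 5,
                       n_outliers = 0, outlier_shift = 20,
                       rogue_ids = integer(0), rogue_scale_error = 0.8,
                       mean_intensity = 5000, b_wilson = 20, seed = 1) {
  cfg <- list(base_cell = as_unit_cell(base_cell), spacegroup = spacegroup,
              d_min = d_min, n_groups = as.integer(n_groups),
              n_per_group = as.integer(n_per_group),
              group_shift = group_shift, cell_jitter = cell_jitter,
              wedge_images = as.integer(wedge_images),
              obs_per_image = as.integer(obs_per_image),
              k_range = k_range, scale_B_range = scale_B_range,
              damage_B = damage_B, noise_frac = noise_frac,
              background_sigma = background_sigma,
              n_outliers = as.integer(n_outliers),
              outlier_shift = outlier_shift,
              rogue_ids = as.integer(rogue_ids),
              rogue_scale_error = rogue_scale_error,
              mean_intensity = mean_intensity, b_wilson = b_wilson,
              seed = as.integer(seed))
  stopifnot(cfg$d_min > 0, cfg$n_groups >= 1, all(cfg$n_per_group >= 0),
            cfg$noise_frac >= 0, cfg$background_sigma >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Ground-truth unique intensities for a simulation
#'
#' Enumerates the unique reflections of the configured cell and symmetry
#' to `d_min` and draws each true intensity from an exponential (acentric
#' Wilson) distribution whose mean falls off as
#' `mean_intensity * exp(-2 * b_wilson * s)`.
#'
#' @param config A [sim_config()].
#' @return `data.table` with columns `h`, `k`, `l`, `key`, `s`,
#'   `intensity_true`, reproducible for a fixed `config$seed`.
#' @export
ground_truth <- function(config) {
  ops <- symmetry_ops(config$spacegroup)
  uniq <- enumerate_unique_reflections(config$base_cell, ops, config$d_min)
  s <- resolution_s(uniq, config$base_cell)
  ord <- order(s)
  uniq <- uniq[ord, , drop = FALSE]; s <- s[ord]
  set.seed(config$seed)
  mean_i <- config$mean_intensity * exp(-2 * config$b_wilson * s)
  out <- data.table::data.table(h = uniq[, 1], k = uniq[, 2], l = uniq[, 3],
                                s = s,
                                intensity_true = stats::rexp(length(s), rate = 1 / mean_i))
  out$key <- paste(out$h, out$k, out$l)
  out
}

# Per-dataset deterministic parameter table derived from the config seed.
sim_plan <- function(config) {
  n_per <- rep_len(config$n_per_group, config$n_groups)
  n_iso <- sum(n_per)
  n_total <- n_iso + config$n_outliers
  set.seed(config$seed + 1L)
  grp <- c(rep(seq_len(config$n_groups), n_per), rep(NA_integer_, config$n_outliers))
  wi <- if (length(config$wedge_images) == 2) {
    sample(config$wedge_images[1]:config$wedge_images[2], n_total, replace = TRUE)
  } else rep(config$wedge_images, n_total)
  dmg <- config$damage_B
  dmgv <- if (length(dmg) == n_total) dmg
          else if (length(dmg) == 2) stats::runif(n_total, dmg[1], dmg[2])
          else rep_len(dmg, n_total)
  data.frame(index = seq_len(n_total), group = grp,
             wedge_images = wi,
             k_true = stats::runif(n_total, config$k_range[1], config$k_range[2]),
             B_true = stats::runif(n_total, config$scale_B_range[1], config$scale_B_range[2]),
             damage_B = dmgv,
             rogue = seq_len(n_total) %in% config$rogue_ids,
             outlier = is.na(grp))
}

#' Simulate one unmerged dataset
#'
#' Builds dataset `index` of the experiment described by `config`: the cell
#' is the base cell plus its group's shift plus jitter (outliers get
#' `outlier_shift` added to every edge); a shuffled walk through the unique
#' reflection list assigns `obs_per_image` observations to each image
#' (recycling when the wedge samples more observations than unique
#' reflections exist, which yields within-dataset multiplicity); each
#' observation's index is a random symmetry mate of its unique key; and
#' intensities follow
#' `k * exp(-2*B*s) * exp(-2*damage_B*(image-1)*s) * I_true + noise`.
#'
#' @param config A [sim_config()].
#' @param index Dataset number, 1-based, in generation order (groups first,
#'   then outliers).
#' @param truth Optional precomputed [ground_truth()] table (recomputed
#'   when omitted).
#' @return An [unmerged_dataset()] with `serial = index`; the true
#'   parameters are attached as attribute `"truth"`.
#' @export
simulate_dataset <- function(config, index, truth = NULL) {
  if (is.null(truth)) truth <- ground_truth(config)
  plan <- sim_plan(config)
  stopifnot(index >= 1, index <= nrow(plan))
  p <- plan[index, ]
  ops <- symmetry_ops(config$spacegroup)
  set.seed(config$seed * 1000L + index)
  cellv <- as.numeric(config$base_cell)
  if (p$outlier) {
    cellv[1:3] <- cellv[1:3] + config$outlier_shift
  } else {
    # groups differ by an overall cell-size offset on all three edges
    cellv[1:3] <- cellv[1:3] + (p$group - 1) * config$group_shift
  }
  cellv[1:3] <- cellv[1:3] + stats::rnorm(3, 0, config$cell_jitter)
  cell <- as_unit_cell(cellv)
  n_img <- p$wedge_images
  n_obs <- n_img * config$obs_per_image
  walk <- sample(nrow(truth))
  pick <- walk[((seq_len(n_obs) - 1L) %% nrow(truth)) + 1L]
  image <- rep(seq_len(n_img), each = config$obs_per_image)
  tru <- truth[pick]
  # random symmetry mate (and Friedel sign) for the recorded index
  nrot <- length(ops$rotations)
  op_i <- sample(nrot, n_obs, replace = TRUE)
  Hm <- matrix(0, n_obs, 3)
  Huniq <- as.matrix(tru[, c("h", "k", "l")])
  for (oi in seq_len(nrot)) {
    rows <- op_i == oi
    if (any(rows)) Hm[rows, ] <- Huniq[rows, , drop = FALSE] %*% ops$rotations[[oi]]
  }
  if (ops$friedel) {
    neg <- sample(c(1, -1), n_obs, replace = TRUE)
    Hm <- Hm * neg
  }
  # the crystal diffracts according to its own (shifted/jittered) lattice
  s <- resolution_s(Huniq, cell)
  clean <- p$k_true * exp(-2 * p$B_true * s) *
    exp(-2 * p$damage_B * (image - 1) * s) * tru$intensity_true
  if (p$rogue) {
    img_fac <- exp(stats::rnorm(n_img, 0, config$rogue_scale_error))
    clean <- clean * img_fac[image]
  }
  sig <- sqrt((config$noise_frac * clean)^2 + config$background_sigma^2)
  noisy <- if (config$noise_frac > 0 || config$background_sigma > 0) {
    clean + stats::rnorm(n_obs, 0, sig)
  } else clean
  sig <- pmax(sig, 1e-6)
  obs <- data.frame(h = Hm[, 1], k = Hm[, 2], l = Hm[, 3],
                    intensity = noisy, sigma = sig, image = image)
  ds <- unmerged_dataset(sprintf("sim_%03d", index), cell, config$spacegroup,
                         obs, 1L, n_img, serial = index)
  attr(ds, "truth") <- p
  ds
}

#' Write a named synthetic scenario to disk
#'
#' Generates a full multi-crystal experiment in canonical-format files plus
#' a JSON manifest of every ground-truth parameter (for recovery tests).
#' Available scenarios:
#' \describe{
#'   \item{teha_like}{63 isomorphous short wedges (20-40 images) in two
#'     tight sub-groups, most with radiation damage, plus 4 gross
#'     cell-parameter outliers: 67 files.}
#'   \item{h1r_like}{18 long-sweep datasets in 3 loose groups, some
#'     damaged.}
#'   \item{two_group}{2 groups of 5 noiseless wedges, group shift 2 A,
#'     jitter 0.05 A: the clustering/scale-recovery bed.}
#'   \item{rogue}{6 isomorphous datasets, one planted rogue with per-image
#'     scale jitter.}
#'   \item{damaged}{5 full-coverage datasets, one with a heavily damaged
#'     image tail: the pruning bed.}
#' }
#'
#' @param name Scenario name.
#' @param dir Output directory (created if needed).
#' @param seed Simulation seed.
#' @param overrides Named list of [sim_config()] arguments to override.
#' @return The scenario config (invisibly); files written to `dir`, the
#'   manifest as `manifest.json`.
#' @export
make_scenario <- function(name = c("teha_like", "h1r_like", "two_group",
                                   "rogue", "damaged"),
                          dir, seed = 1, overrides = list()) {
  name <- match.arg(name)
  config <- scenario_config(name, seed, overrides)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- ground_truth(config)
  plan <- sim_plan(config)
  paths <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ds <- simulate_dataset(config, i, truth)
    paths[i] <- file.path(dir, sprintf("sim_%03d.refl", i))
    write_dataset(ds, paths[i])
  }
  manifest <- list(scenario = name, seed = seed,
                   config = config_to_list(config),
                   datasets = plan, files = basename(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config)
}

#' @rdname make_scenario
#' @export
scenario_config <- function(name = c("teha_like", "h1r_like", "two_group",
                                     "rogue", "damaged"),
                            seed = 1, overrides = list()) {
  name <- match.arg(name)
  args <- switch(name,
    teha_like = list(n_groups = 2, n_per_group = c(31, 32),
                     group_shift = 0.45, cell_jitter = 0.08,
                     wedge_images = c(20, 40), obs_per_image = 40,
                     damage_B = c(0, 0.8), noise_frac = 0.05,
                     n_outliers = 4, outlier_shift = 25, d_min = 3),
    h1r_like = list(base_cell = unit_cell(45, 55, 65, 90, 97, 90),
                    spacegroup = "P21", n_groups = 3, n_per_group = 6,
                    group_shift = 1.5, cell_jitter = 0.1,
                    wedge_images = 60, obs_per_image = 40,
                    damage_B = c(0, 0.5), noise_frac = 0.08, d_min = 3),
    two_group = list(n_groups = 2, n_per_group = 5, group_shift = 2,
                     cell_jitter = 0.05, wedge_images = 10,
                     obs_per_image = 40, damage_B = 0, noise_frac = 0,
                     background_sigma = 0, d_min = 3.5),
    rogue = list(n_groups = 1, n_per_group = 6, group_shift = 0,
                 cell_jitter = 0.05, wedge_images = 20, obs_per_image = 60,
                 damage_B = 0, noise_frac = 0.05, rogue_ids = 3L,
                 d_min = 3.5),
    damaged = list(n_groups = 1, n_per_group = 5, group_shift = 0,
                   cell_jitter = 0.05, wedge_images = 60,
                   obs_per_image = 30, damage_B = c(0, 0, 0, 0, 1.2),
                   k_range = c(0.8, 1.25), scale_B_range = c(0, 3),
                   noise_frac = 0.05, d_min = 3.5))
  args[names(overrides)] <- overrides
  args$seed <- seed
  do.call(sim_config, args)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$base_cell <- as.numeric(out$base_cell)
  out
}

#' Read a scenario manifest
#'
#' @param dir Scenario directory written by [make_scenario()].
#' @return List with `scenario`, `seed`, `config`, `datasets` (ground-truth
#'   parameter table) and `files`.
#' @export
read_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}
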