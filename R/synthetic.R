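# Synthetic DOM study generator: formula libraries obeying the elemental
# bounds, gradient-structured datasets with known ground truth (universal
# core, class depletion, mass-biased removal), and jittered duplicate peak
# lists, so every pipeline stage is testable without field data.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is exercised under:
#' 4 catchments, 4 hillslope positions x 4 soil depths plus one stream
#' sample each (68 samples); a 3000-formula library with a 400-formula
#' universal core dominated by lignin-like compounds; gradient-dependent
#' depletion of plant-derived classes (tannin-, condensed-aromatic-like)
#' and mass-biased depletion of carbohydrate- and
#' unsaturated-hydrocarbon-like compounds (low-mass members preferentially
#' removed, so their intensity-weighted mass rises along the cascade); a
#' universal intensity share rising 10 percentage points from either
#' gradient's first to last level; lognormal intensities; and 0.05 ppm
#' mass jitter for peak-list emulation.
#'
#' The degradation gradient is encoded as a single ordinal cascade stage
#' applied to both the depth and the hillslope factor (stream samples sit
#' at the end of both); effects are additive across the two axes.
#'
#' @param n_catchments,positions,depths,include_stream Sampling design.
#' @param library_size,universal_core_size Formula library and core sizes.
#' @param class_mixture Named per-class target shares of the library
#'   (sums to 1).
#' @param core_mixture Named per-class target shares of the universal core.
#' @param gradient_effects Named per-class fraction of non-core members
#'   removed at the gradient extreme.
#' @param mass_bias Exponent of the power-law mass preference
#'   `(1 - z)^mass_bias` (z = scaled mass within the class) in the removal
#'   probability of the mass-shift classes (carbohydrate-like,
#'   unsaturated-hydrocarbon-like); 0 disables the mass shift.
#' @param universal_intensity_base Universal intensity share at the
#'   gradient origin (fraction).
#' @param universal_intensity_slope_pp Increase of the universal intensity
#'   share, in percentage points, from first to last level of each gradient
#'   axis.
#' @param share_noise_sd Logit-scale noise on the per-sample universal
#'   share.
#' @param intensity_lognormal Meanlog and sdlog of compound intensities.
#' @param detection_prob Detection probability of a surviving non-core
#'   compound in a sample.
#' @param ppm_jitter_sd Gaussian m/z jitter per replicate (ppm).
#' @param intensity_rep_sd Lognormal sdlog of per-replicate intensity
#'   variation (0 = identical intensities in both replicates).
#' @param noise_peak_rate Spurious sub-detection-limit peaks added per real
#'   peak.
#' @param seed Master seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    n_catchments = 4,
    positions = c("shoulder", "back", "foot", "toe"),
    depths = c(5, 15, 30, 60),
    include_stream = TRUE,
    library_size = 3000,
    universal_core_size = 400,
    class_mixture = c("lignin-like" = 0.45, "tannin-like" = 0.12,
                      "condensed-aromatic-like" = 0.08,
                      "carbohydrate-like" = 0.08,
                      "unsaturated-hydrocarbon-like" = 0.07,
                      "protein-like" = 0.08, "lipid-like" = 0.07,
                      "amino-sugar-like" = 0.03, "other" = 0.02),
    core_mixture = c("lignin-like" = 0.79, "tannin-like" = 0.05,
                     "condensed-aromatic-like" = 0.02,
                     "carbohydrate-like" = 0.03,
                     "unsaturated-hydrocarbon-like" = 0.02,
                     "protein-like" = 0.03, "lipid-like" = 0.03,
                     "amino-sugar-like" = 0.02, "other" = 0.01),
    gradient_effects = c("tannin-like" = 0.5,
                         "condensed-aromatic-like" = 0.5,
                         "carbohydrate-like" = 1.0,
                         "unsaturated-hydrocarbon-like" = 1.0),
    mass_bias = 0.3,
    universal_intensity_base = 0.50,
    universal_intensity_slope_pp = 10,
    share_noise_sd = 0.05,
    intensity_lognormal = c(meanlog = 0, sdlog = 1),
    detection_prob = 0.75,
    ppm_jitter_sd = 0.05,
    intensity_rep_sd = 0.05,
    noise_peak_rate = 0.1,
    seed = 1) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-8,
            abs(sum(core_mixture) - 1) < 1e-8,
            all(gradient_effects >= 0 & gradient_effects <= 1),
            library_size > universal_core_size,
            detection_prob > 0, detection_prob <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# Van-Krevelen target boxes the per-class samplers draw from; rejection
# sampling against classify() guarantees the label.
.class_boxes <- list(
  "lignin-like" = list(hc = c(0.8, 1.4), oc = c(0.15, 0.60), n_max = 1),
  "tannin-like" = list(hc = c(0.6, 1.3), oc = c(0.70, 0.95), n_max = 1),
  "condensed-aromatic-like" = list(hc = c(0.30, 0.65), oc = c(0.02, 0.25), n_max = 1),
  "carbohydrate-like" = list(hc = c(1.55, 2.0), oc = c(0.70, 1.0), n_max = 0),
  "amino-sugar-like" = list(hc = c(1.55, 1.9), oc = c(0.57, 0.66), n_min = 1, n_max = 2),
  "protein-like" = list(hc = c(1.55, 1.9), oc = c(0.32, 0.54), n_min = 1, n_max = 3),
  "lipid-like" = list(hc = c(1.55, 2.1), oc = c(0.02, 0.28), n_max = 0),
  "unsaturated-hydrocarbon-like" = list(hc = c(0.75, 1.45), oc = c(0.0, 0.09), n_max = 0),
  "other" = list(hc = c(1.6, 2.0), oc = c(0.35, 0.50), n_max = 0)
)

#' Generate a synthetic formula library
#'
#' Rejection-samples molecular formulas inside the elemental bounds
#' (C 0-100, H 2-200, O 0-70, N 0-3, S 0-2, P 0-2), the 150-1000 Da
#' window and the chemical filters until the per-class target shares are
#' met exactly (rounded counts), verifying every label with [classify()].
#'
#' @param config A [simulation_config()].
#' @param class_table Boundary table used for verification.
#' @return Annotation data frame as from [annotate_formulas()], one row per
#'   unique formula; `library_size` rows.
#' @export
generate_library <- function(config = simulation_config(),
                             class_table = default_class_table()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(config$seed %% 2147483647))
  counts <- round(config$library_size * config$class_mixture)
  counts[1] <- counts[1] + config$library_size - sum(counts)
  seen <- new.env(parent = emptyenv())
  rows <- vector("list", sum(counts))
  ri <- 0L
  for (cls in names(counts)) {
    box <- .class_boxes[[cls]]
    if (is.null(box)) stop("no sampler for class ", cls, call. = FALSE)
    need <- counts[[cls]]
    got <- 0L
    attempts <- 0L
    max_attempts <- 400L * need + 2000L
    while (got < need) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("unreachable class mixture: could not sample enough ", cls,
             " formulas within bounds", call. = FALSE)
      }
      c_ <- sample(8:45, 1)
      hc <- stats::runif(1, box$hc[1], box$hc[2])
      oc <- stats::runif(1, box$oc[1], box$oc[2])
      n_min <- if (is.null(box$n_min)) 0L else box$n_min
      n_ <- if (box$n_max > n_min || n_min > 0)
        sample(n_min:box$n_max, 1) else 0L
      s_ <- if (stats::runif(1) < 0.08) 1L else 0L
      p_ <- if (stats::runif(1) < 0.04) 1L else 0L
      h_ <- as.integer(round(hc * c_))
      if ((h_ + n_ + p_) %% 2L == 1L) h_ <- h_ + sample(c(-1L, 1L), 1)
      o_ <- as.integer(round(oc * c_))
      if (h_ < 2L || h_ > 200L || o_ > 70L || c_ > 100L) next
      f <- data.frame(c = c_, h = h_, n = n_, o = o_, s = s_, p = p_)
      if (!passes_chemical_filters(f)) next
      mass <- exact_neutral_mass(f)
      if (mass < 150 + PROTON_MASS || mass > 1000 + PROTON_MASS) next
      key <- format_formula(f)
      if (!is.null(seen[[key]])) next
      d <- descriptors(f)
      if (classify(d, class_table) != cls) next
      seen[[key]] <- TRUE
      ri <- ri + 1L
      rows[[ri]] <- f
      got <- got + 1L
    }
  }
  lib <- do.call(rbind, rows[seq_len(ri)])
  ann <- annotate_formulas(lib, table = class_table)
  ann[order(ann$formula), ]
}

# Sampling design table for one synthetic study.
.design_table <- function(config) {
  md <- list()
  for (k in seq_len(config$n_catchments)) {
    cat_id <- paste0("C", k)
    for (pi in seq_along(config$positions)) {
      for (di in seq_along(config$depths)) {
        md[[length(md) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s_%dcm", cat_id, config$positions[pi],
                              config$depths[di]),
          catchment = cat_id, position = config$positions[pi],
          depth_cm = config$depths[di], sample_type = "soil",
          g_depth = (di - 1) / (length(config$depths) - 1),
          g_pos = (pi - 1) / (length(config$positions) - 1),
          stringsAsFactors = FALSE)
      }
    }
    if (config$include_stream) {
      md[[length(md) + 1]] <- data.frame(
        sample_id = paste0(cat_id, "_stream"), catchment = cat_id,
        position = "stream", depth_cm = NA_real_, sample_type = "stream",
        g_depth = 1, g_pos = 1, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, md)
}

#' Simulate a gradient-structured DOM dataset with known ground truth
#'
#' The universal core is present in every sample. Non-core members of the
#' depleted classes are removed with probability rising along the cascade
#' gradient; within the mass-shift classes the removal probability decays
#' exponentially with scaled mass (low-mass members lost first). Intensities
#' are lognormal, with core intensities rescaled so the universal intensity
#' share follows the configured base + slope trajectory (additive over the
#' depth and hillslope axes) plus logit-scale noise, then normalised per
#' sample.
#'
#' @param config A [simulation_config()].
#' @param library Optional pre-generated library (as from
#'   [generate_library()]) to reuse across replicate simulations.
#' @return List with `dataset` (a `dom_dataset`), `truth` (core formulas,
#'   per-sample target universal share and design gradients, config) and
#'   `library`.
#' @export
simulate_dataset <- function(config = simulation_config(), library = NULL) {
  if (is.null(library)) library <- generate_library(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer((config$seed + 7919) %% 2147483647))
  design <- .design_table(config)
  nf <- nrow(library)
  # universal core drawn per class to match the core mixture
  core_counts <- round(config$universal_core_size * config$core_mixture)
  core_counts[1] <- core_counts[1] + config$universal_core_size - sum(core_counts)
  core_idx <- integer(0)
  for (cls in names(core_counts)) {
    pool <- which(library$compound_class == cls)
    take <- min(core_counts[[cls]], length(pool))
    core_idx <- c(core_idx, sample(pool, take))
  }
  short <- config$universal_core_size - length(core_idx)
  if (short > 0) {
    core_idx <- c(core_idx, sample(setdiff(seq_len(nf), core_idx), short))
  }
  is_core <- seq_len(nf) %in% core_idx
  cls <- library$compound_class
  depl <- config$gradient_effects[cls]
  depl[is.na(depl)] <- 0
  mass_shift_class <- cls %in% c("carbohydrate-like",
                                 "unsaturated-hydrocarbon-like")
  # scaled mass within each mass-shift class for the removal preference
  zmass <- rep(0, nf)
  for (k in unique(cls[mass_shift_class])) {
    i <- which(cls == k)
    m <- library$neutral_mass[i]
    zmass[i] <- if (diff(range(m)) > 0) (m - min(m)) / diff(range(m)) else 0.5
  }
  # removal preference decays with scaled mass as (1 - z)^mass_bias, so the
  # lower-mass half of a mass-shift class is lost first along the gradient
  wmass <- ifelse(mass_shift_class, (1 - zmass)^config$mass_bias, 1)
  slope <- config$universal_intensity_slope_pp / 100
  mat <- matrix(0, nrow = nf, ncol = nrow(design),
                dimnames = list(library$formula, design$sample_id))
  target_share <- numeric(nrow(design))
  for (s in seq_len(nrow(design))) {
    g <- (design$g_depth[s] + design$g_pos[s]) / 2
    p_remove <- pmin(depl * g * wmass, 1)
    detected <- is_core |
      (stats::runif(nf) < config$detection_prob * (1 - p_remove))
    x <- numeric(nf)
    x[detected] <- stats::rlnorm(sum(detected),
                                 config$intensity_lognormal[["meanlog"]],
                                 config$intensity_lognormal[["sdlog"]])
    t_mean <- config$universal_intensity_base +
      slope * design$g_depth[s] + slope * design$g_pos[s]
    t_obs <- stats::plogis(stats::qlogis(t_mean) +
                             stats::rnorm(1, 0, config$share_noise_sd))
    s_core <- sum(x[is_core])
    s_non <- sum(x[!is_core & detected])
    if (s_non > 0 && s_core > 0) {
      x[is_core] <- x[is_core] * (t_obs / (1 - t_obs)) * (s_non / s_core)
    }
    mat[, s] <- x / sum(x)
    target_share[s] <- t_obs
  }
  md <- sample_metadata(design$sample_id, design$catchment, design$position,
                        design$depth_cm, design$sample_type)
  keep <- rowSums(mat) > 0
  ds <- structure(list(formulas = library[keep, , drop = FALSE],
                       samples = md,
                       intensity = mat[keep, , drop = FALSE]),
                  class = "dom_dataset")
  rownames(ds$formulas) <- NULL
  truth <- list(core_formulas = library$formula[is_core],
                target_universal_share = data.frame(
                  sample_id = design$sample_id,
                  g_depth = design$g_depth, g_pos = design$g_pos,
                  share = target_share, stringsAsFactors = FALSE),
                config = config)
  list(dataset = ds, truth = truth, library = library)
}

#' Emulate duplicate FT-ICR-MS peak lists for one sample
#'
#' Each formula emits its [M-H]- m/z in both replicates with independent
#' Gaussian ppm jitter; spurious noise peaks at random m/z with
#' sub-detection-limit intensities are added per replicate (they are
#' removed again by replicate matching and the detection limit).
#'
#' @param table Data frame with columns formula, intensity (e.g. one
#'   sample's normalised intensities).
#' @param config A [simulation_config()].
#' @param intensity_scale Multiplier turning normalised intensities into
#'   instrument-like signal units.
#' @param seed Seed for the jitter (defaults to the config seed).
#' @return Data frame with columns mz, intensity, replicate_id ("R1", "R2").
#' @export
simulate_peaklist <- function(table, config = simulation_config(),
                              intensity_scale = 1e6,
                              seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer((seed + 104729) %% 2147483647))
  mass <- exact_neutral_mass(parse_formula(table$formula))
  mz <- mass - PROTON_MASS
  base_int <- table$intensity * intensity_scale
  # spurious signals recur in both replicates (so they survive duplicate
  # matching and are removed by the detection limit, not by matching)
  n_noise <- round(config$noise_peak_rate * length(mz))
  noise_mz <- stats::runif(n_noise, 150, 1000)
  # band chosen so twice the median noise intensity (the detection limit at
  # the default factor) sits clearly above the largest noise peak
  noise_int <- stats::runif(n_noise, 0.15, 0.25) * min(base_int)
  reps <- lapply(c("R1", "R2"), function(r) {
    all_mz <- c(mz, noise_mz)
    jit <- stats::rnorm(length(all_mz), 0, config$ppm_jitter_sd) * 1e-6
    data.frame(
      mz = all_mz * (1 + jit),
      intensity = c(base_int * exp(stats::rnorm(length(mz), 0, config$intensity_rep_sd)),
                    noise_int * exp(stats::rnorm(n_noise, 0, config$intensity_rep_sd))),
      replicate_id = r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reps)
  out[order(out$replicate_id, out$mz), ]
}
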