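# Molecular-formula assignment of calibrated negative-mode FT-ICR-MS peak
# lists: replicate merging, detection-limit filtering, exhaustive candidate
# enumeration within elemental bounds, and per-sample intensity
# normalisation.

#' Assignment configuration
#'
#' Defaults reproduce the attribution rules used throughout the package:
#' elemental bounds C 0-100, H 2-200, O 0-70, N 0-3, S 0-2, P 0-2; a mass
#' tolerance of 0.2 ppm; an analytical window of 150-1000 m/z; deprotonated
#' singly charged ions; a method detection limit of 2 times the noise
#' level; and a 0.5 ppm replicate-matching tolerance.
#'
#' @param c_max,h_min,h_max,o_max,n_max,s_max,p_max Elemental bounds.
#' @param ppm_tolerance Assignment tolerance in ppm of neutral mass.
#' @param mz_window Two-element numeric, analytical m/z window.
#' @param mdl_factor Peaks below `mdl_factor * noise` are discarded.
#' @param replicate_match_ppm Tolerance for matching peaks across duplicate
#'   measurements, in ppm.
#' @param require_integer_dbe,require_nonneg_dbe Chemical filter flags.
#' @param hc_cap,oc_cap Optional plausibility caps on H/C and O/C ratios
#'   (`NULL` disables; applied only to formulas with carbon).
#' @param noise_estimator Function mapping a vector of intensities to a
#'   noise level. The default is the median intensity of the
#'   lowest-intensity decile; with fewer than 10 peaks it falls back to the
#'   minimum intensity.
#' @return List of class `assignment_config`.
#' @export
assignment_config <- function(c_max = 100L, h_min = 2L, h_max = 200L,
                              o_max = 70L, n_max = 3L, s_max = 2L,
                              p_max = 2L,
                              ppm_tolerance = 0.2,
                              mz_window = c(150, 1000),
                              mdl_factor = 2,
                              replicate_match_ppm = 0.5,
                              require_integer_dbe = TRUE,
                              require_nonneg_dbe = TRUE,
                              hc_cap = NULL, oc_cap = NULL,
                              noise_estimator = NULL) {
  stopifnot(ppm_tolerance > 0, length(mz_window) == 2,
            mz_window[1] < mz_window[2], mdl_factor >= 0)
  structure(list(
    c_max = as.integer(c_max), h_min = as.integer(h_min),
    h_max = as.integer(h_max), o_max = as.integer(o_max),
    n_max = as.integer(n_max), s_max = as.integer(s_max),
    p_max = as.integer(p_max),
    ppm_tolerance = ppm_tolerance, mz_window = mz_window,
    mdl_factor = mdl_factor, replicate_match_ppm = replicate_match_ppm,
    require_integer_dbe = require_integer_dbe,
    require_nonneg_dbe = require_nonneg_dbe,
    hc_cap = hc_cap, oc_cap = oc_cap,
    noise_estimator = noise_estimator
  ), class = "assignment_config")
}

#' Neutral mass of a deprotonated singly charged ion
#'
#' For [M-H]- ions the neutral mass is the ion m/z plus the proton mass
#' (hydrogen minus electron, [PROTON_MASS]).
#'
#' @param mz Ion m/z (Th; equals Da at |z| = 1).
#' @return Neutral mass in Da.
#' @seealso [ion_mz()] for the inverse.
#' @export
neutral_mass_from_mz <- function(mz) {
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("m/z must be positive and finite", call. = FALSE)
  }
  mz + PROTON_MASS
}

#' [M-H]- ion m/z of a neutral mass
#' @param neutral_mass Neutral mass in Da.
#' @return Ion m/z.
#' @export
ion_mz <- function(neutral_mass) {
  if (any(!is.finite(neutral_mass)) || any(neutral_mass <= PROTON_MASS)) {
    stop("neutral mass must exceed the proton mass", call. = FALSE)
  }
  neutral_mass - PROTON_MASS
}

#' Chemical plausibility filters
#'
#' A formula passes when its DBE is a non-negative integer (both rules
#' individually switchable) and any configured H/C and O/C caps hold.
#' Non-integer DBE corresponds to an odd electron count for CHNOSP
#' molecules and is rejected by default.
#'
#' @param f Data frame with columns c, h, n, o, s, p (or a `mol_formula`).
#' @param config An [assignment_config()].
#' @return Logical vector, one per formula.
#' @export
passes_chemical_filters <- function(f, config = assignment_config()) {
  if (inherits(f, "mol_formula")) f <- as.data.frame(as.list(f))
  dbe <- 1 + f$c - f$h / 2 + f$n / 2 + f$p / 2
  ok <- rep(TRUE, nrow(f))
  if (config$require_integer_dbe) ok <- ok & (abs(dbe - round(dbe)) < 1e-9)
  if (config$require_nonneg_dbe) ok <- ok & (dbe >= -1e-9)
  if (!is.null(config$hc_cap)) ok <- ok & (f$c == 0L | f$h / pmax(f$c, 1L) <= config$hc_cap)
  if (!is.null(config$oc_cap)) ok <- ok & (f$c == 0L | f$o / pmax(f$c, 1L) <= config$oc_cap)
  ok
}

# Grid of all CNOSP element combinations within bounds, with the mass of the
# carbon-plus-heteroatom skeleton. Computed once per config and cached by a
# key over the bounds (the grid is the enumeration search space; hydrogen is
# solved per target mass).
.grid_cache <- new.env(parent = emptyenv())

.cnosp_grid <- function(config) {
  key <- paste(config$c_max, config$n_max, config$o_max, config$s_max,
               config$p_max, config$mz_window[2], sep = "_")
  hit <- .grid_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- expand.grid(c = 0:config$c_max, n = 0:config$n_max,
                   o = 0:config$o_max, s = 0:config$s_max,
                   p = 0:config$p_max, KEEP.OUT.ATTRS = FALSE)
  base <- g$c * MONOISOTOPIC_MASS[["C"]] + g$n * MONOISOTOPIC_MASS[["N"]] +
    g$o * MONOISOTOPIC_MASS[["O"]] + g$s * MONOISOTOPIC_MASS[["S"]] +
    g$p * MONOISOTOPIC_MASS[["P"]]
  # skeleton + minimum hydrogen must fit under the analytical window top
  max_neutral <- config$mz_window[2] + PROTON_MASS + 1
  keep <- base + config$h_min * MONOISOTOPIC_MASS[["H"]] <= max_neutral
  g <- g[keep, , drop = FALSE]
  base <- base[keep]
  ord <- order(base)
  out <- list(grid = g[ord, , drop = FALSE], base = base[ord])
  .grid_cache[[key]] <- out
  out
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Exhaustively enumerates every formula within the configured elemental
#' bounds whose exact neutral mass lies within `ppm_tolerance` of the
#' target and which passes the chemical filters. Candidates are sorted by
#' absolute mass error, ties broken by fewest heteroatoms (N+S+P), then by
#' canonical formula string.
#'
#' @param neutral_mass Target neutral mass in Da; must fall inside the
#'   window implied by the m/z window.
#' @param config An [assignment_config()].
#' @return Data frame with columns formula, c, h, n, o, s, p,
#'   exact_mass, mass_error_ppm; zero rows when no candidate survives.
#' @export
enumerate_candidates <- function(neutral_mass, config = assignment_config()) {
  lo <- config$mz_window[1] + PROTON_MASS
  hi <- config$mz_window[2] + PROTON_MASS
  if (neutral_mass < lo - 1e-6 || neutral_mass > hi + 1e-6) {
    stop("out of analytical window: neutral mass ", format(neutral_mass),
         " outside [", format(lo), ", ", format(hi), "] Da", call. = FALSE)
  }
  gb <- .cnosp_grid(config)
  tol_da <- config$ppm_tolerance * 1e-6 * neutral_mass
  mh <- MONOISOTOPIC_MASS[["H"]]
  # slice of skeletons for which some h in [h_min, h_max] can reach the mass
  i1 <- findInterval(neutral_mass - config$h_max * mh - tol_da, gb$base) + 1L
  i2 <- findInterval(neutral_mass - config$h_min * mh + tol_da, gb$base)
  if (i2 < i1) {
    return(.empty_candidates())
  }
  idx <- i1:i2
  resid <- neutral_mass - gb$base[idx]
  h <- as.integer(round(resid / mh))
  err_da <- gb$base[idx] + h * mh - neutral_mass
  ok <- h >= config$h_min & h <= config$h_max & abs(err_da) <= tol_da
  if (!any(ok)) return(.empty_candidates())
  cand <- gb$grid[idx[ok], , drop = FALSE]
  cand$h <- h[ok]
  cand <- cand[, c("c", "h", "n", "o", "s", "p")]
  keep <- passes_chemical_filters(cand, config)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_candidates())
  cand$exact_mass <- exact_neutral_mass(cand)
  cand$mass_error_ppm <- (cand$exact_mass - neutral_mass) / neutral_mass * 1e6
  cand$formula <- format_formula(cand)
  het <- cand$n + cand$s + cand$p
  ord <- order(abs(cand$mass_error_ppm), het, cand$formula)
  cand <- cand[ord, c("formula", "c", "h", "n", "o", "s", "p",
                      "exact_mass", "mass_error_ppm")]
  rownames(cand) <- NULL
  cand
}

.empty_candidates <- function() {
  data.frame(formula = character(), c = integer(), h = integer(),
             n = integer(), o = integer(), s = integer(), p = integer(),
             exact_mass = numeric(), mass_error_ppm = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge duplicate measurements of one sample
#'
#' Retains only signals detected in both duplicate measurements. Peaks from
#' the two replicates are matched greedily by nearest m/z within
#' `replicate_match_ppm` (each peak used at most once); a matched pair is
#' emitted as one peak with the intensity-weighted mean m/z and the mean
#' intensity. Unmatched peaks are dropped.
#'
#' @param peaks Data frame with columns mz, intensity, replicate_id;
#'   exactly two replicate ids must be present (unless `peaks` is empty).
#' @param config An [assignment_config()].
#' @return Data frame with columns mz, intensity.
#' @export
merge_replicates <- function(peaks, config = assignment_config()) {
  if (nrow(peaks) == 0L) {
    return(data.frame(mz = numeric(), intensity = numeric()))
  }
  reps <- unique(peaks$replicate_id)
  if (length(reps) != 2L) {
    stop("replicate merging requires exactly two replicate ids, got ",
         length(reps), call. = FALSE)
  }
  a <- peaks[peaks$replicate_id == reps[1], , drop = FALSE]
  b <- peaks[peaks$replicate_id == reps[2], , drop = FALSE]
  a <- a[order(a$mz), ]
  b <- b[order(b$mz), ]
  # candidate pairs within tolerance, via a window on the sorted b masses
  tol <- config$replicate_match_ppm * 1e-6
  pairs_i <- integer(0); pairs_j <- integer(0); pairs_d <- numeric(0)
  lo <- findInterval(a$mz * (1 - tol), b$mz) + 1L
  hi <- findInterval(a$mz * (1 + tol), b$mz)
  for (i in seq_len(nrow(a))) {
    if (hi[i] < lo[i]) next
    js <- lo[i]:hi[i]
    d <- abs(b$mz[js] - a$mz[i]) / a$mz[i]
    keep <- d <= tol
    pairs_i <- c(pairs_i, rep.int(i, sum(keep)))
    pairs_j <- c(pairs_j, js[keep])
    pairs_d <- c(pairs_d, d[keep])
  }
  if (length(pairs_i) == 0L) {
    return(data.frame(mz = numeric(), intensity = numeric()))
  }
  ord <- order(pairs_d)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  sel <- logical(length(ord))
  for (k in ord) {
    if (!used_a[pairs_i[k]] && !used_b[pairs_j[k]]) {
      sel[k] <- TRUE
      used_a[pairs_i[k]] <- TRUE
      used_b[pairs_j[k]] <- TRUE
    }
  }
  i <- pairs_i[sel]; j <- pairs_j[sel]
  wa <- a$intensity[i]; wb <- b$intensity[j]
  wsum <- wa + wb
  mz <- ifelse(wsum > 0, (a$mz[i] * wa + b$mz[j] * wb) / wsum,
               (a$mz[i] + b$mz[j]) / 2)
  out <- data.frame(mz = mz, intensity = (wa + wb) / 2)
  out[order(out$mz), , drop = FALSE]
}

#' Apply the method detection limit
#'
#' Retains peaks with intensity at least `mdl_factor` times the estimated
#' noise level. The default noise estimator is the median intensity of the
#' lowest-intensity decile of peaks; with fewer than 10 peaks the minimum
#' intensity is used instead (with a message). A custom estimator can be
#' supplied in the config.
#'
#' @param peaks Data frame with columns mz, intensity.
#' @param config An [assignment_config()].
#' @return Filtered peak data frame; empty (with a warning) when no peak
#'   clears the limit.
#' @export
apply_mdl <- function(peaks, config = assignment_config()) {
  if (nrow(peaks) == 0L) return(peaks)
  est <- config$noise_estimator
  if (is.null(est)) {
    est <- function(x) {
      if (length(x) < 10L) {
        message("fewer than 10 peaks; noise level set to minimum intensity")
        return(min(x))
      }
      stats::median(x[x <= stats::quantile(x, 0.1, names = FALSE)])
    }
  }
  noise <- est(peaks$intensity)
  out <- peaks[peaks$intensity >= config$mdl_factor * noise, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no peak exceeds the method detection limit (",
            config$mdl_factor, " x noise = ",
            format(config$mdl_factor * noise), ")", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assign a peak list to molecular formulas
#'
#' Full per-sample pipeline: merge duplicate measurements, restrict to the
#' analytical m/z window, apply the method detection limit, enumerate
#' candidate formulas per peak and keep the best candidate, sum intensities
#' of peaks mapping to the same formula, and normalise intensities of the
#' assigned peaks to sum to 1.
#'
#' @param peaks Data frame with columns mz, intensity and, unless
#'   `merged = TRUE`, replicate_id.
#' @param config An [assignment_config()].
#' @param merged Set `TRUE` when `peaks` is already a merged single
#'   measurement (no replicate_id column needed).
#' @return List with `table` (data frame formula, intensity; normalised
#'   intensities summing to 1) and `log` (data frame mz, status, formula,
#'   mass_error_ppm, candidate_count; status one of assigned, unassigned,
#'   out_of_window, below_mdl).
#' @export
assign_peaklist <- function(peaks, config = assignment_config(),
                            merged = FALSE) {
  pk <- if (merged) peaks[, c("mz", "intensity")] else merge_replicates(peaks, config)
  in_window <- pk$mz >= config$mz_window[1] & pk$mz <= config$mz_window[2]
  log_rows <- list()
  if (any(!in_window)) {
    log_rows$oow <- data.frame(mz = pk$mz[!in_window], status = "out_of_window",
                               formula = NA_character_,
                               mass_error_ppm = NA_real_,
                               candidate_count = 0L)
  }
  pk <- pk[in_window, , drop = FALSE]
  kept <- apply_mdl(pk, config)
  dropped <- pk[!(pk$mz %in% kept$mz), , drop = FALSE]
  if (nrow(dropped) > 0L) {
    log_rows$mdl <- data.frame(mz = dropped$mz, status = "below_mdl",
                               formula = NA_character_,
                               mass_error_ppm = NA_real_,
                               candidate_count = 0L)
  }
  n <- nrow(kept)
  formula <- rep(NA_character_, n)
  err <- rep(NA_real_, n)
  ncand <- integer(n)
  for (i in seq_len(n)) {
    cand <- enumerate_candidates(neutral_mass_from_mz(kept$mz[i]), config)
    ncand[i] <- nrow(cand)
    if (nrow(cand) > 0L) {
      formula[i] <- cand$formula[1]
      err[i] <- cand$mass_error_ppm[1]
    }
  }
  log_rows$assign <- data.frame(
    mz = kept$mz,
    status = ifelse(is.na(formula), "unassigned", "assigned"),
    formula = formula, mass_error_ppm = err, candidate_count = ncand)
  log <- do.call(rbind, unname(log_rows))
  log <- log[order(log$mz), ]
  rownames(log) <- NULL
  ok <- !is.na(formula)
  if (!any(ok)) {
    warning("no peak could be assigned a molecular formula", call. = FALSE)
    return(list(table = data.frame(formula = character(),
                                   intensity = numeric()),
                log = log))
  }
  raw <- tapply(kept$intensity[ok], formula[ok], sum)
  tab <- data.frame(formula = names(raw),
                    intensity = as.numeric(raw) / sum(raw),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$formula), ]
  rownames(tab) <- NULL
  list(table = tab, log = log)
}
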