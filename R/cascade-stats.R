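# Universal (core) compound-pool statistics, compound-class profiles, and
# intensity-weighted mean masses.

#' Detect the universal compound pool
#'
#' Universal compounds are molecular formulas present (intensity > 0) in at
#' least `threshold` of the samples; at the default threshold of 1 this is
#' the set present in every sample, the definition used throughout the
#' degradation-cascade analysis. Lower thresholds support occupancy
#' sensitivity analyses.
#'
#' @param ds A `dom_dataset`.
#' @param threshold Occupancy threshold as a fraction of samples in (0, 1].
#' @return A `universal_pool`: list with `formulas` (character vector of
#'   canonical formula strings), `occupancy` (named occupancy fractions for
#'   the pool members) and `threshold`.
#' @export
universal_set <- function(ds, threshold = 1) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(ds$intensity) == 0L || ncol(ds$intensity) == 0L) {
    stop("dataset is empty", call. = FALSE)
  }
  occ <- rowMeans(ds$intensity > 0)
  member <- occ >= threshold - 1e-12
  structure(list(formulas = rownames(ds$intensity)[member],
                 occupancy = occ[member],
                 threshold = threshold),
            class = "universal_pool")
}

#' @export
print.universal_pool <- function(x, ...) {
  cat("universal pool:", length(x$formulas), "formulas at occupancy >=",
      x$threshold, "\n")
  invisible(x)
}

#' Per-sample universal richness and intensity fractions
#'
#' For each sample: the percentage of its detected formulas that belong to
#' the universal pool (richness_pct) and the percentage of its total
#' normalised signal intensity carried by pool members (intensity_pct).
#'
#' @param ds A `dom_dataset`.
#' @param pool A `universal_pool` whose formulas are a subset of the
#'   dataset's.
#' @return Data frame with columns sample_id, richness_pct, intensity_pct,
#'   n_present. Samples with zero detected formulas get `NA` with a warning.
#' @export
universal_fractions <- function(ds, pool) {
  if (!all(pool$formulas %in% rownames(ds$intensity))) {
    stop("pool contains formulas absent from the dataset", call. = FALSE)
  }
  in_pool <- rownames(ds$intensity) %in% pool$formulas
  present <- ds$intensity > 0
  n_present <- colSums(present)
  n_pool <- colSums(present & in_pool)
  int_pool <- colSums(ds$intensity * in_pool)
  int_total <- colSums(ds$intensity)
  richness <- ifelse(n_present > 0, 100 * n_pool / n_present, NA_real_)
  intensity <- ifelse(int_total > 0, 100 * int_pool / int_total, NA_real_)
  if (any(n_present == 0)) {
    warning("sample(s) with zero detected formulas reported as NA",
            call. = FALSE)
  }
  data.frame(sample_id = colnames(ds$intensity),
             richness_pct = unname(richness),
             intensity_pct = unname(intensity),
             n_present = unname(n_present),
             stringsAsFactors = FALSE)
}

# Resolve the formula rows selected by a subset keyword.
.subset_rows <- function(ds, subset, pool) {
  subset <- match.arg(subset, c("all", "universal", "non-universal"))
  if (subset == "all") return(rep(TRUE, nrow(ds$intensity)))
  if (is.null(pool)) {
    stop("subset '", subset, "' requires a universal pool", call. = FALSE)
  }
  in_pool <- rownames(ds$intensity) %in% pool$formulas
  if (subset == "universal") in_pool else !in_pool
}

#' Per-sample compound-class profiles
#'
#' Count weighting gives the percentage of detected formulas per class
#' (summing to 100 over classes within the chosen subset); intensity
#' weighting gives the sum of original normalised intensities per class
#' (summing to the subset's share of total signal, NOT renormalised).
#'
#' @param ds A `dom_dataset`.
#' @param weighting "count" or "intensity".
#' @param subset "all", "universal" or "non-universal" (the latter two need
#'   `pool`).
#' @param pool A `universal_pool`, required unless `subset = "all"`.
#' @return Tidy data frame: sample_id, compound_class, weighting, subset,
#'   value. Classes absent from a sample appear with value 0.
#' @export
class_profile <- function(ds, weighting = c("count", "intensity"),
                          subset = "all", pool = NULL) {
  weighting <- match.arg(weighting)
  rows <- .subset_rows(ds, subset, pool)
  classes <- unique(ds$formulas$compound_class)
  cls <- ds$formulas$compound_class
  out <- list()
  for (s in seq_len(ncol(ds$intensity))) {
    x <- ds$intensity[, s]
    sel <- rows & x > 0
    if (weighting == "count") {
      tab <- table(factor(cls[sel], levels = classes))
      val <- if (sum(tab) > 0) 100 * as.numeric(tab) / sum(tab) else rep(NA_real_, length(classes))
    } else {
      val <- vapply(classes, function(k) sum(x[sel & cls == k]), numeric(1))
    }
    out[[s]] <- data.frame(sample_id = colnames(ds$intensity)[s],
                           compound_class = classes,
                           weighting = weighting,
                           subset = subset,
                           value = unname(val),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Class composition of a formula pool (count weighting)
#'
#' Dataset-wide share of each compound class among the formulas of a pool,
#' e.g. the contribution of classes to the universal compound pool.
#'
#' @param ds A `dom_dataset`.
#' @param formulas Character vector of formula strings (e.g.
#'   `pool$formulas`).
#' @return Data frame compound_class, n, pct; pct sums to 100.
#' @export
pool_class_composition <- function(ds, formulas) {
  cls <- ds$formulas$compound_class[ds$formulas$formula %in% formulas]
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(compound_class = names(tab),
             n = as.integer(tab),
             pct = 100 * as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Intensity-weighted mean mass per sample
#'
#' m/z_wm = sum(m_i * I_i) / sum(I_i) over the contributing formulas of a
#' sample, where m_i is the neutral monoisotopic mass (use `mass = "mz"`
#' for the [M-H]- ion m/z; the two differ by a constant offset, so
#' gradient shifts are identical). Scale-invariant in the intensities.
#'
#' @param ds A `dom_dataset`.
#' @param group A compound-class label, or "all".
#' @param subset "all", "universal" or "non-universal".
#' @param pool A `universal_pool`, required unless `subset = "all"`.
#' @param mass "neutral" or "mz".
#' @return Data frame: sample_id, group, subset, mz_wm, n_formulas,
#'   total_intensity. Samples where the group is empty get `NA` mz_wm.
#' @export
weighted_mass <- function(ds, group = "all", subset = "all", pool = NULL,
                          mass = c("neutral", "mz")) {
  mass <- match.arg(mass)
  rows <- .subset_rows(ds, subset, pool)
  if (group != "all") {
    rows <- rows & ds$formulas$compound_class == group
  }
  m <- ds$formulas$neutral_mass
  if (mass == "mz") m <- m - PROTON_MASS
  out <- data.frame(sample_id = colnames(ds$intensity),
                    group = group, subset = subset,
                    mz_wm = NA_real_, n_formulas = 0L,
                    total_intensity = 0,
                    stringsAsFactors = FALSE)
  for (s in seq_len(ncol(ds$intensity))) {
    x <- ds$intensity[, s]
    sel <- rows & x > 0
    tot <- sum(x[sel])
    out$n_formulas[s] <- sum(sel)
    out$total_intensity[s] <- tot
    if (tot > 0) out$mz_wm[s] <- sum(m[sel] * x[sel]) / tot
  }
  out
}
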