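# Rarefaction-based similarity of a sample's formula pool to a reference
# formula set, as used to place samples along a degradation continuum
# relative to an end-member (e.g. deep-sea) DOM pool.

# Stable polynomial string hash used to derive per-unit RNG substreams from
# the master seed, so results do not depend on unit processing order. The
# modulus keeps every intermediate product exactly representable in doubles.
.stable_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 67108859
  as.integer(h)
}

.unit_seed <- function(seed, unit_id) {
  as.integer((as.numeric(seed) + .stable_hash(as.character(unit_id))) %% 2147483647)
}

#' Rarefied shared-formula percentage against a reference set
#'
#' Repeatedly draws `depth` formulas uniformly without replacement from the
#' unit's formula set and scores the percentage of the draw shared with the
#' reference set; returns the mean and standard deviation over iterations.
#' Draws are presence-based (not intensity-weighted). Units with fewer than
#' `depth` formulas are excluded (an exclusion record, not an error),
#' mirroring rarefaction practice in diversity studies.
#'
#' @param formulas Character vector: the unit's detected formula strings.
#' @param reference Character vector: the reference formula set.
#' @param depth Rarefaction depth (default 6000 formulas).
#' @param iterations Number of random draws (default 1000).
#' @param seed Master seed; combined with `unit_id` via a stable hash so
#'   per-unit results are independent of processing order.
#' @param unit_id Label of the unit (sample or study).
#' @return One-row data frame: unit_id, mean_shared_pct, sd_shared_pct,
#'   n_formulas_available, excluded, reason.
#' @export
rarefied_shared_fraction <- function(formulas, reference, depth = 6000,
                                     iterations = 1000, seed = 1,
                                     unit_id = "unit") {
  stopifnot(depth >= 1, iterations >= 1)
  formulas <- unique(formulas)
  n <- length(formulas)
  if (n < depth) {
    return(data.frame(unit_id = unit_id, mean_shared_pct = NA_real_,
                      sd_shared_pct = NA_real_, n_formulas_available = n,
                      excluded = TRUE,
                      reason = sprintf("only %d formulas available at depth %d",
                                       n, depth),
                      stringsAsFactors = FALSE))
  }
  in_ref <- formulas %in% unique(reference)
  shared <- numeric(iterations)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.unit_seed(seed, unit_id))
  for (i in seq_len(iterations)) {
    draw <- sample.int(n, depth, replace = FALSE)
    shared[i] <- 100 * sum(in_ref[draw]) / depth
  }
  data.frame(unit_id = unit_id, mean_shared_pct = mean(shared),
             sd_shared_pct = stats::sd(shared), n_formulas_available = n,
             excluded = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Rarefied similarity of every sample of a dataset to a reference
#'
#' @param ds A `dom_dataset`.
#' @param reference Character vector of reference formula strings.
#' @param depth,iterations,seed As in [rarefied_shared_fraction()].
#' @return Data frame with one row per sample (unit_id = sample_id).
#' @export
similarity_to_reference <- function(ds, reference, depth = 6000,
                                    iterations = 1000, seed = 1) {
  rows <- lapply(colnames(ds$intensity), function(s) {
    f <- rownames(ds$intensity)[ds$intensity[, s] > 0]
    rarefied_shared_fraction(f, reference, depth = depth,
                             iterations = iterations, seed = seed,
                             unit_id = s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rarefaction profile: shared percentage as a function of depth
#'
#' Computes the rarefied shared percentage at a ladder of depths. The mean
#' series is flat in expectation (the hypergeometric expectation does not
#' depend on depth); the sd series shrinks with depth and is the diagnostic
#' for judging whether a depth samples the pool adequately.
#'
#' @param formulas,reference,iterations,seed,unit_id As in
#'   [rarefied_shared_fraction()].
#' @param depths Increasing vector of rarefaction depths, all at most
#'   `length(unique(formulas))`.
#' @return Data frame with one row per depth (column `depth` added).
#' @export
rarefaction_profile <- function(formulas, reference, depths,
                                iterations = 1000, seed = 1,
                                unit_id = "unit") {
  stopifnot(!is.unsorted(depths))
  rows <- lapply(depths, function(d) {
    r <- rarefied_shared_fraction(formulas, reference, depth = d,
                                  iterations = iterations, seed = seed,
                                  unit_id = paste0(unit_id, "@", d))
    r$unit_id <- unit_id
    r$depth <- d
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
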