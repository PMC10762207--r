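# Shared fixtures: a small simulation configuration (2 catchments, a
# 300-formula library) used wherever full study scale is not the point,
# and a hand-built toy dataset with known intensities.

small_config <- function(seed = 1, ...) {
  simulation_config(n_catchments = 2, library_size = 300,
                    universal_core_size = 60, seed = seed, ...)
}

# tiny dataset: 3 formulas x 3 samples with fixed intensities; formula A is
# universal, B in two samples, C in one
toy_dataset <- function() {
  tabs <- list(
    S1 = data.frame(formula = c("C10H12O6", "C6H12O6"),
                    intensity = c(0.7, 0.3)),
    S2 = data.frame(formula = c("C10H12O6", "C6H12O6"),
                    intensity = c(0.5, 0.5)),
    S3 = data.frame(formula = c("C10H12O6", "C16H22O11"),
                    intensity = c(0.4, 0.6)))
  md <- sample_metadata(c("S1", "S2", "S3"), c("C1", "C1", "C1"),
                        c("shoulder", "back", "foot"), c(5, 5, 5),
                        c("soil", "soil", "soil"))
  build_dataset(tabs, md)
}

# random valid formulas for round-trip properties
random_formulas <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    c = sample(1:100, n, replace = TRUE),
    h = sample(2:200, n, replace = TRUE),
    n = sample(0:3, n, replace = TRUE),
    o = sample(0:70, n, replace = TRUE),
    s = sample(0:2, n, replace = TRUE),
    p = sample(0:2, n, replace = TRUE))
}

# independent exhaustive element-grid oracle for candidate enumeration:
# loops the complete (c, h, n, o, s, p) grid bounded by the target mass,
# filters by ppm tolerance and the dbe rules, and returns canonical strings
# with their errors. Deliberately does not solve for hydrogen.
oracle_candidates <- function(neutral_mass, ppm = 0.2) {
  mC <- 12; mH <- 1.007825032; mN <- 14.003074005
  mO <- 15.994914622; mS <- 31.972070690; mP <- 30.973761998
  c_max <- min(100L, floor(neutral_mass / mC) + 1L)
  h_max <- min(200L, floor(neutral_mass / mH) + 1L)
  o_max <- min(70L, floor(neutral_mass / mO) + 1L)
  g <- expand.grid(c = 0:c_max, h = 2:h_max, n = 0:3, o = 0:o_max,
                   s = 0:2, p = 0:2, KEEP.OUT.ATTRS = FALSE)
  mass <- g$c * mC + g$h * mH + g$n * mN + g$o * mO + g$s * mS + g$p * mP
  err_ppm <- (mass - neutral_mass) / neutral_mass * 1e6
  keep <- abs(err_ppm) <= ppm
  g <- g[keep, , drop = FALSE]
  err_ppm <- err_ppm[keep]
  dbe <- 1 + g$c - g$h / 2 + g$n / 2 + g$p / 2
  ok <- abs(dbe - round(dbe)) < 1e-9 & dbe >= -1e-9
  data.frame(formula = format_formula(g[ok, , drop = FALSE]),
             mass_error_ppm = err_ppm[ok], stringsAsFactors = FALSE)
}
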