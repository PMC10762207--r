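# Molecular-formula representation, exact-mass arithmetic, structural
# descriptors and van-Krevelen compound classification for CHNOSP formulas.

#' Monoisotopic atomic masses (Da)
#'
#' Single source of truth for all mass arithmetic in the package.
#' Carbon-12 defines the scale (exactly 12 Da); the remaining values are
#' IUPAC/CODATA monoisotopic masses to at least nine decimal places.
#'
#' @format Named numeric vector with elements C, H, N, O, S, P.
#' @export
MONOISOTOPIC_MASS <- c(
  C = 12,
  H = 1.007825032,
  N = 14.003074005,
  O = 15.994914622,
  S = 31.972070690,
  P = 30.973761998
)

#' Proton mass (Da)
#'
#' Mass added to a deprotonated, singly charged negative ion to recover the
#' neutral molecule: neutral = ion + H - e-. At a 0.2 ppm assignment
#' tolerance the electron mass (~3 ppm at 180 Da) is decisive, so the proton
#' mass (hydrogen minus electron) is used, not the hydrogen atom mass.
#'
#' @export
PROTON_MASS <- 1.007276467

.ELEMENT_ORDER <- c("C", "H", "N", "O", "S", "P")

#' Construct a molecular formula
#'
#' @param c,h,n,o,s,p Non-negative integer element counts (carbon, hydrogen,
#'   nitrogen, oxygen, sulfur, phosphorus).
#' @return A named integer vector of class `mol_formula` with elements
#'   c, h, n, o, s, p.
#' @examples
#' molecular_formula(c = 6, h = 12, o = 6)
#' @export
molecular_formula <- function(c = 0L, h = 0L, n = 0L, o = 0L, s = 0L, p = 0L) {
  counts <- c(c = c, h = h, n = n, o = o, s = s, p = p)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(round(counts)),
            names = c("c", "h", "n", "o", "s", "p"),
            class = "mol_formula")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat(format_formula(x), "\n")
  invisible(x)
}

#' Format a formula as its canonical string
#'
#' Canonical grammar: elements in the fixed order C, H, N, O, S, P; a count
#' of 1 is written as the bare element symbol; zero-count elements are
#' omitted. This string is the identity key used to join formulas across
#' samples.
#'
#' @param f A `mol_formula`, or a data frame / list with columns c, h, n, o,
#'   s, p (vectorised).
#' @return Character vector of canonical formula strings.
#' @examples
#' format_formula(molecular_formula(c = 6, h = 12, o = 6)) # "C6H12O6"
#' @export
format_formula <- function(f) {
  if (inherits(f, "mol_formula")) f <- as.list(f)
  counts <- lapply(c("c", "h", "n", "o", "s", "p"), function(el) as.integer(f[[el]]))
  nrec <- max(lengths(counts))
  out <- character(nrec)
  for (i in seq_along(.ELEMENT_ORDER)) {
    k <- counts[[i]]
    if (length(k) < nrec) k <- rep_len(k, nrec)
    piece <- ifelse(k == 0L, "",
                    ifelse(k == 1L, .ELEMENT_ORDER[i],
                           paste0(.ELEMENT_ORDER[i], k)))
    out <- paste0(out, piece)
  }
  out
}

#' Parse a canonical formula string
#'
#' Inverse of [format_formula()]. The grammar requires elements in the
#' order C, H, N, O, S, P; counts of 2 or more written explicitly; a count
#' of 1 as the bare symbol; zero-count elements omitted.
#'
#' @param text Character scalar or vector of canonical formula strings.
#' @return For a scalar, a `mol_formula`; for a vector, a data frame with
#'   integer columns c, h, n, o, s, p.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C10H14NO2") # bare N means one nitrogen
#' @export
parse_formula <- function(text) {
  parse_one <- function(s) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
      stop("formula text must be a non-empty string", call. = FALSE)
    }
    m <- gregexpr("([A-Za-z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(s)) {
      stop("malformed formula '", s, "': unparseable characters", call. = FALSE)
    }
    counts <- stats::setNames(integer(6), .ELEMENT_ORDER)
    last_idx <- 0L
    for (tok in toks) {
      el <- sub("[0-9]+$", "", tok)
      idx <- match(el, .ELEMENT_ORDER)
      if (is.na(idx)) {
        stop("unknown element symbol '", el, "' in formula '", s, "'",
             call. = FALSE)
      }
      if (idx <= last_idx) {
        stop("element '", el, "' out of canonical order (C,H,N,O,S,P) in '",
             s, "'", call. = FALSE)
      }
      last_idx <- idx
      num <- sub("^[A-Za-z]+", "", tok)
      counts[idx] <- if (nzchar(num)) as.integer(num) else 1L
      if (counts[idx] == 0L) {
        stop("explicit zero count for '", el, "' in '", s,
             "': omit zero-count elements", call. = FALSE)
      }
    }
    counts
  }
  if (length(text) == 1L) {
    k <- parse_one(text)
    return(molecular_formula(k["C"], k["H"], k["N"], k["O"], k["S"], k["P"]))
  }
  mat <- t(vapply(text, parse_one, integer(6)))
  out <- as.data.frame(mat)
  names(out) <- c("c", "h", "n", "o", "s", "p")
  rownames(out) <- NULL
  out
}

#' Exact neutral monoisotopic mass
#'
#' @param f A `mol_formula`, or a data frame with columns c, h, n, o, s, p
#'   (vectorised).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' exact_neutral_mass(parse_formula("C6H12O6")) # 180.063388
#' @export
exact_neutral_mass <- function(f) {
  if (inherits(f, "mol_formula")) f <- as.data.frame(as.list(f))
  total <- f$c * MONOISOTOPIC_MASS[["C"]] + f$h * MONOISOTOPIC_MASS[["H"]] +
    f$n * MONOISOTOPIC_MASS[["N"]] + f$o * MONOISOTOPIC_MASS[["O"]] +
    f$s * MONOISOTOPIC_MASS[["S"]] + f$p * MONOISOTOPIC_MASS[["P"]]
  natoms <- f$c + f$h + f$n + f$o + f$s + f$p
  if (any(natoms < 1L)) {
    stop("empty formula has no defined mass", call. = FALSE)
  }
  unname(total)
}

#' Structural descriptors of a molecular formula
#'
#' Computes elemental ratios (H/C, O/C, N/C), double-bond equivalents
#' (DBE = 1 + C - H/2 + N/2 + P/2), the modified aromaticity index
#' AI_mod = (1 + C - O/2 - S - (N + P + H)/2) / (C - O/2 - S - N - P)
#' of Koch & Dittmar, the heteroatom group label, and the exact neutral
#' mass. AI_mod is defined as 0 when its denominator is <= 0 or the
#' quotient is negative, and clamped to at most 1; this prevents saturated
#' formulas from receiving spurious condensed-aromatic labels.
#'
#' @param f A `mol_formula`, a data frame with columns c, h, n, o, s, p, or
#'   a character vector of canonical formula strings.
#' @return Data frame with columns formula, c, h, n, o, s, p, neutral_mass,
#'   hc, oc, nc, dbe, ai_mod, hetero_group. One row per input formula.
#' @examples
#' descriptors("C15H8O2") # ai_mod = 11/14
#' @export
descriptors <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (inherits(f, "mol_formula")) f <- as.data.frame(as.list(f))
  if (any(f$c < 1L)) {
    stop("elemental ratios require at least one carbon atom", call. = FALSE)
  }
  dbe <- 1 + f$c - f$h / 2 + f$n / 2 + f$p / 2
  ai_num <- 1 + f$c - 0.5 * f$o - f$s - 0.5 * (f$n + f$p + f$h)
  ai_den <- f$c - 0.5 * f$o - f$s - f$n - f$p
  ai <- ifelse(ai_den <= 0, 0, ai_num / ai_den)
  ai <- pmin(pmax(ai, 0), 1)
  hetero <- paste0("CH",
                   ifelse(f$n > 0, "N", ""),
                   "O",
                   ifelse(f$s > 0, "S", ""),
                   ifelse(f$p > 0, "P", ""))
  data.frame(
    formula = format_formula(f),
    c = f$c, h = f$h, n = f$n, o = f$o, s = f$s, p = f$p,
    neutral_mass = exact_neutral_mass(f),
    hc = f$h / f$c,
    oc = f$o / f$c,
    nc = f$n / f$c,
    dbe = dbe,
    ai_mod = ai,
    hetero_group = hetero,
    stringsAsFactors = FALSE
  )
}

#' Default compound-class boundary table
#'
#' First-match rule table assigning van-Krevelen compound classes from H/C,
#' O/C, AI_mod and nitrogen presence. Published boundary schemes differ in
#' their exact cut points, so the table is an ordinary data frame the user
#' can replace or reorder; [classify()] applies whatever table it is given.
#'
#' Bound conventions: `hc_min <= hc < hc_max`, `oc_min < oc <= oc_max`,
#' `ai_min <= ai_mod < ai_max`; `requires_n` demands at least one nitrogen.
#' The terminal catch-all row ("other") guarantees every formula receives
#' exactly one label.
#'
#' @return Data frame with columns class, hc_min, hc_max, oc_min, oc_max,
#'   ai_min, ai_max, requires_n.
#' @export
default_class_table <- function() {
  rule <- function(class, hc_min = -Inf, hc_max = Inf, oc_min = -Inf,
                   oc_max = Inf, ai_min = -Inf, ai_max = Inf,
                   requires_n = FALSE) {
    data.frame(class = class, hc_min = hc_min, hc_max = hc_max,
               oc_min = oc_min, oc_max = oc_max, ai_min = ai_min,
               ai_max = ai_max, requires_n = requires_n,
               stringsAsFactors = FALSE)
  }
  rbind(
    rule("condensed-aromatic-like", ai_min = 0.67),
    rule("tannin-like", oc_min = 0.67, hc_max = 1.5),
    rule("carbohydrate-like", oc_min = 0.67, hc_min = 1.5),
    rule("amino-sugar-like", oc_min = 0.55, oc_max = 0.67, hc_min = 1.5,
         requires_n = TRUE),
    rule("protein-like", oc_min = 0.3, oc_max = 0.55, hc_min = 1.5,
         requires_n = TRUE),
    rule("lipid-like", oc_max = 0.3, hc_min = 1.5),
    rule("unsaturated-hydrocarbon-like", oc_max = 0.1, hc_min = 0.7,
         hc_max = 1.5),
    rule("lignin-like", oc_min = 0.1, oc_max = 0.67, hc_min = 0.7,
         hc_max = 1.5, ai_max = 0.67),
    rule("other")
  )
}

#' All compound-class labels of the default boundary table
#' @return Character vector of class labels, catch-all last.
#' @export
compound_classes <- function() default_class_table()$class

#' Classify formulas into compound classes
#'
#' Applies a first-match boundary table to descriptor rows. Deterministic
#' for a fixed table; the catch-all rule means every row receives exactly
#' one label.
#'
#' @param d Data frame as returned by [descriptors()] (needs columns hc,
#'   oc, ai_mod, n).
#' @param table Boundary table; defaults to [default_class_table()].
#' @return Character vector of class labels, one per row of `d`.
#' @export
classify <- function(d, table = default_class_table()) {
  stopifnot(all(c("hc", "oc", "ai_mod", "n") %in% names(d)))
  if (table$class[nrow(table)] != "other" ||
      !all(is.infinite(unlist(table[nrow(table), 2:7])))) {
    # permissive: only insist that some row is a catch-all
    catch <- apply(table[, 2:7], 1, function(r) all(is.infinite(r)))
    if (!any(catch & !table$requires_n)) {
      stop("boundary table lacks a catch-all rule", call. = FALSE)
    }
  }
  out <- rep(NA_character_, nrow(d))
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    hit <- is.na(out) &
      d$hc >= r$hc_min & d$hc < r$hc_max &
      d$oc > r$oc_min & d$oc <= r$oc_max &
      d$ai_mod >= r$ai_min & d$ai_mod < r$ai_max &
      (!r$requires_n | d$n >= 1L)
    out[hit] <- r$class
  }
  out
}

#' Full formula annotation: descriptors plus compound class
#'
#' @param f Formulas in any form accepted by [descriptors()].
#' @param table Class boundary table.
#' @return The [descriptors()] data frame with an added `compound_class`
#'   column.
#' @export
annotate_formulas <- function(f, table = default_class_table()) {
  d <- descriptors(f)
  d$compound_class <- classify(d, table)
  d
}
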