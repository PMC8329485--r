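#' Monoisotopic atomic masses
#'
#' IUPAC monoisotopic masses of the elements handled by the package, on the
#' unified atomic mass scale (12C = 12 exactly).
#'
#' @format Named numeric vector over C, H, N, O, S, P, Cl (Da).
#' @export
ELEMENT_MASSES <- c(
  C  = 12,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207117,
  P  = 30.97376200,
  Cl = 34.96885268
)

.ELEMENTS <- names(ELEMENT_MASSES)
.ELECTRON_MASS <- 0.00054858
.PROTON_MASS <- ELEMENT_MASSES[["H"]] - .ELECTRON_MASS

#' Parse molecular formula strings
#'
#' Converts formula strings such as `"C20H32O4"` into a count matrix over the
#' supported element alphabet C, H, N, O, S, P, Cl.
#'
#' @param x Character vector of molecular formulas (Hill-style element symbols
#'   followed by optional counts; a missing count means 1).
#' @return Integer matrix with one row per formula and one column per element;
#'   rownames are the input strings.
#' @examples
#' parse_formula(c("C6H12O6", "H2O"))
#' @export
parse_formula <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    stop("`x` must be a non-empty character vector of formulas")
  }
  out <- matrix(0L, nrow = length(x), ncol = length(.ELEMENTS),
                dimnames = list(x, .ELEMENTS))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) stop("empty formula at position ", i)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
    if (sum(nchar(toks)) != nchar(s)) {
      stop("cannot parse formula: '", s, "'")
    }
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% .ELEMENTS) {
        stop("unknown element '", el, "' in formula '", s,
             "' (supported: ", paste(.ELEMENTS, collapse = ", "), ")")
      }
      out[i, el] <- out[i, el] + n
    }
  }
  out
}

# Coerce character / named vector / matrix input to a canonical count matrix.
as_formula_matrix <- function(formula) {
  if (is.character(formula)) return(parse_formula(formula))
  if (is.matrix(formula)) {
    missing <- setdiff(colnames(formula), .ELEMENTS)
    if (length(missing)) stop("unknown element(s): ", paste(missing, collapse = ", "))
    out <- matrix(0, nrow = nrow(formula), ncol = length(.ELEMENTS),
                  dimnames = list(rownames(formula), .ELEMENTS))
    out[, colnames(formula)] <- formula
    return(out)
  }
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(as_formula_matrix(matrix(formula, nrow = 1,
                                    dimnames = list(NULL, names(formula)))))
  }
  stop("`formula` must be a character vector, named count vector, or count matrix")
}

#' Format count matrices as formula strings
#'
#' Inverse of [parse_formula()]: writes counts in C, H, N, O, S, P, Cl order,
#' omitting absent elements and unit counts.
#'
#' @param counts Count matrix (or anything [parse_formula()] accepts).
#' @return Character vector of formula strings.
#' @export
formula_string <- function(counts) {
  counts <- as_formula_matrix(counts)
  apply(counts, 1, function(r) {
    r <- r[r > 0]
    paste0(names(r), ifelse(r == 1, "", r), collapse = "")
  })
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Formula string(s), named count vector, or count matrix over
#'   C, H, N, O, S, P, Cl.
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' formula_mass("H2O")       # 18.010565
#' formula_mass("C20H32O4")  # 336.230060
#' @export
formula_mass <- function(formula) {
  counts <- as_formula_matrix(formula)
  drop(counts %*% ELEMENT_MASSES)
}

#' Supported negative-mode adducts
#'
#' Mass shifts (Da, electron-inclusive) applied to the neutral monoisotopic
#' mass to obtain the singly charged ion m/z: deprotonation removes a proton
#' (H minus its electron); chloride attachment adds a Cl atom plus an electron.
#'
#' @return Named numeric vector of mass shifts for `[M-H]-` and `[M+Cl]-`.
#' @export
adduct_shifts <- function() {
  c("[M-H]-"  = -.PROTON_MASS,
    "[M+Cl]-" = ELEMENT_MASSES[["Cl"]] + .ELECTRON_MASS)
}

#' Theoretical ion m/z for a formula and adduct
#'
#' @inheritParams formula_mass
#' @param adduct `"[M-H]-"` or `"[M+Cl]-"` (charge -1 in both cases).
#' @return Numeric vector of ion m/z values.
#' @examples
#' ion_mz("C20H32O4", "[M-H]-")  # 335.22278
#' @export
ion_mz <- function(formula, adduct = "[M-H]-") {
  shifts <- adduct_shifts()
  if (!all(adduct %in% names(shifts))) {
    stop("unknown adduct: ", paste(setdiff(adduct, names(shifts)), collapse = ", "))
  }
  formula_mass(formula) + shifts[adduct]
}

#' Ring and double-bond equivalents
#'
#' RDBE = C - (H + Cl)/2 + (N + P)/2 + 1 for a neutral formula (P counted
#' with the trivalent convention, so phosphate esters get integer RDBE).
#'
#' @inheritParams formula_mass
#' @return Numeric vector of RDBE values.
#' @export
rdbe <- function(formula) {
  counts <- as_formula_matrix(formula)
  counts[, "C"] - (counts[, "H"] + counts[, "Cl"]) / 2 +
    (counts[, "N"] + counts[, "P"]) / 2 + 1
}

#' Elemental composition class
#'
#' Assigns the compositional class used for van Krevelen coloring:
#' P-containing formulas are classed `"P"` regardless of other heteroatoms;
#' otherwise the class is CHO / CHNO / CHOS / CHNOS by N and S content.
#' Chlorinated, phosphorus-free formulas fall into `"other"`.
#'
#' @inheritParams formula_mass
#' @return Character vector of classes.
#' @export
element_class <- function(formula) {
  counts <- as_formula_matrix(formula)
  cls <- rep("other", nrow(counts))
  hasN <- counts[, "N"] > 0; hasS <- counts[, "S"] > 0
  noCl <- counts[, "Cl"] == 0
  cls[noCl & !hasN & !hasS] <- "CHO"
  cls[noCl & hasN & !hasS] <- "CHNO"
  cls[noCl & !hasN & hasS] <- "CHOS"
  cls[noCl & hasN & hasS] <- "CHNOS"
  cls[counts[, "P"] > 0] <- "P"
  cls
}

#' Chemical plausibility filter for molecular formulas
#'
#' Applies the elemental-ratio and valence rules used throughout the package
#' to decide whether a neutral formula is chemically sensible:
#' 0.3 <= H/C <= 3.0; O/C <= 1.2 (<= 2.0 when P is present); N <= 7, S <= 3,
#' P <= 2, Cl <= 1; RDBE >= 0 and integer (even-electron neutral molecule,
#' nitrogen rule); at least one carbon.
#'
#' @inheritParams formula_mass
#' @return Logical vector, `TRUE` where the formula passes.
#' @examples
#' chemical_filters("C6H12O6")   # TRUE
#' chemical_filters("CH30")      # FALSE (H/C = 30)
#' @export
chemical_filters <- function(formula) {
  counts <- as_formula_matrix(formula)
  C <- counts[, "C"]; H <- counts[, "H"]; N <- counts[, "N"]
  O <- counts[, "O"]; S <- counts[, "S"]; P <- counts[, "P"]
  Cl <- counts[, "Cl"]
  hc <- ifelse(C > 0, H / C, Inf)
  oc <- ifelse(C > 0, O / C, Inf)
  r <- C - (H + Cl) / 2 + (N + P) / 2 + 1
  ok <- C >= 1 &
    hc >= 0.3 & hc <= 3.0 &
    oc <= ifelse(P > 0, 2.0, 1.2) &
    N <= 7 & S <= 3 & P <= 2 & Cl <= 1 &
    r >= 0 & abs(r - round(r)) < 1e-9
  unname(ok)
}
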