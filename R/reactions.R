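#' Construct a reaction-difference library
#'
#' @param name Character vector of unique reaction names.
#' @param delta_formula Character vector of composition changes (as parsable
#'   formulas, e.g. `"CH2O"`); applied in both directions when building
#'   networks.
#' @return Data frame of class `"reaction_library"` with columns `name`,
#'   `delta_formula`, `mass_delta` (Da, recomputed from the formula).
#' @export
reaction_library <- function(name, delta_formula) {
  if (anyDuplicated(name)) stop("reaction names must be unique")
  md <- formula_mass(delta_formula)
  structure(data.frame(name = name, delta_formula = delta_formula,
                       mass_delta = unname(md), stringsAsFactors = FALSE),
            class = c("reaction_library", "data.frame"))
}

# element-count deltas as a matrix (reactions x elements)
reaction_deltas <- function(library) {
  parse_formula(library$delta_formula)
}

#' Built-in biochemical reaction-difference library
#'
#' Core set of named exact-mass differences used for mass-difference networks:
#' redox and substitution steps (hydrogenation, hydroxylation, methylation /
#' chain elongation, methoxylation, water addition), conjugations observed in
#' cereal secondary metabolism (glycosylation and hydrated glycation,
#' pentosylation, sulfation variants, glycerol esters, acylations,
#' phosphorylation), and the 19 proteinogenic amino-acid residue condensations
#' (Leu/Ile collapsed to one mass). Users can extend it with
#' [read_reaction_library()].
#'
#' Three sulfation variants are shipped: `sulfation_a` (+SO3, O-sulfonation),
#' `sulfation_b` (+H2SO3, sulfonation with concomitant hydrogenation, the step
#' linking benzoxazinoid glucosides to their observed sulfates), and
#' `sulfation_c` (+H2SO4).
#'
#' @return A [reaction_library()] with more than 40 entries.
#' @export
builtin_reaction_library <- function() {
  core <- c(
    hydrogenation        = "H2",
    hydroxylation        = "O",
    hydration            = "H2O",
    methylation          = "CH2",     # also chain elongation
    methoxylation        = "CH2O",
    formylation          = "CO",
    acetylation          = "C2H2O",
    ethylation           = "C2H4",
    carboxylation        = "CO2",
    malonylation         = "C3H2O3",
    glycerol_ester       = "C3H6O2",
    glycerol_addition    = "C3H8O3",
    prenylation          = "C5H8",
    pentosylation        = "C5H8O4",
    deoxyhexosylation    = "C6H10O4",
    glycosylation        = "C6H10O5",
    glucose_addition     = "C6H12O6", # hydrated glycation (no water loss)
    sulfation_a          = "SO3",
    sulfation_b          = "H2SO3",
    sulfation_c          = "H2SO4",
    amination            = "NH",
    amidation            = "NH3",
    phosphorylation      = "HPO3",
    galloylation         = "C7H4O4",
    coumaroylation       = "C9H6O2",
    caffeoylation        = "C9H6O3",
    feruloylation        = "C10H8O3"
  )
  aa <- c(
    condensation_Gly = "C2H3NO",  condensation_Ala = "C3H5NO",
    condensation_Ser = "C3H5NO2", condensation_Pro = "C5H7NO",
    condensation_Val = "C5H9NO",  condensation_Thr = "C4H7NO2",
    condensation_Cys = "C3H5NOS", condensation_LeuIle = "C6H11NO",
    condensation_Asn = "C4H6N2O2", condensation_Asp = "C4H5NO3",
    condensation_Gln = "C5H8N2O2", condensation_Lys = "C6H12N2O",
    condensation_Glu = "C5H7NO3", condensation_Met = "C5H9NOS",
    condensation_His = "C6H7N3O", condensation_Phe = "C9H9NO",
    condensation_Arg = "C6H12N4O", condensation_Tyr = "C9H9NO2",
    condensation_Trp = "C11H10N2O"
  )
  all <- c(core, aa)
  reaction_library(names(all), unname(all))
}

#' Read a user reaction library from TSV
#'
#' Expects columns `name` and `delta_formula`; `mass_delta` is recomputed from
#' the formula, so a stale column in the file cannot drift from the chemistry.
#'
#' @param path Path to the TSV.
#' @return A [reaction_library()].
#' @export
read_reaction_library <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("name", "delta_formula") %in% names(df))) {
    stop("reaction library TSV needs columns name, delta_formula")
  }
  reaction_library(df$name, df$delta_formula)
}

#' Write a reaction library to TSV
#'
#' @param library A [reaction_library()].
#' @param path Output path.
#' @export
write_reaction_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
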