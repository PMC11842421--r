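# Monoisotopic mass arithmetic: formula parsing, adduct m/z, ppm errors.
# All adduct arithmetic in the package goes through adduct_mz().

# IUPAC monoisotopic atomic masses (Da), >= 6 decimals.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.98976928,
  K  = 38.96370668,
  Cl = 34.96885268
)

#' Mass of the proton (Da), used for protonation/deprotonation adducts
#' @keywords internal
PROTON_MASS <- 1.007276

.ELECTRON_MASS <- 0.00054858

#' Monoisotopic mass of a molecular formula
#'
#' Sums standard monoisotopic atomic masses over the elements
#' C, H, N, O, P, S, Na, K, Cl. An empty formula has mass 0.
#'
#' @param formula Character scalar, e.g. `"C10H12N2O"` (cotinine).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C10H12N2O")  # cotinine, 176.094963
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- gsub("[[:space:]]", "", formula)
  if (!nzchar(formula)) return(0)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (paste(toks, collapse = "") != formula) {
    stop("unparseable formula: '", formula, "'")
  }
  total <- 0
  for (tok in toks) {
    elem <- sub("[0-9]*$", "", tok)
    nstr <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    if (!elem %in% names(.ATOMIC_MASS)) {
      stop("unknown element symbol '", elem, "' in formula '", formula, "'")
    }
    total <- total + .ATOMIC_MASS[[elem]] * n
  }
  total
}

# Singly charged ESI adducts supported per ionization mode. `delta` is the
# shift added to the neutral monoisotopic mass to obtain the ion m/z.
# "M+" covers permanently charged cations (e.g. acetylcholine): the ion is
# the formula itself minus one electron.
.ADDUCT_TABLE <- local({
  h2o <- 2 * 1.00782503207 + 15.9949146196
  nh4 <- 14.0030740048 + 4 * 1.00782503207 - 0.00054858
  data.frame(
    adduct = c("M+H", "M+Na", "M+NH4", "M+H-H2O", "M+",
               "M-H", "M+Cl", "M-H2O-H"),
    mode = c(rep("HILIC_pos", 5), rep("C18_neg", 3)),
    delta = c(1.007276,
              22.98976928 - 0.00054858,
              nh4,
              1.007276 - h2o,
              -0.00054858,
              -1.007276,
              34.96885268 + 0.00054858,
              -h2o - 1.007276),
    stringsAsFactors = FALSE
  )
})

#' Adducts available in an ionization mode
#' @param mode `"HILIC_pos"` or `"C18_neg"`.
#' @return Character vector of adduct names.
#' @export
mode_adducts <- function(mode) {
  mode <- match.arg(mode, c("HILIC_pos", "C18_neg"))
  .ADDUCT_TABLE$adduct[.ADDUCT_TABLE$mode == mode]
}

#' Theoretical m/z of an adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass (Da); vectorized.
#' @param adduct Adduct name, e.g. `"M+H"`, `"M-H"`, `"M+H-H2O"`.
#' @param mode Ionization mode the adduct must belong to.
#' @return Theoretical m/z.
#' @examples
#' adduct_mz(monoisotopic_mass("C10H12N2O"), "M+H", "HILIC_pos") # 177.1022
#' @export
adduct_mz <- function(neutral_mass, adduct, mode) {
  mode <- match.arg(mode, c("HILIC_pos", "C18_neg"))
  i <- which(.ADDUCT_TABLE$adduct == adduct & .ADDUCT_TABLE$mode == mode)
  if (length(i) != 1L) {
    stop("adduct '", adduct, "' is not defined for mode '", mode, "'")
  }
  neutral_mass + .ADDUCT_TABLE$delta[i]
}

#' Signed mass error in parts per million
#'
#' Defined as `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical m/z values; vectorized.
#' @export
ppm_error <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}
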