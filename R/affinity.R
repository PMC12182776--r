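# Contact-based binding-affinity estimation and Kd conversion.

#' Gas constant in kcal/(mol K)
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

# Default coefficients: the published contact-based linear model of
# Vangone & Bonvin (2015), in kcal/mol per contact or per NIS percent.
.DEFAULT_AFFINITY_COEFS <- c(
  "charged-charged" = -0.09459,
  "apolar-charged"  = -0.10007,
  "charged-polar"   =  0.0,
  "polar-polar"     =  0.19577,
  "apolar-polar"    = -0.22671,
  "apolar-apolar"   =  0.0,
  "nis_apolar"      =  0.18681,
  "nis_charged"     =  0.13810)

#' Affinity-model configuration
#'
#' The binding free energy is a configurable linear combination of typed
#' intermolecular contact counts and non-interacting-surface percentages
#' plus an intercept. Defaults are the published contact-based model
#' coefficients; any coefficient set covering the encountered terms can be
#' supplied.
#'
#' @param coefficients named numeric vector: weights for the six unordered
#'   class pairs (`"charged-charged"`, ..., `"apolar-apolar"`) and the two
#'   surface terms `"nis_apolar"`, `"nis_charged"`.
#' @param intercept model intercept in kcal/mol.
#' @param temperature Kelvin (default 298.15, i.e. 25 C).
#' @return a list of class `affinity_config`.
#' @export
affinity_config <- function(coefficients = .DEFAULT_AFFINITY_COEFS,
                            intercept = -15.9433,
                            temperature = 298.15) {
  stopifnot(temperature > 0, is.numeric(coefficients),
            !is.null(names(coefficients)))
  structure(list(coefficients = coefficients, intercept = intercept,
                 temperature = temperature), class = "affinity_config")
}

#' Predict binding free energy from typed contacts
#'
#' @param contacts output of [intermolecular_contacts()] (computed at the
#'   intermolecular-contact cutoff).
#' @param nis named vector `c(apolar = %, charged = %)` from
#'   [nis_fractions()], or `NULL` to drop the surface terms.
#' @param config an [affinity_config()].
#' @return list of class `affinity_estimate`: `dG` (kcal/mol), `Kd`
#'   (molar, at the configured temperature), `term_breakdown` (named
#'   contributions summing with the intercept to `dG` exactly) and
#'   `counts` (the class-pair contact counts used).
#' @export
predict_dG <- function(contacts, nis = NULL,
                       config = affinity_config()) {
  stopifnot(inherits(config, "affinity_config"))
  counts <- contact_class_summary(contacts)$by_pair
  terms <- setNames(numeric(0), character(0))
  for (nm in names(counts)) {
    if (counts[[nm]] == 0) next
    if (!nm %in% names(config$coefficients))
      stop("no coefficient configured for contact term: ", nm)
    terms[nm] <- counts[[nm]] * config$coefficients[[nm]]
  }
  if (!is.null(nis)) {
    for (nm in c("apolar", "charged")) {
      cf <- paste0("nis_", nm)
      if (!cf %in% names(config$coefficients))
        stop("no coefficient configured for surface term: ", cf)
      terms[cf] <- nis[[nm]] * config$coefficients[[cf]]
    }
  }
  dG <- config$intercept + sum(terms)
  structure(list(dG = dG,
                 Kd = dG_to_Kd(dG, config$temperature),
                 term_breakdown = terms,
                 intercept = config$intercept,
                 counts = counts), class = "affinity_estimate")
}

#' Convert binding free energy to a dissociation constant
#'
#' `Kd = exp(dG / (R T))` with R in kcal/(mol K); at 298.15 K a dG of
#' about -12.3 kcal/mol corresponds to nanomolar affinity.
#'
#' @param dG binding free energy in kcal/mol.
#' @param temperature Kelvin (default 298.15).
#' @return dissociation constant in molar.
#' @export
dG_to_Kd <- function(dG, temperature = 298.15) {
  stopifnot(temperature > 0)
  if (any(!is.finite(dG))) stop("non-finite dG")
  exp(dG / (GAS_CONSTANT_KCAL * temperature))
}

#' Convert a dissociation constant to binding free energy
#' @param Kd dissociation constant in molar (positive).
#' @param temperature Kelvin (default 298.15).
#' @return dG in kcal/mol.
#' @export
Kd_to_dG <- function(Kd, temperature = 298.15) {
  stopifnot(temperature > 0)
  if (any(!is.finite(Kd) | Kd <= 0)) stop("Kd must be positive and finite")
  GAS_CONSTANT_KCAL * temperature * log(Kd)
}

#' Pearson correlation and its square
#'
#' Used to relate predicted binding energy to contact counts and docking
#' scores across a report collection. Zero-variance input yields an
#' explicit undefined result (`NA` with a warning) rather than NaN
#' propagation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r` and `r2`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, r2 = NA_real_))
  }
  r <- cor(x, y)
  list(r = r, r2 = r^2)
}
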