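# 511 keV photon cross sections for the phantom and detector materials.
#
# Each material is anchored by its incoherent (Compton) and photoelectric
# linear attenuation coefficients at 511 keV, derived from standard
# photon cross-section tabulations (XCOM); coherent (Rayleigh) scattering
# is not modelled. Energy dependence over the tracked range
# (~150-511 keV) uses the total Klein-Nishina cross-section ratio for the
# incoherent part and a (511/E)^3 scaling for the photoelectric part.

.MATERIALS <- data.frame(
  material = c("air", "water", "polyethylene", "aluminum", "BGO", "LSO"),
  density = c(0.001205, 1.000, 0.960, 2.699, 7.130, 7.400),      # g/cm^3
  muInc511 = c(1.04e-4, 0.0959, 0.0946, 0.2246, 0.518, 0.547),   # 1/cm
  muPe511 = c(1.0e-8, 2.0e-5, 1.0e-5, 3.0e-4, 0.407, 0.284),     # 1/cm
  # photoelectric energy exponent: tau ~ (511/E)^n; ~3 for low-Z, ~2.5
  # fits the XCOM slope for Bi/Lu compounds over 150-511 keV
  muPeExp = c(3, 3, 3, 3, 2.5, 2.5),
  stringsAsFactors = FALSE)

#' Material table at 511 keV
#'
#' Linear attenuation coefficients (1/cm, coherent scattering excluded)
#' and the Compton branching fraction at 511 keV for the materials used
#' by the phantom scenes and detectors.
#'
#' @return data.frame with columns `material`, `density` (g/cm^3),
#'   `mu511` (total, 1/cm), `muInc511`, `muPe511` and
#'   `comptonFraction511`.
#' @examples
#' materialTable()
#' @export
materialTable <- function() {
  m <- .MATERIALS
  m$mu511 <- m$muInc511 + m$muPe511
  m$comptonFraction511 <- m$muInc511 / m$mu511
  m[, c("material", "density", "mu511", "muInc511", "muPe511",
        "comptonFraction511")]
}

# ratio of the total Klein-Nishina cross section at E to its 511 keV value
.knRatio <- function(energyKeV) {
  kn <- function(a) {
    l <- log(1 + 2 * a)
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - l / a) + l / (2 * a) -
      (1 + 3 * a) / (1 + 2 * a)^2
  }
  kn(energyKeV / 511) / kn(1)
}

#' Attenuation coefficient of a material at a given energy
#'
#' @param material material id, see [materialTable()]
#' @param energyKeV photon energy in keV
#' @return total linear attenuation coefficient, 1/cm
#' @examples
#' muAt("water", 511)
#' @export
muAt <- function(material, energyKeV) {
  i <- match(material, .MATERIALS$material)
  if (anyNA(i)) stop("unknown material: ", material[is.na(i)][1])
  .MATERIALS$muInc511[i] * .knRatio(energyKeV) +
    .MATERIALS$muPe511[i] * (511 / energyKeV)^.MATERIALS$muPeExp[i]
}

#' @rdname muAt
#' @return for `comptonFractionAt`, the probability that an interaction
#'   at this energy is Compton scattering rather than photoelectric
#'   absorption
#' @export
comptonFractionAt <- function(material, energyKeV) {
  i <- match(material, .MATERIALS$material)
  if (anyNA(i)) stop("unknown material: ", material[is.na(i)][1])
  inc <- .MATERIALS$muInc511[i] * .knRatio(energyKeV)
  pe <- .MATERIALS$muPe511[i] * (511 / energyKeV)^.MATERIALS$muPeExp[i]
  inc / (inc + pe)
}

# internal: coefficient vectors in 1/mm for the C++ kernels
.materialsCpp <- function() {
  list(muInc = .MATERIALS$muInc511 / 10,
       muPe = .MATERIALS$muPe511 / 10,
       muPeExp = .MATERIALS$muPeExp,
       names = .MATERIALS$material,
       background = match("air", .MATERIALS$material) - 1L)
}

.materialIndex <- function(material) {
  i <- match(material, .MATERIALS$material)
  if (anyNA(i)) stop("unknown material: ", material[is.na(i)][1])
  i - 1L
}
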