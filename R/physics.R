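# Isotope and Cerenkov physics primitives underpinning the simulator.

.MEC2 <- 510.99895    # electron rest energy, keV
.FINE <- 1 / 137.035999084

#' Load the isotope registry
#'
#' Reads the human-editable YAML isotope registry shipped with the package
#' (or a user-supplied file of the same layout) into a list of
#' [Isotope-class] objects.
#'
#' @param path path to a registry YAML file; defaults to the shipped registry
#'   (Ga-68, F-18, Zr-89, Y-90)
#' @return named list of [Isotope-class] objects
#' @examples
#' names(isotopeRegistry())
#' @export
isotopeRegistry <- function(path = system.file("extdata", "isotopes.yaml",
                                               package = "cliMargin")) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$isotopes))
    stop("registry file has no 'isotopes' key: ", path)
  isos <- lapply(raw$isotopes, function(x) {
    new("Isotope", name = x$name, halfLife = x$half_life_min,
        endpointEnergy = x$endpoint_keV,
        meanPositronRange = x$mean_positron_range_mm,
        branchingFraction = x$branching_beta,
        daughterZ = x$daughter_Z, particle = x$particle)
  })
  names(isos) <- vapply(isos, function(i) i@name, character(1))
  isos
}

#' Look up an isotope by name
#'
#' @param name isotope label, e.g. "Ga-68"
#' @param registry a registry list from [isotopeRegistry()]
#' @return an [Isotope-class]
#' @examples
#' getIsotope("Ga-68")
#' @export
getIsotope <- function(name, registry = isotopeRegistry()) {
  if (!name %in% names(registry))
    stop("unknown isotope '", name, "'; registry has: ",
         paste(names(registry), collapse = ", "))
  registry[[name]]
}

#' Construct an optical band
#'
#' @param lower,upper wavelength bounds (nm), 0 < lower < upper
#' @param muEff effective tissue attenuation coefficient (cm^-1)
#' @return an [OpticalBand-class]
#' @examples
#' opticalBand(400, 550, muEff = 10)
#' @export
opticalBand <- function(lower, upper, muEff) {
  new("OpticalBand", lower = lower, upper = upper, muEff = muEff)
}

#' Default optical bands
#'
#' `unfilteredBand()` is the full detected Cerenkov band (400-800 nm) with a
#' soft-tissue effective attenuation of 2 cm^-1 (transmission through tissue
#' is dominated by the weakly attenuated red end). `shortpassBand()` is the
#' sub-550 nm band passed by the 550 nm shortpass filter, with a much larger
#' effective attenuation of 10 cm^-1. Both coefficients are order-of-
#' magnitude soft-tissue configuration values, not calibrated ground truth;
#' only their ordering (sub-550 attenuates faster) carries scientific weight.
#'
#' @return an [OpticalBand-class]
#' @export
unfilteredBand <- function() opticalBand(400, 800, muEff = 2)

#' @rdname unfilteredBand
#' @export
shortpassBand <- function() opticalBand(400, 550, muEff = 10)

# relative number of Cerenkov photons (1/lambda^2 spectrum) emitted in
# `band` per photon emitted in `reference`
.bandPhotonWeight <- function(band, reference) {
  (1 / band@lower - 1 / band@upper) /
    (1 / reference@lower - 1 / reference@upper)
}

#' Allowed-shape beta decay spectrum
#'
#' Builds the kinetic-energy probability density of the emitted beta
#' particle under the allowed-transition approximation,
#' `dN/dE ~ F(Z, E) p W (Q - E)^2`, with `p` and `W` the particle momentum
#' and total energy and `F` the non-relativistic Fermi function
#' `F = 2 pi eta / (1 - exp(-2 pi eta))`, `eta = +/- Z alpha / beta` (plus
#' for electron emission, minus for positrons, whose low-energy emission is
#' Coulomb-suppressed). The density is normalized to unit area on
#' `[0, endpoint]` and is exactly zero above the endpoint.
#'
#' @param isotope an [Isotope-class]
#' @param gridResolution energy grid spacing (keV), > 0
#' @return a [BetaSpectrum-class]
#' @examples
#' sp <- betaSpectrum(getIsotope("Ga-68"))
#' meanBetaEnergy(sp)
#' @export
betaSpectrum <- function(isotope, gridResolution = 1) {
  stopifnot(is(isotope, "Isotope"))
  if (gridResolution <= 0) stop("gridResolution must be > 0")
  q <- isotope@endpointEnergy
  grid <- seq(0, q, by = gridResolution)
  if (grid[length(grid)] < q) grid <- c(grid, q)
  dens <- .betaShape(grid, q, isotope@daughterZ, isotope@particle)
  area <- .trapz(grid, dens)
  new("BetaSpectrum", energy = grid, density = dens / area,
      isotope = isotope@name)
}

# unnormalized allowed shape with non-relativistic Fermi correction
.betaShape <- function(energy, endpoint, daughterZ, particle) {
  w <- (energy + .MEC2) / .MEC2            # total energy, units of me c^2
  p <- sqrt(pmax(w^2 - 1, 0))              # momentum, units of me c
  beta <- ifelse(w > 1, p / w, 0)
  eta <- ifelse(beta > 0,
                (if (particle == "beta+") -1 else 1) * daughterZ * .FINE / beta,
                0)
  fermi <- ifelse(beta > 0,
                  2 * pi * eta / (1 - exp(-2 * pi * eta)), 0)
  s <- fermi * p * w * (endpoint - energy)^2
  s[energy >= endpoint] <- 0
  s[energy <= 0] <- 0
  s
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Mean beta kinetic energy of a spectrum
#'
#' @param spectrum a [BetaSpectrum-class]
#' @return mean kinetic energy (keV)
#' @export
meanBetaEnergy <- function(spectrum) {
  .trapz(spectrum@energy, spectrum@energy * spectrum@density)
}

#' Cerenkov threshold kinetic energy
#'
#' Kinetic energy at which a charged particle's speed equals the phase
#' velocity of light in a medium of refractive index `n`
#' (`beta n = 1`): `E_th = m_e c^2 (1/sqrt(1 - n^-2) - 1)`.
#'
#' @param refractiveIndex refractive index, > 1
#' @return threshold kinetic energy (keV)
#' @examples
#' cerenkovThresholdEnergy(1.33)  # ~264 keV in water
#' @export
cerenkovThresholdEnergy <- function(refractiveIndex) {
  if (any(refractiveIndex <= 1))
    stop("refractiveIndex must be > 1 (no Cerenkov emission otherwise)")
  .MEC2 * (1 / sqrt(1 - refractiveIndex^-2) - 1)
}

#' Collision stopping power of water for electrons/positrons
#'
#' Log-log interpolation of a compact tabulation of the collision stopping
#' power of liquid water (unit density) between 10 keV and 3 MeV, returned
#' in keV/cm. This is the default continuous-slowing-down model of
#' [cerenkovYield()]; any function with the same signature may replace it.
#'
#' @param energy kinetic energy (keV); values below 10 keV are clamped
#'   (sub-threshold energies never contribute to Cerenkov yield)
#' @return stopping power (keV/cm)
#' @export
waterStoppingPower <- function(energy) {
  tab_e <- c(10, 20, 30, 40, 50, 60, 80, 100, 150, 200, 300, 400,
             500, 600, 800, 1000, 1500, 2000, 3000)
  tab_s <- c(22.56, 13.17, 9.653, 7.777, 6.603, 5.797, 4.757, 4.115,
             3.238, 2.793, 2.355, 2.148, 2.034, 1.963, 1.886, 1.849,
             1.822, 1.824, 1.846) * 1000   # MeV cm2/g -> keV/cm at 1 g/cm3
  e <- pmin(pmax(energy, tab_e[1]), tab_e[length(tab_e)])
  exp(stats::approx(log(tab_e), log(tab_s), xout = log(e))$y)
}

#' Monte-Carlo Frank-Tamm Cerenkov photon yield per decay
#'
#' Expected number of Cerenkov photons emitted in an optical band per decay,
#' under the continuous-slowing-down approximation: initial beta energies
#' are drawn from the decay spectrum and each particle's photon number is
#' the Frank-Tamm emission integrated along its slowing-down path,
#' `N(E0) = int_{E_th}^{E0} 2 pi alpha (1/lambda1 - 1/lambda2)
#' (1 - 1/(beta^2 n^2)) / S(E) dE`, with `S` the stopping power. The result
#' is scaled by the beta branching fraction and is reproducible given
#' `seed`.
#'
#' @param spectrum a [BetaSpectrum-class]
#' @param refractiveIndex medium refractive index (> 1); 1.33 (water) by
#'   default
#' @param band an [OpticalBand-class]; only its wavelength bounds are used
#' @param nSamples number of Monte-Carlo beta particles (>= 1)
#' @param seed integer seed; the caller's RNG stream is left untouched
#' @param stoppingPower function(keV) -> keV/cm; default
#'   [waterStoppingPower()]
#' @param branchingFraction beta branching fraction multiplying the yield
#' @return photons per decay (numeric scalar) with attributes `se`
#'   (Monte-Carlo standard error) and `nSamples`
#' @examples
#' ga <- betaSpectrum(getIsotope("Ga-68"))
#' cerenkovYield(ga, band = opticalBand(400, 800, 0), nSamples = 1e4, seed = 1)
#' @export
cerenkovYield <- function(spectrum, refractiveIndex = 1.33, band,
                          nSamples = 1e5, seed = 1,
                          stoppingPower = waterStoppingPower,
                          branchingFraction = 1) {
  stopifnot(is(spectrum, "BetaSpectrum"), is(band, "OpticalBand"),
            nSamples >= 1)
  eth <- cerenkovThresholdEnergy(refractiveIndex)
  emax <- max(spectrum@energy)
  kband <- 2 * pi * .FINE * (1 / (band@lower * 1e-7) - 1 / (band@upper * 1e-7))
  if (emax <= eth) {
    out <- 0
    attr(out, "se") <- 0
    attr(out, "nSamples") <- nSamples
    return(out)
  }
  # cumulative photon number N(E0) on a fine energy grid above threshold
  eg <- seq(eth, emax, length.out = 4096L)
  w <- (eg + .MEC2) / .MEC2
  beta2 <- 1 - 1 / w^2
  integrand <- kband * pmax(1 - 1 / (beta2 * refractiveIndex^2), 0) /
    stoppingPower(eg)
  cumN <- c(0, cumsum(diff(eg) * (integrand[-1] + integrand[-length(eg)]) / 2))
  # draw initial energies from the spectrum (grid-point sampling)
  prob <- spectrum@density
  e0 <- .withSeed(seed,
                  sample(spectrum@energy, nSamples, replace = TRUE, prob = prob))
  n0 <- ifelse(e0 <= eth, 0,
               stats::approx(eg, cumN, xout = pmin(e0, emax))$y)
  yield <- branchingFraction * mean(n0)
  out <- yield
  attr(out, "se") <- branchingFraction * stats::sd(n0) / sqrt(nSamples)
  attr(out, "nSamples") <- nSamples
  out
}

#' Radioactive decay factor
#'
#' Fraction of activity remaining after `elapsed` minutes:
#' `2^(-elapsed / halfLife)`.
#'
#' @param elapsed elapsed time (minutes)
#' @param halfLife isotope half-life (minutes), > 0
#' @return dimensionless decay factor (vectorized over `elapsed`)
#' @examples
#' decayFactor(68, 68)   # 0.5
#' @export
decayFactor <- function(elapsed, halfLife) {
  if (any(halfLife <= 0)) stop("halfLife must be > 0")
  2^(-elapsed / halfLife)
}

#' Optical transmission of tissue at depth
#'
#' Beer-Lambert transmission `exp(-mu_eff d)` of light in `band` emitted at
#' `depth` millimetres below the tissue surface.
#'
#' @param depth depth below the surface (mm), >= 0
#' @param band an [OpticalBand-class] carrying `muEff` (cm^-1)
#' @return transmission in (0, 1] (vectorized over `depth`)
#' @examples
#' tissueTransmission(3, shortpassBand())
#' @export
tissueTransmission <- function(depth, band) {
  stopifnot(is(band, "OpticalBand"))
  if (any(depth < 0)) stop("depth must be >= 0")
  exp(-band@muEff * depth / 10)   # depth mm -> cm
}
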