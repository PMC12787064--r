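# Fixed unit system used package-wide: time in s, concentration in mol dm^-3 (M),
# path length in cm, incident photon flux in einstein dm^-3 s^-1, decadic
# absorbance (dimensionless). There is no unit-conversion layer.

.species_roles <- c(
  "reactant_X", "coreactant_Xprime", "product_Y",
  "product_Yprime", "product_Ydprime", "product_Ytprime"
)

.stop_domain <- function(msg) stop(msg, call. = FALSE)

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stop_domain(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) .stop_domain(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) .stop_domain(sprintf("'%s' must be >= 0", name))
  x
}

#' Irradiation setup
#'
#' Describes the continuous, monochromatic, collimated irradiation geometry:
#' the irradiation wavelength, the incident photon flux delivered to the
#' reactor, and the optical path lengths of the irradiation and the
#' (spectrophotometric) observation beams.
#'
#' @param lambda_irr Irradiation wavelength (nm), > 0.
#' @param P0 Incident photon flux (einstein dm^-3 s^-1), > 0.
#' @param l_irr Irradiation path length (cm), > 0.
#' @param l_obs Observation path length (cm), > 0; defaults to `l_irr`.
#' @param temperature_label Free-text temperature annotation, carried as
#'   metadata only (no temperature model is applied; the thermal rate constant
#'   is taken as given at the stated temperature).
#' @param V_irr,S_irr Optional irradiated volume (dm^3) and area (cm^2),
#'   metadata only: they are implicit in `P0`.
#'
#' @return An object of class `irradiation_setup`.
#' @examples
#' irradiation_setup(lambda_irr = 365, P0 = 1.2e-6, l_irr = 0.86, l_obs = 1)
#' @export
irradiation_setup <- function(lambda_irr, P0, l_irr, l_obs = l_irr,
                              temperature_label = NULL,
                              V_irr = NULL, S_irr = NULL) {
  structure(
    list(
      lambda_irr = .check_scalar(lambda_irr, "lambda_irr", positive = TRUE),
      P0 = .check_scalar(P0, "P0", positive = TRUE),
      l_irr = .check_scalar(l_irr, "l_irr", positive = TRUE),
      l_obs = .check_scalar(l_obs, "l_obs", positive = TRUE),
      temperature_label = temperature_label,
      V_irr = V_irr, S_irr = S_irr
    ),
    class = "irradiation_setup"
  )
}

#' @export
print.irradiation_setup <- function(x, ...) {
  cat(sprintf(
    "Irradiation setup: lambda = %g nm, P0 = %g einstein dm^-3 s^-1, l_irr = %g cm, l_obs = %g cm\n",
    x$lambda_irr, x$P0, x$l_irr, x$l_obs
  ))
  if (!is.null(x$temperature_label)) cat("  T:", x$temperature_label, "\n")
  invisible(x)
}

#' Species table
#'
#' Ordered table of the species of a reaction scheme: name, decadic
#' absorptivity at the irradiation wavelength, initial concentration, and the
#' role the species plays in the scheme. Exactly one species must carry the
#' role `reactant_X` (the light-absorbing reactant).
#'
#' @param name Character vector of species names (unique).
#' @param epsilon Decadic absorptivity at lambda_irr (M^-1 cm^-1), >= 0.
#' @param C0 Initial concentration (M), >= 0.
#' @param role One of `"reactant_X"`, `"coreactant_Xprime"`, `"product_Y"`,
#'   `"product_Yprime"`, `"product_Ydprime"`, `"product_Ytprime"`.
#'
#' @return A `data.frame` of class `species_table`.
#' @examples
#' species_table(
#'   name = c("X", "Xprime", "Yprime"),
#'   epsilon = c(7211, 0, 0),
#'   C0 = c(8.1e-6, 1.3e-4, 0),
#'   role = c("reactant_X", "coreactant_Xprime", "product_Yprime")
#' )
#' @export
species_table <- function(name, epsilon, C0, role) {
  n <- length(name)
  if (length(epsilon) != n || length(C0) != n || length(role) != n)
    .stop_domain("'name', 'epsilon', 'C0' and 'role' must have equal length")
  if (anyDuplicated(name)) .stop_domain("species names must be unique")
  if (!all(role %in% .species_roles))
    .stop_domain(paste0(
      "unknown role(s): ", paste(setdiff(role, .species_roles), collapse = ", "),
      "; allowed: ", paste(.species_roles, collapse = ", ")
    ))
  if (sum(role == "reactant_X") != 1L)
    .stop_domain("exactly one species must have role 'reactant_X'")
  if (any(!is.finite(epsilon)) || any(epsilon < 0))
    .stop_domain("all 'epsilon' must be finite and >= 0")
  if (any(!is.finite(C0)) || any(C0 < 0))
    .stop_domain("all 'C0' must be finite and >= 0")
  structure(
    data.frame(name = as.character(name), epsilon = as.numeric(epsilon),
               C0 = as.numeric(C0), role = as.character(role),
               stringsAsFactors = FALSE),
    class = c("species_table", "data.frame")
  )
}

#' Look up a species by role
#'
#' @param species A [species_table()].
#' @param role A single role string.
#' @return One-row data frame (errors if the role is absent),
#' @keywords internal
species_by_role <- function(species, role) {
  i <- which(species$role == role)
  if (length(i) == 0L)
    .stop_domain(sprintf("no species with role '%s' in the species table", role))
  species[i[1L], , drop = FALSE]
}

#' Reaction scheme specification
#'
#' Identifies one of the four bimolecular photoreaction topologies and its
#' constants:
#' \describe{
#'   \item{a}{X + hv -> X*; X* + X' -> Y' (photon-coupled thermal step, `k_bim`).}
#'   \item{b}{as (a) plus a concurrent direct photolysis X -> Y with quantum
#'     yield `phi_direct`.}
#'   \item{c}{direct photolysis X -> Y' + Y'' (quantum yield `phi_direct`),
#'     then a ground-state thermal step Y' + X' -> Y''' (`k_bim`).}
#'   \item{d}{X* + X -> Y (photodimerisation-type, `k_bim`).}
#' }
#'
#' Unit convention for `k_bim`: for the photon-coupled step of schemes a, b
#' and d the constant multiplies an absorbed-photon rate (einstein dm^-3
#' s^-1) and a concentration, so its unit is M^-1; for the ground-state
#' thermal step of scheme c it multiplies two concentrations, so dimensional
#' closure requires M^-1 s^-1. The object records the convention per scheme
#' and carries a note about the ambiguity rather than resolving it.
#'
#' @param scheme_id One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param k_bim Thermal bimolecular rate constant, >= 0 (units per scheme,
#'   see Details).
#' @param phi_direct Quantum yield of the direct photoprocess, in [0, 1].
#'   Required for schemes b and c; must be absent or zero for scheme a;
#'   unused for scheme d.
#'
#' @return An object of class `scheme_spec`.
#' @export
scheme_spec <- function(scheme_id, k_bim = 0, phi_direct = NULL) {
  if (!is.character(scheme_id) || length(scheme_id) != 1L ||
      !scheme_id %in% c("a", "b", "c", "d"))
    .stop_domain("'scheme_id' must be one of \"a\", \"b\", \"c\", \"d\"")
  k_bim <- .check_scalar(k_bim, "k_bim", nonneg = TRUE)
  if (is.null(phi_direct)) phi_direct <- 0
  phi_direct <- .check_scalar(phi_direct, "phi_direct", nonneg = TRUE)
  if (phi_direct > 1) .stop_domain("'phi_direct' must be <= 1")
  if (scheme_id == "a" && phi_direct != 0)
    .stop_domain("scheme 'a' has no direct photoprocess: 'phi_direct' must be absent or zero")
  if (scheme_id %in% c("b", "c") && phi_direct == 0 && k_bim == 0)
    .stop_domain(sprintf("scheme '%s' needs phi_direct > 0 and/or k_bim > 0", scheme_id))
  units <- if (scheme_id == "c") "M^-1 s^-1" else "M^-1"
  structure(
    list(
      scheme_id = scheme_id, k_bim = k_bim, phi_direct = phi_direct,
      k_bim_units = units,
      k_bim_units_note = paste(
        "k_bim of the photon-coupled step (schemes a, b, d) carries M^-1;",
        "the ground-state thermal step of scheme c requires M^-1 s^-1 for",
        "dimensional closure of its rate law. Both conventions are recorded",
        "per scheme; the literature prints M^-1 in both contexts."
      )
    ),
    class = "scheme_spec"
  )
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat(sprintf("Reaction scheme (%s): k_bim = %g %s, phi_direct = %g\n",
              x$scheme_id, x$k_bim, x$k_bim_units, x$phi_direct))
  invisible(x)
}

#' Absorbance state of the irradiated medium
#'
#' The reactant absorbance and the total medium absorbance, both decadic and
#' measured along the irradiation path length.
#'
#' @param A_X Reactant absorbance along `l_irr`, >= 0.
#' @param A_tot Total medium absorbance along `l_irr`, >= `A_X`.
#' @return An object of class `absorbance_state`.
#' @export
absorbance_state <- function(A_X, A_tot = A_X) {
  A_X <- .check_scalar(A_X, "A_X", nonneg = TRUE)
  A_tot <- .check_scalar(A_tot, "A_tot", nonneg = TRUE)
  if (A_X > A_tot)
    .stop_domain("invariant violation: A_X must not exceed A_tot")
  structure(list(A_X = A_X, A_tot = A_tot), class = "absorbance_state")
}

#' Photokinetic factor
#'
#' The dimensionless absorption-saturation factor
#' \deqn{PKF(A) = \frac{1 - 10^{-A}}{A}}
#' that multiplies the incident photon flux in the rate of light absorption.
#' It is continuous and strictly decreasing on `[0, Inf)`, bounded in
#' `(0, ln 10]`, with limit `ln 10` as the total absorbance tends to 0.
#'
#' Below a small-argument threshold (`1e-6`) a three-term series continuation
#' in `A ln 10` is used so the value is finite and continuous at `A = 0`;
#' above it, `1 - 10^{-A}` is evaluated with `expm1` for full precision.
#'
#' @param A_tot Total medium absorbance (decadic, dimensionless), >= 0.
#'   Vectorised.
#' @return The photokinetic factor (dimensionless), same length as `A_tot`.
#' @examples
#' photokinetic_factor(1)      # 0.9
#' photokinetic_factor(0)      # ln 10
#' @export
photokinetic_factor <- function(A_tot) {
  if (!is.numeric(A_tot) || any(!is.finite(A_tot)))
    .stop_domain("'A_tot' must be finite numeric")
  if (any(A_tot < 0))
    .stop_domain("'A_tot' must be >= 0 (absorbance is non-negative)")
  ln10 <- log(10)
  out <- numeric(length(A_tot))
  small <- A_tot <= 1e-6
  if (any(small)) {
    z <- A_tot[small] * ln10
    out[small] <- ln10 * (1 - z / 2 + z^2 / 6)
  }
  if (any(!small)) {
    A <- A_tot[!small]
    out[!small] <- -expm1(-A * ln10) / A
  }
  out
}

#' Rate of photon absorption by the reactant
#'
#' The fraction of the incident monochromatic photon flux absorbed by the
#' reactant X in a medium of total absorbance `A_tot`:
#' \deqn{P_a = A_X \, P_0 \, PKF(A_{tot})}
#' When X is the only absorber (`A_X = A_tot`) this reduces to
#' `P0 (1 - 10^{-A_X})`. The result is bounded by `P0` (the beam cannot
#' deposit more photons than it carries).
#'
#' @param state An [absorbance_state()].
#' @param setup An [irradiation_setup()].
#' @return Photon absorption rate (einstein dm^-3 s^-1).
#' @export
absorbed_photon_rate <- function(state, setup) {
  stopifnot(inherits(state, "absorbance_state"), inherits(setup, "irradiation_setup"))
  .pa_rate(state$A_X, state$A_tot, setup$P0)
}

# internal vectorised kernel, no class overhead (used in ODE right-hand sides)
.pa_rate <- function(A_X, A_tot, P0) {
  if (any(A_X > A_tot + 1e-15))
    .stop_domain("invariant violation: A_X must not exceed A_tot")
  A_X * P0 * photokinetic_factor(A_tot)
}

#' Beer-Lambert absorbance from concentration, and its inverse
#'
#' `absorbance_from_concentration` returns `A = epsilon * l * C`;
#' `concentration_from_absorbance` inverts it, requiring `epsilon * l > 0`
#' (a non-absorbing species has no concentration readout via absorbance).
#'
#' @param C Concentration (M), >= 0.
#' @param A Decadic absorbance, >= 0.
#' @param epsilon Decadic absorptivity (M^-1 cm^-1), >= 0.
#' @param l Path length (cm), >= 0.
#' @return Absorbance (dimensionless) or concentration (M). Vectorised in
#'   `C` / `A`.
#' @examples
#' absorbance_from_concentration(8.1e-6, 7211, 0.86)
#' @export
absorbance_from_concentration <- function(C, epsilon, l) {
  if (any(C < 0) || epsilon < 0 || l < 0)
    .stop_domain("'C', 'epsilon' and 'l' must be >= 0")
  epsilon * l * C
}

#' @rdname absorbance_from_concentration
#' @export
concentration_from_absorbance <- function(A, epsilon, l) {
  if (any(A < 0)) .stop_domain("'A' must be >= 0")
  if (epsilon * l <= 0)
    .stop_domain("epsilon * l must be > 0 to invert the Beer-Lambert relation")
  A / (epsilon * l)
}

#' Convert an observed absorbance to the irradiation path length
#'
#' A spectrophotometer measures along the observation path `l_obs`; the
#' kinetic equations need the absorbance along the irradiation path `l_irr`.
#' Assuming Beer-Lambert linearity on both paths, `A_irr = A_obs * l_irr /
#' l_obs`.
#'
#' @param A_obs Measured absorbance along `l_obs`, >= 0. Vectorised.
#' @param setup An [irradiation_setup()].
#' @return Absorbance along `l_irr`.
#' @export
convert_pathlength <- function(A_obs, setup) {
  stopifnot(inherits(setup, "irradiation_setup"))
  if (any(A_obs < 0)) .stop_domain("'A_obs' must be >= 0")
  A_obs * setup$l_irr / setup$l_obs
}

#' Total medium absorbance from a concentration vector
#'
#' Sums `epsilon * l_irr * C` over all species and isolates the reactant
#' term, returning an [absorbance_state()].
#'
#' @param species A [species_table()].
#' @param concentrations Named numeric vector of concentrations (M) covering
#'   every species in the table.
#' @param setup An [irradiation_setup()].
#' @return An [absorbance_state()].
#' @export
total_absorbance <- function(species, concentrations, setup) {
  stopifnot(inherits(species, "species_table"), inherits(setup, "irradiation_setup"))
  missing <- setdiff(species$name, names(concentrations))
  if (length(missing) > 0L)
    .stop_domain(paste0("missing concentration for species: ",
                        paste(missing, collapse = ", ")))
  C <- concentrations[species$name]
  if (any(!is.finite(C)))
    .stop_domain("concentrations must be finite for all listed species")
  terms <- species$epsilon * setup$l_irr * pmax(C, 0)
  A_X <- terms[species$role == "reactant_X"]
  absorbance_state(A_X = unname(A_X), A_tot = sum(terms))
}
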