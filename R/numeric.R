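# ODE right-hand sides for the four schemes and a self-contained classical
# fixed-step RK4 integrator with step-halving refinement (the integration
# method of record for the schemes whose rate laws admit no closed form).

#' Kinetic trace container
#'
#' A time grid with per-species concentration series, an optional reactant
#' absorbance series, and full provenance metadata (scheme, parameters,
#' generator, seed). The underlying object is a `data.frame` whose first
#' column is `t_s`; metadata live in the `"meta"` attribute.
#'
#' @param t Strictly increasing time grid (s).
#' @param conc Named list or data frame of concentration series (M), one per
#'   species. Values may dip to -1e-12 (numerical slack) and are clipped to
#'   0; anything more negative is an error.
#' @param A_X Optional reactant absorbance series (decadic, along `l_irr`).
#' @param meta Named list of provenance metadata. Must contain `generator`
#'   (one of `"analytic"`, `"rk4"`, `"synthetic"`); a `seed` entry is
#'   required when the generator is stochastic. Model traces (`analytic`,
#'   `rk4`) must be non-negative within a -1e-12 numerical slack (clipped to
#'   0); `synthetic` traces keep negative noisy values untouched so that
#'   fitting sees realistic measurement noise.
#' @return An object of class `kinetic_trace` (also a `data.frame`).
#' @export
kinetic_trace <- function(t, conc, A_X = NULL, meta = list()) {
  t <- as.numeric(t)
  if (length(t) < 1L || any(!is.finite(t)))
    .stop_domain("'t' must be a non-empty finite numeric grid")
  if (length(t) > 1L && any(diff(t) <= 0))
    .stop_domain("'t' must be strictly increasing")
  conc <- as.data.frame(conc, optional = TRUE)
  if (nrow(conc) != length(t))
    .stop_domain("concentration series must match the length of 't'")
  synthetic <- identical(meta$generator, "synthetic")
  for (nm in names(conc)) {
    v <- conc[[nm]]
    if (any(!is.finite(v))) .stop_domain(sprintf("non-finite values in series '%s'", nm))
    if (!synthetic) {
      if (any(v < -1e-12))
        .stop_domain(sprintf(
          "series '%s' has concentrations below the -1e-12 numerical slack (min %.3e)",
          nm, min(v)))
      conc[[nm]] <- pmax(v, 0)
    }
  }
  if (is.null(meta$generator) ||
      !meta$generator %in% c("analytic", "rk4", "synthetic"))
    .stop_domain("meta$generator must be one of 'analytic', 'rk4', 'synthetic'")
  df <- cbind(data.frame(t_s = t), conc)
  if (!is.null(A_X)) {
    if (length(A_X) != length(t))
      .stop_domain("'A_X' must match the length of 't'")
    df$A_X <- as.numeric(A_X)
  }
  structure(df, meta = meta, class = c("kinetic_trace", "data.frame"))
}

#' @rdname kinetic_trace
#' @param trace A `kinetic_trace`.
#' @export
trace_meta <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  attr(trace, "meta")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Kinetic trace: %d points, t in [%g, %g] s, scheme %s, generator %s\n",
              nrow(x), x$t_s[1], x$t_s[nrow(x)],
              if (is.null(m$scheme)) "?" else m$scheme, m$generator))
  cat("  columns:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# ---- species bookkeeping -----------------------------------------------

.scheme_roles <- list(
  a = c("reactant_X", "coreactant_Xprime", "product_Yprime"),
  b = c("reactant_X", "coreactant_Xprime", "product_Y", "product_Yprime"),
  c = c("reactant_X", "coreactant_Xprime", "product_Yprime",
        "product_Ydprime", "product_Ytprime"),
  d = c("reactant_X", "product_Y")
)

#' Default species table for a scheme
#'
#' Builds a [species_table()] with the canonical species of the given scheme
#' (named `X`, `Xprime`, `Y`, `Yprime`, `Ydprime`, `Ytprime` as applicable),
#' all products starting at zero concentration and only the reactant
#' absorbing (conditions under which the closed forms hold).
#'
#' @param scheme_id One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param C_X0 Initial reactant concentration (M).
#' @param C_Xprime0 Initial co-reactant concentration (M); ignored for
#'   scheme d, which has no co-reactant.
#' @param epsilon_X Reactant absorptivity (M^-1 cm^-1).
#' @return A [species_table()].
#' @export
default_species <- function(scheme_id, C_X0, C_Xprime0 = 0, epsilon_X) {
  roles <- .scheme_roles[[scheme_id]]
  if (is.null(roles)) .stop_domain("'scheme_id' must be one of \"a\", \"b\", \"c\", \"d\"")
  nm <- c(reactant_X = "X", coreactant_Xprime = "Xprime", product_Y = "Y",
          product_Yprime = "Yprime", product_Ydprime = "Ydprime",
          product_Ytprime = "Ytprime")[roles]
  C0 <- ifelse(roles == "reactant_X", C_X0,
               ifelse(roles == "coreactant_Xprime", C_Xprime0, 0))
  species_table(name = unname(nm),
                epsilon = ifelse(roles == "reactant_X", epsilon_X, 0),
                C0 = C0, role = roles)
}

.role_name <- function(species, role) species_by_role(species, role)$name

.require_scheme_species <- function(scheme, species) {
  need <- .scheme_roles[[scheme$scheme_id]]
  have <- species$role
  miss <- setdiff(need, have)
  if (length(miss) > 0L)
    .stop_domain(sprintf("scheme '%s' requires species with roles: %s",
                         scheme$scheme_id, paste(miss, collapse = ", ")))
  invisible(TRUE)
}

# ---- right-hand sides ---------------------------------------------------

#' Simplified rate law (conditions i-iv) for a scheme
#'
#' Time derivatives of the species concentrations under the solvable-case
#' conditions: only X absorbs, monochromatic collimated light, absorbance
#' within the linearity range, and (schemes a-c) co-reactant in large excess
#' so that its concentration is frozen at `C_Xprime0`.
#'
#' @param state Named numeric vector of concentrations (M), covering every
#'   species of the scheme (the frozen co-reactant entry is accepted but its
#'   derivative is reported as 0 for schemes a and b; for scheme c it
#'   depletes through the thermal step only in the general model, not here).
#' @param scheme A [scheme_spec()].
#' @param species A [species_table()].
#' @param setup An [irradiation_setup()].
#' @return Named vector of derivatives (M s^-1).
#' @export
rhs_simplified <- function(state, scheme, species, setup) {
  stopifnot(inherits(scheme, "scheme_spec"), inherits(species, "species_table"),
            inherits(setup, "irradiation_setup"))
  .require_scheme_species(scheme, species)
  if (any(state < -1e-12)) .stop_domain("concentrations must be >= 0")
  sX <- species_by_role(species, "reactant_X")
  el <- sX$epsilon * setup$l_irr
  C_X <- state[[sX$name]]
  fX <- -expm1(-el * C_X * log(10)) # 1 - 10^(-A_X)
  d <- setNames(numeric(length(state)), names(state))
  id <- scheme$scheme_id
  P0 <- setup$P0
  if (id %in% c("a", "b")) {
    CXp0 <- species_by_role(species, "coreactant_Xprime")$C0
    v_bim <- scheme$k_bim * CXp0 * P0 * fX
    v_phi <- if (id == "b") scheme$phi_direct * P0 * fX else 0
    d[[sX$name]] <- -(v_bim + v_phi)
    d[[.role_name(species, "product_Yprime")]] <- v_bim
    if (id == "b") d[[.role_name(species, "product_Y")]] <- v_phi
  } else if (id == "c") {
    CXp0 <- species_by_role(species, "coreactant_Xprime")$C0
    nYp <- .role_name(species, "product_Yprime")
    v_phi <- scheme$phi_direct * P0 * fX
    v_th <- scheme$k_bim * CXp0 * state[[nYp]]
    d[[sX$name]] <- -v_phi
    d[[.role_name(species, "product_Ydprime")]] <- v_phi
    d[[nYp]] <- v_phi - v_th
    d[[.role_name(species, "product_Ytprime")]] <- v_th
  } else { # d
    v <- scheme$k_bim * P0 * fX * C_X
    d[[sX$name]] <- -v
    d[[.role_name(species, "product_Y")]] <- v
  }
  d
}

#' General (non-simplified) rate law for a scheme
#'
#' As [rhs_simplified()] but without conditions (i) and (iv): every species
#' absorbs according to its own absorptivity (the photon absorption rate of X
#' uses the full multi-species total absorbance and the photokinetic factor),
#' and the co-reactant X' depletes stoichiometrically instead of being frozen
#' at its initial value. With only X absorbing and X' in vast excess the
#' derivatives approach those of the simplified law.
#'
#' @inheritParams rhs_simplified
#' @return Named vector of derivatives (M s^-1).
#' @export
rhs_general <- function(state, scheme, species, setup) {
  stopifnot(inherits(scheme, "scheme_spec"), inherits(species, "species_table"),
            inherits(setup, "irradiation_setup"))
  .require_scheme_species(scheme, species)
  if (any(state < -1e-12)) .stop_domain("concentrations must be >= 0")
  terms <- species$epsilon * setup$l_irr * pmax(state[species$name], 0)
  A_X <- unname(terms[species$role == "reactant_X"])
  Pa <- .pa_rate(A_X, sum(terms), setup$P0)
  sXn <- .role_name(species, "reactant_X")
  d <- setNames(numeric(length(state)), names(state))
  id <- scheme$scheme_id
  if (id %in% c("a", "b")) {
    nXp <- .role_name(species, "coreactant_Xprime")
    v_bim <- scheme$k_bim * Pa * state[[nXp]]
    v_phi <- if (id == "b") scheme$phi_direct * Pa else 0
    d[[sXn]] <- -(v_bim + v_phi)
    d[[nXp]] <- -v_bim
    d[[.role_name(species, "product_Yprime")]] <- v_bim
    if (id == "b") d[[.role_name(species, "product_Y")]] <- v_phi
  } else if (id == "c") {
    nXp <- .role_name(species, "coreactant_Xprime")
    nYp <- .role_name(species, "product_Yprime")
    v_phi <- scheme$phi_direct * Pa
    v_th <- scheme$k_bim * state[[nXp]] * state[[nYp]]
    d[[sXn]] <- -v_phi
    d[[.role_name(species, "product_Ydprime")]] <- v_phi
    d[[nYp]] <- v_phi - v_th
    d[[nXp]] <- -v_th
    d[[.role_name(species, "product_Ytprime")]] <- v_th
  } else { # d
    v <- scheme$k_bim * Pa * state[[sXn]]
    d[[sXn]] <- -v
    d[[.role_name(species, "product_Y")]] <- v
  }
  d
}

# ---- RK4 integrator -----------------------------------------------------

# one classical RK4 pass over t_grid with `substeps` equal substeps per interval
.rk4_path <- function(rhs, y0, t_grid, substeps) {
  n <- length(t_grid)
  Y <- matrix(0, n, length(y0))
  Y[1, ] <- y0
  y <- y0
  for (i in seq_len(n - 1L)) {
    h <- (t_grid[i + 1L] - t_grid[i]) / substeps
    tt <- t_grid[i]
    for (s in seq_len(substeps)) {
      k1 <- rhs(tt, y)
      k2 <- rhs(tt + h / 2, y + (h / 2) * k1)
      k3 <- rhs(tt + h / 2, y + (h / 2) * k2)
      k4 <- rhs(tt + h, y + h * k3)
      y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + h
    }
    Y[i + 1L, ] <- y
  }
  Y
}

#' Integrate a reaction scheme by classical fixed-step RK4
#'
#' Fourth-order Runge-Kutta integration of the simplified or general rate
#' law over a user-supplied time grid, with automatic step refinement: the
#' number of equal substeps per grid interval is doubled until halving the
#' step changes the final state by less than `rel_tol` relative to the
#' initial-concentration scale. The achieved step-halving error is recorded
#' in the trace metadata (`self_consistency`), and serves downstream as the
#' integrator's self-consistency floor when judging model misfit.
#'
#' For schemes a and b the integration state is the reactant absorbance (the
#' natural variable of their rate laws); concentrations are derived after the
#' fact. Concentrations that undershoot 0 by less than 1e-12 are clipped;
#' larger undershoots raise an error (they would signal an integrator bug,
#' not chemistry).
#'
#' @param scheme A [scheme_spec()].
#' @param species A [species_table()].
#' @param setup An [irradiation_setup()].
#' @param t_grid Strictly increasing time grid (s) starting at the initial
#'   time. A length-1 grid returns the initial state unchanged.
#' @param simplified If `TRUE` (default) integrate the conditions-(i)-(iv)
#'   rate law; if `FALSE`, the general multi-absorber law with depleting
#'   co-reactant.
#' @param rel_tol Step-halving convergence tolerance (relative), default 1e-8.
#' @param max_refine Maximum number of step doublings before giving up with
#'   an error, default 16.
#' @return A [kinetic_trace()] with one column per species plus the reactant
#'   absorbance `A_X`.
#' @export
integrate_scheme <- function(scheme, species, setup, t_grid,
                             simplified = TRUE, rel_tol = 1e-8,
                             max_refine = 16L) {
  stopifnot(inherits(scheme, "scheme_spec"), inherits(species, "species_table"),
            inherits(setup, "irradiation_setup"))
  .require_scheme_species(scheme, species)
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0))
    .stop_domain("'t_grid' must be strictly increasing")

  sys <- .build_ode_system(scheme, species, setup, simplified)

  if (length(t_grid) == 1L) {
    Y <- matrix(sys$y0, nrow = 1L)
    return(sys$to_trace(t_grid, Y, self_consistency = 0))
  }

  # initial substep count: max |rate| * h <= 1e-3 * state scale
  f0 <- sys$rhs(t_grid[1L], sys$y0)
  hmax <- max(diff(t_grid))
  scale <- pmax(abs(sys$scale), max(abs(sys$scale)) * 1e-6)
  need <- max(abs(f0) * hmax / (1e-3 * scale), 1)
  substeps <- as.integer(min(2^ceiling(log2(need)), 2^20))

  Y <- .rk4_path(sys$rhs, sys$y0, t_grid, substeps)
  err <- Inf
  for (r in seq_len(max_refine)) {
    Y2 <- .rk4_path(sys$rhs, sys$y0, t_grid, substeps * 2L)
    err <- max(abs(Y2[nrow(Y2), ] - Y[nrow(Y), ]) / scale)
    Y <- Y2
    substeps <- substeps * 2L
    if (err < rel_tol) break
  }
  if (err >= rel_tol)
    .stop_domain(sprintf(
      "RK4 step refinement failed to converge: step-halving error %.3e >= %.3e after %d doublings (substeps = %d)",
      err, rel_tol, max_refine, substeps))
  sys$to_trace(t_grid, Y, self_consistency = err)
}

# Build state layout, rhs closure, and trace assembler for a scheme.
# Simplified schemes a/b integrate the reactant absorbance; everything else
# integrates concentrations directly.
.build_ode_system <- function(scheme, species, setup, simplified) {
  id <- scheme$scheme_id
  sX <- species_by_role(species, "reactant_X")
  el <- sX$epsilon * setup$l_irr
  P0 <- setup$P0
  ln10 <- log(10)
  C_X0 <- sX$C0
  meta <- list(
    scheme = id, generator = "rk4",
    simplified = simplified,
    species = as.data.frame(unclass(species), stringsAsFactors = FALSE),
    setup = list(lambda_irr = setup$lambda_irr, P0 = P0,
                 l_irr = setup$l_irr, l_obs = setup$l_obs),
    params = list(k_bim = scheme$k_bim, phi_direct = scheme$phi_direct)
  )
  finish <- function(t, conc, A_X, self_consistency) {
    meta$self_consistency <- self_consistency
    kinetic_trace(t, conc, A_X = A_X, meta = meta)
  }

  if (!simplified) {
    y0 <- setNames(species$C0, species$name)
    state_template <- y0
    rhs <- function(t, y) {
      names(y) <- names(state_template)
      unname(rhs_general(y, scheme, species, setup))
    }
    to_trace <- function(t, Y, self_consistency) {
      conc <- as.data.frame(Y)
      names(conc) <- species$name
      .guard_negative(conc)
      finish(t, conc, A_X = el * pmax(conc[[sX$name]], 0), self_consistency)
    }
    return(list(rhs = rhs, y0 = unname(y0), scale = unname(pmax(y0, C_X0)),
                to_trace = to_trace))
  }

  if (id %in% c("a", "b")) {
    CXp0 <- species_by_role(species, "coreactant_Xprime")$C0
    kappa_bim <- scheme$k_bim * CXp0 * P0
    kappa_phi <- scheme$phi_direct * P0
    A0 <- el * C_X0
    if (id == "a") {
      rhs <- function(t, y) {
        fA <- -expm1(-y[1L] * ln10)
        -(kappa_bim) * el * fA
      }
      y0 <- A0
      scale <- max(A0, .Machine$double.eps)
      to_trace <- function(t, Y, self_consistency) {
        A <- pmax(Y[, 1L], 0)
        C_X <- A / el
        conc <- data.frame(C_X, CXp0, C_X0 - C_X)
        names(conc) <- c(sX$name, .role_name(species, "coreactant_Xprime"),
                         .role_name(species, "product_Yprime"))
        .guard_negative(conc)
        finish(t, conc, A_X = A, self_consistency)
      }
    } else {
      rhs <- function(t, y) {
        fA <- -expm1(-y[1L] * ln10)
        c(-(kappa_bim + kappa_phi) * el * fA,   # dA_X/dt
          kappa_phi * fA,                        # dC_Y/dt
          kappa_bim * fA)                        # dC_Yprime/dt
      }
      y0 <- c(A0, 0, 0)
      scale <- c(max(A0, .Machine$double.eps), rep(max(C_X0, .Machine$double.eps), 2))
      to_trace <- function(t, Y, self_consistency) {
        A <- pmax(Y[, 1L], 0)
        conc <- data.frame(A / el, CXp0, Y[, 2L], Y[, 3L])
        names(conc) <- c(sX$name, .role_name(species, "coreactant_Xprime"),
                         .role_name(species, "product_Y"),
                         .role_name(species, "product_Yprime"))
        .guard_negative(conc)
        finish(t, conc, A_X = A, self_consistency)
      }
    }
    return(list(rhs = rhs, y0 = y0, scale = scale, to_trace = to_trace))
  }

  if (id == "c") {
    CXp0 <- species_by_role(species, "coreactant_Xprime")$C0
    phi <- scheme$phi_direct
    kth <- scheme$k_bim * CXp0   # s^-1 (k_bim in M^-1 s^-1 for scheme c)
    rhs <- function(t, y) {
      fX <- -expm1(-el * max(y[1L], 0) * ln10)
      v_phi <- phi * P0 * fX
      v_th <- kth * y[2L]
      c(-v_phi, v_phi - v_th, v_th)
    }
    y0 <- c(C_X0, 0, 0)
    scale <- rep(max(C_X0, .Machine$double.eps), 3)
    to_trace <- function(t, Y, self_consistency) {
      C_X <- Y[, 1L]
      conc <- data.frame(C_X, CXp0, Y[, 2L], C_X0 - C_X, Y[, 3L])
      names(conc) <- c(sX$name, .role_name(species, "coreactant_Xprime"),
                       .role_name(species, "product_Yprime"),
                       .role_name(species, "product_Ydprime"),
                       .role_name(species, "product_Ytprime"))
      .guard_negative(conc)
      finish(t, conc, A_X = el * pmax(C_X, 0), self_consistency)
    }
    return(list(rhs = rhs, y0 = y0, scale = scale, to_trace = to_trace))
  }

  # scheme d
  kb <- scheme$k_bim
  rhs <- function(t, y) {
    C <- max(y[1L], 0)
    fX <- -expm1(-el * C * ln10)
    -kb * P0 * fX * C
  }
  y0 <- C_X0
  scale <- max(C_X0, .Machine$double.eps)
  to_trace <- function(t, Y, self_consistency) {
    C_X <- Y[, 1L]
    conc <- data.frame(C_X, C_X0 - C_X)
    names(conc) <- c(sX$name, .role_name(species, "product_Y"))
    .guard_negative(conc)
    finish(t, conc, A_X = el * pmax(C_X, 0), self_consistency)
  }
  list(rhs = rhs, y0 = y0, scale = scale, to_trace = to_trace)
}

.guard_negative <- function(conc) {
  for (nm in names(conc)) {
    v <- conc[[nm]]
    if (any(v < -1e-12))
      .stop_domain(sprintf(
        "integration produced concentrations below -1e-12 in '%s' (min %.3e): integrator failure",
        nm, min(v)))
  }
  invisible(TRUE)
}

# ---- shape diagnostics --------------------------------------------------

#' Two-regime shape diagnostics for a scheme-(c) trace
#'
#' Scheme (c) couples a photochemical depletion of X (producing Y' and Y'')
#' to a thermal consumption of Y' (producing Y'''). When both timescales are
#' active, the intermediate Y' passes through an interior maximum and the end
#' product Y''' grows along a sigmoid with a single inflection. This
#' diagnostic detects both features from the discrete differences of the
#' trace.
#'
#' @param trace A [kinetic_trace()] from a scheme-(c) integration (must hold
#'   the Y' and Y''' columns, at least 5 points).
#' @param tol Relative tolerance (on the series range) below which
#'   differences are treated as zero. Default 1e-9.
#' @return A list: `Yprime_has_interior_max`, `Yprime_max_time`,
#'   `Ytprime_sigmoid`, `inflection_time`.
#' @export
scheme_c_shape_diagnostics <- function(trace, tol = 1e-9) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (nrow(trace) < 5L)
    .stop_domain("trace too short for shape diagnostics (need >= 5 points)")
  m <- trace_meta(trace)
  sp <- m$species
  nYp <- sp$name[sp$role == "product_Yprime"]
  nYt <- sp$name[sp$role == "product_Ytprime"]
  if (length(nYp) != 1L || length(nYt) != 1L)
    .stop_domain("trace does not carry the scheme-(c) product species (Y' and Y''')")
  t <- trace$t_s
  Yp <- trace[[nYp]]
  Yt <- trace[[nYt]]

  # interior maximum of Y'
  ix <- which.max(Yp)
  eps_p <- tol * max(diff(range(Yp)), .Machine$double.xmin)
  has_max <- ix > 1L && ix < length(Yp) &&
    (Yp[ix] - Yp[1L]) > eps_p && (Yp[ix] - Yp[length(Yp)]) > eps_p
  max_time <- if (has_max) t[ix] else NA_real_

  # single inflection of Y''' from the sign of the discrete second difference
  d2 <- diff(diff(Yt))
  eps_t <- tol * max(abs(d2), .Machine$double.xmin)
  s <- sign(ifelse(abs(d2) <= eps_t, 0, d2))
  s <- s[s != 0]
  changes <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  sigmoid <- length(s) > 0L && s[1L] > 0 && changes == 1L
  infl_time <- NA_real_
  if (sigmoid) {
    j <- which(sign(ifelse(abs(d2) <= eps_t, 0, d2)) < 0)[1L]
    infl_time <- t[j + 1L]
  }
  list(Yprime_has_interior_max = has_max, Yprime_max_time = max_time,
       Ytprime_sigmoid = sigmoid, inflection_time = infl_time)
}

# ---- trace I/O ----------------------------------------------------------

#' Read and write kinetic traces as delimited text
#'
#' The on-disk dialect is comma-separated UTF-8 with a mandatory header
#' (`t_s` then one column per species), values printed to 12 significant
#' digits, and optional `# provenance:` comment lines carrying the trace
#' metadata as JSON. The in-memory `A_X` column is not written: it is the
#' reactant concentration times `epsilon_X * l_irr` (both in the
#' provenance), and `read_trace` reconstructs it. `read_trace` skips
#' comment lines, restoring metadata when a provenance line is present; the
#' round trip preserves the printed precision bit-identically.
#'
#' @param trace A [kinetic_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [kinetic_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  m <- trace_meta(trace)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# provenance: ",
                    jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA,
                                     dataframe = "columns", null = "null")),
             con)
  cols <- setdiff(names(trace), "A_X")
  writeLines(paste(cols, collapse = ","), con)
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  body <- do.call(paste, c(lapply(as.list(trace)[cols], fmt), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  prov <- grep("^# provenance:", lines, value = TRUE)
  meta <- list(generator = "synthetic")
  if (length(prov) > 0L) {
    meta <- jsonlite::fromJSON(sub("^# provenance: *", "", prov[1L]),
                               simplifyVector = TRUE)
    if (is.null(meta$generator)) meta$generator <- "synthetic"
  }
  body <- lines[!startsWith(lines, "#")]
  nf <- utils::count.fields(textConnection(body), sep = ",", quote = "\"")
  bad <- which(nf != nf[1L])
  if (length(bad) > 0L) {
    src_line <- which(!startsWith(lines, "#"))[bad[1L]]
    .stop_domain(sprintf(
      "malformed trace file '%s': line %d has %d fields, expected %d",
      path, src_line, nf[bad[1L]], nf[1L]))
  }
  df <- utils::read.csv(text = body, check.names = FALSE)
  if (!"t_s" %in% names(df))
    .stop_domain(sprintf("malformed trace file '%s': no 't_s' column in header", path))
  A_X <- if ("A_X" %in% names(df)) df$A_X else NULL
  conc <- df[setdiff(names(df), c("t_s", "A_X"))]
  if (is.null(A_X) && !is.null(meta$species)) {
    sp <- meta$species
    nX <- sp$name[sp$role == "reactant_X"]
    el <- sp$epsilon[sp$role == "reactant_X"] * (meta$setup$l_irr %||% 0)
    if (length(nX) == 1L && nX %in% names(conc) && isTRUE(el > 0))
      A_X <- el * conc[[nX]]
  }
  kinetic_trace(df$t_s, conc, A_X = A_X, meta = meta)
}
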