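# Fitting the Phi-order law and the classical comparator models to kinetic
# traces, and recovering the physical constants (kr, k_bim, quantum yield).

#' @importFrom stats coef lm optimize setNames
NULL

.new_fit <- function(model, params, rss, residuals, n_points, converged,
                     notes = character(), data = NULL, meta = NULL) {
  structure(
    list(model = model, params = params, rss = rss, residuals = residuals,
         n_points = n_points, converged = converged, notes = notes,
         data = data, meta = meta),
    class = "phikin_fit"
  )
}

#' @export
print.phikin_fit <- function(x, ...) {
  cat(sprintf("Fit [%s]: %s, RSS = %.4g over %d points\n",
              x$model, if (x$converged) "converged" else "NOT converged",
              x$rss, x$n_points))
  for (nm in names(x$params)) {
    p <- x$params[[nm]]
    cat(sprintf("  %-6s = %.6g", nm, p$value))
    if (is.finite(p$stderr)) cat(sprintf("  (se %.3g)", p$stderr))
    cat("\n")
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Serialise a fit result to JSON
#'
#' @param fit A `phikin_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "phikin_fit"))
  obj <- list(
    model = fit$model,
    params = lapply(fit$params, function(p)
      list(value = p$value, stderr = p$stderr)),
    rss = fit$rss, n_points = fit$n_points,
    converged = fit$converged, notes = fit$notes
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# pull (t, A) out of a trace: prefer the A_X column, else convert the
# reactant concentration with epsilon_X * l_irr from the metadata
.trace_absorbance <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$t_s
  if ("A_X" %in% names(trace)) return(list(t = t, A = trace$A_X))
  m <- trace_meta(trace)
  sp <- m$species
  if (is.null(sp)) .stop_domain("trace has no A_X column and no species metadata")
  nX <- sp$name[sp$role == "reactant_X"]
  el <- sp$epsilon[sp$role == "reactant_X"] * m$setup$l_irr
  if (length(nX) != 1L || !nX %in% names(trace) || !isTRUE(el > 0))
    .stop_domain("cannot derive an absorbance series: need reactant column and epsilon_X * l_irr > 0")
  list(t = t, A = el * trace[[nX]])
}

.trace_el <- function(trace) {
  m <- trace_meta(trace)
  sp <- m$species
  if (is.null(sp)) return(NA_real_)
  el <- sp$epsilon[sp$role == "reactant_X"] * m$setup$l_irr
  if (length(el) == 1L && isTRUE(el > 0)) el else NA_real_
}

.reactant_column <- function(trace) {
  m <- trace_meta(trace)
  sp <- m$species
  if (!is.null(sp)) {
    nX <- sp$name[sp$role == "reactant_X"]
    if (length(nX) == 1L && nX %in% names(trace)) return(nX)
  }
  cand <- setdiff(names(trace), c("t_s", "A_X"))
  if (length(cand) == 0L) .stop_domain("trace has no species columns")
  cand[1L]
}

#' Fit the Phi-order integrated rate law to a trace
#'
#' Nonlinear least squares of
#' `A(t) = log10(1 + (10^A0 - 1) exp(-kr t))` on the reactant absorbance
#' series (taken from the `A_X` column, or derived from the reactant
#' concentration via `epsilon_X * l_irr`). By default `A0` is fixed to the
#' first observation, leaving `kr` as the unique fitting parameter; set
#' `fix_A0 = FALSE` to free it. The starting value for `kr` comes from the
#' exact linearisation of the law, `ln(10^A - 1)` being globally linear in
#' `t`, which makes convergence essentially assured. The loss is unweighted
#' least squares on absorbance (spectrophotometric noise is approximately
#' homoscedastic in absorbance units); per-point weights may be supplied.
#' Parameter uncertainties come from the Gauss-Newton covariance
#' approximation at the optimum and are approximate.
#'
#' @param trace A [kinetic_trace()] with at least 5 points.
#' @param fix_A0 Fix `A0` at the first observation (default `TRUE`).
#' @param weights Optional per-point weights (default uniform).
#' @return A `phikin_fit` with `kr` (and `A0`) estimates; a trace whose
#'   fitted decay is negligible over the observation window is annotated
#'   `"non-photoreactive"`.
#' @export
fit_phi_order <- function(trace, fix_A0 = TRUE, weights = NULL) {
  obs <- .trace_absorbance(trace)
  t <- obs$t
  A <- obs$A
  if (length(t) < 5L) .stop_domain("insufficient points for fitting (need >= 5)")
  if (is.null(weights)) weights <- rep(1, length(t))
  A0_fix <- A[1L]

  # convergence-safe start: ln(10^A - 1) is linear in t with slope -kr.
  # The floor keeps the gradient well scaled even for near-constant traces.
  kr_floor <- 1e-3 / (max(t) - min(t))
  pos <- expm1(A * log(10)) > 0
  kr0 <- if (sum(pos) >= 2L) {
    sl <- coef(lm(log(expm1(A[pos] * log(10))) ~ t[pos]))[2L]
    max(-sl, kr_floor)
  } else kr_floor
  A00 <- max(A0_fix, 1e-12)

  df <- data.frame(t = t, A = A)
  fit <- if (fix_A0) {
    minpack.lm::nlsLM(
      A ~ log1p(expm1(A0_fix * log(10)) * exp(-kr * t)) / log(10),
      data = df, start = list(kr = kr0), lower = c(kr = 0),
      weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(
      A ~ log1p(expm1(A0 * log(10)) * exp(-kr * t)) / log(10),
      data = df, start = list(kr = kr0, A0 = A00),
      lower = c(kr = 0, A0 = 0), weights = weights,
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  sm <- summary(fit)
  est <- coef(fit)
  se <- function(p) unname(sm$coefficients[p, "Std. Error"])
  res <- stats::residuals(fit)
  params <- list(kr = list(value = unname(est["kr"]), stderr = se("kr")))
  params$A0 <- if (fix_A0) list(value = A0_fix, stderr = 0)
               else list(value = unname(est["A0"]), stderr = se("A0"))
  notes <- character()
  if (params$kr$value * (max(t) - min(t)) < 1e-3)
    notes <- c(notes, "non-photoreactive: negligible fitted decay over the observation window")
  .new_fit("phi_order", params, rss = sum(res^2), residuals = res,
           n_points = length(t), converged = fit$convInfo$isConv %||% TRUE,
           notes = notes, data = df,
           meta = list(el = .trace_el(trace), P0 = trace_meta(trace)$setup$P0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial reaction rate from a fitted Phi-order model
#'
#' The `t = 0` derivative of the fitted integrated law, converted to
#' concentration units:
#' \deqn{r_0 = -\frac{k_r (1 - 10^{-A_0})}{\ln 10\; \varepsilon_X l_{irr}}}
#' For large `A0` this saturates at `-kr / (ln 10 eps l)` (the zeroth-order
#' cap).
#'
#' @param fit A `phikin_fit` from [fit_phi_order()].
#' @param epsilon_X,l_irr Reactant absorptivity and irradiation path length;
#'   taken from the fit metadata when omitted.
#' @return Initial rate (M s^-1), negative for a depleting reactant.
#' @export
initial_rate_from_fit <- function(fit, epsilon_X = NULL, l_irr = NULL) {
  stopifnot(inherits(fit, "phikin_fit"))
  el <- if (!is.null(epsilon_X) && !is.null(l_irr)) epsilon_X * l_irr
        else fit$meta$el
  if (is.null(el) || !is.finite(el) || el <= 0)
    .stop_domain("epsilon_X * l_irr is required to convert the initial rate to concentration units")
  kr <- fit$params$kr$value
  A0 <- fit$params$A0$value
  -kr * (-expm1(-A0 * log(10))) / (log(10) * el)
}

#' Quantum yield from the fitted initial rate
#'
#' Inverts the unimolecular rate law at `t = 0`:
#' \deqn{\Phi = \frac{-r_0}{P_0 (1 - 10^{-A_0})}}
#' Applicable when the trace comes from the reactant irradiated alone (no
#' bimolecular channel), so that the whole initial rate is carried by the
#' direct photoprocess.
#'
#' @param r0 Initial rate (M s^-1), negative for depletion.
#' @param P0 Incident photon flux (einstein dm^-3 s^-1), > 0.
#' @param A0 Initial reactant absorbance, > 0 (at zero absorbance the
#'   quantum yield is undefined by this route).
#' @return Dimensionless quantum yield.
#' @export
quantum_yield_from_initial_rate <- function(r0, P0, A0) {
  .check_scalar(P0, "P0", positive = TRUE)
  .check_scalar(A0, "A0", nonneg = TRUE)
  if (A0 == 0)
    .stop_domain("A0 = 0: no light absorbed, quantum yield undefined from the initial rate")
  -r0 / (P0 * (-expm1(-A0 * log(10))))
}

#' Extract the thermal bimolecular rate constant from the overall one
#'
#' Inverts the closed-form rate-constant expressions: for scheme (a),
#' `k_bim = kr / (C_Xprime0 P0 eps_X l_irr ln 10)`; for scheme (b) the known
#' quantum yield of the concurrent photolysis is subtracted first. Exact
#' round trip with [rate_constant_scheme_a()] / [rate_constant_scheme_b()].
#'
#' @param kr Overall Phi-order rate constant (s^-1), >= 0.
#' @param C_Xprime0 Initial co-reactant concentration (M), > 0.
#' @param setup An [irradiation_setup()].
#' @param epsilon_X Reactant absorptivity (M^-1 cm^-1), > 0.
#' @param phi Quantum yield of the concurrent direct photolysis (0 for
#'   scheme a).
#' @return `k_bim` (M^-1).
#' @export
extract_kbim <- function(kr, C_Xprime0, setup, epsilon_X, phi = 0) {
  stopifnot(inherits(setup, "irradiation_setup"))
  .check_scalar(kr, "kr", nonneg = TRUE)
  .check_scalar(C_Xprime0, "C_Xprime0", positive = TRUE)
  .check_scalar(epsilon_X, "epsilon_X", positive = TRUE)
  .check_scalar(phi, "phi", nonneg = TRUE)
  total <- kr / (setup$P0 * epsilon_X * setup$l_irr * log(10))
  kb <- (total - phi) / C_Xprime0
  if (kb < -1e-12 * max(total, phi))
    .stop_domain(sprintf(
      "inconsistent inputs: phi (%.4g) exceeds the total rate budget kr/(P0 eps l ln10) = %.4g",
      phi, total))
  max(kb, 0)
}

#' Fit k_bim by repeated numerical integration (schemes c and d)
#'
#' For the schemes whose rate laws admit no closed form, `k_bim` is the only
#' unknown once the photochemical quantum yield is known (scheme c) or
#' absent (scheme d). The fit minimises the residual sum of squares between
#' the observed trace and an RK4 integration, over `k_bim` in `[0, upper]`,
#' by derivative-free bounded scalar minimisation.
#'
#' Identifiability: for scheme (c) the reactant X (and Y'') evolve
#' independently of `k_bim`, so the objective uses the Y' and Y''' columns;
#' a trace carrying neither yields a warning-annotated result. For scheme
#' (d) the reactant itself carries the information.
#'
#' @param trace A [kinetic_trace()] whose metadata identify scheme, species,
#'   and setup.
#' @param phi Quantum yield of the photochemical step (required for scheme
#'   c; ignored for scheme d). Defaults to the value in the trace metadata.
#' @param upper Upper bound of the search interval. Defaults to 100x the
#'   metadata `k_bim` when present, else must be given.
#' @param rel_tol Integrator step-halving tolerance used inside the
#'   objective (default 1e-8; the final fit is refit at this tolerance).
#' @return A `phikin_fit` with the `k_bim` estimate.
#' @export
fit_numeric_kbim <- function(trace, phi = NULL, upper = NULL, rel_tol = 1e-8) {
  m <- trace_meta(trace)
  scheme_id <- m$scheme
  if (is.null(scheme_id) || !scheme_id %in% c("c", "d"))
    .stop_domain("numeric k_bim fitting applies to schemes 'c' and 'd' only")
  sp <- m$species
  species <- species_table(sp$name, sp$epsilon, sp$C0, sp$role)
  setup <- irradiation_setup(m$setup$lambda_irr, m$setup$P0,
                             m$setup$l_irr, m$setup$l_obs)
  if (is.null(phi)) phi <- m$params$phi_direct %||% 0
  if (scheme_id == "c" && (is.null(phi) || phi <= 0))
    .stop_domain("scheme 'c' requires the known quantum yield 'phi' of the photochemical step")
  if (is.null(upper)) {
    kb_meta <- m$params$k_bim
    if (is.null(kb_meta) || !isTRUE(kb_meta > 0))
      .stop_domain("'upper' bound for k_bim is required when the trace metadata carry none")
    upper <- 100 * kb_meta
  }

  fit_cols <- if (scheme_id == "c") {
    intersect(sp$name[sp$role %in% c("product_Yprime", "product_Ytprime")],
              names(trace))
  } else {
    intersect(sp$name[sp$role == "reactant_X"], names(trace))
  }
  notes <- character()
  if (length(fit_cols) == 0L) {
    notes <- "unidentifiable: trace carries no k_bim-sensitive species columns"
    warning(notes, call. = FALSE)
    return(.new_fit("numeric_scheme_" %+% scheme_id,
                    list(k_bim = list(value = NA_real_, stderr = NA_real_)),
                    rss = NA_real_, residuals = NULL, n_points = nrow(trace),
                    converged = FALSE, notes = notes))
  }

  t_grid <- trace$t_s
  obs <- as.matrix(trace[fit_cols])
  objective <- function(kb) {
    sc <- scheme_spec(scheme_id, k_bim = kb,
                      phi_direct = if (scheme_id == "c") phi else NULL)
    sim <- integrate_scheme(sc, species, setup, t_grid, rel_tol = rel_tol)
    sum((as.matrix(sim[fit_cols]) - obs)^2)
  }
  opt <- optimize(objective, c(0, upper), tol = upper * 1e-7)
  kb_hat <- opt$minimum
  rss <- opt$objective
  if (kb_hat > 0.99 * upper)
    notes <- c(notes, sprintf("estimate at the upper bound (%.3g): widen 'upper'", upper))
  # curvature-based standard error: d2(RSS)/dk2 at the optimum
  hstep <- max(kb_hat, upper * 1e-3) * 1e-3
  f_p <- objective(kb_hat + hstep)
  f_m <- objective(max(kb_hat - hstep, 0))
  curv <- (f_p - 2 * rss + f_m) / hstep^2
  sigma2 <- rss / max(length(obs) - 1L, 1L)
  se <- if (is.finite(curv) && curv > 0) sqrt(2 * sigma2 / curv) else NA_real_
  if (is.finite(curv) && curv <= .Machine$double.eps * max(abs(f_p), 1)) {
    notes <- c(notes, "flat objective: k_bim weakly identified from this trace window")
    warning(notes[length(notes)], call. = FALSE)
  }
  .new_fit(paste0("numeric_scheme_", scheme_id),
           list(k_bim = list(value = kb_hat, stderr = se)),
           rss = rss, residuals = NULL, n_points = nrow(trace),
           converged = TRUE, notes = notes,
           meta = list(fit_cols = fit_cols, phi = phi))
}

`%+%` <- function(a, b) paste0(a, b)

#' Fit and rank the classical kinetic models against the Phi-order law
#'
#' Fits four candidate models to a single-species concentration trace:
#' mono-exponential `C0 exp(-k t)` (first-order), reciprocal
#' `C0 / (1 + k C0 t)` (second-order), zeroth-order linear `C0 - a t`, and
#' the Phi-order law (fitted on the derived absorbance, residuals converted
#' back to concentration units so the RSS values are commensurable). `C0` is
#' fixed at the first observation throughout. Results are returned ranked by
#' RSS; this is a diagnostic ranking, no model is declared "true".
#'
#' @param trace A [kinetic_trace()].
#' @param column Species column to fit; defaults to the reactant.
#' @return A list of `phikin_fit` objects sorted by increasing RSS, with
#'   class `phikin_model_comparison`.
#' @export
compare_classical_models <- function(trace, column = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (is.null(column)) column <- .reactant_column(trace)
  t <- trace$t_s
  C <- trace[[column]]
  if (length(t) < 5L) .stop_domain("insufficient points for fitting (need >= 5)")
  C0 <- C[1L]
  fits <- list()

  # first-order mono-exponential
  k0 <- {
    pos <- C > 0
    sl <- if (sum(pos) >= 2L) coef(lm(log(C[pos]) ~ t[pos]))[2L] else -1e-6
    max(-sl, .Machine$double.eps)
  }
  fits$mono_exponential <- tryCatch({
    f <- minpack.lm::nlsLM(C ~ C0 * exp(-k * t), data = data.frame(t = t, C = C),
                           start = list(k = k0), lower = c(k = 0))
    r <- stats::residuals(f)
    .new_fit("mono_exponential",
             list(k = list(value = unname(coef(f)["k"]),
                           stderr = unname(summary(f)$coefficients[, "Std. Error"]["k"]))),
             rss = sum(r^2), residuals = r, n_points = length(t), converged = TRUE)
  }, error = function(e) .new_fit("mono_exponential", list(), NA_real_, NULL,
                                  length(t), FALSE, notes = conditionMessage(e)))

  # reciprocal second-order
  krec0 <- {
    pos <- C > 0
    sl <- if (sum(pos) >= 2L) coef(lm(I(1 / C[pos]) ~ t[pos]))[2L] else 1e-6
    max(sl, .Machine$double.eps)
  }
  fits$reciprocal_second_order <- tryCatch({
    f <- minpack.lm::nlsLM(C ~ C0 / (1 + k * C0 * t), data = data.frame(t = t, C = C),
                           start = list(k = krec0), lower = c(k = 0))
    r <- stats::residuals(f)
    .new_fit("reciprocal_second_order",
             list(k = list(value = unname(coef(f)["k"]),
                           stderr = unname(summary(f)$coefficients[, "Std. Error"]["k"]))),
             rss = sum(r^2), residuals = r, n_points = length(t), converged = TRUE)
  }, error = function(e) .new_fit("reciprocal_second_order", list(), NA_real_, NULL,
                                  length(t), FALSE, notes = conditionMessage(e)))

  # zeroth-order linear, intercept pinned at C0
  fl <- lm(I(C - C0) ~ t - 1)
  rl <- stats::residuals(fl)
  fits$zeroth_order_linear <- .new_fit(
    "zeroth_order_linear",
    list(slope = list(value = unname(coef(fl)[1L]),
                      stderr = unname(summary(fl)$coefficients[1L, "Std. Error"]))),
    rss = sum(rl^2), residuals = rl, n_points = length(t), converged = TRUE)

  # Phi-order (via absorbance when available)
  fits$phi_order <- tryCatch({
    el <- .trace_el(trace)
    if (!is.finite(el)) el <- 1  # concentration-domain fit with unit eps*l
    A <- el * C
    tr_a <- kinetic_trace(t, setNames(list(pmax(C, 0)), column), A_X = A,
                          meta = trace_meta(trace))
    pf <- fit_phi_order(tr_a)
    r <- pf$residuals / el
    pf$rss <- sum(r^2)
    pf$residuals <- r
    pf
  }, error = function(e) .new_fit("phi_order", list(), NA_real_, NULL,
                                  length(t), FALSE, notes = conditionMessage(e)))

  ord <- order(vapply(fits, function(f) ifelse(is.na(f$rss), Inf, f$rss), 1))
  structure(fits[ord], class = "phikin_model_comparison")
}

#' @export
print.phikin_model_comparison <- function(x, ...) {
  cat("Model comparison (ranked by RSS, concentration units):\n")
  for (f in x)
    cat(sprintf("  %-26s RSS = %s\n", f$model,
                if (is.na(f$rss)) "failed" else sprintf("%.4g", f$rss)))
  invisible(x)
}
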