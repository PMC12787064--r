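test_that("the Phi-order integrated law matches an independent RK4 of its rate law", {
  # boundary behaviour
  expect_equal(phi_order_absorbance(0, A0 = 0.5, kr = 1e-3), 0.5)
  expect_identical(phi_order_absorbance(1e9, A0 = 0.5, kr = 1e-3), 0)
  # frozen oracle value at t = ln(2)/kr
  expect_equal(phi_order_absorbance(693.1, A0 = 0.5, kr = 1e-3),
               0.3183117, tolerance = 1e-6)
  # oracle equivalence across the full (A0, kr) grid
  worst <- 0
  for (A0 in c(0.01, 0.1, 0.5, 1, 2)) {
    for (kr in c(1e-4, 1e-3, 1e-2)) {
      t_grid <- seq(0, 5 / kr, length.out = 21)
      dev <- max(abs(phi_order_absorbance(t_grid, A0, kr) -
                     oracle_phi_order(t_grid, A0, kr)))
      worst <- max(worst, dev)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("overall rate constants evaluate to the published-parameter products", {
  setup <- published_setup()
  kr_a <- rate_constant_scheme_a(1.7e-2, 1.3e-4, setup, 7211)
  expect_equal(kr_a, 3.787e-8, tolerance = 1e-3)
  expect_equal(kr_a, 1.7e-2 * 1.3e-4 * 1.2e-6 * 7211 * 0.86 * log(10),
               tolerance = 1e-14)
  # doubling the flux doubles kr
  setup2 <- irradiation_setup(365, 2 * 1.2e-6, 0.86)
  expect_equal(rate_constant_scheme_a(1.7e-2, 1.3e-4, setup2, 7211), 2 * kr_a,
               tolerance = 1e-14)
  expect_identical(rate_constant_scheme_a(0, 1.3e-4, setup, 7211), 0)
  # scheme (b): reduction to scheme (a) at phi = 0, unimolecular limit at k_bim = 0
  expect_equal(rate_constant_scheme_b(1.7e-2, 1.3e-4, 0, setup, 7211), kr_a)
  kr_uni <- rate_constant_scheme_b(0, 1.3e-4, 5.3e-4, setup, 7211)
  expect_equal(kr_uni, 9.082e-6, tolerance = 1e-3)
  expect_identical(rate_constant_scheme_b(0, 1.3e-4, 0, setup, 7211), 0)
  # the ln10-free pseudo-first-order diagnostic is a distinct quantity
  expect_equal(pseudo_first_order_constant(1.7e-2, 1.3e-4, setup, 7211),
               kr_a / log(10), tolerance = 1e-14)
})

test_that("scheme-(b) product traces start at zero, share one clock, and partition C_X0", {
  cfg <- make_scheme_b(A0 = 7211 * 0.86 * 8.1e-6, phi = 5.3e-4, kb_w = 2.21e-6)
  el <- cfg$epsilon_X * cfg$setup$l_irr
  t <- c(0, 10^(seq(1, 6, by = 0.5)))
  Y <- product_Y_trace(t, cfg$kb_w, cfg$phi, cfg$A0, cfg$kr, cfg$epsilon_X, cfg$setup$l_irr)
  Yp <- product_Yprime_trace(t, cfg$kb_w, cfg$phi, cfg$A0, cfg$kr, cfg$epsilon_X, cfg$setup$l_irr)
  expect_identical(Y[1], 0)
  expect_identical(Yp[1], 0)
  expect_true(all(diff(Y) > 0) && all(diff(Yp) > 0))
  # asymptotes partition the initial reactant amount by the branching ratio
  Y_inf <- product_Y_trace(1e12, cfg$kb_w, cfg$phi, cfg$A0, cfg$kr, cfg$epsilon_X, cfg$setup$l_irr)
  Yp_inf <- product_Yprime_trace(1e12, cfg$kb_w, cfg$phi, cfg$A0, cfg$kr, cfg$epsilon_X, cfg$setup$l_irr)
  expect_equal(Y_inf, 8.066e-6, tolerance = 1e-3)
  expect_equal(Yp_inf, 3.36e-8, tolerance = 1e-2)
  expect_equal(Y_inf + Yp_inf, cfg$C_X0, tolerance = 1e-12)
  # the two products share the same logarithmic time factor
  ratio <- Y[-1] / Yp[-1]
  expect_equal(ratio, rep(cfg$phi / cfg$kb_w, length(ratio)), tolerance = 1e-10)
  # asymptote equals the closed-form limit expression
  expect_equal(Y_inf, cfg$C_X0 * cfg$phi / (cfg$kb_w + cfg$phi), tolerance = 1e-12)
  expect_equal(Yp_inf, cfg$C_X0 * cfg$kb_w / (cfg$kb_w + cfg$phi), tolerance = 1e-12)
})

test_that("the analytic scheme-(b) triple balances mass exactly; corruption is detected", {
  cfg <- make_scheme_b(A0 = 0.31, phi = 5.3e-4, kb_w = 2.21e-6)
  el <- cfg$epsilon_X * cfg$setup$l_irr
  t <- seq(0, 5 / cfg$kr, length.out = 40)
  C_X <- phi_order_absorbance(t, cfg$A0, cfg$kr) / el
  Y <- product_Y_trace(t, cfg$kb_w, cfg$phi, cfg$A0, cfg$kr, cfg$epsilon_X, cfg$setup$l_irr)
  Yp <- product_Yprime_trace(t, cfg$kb_w, cfg$phi, cfg$A0, cfg$kr, cfg$epsilon_X, cfg$setup$l_irr)
  res <- mass_balance_residual(C_X, Y, Yp, cfg$C_X0)
  expect_lt(max(abs(res)) / cfg$C_X0, 1e-12)
  expect_identical(mass_balance_residual(cfg$C_X0, 0, 0, cfg$C_X0), 0)
  res_bad <- mass_balance_residual(C_X, 1.1 * Y, Yp, cfg$C_X0)
  expect_gt(max(abs(res_bad)) / cfg$C_X0, 1e-3)
})

test_that("limiting regimes: mono-exponential at low A0, linear early decay at high A0", {
  expect_identical(limit_regime(0.005), "first_order")
  expect_identical(limit_regime(2.5), "zeroth_order")
  expect_identical(limit_regime(0.5), "phi_order")
  # boundary values fall on the limiting-regime side
  expect_identical(limit_regime(0.01), "first_order")
  expect_identical(limit_regime(2), "zeroth_order")
  kr <- 1e-3
  # low-absorbance limit: within 1% of A0 exp(-kr t) over [0, 3/kr]
  t <- seq(0, 3 / kr, length.out = 200)
  A <- phi_order_absorbance(t, 0.005, kr)
  expect_lt(max(abs(A - 0.005 * exp(-kr * t)) / (0.005 * exp(-kr * t))), 0.01)
  # high-absorbance limit: linear of slope -kr/ln10 over the first 10% of decay
  A0 <- 2.5
  t_lin <- seq(0, 0.1 * A0 * log(10) / kr, length.out = 100)
  A_lin <- phi_order_absorbance(t_lin, A0, kr)
  expect_lt(max(abs(A_lin - (A0 - kr / log(10) * t_lin)) / A_lin), 0.01)
  # zeroth-order flattening: negligible initial curvature at high A0
  h <- 1 / kr * 1e-3
  for (A0 in c(2, 2.5, 3)) {
    d2 <- (phi_order_absorbance(2 * h, A0, kr) -
           2 * phi_order_absorbance(h, A0, kr) +
           phi_order_absorbance(0, A0, kr)) / h^2
    expect_lt(abs(d2), kr^2 * A0 / 10)
  }
})

test_that("the Phi-order form is not the reciprocal second-order form", {
  cfg <- make_scheme_a(A0 = 0.5, kr = 1e-3)
  t <- seq(0, 5 / cfg$kr, length.out = 60)
  trace <- generate_trace(cfg$scheme, cfg$species, cfg$setup, t)
  cmp <- compare_classical_models(trace)
  rss <- vapply(cmp, function(f) f$rss, 1)
  names(rss) <- vapply(cmp, function(f) f$model, "")
  expect_gt(rss[["reciprocal_second_order"]], 1e3 * rss[["phi_order"]])
})

test_that("photonic yields evaluate exactly and coincide across scheme-(a) species", {
  setup <- irradiation_setup(365, 1e-6, 1)
  expect_equal(photonic_yield(1e-5, 5e-6, setup, 100), 0.05, tolerance = 1e-14)
  expect_identical(photonic_yield(1e-5, 1e-5, setup, 100), 0)
  expect_error(photonic_yield(1e-5, 5e-6, setup, 0), "undefined")
  # under scheme (a) true stoichiometry (general model, co-reactant depleting),
  # the photonic yields of X, X' and Y' are equal at every time
  cfg <- make_scheme_a(A0 = 0.5, kr = 1e-3, C_Xprime0 = 1e-2)
  t <- seq(0, 3 / cfg$kr, length.out = 20)
  tr <- integrate_scheme(cfg$scheme, cfg$species, cfg$setup, t, simplified = FALSE)
  tt <- t[-1]
  py_X <- photonic_yield(tr$X[1], tr$X[-1], cfg$setup, tt)
  py_Xp <- photonic_yield(tr$Xprime[1], tr$Xprime[-1], cfg$setup, tt)
  py_Yp <- photonic_yield(tr$Yprime[1], tr$Yprime[-1], cfg$setup, tt, is_product = TRUE)
  expect_equal(py_X, py_Xp, tolerance = 1e-9)
  expect_equal(py_X, py_Yp, tolerance = 1e-9)
})
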