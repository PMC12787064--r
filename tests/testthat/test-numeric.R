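test_that("simplified right-hand sides honour the scheme stoichiometries", {
  setup <- published_setup()
  pc <- published_scheme_c()
  state <- setNames(pc$species$C0, pc$species$name)
  d <- rhs_simplified(state, pc$scheme, pc$species, setup)
  # at t = 0 (no Y' yet) the depletion of X equals the formation of Y'
  expect_equal(abs(d[["X"]]), d[["Yprime"]], tolerance = 1e-14)
  expect_equal(d[["X"]], -d[["Ydprime"]], tolerance = 1e-14)
  # no absorber, no reaction
  state0 <- state; state0[["X"]] <- 0
  expect_true(all(rhs_simplified(state0, pc$scheme, pc$species, setup) == 0))

  # scheme (a): absorbance derivative at t = 0 equals the slope of the closed form
  cfg <- make_scheme_a(A0 = 0.5, kr = 1e-3)
  el <- cfg$epsilon_X * cfg$setup$l_irr
  sa <- setNames(cfg$species$C0, cfg$species$name)
  da <- rhs_simplified(sa, cfg$scheme, cfg$species, cfg$setup)
  h <- 1e-4 / cfg$kr
  slope_closed <- (phi_order_absorbance(h, cfg$A0, cfg$kr) - cfg$A0) / h
  expect_equal(el * da[["X"]], -cfg$kr * (1 - 10^(-cfg$A0)) / log(10), tolerance = 1e-12)
  expect_equal(el * da[["X"]], slope_closed, tolerance = 0.05)

  # scheme (d) small-absorbance series: r_X -> -k_bim P0 ln10 eps l C^2
  dd <- make_scheme_d(A0 = 1e-4)
  sd_ <- setNames(dd$species$C0, dd$species$name)
  rd <- rhs_simplified(sd_, dd$scheme, dd$species, dd$setup)
  series <- -dd$k_bim * dd$setup$P0 * log(10) * dd$epsilon_X * dd$setup$l_irr * dd$C_X0^2
  expect_equal(rd[["X"]], series, tolerance = 2e-4)
})

test_that("the general rate law reduces to the simplified one under conditions (i)-(iv)", {
  cfg <- make_scheme_a(A0 = 0.2, kr = 1e-3, C_Xprime0 = 1e-2)
  state <- setNames(cfg$species$C0, cfg$species$name)
  dg <- rhs_general(state, cfg$scheme, cfg$species, cfg$setup)
  ds <- rhs_simplified(state, cfg$scheme, cfg$species, cfg$setup)
  expect_equal(dg[["X"]], ds[["X"]], tolerance = 1e-3)
  expect_lt(abs(dg[["X"]] - ds[["X"]]) / abs(ds[["X"]]), 1e-3)
  expect_error(rhs_general(state - 1e-3, cfg$scheme, cfg$species, cfg$setup), ">= 0")
})

test_that("RK4 integration reproduces the closed form and conserves mass", {
  cfg <- make_scheme_a(A0 = 0.5, kr = 1e-3)
  t <- seq(0, 5 / cfg$kr, length.out = 40)
  tr <- integrate_scheme(cfg$scheme, cfg$species, cfg$setup, t)
  expect_lt(max(abs(tr$A_X - phi_order_absorbance(t, cfg$A0, cfg$kr))), 1e-8)
  expect_lt(trace_meta(tr)$self_consistency, 1e-8)
  # scheme (a) balance
  expect_lt(max(abs(tr$X + tr$Yprime - cfg$C_X0)) / cfg$C_X0, 1e-9)

  # scheme (b): time-resolved mass balance of the RK4 trace
  cfb <- make_scheme_b(A0 = 0.31)
  tb <- seq(0, 5 / cfb$kr, length.out = 40)
  trb <- integrate_scheme(cfb$scheme, cfb$species, cfb$setup, tb)
  resb <- mass_balance_residual(trb$X, trb$Y, trb$Yprime, cfb$C_X0)
  expect_lt(max(abs(resb)) / cfb$C_X0, 1e-9)

  # scheme (c): photochemical and thermal balances
  pc <- published_scheme_c()
  tc <- seq(0, 5 / pc$kr, length.out = 40)
  trc <- integrate_scheme(pc$scheme, pc$species, pc$setup, tc)
  expect_lt(max(abs(trc$X + trc$Ydprime - published_c$C_X0)) / published_c$C_X0, 1e-9)
  expect_lt(max(abs(trc$Yprime + trc$Ytprime - trc$Ydprime)) / published_c$C_X0, 1e-9)

  # zero-length grid returns the initial state unchanged
  tr0 <- integrate_scheme(cfg$scheme, cfg$species, cfg$setup, 0)
  expect_identical(nrow(tr0), 1L)
  expect_equal(tr0$X, cfg$C_X0)
  expect_error(integrate_scheme(cfg$scheme, cfg$species, cfg$setup, c(0, 0)),
               "strictly increasing")
})

test_that("package RK4 agrees with an independent stiff solver on scheme (c)", {
  skip_if_not_installed("deSolve")
  pc <- published_scheme_c()
  el <- published_c$epsilon_X * pc$setup$l_irr
  tc <- seq(0, 3 / pc$kr, length.out = 25)
  trc <- integrate_scheme(pc$scheme, pc$species, pc$setup, tc)
  rhs <- function(t, y, parms) {
    f <- 1 - 10^(-el * max(y[1], 0))
    v_phi <- published_c$phi * pc$setup$P0 * f
    v_th <- published_c$k_bim * published_c$C_Xprime0 * y[2]
    list(c(-v_phi, v_phi - v_th, v_th))
  }
  sol <- deSolve::lsoda(c(published_c$C_X0, 0, 0), tc, rhs, NULL,
                        rtol = 1e-10, atol = 1e-16)
  expect_lt(max(abs(sol[, 2] - trc$X)) / published_c$C_X0, 1e-7)
  expect_lt(max(abs(sol[, 3] - trc$Yprime)) / published_c$C_X0, 1e-7)
  expect_lt(max(abs(sol[, 4] - trc$Ytprime)) / published_c$C_X0, 1e-7)
})

test_that("scheme-(c) shape diagnostics detect the two kinetic regimes", {
  pc <- published_scheme_c()
  tc <- seq(0, 5 / pc$kr, length.out = 80)
  trc <- integrate_scheme(pc$scheme, pc$species, pc$setup, tc)
  dg <- scheme_c_shape_diagnostics(trc)
  expect_true(dg$Yprime_has_interior_max)
  expect_true(dg$Ytprime_sigmoid)
  expect_true(dg$inflection_time > 0 && dg$inflection_time < max(tc))

  # no thermal channel: Y''' stays at zero, no sigmoid, no interior maximum
  sc0 <- scheme_spec("c", k_bim = 0, phi_direct = published_c$phi)
  tr0 <- integrate_scheme(sc0, pc$species, pc$setup, tc)
  expect_true(all(tr0$Ytprime == 0))
  dg0 <- scheme_c_shape_diagnostics(tr0)
  expect_false(dg0$Yprime_has_interior_max)
  expect_false(dg0$Ytprime_sigmoid)

  # monotone synthetic input: both flags false
  t5 <- 0:9
  tr_mono <- kinetic_trace(
    t5, list(Yprime = seq(0, 1e-6, length.out = 10),
             Ytprime = seq(0, 2e-6, length.out = 10)),
    meta = list(generator = "synthetic", scheme = "c",
                species = data.frame(
                  name = c("Yprime", "Ytprime"),
                  role = c("product_Yprime", "product_Ytprime"))))
  dgm <- scheme_c_shape_diagnostics(tr_mono)
  expect_false(dgm$Yprime_has_interior_max)
  expect_false(dgm$Ytprime_sigmoid)
  expect_error(scheme_c_shape_diagnostics(trc[1:3, ]), "5 points")
})

test_that("trace CSV round-trips bit-identically at the printed precision", {
  cfg <- make_scheme_a(A0 = 0.5, kr = 1e-3)
  t <- seq(0, 5 / cfg$kr, length.out = 25)
  tr <- generate_trace(cfg$scheme, cfg$species, cfg$setup, t,
                       noise_model(sigma = 0.002, seed = 11))
  p1 <- file.path(tempdir(), "trace1.csv")
  p2 <- file.path(tempdir(), "trace2.csv")
  write_trace(tr, p1)
  tr2 <- read_trace(p1)
  write_trace(tr2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(names(tr2)[1], "t_s")
  expect_true(all(cfg$species$name %in% names(tr2)))
  expect_identical(trace_meta(tr2)$seed, 11L)
  # reconstructed absorbance matches eps*l times the reactant column
  expect_equal(tr2$A_X, cfg$epsilon_X * cfg$setup$l_irr * tr2$X, tolerance = 1e-12)

  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("t_s,X", "0,1", "1,2,3"), bad)
  expect_error(read_trace(bad), "line 3")
})

test_that("the trace container enforces its invariants", {
  expect_error(kinetic_trace(c(0, 1, 1), list(X = 1:3),
                             meta = list(generator = "rk4")), "strictly increasing")
  expect_error(kinetic_trace(0:2, list(X = c(1, 2, -1e-10)),
                             meta = list(generator = "rk4")), "slack")
  tr <- kinetic_trace(0:2, list(X = c(1, 2, -1e-13)), meta = list(generator = "rk4"))
  expect_identical(tr$X[3], 0)   # tiny undershoot clipped
  # synthetic traces keep negative noisy values
  trs <- kinetic_trace(0:2, list(X = c(1, 0.5, -0.01)),
                       meta = list(generator = "synthetic"))
  expect_identical(trs$X[3], -0.01)
  expect_error(kinetic_trace(0:2, list(X = 1:3), meta = list()), "generator")
})
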