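test_that("bare interfaces reproduce the Fresnel closed form", {
  wl <- seq(400, 700, by = 50)
  # index-matched: no reflection
  st0 <- layer_stack(substrate = constant_dispersion(1))
  expect_equal(tmm_reflectance(st0, wl)$reflectance, rep(0, length(wl)))
  # air | n = 3 substrate: ((1-3)/(1+3))^2 = 0.25
  st <- layer_stack(substrate = constant_dispersion(3))
  expect_equal(tmm_reflectance(st, wl)$reflectance, rep(0.25, length(wl)),
               tolerance = 1e-12)
  # absorbing substrate against the complex Fresnel formula
  stk <- layer_stack(substrate = constant_dispersion(4, 1))
  r_oracle <- Mod((1 - (4 - 1i)) / (1 + (4 - 1i)))^2
  expect_equal(tmm_reflectance(stk, 550)$reflectance, r_oracle,
               tolerance = 1e-12)
})

test_that("single lossless layers match the Airy closed form to 1e-9", {
  wl <- seq(360, 830, by = 5)
  cases <- list(c(n1 = 2.0, ns = 4.0, d = 68.75),   # quarter-wave at 550
                c(n1 = 1.38, ns = 1.52, d = 99.6),  # MgF2-like AR coating
                c(n1 = 2.02, ns = 3.9, d = 243))    # nitride-on-silicon-like
  for (cs in cases) {
    st <- layer_stack(
      list(list(dispersion = constant_dispersion(cs[["n1"]]),
                thickness_nm = cs[["d"]])),
      substrate = constant_dispersion(cs[["ns"]]))
    got <- tmm_reflectance(st, wl)$reflectance
    want <- airy_reflectance(1, cs[["n1"]], cs[["ns"]], cs[["d"]], wl)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # quarter-wave reflectance extremum at the design wavelength
  st <- layer_stack(
    list(list(dispersion = constant_dispersion(2), thickness_nm = 550 / 8)),
    substrate = constant_dispersion(4))
  r550 <- tmm_reflectance(st, 550)$reflectance
  expect_equal(r550, ((1 * 4 - 4) / (1 * 4 + 4))^2, tolerance = 1e-12)
})

test_that("zero-thickness layers leave the spectrum unchanged", {
  wl <- default_wavelengths()
  base <- layer_stack(
    list(list(dispersion = nos_material("si3n4"), thickness_nm = 243)),
    substrate = nos_material("si"))
  padded <- layer_stack(
    list(list(dispersion = constant_dispersion(1.7), thickness_nm = 0),
         list(dispersion = nos_material("si3n4"), thickness_nm = 243)),
    substrate = nos_material("si"))
  expect_equal(tmm_reflectance(padded, wl)$reflectance,
               tmm_reflectance(base, wl)$reflectance, tolerance = 1e-12)
})

test_that("reflectance stays in [0, 1] for random passive stacks", {
  set.seed(42)
  wl <- seq(360, 830, by = 10)
  for (rep in 1:20) {
    nlay <- sample(0:3, 1)
    layers <- lapply(seq_len(nlay), function(i)
      list(dispersion = constant_dispersion(runif(1, 1.2, 4),
                                            runif(1, 0, 0.5)),
           thickness_nm = runif(1, 10, 800)))
    st <- layer_stack(layers,
                      substrate = constant_dispersion(runif(1, 1.2, 5),
                                                      runif(1, 0, 3)))
    ang <- runif(1, 0, 80)
    for (pol in c("s", "p", "unpolarized")) {
      R <- tmm_reflectance(st, wl, angle = ang, polarization = pol)$reflectance
      expect_true(all(R >= 0 & R <= 1))
    }
  }
})

test_that("oblique incidence matches the single-interface Fresnel formulas", {
  n2 <- 1.5; th <- 35 * pi / 180
  st <- layer_stack(substrate = constant_dispersion(n2))
  cos2 <- sqrt(1 - (sin(th) / n2)^2)
  rs <- fresnel_r(1, n2, "s", cos(th), cos2)
  rp <- fresnel_r(1, n2, "p", cos(th), cos2)
  expect_equal(tmm_reflectance(st, 550, angle = 35, polarization = "s")$reflectance,
               rs^2, tolerance = 1e-9)
  expect_equal(tmm_reflectance(st, 550, angle = 35, polarization = "p")$reflectance,
               rp^2, tolerance = 1e-9)
  # Brewster angle: p reflectance vanishes
  brewster <- atan(n2) * 180 / pi
  expect_lt(tmm_reflectance(st, 550, angle = brewster,
                            polarization = "p")$reflectance, 1e-12)
})

test_that("degenerate inputs are refused", {
  st <- layer_stack(substrate = constant_dispersion(3))
  expect_error(tmm_reflectance(st, numeric(0)), "empty")
  expect_error(tmm_reflectance(st, 550, angle = 90), "angle")
  expect_error(layer_stack(list(list(dispersion = constant_dispersion(2),
                                     thickness_nm = Inf)),
                           substrate = constant_dispersion(3)),
               "finite")
})
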