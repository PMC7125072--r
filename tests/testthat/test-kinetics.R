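test_that("Monod derivative matches hand evaluation and limiting cases", {
  p <- monod_params(mu_max = 1, K_H = 1, Y = 1, k_d = 0.1)
  # H = K_H: uptake at half its maximum
  d <- monod_rhs(culture_state(H = 1, P = 0, X = 1), p)
  expect_equal(unname(d), c(-0.5, 0.125, 0.5 - 0.1))
  # zero substrate: only death remains
  d0 <- monod_rhs(culture_state(H = 0, P = 5, X = 2), p)
  expect_equal(unname(d0), c(0, 0, -0.2))
  # no biomass: nothing happens
  dx <- monod_rhs(culture_state(H = 100, P = 0, X = 0), p)
  expect_equal(unname(dx), c(0, 0, 0))
})

test_that("first-order derivative matches hand evaluation at reference estimates", {
  d <- first_order_rhs(culture_state(H = 100, P = 0, X = 0.1),
                       ref_first_order())
  expect_equal(unname(d["dH"]), -0.0008 * 0.1 * 100 / 0.0037)
  expect_equal(unname(d["dH"]), -2.162162, tolerance = 1e-6)
  expect_equal(unname(d["dP"]), -unname(d["dH"]) / 4)
  expect_equal(unname(d["dX"]), -0.0037 * unname(d["dH"]) - 0.087 * 0.1)
  # H = 0 shuts uptake down
  expect_equal(unname(first_order_rhs(culture_state(H = 0, P = 0, X = 1),
                                      ref_first_order())["dH"]), 0)
})

test_that("first-order kinetics approximates Monod for H much below K_H", {
  mu <- 0.4; KH <- 300; Y <- 0.002; kd <- 0.02
  pm <- monod_params(mu, KH, Y, kd)
  pf <- first_order_params(eta = mu / KH, Y = Y, k_d = kd)
  for (H in c(KH / 200, KH / 1000)) {
    st <- culture_state(H = H, P = 0, X = 0.3)
    dm <- monod_rhs(st, pm)["dH"]; df <- first_order_rhs(st, pf)["dH"]
    expect_lt(abs(df - dm) / abs(dm), 0.01)
  }
  # and the approximation error vanishes as H/K_H -> 0
  err <- sapply(KH / c(1e2, 1e3, 1e4), function(H) {
    st <- culture_state(H = H, P = 0, X = 0.3)
    abs(first_order_rhs(st, pf)["dH"] - monod_rhs(st, pm)["dH"])
  })
  expect_true(all(diff(err) < 0))
})

test_that("T1 hard threshold switches uptake off at and below H_t", {
  p <- ref_t1()
  # hand evaluation 100 mM above the threshold
  d <- t1_rhs(culture_state(H = 186.2, P = 0, X = 0.1), p)
  expect_equal(unname(d["dH"]), -0.0008 * 100 * 0.1 / 0.0014)
  expect_equal(unname(d["dH"]), -5.714286, tolerance = 1e-6)
  # below and at the threshold: no uptake, only death
  for (H in c(p$H_t / 2, p$H_t)) {
    d <- t1_rhs(culture_state(H = H, P = 0, X = 0.5), p)
    expect_equal(unname(d["dH"]), 0)
    expect_equal(unname(d["dX"]), -p$k_d * 0.5)
  }
  # continuity across the kink
  eps <- 1e-9
  d_above <- t1_rhs(culture_state(H = p$H_t + eps, P = 0, X = 1), p)["dH"]
  expect_lt(abs(d_above), 1e-6)
})

test_that("T2 sigmoid gate has the midpoint, saturation and analytic inverse", {
  p <- ref_t2()
  expect_equal(t2_gate(p$T, p), 0.5)
  # F = 0.75 at H = T + ln(3)/A by inverting the sigmoid
  expect_equal(t2_gate(p$T + log(3) / p$A, p), 0.75)
  expect_equal(t2_gate(1e6, p), 1)
  expect_equal(t2_gate(-1e6, p), 0)
  # overflow-safe at extreme arguments
  expect_true(is.finite(t2_gate(1e12, p)) && is.finite(t2_gate(-1e12, p)))
  # gate bounded in [0, 1] across a wide sweep
  expect_true(all(t2_gate(seq(-1e4, 1e4, by = 97), p) >= 0))
  expect_true(all(t2_gate(seq(-1e4, 1e4, by = 97), p) <= 1))
})

test_that("T2 derivative gates the first-order law", {
  p <- ref_t2()
  # at the midpoint the gate halves the first-order rate
  d <- t2_rhs(culture_state(H = 336, P = 0, X = 0.1), p)
  expect_equal(unname(d["dH"]), -0.0054 * 0.1 * 336 * 0.5 / 0.0017)
  # H = 0: no uptake
  expect_equal(unname(t2_rhs(culture_state(H = 0, P = 0, X = 1), p)["dH"]), 0)
  # saturated gate: reduces to first-order kinetics
  pf <- first_order_params(eta = p$eta, Y = p$Y, k_d = p$k_d)
  st <- culture_state(H = p$T + 2000, P = 0, X = 0.2)
  expect_equal(t2_rhs(st, p), first_order_rhs(st, pf), tolerance = 1e-8)
})

test_that("T3 reversible kinetics has zero flux at the steady ratio and signed flux off it", {
  p <- ref_t3()
  ratio <- t3_steady_state_ratio(p)
  expect_equal(unname(t3_rhs(culture_state(H = 0, P = 0, X = 1), p)["dH"]), 0)
  # flux vanishes exactly on the steady-state ray
  d <- t3_rhs(culture_state(H = 50, P = ratio * 50, X = 0.3), p)
  expect_equal(unname(d["dH"]), 0, tolerance = 1e-12)
  # above the ray the reaction runs in reverse (hydrogen accumulates)
  expect_gt(t3_rhs(culture_state(H = 50, P = 3 * ratio * 50, X = 0.3),
                   p)["dH"], 0)
  # sign property under random states
  for (seed in 1:10) {
    st <- acetokin:::with_seed(seed, culture_state(H = runif(1, 0, 500),
                                                   P = runif(1, 0, 500),
                                                   X = runif(1, 0, 1)))
    num <- p$mu_max_H * st$H / p$K_H - p$mu_max_R * st$P / p$K_R
    expect_equal(sign(t3_rhs(st, p)["dH"]), -sign(num) * (st$X > 0),
                 ignore_attr = TRUE)
  }
})

test_that("yeast-extract extension augments acetate and biomass, leaves hydrogen alone", {
  ext <- yeast_extension_params(eta_E = 0.0018, Y_E = 0.02, b_EP = 0.43)
  spec <- model_spec("t2", ref_t2(), extension = ext)
  st <- culture_state(H = 200, P = 10, X = 0.1, E = 100)
  d <- extended_rhs(st, spec)
  expect_equal(unname(d["dE"]), -0.0018 * 0.1 * 100 / 0.02)
  expect_equal(unname(d["dE"]), -0.9)
  base <- t2_rhs(culture_state(H = 200, P = 10, X = 0.1), ref_t2())
  expect_equal(unname(d["dH"]), unname(base["dH"]))
  expect_equal(unname(d["dP"]), unname(base["dP"]) - 0.43 * d[["dE"]])
  expect_equal(unname(d["dX"]), unname(base["dX"]) - 0.02 * d[["dE"]])
  # E = 0 makes the extension inert
  d0 <- extended_rhs(culture_state(H = 200, P = 10, X = 0.1, E = 0), spec)
  expect_equal(d0[c("dH", "dP", "dX")], base)
  expect_equal(unname(d0["dE"]), 0)
  # a state without E is rejected
  expect_error(extended_rhs(culture_state(H = 200, P = 10, X = 0.1), spec),
               class = "acetokin_invalid_input")
})

test_that("stoichiometric coupling dP = -dH/4 holds for every base structure", {
  for (s in base_structures) {
    for (seed in 1:5) {
      spec <- random_spec(s, seed = 100 * match(s, base_structures) + seed)
      st <- acetokin:::with_seed(seed, culture_state(H = runif(1, 0, 500),
                                                     P = runif(1, 0, 100),
                                                     X = runif(1, 0, 1)))
      d <- model_rhs(spec, st)
      expect_equal(unname(d["dP"]), -unname(d["dH"]) / 4)
      if (s != "t3") expect_lte(unname(d["dH"]), 0)
    }
  }
})

test_that("parameter records validate positivity and structure matching", {
  expect_error(t1_params(eta = -1, Y = 0.001, k_d = 0.01, H_t = 80),
               class = "acetokin_invalid_input")
  expect_error(monod_params(mu_max = 1, K_H = Inf, Y = 1, k_d = 1),
               class = "acetokin_invalid_input")
  expect_error(model_spec("t1", ref_t2()),
               class = "acetokin_invalid_input")
  expect_error(model_spec("monod", ref_monod(),
                          extension = yeast_extension_params(0.001, 0.01, 0.5)),
               class = "acetokin_invalid_input")
  expect_error(culture_state(H = -1, P = 0, X = 0),
               class = "acetokin_invalid_input")
})

test_that("model specs round-trip through flat JSON configs", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  spec <- model_spec("t3", ref_t3(),
                     extension = yeast_extension_params(0.002, 0.013, 0.5))
  write_model_spec_json(spec, tmp)
  back <- read_model_spec_json(tmp)
  expect_equal(back$structure, "t3")
  expect_equal(flatten_params(back), flatten_params(spec))
  # missing key errors name the key
  spec2 <- reference_params("t1")
  fl <- flatten_params(spec2)
  expect_error(acetokin:::spec_from_flat("t1", fl[names(fl) != "H_t"]),
               "H_t", class = "acetokin_invalid_input")
})

test_that("non-linearised threshold variants reduce sensibly", {
  # hard-threshold Monod form: off below threshold, Monod-like far above
  p <- t1_nonlinear_params(mu_max = 0.4, K_H = 300, Y = 0.002, k_d = 0.02,
                           H_t = 80)
  expect_equal(unname(t1_nonlinear_rhs(culture_state(H = 40, P = 0, X = 1),
                                       p)["dH"]), 0)
  pm <- monod_params(mu_max = 0.4, K_H = 300, Y = 0.002, k_d = 0.02)
  d_thr <- t1_nonlinear_rhs(culture_state(H = 5080, P = 0, X = 1), p)["dH"]
  d_mon <- monod_rhs(culture_state(H = 5000, P = 0, X = 1), pm)["dH"]
  expect_equal(unname(d_thr), unname(d_mon), tolerance = 1e-12)
})
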