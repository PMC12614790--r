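test_that("tangent residual vanishes at the optimum and goes negative beyond", {
  prm <- hyp_params()
  # both sides hand-evaluate to 1.5625 at the known optimum w* = 1.2
  expect_equal(tangent_residual(prm, c = 10, w = 1.2), 0, tolerance = 1e-12)
  expect_lt(tangent_residual(prm, c = 10, w = 40), 0)
  expect_gt(tangent_residual(prm, c = 10, w = 0.1), 0)
  # finite-difference fallback agrees with the closed form
  expect_equal(tangent_residual(prm, 10, 2.5, derivative = "numeric"),
               tangent_residual(prm, 10, 2.5), tolerance = 1e-6)
  expect_error(tangent_residual(attraction_params(A = 10, a = 0.4),
                                10, 1, form = "power"),
               "no closed-form derivative")
})

test_that("closed-form w* solves the optimality quadratic", {
  # 20 w^2 + 8 w - 38.4 = 0 -> w* = (-8 + 56) / 40 = 1.2
  opt <- optimal_w_analytic(hyp_params(), c = 10)
  expect_equal(opt$location, 1.2)
  expect_equal(opt$objective, 15.625)
  expect_false(opt$at_boundary)
  expect_lt(abs(opt$residual), 1e-9)
  # N_c = 0 reduces the quadratic to A w^2 = A a c, so w* = sqrt(a c)
  opt0 <- optimal_w_analytic(attraction_params(A = 10, a = 0.4), c = 10)
  expect_equal(opt0$location, 2)
  # at the threshold the optimum collapses to the boundary
  c0 <- facilitation_threshold(hyp_params())
  optb <- optimal_w_analytic(hyp_params(), c = c0)
  expect_equal(optb$location, 0)
  expect_true(optb$at_boundary)
  expect_equal(optb$objective, 10)  # F(c, 0) = N_c
})

test_that("facilitation threshold is N_c a / A and delimits interior optima", {
  expect_equal(facilitation_threshold(hyp_params()), 0.4)
  expect_equal(facilitation_threshold(attraction_params(A = 5, a = 2)), 0)
  expect_error(facilitation_threshold(attraction_params(A = 0, a = 1,
                                                        N_c = 1)),
               "A > 0")
  expect_gt(optimal_w_analytic(hyp_params(), 0.4 * 1.001)$location, 0)
  expect_true(optimal_w_analytic(hyp_params(), 0.4 * 0.999)$at_boundary)
})

test_that("numeric optimizer agrees with the closed form and an independent oracle", {
  prm <- hyp_params()
  num <- optimal_w_numeric("hyperbolic", prm, c = 10, w_max = 50)
  expect_equal(num$location, 1.2, tolerance = 1e-6)
  # independent oracle: Brent's method on the same objective
  brent <- stats::optimize(function(w)
    visit_rates("hyperbolic", prm, patch_state(10, w))$F_crop,
    c(0, 50), maximum = TRUE, tol = 1e-10)
  expect_equal(num$location, brent$maximum, tolerance = 1e-6)
  # flat objective reports the conservative boundary answer
  flat <- optimal_w_numeric("linear_additive", attraction_params(g = 1),
                            c = 10)
  expect_equal(flat$location, 0)
  expect_true(flat$at_boundary)
  # strictly decreasing objective pins to zero
  dec <- optimal_w_numeric("linear_plus_local",
                           attraction_params(L = 10, g = 1), c = 10)
  expect_equal(dec$location, 0)
  expect_true(dec$at_boundary)
  # optimum at the window edge warns
  expect_warning(optimal_w_numeric("power",
                                   attraction_params(A = 1, a = 0.5),
                                   c = 10, w_max = 2),
                 "upper search bound")
})

test_that("analytic and numeric w* agree across random parameter draws", {
  set.seed(42)
  draws <- draw_hyperbolic(200)
  for (i in seq_len(nrow(draws))) {
    prm <- attraction_params(A = draws$A[i], a = draws$a[i],
                             N_c = draws$N_c[i])
    ana <- optimal_w_analytic(prm, draws$c[i])
    num <- optimal_w_numeric("hyperbolic", prm, draws$c[i], w_max = 50,
                             tol = 1e-9)
    expect_equal(num$location, ana$location, tolerance = 1e-5,
                 info = paste("draw", i))
    expect_identical(num$at_boundary, ana$at_boundary,
                     info = paste("draw", i))
    # threshold property: interior optimum iff c exceeds c0
    c0 <- facilitation_threshold(prm)
    expect_identical(ana$location > 0, draws$c[i] > c0,
                     info = paste("draw", i))
    # facilitation at the optimum: the definitional gain over w = 0
    if (!ana$at_boundary)
      expect_gt(ana$objective, draws$N_c[i])
  }
})

test_that("w*(c) is non-decreasing and strictly increasing above threshold", {
  prm <- hyp_params()
  c0 <- facilitation_threshold(prm)
  curve <- w_star_curve(prm, seq(0, c0, length.out = 10))
  expect_true(all(curve$w_star == 0))           # flat at zero below c0
  set.seed(7)
  cg <- sort(runif(60, 0, 40))
  curve <- w_star_curve(prm, cg)
  expect_true(all(diff(curve$w_star) >= 0))
  above <- curve$c > c0 * (1 + 1e-9)
  expect_true(all(diff(curve$w_star[above]) > 0))
  # sqrt(a c) closed form when N_c = 0
  curve0 <- w_star_curve(attraction_params(A = 10, a = 0.4), c(1, 4, 9))
  expect_equal(curve0$w_star, sqrt(0.4 * c(1, 4, 9)))
  expect_error(w_star_curve(prm, numeric(0)), "ascending")
})

test_that("fixed-area stationarity residual vanishes exactly at p*", {
  cfg <- fig3a_config()
  opt <- optimal_p_numeric(cfg)
  expect_false(opt$at_boundary)
  expect_lt(abs(model_b_stationarity_residual(cfg, opt$location)), 1e-6)
  # residual changes sign across p* on a bracketing pair
  expect_gt(model_b_stationarity_residual(cfg, opt$location - 0.01), 0)
  expect_lt(model_b_stationarity_residual(cfg, opt$location + 0.01), 0)
  # closed-form and finite-difference derivatives agree
  p <- c(0.1, 0.3, 0.6, 0.9)
  expect_equal(model_b_stationarity_residual(cfg, p),
               model_b_stationarity_residual(cfg, p, derivative = "numeric"),
               tolerance = 1e-6)
  expect_error(model_b_stationarity_residual(cfg, 0), "0 < p < 1")
})

test_that("fixed-area optima: p* trades area against attraction", {
  cfg <- fig3a_config()
  yield_opt <- optimal_p_numeric(cfg)
  attr_opt <- argmax_attraction_p(cfg)
  # equal mix maximizes attraction (exact by symmetry)
  expect_equal(attr_opt$location, 0.5, tolerance = 1e-6)
  # the reference optimum at two-decimal precision
  expect_equal(round(yield_opt$location, 2), 0.05)
  # area cost shifts the yield optimum far left of the attraction optimum
  expect_lt(yield_opt$location, attr_opt$location)
  # independent oracle on the yield curve
  brent <- stats::optimize(function(p) model_b_yield(cfg, p), c(0, 1),
                           maximum = TRUE, tol = 1e-10)
  expect_equal(yield_opt$location, brent$maximum, tolerance = 1e-6)

  # asymmetric attractiveness pulls the attraction argmax toward w
  expect_gt(argmax_attraction_p(fig3b_config())$location, 0.5)
  # only the crop attracts: everything in crop
  onlyc <- model_b_config(b = 1, params = attraction_params(
    A_w = 0, A_c = 1, a_w = 0.4, a_c = 0.4))
  expect_equal(argmax_attraction_p(onlyc)$location, 0)
  # more attractive wildflowers raise the achievable crop yield
  expect_gt(optimal_p_numeric(fig3b_config())$objective,
            optimal_p_numeric(fig3a_config())$objective)
  # worthless wildflowers (b -> 0) attract nothing and only cost area
  b0 <- model_b_config(b = 1e-9, params = fig3a_config()$params)
  expect_equal(optimal_p_numeric(b0)$location, 0)
})
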