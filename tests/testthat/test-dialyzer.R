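test_that("flow settings convert ml/h to ml/min exactly once and validate", {
  fs <- flow_setting(150, 2000)
  expect_identical(fs$qd, 2000 / 60)
  expect_identical(fs$qd_input, 2000)
  expect_error(flow_setting(0, 1000), "positive")
  expect_error(flow_setting(100, -5), "positive")
  grid <- flow_grid()
  expect_length(grid, 9)
  expect_equal(vapply(grid, `[[`, 0, "qb"), rep(c(100, 150, 200), each = 3))
  # arbitrary positive flows outside the bench grid are accepted
  expect_silent(flow_setting(73.2, 4321))
})

test_that("dialyzer parameter invariants are enforced", {
  expect_error(dialyzer_params(k0a = 50, sieving_membrane = 0), "sieving")
  expect_error(dialyzer_params(k0a = 50, sieving_membrane = 1.2), "sieving")
  expect_error(dialyzer_params(k0a = 50, permeability_reduction = 1), "permeability")
  expect_error(dialyzer_params(k0a = 50, alpha_backfiltration = 0), "alpha")
  expect_error(dialyzer_params(k0a = -1))
})

test_that("clearance reproduces the zero- and infinite-K0A limits", {
  fs <- flow_setting(100, 16.67 * 60)
  expect_identical(clearance(fs, dialyzer_params(k0a = 0)), 0)
  fs2 <- flow_setting(200, 16.67 * 60)
  expect_equal(clearance(fs2, dialyzer_params(k0a = 1e6)), 16.67,
               tolerance = 1e-9)
})

test_that("clearance matches the frozen countercurrent BVP oracle value", {
  # bvp_clearance(150, 33.33, 50) computed by linear shooting at
  # rtol 1e-12 (helper-oracles.R)
  fs <- flow_setting(150, 33.33 * 60)
  expect_equal(clearance(fs, dialyzer_params(k0a = 50)),
               24.6584427760243, tolerance = 1e-10)
})

test_that("closed-form clearance agrees with the BVP oracle on a grid", {
  qb_g <- c(50, 100, 150, 200, 300)
  qd_g <- c(10, 20, 33.33, 50, 80)       # ml/min
  k0a_g <- c(5, 20, 50, 150, 400)
  for (qb in qb_g) for (qd in qd_g) for (k0a in k0a_g) {
    fs <- flow_setting(qb, qd * 60)
    k_closed <- clearance(fs, dialyzer_params(k0a = k0a))
    k_bvp <- bvp_clearance(qb, qd, k0a)
    expect_equal(k_closed, k_bvp, tolerance = 1e-6,
                 label = sprintf("K(qb=%g, qd=%g, k0a=%g)", qb, qd, k0a))
  }
  # partition (sieving < 1) variant against the same oracle
  for (s in c(0.93, 0.7)) {
    fs <- flow_setting(150, 33.33 * 60)
    expect_equal(clearance(fs, dialyzer_params(k0a = 50, sieving_membrane = s)),
                 bvp_clearance(150, 33.33, 50, s = s), tolerance = 1e-6)
  }
})

test_that("clearance is nondecreasing in qb, qd and k0a", {
  set.seed(42)
  for (i in 1:200) {
    qb <- runif(1, 50, 400); qd_h <- runif(1, 500, 6000)
    k0a <- runif(1, 1, 800)
    base <- clearance(flow_setting(qb, qd_h), dialyzer_params(k0a = k0a))
    up_qb <- clearance(flow_setting(qb * runif(1, 1, 2), qd_h),
                       dialyzer_params(k0a = k0a))
    up_qd <- clearance(flow_setting(qb, qd_h * runif(1, 1, 2)),
                       dialyzer_params(k0a = k0a))
    up_k <- clearance(flow_setting(qb, qd_h),
                      dialyzer_params(k0a = k0a * runif(1, 1, 2)))
    expect_gte(up_qb, base - 1e-12)
    expect_gte(up_qd, base - 1e-12)
    expect_gte(up_k, base - 1e-12)
  }
})

test_that("clearance stays within [0, min(qb, qd)] and obeys asymptotic limits", {
  set.seed(7)
  for (i in 1:200) {
    qb <- runif(1, 50, 400); qd_h <- runif(1, 500, 6000)
    fs <- flow_setting(qb, qd_h)
    s <- runif(1, 0.5, 1)
    k <- clearance(fs, dialyzer_params(k0a = runif(1, 0, 1e4),
                                       sieving_membrane = s))
    expect_gte(k, 0)
    expect_lte(k, min(qb, fs$qd) + 1e-9)
  }
  # small-k0a limit: K -> k0a * (1 - perm_red) * sieving
  for (qb in c(100, 200)) for (qd_h in c(1000, 3000)) {
    fs <- flow_setting(qb, qd_h)
    k0a <- 1e-8 * qb
    k <- clearance(fs, dialyzer_params(k0a = k0a, sieving_membrane = 0.93,
                                       permeability_reduction = 0.1))
    expect_equal(k / (k0a * 0.9 * 0.93), 1, tolerance = 1e-6)
    # first-order Taylor correction dominates at k0a = 1e-4 qb
    k0a <- 1e-4 * qb
    k <- clearance(fs, dialyzer_params(k0a = k0a))
    expect_equal(k / k0a, 1, tolerance = 1e-3)
  }
  # infinite-k0a saturation
  fs <- flow_setting(100, 3000)
  expect_equal(clearance(fs, dialyzer_params(k0a = 1e9)), 50, tolerance = 1e-9)
  # exponent guard: huge k0a with qb < qd must not overflow
  expect_equal(clearance(flow_setting(100, 60 * 500),
                         dialyzer_params(k0a = 1e6)), 100, tolerance = 1e-6)
})

test_that("clearance is continuous across the equal-flow branch", {
  qb <- 120
  k0a <- 80
  k_eq <- clearance(flow_setting(qb, qb * 60), dialyzer_params(k0a = k0a))
  for (eps in c(1e-6, -1e-6)) {
    k <- clearance(flow_setting(qb, qb * 60 / (1 + eps)),
                   dialyzer_params(k0a = k0a))
    expect_lt(abs(k - k_eq), 1e-6 * qb)
  }
})

test_that("single_pass conserves mass and keeps c_rl between c_al and cd_in", {
  set.seed(11)
  for (i in 1:1000) {
    fs <- flow_setting(runif(1, 50, 400), runif(1, 500, 6000))
    params <- dialyzer_params(k0a = runif(1, 0, 1000),
                              sieving_membrane = runif(1, 0.5, 1),
                              alpha_backfiltration = runif(1, 0.2, 1))
    c_al <- runif(1, 0, 64); cd <- runif(1, 0, 64)
    p <- single_pass(c_al, cd, fs, params)
    lhs <- fs$qb * (p$c_al - p$c_rl)
    rhs <- fs$qd * (p$c_el - p$cd_in)
    expect_lte(abs(lhs - rhs), 1e-12 * max(1, abs(lhs)))
    lo <- min(c_al, cd); hi <- max(c_al, cd)
    expect_gte(p$c_rl, lo - 1e-12)
    expect_lte(p$c_rl, hi + 1e-12)
  }
})

test_that("equilibrated dialysate eliminates the per-pass loss at any flows", {
  for (fs in flow_grid()) {
    for (k0a in c(0.1, 45, 1e5)) {
      p <- single_pass(16, 16, fs, dialyzer_params(k0a = k0a))
      expect_identical(p$c_rl, 16)
      expect_identical(p$c_el, 16)
    }
  }
})

test_that("zero clearance passes concentrations through unchanged", {
  p <- single_pass(5, 3, flow_setting(100, 2000), dialyzer_params(k0a = 0))
  expect_identical(p$c_rl, 5)
  expect_identical(p$c_el, 3)
})

test_that("a 35.6% single-pass loss takes 16 mg/L blood to ~10 mg/L", {
  # choose K so that K/qb = 0.356 at qb = 100, qd = 3000 ml/h
  fs <- flow_setting(100, 3000)
  k0a <- invert_clearance(0.356 * fs$qb, fs)
  p <- single_pass(16, 0, fs, dialyzer_params(k0a = k0a))
  expect_equal(p$c_rl, 10.304, tolerance = 1e-9)
  expect_equal(round(p$c_rl), 10)
  expect_equal(percent_change(p), -35.6, tolerance = 1e-9)
})

test_that("percent change is signed and undefined at zero inlet", {
  fs <- flow_setting(150, 2000)
  p_eq <- single_pass(16, 16, fs, dialyzer_params(k0a = 45))
  expect_identical(percent_change(p_eq), 0)
  p0 <- single_pass(0, 16, fs, dialyzer_params(k0a = 45))
  expect_true(is.na(p0$extraction))
  expect_error(percent_change(p0), "undefined")
  # enrichment gain is positive: 16 -> 28.608 is +78.8%
  p_gain <- list(c_al = 16, c_rl = 28.608)
  expect_equal(100 * (p_gain$c_rl - p_gain$c_al) / p_gain$c_al, 78.8,
               tolerance = 1e-9)
})

test_that("the effluent/inlet ratio estimates the membrane partition at saturation", {
  fs <- flow_setting(200, 1000)
  p1 <- single_pass(16, 0, fs, dialyzer_params(k0a = 1e4))
  expect_equal(estimate_sieving(p1$c_el, p1$c_al), 1, tolerance = 1e-3)
  p93 <- single_pass(16, 0, fs, dialyzer_params(k0a = 1e4,
                                                sieving_membrane = 0.93))
  expect_equal(estimate_sieving(p93$c_el, p93$c_al), 0.93, tolerance = 1e-3)
  expect_identical(estimate_sieving(12, 12), 1)
  expect_error(estimate_sieving(1, 0), "undefined")
})

test_that("back-filtration asymmetry scales only the dialysate-to-blood direction", {
  fs <- flow_setting(150, 2000)
  sym <- dialyzer_params(k0a = 45)
  asym <- dialyzer_params(k0a = 45, alpha_backfiltration = 0.5)
  loss_sym <- single_pass(16, 0, fs, sym)
  loss_asym <- single_pass(16, 0, fs, asym)
  expect_identical(loss_sym$c_rl, loss_asym$c_rl)
  gain_sym <- single_pass(16, 64, fs, sym)
  gain_asym <- single_pass(16, 64, fs, asym)
  expect_identical(gain_asym$clearance, 0.5 * gain_sym$clearance)
  # cap: huge alpha cannot push clearance past min(qb, qd)
  huge <- single_pass(16, 64, fs, dialyzer_params(k0a = 45,
                                                  alpha_backfiltration = 100))
  expect_lte(huge$clearance, min(fs$qb, fs$qd))
  expect_gte(huge$c_rl, 16)
  expect_lte(huge$c_rl, 64)
})

test_that("pass-result tables round-trip through CSV in the documented schema", {
  passes <- lapply(flow_grid()[1:3], function(fs)
    single_pass(16, 0, fs, dialyzer_params(k0a = 45)))
  tab <- pass_results_table(passes)
  expect_named(tab, c("setting", "qb_ml_min", "qd_ml_h", "cd_mg_l",
                      "c_al_mg_l", "c_rl_mg_l", "c_el_mg_l",
                      "clearance_ml_min", "extraction_pct"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pass_results(passes, path)
  back <- read_pass_results(path)
  expect_equal(back$c_rl_mg_l, tab$c_rl_mg_l, tolerance = 1e-12)
  expect_error(read_pass_results(withr::local_tempfile(lines = "a,b\n1,2",
                                                       fileext = ".csv")),
               "missing columns")
})
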