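nta <- ligand_record("NTA", c(9.84, 12.40, 14.23))

test_that("required constants reproduce the published cross-tabulation", {
  exp <- expected_required_k
  for (i in seq_along(exp$f)) {
    got <- required_log_beta_eff(exp$f[i], exp$m0[i], exp$ratios)
    expect_equal(round(got, 2), unname(exp$vals[i, ]),
                 info = sprintf("M0=%g f=%g", exp$m0[i], exp$f[i]))
  }
  # trivial closed-form anchor: 0.5 / (2 * 0.5 * 0.5) = 1
  expect_equal(required_log_beta_eff(0.5, 2, 1), 0)
})

test_that("required constants are monotone and reject impossible demands", {
  f <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(required_log_beta_eff(f, 2e-5, 50)) > 0))
  for (fi in c(0.25, 0.75, 0.99)) {
    rr <- vapply(c(2, 5, 20, 50, 100), function(r)
      required_log_beta_eff(fi, 2e-5, r), 1)
    expect_true(all(diff(rr) < 0))
    mm <- vapply(c(2e-6, 2e-5, 2e-4, 2e-3), function(m)
      required_log_beta_eff(fi, m, 50), 1)
    expect_true(all(diff(mm) < 0))
  }
  expect_error(required_log_beta_eff(1.2, 2e-5, 50), "\\(0, 1\\)")
  expect_error(required_log_beta_eff(0.9, 2e-5, 0.5), "ratio > f")
})

test_that("log D matches a direct high-precision polynomial evaluation", {
  # independent oracle: evaluate 1 + sum beta_j [H]^j directly
  direct <- function(lb, ph) log10(1 + sum(10^lb * (10^-ph)^seq_along(lb)))
  for (ph in c(-1, 0, 2.79, 5.05, 7, 10, 14)) {
    expect_equal(log_d(nta, ph), direct(c(9.84, 12.40, 14.23), ph),
                 tolerance = 1e-12)
  }
  expect_equal(round(log_d(nta, 14), 2), 0.00)
  expect_equal(round(log_d(nta, 5.05), 2), 4.79)
  expect_equal(round(log_d(nta, 2.79), 2), 7.27)
})

test_that("log D survives extreme arguments without overflow", {
  big <- ligand_record("BIG", c(10, 20, 30))
  # naive 10^30 * (10^2)^3 would overflow a direct sum of betas times [H]^j
  expect_true(is.finite(log_d(big, -2)))
  expect_equal(log_d(big, -2), 36, tolerance = 1e-6)
  expect_true(log_d(big, 20) < 1e-6)
})

test_that("log D is non-increasing in pH and vanishes at high pH", {
  grid <- seq(-2, 14, by = 0.05)
  for (seed in c(1, 2, 3, 10)) {
    lig <- synthesize_ligand(seed, n = 1 + (seed %% 6))
    v <- log_d(lig, grid)
    expect_true(all(diff(v) <= 0))
    expect_true(all(v >= 0))
    expect_lt(log_d(lig, 20), 1e-6)
  }
})

test_that("effective constants follow the quotient convention", {
  # worked reference: log beta(Cd-NTA) = 9.8
  # worked values are quoted to 2 dp at pH values that are themselves
  # rounded, so match at the 0.01 level rather than by exact re-rounding
  expect_lt(abs(log_beta_eff(9.8, nta, 2.79) - 2.53), 0.01)
  expect_lt(abs(log_beta_eff(9.8, nta, 5.05) - 5.00), 0.01)
  # high-pH limit recovers the stoichiometric constant
  expect_equal(round(log_beta_eff(9.8, nta, 14), 2), 9.80)
  # non-decreasing in pH
  v <- log_beta_eff(9.8, nta, seq(0, 14, by = 0.1))
  expect_true(all(diff(v) >= 0))
})

test_that("F(H) curves are vertical translations of log D", {
  grid <- seq(0, 14, by = 0.25)
  d0 <- log_f_curve(nta, 0, 2e-5, 50, grid)
  expect_equal(d0, log_d(nta, grid))  # 0 % curve is D(H) itself
  c25 <- log_f_curve(nta, 0.25, 2e-5, 50, grid)
  c99 <- log_f_curve(nta, 0.99, 2e-5, 50, grid)
  diffs <- c99 - c25
  expect_lt(max(diffs) - min(diffs), 1e-10)
  expect_lt(abs(diffs[1] - (5.00 - 2.53)), 0.01)
  # the 25 % curve meets log beta(Cd-NTA) = 9.8 at pH 2.79
  expect_lt(abs(log_f_curve(nta, 0.25, 2e-5, 50, 2.79) - 9.80), 0.01)
})

test_that("complexed fraction solves the 1:1 mass balances stably", {
  expect_equal(complexed_fraction(9.8, nta, c(2, 7, 12), 2e-5, 0), c(0, 0, 0))
  expect_equal(round(complexed_fraction(9.8, nta, 3.15, 2e-5, 1e-3), 2), 0.50)
  # limiting stoichiometry: overwhelming constant, excess ligand
  expect_equal(complexed_fraction(40, nta, 7, 2e-5, 1e-3), 1, tolerance = 1e-9)
  # underflowing constant degrades gracefully to zero
  expect_equal(complexed_fraction(-300, nta, 7, 2e-5, 1e-3), 0)
  # monotone in pH, in ligand excess, and in the constant
  ph <- seq(1, 12, by = 0.5)
  expect_true(all(diff(complexed_fraction(9.8, nta, ph, 2e-5, 1e-3)) > 0))
  fl <- vapply(c(1e-4, 5e-4, 1e-3, 5e-3), function(l0)
    complexed_fraction(9.8, nta, 4, 2e-5, l0), 1)
  expect_true(all(diff(fl) > 0))
  fb <- vapply(c(8, 9, 10, 11), function(b)
    complexed_fraction(b, nta, 4, 2e-5, 1e-3), 1)
  expect_true(all(diff(fb) > 0))
})

test_that("pH solver reproduces the worked cadmium example", {
  r <- ph_for_fraction(9.8, nta, 0.25, 2e-5, 50)
  expect_identical(r$status, "ok")
  expect_lt(abs(r$ph - 2.79), 0.005)
  expect_lt(abs(ph_for_fraction(9.8, nta, 0.50, 2e-5, 50)$ph - 3.15), 0.005)
  expect_lt(abs(ph_for_fraction(9.8, nta, 0.99, 2e-5, 50)$ph - 5.05), 0.005)
  # weakly bound calcium complexes only at high pH
  expect_equal(round(ph_for_fraction(6.57, nta, 0.25, 2e-5, 50)$ph, 1), 5.8)
})

test_that("pH solver types its non-numeric outcomes", {
  # a constant one log unit below the requirement can never reach f
  req <- required_log_beta_eff(0.5, 2e-5, 50)
  expect_identical(ph_for_fraction(req - 1, nta, 0.5, 2e-5, 50)$status,
                   "unattainable")
  expect_true(is.na(ph_for_fraction(req - 1, nta, 0.5, 2e-5, 50)$ph))
  # a monoprotic ligand with a huge constant is done complexing below pH -2
  weak <- ligand_record("MONO", 5)
  expect_identical(ph_for_fraction(12, weak, 0.25, 2e-5, 50)$status,
                   "below_range")
  # marginally attainable: root beyond pH 14
  lb <- required_log_beta_eff(0.25, 2e-5, 50) + 1e-9
  expect_identical(ph_for_fraction(lb, nta, 0.25, 2e-5, 50)$status,
                   "above_range")
})

test_that("pH solver agrees with stats::uniroot and inverts complexed_fraction", {
  # independent root-finder on the same monotone equation
  for (case in list(list(lb = 9.8, f = 0.75), list(lb = 13.48, f = 0.25),
                    list(lb = 6.57, f = 0.99))) {
    target <- case$lb - required_log_beta_eff(case$f, 2e-5, 50)
    ind <- stats::uniroot(function(p) log_d(nta, p) - target, c(-2, 14),
                          tol = 1e-10)$root
    expect_equal(ph_for_fraction(case$lb, nta, case$f, 2e-5, 50)$ph, ind,
                 tolerance = 1e-3)
  }

  # property: complexed_fraction at the solved pH returns f
  for (i in 1:40) {
    p <- random_system_params(i)
    f <- stats::runif(1, 0.05, 0.99)
    r <- ph_for_fraction(p$log_beta_ml, p$ligand, f, p$m_total, p$ratio)
    if (r$status != "ok") next
    got <- complexed_fraction(p$log_beta_ml, p$ligand, r$ph,
                              p$m_total, p$ratio * p$m_total)
    expect_equal(got, f, tolerance = 1e-3)
  }
})

test_that("minimal ratio inverts the required-constant relation", {
  # algebraic anchor: 10^lbe * M0 = 1, f = 0.5 -> R = 0.5 + 0.5/0.5
  expect_equal(min_ratio_for_fraction(0.5, log10(1 / 2e-5), 2e-5), 1.5)
  # vanishing demand needs vanishing ligand
  expect_lt(min_ratio_for_fraction(1e-9, 5, 2e-5), 1e-6)
  # round-trip through the published 75 % requirement
  lbe <- required_log_beta_eff(0.75, 2e-5, 50)
  expect_equal(round(lbe, 2), 3.48)
  r <- min_ratio_for_fraction(0.75, lbe, 2e-5)
  expect_equal(r, 50, tolerance = 1e-9)
  expect_equal(required_log_beta_eff(0.75, 2e-5, r), lbe, tolerance = 1e-6)
})

test_that("scenario validation guards its invariants", {
  expect_error(scenario(m_total = 0), "m_total")
  expect_error(scenario(ratio = 0.5), "ratio")
  expect_error(scenario(target_fractions = c(0.5, 0.25)), "increasing")
  expect_error(scenario(target_fractions = c(0.5, 1.0)), "\\(0, 1\\)")
  s <- scenario(2e-5, 50)
  expect_equal(s$l_total, 1e-3)
})
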