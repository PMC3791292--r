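test_that("shell averaging is the arithmetic mean within each shell", {
  shells <- tibble::tibble(shell = 1:2, b_center = c(0, 700),
                           n_volumes = c(2L, 3L),
                           volumes = list(1:2, 3:5))
  sig <- tibble::tibble(volume = 1:5, signal = c(4, 4, 1, 2, 3))
  means <- shell_average(sig, shells)
  expect_equal(means$signal, c(4, 2))
  expect_equal(means$n_volumes, c(2L, 3L))

  expect_error(shell_average(sig[-3, ], shells), "volume index 3")
})

test_that("mono-exponential fits recover exact mono data and reject degenerate input", {
  shells <- mbi_shells()
  dec <- synthesize_shell_signals(shells, s0 = 1, mu = 1, du = 3e-3, dr = 0,
                                  mode = "shell-mean")
  fit <- fit_mono(dec)
  expect_equal(fit$s0, 1, tolerance = 1e-9)
  expect_equal(fit$adc, 3e-3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$converged)

  expect_error(fit_mono(tibble::tibble(b = c(0, 0), signal = c(1, 1))),
               "distinct b-values")
  expect_error(fit_mono(tibble::tibble(b = c(0, 700), signal = c(0, 0))),
               "all-zero")
})

test_that("the two-compartment fit recovers published patient parameters from noiseless data", {
  fit <- fit_biexp(make_decay())
  expect_true(fit$converged)
  expect_false(fit$at_boundary)
  expect_equal(fit$mu, 0.55, tolerance = 1e-6)
  expect_equal(fit$du, 1.8e-3, tolerance = 1e-6)
  expect_equal(fit$dr, 7.1e-5, tolerance = 1e-6)
  expect_equal(fit$s0, 1, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("noiseless recovery holds across the physiological parameter box", {
  shells <- mbi_shells()
  draws <- withr::with_seed(99, tibble::tibble(
    mu = runif(20, 0.3, 0.7),
    du = runif(20, 1e-3, 3e-3),
    dr = runif(20, 2e-5, 2e-4)
  ))
  for (i in seq_len(nrow(draws))) {
    dec <- synthesize_shell_signals(shells, s0 = 1, mu = draws$mu[i],
                                    du = draws$du[i], dr = draws$dr[i],
                                    mode = "shell-mean")
    fit <- fit_biexp(dec)
    expect_equal(fit$mu, draws$mu[i], tolerance = 1e-5)
    expect_equal(fit$du, draws$du[i], tolerance = 1e-5)
    expect_equal(fit$dr, draws$dr[i], tolerance = 1e-5)
  }
})

test_that("pure mono-exponential input drives the two-compartment fit to a degenerate labeling", {
  shells <- mbi_shells()
  dec <- synthesize_shell_signals(shells, s0 = 1, mu = 1, du = 1e-3, dr = 0,
                                  mode = "shell-mean")
  fit <- fit_biexp(dec)
  expect_true(fit$at_boundary)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("component relabeling makes the fit invariant to a swapped start", {
  dec <- make_decay()
  default_fit <- fit_biexp(dec)
  # the exact optimum with component labels exchanged: (mu, du) <-> (1-mu, dr)
  swapped <- fit_biexp(dec, start = list(s0 = 1, mu = 1 - 0.55,
                                         du = 7.1e-5, dr = 1.8e-3))
  expect_gte(swapped$du, swapped$dr)
  expect_equal(swapped$mu, default_fit$mu, tolerance = 1e-5)
  expect_equal(swapped$du, default_fit$du, tolerance = 1e-5)
  expect_equal(swapped$dr, default_fit$dr, tolerance = 1e-5)
})

test_that("the bi-exponential model never fits worse than the mono-exponential (nested models)", {
  shells <- mbi_shells()
  cases <- list(
    make_decay(),
    synthesize_shell_signals(shells, 1, mu = 1, du = 3e-3, dr = 0,
                             mode = "shell-mean"),
    {
      d <- make_decay()
      d$signal <- add_rician_noise(d$signal, 0.02, seed = 4)
      d
    }
  )
  for (dec in cases) {
    bi <- fit_biexp(dec)
    mono <- fit_mono(dec)
    expect_lte(bi$ssr, mono$ssr + 1e-12)
    expect_gte(bi$r_squared, mono$r_squared - 1e-12)
  }
})

test_that("fits are scale-equivariant in the signal amplitude", {
  dec <- make_decay()
  dec$signal <- add_rician_noise(dec$signal, 0.01, seed = 2)
  f1 <- fit_biexp(dec)
  scaled <- dec
  scaled$signal <- dec$signal * 1000
  f2 <- fit_biexp(scaled)
  expect_equal(f2$s0, 1000 * f1$s0, tolerance = 1e-6)
  expect_equal(f2$mu, f1$mu, tolerance = 1e-6)
  expect_equal(f2$du, f1$du, tolerance = 1e-6)
  expect_equal(f2$dr, f1$dr, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("r_squared matches its definition and rejects constant data", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_error(r_squared(rep(2, 4), rep(2, 4)), "zero total sum of squares")
  expect_error(r_squared(1:3, 1:4), "same length")
})

test_that("the grid oracle finds the truth on-grid and the optimizer refines it", {
  dec <- make_decay()
  oracle <- grid_oracle(dec,
                        s0 = c(0.9, 1, 1.1),
                        mu = c(0.45, 0.55, 0.65),
                        du = c(1.6e-3, 1.8e-3, 2.0e-3),
                        dr = c(5e-5, 7.1e-5, 9e-5))
  expect_equal(unname(oracle$par),
               c(1, 0.55, 1.8e-3, 7.1e-5), tolerance = 1e-12)
  expect_equal(oracle$ssr, 0, tolerance = 1e-20)

  # single-point grid returns that point
  single <- grid_oracle(dec, 1, 0.5, 2e-3, 1e-4)
  expect_equal(unname(single$par), c(1, 0.5, 2e-3, 1e-4))

  # started from the oracle's best point, the fit ends at least as low
  noisy <- dec
  noisy$signal <- add_rician_noise(noisy$signal, 0.02, seed = 9)
  oracle2 <- grid_oracle(noisy,
                         s0 = seq(0.9, 1.1, length.out = 5),
                         mu = seq(0.3, 0.8, length.out = 8),
                         du = seq(1e-3, 3e-3, length.out = 8),
                         dr = seq(1e-5, 2e-4, length.out = 8))
  fit <- fit_biexp(noisy, start = as.list(oracle2$par))
  expect_lte(fit$ssr, oracle2$ssr + 1e-10)
  # and the default-start fit agrees with the oracle-refined optimum
  default_fit <- fit_biexp(noisy)
  expect_equal(default_fit$ssr, fit$ssr, tolerance = 1e-6)
})

test_that("tidy and glance expose the fitted parameters and diagnostics", {
  fit <- fit_biexp(make_decay())
  td <- tidy(fit)
  expect_equal(td$term, c("s0", "mu", "du", "dr"))
  gl <- glance(fit)
  expect_equal(gl$pdi, fit$dr / fit$du)
  expect_true(gl$converged)
  mono <- fit_mono(make_decay())
  expect_equal(tidy(mono)$term, c("s0", "adc"))
  expect_lt(glance(mono)$r.squared, 1)
})
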