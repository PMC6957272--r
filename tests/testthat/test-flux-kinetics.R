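test_that("normalization pins the anchors and matches the closed form", {
  tr <- simulate_flux_trace(k_fast = 0.05, floor = 0.25, noise_sigma = 0,
                            valinomycin = TRUE)
  nt <- normalize_trace(tr, mode = "valinomycin")
  f_ini <- attr(nt, "f_ini"); f_val <- attr(nt, "f_floor")
  # last baseline point maps to 1, valinomycin floor to 0
  expect_equal(nt$nf[max(which(nt$time <= 100))], 1, tolerance = 1e-12)
  expect_equal(min(nt$nf), 0, tolerance = 1e-9)
  # pointwise hand evaluation of (F - F_val) / (F_ini - F_val)
  expect_equal(nt$nf, (tr$fluorescence - f_val) / (f_ini - f_val),
               tolerance = 1e-12)
})

test_that("normalization is invariant to affine rescaling of the raw signal", {
  tr <- simulate_flux_trace(k_fast = 0.096, noise_sigma = 0.005, seed = 5)
  nt1 <- normalize_trace(tr, mode = "steady_state")
  tr2 <- tr
  tr2$fluorescence <- 3.7 * tr$fluorescence - 120
  nt2 <- normalize_trace(tr2, mode = "steady_state")
  expect_equal(nt1$nf, nt2$nf, tolerance = 1e-9)
})

test_that("degenerate and misconfigured traces are rejected", {
  flat <- as_flux_trace(tibble::tibble(time = seq(0, 500, 2),
                                       fluorescence = 1000))
  expect_error(normalize_trace(flat, mode = "steady_state"),
               class = "rck_degenerate_error")
  tr <- simulate_flux_trace(k_fast = 0.05)
  expect_error(normalize_trace(tr, mode = "valinomycin"),
               class = "rck_usage_error")   # no valinomycin segment
  expect_error(as_flux_trace(tibble::tibble(time = c(0, 2, 2),
                                            fluorescence = 1:3)),
               class = "rck_validation_error")
})

test_that("noiseless single exponentials are recovered to numerical precision", {
  for (k in c(0.096, 0.011, 1)) {
    tr <- simulate_flux_trace(k_fast = k, noise_sigma = 0)
    fit <- fit_exponential(normalize_trace(tr, "steady_state"), 1)
    expect_equal(1 / fit$pars[["tau"]], k, tolerance = 1e-6)
  }
})

test_that("the first post-addition point is excluded from the fit", {
  tr <- simulate_flux_trace(k_fast = 0.096, noise_sigma = 0)
  nt <- normalize_trace(tr, "steady_state")
  fit <- fit_exponential(nt, 1)
  n_from_x0 <- sum(nt$time >= 100)
  expect_equal(fit$n, n_from_x0 - 1L)
  expect_false(102 %in% fit$data$time)
  expect_true(100 %in% fit$data$time)
})

test_that("flat segments and short segments fail with explicit errors", {
  rising <- as_flux_trace(tibble::tibble(
    time = seq(0, 500, 2),
    fluorescence = 1000 + 0.01 * seq(0, 500, 2)))
  # monotone time, but no decay after x0
  expect_error(fit_exponential(rising, 1), class = "rck_degenerate_error")
  tr <- simulate_flux_trace(k_fast = 0.05, noise_sigma = 0)
  # only a handful of points remain beyond a late x0
  expect_error(fit_exponential(tr, 2, x0 = 492), class = "rck_usage_error")
})

test_that("noisy single-exponential recovery stays within a few percent", {
  k_true <- 1 / 10.4
  ks <- sapply(1:25, function(s) {
    tr <- simulate_flux_trace(k_fast = k_true, noise_sigma = 0.01, seed = s)
    extract_rate(fit_exponential(normalize_trace(tr, "steady_state"), 1))$k
  })
  expect_lt(abs(mean(ks) - k_true) / k_true, 0.02)
  expect_true(all(abs(ks - k_true) / k_true < 0.05))
})

test_that("two-phase fits recover both time constants", {
  tr <- simulate_flux_trace(k_fast = 1 / 8, k_slow = 1 / 80, amp_fast = 0.6,
                            noise_sigma = 0.01, seed = 17)
  fit <- fit_exponential(normalize_trace(tr, "steady_state"), 2)
  expect_equal(fit$pars[["tau_fast"]], 8, tolerance = 0.1)
  expect_equal(fit$pars[["tau_slow"]], 80, tolerance = 0.1)
  expect_lte(fit$pars[["tau_fast"]], fit$pars[["tau_slow"]])
})

test_that("model selection prefers the simplest adequate model", {
  single <- normalize_trace(simulate_flux_trace(k_fast = 0.08,
                                                noise_sigma = 0.01, seed = 3),
                            "steady_state")
  f1 <- fit_exponential(single, 1); f2 <- fit_exponential(single, 2)
  expect_equal(select_model(f1, f2)$order, 1L)

  biphasic <- normalize_trace(
    simulate_flux_trace(k_fast = 1 / 8, k_slow = 1 / 80, amp_fast = 0.5,
                        noise_sigma = 0.01, seed = 4), "steady_state")
  g1 <- fit_exponential(biphasic, 1); g2 <- fit_exponential(biphasic, 2)
  expect_equal(select_model(g1, g2)$order, 2L)

  # exact criterion tie falls back to order 1
  g2_tied <- g2
  g2_tied$aicc <- g1$aicc
  expect_equal(select_model(g1, g2_tied)$order, 1L)
  expect_error(select_model(f1, g2), class = "rck_usage_error")
  expect_error(select_model(f2, f1), class = "rck_usage_error")
})

test_that("rate extraction inverts tau and reports fast-component dominance", {
  tr <- simulate_flux_trace(k_fast = 1 / 10.417, noise_sigma = 0)
  fit <- fit_exponential(normalize_trace(tr, "steady_state"), 1)
  rate <- extract_rate(fit)
  expect_equal(rate$k, 0.096, tolerance = 1e-3)
  expect_equal(rate$component, "single")
  # inversion is an exact identity on the fitted tau
  expect_equal(1 / rate$k, fit$pars[["tau"]], tolerance = 1e-12)

  biph <- fit_exponential(normalize_trace(
    simulate_flux_trace(k_fast = 1 / 8, k_slow = 1 / 80, amp_fast = 0.3,
                        noise_sigma = 0.005, seed = 8), "steady_state"), 2)
  r2 <- extract_rate(biph)
  expect_equal(r2$component, "fast")
  expect_equal(r2$k, 1 / biph$pars[["tau_fast"]], tolerance = 1e-12)
  expect_false(r2$fast_dominant)   # fast amplitude is the minor one here
})

test_that("Hill fits recover noiseless parameters exactly", {
  tit <- simulate_titration(k_half = 155, n_hill = 1.8, start = 0.01,
                            end = 0.10, noise_sigma = 0, n_replicates = 1)
  fit <- fit_hill(tit)
  expect_equal(fit$pars[["K_half"]], 155, tolerance = 1e-6)
  expect_equal(fit$pars[["n_hill"]], 1.8, tolerance = 1e-6)
  expect_equal(fit$pars[["Start"]], 0.01, tolerance = 1e-6)
  expect_equal(fit$pars[["End"]], 0.10, tolerance = 1e-6)
})

test_that("Hill preconditions and unit handling are enforced", {
  expect_error(fit_hill(tibble::tibble(conc = c(0, 100), rate = c(0.01, 0.1))),
               class = "rck_usage_error")
  mixed <- tibble::tibble(conc = c(0, 10, 100, 1000), rate = c(1, 2, 3, 4),
                          unit = c("uM", "uM", "mM", "uM"))
  expect_error(fit_hill(mixed), class = "rck_usage_error")
  expect_error(fit_hill(tibble::tibble(conc = c(-1, 1, 2, 3), rate = 1:4)),
               class = "rck_usage_error")
})

test_that("replicate Hill fitting reports mean and SD per parameter", {
  tit <- simulate_titration(seed = 12)
  res <- fit_hill_replicates(tit)
  expect_equal(nrow(res$summary), 4L)
  expect_equal(res$summary$n_replicates, rep(3L, 4))
  expect_lt(unname(abs(res$summary$mean[res$summary$term == "K_half"] - 155)) / 155,
            0.15)
  expect_length(res$fits, 3L)
})

test_that("broom-style accessors expose fit results as tibbles", {
  tr <- simulate_flux_trace(k_fast = 0.05, noise_sigma = 0.005, seed = 2)
  fit <- fit_exponential(normalize_trace(tr, "steady_state"), 1)
  td <- tidy(fit)
  expect_true(all(c("y0", "A1", "tau") %in% td$term))
  expect_equal(glance(fit)$order, 1L)
  hf <- fit_hill(simulate_titration(noise_sigma = 0, n_replicates = 1))
  expect_equal(tidy(hf)$term, c("Start", "End", "K_half", "n_hill"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(hf), "ggplot")
})
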