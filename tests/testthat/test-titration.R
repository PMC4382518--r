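test_that("model identities: half-point value, zero limit, monotonicity", {
  expect_identical(model_efret(0.2, 0.36, 1 / 90, 1, 0), 0.2)
  expect_equal(model_efret(0.2, 0.36, 1 / 90, 1, 90), 0.2 + 0.18,
               tolerance = 1e-12)
  # half-point relation for random parameter draws
  draws <- withr::with_seed(42, data.frame(
    E0 = runif(50, 0, 0.4), dE = runif(50, 0.05, 0.6),
    KA = exp(runif(50, -8, 2)), n = runif(50, 0.4, 4)))
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    hp <- half_point(d$KA, d$n)
    expect_equal(model_efret(d$E0, d$dE, d$KA, d$n, hp), d$E0 + d$dE / 2,
                 tolerance = 1e-12)
  }
  conc <- seq(0, 1000, length.out = 200)
  e <- model_efret(0.2, 0.36, 1 / 70, 1.5, conc)
  expect_true(all(diff(e) > 0))
  expect_error(model_efret(0.2, 0.36, 1 / 70, 1, -1), class = "kt_input_error")
  expect_error(model_efret(0.2, 0.36, 0, 1, 1), class = "kt_input_error")
})

test_that("half_point algebra", {
  expect_equal(half_point(1 / 90, 1), 90, tolerance = 1e-12)
  expect_equal(half_point(1, 3.7), 1, tolerance = 1e-12)
  expect_equal(half_point(4, 2), 0.5, tolerance = 1e-12)  # (1/4)^(1/2)
  expect_error(half_point(-1, 1), class = "kt_domain_error")
  expect_error(half_point(1, 0), class = "kt_domain_error")
})

test_that("titration_curve validates and sorts its inputs", {
  tc <- titration_curve(c(100, 1, 10), c(0.5, 0.2, 0.3))
  expect_identical(tc$conc, c(1, 10, 100))
  expect_identical(tc$efret, c(0.2, 0.3, 0.5))
  expect_error(titration_curve(c(1, 2), 0.2), class = "kt_input_error")
  expect_error(titration_curve(c(-1, 2), c(0.2, 0.3)), class = "kt_input_error")
  expect_error(titration_curve(c(1, 2), c(0.2, 1.5)), class = "kt_input_error")
})

test_that("noise-free generator/fitter round trip recovers parameters to 1e-6", {
  truth <- list(E0 = 0.2, dE = 0.36, KA = 1 / 70, n = 1)
  curve <- simulate_titration(titration_spec(E0 = truth$E0, dE = truth$dE,
                                             KA = truth$KA, n = truth$n,
                                             noise_sd = 0))
  fit <- fit_titration(curve)
  for (p in names(truth))
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6, info = p)
  expect_equal(fit$half_point, 70, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  # a cooperative curve round-trips too
  curve2 <- simulate_titration(titration_spec(E0 = 0.15, dE = 0.45,
                                              half_point = 200, n = 1.8,
                                              noise_sd = 0))
  fit2 <- fit_titration(curve2)
  expect_equal(fit2$n, 1.8, tolerance = 1e-6)
  expect_equal(fit2$half_point, 200, tolerance = 1e-5)
})

test_that("the half-point identity holds for every returned fit", {
  specs <- list(kt7_titration_spec(noise_sd = 0.02, seed = 3),
                titration_spec(E0 = 0.1, dE = 0.5, half_point = 300, n = 2,
                               noise_sd = 0.01, seed = 9))
  for (sp in specs) {
    fit <- fit_titration(simulate_titration(sp))
    expect_equal(model_efret(fit$E0, fit$dE, fit$KA, fit$n, fit$half_point),
                 fit$E0 + fit$dE / 2, tolerance = 1e-12)
  }
})

test_that("noisy half-point estimation is unbiased (< 2%) over 200 seeds", {
  # At noise sd 0.02 on a 12-point curve of amplitude 0.36 the half-point
  # estimator is noisy (Cramer-Rao relative SE ~0.19) but essentially
  # unbiased; the bias bound is the module's stated invariant.
  hp <- vapply(1:200, function(s) {
    curve <- simulate_titration(kt7_titration_spec(noise_sd = 0.02, seed = s))
    fit_titration(curve)$half_point
  }, numeric(1))
  expect_lt(abs(mean(hp) / 70 - 1), 0.02)
  expect_lt(stats::median(abs(hp - 70) / 70), 0.25)
})

test_that("preconditions and degenerate curves", {
  short <- titration_curve(c(1, 10, 100, 1000), c(0.2, 0.3, 0.4, 0.5))
  expect_error(fit_titration(short), class = "kt_precondition_error")

  flat <- titration_curve(10^(0:6), rep(0.25, 7))
  fit <- fit_titration(flat)
  expect_identical(fit$dE, 0)
  expect_true("no_transition" %in% fit$flags)
  expect_equal(fit$E0, 0.25, tolerance = 1e-12)

  narrow <- titration_curve(seq(10, 50, length.out = 6),
                            model_efret(0.2, 0.36, 1 / 30, 1,
                                        seq(10, 50, length.out = 6)))
  expect_true("narrow_range" %in% fit_titration(narrow)$flags)
})

test_that("fix_n constrains the Hill coefficient", {
  curve <- simulate_titration(kt7_titration_spec(noise_sd = 0.02, seed = 11))
  fit <- fit_titration(curve, fix_n = 1)
  expect_identical(fit$n, 1)
  expect_true(fit$fixed_n)
})

test_that("unit equivariance: uM -> mM rescales KA by 1000^n", {
  for (n_true in c(1, 1.7)) {
    sp <- titration_spec(E0 = 0.2, dE = 0.4, half_point = 150, n = n_true,
                         noise_sd = 0)
    c_um <- simulate_titration(sp)
    c_mm <- convert_unit(c_um, "mM")
    f_um <- fit_titration(c_um)
    f_mm <- fit_titration(c_mm)
    expect_equal(f_mm$KA / f_um$KA, 1000^f_um$n, tolerance = 1e-4)
    expect_equal(f_mm$half_point * 1000, f_um$half_point, tolerance = 1e-5)
    expect_equal(f_mm$n, f_um$n, tolerance = 1e-5)
  }
})

test_that("titration tables round trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ligand=Na+ unit=mM",
               "concentration\tefret",
               "0\t0.21", "5\t0.24", "15\t0.33", "30\t0.38", "60\t0.47",
               "120\t0.52"), path)
  tc <- read_titration_table(path)
  expect_identical(tc$ligand, "Na+")
  expect_identical(tc$unit, "mM")
  expect_length(tc$conc, 6L)
  expect_error(read_titration_table(withr::local_tempfile(lines = "# nothing")),
               class = "kt_format_error")
})

test_that("bootstrap intervals are seeded, near-degenerate without noise, and warn when small", {
  curve <- simulate_titration(kt7_titration_spec(noise_sd = 0))
  fit <- fit_titration(curve)
  ci0 <- bootstrap_ci(curve, fit, n_boot = 60, seed = 5)
  expect_lt(max(ci0$ci[, "upper"] - ci0$ci[, "lower"]), 1e-6)

  noisy <- simulate_titration(kt7_titration_spec(noise_sd = 0.02, seed = 2))
  nf <- fit_titration(noisy)
  a <- bootstrap_ci(noisy, nf, n_boot = 80, seed = 7)
  b <- bootstrap_ci(noisy, nf, n_boot = 80, seed = 7)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci["half_point", "lower"] < nf$half_point &&
                nf$half_point < a$ci["half_point", "upper"])

  small <- bootstrap_ci(noisy, nf, n_boot = 20, seed = 1)
  expect_true(any(grepl("below 50", small$warnings)))
})
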