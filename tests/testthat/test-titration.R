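test_that("species fractions obey limits, identities and normalization", {
  m <- ionization_model(5.7, 8.8)
  # acid limit: fully protonated
  fr <- species_fractions(1, m)
  expect_gt(fr[1, "SH/OH"], 0.999)
  # at pH = pKa1 the first two species are equally populated
  fr2 <- species_fractions(5.7, m)
  expect_equal(unname(fr2[1, "SH/OH"]), unname(fr2[1, "SH/O-"]),
               tolerance = 1e-12)
  # normalization and monotonicity across a pH sweep
  ph <- seq(0, 14, by = 0.25)
  fr3 <- species_fractions(ph, m)
  expect_equal(rowSums(fr3), rep(1, length(ph)), tolerance = 1e-12)
  expect_true(all(diff(fr3[, "SH/OH"]) <= 1e-15))
  expect_true(all(diff(fr3[, "S-/O-"]) >= -1e-15))
  # neutral pH is dominated by the thiol-phenolate form
  fr7 <- species_fractions(7, m)
  expect_equal(unname(which.max(fr7[1, ])), 2L)
  expect_gt(fr7[1, "SH/O-"], 0.9)
  # one-site analogue
  m1 <- ionization_model(4.4)
  fr1 <- species_fractions(4.4, m1)
  expect_equal(unname(fr1[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_error(ionization_model(9, 5), "pka1 must be <")
})

test_that("predicted spectra peak at the dominant species' band", {
  m <- ionization_model(5.7, 8.8)
  wl <- seq(350, 650, by = 1)
  # extreme acid: pure protonated band at 420
  s_acid <- predict_spectrum(2, m, wavelengths = wl)
  expect_equal(wl[which.max(s_acid)], 420)
  # high pH: thiolate-phenolate at 543 (within one grid step; the
  # residual 566 species at pH 10 skews the argmax by at most 1 nm)
  s10 <- predict_spectrum(10, m, wavelengths = wl)
  expect_lte(abs(wl[which.max(s10)] - 543), 1)
  expect_equal(wl[which.max(predict_spectrum(12, m, wavelengths = wl))], 543)
  # convexity: mixture absorbance bounded by the largest basis peak
  basis <- default_basis(m)
  amax <- max(vapply(basis, function(b)
    max(.Machine$double.eps, b$amplitude +
          if (is.null(b$secondary)) 0 else b$secondary$amplitude), 1))
  for (p in c(3, 6, 8, 10)) expect_lt(max(predict_spectrum(p, m)), amax)
  # basis must cover the model's species
  expect_error(predict_spectrum(7, m, basis = basis[1:2]), "cover")
})

test_that("ratio curves are constant for pH-independent spectra and drop zeros", {
  wl <- seq(400, 600, by = 2)
  flat <- titration_series(c(5, 6, 7), wl,
                           matrix(rep(exp(-(wl - 500)^2 / 2000), 3),
                                  nrow = 3, byrow = TRUE))
  rc <- ratio_curve(flat, 520, 480)
  expect_equal(diff(range(rc$ratio)), 0, tolerance = 1e-12)
  expect_error(ratio_curve(flat, 320, 480), "not on the measured grid")
  # zero denominator points dropped with a warning
  ab <- matrix(1, 3, length(wl)); ab[2, which.min(abs(wl - 480))] <- 0
  noisy <- titration_series(c(5, 6, 7), wl, ab)
  expect_warning(rc2 <- ratio_curve(noisy, 520, 480), "dropped")
  expect_equal(nrow(rc2), 2L)
})

test_that("fit_pka recovers parameters of self-generated sigmoids", {
  ph <- seq(3, 11, by = 0.5)
  r <- 0.2 + (1.8 - 0.2) / (1 + 10^(6.3 - ph))
  f <- fit_pka(data.frame(ph = ph, ratio = r))
  expect_equal(f$pka, 6.3, tolerance = 0.01 / 6.3)
  expect_equal(f$r_lo, 0.2, tolerance = 1e-6)
  expect_equal(f$r_hi, 1.8, tolerance = 1e-6)
  expect_lt(f$residual_norm, 1e-8)
  expect_error(fit_pka(data.frame(ph = ph, ratio = rep(1, length(ph)))),
               "no transition")
  expect_error(fit_pka(data.frame(ph = 1:3, ratio = c(1, 2, 3))), ">= 4")
})

test_that("fit_pka is invariant to affine rescaling of the ratio axis", {
  ph <- seq(4, 10, by = 0.5)
  r <- 1 + 2 / (1 + 10^(7.1 - ph))
  f1 <- fit_pka(data.frame(ph = ph, ratio = r))
  f2 <- fit_pka(data.frame(ph = ph, ratio = 5 * r - 2))
  expect_equal(f1$pka, f2$pka, tolerance = 1e-8)
})

test_that("noiseless three-state titrations yield both pKa values", {
  m <- ionization_model(5.7, 8.8)
  g <- gen_titration(titration_spec(m))
  lo <- ratio_assay("low"); hi <- ratio_assay("high")
  f_lo <- fit_pka(ratio_curve(g$series, lo$num, lo$den, lo$window))
  f_hi <- fit_pka(ratio_curve(g$series, hi$num, hi$den, hi$window))
  expect_equal(f_lo$pka, 5.7, tolerance = 0.1 / 5.7)
  expect_equal(f_hi$pka, 8.8, tolerance = 0.1 / 8.8)
  # and the ratio curves are sigmoidal (monotone) in their windows
  expect_true(all(diff(ratio_curve(g$series, lo$num, lo$den, lo$window)$ratio) > 0))
})

test_that("one-site titration recovers the planted pKa", {
  g <- gen_titration(titration_spec(ionization_model(4.4)))
  os <- ratio_assay("one_site")
  f <- fit_pka(ratio_curve(g$series, os$num, os$den, os$window))
  expect_equal(f$pka, 4.4, tolerance = 0.1 / 4.4)
})

test_that("median pKa error stays below 0.1 over noisy replicates", {
  set.seed(2024)
  ph <- seq(2, 12, by = 0.5)
  errs <- vapply(1:100, function(i) {
    pka <- runif(1, 4, 10)
    rlo <- runif(1, 0, 0.5); rhi <- rlo + runif(1, 0.5, 2)
    r <- rlo + (rhi - rlo) / (1 + 10^(pka - ph))
    r <- r + rnorm(length(ph), 0, 0.02 * (rhi - rlo))
    abs(fit_pka(data.frame(ph = ph, ratio = r))$pka - pka)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("titration series round-trips through long-format CSV", {
  g <- gen_titration(titration_spec(ionization_model(5.7, 8.8),
                                    wavelengths = seq(400, 600, by = 5),
                                    noise_sd = 0.002, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_titration(g$series, f)
  back <- read_titration(f)
  expect_equal(back$ph, g$series$ph)
  expect_equal(back$wavelengths, g$series$wavelengths)
  expect_equal(back$absorbance, g$series$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)
})
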