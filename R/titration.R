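# Sequential chromophore ionization model, species-mixture spectra,
# dual-wavelength ratio curves and Henderson-Hasselbalch pKa fitting.

#' Chromophore ionization model
#'
#' Sequential (de)protonation scheme. With two sites the phenol
#' deprotonates first (`pka1`, low range) and the thiol second (`pka2`,
#' high range); the doubly-ordered scheme has species SH/OH, SH/O- and
#' S-/O- (no S-/OH population). With one site (phenol only) the species
#' are OH and O-.
#'
#' @param pka1 first ionization constant (phenol)
#' @param pka2 optional second ionization constant (thiol); must exceed
#'   `pka1`
#' @return object of class `ionization_model` with `n_sites` 1 or 2
#' @export
ionization_model <- function(pka1, pka2 = NULL) {
  if (!is.finite(pka1)) stop("pka1 must be finite")
  if (!is.null(pka2)) {
    if (!is.finite(pka2)) stop("pka2 must be finite")
    if (pka1 >= pka2) stop("pka1 must be < pka2")
  }
  structure(list(pka1 = pka1, pka2 = pka2,
                 n_sites = if (is.null(pka2)) 1L else 2L),
            class = "ionization_model")
}

#' Species labels of an ionization model
#' @param model an `ionization_model`
#' @return character vector, protonated first
#' @export
species_labels <- function(model) {
  if (model$n_sites == 2L) c("SH/OH", "SH/O-", "S-/O-") else c("OH", "O-")
}

#' Equilibrium species fractions at a given pH
#'
#' For the sequential two-site scheme with `h = 10^-pH`,
#' `K1 = 10^-pka1`, `K2 = 10^-pka2`:
#' `p(SH/OH) = h^2/D`, `p(SH/O-) = h*K1/D`, `p(S-/O-) = K1*K2/D`,
#' `D = h^2 + h*K1 + K1*K2`. The one-site analogue is the usual
#' Henderson-Hasselbalch pair.
#'
#' @param ph pH value(s)
#' @param model an `ionization_model`
#' @return matrix with one row per pH and one column per species
#'   (fractions sum to 1)
#' @export
species_fractions <- function(ph, model) {
  stopifnot(inherits(model, "ionization_model"))
  h <- 10^(-ph)
  if (model$n_sites == 2L) {
    k1 <- 10^(-model$pka1); k2 <- 10^(-model$pka2)
    d <- h^2 + h * k1 + k1 * k2
    out <- cbind(h^2 / d, h * k1 / d, k1 * k2 / d)
  } else {
    k1 <- 10^(-model$pka1)
    d <- h + k1
    out <- cbind(h / d, k1 / d)
  }
  colnames(out) <- species_labels(model)
  rownames(out) <- NULL
  out
}

#' Species basis spectrum (Gaussian band, optional secondary band)
#'
#' Each ionized species absorbs as a Gaussian band in wavelength,
#' optionally with a weaker secondary band at higher energy (every
#' conjugated chromophore has higher electronic transitions in the
#' blue; modelling them matters for ratiometric analysis, see
#' [default_basis()]).
#'
#' @param label species label
#' @param center main band centre, nm
#' @param width Gaussian sigma, nm (default 30)
#' @param amplitude main band peak absorbance
#' @param secondary optional list(center, width, amplitude) of a
#'   secondary band
#' @return object of class `species_spectrum`
#' @export
species_spectrum <- function(label, center, width = 30, amplitude = 1,
                             secondary = NULL) {
  if (width <= 0) stop("width must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(label = label, center = center, width = width,
                 amplitude = amplitude, secondary = secondary),
            class = "species_spectrum")
}

.band_absorbance <- function(spec, wavelengths) {
  a <- spec$amplitude *
    exp(-(wavelengths - spec$center)^2 / (2 * spec$width^2))
  if (!is.null(spec$secondary)) {
    s <- spec$secondary
    a <- a + s$amplitude * exp(-(wavelengths - s$center)^2 / (2 * s$width^2))
  }
  a
}

#' Default species basis spectra
#'
#' Band centres follow the three observed spectral forms (420 nm
#' protonated, 566 nm thiol-phenolate, 543 nm thiolate-phenolate; for
#' the one-site model 438 nm neutral and 587 nm anionic). Amplitudes
#' are chosen so that the reference (denominator) wavelengths of the
#' shipped ratio assays are isosbestic points of the transitions they
#' normalize -- the standard validity condition for ratiometric pKa
#' determination: anionic species carry a weak blue secondary band with
#' the same shape as the neutral species' main band, and the
#' thiolate-phenolate main amplitude is `1/g(566; 543, width)` so both
#' anions absorb equally at 566 nm.
#'
#' @param model an `ionization_model`
#' @param width Gaussian sigma of all bands, nm
#' @param neutral_amplitude peak absorbance of the protonated species'
#'   band (also the amplitude of the anions' blue secondary band)
#' @return list of `species_spectrum`, one per model species
#' @export
default_basis <- function(model, width = 30, neutral_amplitude = 0.35) {
  g <- function(lambda, center) exp(-(lambda - center)^2 / (2 * width^2))
  if (model$n_sites == 2L) {
    blue <- list(center = 420, width = width, amplitude = neutral_amplitude)
    list(
      species_spectrum("SH/OH", 420, width, neutral_amplitude),
      species_spectrum("SH/O-", 566, width, 1, secondary = blue),
      species_spectrum("S-/O-", 543, width, 1 / g(566, 543), secondary = blue))
  } else {
    blue <- list(center = 438, width = width, amplitude = neutral_amplitude)
    list(
      species_spectrum("OH", 438, width, neutral_amplitude),
      species_spectrum("O-", 587, width, 1, secondary = blue))
  }
}

#' Predict the absorbance spectrum of the species mixture at a pH
#'
#' Pointwise `sum_s fraction_s * band_s(lambda)`.
#'
#' @param ph a single pH value
#' @param model an `ionization_model`
#' @param basis list of `species_spectrum`, one per model species
#' @param wavelengths wavelength grid, nm
#' @return numeric vector of absorbances on `wavelengths`
#' @export
predict_spectrum <- function(ph, model, basis = default_basis(model),
                             wavelengths = seq(350, 650, by = 1)) {
  labs <- vapply(basis, `[[`, "", "label")
  need <- species_labels(model)
  if (!all(need %in% labs))
    stop("basis does not cover species: ",
         paste(setdiff(need, labs), collapse = ", "))
  fr <- species_fractions(ph, model)[1, ]
  a <- numeric(length(wavelengths))
  for (s in need)
    a <- a + fr[[s]] * .band_absorbance(basis[[which(labs == s)[1]]], wavelengths)
  a
}

#' Titration series container
#'
#' @param ph vector of pH points
#' @param wavelengths wavelength grid, nm
#' @param absorbance matrix, `length(ph)` rows x `length(wavelengths)`
#'   columns, absorbance >= 0
#' @return object of class `titration_series`
#' @export
titration_series <- function(ph, wavelengths, absorbance) {
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(ph) || ncol(absorbance) != length(wavelengths))
    stop("absorbance must be length(ph) x length(wavelengths)")
  if (any(absorbance < 0)) stop("negative absorbance")
  structure(list(ph = as.numeric(ph), wavelengths = as.numeric(wavelengths),
                 absorbance = absorbance),
            class = "titration_series")
}

#' Read a titration series from long-format delimited text
#'
#' Expects columns `ph`, `wavelength_nm`, `absorbance` (CSV by default).
#'
#' @param path input file
#' @param sep field separator
#' @return a `titration_series`
#' @export
read_titration <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("ph", "wavelength_nm", "absorbance")
  if (!all(need %in% names(df)))
    stop("titration file must have columns: ", paste(need, collapse = ", "))
  ph <- sort(unique(df$ph)); wl <- sort(unique(df$wavelength_nm))
  a <- matrix(NA_real_, length(ph), length(wl))
  a[cbind(match(df$ph, ph), match(df$wavelength_nm, wl))] <- df$absorbance
  if (anyNA(a)) stop("titration table is not a complete ph x wavelength grid")
  titration_series(ph, wl, a)
}

#' Write a titration series as long-format CSV
#' @param series a `titration_series`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_titration <- function(series, path) {
  df <- expand.grid(wavelength_nm = series$wavelengths, ph = series$ph)[, 2:1]
  df$absorbance <- as.numeric(t(series$absorbance))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dual-wavelength absorbance ratio curve
#'
#' Per-pH ratio of the absorbances at two wavelengths (nearest grid
#' wavelength within `tol`); points whose denominator falls below
#' `floor` are dropped with a warning.
#'
#' @param series a `titration_series`
#' @param num_wavelength,den_wavelength numerator / denominator
#'   wavelengths, nm
#' @param window optional `c(min_ph, max_ph)` restriction
#' @param tol wavelength matching tolerance, nm
#' @param floor minimum usable denominator absorbance
#' @return data.frame `ph`, `ratio`
#' @export
ratio_curve <- function(series, num_wavelength, den_wavelength,
                        window = NULL, tol = 2, floor = 1e-6) {
  pick <- function(w) {
    i <- which.min(abs(series$wavelengths - w))
    if (abs(series$wavelengths[i] - w) > tol)
      stop("wavelength ", w, " nm not on the measured grid (tolerance ",
           tol, " nm)")
    i
  }
  ni <- pick(num_wavelength); di <- pick(den_wavelength)
  keep <- rep(TRUE, length(series$ph))
  if (!is.null(window))
    keep <- series$ph >= window[1] & series$ph <= window[2]
  den <- series$absorbance[keep, di]
  num <- series$absorbance[keep, ni]
  ph <- series$ph[keep]
  low <- den < floor
  if (any(low)) {
    warning(sum(low), " point(s) dropped: denominator below floor")
    ph <- ph[!low]; num <- num[!low]; den <- den[!low]
  }
  data.frame(ph = ph, ratio = num / den)
}

#' Fit a Henderson-Hasselbalch sigmoid to a ratio curve
#'
#' Least-squares fit of
#' `R(pH) = R_lo + (R_hi - R_lo) / (1 + 10^(pKa - pH))`
#' (Hill coefficient fixed at 1 unless `free_hill = TRUE`). Start
#' values come from the data (asymptotes from the extremes, pKa from
#' the half-range crossing).
#'
#' @param curve data.frame with columns `ph` and `ratio` (>= 4 points)
#' @param free_hill also fit a Hill coefficient `n` (default fixed at 1)
#' @return list: `pka`, `r_lo`, `r_hi`, `hill`, `residual_norm`, `fit`
#'   (the `nls` object)
#' @export
fit_pka <- function(curve, free_hill = FALSE) {
  stopifnot(all(c("ph", "ratio") %in% names(curve)))
  curve <- curve[order(curve$ph), , drop = FALSE]
  if (nrow(curve) < 4L) stop("pKa fit needs >= 4 points")
  rng <- diff(range(curve$ratio))
  if (rng < 1e-12 * max(abs(curve$ratio), 1))
    stop("no transition: ratio curve is constant")
  mid <- (min(curve$ratio) + max(curve$ratio)) / 2
  pka0 <- curve$ph[which.min(abs(curve$ratio - mid))]
  start <- list(r_lo = min(curve$ratio), r_hi = max(curve$ratio), pka = pka0)
  fml <- ratio ~ r_lo + (r_hi - r_lo) / (1 + 10^(pka - ph))
  if (free_hill) {
    fml <- ratio ~ r_lo + (r_hi - r_lo) / (1 + 10^(n * (pka - ph)))
    start$n <- 1
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = curve, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("pKa fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  list(pka = unname(cf["pka"]), r_lo = unname(cf["r_lo"]),
       r_hi = unname(cf["r_hi"]),
       hill = if (free_hill) unname(cf["n"]) else 1,
       residual_norm = sqrt(sum(stats::resid(fit)^2)), fit = fit)
}

#' Shipped ratio assay windows
#'
#' The low-range assay ratios the thiol-phenolate band to the neutral
#' band (566/425 nm) over pH 4.5-8; the high-range assay ratios the
#' thiolate-phenolate to the thiol-phenolate band (544/566 nm) over
#' pH 6-11; the one-site assay ratios the anionic to the neutral band
#' (587/438 nm) over the full measured range.
#'
#' @param which one of `"low"`, `"high"`, `"one_site"`
#' @return list: `num`, `den` (nm), `window` (pH)
#' @export
ratio_assay <- function(which = c("low", "high", "one_site")) {
  which <- match.arg(which)
  switch(which,
         low = list(num = 566, den = 425, window = c(4.5, 8)),
         high = list(num = 544, den = 566, window = c(6, 11)),
         one_site = list(num = 587, den = 438, window = c(0, 14)))
}
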