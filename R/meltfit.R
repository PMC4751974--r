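# Gas constant in kcal mol^-1 K^-1
R_KCAL <- 1.987204e-3

# Fraction folded of a two-state dimer (D <=> 2M) at temperatures T (deg C),
# for folding enthalpy `enthalpy` (kcal/mol, negative), midpoint tm (deg C)
# at the reference concentration pt_ref, and actual total peptide
# concentration pt (M, in monomer units). The dimer dissociation constant
# K = [M]^2/[D] follows van 't Hoff with dCp = 0 and is anchored so that
# K(tm) = pt_ref, the condition under which the folded fraction is exactly
# 1/2 at tm when pt == pt_ref; at higher concentrations the apparent
# midpoint shifts upward, as dimer dissociation is concentration dependent.
dimer_fraction_folded <- function(temperature, tm, enthalpy, pt,
                                  pt_ref = pt) {
  tK <- temperature + 273.15
  tmK <- tm + 273.15
  dH_unfold <- -enthalpy
  K <- pt_ref * exp((dH_unfold / R_KCAL) * (1 / tmK - 1 / tK))
  monomer <- (-K + sqrt(K^2 + 8 * K * pt)) / 4
  1 - monomer / pt
}

melt_signal <- function(temperature, tm, enthalpy, pt, bf0, bf1, bu0, bu1) {
  f <- dimer_fraction_folded(temperature, tm, enthalpy, pt)
  (bf0 + bf1 * temperature) * f + (bu0 + bu1 * temperature) * (1 - f)
}

#' Simulate a two-state dimer thermal denaturation curve
#'
#' Generates a synthetic circular-dichroism melt (signal at 222 nm versus
#' temperature) for a dimeric coiled coil unfolding by the two-state
#' dimer-to-two-monomers mechanism, with linear folded and unfolded
#' baselines and optional Gaussian noise. Because dissociation is
#' concentration dependent, the apparent midpoint rises with total peptide
#' concentration; at `pt` itself the folded fraction is exactly 1/2 at
#' `tm`.
#'
#' @param tm Midpoint temperature (deg C) at concentration `pt`; must lie
#'   within the temperature grid.
#' @param enthalpy Folding (van 't Hoff) enthalpy in kcal/mol; must be
#'   negative.
#' @param pt Total peptide concentration in M (monomer units); the worked
#'   example's experiments used 150e-6.
#' @param baselines List with numeric length-2 elements `folded` and
#'   `unfolded`, each `c(intercept, slope)` in signal units and signal
#'   units per deg C.
#' @param noise_sd Standard deviation of added Gaussian noise (signal
#'   units); 0 for a noiseless curve.
#' @param seed Integer seed fixing the noise stream.
#' @param temperature Temperature grid (deg C), strictly increasing.
#' @return Object of class `melt_curve`: data frame fields `temperature`
#'   and `signal` plus attributes `pt` and `truth`.
#' @examples
#' mc <- simulate_melt(tm = 63, enthalpy = -50, noise_sd = 0)
#' plot(mc$temperature, mc$signal, type = "l")
#' @export
simulate_melt <- function(tm, enthalpy, pt = 150e-6,
                          baselines = list(folded = c(-33, 0.08),
                                           unfolded = c(-5, -0.02)),
                          noise_sd = 0, seed = 1L,
                          temperature = seq(-8, 95, by = 1)) {
  stopifnot(is.numeric(temperature), length(temperature) >= 2L,
            all(diff(temperature) > 0), noise_sd >= 0, pt > 0)
  if (enthalpy >= 0) {
    stop("folding enthalpy must be negative (unfolding absorbs heat)")
  }
  if (tm < min(temperature) || tm > max(temperature)) {
    stop("tm (", tm, ") lies outside the temperature grid")
  }
  bf <- baselines$folded
  bu <- baselines$unfolded
  stopifnot(length(bf) == 2L, length(bu) == 2L)
  signal <- melt_signal(temperature, tm, enthalpy, pt,
                        bf[1L], bf[2L], bu[1L], bu[2L])
  if (noise_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    signal <- signal + stats::rnorm(length(signal), sd = noise_sd)
  }
  structure(
    data.frame(temperature = temperature, signal = signal),
    pt = pt,
    truth = list(tm = tm, enthalpy = enthalpy, baselines = baselines,
                 noise_sd = noise_sd, seed = seed),
    class = c("melt_curve", "data.frame")
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fit a two-state dimer model to a thermal denaturation curve
#'
#' Least-squares fit of the concentration-dependent two-state dimer
#' unfolding model (the same closed form as [simulate_melt()]) with linear
#' folded and unfolded baselines. Start values are deterministic: the
#' midpoint starts at the temperature of steepest signal change (after
#' light smoothing), the folding enthalpy at -50 kcal/mol, and the
#' baselines at straight-line fits through the first and last 15% of
#' points. Non-convergence, a vanishing transition amplitude or a fitted
#' midpoint outside the data's temperature span are flagged rather than
#' failing silently.
#'
#' @param curve A `melt_curve` or any data frame with `temperature` and
#'   `signal` columns (at least 20 points spanning both baselines).
#' @param pt Total peptide concentration in M; defaults to the curve's `pt`
#'   attribute, else 150e-6.
#' @return Object of class `melt_fit`: `tm` (deg C), `enthalpy` (kcal/mol),
#'   `baselines`, `rss` (residual sum of squares), `converged` (logical)
#'   and `message`.
#' @examples
#' fit <- fit_two_state(simulate_melt(tm = 63, enthalpy = -50, noise_sd = 0))
#' fit$tm
#' @export
fit_two_state <- function(curve, pt = NULL) {
  stopifnot(all(c("temperature", "signal") %in% names(curve)))
  temperature <- curve$temperature
  signal <- curve$signal
  if (length(temperature) < 20L) {
    stop("need >= 20 points spanning both baselines")
  }
  if (is.null(pt)) pt <- attr(curve, "pt")
  if (is.null(pt)) pt <- 150e-6
  n <- length(signal)
  k <- max(3L, round(n * 0.15))
  lo <- seq_len(k)
  hi <- seq.int(n - k + 1L, n)
  fit_line <- function(idx) {
    co <- stats::coef(stats::lm(signal[idx] ~ temperature[idx]))
    c(co[[1L]], co[[2L]])
  }
  bf <- fit_line(lo)
  bu <- fit_line(hi)
  # steepest change of the lightly smoothed curve as the tm start value,
  # evaluated only where the running mean is fully defined so that edge
  # noise cannot masquerade as the transition
  sm <- as.numeric(stats::filter(signal, rep(1 / 5, 5), sides = 2))
  interior <- which(!is.na(sm))
  slope <- diff(sm[interior]) / diff(temperature[interior])
  tm0 <- temperature[interior][which.max(abs(slope))]
  df <- data.frame(temperature = temperature, signal = signal)
  run_fit <- function(tm_start) {
    tryCatch(
      minpack.lm::nlsLM(
        signal ~ melt_signal(temperature, tm, enthalpy, pt, bf0, bf1, bu0, bu1),
        data = df,
        start = list(tm = tm_start, enthalpy = -50,
                     bf0 = bf[1L], bf1 = bf[2L], bu0 = bu[1L], bu1 = bu[2L]),
        lower = c(tm = -273, enthalpy = -1000, bf0 = -Inf, bf1 = -Inf,
                  bu0 = -Inf, bu1 = -Inf),
        upper = c(tm = 500, enthalpy = -1e-6, bf0 = Inf, bf1 = Inf,
                  bu0 = Inf, bu1 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
  }
  ok <- function(f) {
    !inherits(f, "error") &&
      stats::coef(f)[["tm"]] >= min(temperature) &&
      stats::coef(f)[["tm"]] <= max(temperature)
  }
  fit <- run_fit(tm0)
  if (!ok(fit)) {
    # deterministic fallback start at the middle of the temperature span
    fit2 <- run_fit(stats::median(temperature))
    if (ok(fit2) || inherits(fit, "error")) fit <- fit2
  }
  bad <- function(msg) {
    structure(list(tm = NA_real_, enthalpy = NA_real_,
                   baselines = list(folded = bf, unfolded = bu),
                   rss = NA_real_, converged = FALSE, message = msg),
              class = "melt_fit")
  }
  if (inherits(fit, "error")) return(bad(conditionMessage(fit)))
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  # a transition has to exist: the folded/unfolded states must differ by
  # more than the residual scatter at the fitted midpoint
  amp <- abs((co[["bf0"]] + co[["bf1"]] * co[["tm"]]) -
             (co[["bu0"]] + co[["bu1"]] * co[["tm"]]))
  if (!is.finite(co[["tm"]]) ||
      co[["tm"]] < min(temperature) || co[["tm"]] > max(temperature)) {
    return(bad("fitted midpoint outside the data's temperature span"))
  }
  if (amp < 3 * sqrt(rss / length(signal)) || amp < 1e-8) {
    return(bad("no resolvable folding transition (flat curve?)"))
  }
  structure(
    list(tm = co[["tm"]], enthalpy = co[["enthalpy"]],
         baselines = list(folded = c(co[["bf0"]], co[["bf1"]]),
                          unfolded = c(co[["bu0"]], co[["bu1"]])),
         rss = rss, converged = TRUE, message = "converged"),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  if (x$converged) {
    cat("<melt_fit> Tm = ", round(x$tm, 2), " degC, dH = ",
        round(x$enthalpy, 1), " kcal/mol, rss = ", signif(x$rss, 4), "\n",
        sep = "")
  } else {
    cat("<melt_fit> NOT converged: ", x$message, "\n", sep = "")
  }
  invisible(x)
}

#' Dimer-exchange excess signal
#'
#' Compares the spectrum of a mixture of two preformed peptide pairs with
#' the average of the component spectra recorded separately. If the
#' partners repartition on mixing, new (more stable) helical pairs form and
#' the mixture's 222 nm signal becomes more negative than the average:
#' positive excess helicity indicates partner exchange, zero indicates the
#' preformed pairs were already the preferred ones.
#'
#' @param spectrumA,spectrumB,spectrum_mixed Data frames with `wavelength`
#'   (nm) and `signal` columns on a common wavelength grid.
#' @param summary_wavelength Wavelength (nm) for the scalar summary;
#'   default 222, the helix diagnostic band.
#' @return List with `excess` (data frame `wavelength`, `excess` =
#'   mixed minus average, pointwise) and `excess_helicity` (average minus
#'   mixed at `summary_wavelength`; positive means the mixture is more
#'   helical than its components' average).
#' @export
exchange_excess <- function(spectrumA, spectrumB, spectrum_mixed,
                            summary_wavelength = 222) {
  for (s in list(spectrumA, spectrumB, spectrum_mixed)) {
    stopifnot(all(c("wavelength", "signal") %in% names(s)))
  }
  if (!isTRUE(all.equal(spectrumA$wavelength, spectrumB$wavelength)) ||
      !isTRUE(all.equal(spectrumA$wavelength, spectrum_mixed$wavelength))) {
    stop("spectra are not on a common wavelength grid")
  }
  avg <- (spectrumA$signal + spectrumB$signal) / 2
  excess <- spectrum_mixed$signal - avg
  i <- which.min(abs(spectrumA$wavelength - summary_wavelength))
  if (abs(spectrumA$wavelength[i] - summary_wavelength) > 0.5) {
    stop("summary wavelength ", summary_wavelength,
         " nm is not covered by the spectra")
  }
  list(
    excess = data.frame(wavelength = spectrumA$wavelength, excess = excess),
    excess_helicity = avg[i] - spectrum_mixed$signal[i]
  )
}
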