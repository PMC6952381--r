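## Complex atomic form factor f(q, omega) = f0(q) + f'(omega) + i f''(omega).
##
## f0 is the Fourier transform of the spherically averaged HFS electron
## density; f'' follows from the optical theorem applied to the total
## photoabsorption cross section (continuum + resonant Lorentzian lines);
## f' is the Kramers-Kronig transform of f'' (numeric principal value for
## the continuum part, analytic dispersion partner for each Lorentzian).

#' Dispersion-free form factor f0(q)
#'
#' Fourier transform of the radial electron density,
#' \eqn{f_0(q) = \int \rho(r)\,\mathrm{sinc}(qr)\,4\pi r^2 dr}, so that
#' f0(0) equals the number of bound electrons.
#'
#' @inheritParams photoionization_cs
#' @param q_nm_inv momentum transfer |q| in nm^-1 (convention
#'   q = (4 pi / lambda) sin(theta/2)); scalar or vector.
#' @return dimensionless form factor (electron units).
#' @export
form_factor_f0 <- function(atomic_data, q_nm_inv) {
  ad <- atomic_data
  if (ad$n_bound == 0L) return(rep(0, length(q_nm_inv)))
  w <- ad$r * ad$h
  q_au <- q_nm_inv * dynscat_constants$bohr_nm
  vapply(q_au, function(q) {
    if (q < 1e-12) return(sum(ad$rho_rad * w))
    sum(ad$rho_rad * sin(q * ad$r) / (q * ad$r) * w)
  }, numeric(1))
}

# photon-energy grid for the tabulated continuum f'' (eV)
.ff_omega_grid <- function() exp(seq(log(5), log(30000), length.out = 100))

# continuum (photoionization) part of f'' on the cached grid.
# Each subshell is computed with the partial-wave solver up to a cap
# (where the radial grid resolves the continuum oscillation) and extended
# with a power-law tail fitted to the last half-decade - the standard
# high-energy asymptote sigma ~ omega^p with p near -3.
.ff_continuum_table <- function(ad) {
  key <- paste0(config_key(ad$configuration), "#",
                control_key(ad$control), "#f2")
  hit <- .dynscat_cache[[key]]
  if (!is.null(hit)) return(hit)
  om <- .ff_omega_grid()
  k <- length(ad$eigen_au)
  sig_barn <- rep(0, length(om))
  for (s in seq_len(k)) {
    if (ad$configuration$occupations[s] == 0L) next
    B <- ionization_threshold_ev(ad, s)
    if (!is.finite(B) || B <= 0) next
    cap <- min(max(om), max(2500, 4 * B))
    solver_pts <- which(om <= cap)
    sg <- photoionization_cs(ad, .subshell_names[s], om[solver_pts])
    sig_s <- rep(0, length(om))
    sig_s[solver_pts] <- sg
    tail_pts <- which(om > cap)
    if (length(tail_pts) > 0) {
      fit_pts <- which(om > cap / 2 & om <= cap & sig_s > 0)
      p <- -3
      if (length(fit_pts) >= 3) {
        cf <- stats::coef(stats::lm(log(sig_s[fit_pts]) ~
                                      log(om[fit_pts])))
        if (is.finite(cf[2]) && cf[2] < -1) p <- cf[2]
      }
      s_cap <- sig_s[max(which(om <= cap))]
      sig_s[tail_pts] <- s_cap * (om[tail_pts] / cap)^p
    }
    sig_barn <- sig_barn + sig_s
  }
  f2 <- ev_to_au(om) / (4 * pi * dynscat_constants$alpha) *
    (sig_barn / dynscat_constants$au_area_barn)
  tab <- list(omega_ev = om, f2 = f2)
  .dynscat_cache[[key]] <- tab
  tab
}

# principal-value Kramers-Kronig transform of a tabulated f''(omega):
# f'(w) = (2/pi) P int w' f''(w') / (w^2 - w'^2) dw'
# (this sign convention makes f' negative just below an absorption edge
# and zero in the high-frequency limit, as for the Henke f1 - Z tables)
#' Kramers-Kronig transform of an imaginary form-factor table
#'
#' @param omega_ev tabulation grid (eV), strictly increasing.
#' @param f2 values of f'' on the grid.
#' @param omega_eval_ev energies at which to evaluate f' (eV).
#' @return f' values (dimensionless).
#' @export
kramers_kronig <- function(omega_ev, f2, omega_eval_ev) {
  stopifnot(length(omega_ev) == length(f2), all(diff(omega_ev) > 0))
  a <- omega_ev[1]; b <- omega_ev[length(omega_ev)]
  w <- c(diff(omega_ev) / 2, 0) + c(0, diff(omega_ev) / 2)  # trapezoid
  vapply(omega_eval_ev, function(om) {
    g_at <- if (om >= a && om <= b) {
      om * stats::approx(omega_ev, f2, om)$y
    } else 0
    num <- omega_ev * f2 - g_at
    den <- om^2 - omega_ev^2
    reg <- num / den
    sing <- abs(den) < 1e-12 * om^2
    reg[sing] <- 0
    pv_rest <- if (g_at != 0) {
      # analytic PV of g(om) / (om^2 - w'^2) over [a, b]
      g_at / (2 * om) *
        log(((om + b) * abs(om - a)) / (abs(om - b) * (om + a)))
    } else 0
    (2 / pi) * (sum(reg * w) + pv_rest)
  }, numeric(1))
}

#' Complex atomic form factor
#'
#' Evaluates \eqn{f(q,\omega) = f_0(q) + f'(\omega) + i f''(\omega)} for an
#' HFS configuration. The anomalous terms comprise the photoionization
#' continuum (optical theorem + numeric Kramers-Kronig transform on a
#' tabulated grid) and the resonant bound-bound lines (Lorentzian in f''
#' with its analytic dispersion partner in f').
#'
#' @inheritParams form_factor_f0
#' @param omega_ev photon energy in eV; must lie inside the tabulated
#'   anomalous-term grid (5 eV to 30 keV) - values outside raise an error
#'   rather than extrapolating.
#' @return a complex number (or vector over `q_nm_inv`).
#' @export
form_factor <- function(atomic_data, q_nm_inv, omega_ev) {
  ad <- atomic_data
  stopifnot(length(omega_ev) == 1, omega_ev > 0)
  if (ad$n_bound == 0L) return(complex(real = rep(0, length(q_nm_inv))))
  f0 <- form_factor_f0(ad, q_nm_inv)
  an <- anomalous_terms(ad, omega_ev)
  f0 + complex(real = an$f1, imaginary = an$f2)
}

#' Anomalous scattering terms f'(omega), f''(omega)
#'
#' @inheritParams form_factor
#' @param resonance_broadening_ev additional width added to the natural
#'   linewidth of the bound-bound resonance terms. The coherent-imaging
#'   quadratures pass the pulse bandwidth here: within a broadband pulse
#'   only the bandwidth-averaged amplitude stays phase-coherent across the
#'   cluster, and the residual narrow-line response (resonance
#'   fluorescence, Auger-dominated) does not contribute to the coherent
#'   image. Absorption rates keep the natural linewidth (default 0).
#' @return list with `f1` (= f') and `f2` (= f'').
#' @export
anomalous_terms <- function(atomic_data, omega_ev,
                            resonance_broadening_ev = 0) {
  ad <- atomic_data
  if (ad$n_bound == 0L) return(list(f1 = 0, f2 = 0))
  tab <- .ff_continuum_table(ad)
  rng <- range(tab$omega_ev)
  if (omega_ev < rng[1] || omega_ev > rng[2]) {
    stop("photon energy ", omega_ev, " eV outside the tabulated anomalous",
         "-term grid [", round(rng[1], 1), ", ", round(rng[2], 1),
         "] eV; refusing to extrapolate")
  }
  f2_cont <- stats::approx(tab$omega_ev, tab$f2, omega_ev)$y
  f1_cont <- kramers_kronig(tab$omega_ev, tab$f2, omega_ev)
  f1_res <- 0; f2_res <- 0
  tr <- atomic_data$transitions
  if (!is.null(tr) && nrow(tr) > 0) {
    for (k in seq_len(nrow(tr))) {
      om0 <- tr$omega_ev[k]; f <- tr$f_osc[k]
      gam <- tr$gamma_ev[k] + resonance_broadening_ev
      # (pi/2) w0 f L(w) in a.u.; expressed directly in eV
      pref <- (pi / 2) * ev_to_au(om0) * f / pi
      d <- omega_ev - om0
      denom <- d^2 + gam^2 / 4
      f2_res <- f2_res + pref * (gam / 2) / (denom / dynscat_constants$hartree_ev)
      f1_res <- f1_res + pref * d / (denom / dynscat_constants$hartree_ev)
    }
  }
  list(f1 = f1_cont + f1_res, f2 = f2_cont + f2_res)
}
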