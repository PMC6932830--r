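# Per-voxel pH from the charge-balance equation, closed-form acid-base
# speciation as a function of [H+], and gas-liquid transfer rates.

#' Define an acid-base system
#'
#' Each dissociating nutrient is described by its ladder of forms from most
#' protonated to fully deprotonated: `charges` gives the (small integer)
#' charge of every form and `K` the successive equilibrium constants
#' `K_j = [form_j][H+] / [form_{j-1}]` (mol L^-1). The speciation fractions
#' are then closed-form functions of the proton concentration.
#'
#' @param nutrients named list; each entry a list with `charges` (length
#'   k + 1 integer vector) and `K` (length k positive numerics).
#' @param Kw water ion product (mol^2 L^-2), default 1e-14.
#' @param temperature temperature (K), default 298.15. Equilibrium constants
#'   are taken as supplied at this temperature.
#' @return an object of class `ibm_acid_base`.
#' @export
ibm_acid_base <- function(nutrients = list(), Kw = 1e-14,
                          temperature = 298.15) {
  for (nm in names(nutrients)) {
    nut <- nutrients[[nm]]
    if (length(nut$charges) != length(nut$K) + 1L)
      stop(sprintf("nutrient %s: need one more form than equilibrium constants", nm))
    if (any(unlist(nut$K) <= 0))
      stop(sprintf("nutrient %s: equilibrium constants must be > 0", nm))
  }
  structure(list(nutrients = nutrients, Kw = Kw, temperature = temperature),
            class = "ibm_acid_base")
}

# Speciation fractions of one nutrient at proton concentration H:
# w_0 = 1, w_j = w_{j-1} K_j / H; alpha_j = w_j / sum(w).
speciation_fractions <- function(nutrient, H) {
  k <- length(nutrient$K)
  w <- numeric(k + 1L)
  w[1L] <- 1
  if (k > 0) for (j in seq_len(k)) w[j + 1L] <- w[j] * nutrient$K[[j]] / H
  w / sum(w)
}

# Signed charge imbalance f(H) = [H+] + sum cations - [OH-] - sum anions.
# Monotonically increasing in H for valid inputs.
charge_imbalance <- function(H, totals, system) {
  f <- H - system$Kw / H
  for (nm in names(totals)) {
    nut <- system$nutrients[[nm]]
    if (is.null(nut)) next
    alpha <- speciation_fractions(nut, H)
    f <- f + totals[[nm]] * sum(alpha * nut$charges)
  }
  f
}

#' Solve the per-voxel charge balance for the proton concentration
#'
#' Finds the root of
#' `[H+] + sum_i m [S_i^m+] = [OH-] + sum_j n [S_j^n-]`
#' with `[OH-] = Kw / [H+]` and all dissociated/undissociated concentrations
#' expressed in closed form through the speciation fractions. The root is
#' bracketed in `[1e-14, 1]` mol L^-1 and found by Newton-Raphson on
#' `log[H+]` with bisection fallback; the returned solution has a charge
#' imbalance below `1e-12 * max(1, total ionic strength)`.
#'
#' @param totals named numeric vector of total nutrient concentrations
#'   (mol L^-1), >= 0; names must match the system's nutrients.
#' @param system an [ibm_acid_base()].
#' @return list with `H` (mol L^-1), `pH`, `OH`, `residual`, and
#'   `speciation` (named list of per-form concentration vectors, mol L^-1).
#' @export
solve_ph <- function(totals, system) {
  if (any(totals < 0)) stop("total concentrations must be >= 0")
  lo <- 1e-14; hi <- 1
  f_lo <- charge_imbalance(lo, totals, system)
  f_hi <- charge_imbalance(hi, totals, system)
  if (f_lo > 0 || f_hi < 0)
    stop(sprintf("charge balance has no sign change in [1e-14, 1] (f(lo)=%.3g, f(hi)=%.3g); totals: %s",
                 f_lo, f_hi, paste(sprintf("%s=%.3g", names(totals), totals),
                                   collapse = ", ")))
  x <- 0.5 * (log(lo) + log(hi))     # Newton iterate on log[H+]
  tol_res <- 1e-12 * max(1, sum(abs(totals)))
  for (iter in 1:200) {
    H <- exp(x)
    fx <- charge_imbalance(H, totals, system)
    if (abs(fx) < tol_res) break
    if (fx > 0) { hi <- min(hi, H); f_hi <- fx } else { lo <- max(lo, H); f_lo <- fx }
    h <- max(1e-8, abs(x) * 1e-8)
    dfdx <- (charge_imbalance(exp(x + h), totals, system) - fx) / h
    x_new <- if (is.finite(dfdx) && dfdx > 0) x - fx / dfdx else NA_real_
    if (!is.finite(x_new) || exp(x_new) <= lo || exp(x_new) >= hi)
      x_new <- 0.5 * (log(lo) + log(hi))   # bisection fallback
    x <- x_new
  }
  H <- exp(x)
  spec <- lapply(names(system$nutrients), function(nm) {
    nut <- system$nutrients[[nm]]
    tot <- if (nm %in% names(totals)) totals[[nm]] else 0
    conc <- tot * speciation_fractions(nut, H)
    names(conc) <- paste0(nm, "_", seq_along(conc) - 1L)
    conc
  })
  names(spec) <- names(system$nutrients)
  list(H = H, pH = -log10(H), OH = system$Kw / H,
       residual = charge_imbalance(H, totals, system), speciation = spec)
}

#' Gas-liquid transfer rates of a volatile solute
#'
#' The gas-to-liquid rate follows two-film mass transfer,
#' `R_GL = KLa (S_gas - S_liq / K_H)`; the matching liquid-to-gas rate on the
#' head-space balance is `R_LG = -R_GL V_gas / (R_g T)` with the head space
#' taken equal in size to the computational domain. Both rates vanish at
#' Henry equilibrium `S_liq = K_H S_gas`.
#'
#' @param KLa volumetric mass-transfer coefficient (s^-1), > 0.
#' @param KH Henry constant (liquid/gas concentration ratio), > 0.
#' @param Sgas head-space gas concentration.
#' @param Sliq liquid concentration.
#' @param Vgas head-space volume (m^3), defaults to 1 domain volume.
#' @param Rg ideal gas constant (J mol^-1 K^-1).
#' @param temperature temperature (K).
#' @return list with `R_GL` (added to the liquid reaction term) and `R_LG`
#'   (added to the gas balance).
#' @export
gas_liquid_rates <- function(KLa, KH, Sgas, Sliq, Vgas = 1,
                             Rg = 8.314, temperature = 298.15) {
  if (KLa <= 0 || KH <= 0) stop("KLa and KH must be > 0")
  R_GL <- KLa * (Sgas - Sliq / KH)
  R_LG <- -R_GL * Vgas / (Rg * temperature)
  list(R_GL = R_GL, R_LG = R_LG)
}
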