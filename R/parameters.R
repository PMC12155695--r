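#' Molecular constants for the antibody--VEGF system
#'
#' Bundles the molecular weights and physical constants needed for dose
#' conversion, assay-limit conversion and hydrodynamic-radius calculations.
#' The complex weights are always derived: `MW_C = MW_V + MW_R` (one antibody
#' bound) and `MW_H = MW_V + 2 * MW_R` (both VEGF sites occupied).
#'
#' The default antibody weight is that of the ranibizumab Fab (48 kDa). The
#' default VEGF weight, 44 kDa, is the effective weight of the glycosylated
#' VEGF homodimer that makes the cube-root elimination-rate scaling reproduce
#' the literature rate constants for VEGF and the fully bound complex at
#' their printed precision (see the methods vignette).
#'
#' @param MW_R antibody molecular weight, g/mol.
#' @param MW_V VEGF homodimer molecular weight, g/mol.
#' @param nu partial specific volume of protein, cm^3/g.
#' @param N_A Avogadro's number, 1/mol.
#' @return An object of class `molecular_constants` with fields `MW_R`,
#'   `MW_V`, `MW_C`, `MW_H`, `nu`, `N_A`.
#' @examples
#' mc <- molecular_constants()
#' mc$MW_H # 136000
#' @export
molecular_constants <- function(MW_R = 48000, MW_V = 44000,
                                nu = 0.73, N_A = 6.02214076e23) {
  stopifnot(MW_R > 0, MW_V > 0, nu > 0, N_A > 0)
  mc <- list(MW_R = MW_R, MW_V = MW_V,
             MW_C = MW_V + MW_R, MW_H = MW_V + 2 * MW_R,
             nu = nu, N_A = N_A)
  class(mc) <- "molecular_constants"
  mc
}

#' Model parameters of the two-compartment ocular system
#'
#' Constructs and validates the kinetic and physiological parameter set.
#' All concentrations are in pM and times in days throughout the package.
#' The association rate constant is never stored: it is always derived as
#' `k_on = k_off / K_D` (pM^-1 day^-1).
#'
#' @param kel_r,kel_v,kel_c,kel_h first-order vitreous-to-aqueous elimination
#'   rate constants (1/day) for free antibody, free VEGF, the singly bound
#'   complex VR, and the doubly bound complex RVR.
#' @param k_off dissociation rate constant, 1/day.
#' @param K_D equilibrium dissociation constant, pM. `Inf` is allowed and
#'   turns binding off (`k_on = 0`).
#' @param CL aqueous humor clearance rate, mL/day.
#' @param V_in retinal VEGF production rate, pM mL/day.
#' @param V_vit,V_aq vitreous and aqueous humor volumes, mL (defaults are the
#'   midpoints of the literature ranges for the cynomolgus macaque).
#' @return An object of class `ocular_params` (a named list).
#' @seealso [k_on()], [literature_params()], [posterior_mean_params()]
#' @examples
#' p <- literature_params()
#' k_on(p)
#' @export
ocular_params <- function(kel_r, kel_v, kel_c, kel_h, k_off, K_D,
                          CL, V_in, V_vit = 2.0, V_aq = 0.105) {
  p <- list(kel_r = kel_r, kel_v = kel_v, kel_c = kel_c, kel_h = kel_h,
            k_off = k_off, K_D = K_D, CL = CL, V_in = V_in,
            V_vit = V_vit, V_aq = V_aq)
  rates <- c("kel_r", "kel_v", "kel_c", "kel_h", "k_off")
  for (nm in rates) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a strictly positive finite number", nm))
  }
  if (is.na(p$K_D) || p$K_D <= 0) stop("'K_D' must be strictly positive")
  for (nm in c("CL", "V_vit", "V_aq")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a strictly positive finite number", nm))
  }
  if (!is.finite(p$V_in) || p$V_in < 0) stop("'V_in' must be >= 0")
  class(p) <- "ocular_params"
  p
}

#' Derived association rate constant
#'
#' @param params an [ocular_params()] object.
#' @return `k_off / K_D` in pM^-1 day^-1 (0 when `K_D = Inf`).
#' @export
k_on <- function(params) {
  if (is.infinite(params$K_D)) 0 else params$k_off / params$K_D
}

#' Literature parameter set (cynomolgus macaque)
#'
#' Midpoint/point values of the rate constants, clearance and volumes
#' reported across the experimental literature for the macaque eye, with the
#' VEGF production rate set to the value recovered in this package's own
#' Bayesian fit (no direct experimental measurement exists).
#'
#' @param V_in VEGF production rate, pM mL/day.
#' @param K_D dissociation constant, pM; the default is the kinetically
#'   consistent `k_off / k_on` using the midpoint of the measured `k_on`
#'   range (0.85 / 0.0215).
#' @return An [ocular_params()] object.
#' @export
literature_params <- function(V_in = 5.408, K_D = 0.85 / 0.0215) {
  ocular_params(kel_r = 0.300, kel_v = 0.309, kel_c = 0.245, kel_h = 0.210,
                k_off = 0.85, K_D = K_D, CL = 2.9, V_in = V_in)
}

#' Posterior-mean parameter set
#'
#' The marginal posterior means recovered from the macaque aqueous humor
#' time-series fit; the default reference parameter set (`theta_ref`) for
#' every synthetic-data experiment in the package.
#'
#' @return An [ocular_params()] object.
#' @export
posterior_mean_params <- function() {
  ocular_params(kel_r = 0.293, kel_v = 0.575, kel_c = 0.259, kel_h = 0.176,
                k_off = 1.669, K_D = 1459, CL = 2.505, V_in = 5.408)
}

#' Observation-noise parameters
#'
#' Additive Gaussian observation noise standard deviations, each on its
#' series' own observation unit: aqueous VEGF in pM, aqueous antibody in uM.
#'
#' @param sigma_v VEGF observation SD, pM.
#' @param sigma_r antibody observation SD, uM.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma_v = 0.25, sigma_r = 0.25) {
  stopifnot(sigma_v > 0, sigma_r > 0)
  structure(list(sigma_v = sigma_v, sigma_r = sigma_r),
            class = "noise_params")
}

#' ELISA contamination fractions for the adapted observation model
#'
#' In the adapted observation model the "free VEGF" measurement is a linear
#' combination of free, singly bound and doubly bound aqueous VEGF:
#' `mv_aq = v_aq + gamma * c_aq + eta * h_aq`.
#'
#' @param gamma fraction of singly bound (VR) VEGF captured by the assay,
#'   in `[0, 1]`.
#' @param eta fraction of doubly bound (RVR) VEGF captured, in `[0, 1]`.
#' @return An object of class `adapted_obs_params`.
#' @export
adapted_obs_params <- function(gamma = 0, eta = 0) {
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("'gamma' must lie in [0, 1]")
  if (!is.finite(eta) || eta < 0 || eta > 1)
    stop("'eta' must lie in [0, 1]")
  structure(list(gamma = gamma, eta = eta), class = "adapted_obs_params")
}

#' Unit conversions between mass concentrations and molarity
#'
#' Central conversion utilities: all internal model concentrations are pM;
#' assay limits are quoted as mass concentrations (pg/mL, ng/mL).
#'
#' @param x concentration to convert.
#' @param MW molecular weight, g/mol.
#' @return Converted concentration.
#' @name unit-conversion
NULL

#' @rdname unit-conversion
#' @details `pg_per_ml_to_pM()`: pg/mL -> pM; `ng_per_ml_to_pM()`:
#'   ng/mL -> pM; `pM_to_uM()` and `uM_to_pM()` rescale molarity.
#' @export
pg_per_ml_to_pM <- function(x, MW) {
  stopifnot(MW > 0)
  # pg/mL = 1e-9 g/L; divide by g/mol -> mol/L; 1 mol/L = 1e12 pM
  x * 1e-9 / MW * 1e12
}

#' @rdname unit-conversion
#' @export
ng_per_ml_to_pM <- function(x, MW) pg_per_ml_to_pM(x * 1000, MW)

#' @rdname unit-conversion
#' @export
pM_to_uM <- function(x) x * 1e-6

#' @rdname unit-conversion
#' @export
uM_to_pM <- function(x) x * 1e6

#' Assay lower limits of quantification in model units
#'
#' The ELISA limits are 9.0 pg/mL for VEGF and 0.156 ng/mL for ranibizumab;
#' this helper converts them to the package's observation units (VEGF pM,
#' antibody uM) using the supplied molecular weights, rather than
#' hard-coding the converted values.
#'
#' @param mc a [molecular_constants()] object.
#' @param vegf_pg_ml VEGF LLQ as quoted by the assay, pg/mL.
#' @param ranibizumab_ng_ml antibody LLQ as quoted by the assay, ng/mL.
#' @return Named list `llq_v` (pM) and `llq_r` (uM).
#' @examples
#' default_llq() # llq_v ~ 0.2 pM, llq_r ~ 3.25e-6 uM
#' @export
default_llq <- function(mc = molecular_constants(),
                        vegf_pg_ml = 9.0, ranibizumab_ng_ml = 0.156) {
  list(llq_v = pg_per_ml_to_pM(vegf_pg_ml, mc$MW_V),
       llq_r = pM_to_uM(ng_per_ml_to_pM(ranibizumab_ng_ml, mc$MW_R)))
}

#' @export
print.ocular_params <- function(x, ...) {
  cat("Two-compartment ocular model parameters (pM, mL, day):\n")
  vals <- unlist(x[names(x)])
  print(signif(vals, 4))
  cat(sprintf("derived k_on = k_off/K_D = %.4g pM^-1 day^-1\n", k_on(x)))
  invisible(x)
}
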