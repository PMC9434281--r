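#' Activation thermodynamics from kinetic results
#'
#' Per conversion level computes the activation enthalpy, Gibbs energy and
#' entropy from the transition-state (Eyring) relations
#' `dH = Ea - R T_ref`,
#' `dG = Ea + R T_p ln(kB T_p / (h A))`,
#' `dS = (dH - dG) / T_p`,
#' with `kB` the Boltzmann constant and `h` the Planck constant. `T_ref`
#' (the temperature entering `dH`) and `T_p` (the DTG peak temperature
#' entering `dG`/`dS`) are deliberately separate explicit arguments rather
#' than a single implied temperature. Because `kB T / h` is a frequency in
#' 1/s, a pre-exponential factor in 1/min is converted to 1/s inside the
#' `dG` formula when `convert_A = TRUE` (the default; set `FALSE` to
#' reproduce tabulations that skipped the conversion).
#'
#' @param ea_profile an `ea_profile`, or any data frame with columns
#'   `alpha` and `Ea_kJ_per_mol`.
#' @param A_per_alpha pre-exponential factor per row; taken from the
#'   profile's `A_per_min` column when omitted.
#' @param T_ref temperature (K) in the enthalpy relation.
#' @param T_p DTG peak temperature (K) in the Gibbs/entropy relations.
#' @param a_units units of `A_per_alpha`.
#' @param convert_A convert A to 1/s inside the Gibbs relation when it is
#'   supplied per minute.
#' @return a data frame of class `thermo_profile` with columns `alpha`,
#'   `Ea_kJ_per_mol`, `A`, `dH_kJ_per_mol`, `dG_kJ_per_mol`,
#'   `dS_kJ_per_mol_K`; `T_ref`, `T_p`, units and the conversion flag are
#'   recorded as attributes.
#' @export
thermo_params <- function(ea_profile, A_per_alpha = NULL, T_ref, T_p,
                          a_units = c("per_minute", "per_second"),
                          convert_A = TRUE) {
  a_units <- match.arg(a_units)
  stopifnot(is.data.frame(ea_profile))
  if (missing(T_p) || is.null(T_p) || !is.finite(T_p) || T_p <= 0)
    stop("a positive peak temperature T_p is required")
  if (missing(T_ref) || !is.finite(T_ref) || T_ref <= 0)
    stop("a positive reference temperature T_ref is required")
  if (is.null(A_per_alpha)) A_per_alpha <- ea_profile$A_per_min
  if (is.null(A_per_alpha))
    stop("no pre-exponential factors: supply A_per_alpha or a profile ",
         "with an A_per_min column (see preexponential())")
  if (any(!is.finite(A_per_alpha) | A_per_alpha <= 0))
    stop("pre-exponential factors must be positive and finite at every row")
  Ea <- ea_profile$Ea_kJ_per_mol
  A_s <- if (a_units == "per_minute" && convert_A) A_per_alpha / 60
         else A_per_alpha
  dH <- Ea - .Rgas * T_ref / 1000
  dG <- Ea + .Rgas * T_p * log(.kB * T_p / (.h * A_s)) / 1000
  dS <- (dH - dG) / T_p
  out <- data.frame(alpha = ea_profile$alpha, Ea_kJ_per_mol = Ea,
                    A = A_per_alpha, dH_kJ_per_mol = dH,
                    dG_kJ_per_mol = dG, dS_kJ_per_mol_K = dS)
  structure(out, T_ref = T_ref, T_p = T_p, a_units = a_units,
            convert_A = convert_A,
            class = c("thermo_profile", "data.frame"))
}

#' Summarize a thermodynamic profile
#'
#' Arithmetic means and sample standard deviations of the activation
#' parameters, plus the conversion interval over which the activation
#' entropy changes sign (if it does) -- the crossover from an ordered
#' activated complex to one less ordered than the reactant.
#'
#' @param profile a `thermo_profile` with at least 2 rows.
#' @return a list with `mean`, `sd` (named vectors over Ea, dH, dG, dS)
#'   and `dS_sign_change` (length-2 conversion bracket, or `NULL`).
#' @export
summarize_thermo <- function(profile) {
  stopifnot(inherits(profile, "data.frame"))
  if (nrow(profile) < 2L)
    stop("summary needs at least 2 rows, got ", nrow(profile))
  cols <- c("Ea_kJ_per_mol", "dH_kJ_per_mol", "dG_kJ_per_mol",
            "dS_kJ_per_mol_K")
  mu <- vapply(cols, function(cn) mean(profile[[cn]]), 0)
  sdv <- vapply(cols, function(cn) stats::sd(profile[[cn]]), 0)
  s <- sign(profile$dS_kJ_per_mol_K)
  flip <- which(s[-1] * s[-length(s)] < 0)
  change <- if (length(flip))
    c(profile$alpha[flip[1]], profile$alpha[flip[1] + 1L]) else NULL
  list(mean = mu, sd = sdv, dS_sign_change = change)
}
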