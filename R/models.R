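## Registry of ideal solid-state reaction models. Each entry is the standard
## differential form f(alpha) together with its integral form
## g(alpha) = integral_0^alpha d a / f(a).
.model_registry <- list(
  F1 = list(f = function(a) (1 - a),
            g = function(a) -log(1 - a)),
  F2 = list(f = function(a) (1 - a)^2,
            g = function(a) 1 / (1 - a) - 1),
  F3 = list(f = function(a) (1 - a)^3,
            g = function(a) ((1 - a)^-2 - 1) / 2),
  A2 = list(f = function(a) 2 * (1 - a) * (-log(1 - a))^(1 / 2),
            g = function(a) (-log(1 - a))^(1 / 2)),
  A3 = list(f = function(a) 3 * (1 - a) * (-log(1 - a))^(2 / 3),
            g = function(a) (-log(1 - a))^(1 / 3)),
  R2 = list(f = function(a) 2 * (1 - a)^(1 / 2),
            g = function(a) 1 - (1 - a)^(1 / 2)),
  R3 = list(f = function(a) 3 * (1 - a)^(2 / 3),
            g = function(a) 1 - (1 - a)^(1 / 3)),
  D1 = list(f = function(a) 1 / (2 * a),
            g = function(a) a^2),
  D2 = list(f = function(a) -1 / log(1 - a),
            g = function(a) (1 - a) * log(1 - a) + a),
  D3 = list(f = function(a) 3 * (1 - a)^(2 / 3) / (2 * (1 - (1 - a)^(1 / 3))),
            g = function(a) (1 - (1 - a)^(1 / 3))^2),
  P2 = list(f = function(a) 2 * a^(1 / 2),
            g = function(a) a^(1 / 2))
)

#' Ideal solid-state reaction model
#'
#' Returns one of the classical reaction models used in solid-state kinetics,
#' as a pair of its differential form `f(alpha)` and integral form
#' `g(alpha)`. Registry: reaction order F1-F3, Avrami-Erofeev nucleation
#' A2/A3, phase-boundary contraction R2/R3, diffusion D1-D3 (D3 is the
#' Jander form), and power law P2.
#'
#' @param name model name, one of
#'   `"F1" "F2" "F3" "A2" "A3" "R2" "R3" "D1" "D2" "D3" "P2"`.
#' @return an object of class `kinetic_model`: a list with elements
#'   `name`, `f` and `g` (both functions of conversion `alpha`).
#' @examples
#' m <- ideal_model("F1")
#' m$f(0.5)   # 0.5
#' m$g(0.5)   # -log(0.5)
#' @export
ideal_model <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.model_registry))
    stop("unknown model '", paste(name, collapse = ","),
         "'; registry: ", paste(names(.model_registry), collapse = ", "))
  structure(c(list(name = name), .model_registry[[name]]),
            class = "kinetic_model")
}

#' Names of all registered ideal models
#' @return character vector of model names.
#' @export
model_registry <- function() names(.model_registry)

#' Truncated Sestak-Berggren model
#'
#' The empirical two-exponent kinetic model `f(alpha) = c (1-alpha)^n alpha^m`
#' used by the combined kinetic analysis. It has no closed integral form in
#' general, so `g` is `NULL`.
#'
#' @param n reaction-order exponent on `(1 - alpha)`.
#' @param m exponent on `alpha`.
#' @param c scale constant (default 1; it is absorbed into the
#'   pre-exponential factor in fits).
#' @return an object of class `kinetic_model` with `g = NULL`.
#' @export
sb_model <- function(n, m, c = 1) {
  force(n); force(m); force(c)
  structure(list(name = sprintf("SB(n=%g,m=%g)", n, m),
                 f = function(a) c * (1 - a)^n * a^m,
                 g = NULL),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model", x$name,
      if (is.null(x$g)) "(differential form only)" else "(f and g forms)",
      "\n")
  invisible(x)
}
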