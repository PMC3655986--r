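#' Voltage-dependent rate laws
#'
#' Transition rates in a gating scheme are functions of membrane voltage.
#' Four families are supported:
#'
#' * **exponential**: `rate(V) = k * exp(V / n)`, the workhorse law. `k` is the
#'   pre-exponential factor (1/ms) and `n` the exponential voltage factor (mV);
#'   a negative `n` makes the rate grow with hyperpolarization. A
#'   voltage-independent rate is expressed explicitly as the constant mode
#'   `n = Inf` (so `rate(V) = k` exactly, with no overflow for any finite `V`).
#' * **sigmoid**: `rate(V) = g / (1 + exp(-(V + a) / f))`, saturating at the
#'   maximal rate `g` (1/ms) with half-activation at `V = -a` and slope factor
#'   `f` (mV).
#' * **scaled**: `c` times another law, `c > 0` dimensionless.
#' * **derived**: a placeholder whose value is computed at generator-assembly
#'   time from microscopic reversibility of a reaction cycle (see
#'   [derive_reversibility_rate()]).
#'
#' @param k Pre-exponential factor, 1/ms. Must be positive.
#' @param n Exponential voltage factor, mV. Nonzero; `Inf` (or `-Inf`) selects
#'   the constant mode.
#' @param g Maximal rate, 1/ms. Must be positive.
#' @param a Half-activation offset, mV: the rate equals `g/2` at `V = -a`.
#' @param f Slope factor, mV. Must be positive.
#' @param base Another `rate_law` to scale.
#' @param c Positive dimensionless multiplier.
#' @param cycle Optional list of `c(from, to)` pairs describing the closed
#'   reaction cycle used to derive the rate; usually left `NULL` and resolved
#'   automatically by [kinetic_scheme()].
#' @return An object of class `rate_law`.
#' @examples
#' eval_rate(rate_exp(9.435, 39.70), 0)        # = k at V = 0
#' eval_rate(rate_sigmoid(0.01296, 85.62, 15.64), -85.62)  # = g/2
#' eval_rate(rate_scaled(rate_exp(1, 20), 2.146), -50)
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
rate_exp <- function(k, n = Inf) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            is.numeric(n), length(n) == 1L, !is.na(n))
  if (n == 0) stop("'n' must be nonzero; use n = Inf for a constant rate")
  structure(list(k = k, n = n), class = c("exp_law", "rate_law"))
}

#' @rdname rate_laws
#' @export
rate_sigmoid <- function(g, a, f) {
  stopifnot(is.numeric(g), is.finite(g), g > 0,
            is.numeric(a), is.finite(a),
            is.numeric(f), is.finite(f), f > 0)
  structure(list(g = g, a = a, f = f), class = c("sigmoid_law", "rate_law"))
}

#' @rdname rate_laws
#' @export
rate_scaled <- function(base, c) {
  stopifnot(inherits(base, "rate_law"), is.numeric(c), is.finite(c), c > 0)
  structure(list(base = base, c = c), class = c("scaled_law", "rate_law"))
}

#' @rdname rate_laws
#' @export
rate_derived <- function(cycle = NULL) {
  structure(list(cycle = cycle), class = c("derived_law", "rate_law"))
}

#' Evaluate a rate law at one or more membrane voltages
#'
#' @param law A `rate_law` object.
#' @param V Membrane voltage(s), mV. Must be finite.
#' @return Numeric vector of rates (1/ms), strictly positive.
#' @export
eval_rate <- function(law, V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("membrane voltage 'V' must be finite numeric (got ",
         paste(utils::head(V, 3), collapse = ", "), ")")
  UseMethod("eval_rate")
}

#' @export
eval_rate.exp_law <- function(law, V) law$k * exp(V / law$n)

#' @export
eval_rate.sigmoid_law <- function(law, V) law$g / (1 + exp(-(V + law$a) / law$f))

#' @export
eval_rate.scaled_law <- function(law, V) law$c * eval_rate(law$base, V)

#' @export
eval_rate.derived_law <- function(law, V)
  stop("a derived rate has no standalone value; it is resolved from its ",
       "cycle when the generator matrix is assembled")

#' @export
print.rate_law <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.exp_law <- function(x, ...) {
  if (is.infinite(x$n)) sprintf("<rate: %g /ms (constant)>", x$k)
  else sprintf("<rate: %g * exp(V/%g) /ms>", x$k, x$n)
}

#' @export
format.sigmoid_law <- function(x, ...)
  sprintf("<rate: %g / (1 + exp(-(V+%g)/%g)) /ms>", x$g, x$a, x$f)

#' @export
format.scaled_law <- function(x, ...)
  sprintf("<rate: %g * %s>", x$c, format(x$base))

#' @export
format.derived_law <- function(x, ...)
  "<rate: derived from microscopic reversibility>"
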