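#' Uptake bound functions
#'
#' An uptake bound function gives the maximum rate (mmol/gDW/h) at which an
#' organism can import an environmental metabolite, as a non-decreasing
#' function of that metabolite's current amount `y`. Three kinds are
#' supported:
#'
#' * `"constant"`: `f(y) = value`,
#' * `"linear"`: `f(y) = kappa * y` (first-order kinetics),
#' * `"michaelis_menten"`: `f(y) = Vmax * y / (K + y)`.
#'
#' @param kind One of `"constant"`, `"linear"`, `"michaelis_menten"`.
#' @param ... Parameters of the chosen kind: `value` (constant), `kappa`
#'   (linear), `Vmax` and `K` (michaelis_menten).
#' @return An object of class `dfba_bound`.
#' @examples
#' f <- bound_function("linear", kappa = 1)
#' bf_eval(f, 2)    # 2
#' bf_deriv(f, 2)   # 1
#' @export
bound_function <- function(kind = c("constant", "linear", "michaelis_menten"),
                           ...) {
  kind <- match.arg(kind)
  params <- list(...)
  params <- switch(kind,
    constant = {
      value <- params$value
      if (is.null(value) && length(params) == 1L && is.null(names(params)))
        value <- params[[1L]]
      if (is.null(value) || !is.finite(value) || value < 0)
        stop("constant bound requires a finite non-negative 'value'")
      list(value = as.numeric(value))
    },
    linear = {
      kappa <- params$kappa
      if (is.null(kappa) || !is.finite(kappa) || kappa < 0)
        stop("linear bound requires a finite non-negative slope 'kappa'")
      list(kappa = as.numeric(kappa))
    },
    michaelis_menten = {
      if (is.null(params$Vmax) || is.null(params$K))
        stop("michaelis_menten bound requires 'Vmax' and 'K'")
      if (params$Vmax < 0 || params$K <= 0)
        stop("michaelis_menten bound requires Vmax >= 0 and K > 0")
      list(Vmax = as.numeric(params$Vmax), K = as.numeric(params$K))
    })
  structure(list(kind = kind, params = params), class = "dfba_bound")
}

#' Evaluate an uptake bound function
#'
#' @param f A [bound_function()].
#' @param y Metabolite amount(s), `>= 0` (negative inputs are treated as 0,
#'   matching the non-negative orthant the dynamics live in).
#' @return Numeric vector of bound values.
#' @export
bf_eval <- function(f, y) {
  stopifnot(inherits(f, "dfba_bound"))
  y <- pmax(y, 0)
  switch(f$kind,
    constant = rep(f$params$value, length(y)),
    linear = f$params$kappa * y,
    michaelis_menten = f$params$Vmax * y / (f$params$K + y))
}

#' Derivative of an uptake bound function with respect to y
#'
#' Used when testing whether a candidate basis remains feasible to first
#' order: slack derivatives of monitored constraints need `d c2/d y`.
#'
#' @inheritParams bf_eval
#' @return Numeric vector `f'(y)`.
#' @export
bf_deriv <- function(f, y) {
  stopifnot(inherits(f, "dfba_bound"))
  y <- pmax(y, 0)
  switch(f$kind,
    constant = rep(0, length(y)),
    linear = rep(f$params$kappa, length(y)),
    michaelis_menten = f$params$Vmax * f$params$K / (f$params$K + y)^2)
}

#' @export
print.dfba_bound <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat(sprintf("<uptake bound: %s (%s)>\n", x$kind, p))
  invisible(x)
}

#' @export
format.dfba_bound <- function(x, ...) {
  paste0(x$kind, "(", paste(names(x$params), unlist(x$params),
                            sep = "=", collapse = ","), ")")
}
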