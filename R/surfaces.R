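#' Analytic potential surface
#'
#' A lightweight wrapper for a potential energy function on a configuration
#' vector, standing in for the electronic-structure energies that a
#' transition-state search would normally evaluate. The gradient is analytic
#' when supplied, otherwise a central finite difference.
#'
#' @param fun Function of a length-`dimension` numeric vector returning the
#'   energy in kcal/mol. May optionally also accept an n x dimension matrix
#'   and return a vector (used for fast grid evaluation).
#' @param grad Function returning the gradient vector, or `NULL` for the
#'   finite-difference fallback.
#' @param dimension Configuration-space dimension.
#' @param fd_step Finite-difference step for the fallback gradient.
#' @return Object of class `potential_surface`.
#' @examples
#' dw <- potential_surface(function(x) 5 * (x^2 - 1)^2,
#'                         function(x) 20 * x * (x^2 - 1), dimension = 1)
#' surface_energy(dw, 0)     # barrier top
#' surface_gradient(dw, 0.5)
#' @export
potential_surface <- function(fun, grad = NULL, dimension, fd_step = 1e-6) {
  stopifnot(is.function(fun), is.null(grad) || is.function(grad),
            dimension >= 1)
  structure(list(fun = fun, grad = grad, dimension = as.integer(dimension),
                 fd_step = fd_step),
            class = "potential_surface")
}

#' @rdname potential_surface
#' @param surface A `potential_surface`.
#' @param x Configuration vector.
#' @export
surface_energy <- function(surface, x) surface$fun(x)

#' @rdname potential_surface
#' @export
surface_gradient <- function(surface, x) {
  if (!is.null(surface$grad)) return(surface$grad(x))
  h <- surface$fd_step
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (surface$fun(xp) - surface$fun(xm)) / (2 * h)
  }, numeric(1))
}

# evaluate the surface on many points (rows); uses a vectorized fun if the
# function accepts a matrix, otherwise falls back to a loop
.surface_energy_many <- function(surface, x) {
  x <- as.matrix(x)
  out <- tryCatch(surface$fun(x), error = function(e) NULL)
  if (is.numeric(out) && length(out) == nrow(x)) return(out)
  apply(x, 1, function(p) surface$fun(as.numeric(p)))
}
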