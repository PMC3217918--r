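#' Rate parameters of the two-compartment sphere-culture model
#'
#' Bundles the four per-day rates of the linear growth/interconversion model:
#' the intrinsic (net birth) growth rates of cancer stem cells (CSCs) and of
#' differentiated cancer cells, and the two conversion rates between the
#' compartments. The symbols \code{k1}, \code{k2}, \code{a}, \code{b} are
#' package conventions for these four rates.
#'
#' @param k1 Intrinsic growth rate of CSCs (per day, >= 0).
#' @param k2 Intrinsic growth rate of differentiated cancer cells (per day,
#'   >= 0).
#' @param a Conversion rate from CSCs to differentiated cancer cells during
#'   CSC proliferation (per day, >= 0). Encodes asymmetric division as
#'   symmetric division followed by conversion.
#' @param b Conversion rate from differentiated cancer cells back to CSCs
#'   (per day, >= 0), e.g. through epithelial-mesenchymal transition.
#' @return An object of class \code{"csc_params"}: a named list with
#'   elements \code{k1}, \code{k2}, \code{a}, \code{b}.
#' @examples
#' p <- rate_params(k1 = 0.2, k2 = 0.22, a = 0.01, b = 0.001)
#' limiting_ratio(p)
#' @export
rate_params <- function(k1, k2, a, b) {
  p <- list(k1 = as.numeric(k1), k2 = as.numeric(k2),
            a = as.numeric(a), b = as.numeric(b))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v))
      stop("rate parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v < 0)
      stop("rate parameter '", nm, "' must be non-negative, got ", v,
           call. = FALSE)
  }
  structure(p, class = "csc_params")
}

#' @export
print.csc_params <- function(x, ...) {
  cat("Two-compartment sphere-culture rates (per day):\n")
  cat(sprintf("  k1 (CSC growth)                 = %g\n", x$k1))
  cat(sprintf("  k2 (differentiated growth)      = %g\n", x$k2))
  cat(sprintf("  a  (CSC -> differentiated)      = %g\n", x$a))
  cat(sprintf("  b  (differentiated -> CSC)      = %g\n", x$b))
  invisible(x)
}

as_rate_params <- function(x) {
  if (inherits(x, "csc_params")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    nm <- names(x)
    if (is.null(nm)) nm <- c("k1", "k2", "a", "b")
    return(rate_params(x[["k1"]] %||% x[[1L]], x[["k2"]] %||% x[[2L]],
                       x[["a"]] %||% x[[3L]], x[["b"]] %||% x[[4L]]))
  }
  if (is.list(x)) return(rate_params(x$k1, x$k2, x$a, x$b))
  stop("cannot interpret object as rate parameters", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' System matrix of the model
#'
#' Returns the 2x2 matrix of the linear system for (S, D): growth net of
#' outgoing conversion on the diagonal, conversion fluxes off-diagonal.
#'
#' @param params A \code{\link{rate_params}} object.
#' @return A 2x2 numeric matrix \code{[[k1 - a, b], [a, k2 - b]]}.
#' @keywords internal
system_matrix <- function(params) {
  params <- as_rate_params(params)
  matrix(c(params$k1 - params$a, params$a,
           params$b, params$k2 - params$b), 2L, 2L)
}
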