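#' Parameters of the general geometric indel (GGI) process
#'
#' Constructs and validates the parameter set of the GGI model: insertions
#' are initiated at rate `lambda` per site and deletions at rate `mu` per
#' residue, and each event removes or adds a geometrically distributed number
#' of residues, with extension probabilities `x` (insertions) and `y`
#' (deletions).  The mean event lengths are `1/(1-x)` and `1/(1-y)`.
#'
#' @param lambda Insertion initiation rate per site (events per unit time),
#'   `lambda >= 0`.
#' @param mu Deletion initiation rate per residue, `mu >= 0`.
#' @param x Insertion extension probability, `0 <= x < 1`.
#' @param y Deletion extension probability, `0 <= y < 1`.
#'
#' @return An object of class `"ggi_params"`: a list with elements `lambda`,
#'   `mu`, `x`, `y`.
#'
#' @examples
#' p <- ggi_params(1, 1, 0.5, 0.5)
#' is_reversible(p)
#'
#' @export
ggi_params <- function(lambda, mu, x, y) {
  for (nm in c("lambda", "mu", "x", "y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite numeric value", call. = FALSE)
  }
  if (lambda < 0 || mu < 0)
    stop("indel rates 'lambda' and 'mu' must be nonnegative", call. = FALSE)
  if (x < 0 || x >= 1)
    stop("insertion extension probability 'x' must satisfy 0 <= x < 1 ",
         "(mean event length 1/(1-x) diverges at x = 1)", call. = FALSE)
  if (y < 0 || y >= 1)
    stop("deletion extension probability 'y' must satisfy 0 <= y < 1",
         call. = FALSE)
  structure(list(lambda = lambda, mu = mu, x = x, y = y),
            class = "ggi_params")
}

#' @rdname ggi_params
#' @param ... Passed to `ggi_params()` (rate and extension parameters).
#' @export
validate_params <- function(...) ggi_params(...)

#' Test detailed balance of a GGI parameter set
#'
#' The indel process is reversible iff `lambda * y * (1 - x) ==
#' mu * x * (1 - y)`, i.e. the insertion and deletion length/rate products
#' balance.
#'
#' @param p A [ggi_params()] object.
#' @param tol Absolute tolerance of the balance check.
#' @return `TRUE` or `FALSE`.
#' @export
is_reversible <- function(p, tol = 1e-9) {
  stopifnot(inherits(p, "ggi_params"))
  abs(p$lambda * p$y * (1 - p$x) - p$mu * p$x * (1 - p$y)) <= tol
}

#' Instantaneous rate of an indel event of a given length
#'
#' At any site, an event inserting `n` residues has rate
#' `lambda * x^(n-1) * (1-x)`; an event deleting `n` residues has rate
#' `mu * y^(n-1) * (1-y)`.  Summed over `n >= 1` these give back `lambda`
#' and `mu`.
#'
#' @param p A [ggi_params()] object.
#' @param kind `"ins"` or `"del"`.
#' @param n Event length(s), positive integer(s).
#' @return Numeric vector of rates, one per element of `n`.
#' @export
indel_event_rate <- function(p, kind = c("ins", "del"), n) {
  stopifnot(inherits(p, "ggi_params"))
  kind <- match.arg(kind)
  if (any(n < 1) || any(n != round(n)))
    stop("event length 'n' must be a positive integer", call. = FALSE)
  if (kind == "ins") p$lambda * p$x^(n - 1) * (1 - p$x)
  else               p$mu * p$y^(n - 1) * (1 - p$y)
}

#' @export
print.ggi_params <- function(x, ...) {
  cat("GGI indel process parameters\n")
  cat(sprintf("  insertion rate lambda = %g, extension x = %g (mean length %g)\n",
              x$lambda, x$x, 1 / (1 - x$x)))
  cat(sprintf("  deletion  rate mu     = %g, extension y = %g (mean length %g)\n",
              x$mu, x$y, 1 / (1 - x$y)))
  cat(sprintf("  reversible: %s\n", is_reversible(x)))
  invisible(x)
}
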