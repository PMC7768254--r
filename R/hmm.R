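#' Fit the finite-time alignment machine of the GGI indel process
#'
#' The central fitting function of the package.  Given the indel parameters
#' and a divergence time, it computes the transition probabilities of the
#' three-state pair hidden Markov model describing pairwise alignments of an
#' ancestor and descendant separated by time `t`: either by numerical
#' integration of the expected-transition-count ODE system
#' (`method = "h20"`, the default, exact for `x = y = 0`) or by the TKF91
#' closed form (`method = "tkf91"`, which ignores `x` and `y` since the
#' links model only has single-residue events).
#'
#' @param lambda,mu,x,y GGI parameters (see [ggi_params()]); alternatively
#'   pass a `ggi_params` object as `lambda`.
#' @param t Nonnegative divergence time.
#' @param method `"h20"` (ODE integration) or `"tkf91"` (closed form).
#' @param subst Optional [subst_model()] used by emission-aware methods
#'   (alignment, [forward_likelihood()]); defaults to a symmetric DNA model
#'   when needed.
#' @param ... Further arguments passed to [solve_transition_probs()].
#'
#' @return An object of class `"ggi_hmm"`: a list with components `params`
#'   ([ggi_params()]), `t`, `method`, `probs` ([transition_probs()]) and
#'   `subst`.  Methods: [print.ggi_hmm()], [summary.ggi_hmm()],
#'   [coef.ggi_hmm()] (the nine transition probabilities),
#'   [simulate.ggi_hmm()] (exact stochastic simulation of the underlying
#'   indel process) and [plot.ggi_hmm()] (gap-length distribution).
#'
#' @examples
#' fit <- ggi_hmm(lambda = 1, mu = 1, x = 0.5, y = 0.5, t = 0.5)
#' coef(fit)
#' transition_matrix(fit$probs)
#'
#' @export
ggi_hmm <- function(lambda, mu, x, y, t, method = c("h20", "tkf91"),
                    subst = NULL, ...) {
  method <- match.arg(method)
  p <- if (inherits(lambda, "ggi_params")) lambda
       else ggi_params(lambda, mu, x, y)
  if (!is.null(subst)) stopifnot(inherits(subst, "subst_model"))
  probs <- switch(method,
                  h20 = solve_transition_probs(p, t, ...),
                  tkf91 = tkf91_probs(p$lambda, p$mu, t))
  structure(list(params = p, t = t, method = method, probs = probs,
                 subst = subst),
            class = "ggi_hmm")
}

#' @export
print.ggi_hmm <- function(x, ...) {
  cat(sprintf("GGI alignment pair HMM (method: %s) at t = %g\n",
              x$method, x$t))
  cat(sprintf("  lambda = %g, mu = %g, x = %g, y = %g\n",
              x$params$lambda, x$params$mu, x$params$x, x$params$y))
  cat("transition matrix (M, I, D):\n")
  print(round(transition_matrix(x$probs), 6))
  invisible(x)
}

#' @export
#' @method summary ggi_hmm
summary.ggi_hmm <- function(object, G = 20, ...) {
  d <- hmm_gap_distribution(object$probs, G)
  m <- moments(d)
  occ <- occupancy_closed_form(object$params, object$t)
  out <- list(hmm = object, G = G, moments = m, occupancy = occ,
              tail = d$tail)
  class(out) <- "summary.ggi_hmm"
  out
}

#' @export
print.summary.ggi_hmm <- function(x, ...) {
  print(x$hmm)
  cat(sprintf("expected occupancies (closed form): S_I = %.6g, S_D = %.6g\n",
              x$occupancy$S_I, x$occupancy$S_D))
  cat(sprintf("gap-length distribution on 0..%d (tail bound %.3g):\n",
              x$G, x$tail))
  print(x$moments)
  invisible(x)
}

#' @export
#' @method coef ggi_hmm
coef.ggi_hmm <- function(object, ...) {
  with(object$probs, c(a = a, b = b, c = c, f = f, g = g, h = h,
                       p = p, q = q, r = r))
}

#' Simulate alignments from the underlying indel process
#'
#' Draws `nsim` replicate alignments by exact stochastic simulation of the
#' GGI process at the fitted parameters and divergence time (see
#' [evolve()]).  Note this simulates the process itself, not the fitted
#' HMM approximation, so it can be used to assess the approximation.
#'
#' @param object A [ggi_hmm()] fit.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param L Ancestral sequence length.
#' @param ... Unused.
#' @return List of `alignment_rle` objects.
#' @export
#' @method simulate ggi_hmm
simulate.ggi_hmm <- function(object, nsim = 1, seed = NULL, L = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, evolve(object$params, L, object$t), simplify = FALSE)
}

#' Plot the fitted gap-length distribution
#'
#' Displays `log10 P(S_I, S_D)` of the fitted machine as an image over the
#' gap-length grid.
#'
#' @param x A [ggi_hmm()] fit.
#' @param G Grid size.
#' @param ... Passed to [graphics::image()].
#' @export
#' @method plot ggi_hmm
plot.ggi_hmm <- function(x, G = 20, ...) {
  d <- hmm_gap_distribution(x$probs, G)
  z <- log10(pmax(d$P, 1e-300))
  graphics::image(0:G, 0:G, z, xlab = expression(S[I]),
                  ylab = expression(S[D]),
                  main = sprintf("log10 P(S_I, S_D), t = %g", x$t), ...)
  invisible(x)
}
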