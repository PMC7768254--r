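#' Expected transition counts of the alignment machine
#'
#' Container for the expected numbers of M/I/D transition usages (and I/D
#' occupancies) in walks of the three-state alignment machine that begin and
#' end in the Match state.  The counts satisfy the occupancy identities
#' `S_I = T_MI + T_II + T_DI = T_IM + T_II + T_ID` (and likewise for `S_D`),
#' and `T_MM + T_MI + T_MD = 1`.
#'
#' @param t Divergence time.
#' @param T_MM,T_MI,T_MD,T_IM,T_II,T_ID,T_DM,T_DI,T_DD Expected transition
#'   counts.
#' @param S_I,S_D Expected insert/delete state occupancies.
#' @param tol Tolerance for the consistency checks.
#' @return An object of class `"transition_counts"`.
#' @export
transition_counts <- function(t, T_MM, T_MI, T_MD, T_IM, T_II, T_ID,
                              T_DM, T_DI, T_DD, S_I, S_D, tol = 1e-8) {
  v <- c(T_MM = T_MM, T_MI = T_MI, T_MD = T_MD, T_IM = T_IM, T_II = T_II,
         T_ID = T_ID, T_DM = T_DM, T_DI = T_DI, T_DD = T_DD,
         S_I = S_I, S_D = S_D)
  if (any(v < -tol))
    stop("expected counts must be nonnegative", call. = FALSE)
  if (abs(T_MM + T_MI + T_MD - 1) > tol)
    stop("match-row counts must sum to 1", call. = FALSE)
  if (abs(T_MI + T_II + T_DI - S_I) > tol ||
      abs(T_IM + T_II + T_ID - S_I) > tol)
    stop("insert occupancy identities violated", call. = FALSE)
  if (abs(T_MD + T_ID + T_DD - S_D) > tol ||
      abs(T_DM + T_DI + T_DD - S_D) > tol)
    stop("delete occupancy identities violated", call. = FALSE)
  structure(c(list(t = t), as.list(pmax(v, 0))), class = "transition_counts")
}

#' Transition probabilities of the three-state alignment machine
#'
#' The nine entries `a, b, c` (from Match), `f, g, h` (from Insert) and
#' `p, q, r` (from Delete) of the row-stochastic transition matrix, at
#' divergence time `t`, together with the expected occupancies `S_I`, `S_D`.
#'
#' @param t Divergence time.
#' @param a,b,c,f,g,h,p,q,r Transition probabilities; each row triple must
#'   sum to 1.
#' @param S_I,S_D Optional expected occupancies carried along.
#' @param method Label recording how the probabilities were obtained.
#' @param tol Tolerance for the simplex checks.
#' @return An object of class `"transition_probs"`.
#' @export
transition_probs <- function(t, a, b, c, f, g, h, p, q, r,
                             S_I = NA_real_, S_D = NA_real_,
                             method = "direct", tol = 1e-7) {
  v <- c(a, b, c, f, g, h, p, q, r)
  names(v) <- c("a", "b", "c", "f", "g", "h", "p", "q", "r")
  if (any(v < -tol) || any(v > 1 + tol))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(a + b + c - 1) > tol || abs(f + g + h - 1) > tol ||
      abs(p + q + r - 1) > tol)
    stop("each row of the transition matrix must sum to 1", call. = FALSE)
  v <- pmin(pmax(v, 0), 1)
  structure(c(list(t = t), as.list(v),
              list(S_I = S_I, S_D = S_D, method = method)),
            class = "transition_probs")
}

#' @export
print.transition_probs <- function(x, ...) {
  cat(sprintf("Alignment transition probabilities at t = %g (%s)\n",
              x$t, x$method))
  print(round(transition_matrix(x), 6))
  if (is.finite(x$S_I))
    cat(sprintf("expected occupancies: S_I = %g, S_D = %g\n", x$S_I, x$S_D))
  invisible(x)
}

#' Transition matrix of a `transition_probs` object
#'
#' @param probs A [transition_probs()] object.
#' @return 3x3 row-stochastic matrix with rows/columns M, I, D.
#' @export
transition_matrix <- function(probs) {
  stopifnot(inherits(probs, "transition_probs"))
  m <- rbind(c(probs$a, probs$b, probs$c),
             c(probs$f, probs$g, probs$h),
             c(probs$p, probs$q, probs$r))
  dimnames(m) <- list(c("M", "I", "D"), c("M", "I", "D"))
  m
}

#' Closed-form expected occupancies
#'
#' The expected numbers of inserted and deleted residues per inter-match
#' interval have the closed forms `S_I(t) = exp(lambda*t/(1-x)) - 1` and
#' `S_D(t) = exp(mu*t/(1-y)) - 1`, solving `dS_I/dt = lambda*(1+S_I)/(1-x)`
#' (and likewise for deletions).  To first order in `t` these are
#' `lambda*t/(1-x)` and `mu*t/(1-y)`: initiation rate times mean geometric
#' event length.
#'
#' @param p A [ggi_params()] object.
#' @param t Nonnegative time (vectorized).
#' @return List with numeric elements `S_I` and `S_D`.
#' @export
occupancy_closed_form <- function(p, t) {
  stopifnot(inherits(p, "ggi_params"))
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  list(S_I = expm1(p$lambda * t / (1 - p$x)),
       S_D = expm1(p$mu * t / (1 - p$y)))
}

#' Convert expected counts to transition probabilities
#'
#' `a = T_MM`, `b = T_MI`, `c = T_MD`; the Insert and Delete rows are the
#' corresponding counts divided by the occupancies `S_I`, `S_D`.  When an
#' occupancy is below `eps` the 0/0 ratios are replaced by their `t = 0`
#' limits `f = 1-x, g = x, h = 0` (resp. `p = 1-y, r = y, q = 0`), which is
#' why the indel parameters are required.
#'
#' @param counts A [transition_counts()] object.
#' @param p A [ggi_params()] object supplying the boundary limits.
#' @param eps Occupancy threshold below which the boundary limits are used.
#' @return A [transition_probs()] object.
#' @export
counts_to_probs <- function(counts, p, eps = 1e-12) {
  stopifnot(inherits(counts, "transition_counts"), inherits(p, "ggi_params"))
  with(counts, {
    if (S_I > eps) {
      f <- T_IM / S_I; g <- T_II / S_I; h <- T_ID / S_I
    } else {
      f <- 1 - p$x; g <- p$x; h <- 0
    }
    if (S_D > eps) {
      pp <- T_DM / S_D; q <- T_DI / S_D; r <- T_DD / S_D
    } else {
      pp <- 1 - p$y; q <- 0; r <- p$y
    }
    transition_probs(t, a = T_MM, b = T_MI, c = T_MD,
                     f = f, g = g, h = h, p = pp, q = q, r = r,
                     S_I = S_I, S_D = S_D, method = "counts")
  })
}

#' Complete the count vector from its primary components
#'
#' Given the four primary counts `T_MM, T_MI, T_IM, T_DI` and the
#' occupancies, the remaining five counts follow from linear identities:
#' `T_MD = 1 - T_MM - T_MI`, `T_II = S_I - T_MI - T_DI`,
#' `T_ID = T_MI + T_DI - T_IM`, `T_DM = 1 - T_MM - T_IM`,
#' `T_DD = S_D + T_MM + T_IM - T_DI - 1`.
#'
#' @param T_MM,T_MI,T_IM,T_DI Primary expected counts.
#' @param S_I,S_D Expected occupancies.
#' @param t Time attached to the result.
#' @param tol Consistency tolerance: a derived count below `-tol` raises an
#'   error.
#' @return A [transition_counts()] object.
#' @export
derived_counts <- function(T_MM, T_MI, T_IM, T_DI, S_I, S_D, t = NA_real_,
                           tol = 1e-8) {
  T_MD <- 1 - T_MM - T_MI
  T_II <- S_I - T_MI - T_DI
  T_ID <- T_MI + T_DI - T_IM
  T_DM <- 1 - T_MM - T_IM
  T_DD <- S_D + T_MM + T_IM - T_DI - 1
  d <- c(T_MD = T_MD, T_II = T_II, T_ID = T_ID, T_DM = T_DM, T_DD = T_DD)
  if (any(d < -tol))
    stop("inconsistent primary counts: derived count(s) negative: ",
         paste(names(d)[d < -tol], collapse = ", "), call. = FALSE)
  transition_counts(t, T_MM = T_MM, T_MI = T_MI, T_MD = max(T_MD, 0),
                    T_IM = T_IM, T_II = max(T_II, 0), T_ID = max(T_ID, 0),
                    T_DM = max(T_DM, 0), T_DI = T_DI, T_DD = max(T_DD, 0),
                    S_I = S_I, S_D = S_D, tol = tol)
}

#' Time derivatives of the primary expected counts
#'
#' The right-hand sides of the coupled ODE system for the primary counts,
#' expressed in the current transition probabilities `a ... r` and the indel
#' parameters:
#' \deqn{dT_{MM}/dt = \mu b f (1-y)/(1-gy) - (\lambda+\mu) a}
#' \deqn{dT_{MI}/dt = -\mu b (1-g)/(1-gy) + \lambda (1-b)}
#' \deqn{dT_{IM}/dt = \lambda a - \mu f (1-g)\,\frac{b(1-r)+cq}{(1-gy)(f(1-r)+hp)}}
#' \deqn{dT_{DI}/dt = \mu (1-g)\,\frac{b(1-r-hq)+cgq}{(1-gy)(f(1-r)+hp)}}
#' At `t = 0` (where `a = 1`, `b = c = 0`) these reduce to
#' `(-(lambda+mu), lambda, lambda, 0)`.
#'
#' @param probs A [transition_probs()] object.
#' @param p A [ggi_params()] object.
#' @return Named numeric vector `d(T_MM, T_MI, T_IM, T_DI)/dt`.
#' @export
count_derivatives <- function(probs, p) {
  stopifnot(inherits(probs, "transition_probs"), inherits(p, "ggi_params"))
  lam <- p$lambda; mu <- p$mu; y <- p$y
  with(probs, {
    den <- 1 - g * y
    fh <- f * (1 - r) + h * p
    c(T_MM = mu * b * f * (1 - y) / den - (lam + mu) * a,
      T_MI = -mu * b * (1 - g) / den + lam * (1 - b),
      T_IM = lam * a - mu * f * (1 - g) * (b * (1 - r) + c * q) / (den * fh),
      T_DI = mu * (1 - g) * (b * (1 - r - h * q) + c * g * q) / (den * fh))
  })
}

probs_from_state <- function(state, t, p, eps = 1e-12) {
  state <- unname(state); t <- unname(t)
  occ <- occupancy_closed_form(p, t)
  T_MM <- state[1]; T_MI <- state[2]; T_IM <- state[3]; T_DI <- state[4]
  S_I <- occ$S_I; S_D <- occ$S_D
  # roundoff can push counts a hair outside [0, 1] mid-step, so clamp softly
  clamp01 <- function(z) pmin(pmax(z, 0), 1)
  a <- clamp01(T_MM); b <- clamp01(T_MI)
  cc <- clamp01(1 - T_MM - T_MI)
  T_II <- S_I - T_MI - T_DI
  T_DM <- 1 - T_MM - T_IM
  if (S_I > eps) {
    f <- clamp01(T_IM / S_I); g <- clamp01(T_II / S_I)
    h <- clamp01(1 - f - g)
  } else {
    f <- 1 - p$x; g <- p$x; h <- 0
  }
  if (S_D > eps) {
    pp <- clamp01(T_DM / S_D); q <- clamp01(T_DI / S_D)
    r <- clamp01(1 - pp - q)
  } else {
    pp <- 1 - p$y; q <- 0; r <- p$y
  }
  s <- a + b + cc; a <- a / s; b <- b / s; cc <- cc / s
  s <- f + g + h; f <- f / s; g <- g / s; h <- h / s
  s <- pp + q + r; pp <- pp / s; q <- q / s; r <- r / s
  transition_probs(t, a = a, b = b, c = cc, f = f, g = g, h = h,
                   p = pp, q = q, r = r, S_I = S_I, S_D = S_D,
                   method = "ode")
}

#' Finite-time transition probabilities by ODE integration
#'
#' Integrates the coupled ODE system for the primary expected counts
#' `(T_MM, T_MI, T_IM, T_DI)` from the `t = 0` boundary (`T_MM = 1`, all
#' others 0), carrying the occupancies by their closed form and completing
#' the remaining counts by the linear identities at every right-hand-side
#' evaluation.  The result is the row-stochastic transition matrix of the
#' three-state alignment machine at time `t`.  For `x = y = 0` the result
#' agrees with the exact TKF91 solution ([tkf91_probs()]).
#'
#' @param p A [ggi_params()] object.
#' @param t Nonnegative divergence time.
#' @param times Optional increasing vector of output times (dense output);
#'   overrides `t`.
#' @param rtol,atol Integrator tolerances.
#' @param method `deSolve` integration method.
#' @return A [transition_probs()] object at time `t`, or -- when `times` is
#'   given -- a list of such objects, one per output time.
#' @export
solve_transition_probs <- function(p, t, times = NULL,
                                   rtol = 1e-10, atol = 1e-12,
                                   method = "lsoda") {
  stopifnot(inherits(p, "ggi_params"))
  dense <- !is.null(times)
  if (!dense) {
    if (!is.numeric(t) || length(t) != 1L || t < 0)
      stop("'t' must be a single nonnegative time", call. = FALSE)
    times <- c(0, t)
  } else {
    if (is.unsorted(times) || any(times < 0))
      stop("'times' must be nonnegative and increasing", call. = FALSE)
    if (times[1] > 0) times <- c(0, times)
  }
  y0 <- c(T_MM = 1, T_MI = 0, T_IM = 0, T_DI = 0)
  if (max(times) == 0 || (p$lambda + p$mu) == 0) {
    out_probs <- lapply(times, function(tt) probs_from_state(y0, tt, p))
  } else {
    rhs <- function(tt, state, parms) {
      pr <- probs_from_state(state, tt, p)
      list(count_derivatives(pr, p))
    }
    hini <- min(1e-6 / (p$lambda + p$mu), diff(range(times)) / 10)
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        hini = hini)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed: ", paste(
        utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n"),
        call. = FALSE)
    out_probs <- lapply(seq_len(nrow(sol)), function(i)
      probs_from_state(sol[i, -1], sol[i, 1], p))
  }
  for (i in seq_along(out_probs)) out_probs[[i]]$method <- "h20"
  if (dense) out_probs else out_probs[[length(out_probs)]]
}

#' Exact TKF91 transition probabilities
#'
#' Closed-form solution of the single-residue indel (links) model:
#' `alpha = exp(-mu*t)`,
#' `beta = lambda*(exp(-lambda*t) - exp(-mu*t)) /
#'         (mu*exp(-lambda*t) - lambda*exp(-mu*t))`,
#' `gamma = 1 - mu*beta / (lambda*(1 - alpha))`, and transition rows
#' `(a,b,c) = ((1-beta)*alpha, beta, (1-beta)*(1-alpha))`,
#' `(f,g,h)` identical, `(p,q,r) = ((1-gamma)*alpha, gamma,
#' (1-gamma)*(1-alpha))`.  The degenerate cases `lambda = mu` (where the
#' printed `beta` is 0/0, with analytic limit `lambda*t/(1+lambda*t)`),
#' `lambda = 0`, `mu = 0` and `t = 0` are handled by their analytic limits.
#'
#' @param lambda,mu Insertion and deletion rates (`lambda < mu` not
#'   required).
#' @param t Nonnegative time.
#' @return A [transition_probs()] object.
#' @export
tkf91_probs <- function(lambda, mu, t) {
  if (lambda < 0 || mu < 0 || t < 0)
    stop("'lambda', 'mu' and 't' must be nonnegative", call. = FALSE)
  alpha <- exp(-mu * t)
  if (t == 0 || (lambda == 0 && mu == 0)) {
    beta <- 0; gam <- 0
  } else if (abs(lambda - mu) < 1e-9 * max(lambda, mu)) {
    beta <- lambda * t / (1 + lambda * t)
    gam <- 1 - beta / (1 - alpha)
  } else if (lambda == 0) {
    beta <- 0
    gam <- 0
  } else if (mu == 0) {
    beta <- 1 - exp(-lambda * t)
    # limit of 1 - mu*beta/(lambda*(1-alpha)) as mu -> 0: 1 - beta/(lambda*t)
    gam <- 1 - beta / (lambda * t)
  } else {
    el <- exp(-lambda * t); em <- exp(-mu * t)
    beta <- lambda * (el - em) / (mu * el - lambda * em)
    gam <- 1 - mu * beta / (lambda * (1 - alpha))
  }
  transition_probs(t,
                   a = (1 - beta) * alpha, b = beta,
                   c = (1 - beta) * (1 - alpha),
                   f = (1 - beta) * alpha, g = beta,
                   h = (1 - beta) * (1 - alpha),
                   p = (1 - gam) * alpha, q = gam,
                   r = (1 - gam) * (1 - alpha),
                   S_I = expm1(lambda * t), S_D = expm1(mu * t),
                   method = "tkf91")
}

#' Alignment machine with start and end states for finite sequences
#'
#' Augments the three-state alignment machine with explicit start and end
#' states so it can be applied to finite sequences.  The start state copies
#' the Match state's outgoing weights; the end state is reachable from state
#' `s` with weight `1 - Q[s, I]` -- once the input sequence is exhausted only
#' further insertions or termination are possible -- which keeps the machine
#' exactly normalized as a conditional distribution over descendants.
#' Removing the start and end states recovers the original machine.
#'
#' @param probs A [transition_probs()] object.
#' @return A [state_machine()] with states M, I, D, S (start), E (end); the
#'   interior 3x3 block equals the transition matrix of `probs`.  Attributes
#'   `start` and `end` give the state indices.
#' @export
finite_machine <- function(probs) {
  stopifnot(inherits(probs, "transition_probs"))
  Q3 <- transition_matrix(probs)
  Q <- matrix(0, 5, 5)
  Q[1:3, 1:3] <- Q3
  Q[1:3, 5] <- 1 - Q3[, 2]           # M,I,D -> E
  Q[4, 1:3] <- Q3[1, ]               # S mirrors M
  Q[4, 5] <- 1 - Q3[1, 2]            # S -> E
  m <- state_machine(c("M", "I", "D", "S", "E"),
                     c("M", "I", "D", "N", "N"), Q)
  attr(m, "start") <- 4L
  attr(m, "end") <- 5L
  m
}
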