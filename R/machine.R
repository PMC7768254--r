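#' Weighted pair state machines
#'
#' A pair state machine is a set of states, each of class M (reads input and
#' writes output), I (writes only), D (reads only) or N (neither), together
#' with a square nonnegative transition weight matrix `Q`.  The
#' expected-transition-count calculus ([expected_transition_count()])
#' requires exactly one M state, placed first; machines carrying explicit
#' start/end states (see [finite_machine()]) may relax this via
#' `check_match_first = FALSE`.
#'
#' @param names Character vector of state names.
#' @param classes Character vector, one of `"M"`, `"I"`, `"D"`, `"N"` per
#'   state.
#' @param Q Square nonnegative weight matrix, `K x K`.
#' @param check_match_first If `TRUE` (default), require exactly one M state
#'   in position 1.
#' @return An object of class `"state_machine"`.
#' @export
state_machine <- function(names, classes, Q, check_match_first = TRUE) {
  Q <- as.matrix(Q)
  K <- length(names)
  if (length(classes) != K || nrow(Q) != K || ncol(Q) != K)
    stop("states, classes and Q must have matching dimension", call. = FALSE)
  if (!all(classes %in% c("M", "I", "D", "N")))
    stop("state classes must be M, I, D or N", call. = FALSE)
  if (any(Q < 0))
    stop("transition weights must be nonnegative", call. = FALSE)
  if (check_match_first) {
    if (sum(classes == "M") != 1L || classes[1] != "M")
      stop("machine must have exactly one M state, in first position",
           call. = FALSE)
  }
  dimnames(Q) <- list(names, names)
  structure(list(states = names, classes = classes, Q = Q),
            class = "state_machine")
}

#' @export
print.state_machine <- function(x, ...) {
  cat(sprintf("Pair state machine with %d states\n", length(x$states)))
  tags <- c(M = "reads+writes", I = "writes", D = "reads", N = "silent")
  cat(paste0("  ", format(x$states), "  [", x$classes, ": ",
             tags[x$classes], "]", collapse = "\n"), "\n")
  cat("transition weights:\n")
  print(round(x$Q, 6))
  invisible(x)
}

#' Emission behaviour implied by a state class
#'
#' @param classes Character vector of state classes.
#' @return Character vector: `"read+write"`, `"write"`, `"read"`, `"none"`.
#' @export
emission_tag <- function(classes) {
  c(M = "read+write", I = "write", D = "read", N = "none")[classes]
}

state_indices <- function(m, sel) which(m$classes %in% sel)

#' Select transitions between state classes
#'
#' Returns the weight matrix with every entry zeroed except those from a
#' state in `from` to a state in `to` (the pointwise product of `Q` with the
#' 0/1 class-selector matrix).
#'
#' @param m A [state_machine()].
#' @param from,to Character vectors of state classes (subsets of M, I, D, N).
#' @return `K x K` numeric matrix.
#' @export
select_transitions <- function(m, from, to) {
  stopifnot(inherits(m, "state_machine"))
  out <- matrix(0, nrow(m$Q), ncol(m$Q), dimnames = dimnames(m$Q))
  i <- state_indices(m, from); j <- state_indices(m, to)
  out[i, j] <- m$Q[i, j]
  out
}

geom_inverse <- function(A, what) {
  # sum of the geometric series I + A + A^2 + ... = (I - A)^{-1};
  # requires spectral radius < 1 for the path sum to converge
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr >= 1 - 1e-12)
    stop("machine is non-terminating: geometric series over ", what,
         " does not converge (spectral radius ", format(sr), ")",
         call. = FALSE)
  solve(diag(nrow(A)) - A)
}

#' Expected transition usage between state classes
#'
#' Expectation, over random walks that begin and end in the Match state
#' (visiting only non-Match states in between), of the number of transitions
#' from a class-`from` state to a class-`to` state after null states have
#' been removed from the walk.  Computed as the `(1,1)` entry of
#' `U (J o (V Q)) W` where `U`, `V`, `W` are geometric-series sums over,
#' respectively, transitions into non-Match states, transitions into null
#' states, and transitions out of non-Match states, and `J` selects the
#' `from -> to` class pairs.
#'
#' @param m A [state_machine()] whose first state is the unique M state.
#' @param from,to Character vectors of state classes.
#' @return Nonnegative expected count.
#' @seealso [expected_occupancy()]
#' @export
expected_transition_count <- function(m, from, to) {
  stopifnot(inherits(m, "state_machine"))
  K <- nrow(m$Q)
  Q <- m$Q
  U <- geom_inverse(class_mask(m, c("M", "I", "D", "N"), c("I", "D", "N")),
                    "transitions into non-match states")
  V <- geom_inverse(class_mask(m, c("M", "I", "D", "N"), "N"),
                    "null-state transitions")
  W <- geom_inverse(class_mask(m, c("I", "D", "N"), c("M", "I", "D", "N")),
                    "transitions out of non-match states")
  J <- matrix(0, K, K)
  J[state_indices(m, from), state_indices(m, to)] <- 1
  (U %*% (J * (V %*% Q)) %*% W)[1, 1]
}

class_mask <- function(m, from, to) {
  out <- matrix(0, nrow(m$Q), ncol(m$Q))
  i <- state_indices(m, from); j <- state_indices(m, to)
  out[i, j] <- m$Q[i, j]
  out
}

#' Expected state occupancy of a class
#'
#' Expected number of visits to class-`X` states (excluding the final state)
#' in walks that begin and end in the Match state; equals the sum over the
#' non-null classes `Y` of the expected `X -> Y` transition counts, and also
#' the sum of the `Y -> X` counts (transition counts are defined on the walk
#' with null states removed, so no transition ends in a null state).  The
#' Match occupancy equals the total walk mass, 1 for a stochastic machine.
#'
#' @param m A [state_machine()].
#' @param X Character vector of state classes.
#' @return Nonnegative expected count.
#' @export
expected_occupancy <- function(m, X) {
  sum(vapply(c("M", "I", "D"),
             function(Y) expected_transition_count(m, X, Y), numeric(1)))
}

#' The instantaneous-evolution machine of the GGI model
#'
#' Three-state machine describing one instant `dt` of GGI evolution: from the
#' Match state an insertion opens with weight `lambda*dt` and a deletion with
#' weight `mu*dt`; open indels extend with probability `x` (resp. `y`) or
#' close back to Match.
#'
#' @param p A [ggi_params()] object.
#' @param dt Small nonnegative time step with `dt * (lambda + mu) < 1`.
#' @return A [state_machine()] with states M, I, D.
#' @export
infinitesimal_machine <- function(p, dt) {
  stopifnot(inherits(p, "ggi_params"))
  if (dt < 0) stop("'dt' must be nonnegative", call. = FALSE)
  if (dt * (p$lambda + p$mu) >= 1)
    stop("'dt' too large: dt * (lambda + mu) must be < 1", call. = FALSE)
  Q <- rbind(c(1 - (p$lambda + p$mu) * dt, p$lambda * dt, p$mu * dt),
             c(1 - p$x,                    p$x,           0),
             c(1 - p$y,                    0,             p$y))
  state_machine(c("M", "I", "D"), c("M", "I", "D"), Q)
}

#' Three-state alignment machine from transition probabilities
#'
#' @param probs A [transition_probs()] object (entries `a ... r`).
#' @return A [state_machine()] with states M, I, D and the 3x3 stochastic
#'   matrix of `probs`.
#' @export
three_state_machine <- function(probs) {
  stopifnot(inherits(probs, "transition_probs"))
  state_machine(c("M", "I", "D"), c("M", "I", "D"),
                transition_matrix(probs))
}

#' Composite machine of the alignment machine and the instantaneous machine
#'
#' The product machine obtained by feeding the output of the three-state
#' alignment machine `F` (transition probabilities `a ... r`) into the input
#' of the instantaneous GGI machine over time step `dt`.  Its nine states are
#' labelled by the component states (uppercase where the component machine
#' moves on entry): MM, mI, IM, iI are Match/Insert-class, MD, Dm, Dd, Di are
#' Delete-class, and ID -- which neither reads input nor writes output -- is
#' a null state.  At `dt = 0` its expected transition counts coincide with
#' those of `F`.
#'
#' @param F A three-state [state_machine()] or a [transition_probs()] object.
#' @param p A [ggi_params()] object.
#' @param dt Small time step (may be negative for finite-difference probes;
#'   the weight matrix is then no longer nonnegative and is stored as-is).
#' @return A [state_machine()] with 9 states.
#' @export
compose_fg <- function(F, p, dt) {
  stopifnot(inherits(p, "ggi_params"))
  if (inherits(F, "transition_probs")) F <- three_state_machine(F)
  stopifnot(inherits(F, "state_machine"), nrow(F$Q) == 3)
  a <- F$Q[1, 1]; b <- F$Q[1, 2]; cc <- F$Q[1, 3]
  f <- F$Q[2, 1]; g <- F$Q[2, 2]; h <- F$Q[2, 3]
  pp <- F$Q[3, 1]; q <- F$Q[3, 2]; r <- F$Q[3, 3]
  lam <- p$lambda; mu <- p$mu; x <- p$x; y <- p$y
  z <- 1 - (lam + mu) * dt; ld <- lam * dt; md <- mu * dt
  Q <- rbind(
    #  MM        mI  IM        iI  MD       Dm  Dd  Di  ID
    c(a * z,     ld, b * z,    0,  a * md,  cc, 0,  0,  b * md),  # MM
    c(a * (1-x), x,  b * (1-x), 0, 0,       0,  0,  cc, 0),       # mI
    c(f * z,     0,  g * z,    ld, f * md,  h,  0,  0,  g * md),  # IM
    c(f * (1-x), 0,  g * (1-x), x, 0,       0,  0,  h,  0),       # iI
    c(a * (1-y), 0,  b * (1-y), 0, a * y,   0,  cc, 0,  b * y),   # MD
    c(pp * z,    0,  q * z,    0,  pp * md, r,  0,  0,  q * md),  # Dm
    c(pp * (1-y), 0, q * (1-y), 0, pp * y,  0,  r,  0,  q * y),   # Dd
    c(pp * (1-x), 0, q * (1-x), 0, 0,       0,  0,  r,  0),       # Di
    c(f * (1-y), 0,  g * (1-y), 0, f * y,   0,  h,  0,  g * y))   # ID
  nm <- c("MM", "mI", "IM", "iI", "MD", "Dm", "Dd", "Di", "ID")
  cl <- c("M", "I", "I", "I", "D", "D", "D", "D", "N")
  dimnames(Q) <- list(nm, nm)
  # negative dt probes used by finite-difference checks bypass the
  # nonnegativity validation
  structure(list(states = nm, classes = cl, Q = Q), class = "state_machine")
}

#' Read and write state machines as JSON
#'
#' Schema: object with `states` (array of `{name, class}`) and `weights`
#' (array of rows).  Round-tripping is the identity.
#'
#' @param m A [state_machine()].
#' @param path File path.
#' @return `read_machine()` returns a [state_machine()];
#'   `write_machine()` returns `path` invisibly.
#' @export
write_machine <- function(m, path) {
  stopifnot(inherits(m, "state_machine"))
  obj <- list(states = lapply(seq_along(m$states), function(i)
                list(name = m$states[i], class = m$classes[i])),
              weights = unname(lapply(seq_len(nrow(m$Q)),
                                      function(i) unname(m$Q[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_machine
#' @export
read_machine <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  names_ <- vapply(obj$states, function(s) s$name, character(1))
  classes <- vapply(obj$states, function(s) s$class, character(1))
  Q <- do.call(rbind, lapply(obj$weights, function(r) as.numeric(unlist(r))))
  state_machine(names_, classes, Q,
                check_match_first = identical(classes[1], "M") &&
                  sum(classes == "M") == 1L)
}
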