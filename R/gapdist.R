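#' Joint gap-length distributions
#'
#' A gap is a maximal run of insert/delete columns between two match columns
#' of a pairwise alignment; `S_I` and `S_D` count the inserted and deleted
#' residues it contains (the `(0, 0)` cell is a pair of adjacent match
#' columns).  A `gap_distribution` stores the joint law of `(S_I, S_D)` on
#' the grid `0..G` by `0..G`, either exactly (probabilities, total mass at
#' most 1 with a reported tail bound) or empirically (integer interval
#' counts with an overflow bucket).
#'
#' @param P `(G+1) x (G+1)` matrix; rows index `S_I = 0..G`, columns
#'   `S_D = 0..G`.
#' @param kind `"exact"` or `"empirical"`.
#' @param n_intervals For empirical distributions, the number of observed
#'   inter-match intervals (including overflow).
#' @param overflow For empirical distributions, the number of intervals with
#'   `S_I > G` or `S_D > G`.
#' @param tail For exact distributions, an upper bound on the probability
#'   mass beyond the grid.
#' @return An object of class `"gap_distribution"`.
#' @export
gap_distribution <- function(P, kind = c("exact", "empirical"),
                             n_intervals = NA_integer_, overflow = 0,
                             tail = NA_real_) {
  kind <- match.arg(kind)
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("grid must be square", call. = FALSE)
  if (any(P < 0)) stop("grid entries must be nonnegative", call. = FALSE)
  G <- nrow(P) - 1L
  if (kind == "empirical") {
    if (any(P != round(P)))
      stop("empirical grid must hold integer counts", call. = FALSE)
    if (is.na(n_intervals)) n_intervals <- sum(P) + overflow
    if (sum(P) + overflow != n_intervals)
      stop("counts plus overflow must equal n_intervals", call. = FALSE)
  } else {
    if (sum(P) > 1 + 1e-9)
      stop("exact distribution has total mass > 1", call. = FALSE)
  }
  dimnames(P) <- list(S_I = 0:G, S_D = 0:G)
  structure(list(G = G, P = P, kind = kind,
                 n_intervals = n_intervals, overflow = overflow,
                 tail = tail),
            class = "gap_distribution")
}

#' @export
print.gap_distribution <- function(x, ...) {
  cat(sprintf("%s joint gap-length distribution on 0..%d x 0..%d\n",
              if (x$kind == "exact") "Exact" else "Empirical", x$G, x$G))
  if (x$kind == "empirical")
    cat(sprintf("  %d intervals (%d beyond the grid)\n",
                x$n_intervals, x$overflow))
  else
    cat(sprintf("  grid mass %.6g (tail bound %.3g)\n", sum(x$P),
                x$tail))
  m <- moments(x)
  cat(sprintf("  E[S_I] = %.4g, E[S_D] = %.4g, P(0,0) = %.4g, cov = %.4g\n",
              m$mean_SI, m$mean_SD, m$p00, m$cov))
  invisible(x)
}

#' Exact gap-length distribution of the three-state alignment machine
#'
#' Dynamic program over walks that begin and end in the Match state: with
#' transition probabilities `a ... r`, the open-gap weights satisfy
#' `w_I(1,0) = b`, `w_D(0,1) = c`,
#' `w_I(i,j) = g*w_I(i-1,j) + q*w_D(i-1,j)` and
#' `w_D(i,j) = h*w_I(i,j-1) + r*w_D(i,j-1)`, and the cell probabilities are
#' `P(0,0) = a` and `P(i,j) = f*w_I(i,j) + p*w_D(i,j)` otherwise.
#'
#' @param probs A [transition_probs()] object.
#' @param G Maximum gap length per axis, `G >= 1`.
#' @return An exact [gap_distribution()] with its [tail_bound()] attached.
#' @export
hmm_gap_distribution <- function(probs, G) {
  stopifnot(inherits(probs, "transition_probs"))
  if (G < 1) stop("'G' must be at least 1", call. = FALSE)
  G <- as.integer(G)
  wI <- matrix(0, G + 1, G + 1)  # [i+1, j+1]: paths ending in I with (i, j)
  wD <- matrix(0, G + 1, G + 1)
  wI[2, 1] <- probs$b
  wD[1, 2] <- probs$c
  for (i in 0:G) {
    for (j in 0:G) {
      if (i + j < 2) next
      if (i >= 1)
        wI[i + 1, j + 1] <- probs$g * wI[i, j + 1] + probs$q * wD[i, j + 1]
      if (j >= 1)
        wD[i + 1, j + 1] <- probs$h * wI[i + 1, j] + probs$r * wD[i + 1, j]
    }
  }
  P <- probs$f * wI + probs$p * wD
  P[1, 1] <- probs$a
  gap_distribution(P, "exact", tail = tail_bound(probs, G))
}

#' Upper bound on gap probability mass beyond the grid
#'
#' Every cell outside the `G x G` grid corresponds to walks with more than
#' `G` insert/delete steps.  With extension matrix
#' `A = rbind(c(g, q), c(h, r))` acting on the open-gap weight vector, the
#' total mass of walks with more than `G` such steps is
#' `(f, p) %*% A^G %*% solve(I - A) %*% c(b, c)`, which therefore bounds the
#' off-grid mass.  The bound decreases monotonically in `G`.
#'
#' @param probs A [transition_probs()] object.
#' @param G Grid size.
#' @return Nonnegative scalar bound.
#' @export
tail_bound <- function(probs, G) {
  stopifnot(inherits(probs, "transition_probs"))
  A <- rbind(c(probs$g, probs$q), c(probs$h, probs$r))
  w1 <- c(probs$b, probs$c)
  close_w <- c(probs$f, probs$p)
  AG <- diag(2)
  Apow <- A
  n <- as.integer(G)
  while (n > 0) {                      # A^G by binary exponentiation
    if (n %% 2L == 1L) AG <- AG %*% Apow
    Apow <- Apow %*% Apow
    n <- n %/% 2L
  }
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr >= 1) return(Inf)
  as.numeric(close_w %*% AG %*% solve(diag(2) - A) %*% w1)
}

#' Moments of a gap-length distribution
#'
#' Mean inserted and deleted residues per interval, the empty-gap
#' probability `P(S_I = S_D = 0)`, and the covariance of `(S_I, S_D)`,
#' computed on the (truncated) grid after normalization; for exact
#' distributions the unaccounted tail mass is reported alongside.
#'
#' @param d A [gap_distribution()].
#' @return An object of class `"gap_moments"`: list with `mean_SI`,
#'   `mean_SD`, `p00`, `cov`, `tail_mass`.
#' @export
moments <- function(d) {
  stopifnot(inherits(d, "gap_distribution"))
  tot <- sum(d$P)
  if (tot == 0)
    stop("distribution has no observations on the grid", call. = FALSE)
  P <- d$P / tot
  i <- 0:d$G
  mi <- rowSums(P); mj <- colSums(P)
  mean_SI <- sum(i * mi); mean_SD <- sum(i * mj)
  eIJ <- sum(outer(i, i) * P)
  structure(list(mean_SI = mean_SI, mean_SD = mean_SD,
                 p00 = P[1, 1], cov = eIJ - mean_SI * mean_SD,
                 tail_mass = if (d$kind == "exact") 1 - tot
                             else d$overflow / d$n_intervals),
            class = "gap_moments")
}

#' @export
print.gap_moments <- function(x, ...) {
  cat(sprintf(
    "gap moments: E[S_I] = %.6g, E[S_D] = %.6g, P(0,0) = %.6g, cov = %.6g\n",
    x$mean_SI, x$mean_SD, x$p00, x$cov))
  invisible(x)
}

#' Relative entropy between two gap-length distributions
#'
#' Kullback-Leibler divergence `sum P_ref * log(P_ref / P_model)` over the
#' common grid, after renormalizing both distributions over it (i.e.
#' conditioning on `S_I <= G, S_D <= G`).  Cells where `P_ref = 0`
#' contribute 0; a supported cell where `P_model = 0` yields `Inf` (no
#' pseudocounts are applied).  `truncate_to` conditions both distributions
#' on the smaller grid `S_I <= G', S_D <= G'` first, as used when comparing
#' against methods that only cover short gaps.
#'
#' @param P_ref Reference [gap_distribution()] (empirical or exact).
#' @param P_model Model [gap_distribution()].
#' @param truncate_to Optional grid size `G'` for the truncated conditional
#'   comparison.
#' @return Nonnegative number (possibly `Inf`), in nats.
#' @export
kl_divergence <- function(P_ref, P_model, truncate_to = NULL) {
  stopifnot(inherits(P_ref, "gap_distribution"),
            inherits(P_model, "gap_distribution"))
  G <- min(P_ref$G, P_model$G)
  if (!is.null(truncate_to)) {
    if (truncate_to > G)
      stop("'truncate_to' exceeds the available grid", call. = FALSE)
    G <- as.integer(truncate_to)
  }
  idx <- seq_len(G + 1)
  A <- P_ref$P[idx, idx]; B <- P_model$P[idx, idx]
  if (sum(A) == 0) stop("reference distribution is empty", call. = FALSE)
  A <- A / sum(A)
  if (sum(B) == 0) stop("model distribution is empty on the grid",
                        call. = FALSE)
  B <- B / sum(B)
  s <- A > 0
  if (any(B[s] == 0)) return(Inf)
  sum(A[s] * log(A[s] / B[s]))
}

#' Read and write gap-length grids as TSV
#'
#' Three-column tab-separated format `S_I`, `S_D`, `value` covering the full
#' grid (zeros included).
#'
#' @param d A [gap_distribution()].
#' @param path File path.
#' @param kind Interpretation of the values when reading.
#' @param n_intervals,overflow Metadata when reading empirical counts; by
#'   default inferred from the counts themselves (zero overflow).
#' @return `read_gap_distribution()` returns a [gap_distribution()];
#'   `write_gap_distribution()` returns `path` invisibly.
#' @export
write_gap_distribution <- function(d, path) {
  stopifnot(inherits(d, "gap_distribution"))
  G <- d$G
  df <- data.frame(S_I = rep(0:G, times = G + 1),
                   S_D = rep(0:G, each = G + 1),
                   value = as.vector(d$P))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gap_distribution
#' @export
read_gap_distribution <- function(path, kind = c("empirical", "exact"),
                                  n_intervals = NA_integer_, overflow = 0) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  G <- max(df$S_I, df$S_D)
  P <- matrix(0, G + 1, G + 1)
  P[cbind(df$S_I + 1, df$S_D + 1)] <- df$value
  gap_distribution(P, kind, n_intervals = n_intervals, overflow = overflow)
}
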