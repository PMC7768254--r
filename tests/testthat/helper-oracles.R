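# Independent oracles used across the test files.

# Naive expanded-column simulator of the indel process.  Follows the same
# uniform-draw protocol as the package's Fenwick-tree implementation
# (u1 wait, u2 type, u3 site, u4 length, all runif) so that with an
# identical RNG state the two produce identical alignments.
naive_evolve <- function(p, L, t) {
  cols <- rep(0L, L)  # 0 = M, 1 = I, 2 = D; descendant residues are cols != 2
  now <- 0
  repeat {
    len <- sum(cols != 2L)
    rate <- (len + 1) * p$lambda + len * p$mu
    if (rate <= 0) break
    now <- now - log(runif(1)) / rate
    if (now > t) break
    u2 <- runif(1)
    is_ins <- u2 * rate < (len + 1) * p$lambda
    u3 <- runif(1)
    u4 <- runif(1)
    glen <- function(ext) if (ext > 0) 1 + floor(log(u4) / log(ext)) else 1
    desc_idx <- which(cols != 2L)
    if (is_ins) {
      k <- min(floor(u3 * (len + 1)), len)
      n <- glen(p$x)
      at <- if (k == 0) 0 else desc_idx[k]   # insert after this column
      cols <- append(cols, rep(1L, n), after = at)
    } else {
      k <- 1 + min(floor(u3 * len), len - 1)
      m <- glen(p$y)
      kill <- desc_idx[seq(k, min(k + m - 1, len))]
      conv <- kill[cols[kill] == 0L]
      cols[conv] <- 2L
      drop <- kill[cols[kill] == 1L]
      if (length(drop)) cols <- cols[-drop]
    }
  }
  cols
}

# Truncated explicit-series evaluation of the expected transition usage:
# sums path probabilities over walks of bounded length instead of solving
# the geometric-series linear systems.
path_sum_count <- function(m, from, to, max_steps = 25) {
  K <- nrow(m$Q)
  idx <- function(sel) which(m$classes %in% sel)
  maskQ <- function(rows, cols) {
    out <- matrix(0, K, K)
    out[rows, cols] <- m$Q[rows, cols]
    out
  }
  MIDN <- idx(c("M", "I", "D", "N")); IDN <- idx(c("I", "D", "N"))
  Nst <- idx("N")
  A <- maskQ(MIDN, IDN)   # steps before the counted transition
  B <- maskQ(MIDN, Nst)   # null-state hops inside it
  C <- maskQ(IDN, MIDN)   # steps after it
  J <- matrix(0, K, K); J[idx(from), idx(to)] <- 1
  series <- function(X) {
    S <- diag(K); P <- diag(K)
    for (k in seq_len(max_steps)) { P <- P %*% X; S <- S + P }
    S
  }
  (series(A) %*% (J * (series(B) %*% m$Q)) %*% series(C))[1, 1]
}

# Brute-force gap-cell probabilities: enumerate every walk
# M -> {I,D}^k -> M with k <= max_interior and accumulate weights per
# (insertions, deletions) cell.
enum_gap_grid <- function(probs, G, max_interior = 10) {
  Q <- transition_matrix(probs)
  P <- matrix(0, G + 1, G + 1)
  P[1, 1] <- Q[1, 1]
  recurse <- function(state, ni, nd, w, depth) {
    # state: 2 = I, 3 = D; try closing or extending
    wclose <- w * Q[state, 1]
    if (ni <= G && nd <= G) P[ni + 1, nd + 1] <<- P[ni + 1, nd + 1] + wclose
    if (depth >= max_interior) return()
    recurse(2, ni + 1, nd, w * Q[state, 2], depth + 1)
    recurse(3, ni, nd + 1, w * Q[state, 3], depth + 1)
  }
  recurse(2, 1, 0, Q[1, 2], 1)
  recurse(3, 0, 1, Q[1, 3], 1)
  P
}

# Exhaustive alignment enumeration for the forward likelihood: sums
# transition x emission weights over every M/I/D column string compatible
# with the sequence lengths, using the finite machine's weights directly.
enum_forward <- function(machine, subst, t, anc, des) {
  Q <- machine$Q
  M <- substitution_probs(subst, t)
  rho <- subst$rho
  ai <- match(anc, subst$alphabet); di <- match(des, subst$alphabet)
  n <- length(anc); m <- length(des)
  total <- 0
  recurse <- function(i, j, state, w) {
    # state indices in the machine: 1 M, 2 I, 3 D, 4 S(start)
    if (i == n && j == m) total <<- total + w * Q[state, 5]
    if (i < n && j < m)
      recurse(i + 1, j + 1, 1, w * Q[state, 1] * M[ai[i + 1], di[j + 1]])
    if (j < m)
      recurse(i, j + 1, 2, w * Q[state, 2] * rho[di[j + 1]])
    if (i < n)
      recurse(i + 1, j, 3, w * Q[state, 3])
  }
  recurse(0, 0, 4, 1)
  unname(total)
}

# All sequences over an alphabet up to a maximum length (including the
# empty sequence), as character vectors.
all_seqs <- function(alphabet, max_len) {
  out <- list(character(0))
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, lapply(seq_len(nrow(grid)),
                         function(i) as.character(unlist(grid[i, ]))))
  }
  out
}

# Random valid transition-probability objects for property tests.
random_probs <- function(t = 0.5) {
  rdir <- function(alpha) { g <- rgamma(3, alpha); g / sum(g) }
  rm_ <- rdir(c(4, 1, 1)); ri <- rdir(c(2, 2, 1)); rd <- rdir(c(2, 1, 2))
  transition_probs(t, a = rm_[1], b = rm_[2], c = rm_[3],
                   f = ri[1], g = ri[2], h = ri[3],
                   p = rd[1], q = rd[2], r = rd[3])
}

# Random small machines (with a null state) whose path sums converge fast,
# for the path-sum property test.
random_small_machine <- function() {
  K <- 4
  Q <- matrix(runif(K * K), K, K)
  Q <- Q / rowSums(Q) * 0.55   # substochastic: geometric tail < 0.55^k
  state_machine(c("M", "I", "D", "N"), c("M", "I", "D", "N"), Q)
}
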