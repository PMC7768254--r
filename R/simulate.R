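#' Run-length-encoded pairwise alignment
#'
#' Stores an M/I/D column sequence as maximal runs `(type, length)`.  The
#' M and D run lengths sum to the ancestral sequence length; the M and I
#' run lengths sum to the descendant length.
#'
#' @param types Character vector of run types (`"M"`, `"I"`, `"D"`),
#'   adjacent entries distinct.
#' @param lengths Positive integer run lengths.
#' @return An object of class `"alignment_rle"`.
#' @export
alignment_rle <- function(types, lengths) {
  if (length(types) != length(lengths))
    stop("types and lengths must match", call. = FALSE)
  if (!all(types %in% c("M", "I", "D")))
    stop("column types must be M, I or D", call. = FALSE)
  if (any(lengths < 1) || any(lengths != round(lengths)))
    stop("run lengths must be positive integers", call. = FALSE)
  if (length(types) > 1 && any(types[-1] == types[-length(types)]))
    stop("adjacent runs must have distinct types (maximal runs)",
         call. = FALSE)
  structure(list(types = types, lengths = as.integer(lengths)),
            class = "alignment_rle")
}

columns_to_rle <- function(cols) {
  # cols: integer vector, 0 = M, 1 = I, 2 = D
  if (length(cols) == 0)
    return(structure(list(types = character(0), lengths = integer(0)),
                     class = "alignment_rle"))
  r <- rle(cols)
  alignment_rle(c("M", "I", "D")[r$values + 1L], r$lengths)
}

#' @export
print.alignment_rle <- function(x, ...) {
  anc <- sum(x$lengths[x$types %in% c("M", "D")])
  des <- sum(x$lengths[x$types %in% c("M", "I")])
  cat(sprintf("alignment: ancestor %d, descendant %d residues, %d runs\n",
              anc, des, length(x$types)))
  cat(paste0(x$types, x$lengths, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.character.alignment_rle <- function(x, ...) {
  paste(rep(x$types, x$lengths), collapse = "")
}

#' Simulate one alignment under the GGI indel process
#'
#' Exact Gillespie simulation: events arrive with total rate
#' `(len+1)*lambda + len*mu` where `len` is the current descendant length;
#' insertions add a Geometric(`x`) number of residues immediately right of a
#' uniformly chosen descendant residue (or at the left edge); deletions
#' remove a Geometric(`y`) run starting at a uniformly chosen residue,
#' truncated at the sequence end (so the per-residue deletion rate is
#' exactly `mu`).  Later events can overlap earlier ones: inserted residues
#' are themselves deletable, and an insertion deleted in full leaves no
#' alignment column.  Uses R's RNG stream.
#'
#' @param p A [ggi_params()] object.
#' @param L Ancestral sequence length.
#' @param t Total evolutionary time.
#' @return An [alignment_rle()].  An extinct sequence gives the all-D
#'   alignment.
#' @export
evolve <- function(p, L, t) {
  stopifnot(inherits(p, "ggi_params"))
  if (L < 1 || L != round(L)) stop("'L' must be a positive integer",
                                   call. = FALSE)
  if (t < 0) stop("'t' must be nonnegative", call. = FALSE)
  columns_to_rle(cpp_evolve(p$lambda, p$mu, p$x, p$y, as.integer(L), t))
}

#' Gap observations of an alignment
#'
#' One `(S_I, S_D)` observation per interval between consecutive match
#' columns, including `(0, 0)` for adjacent matches.  Intervals before the
#' first and after the last match column are discarded (end gaps have
#' different statistics); intervals with `S_I > G` or `S_D > G` go to an
#' overflow bucket.
#'
#' @param a An [alignment_rle()] or an integer column vector
#'   (0 = M, 1 = I, 2 = D).
#' @param G Maximum recorded gap size per axis.
#' @return An empirical [gap_distribution()]; an alignment with fewer than
#'   two match columns yields zero observations.
#' @export
extract_gaps <- function(a, G) {
  if (inherits(a, "alignment_rle")) {
    cols <- rep(match(a$types, c("M", "I", "D")) - 1L, a$lengths)
  } else cols <- as.integer(a)
  if (G < 1) stop("'G' must be at least 1", call. = FALSE)
  counts <- gap_count_grid(cols, as.integer(G))
  gap_distribution(counts$P, "empirical",
                   n_intervals = counts$n, overflow = counts$overflow)
}

gap_count_grid <- function(cols, G) {
  mpos <- which(cols == 0L)
  if (length(mpos) < 2)
    return(list(P = matrix(0L, G + 1, G + 1), n = 0L, overflow = 0L))
  cumI <- cumsum(cols == 1L)
  cumD <- cumsum(cols == 2L)
  si <- diff(cumI[mpos])
  sd_ <- diff(cumD[mpos])
  over <- si > G | sd_ > G
  P <- matrix(0L, G + 1, G + 1)
  if (any(!over)) {
    tab <- table(factor(si[!over], levels = 0:G),
                 factor(sd_[!over], levels = 0:G))
    P <- matrix(as.integer(tab), G + 1, G + 1)
  }
  list(P = P, n = length(si), overflow = sum(over))
}

#' Simulation configuration
#'
#' @param N Number of replicate simulations.
#' @param L Ancestral sequence length (at least 2).
#' @param G Maximum recorded gap size.
#' @param t Total evolutionary time.
#' @param seed Base RNG seed; replicate `i` runs on stream
#'   `(seed + i) mod (2^31 - 1)` so replicates are independently
#'   reproducible.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(N, L, G, t, seed = 1L) {
  if (N < 1 || L < 2 || G < 1 || t < 0)
    stop("need N >= 1, L >= 2, G >= 1, t >= 0", call. = FALSE)
  structure(list(N = as.integer(N), L = as.integer(L), G = as.integer(G),
                 t = t, seed = as.integer(seed)),
            class = "sim_config")
}

#' Empirical gap-length distribution by simulation
#'
#' Runs `cfg$N` replicate simulations of the indel process and pools the
#' gap observations of all inter-match intervals (each interval contributes
#' one observation) into an empirical [gap_distribution()].
#'
#' @param p A [ggi_params()] object.
#' @param cfg A [sim_config()].
#' @return Empirical [gap_distribution()] with `n_intervals` and overflow
#'   recorded.
#' @export
simulate_distribution <- function(p, cfg) {
  stopifnot(inherits(p, "ggi_params"), inherits(cfg, "sim_config"))
  P <- matrix(0L, cfg$G + 1, cfg$G + 1)
  n <- 0L; overflow <- 0L
  for (i in seq_len(cfg$N)) {
    set.seed((cfg$seed + i) %% (2^31 - 1))
    cols <- cpp_evolve(p$lambda, p$mu, p$x, p$y, cfg$L, cfg$t)
    g <- gap_count_grid(cols, cfg$G)
    P <- P + g$P
    n <- n + g$n
    overflow <- overflow + g$overflow
  }
  gap_distribution(P, "empirical", n_intervals = n, overflow = overflow)
}
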