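seq_to_vec <- function(s, alphabet, what) {
  v <- if (length(s) == 1L && is.character(s)) strsplit(s, "")[[1]] else
    as.character(s)
  bad <- which(!(v %in% alphabet))
  if (length(bad))
    stop(sprintf("%s contains symbol '%s' outside the model alphabet at position %d",
                 what, v[bad[1]], bad[1]), call. = FALSE)
  v
}

finite_weights <- function(machine) {
  if (inherits(machine, "transition_probs")) machine <- finite_machine(machine)
  stopifnot(inherits(machine, "state_machine"))
  if (is.null(attr(machine, "start")))
    stop("machine must carry start/end states; see finite_machine()",
         call. = FALSE)
  machine$Q
}

#' Forward log-likelihood of a descendant given an ancestor
#'
#' Sums the probability of the descendant over all alignments (state paths)
#' of the finite-sequence alignment machine, conditional on the ancestor:
#' Match states emit the descendant residue with probability
#' `expm(R*t)[anc, des]`, Insert states with the stationary probability
#' `rho[des]`, Delete states emit nothing.  Row-wise rescaling keeps the
#' recursion stable for long sequences.
#'
#' @param machine A [finite_machine()] (or a [transition_probs()] object,
#'   which is augmented automatically).
#' @param subst A [subst_model()].
#' @param t Divergence time (for the emission matrix).
#' @param ancestor,descendant Sequences: single strings or character
#'   vectors over the model alphabet.
#' @return Log of the summed path probability.
#' @export
forward_likelihood <- function(machine, subst, t, ancestor, descendant) {
  stopifnot(inherits(subst, "subst_model"))
  Q <- finite_weights(machine)
  anc <- seq_to_vec(ancestor, subst$alphabet, "ancestor")
  des <- seq_to_vec(descendant, subst$alphabet, "descendant")
  M <- substitution_probs(subst, t)
  rho <- subst$rho
  n <- length(anc); m <- length(des)
  ai <- match(anc, subst$alphabet); di <- match(des, subst$alphabet)
  aM <- matrix(0, n + 1, m + 1); aI <- aM; aD <- aM
  logscale <- 0
  for (i in 0:n) {
    for (j in 0:m) {
      if (i >= 1 && j >= 1) {
        pre <- Q[1, 1] * aM[i, j] + Q[2, 1] * aI[i, j] + Q[3, 1] * aD[i, j]
        if (i == 1 && j == 1) pre <- pre + Q[4, 1]
        aM[i + 1, j + 1] <- M[ai[i], di[j]] * pre
      }
      if (j >= 1) {
        pre <- Q[1, 2] * aM[i + 1, j] + Q[2, 2] * aI[i + 1, j] +
          Q[3, 2] * aD[i + 1, j]
        if (i == 0 && j == 1) pre <- pre + Q[4, 2]
        aI[i + 1, j + 1] <- rho[di[j]] * pre
      }
      if (i >= 1) {
        pre <- Q[1, 3] * aM[i, j + 1] + Q[2, 3] * aI[i, j + 1] +
          Q[3, 3] * aD[i, j + 1]
        if (i == 1 && j == 0) pre <- pre + Q[4, 3]
        aD[i + 1, j + 1] <- pre
      }
    }
    s <- max(aM[i + 1, ], aI[i + 1, ], aD[i + 1, ])
    if (s > 0 && (s < 1e-100 || s > 1e100)) {
      aM[i + 1, ] <- aM[i + 1, ] / s
      aI[i + 1, ] <- aI[i + 1, ] / s
      aD[i + 1, ] <- aD[i + 1, ] / s
      logscale <- logscale + log(s)
    }
  }
  total <- Q[1, 5] * aM[n + 1, m + 1] + Q[2, 5] * aI[n + 1, m + 1] +
    Q[3, 5] * aD[n + 1, m + 1]
  if (n == 0 && m == 0) total <- total + Q[4, 5]
  log(total) + logscale
}

#' Best-path (Viterbi) pairwise alignment
#'
#' Max-product counterpart of [forward_likelihood()]: finds the single
#' highest-probability alignment.  Ties are broken deterministically,
#' preferring Match over Delete over Insert.
#'
#' @inheritParams forward_likelihood
#' @return An object of class `"alignment_result"`: list with
#'   `log_likelihood` (forward), `best_path_logprob`, `best_path` (M/I/D
#'   string), `ancestor_aligned` and `descendant_aligned` (gapped strings,
#'   gap character `-`).
#' @export
viterbi_align <- function(machine, subst, t, ancestor, descendant) {
  stopifnot(inherits(subst, "subst_model"))
  Q <- finite_weights(machine)
  anc <- seq_to_vec(ancestor, subst$alphabet, "ancestor")
  des <- seq_to_vec(descendant, subst$alphabet, "descendant")
  M <- substitution_probs(subst, t)
  rho <- subst$rho
  n <- length(anc); m <- length(des)
  ai <- match(anc, subst$alphabet); di <- match(des, subst$alphabet)
  NEG <- -Inf
  vM <- matrix(NEG, n + 1, m + 1); vI <- vM; vD <- vM
  ptr <- array(0L, c(n + 1, m + 1, 3))  # predecessor state: 1 M, 2 I, 3 D, 4 S
  lQ <- log(Q); lQ[Q == 0] <- NEG
  # tie-break order when scores are equal: M (1) over D (3) over I (2)
  pick <- function(scores) {
    ord <- c(1L, 3L, 2L, 4L)
    best <- ord[which.max(scores[ord])]
    best
  }
  for (i in 0:n) {
    for (j in 0:m) {
      if (i >= 1 && j >= 1) {
        sc <- c(lQ[1, 1] + vM[i, j], lQ[2, 1] + vI[i, j],
                lQ[3, 1] + vD[i, j],
                if (i == 1 && j == 1) lQ[4, 1] else NEG)
        k <- pick(sc)
        vM[i + 1, j + 1] <- log(M[ai[i], di[j]]) + sc[k]
        ptr[i + 1, j + 1, 1] <- k
      }
      if (j >= 1) {
        sc <- c(lQ[1, 2] + vM[i + 1, j], lQ[2, 2] + vI[i + 1, j],
                lQ[3, 2] + vD[i + 1, j],
                if (i == 0 && j == 1) lQ[4, 2] else NEG)
        k <- pick(sc)
        vI[i + 1, j + 1] <- log(rho[di[j]]) + sc[k]
        ptr[i + 1, j + 1, 2] <- k
      }
      if (i >= 1) {
        sc <- c(lQ[1, 3] + vM[i, j + 1], lQ[2, 3] + vI[i, j + 1],
                lQ[3, 3] + vD[i, j + 1],
                if (i == 1 && j == 0) lQ[4, 3] else NEG)
        k <- pick(sc)
        vD[i + 1, j + 1] <- sc[k]
        ptr[i + 1, j + 1, 3] <- k
      }
    }
  }
  end_sc <- c(lQ[1, 5] + vM[n + 1, m + 1], lQ[2, 5] + vI[n + 1, m + 1],
              lQ[3, 5] + vD[n + 1, m + 1],
              if (n == 0 && m == 0) lQ[4, 5] else NEG)
  last <- pick(end_sc)
  best_lp <- end_sc[last]
  # traceback
  path <- character(0)
  i <- n; j <- m; st <- last
  while (st != 4L) {
    path <- c(c("M", "I", "D")[st], path)
    prev <- ptr[i + 1, j + 1, st]
    if (st == 1L) { i <- i - 1; j <- j - 1 }
    else if (st == 2L) { j <- j - 1 }
    else { i <- i - 1 }
    st <- if (i == 0 && j == 0 && prev == 4L) 4L else prev
    if (length(path) > n + m + 1) stop("traceback failed")  # safety
  }
  gapped <- render_alignment(path, anc, des)
  structure(list(log_likelihood = forward_likelihood(machine, subst, t,
                                                     anc, des),
                 best_path_logprob = best_lp,
                 best_path = paste(path, collapse = ""),
                 ancestor_aligned = gapped$anc,
                 descendant_aligned = gapped$des),
            class = "alignment_result")
}

render_alignment <- function(path, anc, des) {
  i <- 0; j <- 0
  ga <- gd <- character(length(path))
  for (k in seq_along(path)) {
    if (path[k] == "M") { i <- i + 1; j <- j + 1
      ga[k] <- anc[i]; gd[k] <- des[j] }
    else if (path[k] == "I") { j <- j + 1; ga[k] <- "-"; gd[k] <- des[j] }
    else { i <- i + 1; ga[k] <- anc[i]; gd[k] <- "-" }
  }
  list(anc = paste(ga, collapse = ""), des = paste(gd, collapse = ""))
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("pairwise alignment (forward log-likelihood %.6f)\n",
              x$log_likelihood))
  cat(sprintf("best path (log prob %.6f): %s\n",
              x$best_path_logprob, x$best_path))
  cat(x$ancestor_aligned, "\n")
  cat(x$descendant_aligned, "\n")
  invisible(x)
}

#' Read two sequences from a FASTA file
#'
#' @param path FASTA file with at least two records; the first is taken as
#'   the ancestor, the second as the descendant.
#' @return Named list with character vectors `ancestor`, `descendant` and
#'   their names.
#' @export
read_fasta_pair <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2)
    stop("FASTA file must contain two sequences", call. = FALSE)
  list(ancestor = strsplit(as.character(ss[[1]]), "")[[1]],
       descendant = strsplit(as.character(ss[[2]]), "")[[1]],
       names = names(ss)[1:2])
}

#' Write a gapped sequence pair as FASTA
#'
#' @param result An `alignment_result` from [viterbi_align()].
#' @param names Record names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_pair <- function(result, names, path) {
  ss <- Biostrings::BStringSet(c(result$ancestor_aligned,
                                 result$descendant_aligned))
  names(ss) <- names
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
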