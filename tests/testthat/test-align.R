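two_letter_model <- function() {
  R <- rbind(c(-1, 1), c(1, -1))
  dimnames(R) <- list(c("A", "B"), c("A", "B"))
  subst_model(R)
}

test_that("forward likelihood equals exhaustive alignment enumeration", {
  s <- two_letter_model()
  pr <- solve_transition_probs(ggi_params(0.9, 0.7, 0.35, 0.25), 0.6)
  fm <- finite_machine(pr)
  seqs <- all_seqs(c("A", "B"), 3)
  for (anc in seqs) {
    for (des in seqs) {
      exact <- enum_forward(fm, s, 0.6, anc, des)
      got <- forward_likelihood(fm, s, 0.6, anc, des)
      expect_equal(exp(got), exact, tolerance = 1e-12)
    }
  }
})

test_that("forward probabilities sum to one over all descendants", {
  s <- two_letter_model()
  pr <- solve_transition_probs(ggi_params(0.8, 0.8, 0.3, 0.3), 0.4)
  fm <- finite_machine(pr)
  anc <- c("A", "B")
  seqs <- all_seqs(c("A", "B"), 9)
  total <- sum(vapply(seqs, function(des)
    exp(forward_likelihood(fm, s, 0.4, anc, des)), numeric(1)))
  expect_lte(total, 1 + 1e-10)
  expect_gt(total, 0.99)  # mass beyond length 9 is tiny at these settings
})

test_that("identity limit: likelihood of an unchanged residue tends to one", {
  s <- two_letter_model()
  ll <- vapply(c(0.1, 0.01, 0.001), function(t) {
    pr <- solve_transition_probs(ggi_params(1, 1, 0.4, 0.4), t)
    forward_likelihood(finite_machine(pr), s, t, "A", "A")
  }, numeric(1))
  expect_true(all(diff(ll) > 0))
  expect_gt(ll[3], log(0.99))
})

test_that("out-of-alphabet symbols are reported with their position", {
  s <- two_letter_model()
  pr <- solve_transition_probs(ggi_params(1, 1, 0.3, 0.3), 0.5)
  expect_error(forward_likelihood(finite_machine(pr), s, 0.5, "ABXA", "AB"),
               "position 3")
})

test_that("viterbi alignment recovers obvious homologies", {
  s <- two_letter_model()
  t <- 0.05
  pr <- solve_transition_probs(ggi_params(0.5, 0.5, 0.4, 0.4), t)
  fm <- finite_machine(pr)
  # identical sequences at small t: all-match path
  res <- viterbi_align(fm, s, t, "ABAB", "ABAB")
  expect_equal(res$best_path, "MMMM")
  expect_equal(res$ancestor_aligned, "ABAB")
  expect_lte(res$best_path_logprob, res$log_likelihood)
  # internal block deleted: one contiguous deletion gap
  res2 <- viterbi_align(fm, s, t, c("A", "B", "B", "A", "A", "B"),
                        c("A", "B", "A", "B"))
  expect_equal(res2$best_path, "MMDDMM")
  expect_equal(res2$descendant_aligned, "AB--AB")
})

test_that("viterbi best path weight matches exhaustive path maximization", {
  s <- two_letter_model()
  pr <- solve_transition_probs(ggi_params(1, 0.8, 0.3, 0.4), 0.5)
  fm <- finite_machine(pr)
  Q <- fm$Q; M <- substitution_probs(s, 0.5); rho <- s$rho
  best_path_enum <- function(anc, des) {
    ai <- match(anc, s$alphabet); di <- match(des, s$alphabet)
    best <- -Inf
    recurse <- function(i, j, st, w) {
      if (i == length(anc) && j == length(des))
        best <<- max(best, w * Q[st, 5])
      if (i < length(anc) && j < length(des))
        recurse(i + 1, j + 1, 1, w * Q[st, 1] * M[ai[i + 1], di[j + 1]])
      if (j < length(des)) recurse(i, j + 1, 2, w * Q[st, 2] * rho[di[j + 1]])
      if (i < length(anc)) recurse(i + 1, j, 3, w * Q[st, 3])
    }
    recurse(0, 0, 4, 1)
    log(best)
  }
  set.seed(8)
  for (rep in 1:10) {
    anc <- sample(c("A", "B"), sample(1:5, 1), replace = TRUE)
    des <- sample(c("A", "B"), sample(1:5, 1), replace = TRUE)
    res <- viterbi_align(fm, s, 0.5, anc, des)
    expect_equal(res$best_path_logprob, best_path_enum(anc, des),
                 tolerance = 1e-10)
  }
})

test_that("fasta pairs round-trip through files", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">anc", "ACGT", ">des", "ACT"), path)
  pair <- read_fasta_pair(path)
  expect_equal(pair$ancestor, c("A", "C", "G", "T"))
  expect_equal(pair$descendant, c("A", "C", "T"))
  s <- jc_model()
  pr <- solve_transition_probs(ggi_params(0.5, 0.5, 0.2, 0.2), 0.2)
  res <- viterbi_align(finite_machine(pr), s, 0.2, pair$ancestor,
                       pair$descendant)
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta_pair(res, pair$names, out)
  back <- Biostrings::readBStringSet(out)
  expect_equal(nchar(as.character(back[[1]])), nchar(as.character(back[[2]])))
  expect_equal(gsub("-", "", as.character(back[[1]])), "ACGT")
})
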