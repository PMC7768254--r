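test_that("class selectors zero out the right transitions", {
  pr <- transition_probs(0.5, a = 0.6, b = 0.3, c = 0.1,
                         f = 0.5, g = 0.4, h = 0.1,
                         p = 0.3, q = 0.2, r = 0.5)
  m <- three_state_machine(pr)
  sel <- select_transitions(m, c("M", "I", "D"), c("I", "D"))
  expect_equal(unname(sel[, 1]), c(0, 0, 0))     # first column zeroed
  expect_equal(unname(sel[, 2:3]), unname(m$Q[, 2:3]))
  expect_equal(select_transitions(m, c("M", "I", "D", "N"),
                                  c("M", "I", "D", "N")), m$Q)
  expect_equal(unname(select_transitions(m, "M", "N")),
               matrix(0, 3, 3))                  # no null states
})

test_that("infinitesimal machine matches the instantaneous GGI generator", {
  p <- ggi_params(1, 1, 0.5, 0.5)
  g <- infinitesimal_machine(p, 0.001)
  expect_equal(unname(g$Q[1, ]), c(0.998, 0.001, 0.001))
  expect_equal(unname(g$Q[2, ]), c(0.5, 0.5, 0))
  expect_equal(unname(rowSums(g$Q)), rep(1, 3))
  g0 <- infinitesimal_machine(p, 0)
  expect_equal(unname(g0$Q[1, ]), c(1, 0, 0))
  g1 <- infinitesimal_machine(ggi_params(2, 3, 0, 0), 0.01)
  expect_equal(unname(g1$Q[2:3, 1]), c(1, 1))    # single-residue: return to M
  expect_error(infinitesimal_machine(p, 1), "too large")
})

test_that("expected counts on the three-state machine have known values", {
  pr <- transition_probs(0.5, a = 0.55, b = 0.25, c = 0.2,
                         f = 0.45, g = 0.35, h = 0.2,
                         p = 0.35, q = 0.15, r = 0.5)
  m <- three_state_machine(pr)
  expect_equal(expected_transition_count(m, "M", "I"), pr$b)  # E[T_MI] = b
  expect_equal(expected_occupancy(m, "M"), 1)
  # closed-form occupancy from the transition entries
  den <- (1 - pr$g) * (1 - pr$r) - pr$h * pr$q
  SI <- (pr$b * (1 - pr$r) + pr$c * pr$q) *
    (pr$f * (1 - pr$r) + pr$h * pr$p) / den^2
  SD <- (pr$c * (1 - pr$g) + pr$b * pr$h) *
    (pr$p * (1 - pr$g) + pr$f * pr$q) / den^2
  expect_equal(expected_occupancy(m, "I"), SI, tolerance = 1e-12)
  expect_equal(expected_occupancy(m, "D"), SD, tolerance = 1e-12)
  # b = c = 0: no insertions or deletions ever entered
  pr0 <- transition_probs(0, a = 1, b = 0, c = 0, f = 0.5, g = 0.5, h = 0,
                          p = 0.5, q = 0, r = 0.5)
  m0 <- three_state_machine(pr0)
  expect_equal(expected_occupancy(m0, "I"), 0)
  expect_equal(expected_occupancy(m0, "D"), 0)
})

test_that("expected counts equal truncated path sums on random machines", {
  set.seed(42)
  for (rep in 1:20) {
    m <- random_small_machine()
    for (cls in list(c("M", "I"), c("I", "D"), c("D", "M"), c("I", "N"))) {
      exact <- expected_transition_count(m, cls[1], cls[2])
      approx <- path_sum_count(m, cls[1], cls[2], max_steps = 25)
      expect_equal(approx, exact, tolerance = 1e-5)
    }
  }
})

test_that("non-terminating machines are rejected", {
  Q <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))  # I state absorbs
  m <- state_machine(c("M", "I", "D"), c("M", "I", "D"), Q)
  expect_error(expected_transition_count(m, "M", "I"), "non-terminating")
})

test_that("composite machine has the printed structure and limits", {
  p <- ggi_params(0.8, 0.6, 0.4, 0.3)
  pr <- solve_transition_probs(p, 0.4)
  dt <- 2e-3
  fg <- compose_fg(pr, p, dt)
  expect_equal(fg$classes, c("M", "I", "I", "I", "D", "D", "D", "D", "N"))
  # spot entries from the machine-product rules
  expect_equal(fg$Q["mI", "MM"], pr$a * (1 - p$x))
  expect_equal(fg$Q["MM", "Dm"], pr$c)
  expect_equal(fg$Q["MM", "mI"], p$lambda * dt)
  expect_equal(fg$Q["ID", "Dd"], pr$h)
  # at dt = 0 expected counts reduce to those of the three-state machine
  fg0 <- compose_fg(pr, p, 0)
  f3 <- three_state_machine(pr)
  for (cls in list(c("M", "M"), c("M", "I"), c("I", "M"), c("D", "I"),
                   c("I", "D"), c("D", "D"))) {
    expect_equal(expected_transition_count(fg0, cls[1], cls[2]),
                 expected_transition_count(f3, cls[1], cls[2]),
                 tolerance = 1e-10)
  }
})

test_that("row- and column-sum occupancy identities agree on the composite", {
  p <- ggi_params(1, 1, 0.5, 0.5)
  pr <- solve_transition_probs(p, 0.5)
  fg <- compose_fg(pr, p, 1e-3)
  for (X in c("M", "I", "D")) {
    row_sum <- sum(vapply(c("M", "I", "D"), function(Y)
      expected_transition_count(fg, X, Y), numeric(1)))
    col_sum <- sum(vapply(c("M", "I", "D"), function(Y)
      expected_transition_count(fg, Y, X), numeric(1)))
    expect_lt(abs(row_sum - col_sum), 1e-10)
  }
  # on the stochastic three-state machine the match occupancy is exactly 1
  expect_equal(expected_occupancy(three_state_machine(pr), "M"), 1,
               tolerance = 1e-12)
})

test_that("machines round-trip through JSON", {
  p <- ggi_params(1, 0.5, 0.3, 0.2)
  g <- infinitesimal_machine(p, 0.01)
  path <- withr::local_tempfile(fileext = ".json")
  write_machine(g, path)
  g2 <- read_machine(path)
  expect_equal(g2$states, g$states)
  expect_equal(g2$classes, g$classes)
  expect_equal(g2$Q, g$Q)
})
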