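test_that("closed-form occupancies solve their ODE and small-t law", {
  p <- ggi_params(1, 1, 0.5, 0.5)
  occ0 <- occupancy_closed_form(p, 0)
  expect_equal(occ0$S_I, 0); expect_equal(occ0$S_D, 0)
  expect_equal(occupancy_closed_form(ggi_params(1, 1, 0.5, 0.3), 0.5)$S_I,
               exp(1) - 1, tolerance = 1e-12)
  # independent check: integrate dS/dt = lambda*(1+S)/(1-x) numerically
  p2 <- ggi_params(0.7, 1.1, 0.45, 0.25)
  ts <- seq(0, 2, by = 0.1)
  sol <- deSolve::ode(c(SI = 0, SD = 0), ts, function(t, s, .)
    list(c(p2$lambda * (1 + s[1]) / (1 - p2$x),
           p2$mu * (1 + s[2]) / (1 - p2$y))),
    parms = NULL, rtol = 1e-12, atol = 1e-14)
  occ <- occupancy_closed_form(p2, ts)
  expect_equal(unname(sol[, "SI"]), occ$S_I, tolerance = 1e-9)
  expect_equal(unname(sol[, "SD"]), occ$S_D, tolerance = 1e-9)
  # symmetry
  occ_s <- occupancy_closed_form(ggi_params(1.3, 1.3, 0.4, 0.4), 0.8)
  expect_equal(occ_s$S_I, occ_s$S_D)
})

test_that("counts convert to probabilities with correct boundary limits", {
  p <- ggi_params(1, 1, 0.3, 0.6)
  c0 <- transition_counts(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  pr <- counts_to_probs(c0, p)
  expect_equal(pr$a, 1); expect_equal(pr$b, 0); expect_equal(pr$c, 0)
  expect_equal(pr$f, 0.7); expect_equal(pr$g, 0.3); expect_equal(pr$h, 0)
  expect_equal(pr$p, 0.4); expect_equal(pr$q, 0); expect_equal(pr$r, 0.6)
  # direct ratios away from the boundary
  cts <- derived_counts(T_MM = 0.7, T_MI = 0.2, T_IM = 0.15, T_DI = 0.05,
                        S_I = 0.4, S_D = 0.3, t = 0.5)
  pr2 <- counts_to_probs(cts, p)
  expect_equal(pr2$a, 0.7); expect_equal(pr2$b, 0.2); expect_equal(pr2$c, 0.1)
  expect_equal(pr2$f, 0.15 / 0.4)
  expect_equal(unname(rowSums(transition_matrix(pr2))), rep(1, 3))
})

test_that("derived counts satisfy the linear identities", {
  d0 <- derived_counts(1, 0, 0, 0, 0, 0, t = 0)
  expect_equal(d0$T_MD, 0); expect_equal(d0$T_II, 0); expect_equal(d0$T_DD, 0)
  d <- derived_counts(T_MM = 0.6, T_MI = 0.25, T_IM = 0.2, T_DI = 0.1,
                      S_I = 0.5, S_D = 0.45, t = 1)
  expect_equal(d$T_MD, 1 - 0.6 - 0.25)
  expect_equal(d$T_MI + d$T_II + d$T_DI, d$S_I)
  expect_equal(d$T_IM + d$T_II + d$T_ID, d$S_I)
  expect_equal(d$T_DM + d$T_DI + d$T_DD, d$S_D)
  expect_error(derived_counts(0.9, 0.3, 0, 0, 0.1, 0.1), "negative")
})

test_that("derived counts match the path-sum engine on the TKF91 machine", {
  lam <- 1; mu <- 1; t <- 0.5
  k <- tkf91_probs(lam, mu, t)
  m <- three_state_machine(k)
  T_MM <- expected_transition_count(m, "M", "M")
  T_MI <- expected_transition_count(m, "M", "I")
  T_IM <- expected_transition_count(m, "I", "M")
  T_DI <- expected_transition_count(m, "D", "I")
  S_I <- expected_occupancy(m, "I"); S_D <- expected_occupancy(m, "D")
  d <- derived_counts(T_MM, T_MI, T_IM, T_DI, S_I, S_D, t = t)
  expect_equal(d$T_MD, expected_transition_count(m, "M", "D"),
               tolerance = 1e-10)
  expect_equal(d$T_II, expected_transition_count(m, "I", "I"),
               tolerance = 1e-10)
  expect_equal(d$T_ID, expected_transition_count(m, "I", "D"),
               tolerance = 1e-10)
  expect_equal(d$T_DM, expected_transition_count(m, "D", "M"),
               tolerance = 1e-10)
  expect_equal(d$T_DD, expected_transition_count(m, "D", "D"),
               tolerance = 1e-10)
})

test_that("count derivatives have the stated boundary values", {
  for (p in list(ggi_params(1, 1, 0.5, 0.5), ggi_params(0.3, 0.9, 0, 0.6))) {
    pr0 <- counts_to_probs(transition_counts(0, 1, 0, 0, 0, 0, 0, 0, 0, 0,
                                             0, 0), p)
    d <- count_derivatives(pr0, p)
    expect_equal(unname(d), c(-(p$lambda + p$mu), p$lambda, p$lambda, 0))
  }
})

test_that("ODE solution stays on the probability simplex with consistent occupancies", {
  p <- ggi_params(0.9, 0.7, 0.55, 0.35)
  ts <- c(0.01, 0.05, 0.2, 0.5, 1, 2)
  traj <- solve_transition_probs(p, max(ts), times = c(0, ts))
  occ <- occupancy_closed_form(p, c(0, ts))
  for (i in seq_along(traj)) {
    Q <- transition_matrix(traj[[i]])
    expect_equal(unname(rowSums(Q)), rep(1, 3), tolerance = 1e-8)
    expect_true(all(Q >= -1e-10))
    expect_equal(traj[[i]]$S_I, occ$S_I[i], tolerance = 1e-8)
    expect_equal(traj[[i]]$S_D, occ$S_D[i], tolerance = 1e-8)
  }
  # t = 0 returns the boundary
  pr0 <- solve_transition_probs(p, 0)
  expect_equal(pr0$a, 1); expect_equal(pr0$g, p$x); expect_equal(pr0$r, p$y)
})

test_that("TKF91 closed form handles the degenerate parameter limits", {
  k0 <- tkf91_probs(1, 1, 0)
  expect_equal(k0$a, 1); expect_equal(k0$b, 0); expect_equal(k0$c, 0)
  # lambda == mu: beta = lambda t / (1 + lambda t), via numerical limit
  lam <- 0.8; t <- 0.7
  k_eq <- tkf91_probs(lam, lam, t)
  k_up <- tkf91_probs(lam, lam * (1 + 1e-7), t)
  k_dn <- tkf91_probs(lam, lam * (1 - 1e-7), t)
  expect_equal(k_eq$b, lam * t / (1 + lam * t), tolerance = 1e-12)
  expect_equal(k_eq$b, (k_up$b + k_dn$b) / 2, tolerance = 1e-6)
  # deletion-only process: alpha = exp(-mu t), no insertions ever
  k_del <- tkf91_probs(0, 1.3, 0.9)
  expect_equal(k_del$a, exp(-1.3 * 0.9))
  expect_equal(k_del$b, 0)
  expect_equal(k_del$q, 0)
  # insertion-only process stays stochastic
  k_ins <- tkf91_probs(1.1, 0, 0.6)
  expect_equal(unname(rowSums(transition_matrix(k_ins))), rep(1, 3))
  expect_equal(k_ins$b, 1 - exp(-1.1 * 0.6), tolerance = 1e-12)
})

test_that("ODE solver reproduces TKF91 exactly in the single-residue limit", {
  for (par in list(c(0.3, 2), c(1, 1), c(2, 0.3))) {
    for (t in c(2^-7, 0.5, 2)) {
      p <- ggi_params(par[1], par[2], 0, 0)
      h <- solve_transition_probs(p, t)
      k <- tkf91_probs(par[1], par[2], t)
      expect_lt(max(abs(transition_matrix(h) - transition_matrix(k))), 1e-6)
    }
  }
})

test_that("finite-sequence machine wraps the interior block with start/end", {
  pr <- solve_transition_probs(ggi_params(1, 1, 0.4, 0.4), 0.3)
  fm <- finite_machine(pr)
  expect_equal(fm$Q[1:3, 1:3], transition_matrix(pr), ignore_attr = TRUE)
  expect_equal(unname(fm$Q[4, 1:3]), unname(fm$Q[1, 1:3]))  # S mirrors M
  expect_equal(unname(fm$Q[1:3, 5]), 1 - unname(fm$Q[1:3, 2]))
  # at t = 0 the all-match path through equal-length sequences has weight 1
  fm0 <- finite_machine(solve_transition_probs(ggi_params(1, 1, 0.4, 0.4), 0))
  expect_equal(unname(fm0$Q[4, 1] * fm0$Q[1, 1]^3 * fm0$Q[1, 5]), 1)
})
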