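# shared helpers: random parameter draws and an independent fixed-step
# Euler integrator used as an oracle for trajectory verdicts

draw_params <- function(n, seed) {
  set.seed(seed)
  random_params(n)
}

# independent forward-Euler path, deliberately naive: fixed step, clipping
euler_final <- function(params, init, t_max = 200, dt = 1e-3) {
  s <- init
  for (i in seq_len(round(t_max / dt))) {
    f <- c(liabgame::school_flow(params, s), liabgame::student_flow(params, s))
    s <- pmin(pmax(s + dt * f, 0), 1)
  }
  s
}

expect_corner <- function(traj, corner) {
  expect_identical(traj$verdict, "corner")
  expect_equal(unname(traj$corner), corner)
}
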