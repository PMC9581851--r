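# Independent numerical oracle for the constant-rate two-pool model:
# integrates dC/dt = gp - gc and d(excess label)/dt = -gc * APE with a
# stiff ODE solver, without reference to the closed-form trajectory.
ode_ape <- function(t_day, gp, gc, c0, ape0) {
  rhs <- function(t, y, p) {
    list(c(p$gp - p$gc, -p$gc * y[2] / y[1]))
  }
  out <- deSolve::lsoda(y = c(C = c0, X = ape0 * c0),
                        times = c(0, t_day), func = rhs,
                        parms = list(gp = gp, gc = gc),
                        rtol = 1e-12, atol = 1e-12)
  data.frame(t_day = out[-1, "time"],
             conc = out[-1, "C"],
             ape = out[-1, "X"] / out[-1, "C"])
}

# One labeled record in the shape compute_rates() expects.
rec <- function(conc, at_meas, time_h, n_total_ug = conc) {
  list(conc = conc, at_meas = at_meas, n_total_ug = n_total_ug,
       time_h = time_h)
}

no_blank <- list(at_blk = 0, n_blk_ug = 0)
bg_ref <- function(at) list(at_meas = at, tracer_mode = "none")
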