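# Shared fixtures, memoized across test files (test_dir runs everything in
# one session). Expensive objects are built once on first use.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# default ToF-like scenario parameters
fix_params <- function() memo("params", function() make_tof_scenario(1)$params)

# converged periodic run at the forward-algorithm tolerance
fix_sim <- function() memo("sim", function()
  run_cycles(NULL, fix_params(), dt = 1e-3, eps_cycl = 0.04))

# tightly converged limit cycle (ground truth for twin-style checks)
fix_sim_tight <- function() memo("sim_tight", function()
  run_cycles(NULL, fix_params(), dt = 1e-3, eps_cycl = 1e-4,
             max_cycles = 100L))

# noiseless synthetic measurements of the tight run
fix_mset <- function() memo("mset", function()
  synthesize_measurements(fix_sim_tight(), noise = NULL, seed = 1))

# full noiseless twin experiment (windkessel + valve + active-stress fits
# and the replacement prediction); the heavyweight fixture
fix_twin <- function() memo("twin", function()
  run_twin_experiment(seed = 1, noise = "none"))

# a random state vector away from valve-branch kinks (all transvalvular
# gradients O(1) kPa from zero), for Jacobian checks
fix_random_state <- function(seed = 42) {
  set.seed(seed)
  x <- as.numeric(initial_state(fix_params()))
  pr <- c(p_at_l = 1.6, p_v_l = 0.7, p_ar_sys = 9.2, p_ven_sys = 0.9,
          p_at_r = 0.85, p_v_r = 2.4, p_ar_pul = 1.3, p_ven_pul = 1.15)
  for (nm in names(pr)) x[cardioloop:::iS[[nm]]] <- pr[[nm]]
  x <- x * (1 + 0.03 * stats::rnorm(28))
  x[c(3, 5, 13, 15)] <- stats::runif(4, 0.2, 0.8)
  x[c(2, 4, 12, 14)] <- stats::rnorm(4, 2e4, 8e3)
  x[c(8, 10, 18, 20)] <- stats::rnorm(4, 5e4, 1e4)
  x[21:24] <- abs(x[21:24]) + 1e4
  x[25:28] <- stats::runif(4, 1, 30)
  x
}
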