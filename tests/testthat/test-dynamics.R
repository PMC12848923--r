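test_that("modulation functions hit their closed-form anchor points", {
  p <- dyn_params()
  expect_equal(phi_shrub(p$R0, p), 1)
  expect_equal(phi_shrub(0, p), 1)
  expect_equal(phi_shrub(p$R0 + 1 / p$k, p), exp(-1))
  expect_equal(phi_herb(p$Rc, p), 1)
  expect_equal(phi_herb(1.61, p), 2 / (1 + exp(3 * (1.61 - 1.4))))
  expect_equal(phi_herb(1.61, p), 0.695, tolerance = 1e-3)
  # limit R -> 0 with a steep sigmoid approaches 2
  steep <- dyn_params(b = 20, Rc = 1.4)
  expect_equal(phi_herb(0, steep), 2, tolerance = 1e-9)
})

test_that("modulation functions are continuous, bounded and monotone", {
  p <- dyn_params()
  eps <- 1e-10
  expect_equal(phi_shrub(p$R0 - eps, p), phi_shrub(p$R0 + eps, p),
               tolerance = 1e-8)
  R <- seq(0, 5, by = 0.01)
  expect_true(all(phi_shrub(R, p) > 0 & phi_shrub(R, p) <= 1))
  expect_true(all(phi_herb(R, p) > 0 & phi_herb(R, p) < 2))
  expect_true(all(diff(phi_herb(R, p)) < 0))
})

test_that("vector field evaluates the printed equations", {
  p <- dyn_params()  # R0 = 0.9, Rc = 1.4, k_h = k_s = 1
  f <- vector_field(1, 1, p)  # R = 1
  expect_equal(unname(f["dW_s"]), 0.35 * exp(-0.12) - 0.08, tolerance = 1e-12)
  expect_equal(unname(f["dW_s"]), 0.23042, tolerance = 1e-5)
  expect_equal(unname(f["dW_h"]), 0.8 * 2 / (1 + exp(-1.2)) - 0.25,
               tolerance = 1e-12)
  expect_equal(unname(f["dW_h"]), 0.97964, tolerance = 1e-5)
  # shrub-only limit: W_h = 0 gives R = 0 and pure exponential shrub growth
  f0 <- vector_field(2, 0, p)
  expect_equal(unname(f0["dW_s"]), (0.35 - 0.08) * 2)
  expect_equal(unname(f0["dW_h"]), 0)
  expect_error(vector_field(-1, 1, p), "domain error")
})

test_that("equilibrium expressions evaluate the printed rate ratios", {
  p <- dyn_params()
  eq <- equilibrium_biomass(p, R = 0.5)      # below R0: phi_s = 1
  expect_equal(unname(eq["W_s_star"]), 0.35 / 0.08)
  eq2 <- equilibrium_biomass(p, R = p$Rc)    # sigmoid midpoint: phi_h = 1
  expect_equal(unname(eq2["W_h_star"]), 0.8 / 0.25)
  eq3 <- equilibrium_biomass(p, R = 50)      # deep stress: shrub equilibrium -> 0
  expect_lt(unname(eq3["W_s_star"]), 1e-10)
  # equilibrium condition: growth balancing death zeroes the field
  peq <- dyn_params(r_s = 0.35, u_s = 0.35, r_h = 0.8, u_h = 0.8, R0 = 2, Rc = 1)
  f <- vector_field(1, 1, peq)  # R = 1: phi_s = 1, phi_h = 1
  expect_equal(unname(f), c(0, 0), tolerance = 1e-12)
})

test_that("trajectories match closed forms and converge at 4th order", {
  # modulation frozen at 1 (huge R0, flat sigmoid): exact exponentials
  p <- dyn_params(R0 = 1e6, b = 1e-9)
  tr <- simulate_dynamics(1, 1, p, t_max = 1, step = 0.01)
  expect_equal(tr$W_s[nrow(tr)], exp(0.35 - 0.08), tolerance = 1e-6)
  expect_equal(tr$W_h[nrow(tr)], exp(0.80 - 0.25), tolerance = 1e-6)
  # step halving moves the endpoint by < 1e-6 relative
  pd <- dyn_params()
  a <- simulate_dynamics(2, 1, pd, t_max = 5, step = 0.01)
  b <- simulate_dynamics(2, 1, pd, t_max = 5, step = 0.005)
  expect_equal(a$W_s[nrow(a)], b$W_s[nrow(b)], tolerance = 1e-6)
  expect_equal(a$W_h[nrow(a)], b$W_h[nrow(b)], tolerance = 1e-6)
  expect_error(simulate_dynamics(0, 1, pd), "biomasses")
  expect_error(simulate_dynamics(1, 1, pd, step = 0), "step")
})

test_that("the ratio dynamics close: R follows its own autonomous equation", {
  # with k_h = k_s, dR/dt = R * [(r_h phi_h - u_h) - (r_s phi_s - u_s)]
  p <- dyn_params()
  tr <- simulate_dynamics(1.5, 1.2, p, t_max = 10, step = 0.01)
  ratio_rhs <- function(t, y, parms) {
    R <- y[1]
    list(R * ((p$r_h * phi_herb(R, p) - p$u_h) -
              (p$r_s * phi_shrub(R, p) - p$u_s)))
  }
  ref <- deSolve::ode(c(R = tr$R[1]), tr$time, ratio_rhs, NULL, method = "rk4")
  expect_equal(tr$R, unname(ref[, 2]), tolerance = 1e-6)

  # starting at the growth-balance ratio, R stays constant
  gap <- function(R) (p$r_h * phi_herb(R, p) - p$u_h) -
                     (p$r_s * phi_shrub(R, p) - p$u_s)
  R_star <- uniroot(gap, c(1.4, 3), tol = 1e-12)$root
  tr2 <- simulate_dynamics(1, R_star, p, t_max = 5, step = 0.01)
  expect_lt(max(abs(tr2$R - R_star)), 1e-6)
})

test_that("analytic Jacobian reproduces limiting entries and both forms agree", {
  p <- dyn_params()
  J <- jacobian_analytic(0.5, p)   # below R0: phi_s = 1, derivative 0
  expect_equal(J[1, 2], 0)
  expect_equal(J[1, 1], 0.35 - 0.08)
  Jg <- jacobian_analytic(1.2, p, form = "general")
  expect_equal(jacobian_analytic(1.2, p, form = "printed"), Jg)
  pk <- dyn_params(k_h = 2, k_s = 1)
  expect_error(jacobian_analytic(1.2, pk), "unsupported configuration")
  expect_silent(jacobian_analytic(1.2, pk, form = "general"))
})

test_that("analytic Jacobian matches finite differences of the vector field", {
  set.seed(31)
  h <- 1e-6
  for (i in 1:200) {
    p <- dyn_params(r_s = runif(1, 0.1, 1), u_s = runif(1, 0.01, 0.5),
                    r_h = runif(1, 0.1, 1.5), u_h = runif(1, 0.05, 0.6),
                    k = runif(1, 0.5, 4), b = runif(1, 0.5, 6),
                    R0 = runif(1, 0.3, 1.5), Rc = runif(1, 0.5, 2),
                    k_h = runif(1, 0.5, 2), k_s = runif(1, 0.5, 2))
    W_s <- runif(1, 0.5, 4)
    repeat {  # keep R away from the modulation kink
      W_h <- runif(1, 0.5, 4)
      R <- biomass_ratio(W_s, W_h, p)
      if (abs(R - p$R0) > 1e-3) break
    }
    J <- jacobian_analytic(R, p, form = "general")
    fd <- matrix(NA_real_, 2, 2)
    fd[, 1] <- (vector_field(W_s + h, W_h, p) - vector_field(W_s - h, W_h, p)) / (2 * h)
    fd[, 2] <- (vector_field(W_s, W_h + h, p) - vector_field(W_s, W_h - h, p)) / (2 * h)
    expect_equal(J, fd, tolerance = 1e-5)
  }
})

test_that("trace/determinant eigenvalues agree with hand cases and a generic solver", {
  st <- eigen_stability(diag(c(-1, -2)))
  expect_equal(sort(Re(st$eigenvalues)), c(-2, -1))
  expect_equal(st$regime, "stable")
  rot <- eigen_stability(matrix(c(0, -1, 1, 0), 2))
  expect_equal(rot$max_re, 0)
  expect_equal(rot$regime, "marginal")
  expect_equal(sort(Im(rot$eigenvalues)), c(-1, 1))
  sym <- eigen_stability(matrix(c(2, 1, 1, 2), 2))
  expect_equal(sort(Re(sym$eigenvalues)), c(1, 3))
  expect_equal(sym$regime, "unstable")
  set.seed(32)
  for (i in 1:200) {
    J <- matrix(rnorm(4, sd = 3), 2)
    lam <- eigen_stability(J)$eigenvalues
    ref <- eigen(J, only.values = TRUE)$values
    expect_equal(sort(Re(lam)), sort(Re(ref)), tolerance = 1e-9)
    expect_equal(sort(abs(Im(lam))), sort(abs(Im(ref))), tolerance = 1e-9)
  }
})

test_that("site stability is internally consistent with its own Jacobian", {
  p <- dyn_params()
  for (R in c(0.81, 1.05, 1.61)) {
    st <- site_stability(R, p)
    ref <- eigen_stability(st$jacobian)
    expect_equal(st$regime, ref$regime)
    expect_equal(st$max_re, ref$max_re)
    expect_equal(unname(st$evaluation_point["R"]), R)
  }
  expect_error(site_stability(-0.5, p), "domain error")
})

test_that("bifurcation scan finds sign changes and honours degenerate grids", {
  # constructed family with a known root at R = 1.4
  fam <- function(R) diag(c(R - 1.4, -1))
  scan <- bifurcation_scan(R_grid = seq(0.5, 2, by = 0.01), zero_tol = 1e-9,
                           jacobian_fun = fam)
  cross <- attr(scan, "bifurcations")
  expect_equal(length(cross), 1L)
  expect_equal(cross, 1.4, tolerance = 0.01)
  # denser grid: same crossing
  scan2 <- bifurcation_scan(R_grid = seq(0.5, 2, by = 0.001), zero_tol = 1e-9,
                            jacobian_fun = fam)
  expect_equal(attr(scan2, "bifurcations"), 1.4, tolerance = 0.001)
  # all same sign: no bifurcations
  flat <- bifurcation_scan(R_grid = seq(0.5, 2, by = 0.1), zero_tol = 1e-9,
                           jacobian_fun = function(R) diag(c(-0.5, -1)))
  expect_equal(length(attr(flat, "bifurcations")), 0L)
  expect_error(bifurcation_scan(R_grid = c(2, 1)), "strictly increasing")
})

test_that("regime calibration honours consistent targets and verifies refits", {
  p <- dyn_params()
  # targets matching what the default parameters already produce
  Rs <- c(0.6, 1.2)
  current <- vapply(Rs, function(R) site_stability(R, p)$regime, character(1))
  fit <- calibrate_regimes(data.frame(R = Rs, regime = current), p)
  expect_equal(fit$misclassified, 0L)
  expect_true(fit$attainable)
  expect_equal(unlist(fit$params), unlist(p))

  # single attainable target: refit verified by re-evaluation
  fit2 <- calibrate_regimes(data.frame(R = 1.61, regime = "unstable"), p,
                            free = c("R0", "Rc"))
  expect_equal(site_stability(1.61, fit2$params)$regime, "unstable")
  expect_true(all(fit2$report$achieved ==
                  vapply(fit2$report$R,
                         function(R) site_stability(R, fit2$params)$regime,
                         character(1))))
  expect_error(calibrate_regimes(data.frame(R = 1, regime = "stable")[0, ], p),
               "target")
})

test_that("calibration reports attainability of the full observed regime pattern", {
  targets <- data.frame(
    R = c(0.81, 0.86, 1.01, 1.03, 1.05, 1.08, 1.45, 1.61),
    regime = c("stable", "stable", rep("marginal", 4), "unstable", "unstable"))
  fit <- calibrate_regimes(targets, dyn_params())
  expect_s3_class(fit$report, "data.frame")
  expect_equal(nrow(fit$report), 8L)
  expect_type(fit$attainable, "logical")
  # the report must be self-consistent: achieved labels recomputed from params
  recheck <- vapply(fit$report$R,
                    function(R) site_stability(R, fit$params)$regime, character(1))
  expect_equal(fit$report$achieved, recheck)
  expect_equal(fit$misclassified, sum(!fit$report$ok))
})
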