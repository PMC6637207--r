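#' Kinetic parameters of the SiR-actin ligand-receptor binding model
#'
#' The probe (ligand, L) binds F-actin sites (receptor, R) reversibly,
#' `L + R <-> C`, and only the bound complex C fluoresces. With binding
#' sites in excess, the forward rate constant and the total site abundance
#' are structurally unidentifiable separately and enter both rate equations
#' only as the composite `kf_d = kf * R_T`. `kr` is the dissociation rate,
#' driven by actin filament turnover stripping the probe off. `L_T` is the
#' free-ligand abundance, used only in association mode, where the
#' effective association rate is `kf_a = kf_d * L_T`.
#'
#' @param kf_d Effective forward rate `kf * R_T` (1/min), >= 0.
#' @param kr Dissociation rate (1/min), >= 0.
#' @param L_T Free-ligand abundance (dimensionless), >= 0. Only meaningful
#'   in association mode.
#' @param C0 Initial bound-probe signal. Defaults to 1, the value after
#'   normalization to the first timepoint.
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params(kf_d = 0.2, kr = 1.0)
#' kf_a(kinetic_params(kf_d = 0.5, kr = 1, L_T = 2))
#' @export
kinetic_params <- function(kf_d, kr, L_T = 0, C0 = 1) {
  stopifnot(is.numeric(kf_d), is.numeric(kr), is.numeric(L_T), is.numeric(C0))
  if (kf_d < 0 || kr < 0 || L_T < 0)
    stop("invalid kinetic parameters: rates and L_T must be non-negative")
  if (C0 <= 0)
    stop("invalid kinetic parameters: C0 must be positive")
  structure(list(kf_d = kf_d, kr = kr, L_T = L_T, C0 = C0),
            class = "kinetic_params")
}

#' @rdname kinetic_params
#' @param params A `kinetic_params` object.
#' @export
kf_a <- function(params) params$kf_d * params$L_T

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: kf_d = %g /min, kr = %g /min, L_T = %g, C0 = %g\n",
              x$kf_d, x$kr, x$L_T, x$C0))
  invisible(x)
}

new_trajectory <- function(times, values, mode) {
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 mode = mode), class = "bound_probe_trajectory")
}

#' Construct a bound-probe trajectory
#'
#' A time series of the bound-probe signal C(t), either observed (for
#' fitting) or simulated.
#'
#' @param times Sampling times (min), strictly increasing.
#' @param values Bound-probe signal per time, non-negative.
#' @param mode `"dissociation"` or `"association"`.
#' @return A `bound_probe_trajectory` object.
#' @export
bound_probe_trajectory <- function(times, values,
                                   mode = c("dissociation", "association")) {
  mode <- match.arg(mode)
  if (any(values < 0)) stop("trajectory values must be non-negative")
  new_trajectory(times, values, mode)
}

# General solution of the linear ODE dC/dt = a - b*C from C(t0) = c_init:
# C(t) = a/b + (c_init - a/b) * exp(-b (t - t0)); for b = 0 a linear ramp.
linear_binding_solution <- function(a, b, c_init, times, t0 = times[1]) {
  dt <- times - t0
  if (b == 0) return(c_init + a * dt)
  ceq <- a / b
  ceq + (c_init - ceq) * exp(-b * dt)
}

#' Simulate the dissociation phase of probe binding
#'
#' Closed-form solution of `dC/dt = kf_d * (C0 - C) - kr * C` with
#' `C(0) = C0`: after the staining medium is washed out, net probe loss
#' relaxes the signal from `C0` toward the equilibrium
#' `C_inf = kf_d * C0 / (kf_d + kr)` with rate `kf_d + kr`.
#'
#' @param params A `kinetic_params` object.
#' @param times Time grid (min), starting at 0, strictly increasing.
#' @return A `bound_probe_trajectory` in dissociation mode.
#' @examples
#' simulate_dissociation(kinetic_params(0.2, 1.0), seq(0, 10, by = 1))
#' @export
simulate_dissociation <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (times[1] != 0) stop("dissociation time grid must start at 0")
  vals <- linear_binding_solution(a = params$kf_d * params$C0,
                                  b = params$kf_d + params$kr,
                                  c_init = params$C0, times = times)
  new_trajectory(times, vals, "dissociation")
}

#' Simulate the association phase of probe binding
#'
#' Closed-form solution of `dC/dt = kf_d * L_T - kr * C` from
#' `C(0) = c_init`: with unbound ligand in excess the signal relaxes toward
#' `Ceq = kf_d * L_T / kr` with rate `kr` (a linear ramp when `kr = 0`).
#' The default `c_init = 0` corresponds to initially unstained cells.
#'
#' @inheritParams simulate_dissociation
#' @param c_init Initial bound-probe signal, >= 0.
#' @return A `bound_probe_trajectory` in association mode.
#' @export
simulate_association <- function(params, times, c_init = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (c_init < 0) stop("invalid parameter: c_init must be non-negative")
  vals <- linear_binding_solution(a = kf_a(params), b = params$kr,
                                  c_init = c_init, times = times,
                                  t0 = times[1])
  new_trajectory(times, vals, "association")
}

new_fit_result <- function(params, residual_sse, stderr, converged,
                           identifiable = TRUE) {
  structure(list(params = params, residual_sse = residual_sse,
                 stderr = stderr, converged = converged,
                 identifiable = identifiable), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("kinetic_fit:", if (x$converged) "converged" else "NOT converged", "\n")
  print(x$params)
  cat(sprintf("  SSE = %g\n", x$residual_sse))
  invisible(x)
}

# SSE of the dissociation closed form against observed values.
dissociation_sse <- function(theta, times, values, C0) {
  pred <- linear_binding_solution(a = theta[1] * C0, b = theta[1] + theta[2],
                                  c_init = C0, times = times)
  sum((values - pred)^2)
}

# Numerical Jacobian of predicted trajectory wrt theta (for stderr).
num_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    J[, j] <- (fn(tp) - f0) / h
  }
  J
}

fit_stderr <- function(predict_fn, theta, values) {
  J <- num_jacobian(predict_fn, theta)
  res <- values - predict_fn(theta)
  dof <- length(values) - length(theta)
  if (dof <= 0) return(rep(NA_real_, length(theta)))
  s2 <- sum(res^2) / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * s2, error = function(e) NULL)
  if (is.null(cov)) rep(Inf, length(theta)) else sqrt(pmax(diag(cov), 0))
}

#' Fit the dissociation model to a decay trajectory
#'
#' Least-squares estimation of `(kf_d, kr)` against
#' [simulate_dissociation()]. `C0` is fixed at 1 by default because SMAT
#' curves are normalized to the first timepoint; set `fix_C0 = FALSE` for
#' un-normalized data, in which case `C0` is estimated as a third
#' parameter. Optimization is multi-start box-constrained least squares
#' over a fixed log-spaced grid of starting points (deterministic; best
#' SSE wins, ties broken by smaller `kr`), so no random seed is involved.
#'
#' @param traj A dissociation-mode `bound_probe_trajectory` with >= 4
#'   timepoints.
#' @param fix_C0 Keep `C0` fixed at the first observed value scale (1 for
#'   normalized data)? Default `TRUE`.
#' @param starts_per_dim Number of log-spaced multi-start values per rate
#'   in `[1e-3, 10]` /min. Default 5 (a 5 x 5 grid).
#' @return A `kinetic_fit` with fields `params`, `residual_sse`, `stderr`
#'   (for `kf_d` and `kr`), `converged`.
#' @examples
#' tr <- simulate_dissociation(kinetic_params(0.2, 1.0), seq(0, 14, by = 1))
#' fit_dissociation(tr)$params
#' @export
fit_dissociation <- function(traj, fix_C0 = TRUE, starts_per_dim = 5) {
  stopifnot(inherits(traj, "bound_probe_trajectory"))
  if (traj$mode != "dissociation") stop("trajectory must be in dissociation mode")
  if (length(traj$times) < 4) stop("need at least 4 timepoints to fit")
  times <- traj$times; values <- traj$values
  C0 <- if (fix_C0) 1 else values[1]
  grid <- 10^seq(-3, 1, length.out = starts_per_dim)
  starts <- as.matrix(expand.grid(kf_d = grid, kr = grid))

  obj <- if (fix_C0) {
    function(th) dissociation_sse(th, times, values, C0 = 1)
  } else {
    function(th) dissociation_sse(th[1:2], times, values, C0 = th[3])
  }
  lower <- if (fix_C0) c(0, 0) else c(0, 0, 1e-8)
  upper <- if (fix_C0) c(100, 100) else c(100, 100, Inf)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- if (fix_C0) starts[i, ] else c(starts[i, ], values[1])
    res <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e4,
                                  ndeps = rep(1e-7, length(th0)))),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && res$par[2] < best$par[2])) {
      best <- res
    }
  }
  if (!is.null(best)) {
    polish <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1, pgtol = 1e-14, maxit = 1000,
                                  ndeps = rep(1e-8, length(best$par)))),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  if (is.null(best)) {
    return(new_fit_result(kinetic_params(0, 0, C0 = C0), Inf,
                          c(kf_d = NA_real_, kr = NA_real_), converged = FALSE))
  }
  th <- best$par
  C0_hat <- if (fix_C0) 1 else th[3]
  pfun <- function(t2) linear_binding_solution(t2[1] * C0_hat, t2[1] + t2[2],
                                               C0_hat, times)
  se <- fit_stderr(pfun, th[1:2], values)
  names(se) <- c("kf_d", "kr")
  new_fit_result(kinetic_params(th[1], th[2], C0 = C0_hat), best$value, se,
                 converged = all(is.finite(se)) || best$value < 1e-12)
}

#' Fit the free-ligand abundance from an association trajectory
#'
#' The sequential second step of parameter estimation: with `kf_d` and
#' `kr` already fitted from dissociation data and held fixed, the
#' association solution is linear in `L_T`, so the least-squares estimate
#' is computed in closed form. With `kf_d = 0` the trajectory carries no
#' information about `L_T`; the fit is then flagged non-identifiable
#' rather than raising an error.
#'
#' @param traj An association-mode `bound_probe_trajectory`.
#' @param fixed A `kinetic_params` carrying the dissociation-fitted `kf_d`
#'   and `kr`.
#' @param c_init Initial bound signal at the start of the association
#'   window (default 0, unstained cells).
#' @return A `kinetic_fit` whose `params` carry the fixed rates plus the
#'   estimated `L_T`; `identifiable = FALSE` when `kf_d = 0`.
#' @export
fit_association <- function(traj, fixed, c_init = 0) {
  stopifnot(inherits(traj, "bound_probe_trajectory"),
            inherits(fixed, "kinetic_params"))
  if (traj$mode != "association") stop("trajectory must be in association mode")
  times <- traj$times; values <- traj$values
  dt <- times - times[1]
  # C(t) = c_init e^{-kr t} + L_T * w(t),  w(t) = (kf_d/kr)(1 - e^{-kr t})
  w <- if (fixed$kr == 0) fixed$kf_d * dt
       else (fixed$kf_d / fixed$kr) * (1 - exp(-fixed$kr * dt))
  r <- values - c_init * exp(-fixed$kr * dt)
  sw2 <- sum(w^2)
  if (fixed$kf_d == 0 || sw2 == 0) {
    p <- kinetic_params(fixed$kf_d, fixed$kr, L_T = 0, C0 = fixed$C0)
    return(new_fit_result(p, sum(r^2), c(L_T = NA_real_),
                          converged = TRUE, identifiable = FALSE))
  }
  lt <- max(0, sum(w * r) / sw2)
  sse <- sum((r - lt * w)^2)
  dof <- length(values) - 1
  se <- if (dof > 0) sqrt(sum((r - lt * w)^2) / dof / sw2) else NA_real_
  p <- kinetic_params(fixed$kf_d, fixed$kr, L_T = lt, C0 = fixed$C0)
  new_fit_result(p, sse, c(L_T = se), converged = TRUE)
}

#' Dissociation-pressure ratio kr / kf_d
#'
#' The lineage-discriminating summary of the binding model: conditions
#' with slower actin turnover dissociate the probe less per unit of
#' effective association and thus have a smaller ratio. Because the
#' forward rate and site abundance are identifiable only as the product
#' `kf_d = kf * R_T`, the implementable ratio is `kr / kf_d`.
#'
#' @param params A `kinetic_params` with `kf_d > 0`.
#' @return The scalar `kr / kf_d`.
#' @examples
#' dissociation_ratio(kinetic_params(0.5, 1.0))  # 2
#' @export
dissociation_ratio <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$kf_d == 0) stop("kr/kf_d undefined: kf_d is zero")
  params$kr / params$kf_d
}
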