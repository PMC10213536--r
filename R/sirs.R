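#' Parameters of the SIRS formal-care diffusion model
#'
#' The formal-care market is modelled as a closed population of size N in
#' three compartments: S, people who have not chosen formal care; I, people
#' who perceive the care risk but have not (yet) chosen formal care; and R,
#' people currently choosing formal care. `alpha` is the social-contact /
#' tie-strength rate driving the bilinear transmission term alpha*S*I,
#' `beta` the rate at which risk-aware people adopt formal care by learning
#' and imitation (I -> R), `delta` the rate at which risk-aware people
#' revert without adopting (I -> S), and `lam` the abandonment rate of
#' formal care (R -> S). All four rates must be strictly positive.
#'
#' @param alpha,beta,lam,delta positive rates (per unit time; `alpha` per
#'   contact partner per unit time).
#' @param N total population, constant over time (default 1: compartments
#'   as population shares, under which bilinear and frequency-dependent
#'   transmission coincide).
#' @return object of class `sirs_params`.
#' @export
sirs_params <- function(alpha, beta, lam, delta, N = 1) {
  vals <- c(alpha = alpha, beta = beta, lam = lam, delta = delta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("alpha, beta, lam and delta must all be > 0", call. = FALSE)
  if (!is.finite(N) || N <= 0) stop("N must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lam = lam, delta = delta, N = N),
            class = "sirs_params")
}

#' Right-hand side of the SIRS dynamics
#'
#' dS/dt = -alpha*S*I + lam*R + delta*I;
#' dI/dt =  alpha*S*I - beta*I - delta*I;
#' dR/dt =  beta*I - lam*R.
#' The three terms cancel, so S + I + R is conserved.
#'
#' @param state numeric vector `c(S, I, R)`, all components >= 0.
#' @param params a [sirs_params()].
#' @return named numeric vector `c(dS, dI, dR)`.
#' @export
sirs_derivatives <- function(state, params) {
  stopifnot(inherits(params, "sirs_params"))
  if (any(state < 0)) stop("state components must be >= 0", call. = FALSE)
  S <- state[[1]]; I <- state[[2]]; R <- state[[3]]
  with(params, c(
    dS = -alpha * S * I + lam * R + delta * I,
    dI = alpha * S * I - beta * I - delta * I,
    dR = beta * I - lam * R
  ))
}

#' Closed-form steady states of the SIRS model
#'
#' Setting the dynamics to zero yields the interior (endemic) equilibrium
#' S* = (beta + delta)/alpha,
#' I* = lam*(N - (beta + delta)/alpha) / (beta + lam),
#' R* = beta*(N*alpha - beta - delta) / (alpha*(lam + beta)),
#' feasible iff alpha*N > beta + delta; otherwise the population settles at
#' the diffusion-free state (N, 0, 0).
#'
#' @param params a [sirs_params()].
#' @return object of class `sirs_equilibrium`: list with `S_star`,
#'   `I_star`, `R_star` and logical `endemic`.
#' @export
sirs_steady_state <- function(params) {
  stopifnot(inherits(params, "sirs_params"))
  out <- with(params, {
    if (alpha * N > beta + delta) {
      S <- (beta + delta) / alpha
      I <- lam * (N - (beta + delta) / alpha) / (beta + lam)
      R <- beta * (N * alpha - beta - delta) / (alpha * (lam + beta))
      list(S_star = S, I_star = I, R_star = R, endemic = TRUE)
    } else {
      list(S_star = N, I_star = 0, R_star = 0, endemic = FALSE)
    }
  })
  structure(out, class = "sirs_equilibrium")
}

#' @export
print.sirs_equilibrium <- function(x, ...) {
  cat(sprintf("SIRS equilibrium: S* = %.6g, I* = %.6g, R* = %.6g (%s)\n",
              x$S_star, x$I_star, x$R_star,
              if (x$endemic) "endemic" else "diffusion-free"))
  invisible(x)
}

#' Integrate the SIRS dynamics
#'
#' Classical fixed-step fourth-order Runge--Kutta. The step size is chosen
#' from `dt`; a built-in step-halving check (`verify = TRUE`) re-integrates
#' at dt/2 and errors if the terminal states disagree beyond `check_tol`,
#' guarding against too-coarse steps.
#'
#' @param params a [sirs_params()].
#' @param init numeric `c(S, I, R)`, nonnegative, summing to `N` (tolerance
#'   1e-9 relative).
#' @param t_end end time (> 0).
#' @param dt time step (default 0.05).
#' @param verify logical; run the step-halving self-check.
#' @param check_tol tolerance for the self-check on the terminal state.
#' @return data frame of class `sirs_trajectory` with columns `time`, `S`,
#'   `I`, `R`.
#' @export
sirs_simulate <- function(params, init, t_end, dt = 0.05, verify = FALSE,
                          check_tol = 1e-6) {
  stopifnot(inherits(params, "sirs_params"), t_end > 0, dt > 0)
  if (any(init < 0)) stop("initial state components must be >= 0", call. = FALSE)
  if (abs(sum(init) - params$N) > 1e-9 * max(1, params$N))
    stop("initial state must sum to N", call. = FALSE)
  traj <- rk4_sirs(params, init, t_end, dt)
  if (verify) {
    traj2 <- rk4_sirs(params, init, t_end, dt / 2)
    d <- max(abs(unlist(traj[nrow(traj), -1]) -
                 unlist(traj2[nrow(traj2), -1])))
    if (d > check_tol * max(1, params$N))
      stop(sprintf(
        "step-size check failed: halving dt moved the terminal state by %.3g; decrease dt",
        d), call. = FALSE)
  }
  traj
}

rk4_sirs <- function(params, init, t_end, dt) {
  n_steps <- ceiling(t_end / dt - 1e-12)
  out <- matrix(NA_real_, n_steps + 1, 3)
  state <- as.numeric(init)
  out[1, ] <- state
  f <- function(s) unname(sirs_derivatives(pmax(s, 0), params))
  for (i in seq_len(n_steps)) {
    h <- min(dt, t_end - (i - 1) * dt)
    k1 <- f(state)
    k2 <- f(state + h / 2 * k1)
    k3 <- f(state + h / 2 * k2)
    k4 <- f(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- state
  }
  traj <- data.frame(time = c(0, pmin(seq_len(n_steps) * dt, t_end)),
                     S = out[, 1], I = out[, 2], R = out[, 3])
  class(traj) <- c("sirs_trajectory", "data.frame")
  traj
}

#' Comparative statics of the equilibria in tie strength
#'
#' Evaluates the closed-form steady state over a grid of contact rates.
#' Within the endemic region S* = (beta + delta)/alpha falls as alpha
#' rises --- stronger ties move people out of the undecided pool --- while
#' I* and R* rise; S* does not depend on the abandonment rate lam.
#'
#' @param params a [sirs_params()] supplying beta, lam, delta and N.
#' @param alpha_grid positive, strictly increasing vector of contact rates.
#' @return data frame with columns `alpha`, `S_star`, `I_star`, `R_star`,
#'   `endemic`.
#' @export
sirs_comparative_statics <- function(params, alpha_grid) {
  stopifnot(inherits(params, "sirs_params"))
  if (any(alpha_grid <= 0) || is.unsorted(alpha_grid, strictly = TRUE))
    stop("alpha_grid must be positive and strictly increasing", call. = FALSE)
  rows <- lapply(alpha_grid, function(a) {
    eq <- sirs_steady_state(sirs_params(a, params$beta, params$lam,
                                        params$delta, params$N))
    data.frame(alpha = a, S_star = eq$S_star, I_star = eq$I_star,
               R_star = eq$R_star, endemic = eq$endemic)
  })
  do.call(rbind, rows)
}
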