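#' Fixed-step fourth-order Runge-Kutta integration
#'
#' Classic RK4 with a fixed nominal step, landing exactly on every
#' requested output time (the step preceding a requested time is
#' shortened; no interpolation is performed). This is the generic,
#' pure-R integrator used for arbitrary right-hand sides; the two
#' built-in models are integrated by an equivalent compiled core inside
#' [simulate_experiment()].
#'
#' @param rhs Function `function(t, state)` returning the state
#'   derivative (numeric vector of the same length as `state`).
#' @param x0 Initial state at `t_grid[1]`.
#' @param t_grid Increasing vector of output times (h).
#' @param step Nominal step size (h), `> 0`.
#' @return Matrix with `length(t_grid)` rows (one per output time) and
#'   one column per state component, with `t_grid` as the `"times"`
#'   attribute.
#' @examples
#' # exponential decay, compared to its closed form
#' out <- integrate_rk4(function(t, y) -0.011 * y, 25, c(0, 24), step = 0.01)
#' out[2, 1] - 25 * exp(-0.011 * 24)
#' @export
integrate_rk4 <- function(rhs, x0, t_grid, step = 0.01) {
  if (step <= 0) stop("'step' must be positive", call. = FALSE)
  if (any(diff(t_grid) <= 0))
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  d <- length(x0)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = d)
  colnames(out) <- names(x0)
  out[1L, ] <- x0
  s <- as.numeric(x0)
  for (i in seq_len(length(t_grid) - 1L)) {
    t0 <- t_grid[i]; t1 <- t_grid[i + 1L]
    n_sub <- max(1L, ceiling((t1 - t0) / step - 1e-9))
    h <- (t1 - t0) / n_sub
    t <- t0
    for (k in seq_len(n_sub)) {
      k1 <- rhs(t, s)
      k2 <- rhs(t + h / 2, s + h / 2 * k1)
      k3 <- rhs(t + h / 2, s + h / 2 * k2)
      k4 <- rhs(t + h, s + h * k3)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t0 + k * h
      if (any(!is.finite(s)))
        stop("integration failure: non-finite state at t = ", signif(t, 6),
             call. = FALSE)
    }
    out[i + 1L, ] <- s
  }
  attr(out, "times") <- t_grid
  out
}

#' Instantaneous medium replacement (pulse dosing event)
#'
#' Realizes the Dirac impulse of the pulse design: at the replacement
#' time the drug-containing supernatant is swapped for fresh medium, so
#' the medium concentration `Y` jumps to `Ystar_plus` while every
#' intracellular pool (`Z`, `G`, and `B` for Model 2) is untouched.
#'
#' @param state_pre Named state vector immediately before the event.
#' @param za A [za_params()] block (supplies `Ystar_plus`).
#' @param design Optional [experiment_design()]; if given, it must be a
#'   pulse design (the event has no meaning in continuous mode).
#' @return The post-event state.
#' @examples
#' za <- za_params(0.607, 0.029, 18.06, 14.91, Ystar_plus = 0)
#' apply_medium_replacement(c(Y = 18.3, Z = 4.4, G = 2.7), za)
#' @export
apply_medium_replacement <- function(state_pre, za, design = NULL) {
  stopifnot(inherits(za, "za_params"))
  if (!is.null(design) && design$mode != "pulse")
    stop("medium replacement is a pulse-mode event; the design is ",
         design$mode, call. = FALSE)
  if (is.null(names(state_pre)) || !"Y" %in% names(state_pre))
    stop("'state_pre' must be a named state vector containing 'Y'",
         call. = FALSE)
  state_pre[["Y"]] <- za$Ystar_plus
  state_pre
}

# Uniform step nodes over [0, t_end] with requested times snapped onto
# the grid exactly (inserted where no node lies within tolerance), so no
# interval exceeds `step` and every requested time is a node.
build_time_grid <- function(t_end, step, extra = numeric()) {
  n <- ceiling(t_end / step - 1e-9)
  nodes <- (0:n) * step
  nodes[length(nodes)] <- t_end
  extra <- unique(c(extra, t_end))
  extra <- extra[extra >= 0 & extra <= t_end]
  for (e in extra) {
    i <- which(abs(nodes - e) < 1e-8)
    if (length(i)) nodes[i[1L]] <- e else nodes <- c(nodes, e)
  }
  sort(unique(nodes))
}

#' Simulate an exposure experiment
#'
#' Integrates Model 1 or Model 2 over an [experiment_design()] with the
#' compiled fixed-step RK4 core. The initial state is
#' `(Y = Y0, Z = 0, G = G0[, B = 0])`. In pulse mode integration runs to
#' `t_star`, the medium replacement is applied as an instantaneous jump
#' of `Y` (see [apply_medium_replacement()]), and integration continues;
#' the stored state at `t_star` is the post-event state, with the
#' pre-event medium concentration kept alongside.
#'
#' @param model_id 1 or 2.
#' @param za A [za_params()] block.
#' @param ag The matching antigen block ([model1_ag_params()] or
#'   [model2_ag_params()]).
#' @param design An [experiment_design()].
#' @param step RK4 step size (h). The 0.01 h default makes the
#'   integration error negligible against measurement noise (see the
#'   closed-form oracle checks in the test-suite).
#' @return A `za_trajectory`: time grid, state matrix (`Y`, `Z`, `G`,
#'   plus `B` and the algebraic `U = U0 - B` for Model 2), the design,
#'   and for pulse runs the pre-event medium concentration `y_pre`.
#' @examples
#' tr <- with(scenario_truth("model1_continuous"),
#'            simulate_experiment(1, za, ag, design))
#' trajectory_at(tr, c(24, 48))
#' @export
simulate_experiment <- function(model_id, za, ag, design, step = 0.01) {
  stopifnot(model_id %in% c(1L, 2L), inherits(za, "za_params"),
            inherits(design, "experiment_design"))
  if (model_id == 1 && !inherits(ag, "model1_ag_params"))
    stop("'ag' must be a model1_ag_params block for model 1", call. = FALSE)
  if (model_id == 2 && !inherits(ag, "model2_ag_params"))
    stop("'ag' must be a model2_ag_params block for model 2", call. = FALSE)

  pulse <- design$mode == "pulse"
  extra <- c(design$sample_times, if (pulse) design$t_star)
  t_nodes <- build_time_grid(design$t_end, step, extra)

  if (model_id == 1) {
    params <- c(za$kZY, za$kXY, za$kYZ, za$rhoZY, za$kXZ,
                ag$kXG, ag$kXGZ, ag$lambdaGZ, ag$G0)
    x0 <- c(design$Y0, 0, ag$G0)
    cols <- c("Y", "Z", "G")
  } else {
    params <- c(za$kZY, za$kXY, za$kYZ, za$rhoZY, za$kXZ,
                ag$kXG, ag$kXGU, ag$lambdaUBG, ag$kBUZ, ag$kUBG,
                ag$G0, ag$U0)
    x0 <- c(design$Y0, 0, ag$G0, 0)
    cols <- c("Y", "Z", "G", "B")
  }
  res <- .rk4_traj_cpp(as.integer(model_id), params, x0, t_nodes,
                       pulse, if (pulse) design$t_star else -1,
                       za$Ystar_plus)
  states <- res$states
  colnames(states) <- cols
  if (model_id == 2) states <- cbind(states, U = ag$U0 - states[, "B"])
  structure(list(times = t_nodes, states = states,
                 model_id = as.integer(model_id), design = design,
                 step = step,
                 y_pre = if (pulse) res$y_pre else NA_real_),
            class = "za_trajectory")
}

#' Extract trajectory states at given times
#'
#' @param traj A `za_trajectory` from [simulate_experiment()].
#' @param times Times (h) to extract; each must be a grid node of the
#'   trajectory (sample times and the event time always are).
#' @return A data frame with column `time` and one column per state.
#' @export
trajectory_at <- function(traj, times) {
  stopifnot(inherits(traj, "za_trajectory"))
  idx <- vapply(times, function(t) {
    i <- which(abs(traj$times - t) < 1e-8)
    if (!length(i))
      stop("time ", t, " is not a node of the trajectory", call. = FALSE)
    i[1L]
  }, integer(1))
  data.frame(time = traj$times[idx], traj$states[idx, , drop = FALSE])
}

#' @export
print.za_trajectory <- function(x, ...) {
  cat(sprintf("Model %d trajectory, %s experiment, %d nodes over [0, %g] h (step %g h)\n",
              x$model_id, x$design$mode, length(x$times), x$design$t_end,
              x$step))
  print(utils::head(trajectory_at(x, x$design$sample_times)))
  invisible(x)
}

#' @export
as.data.frame.za_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  df <- data.frame(time_h = x$times,
                   Y_uM = x$states[, "Y"],
                   Z_pmol_per_mgprot = x$states[, "Z"],
                   G_pmol_per_mgprot = x$states[, "G"])
  if (x$model_id == 2L) {
    df$B_pct <- x$states[, "B"]
    df$U_pct <- x$states[, "U"]
  }
  df
}

#' Closed-form solution of the linear ZA subsystem
#'
#' Between dosing events the `(Y, Z)` kinetics are an autonomous linear
#' system with rate matrix
#' `A = [[-(kZY+kXY), kYZ/rhoZY], [rhoZY*kZY, -(kXZ+kYZ)]]`.
#' This returns the exact matrix-exponential solution from initial state
#' `(Y0, 0)`, via eigendecomposition in the generic diagonalizable case
#' and the confluent formula `exp(lambda t) (I + (A - lambda I) t)` for a
#' (near-)repeated eigenvalue. It serves as an independent oracle for
#' the RK4 integrator in tests and cross-checks; it plays no part in the
#' simulation path.
#'
#' @param za A [za_params()] block.
#' @param Y0 Initial medium concentration (uM).
#' @param t Vector of times (h).
#' @return Matrix with columns `Y`, `Z` and one row per time.
#' @examples
#' za <- za_params(0.007, 0.004, 0.001, 25.46)
#' za_subsystem_closed_form(za, 25, c(0, 24, 48))
#' @export
za_subsystem_closed_form <- function(za, Y0, t) {
  stopifnot(inherits(za, "za_params"))
  A <- matrix(c(-(za$kZY + za$kXY), za$kYZ / za$rhoZY,
                za$rhoZY * za$kZY, -(za$kXZ + za$kYZ)),
              nrow = 2, byrow = TRUE)
  x0 <- c(Y0, 0)
  ev <- eigen(A)
  sep <- abs(ev$values[1] - ev$values[2])
  scale <- max(abs(ev$values), 1e-12)
  out <- matrix(NA_real_, nrow = length(t), ncol = 2,
                dimnames = list(NULL, c("Y", "Z")))
  if (Re(sep) / scale > 1e-7 || Im(sep) / scale > 1e-7) {
    Vm <- ev$vectors
    c0 <- solve(Vm, x0)
    for (i in seq_along(t)) {
      x <- Vm %*% (exp(ev$values * t[i]) * c0)
      out[i, ] <- Re(x)
    }
  } else {
    lambda <- Re(ev$values[1])
    N <- A - lambda * diag(2)  # nilpotent (or negligible) part
    for (i in seq_along(t)) {
      x <- exp(lambda * t[i]) * ((diag(2) + N * t[i]) %*% x0)
      out[i, ] <- x
    }
  }
  out
}
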