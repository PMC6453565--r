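#' Create an estimator/controller state
#'
#' Holds the current position and velocity estimates, the forward-projected
#' position estimate, and the accumulated integral used by the PI
#' controller.
#'
#' @param x_hat estimated relative position (position units).
#' @param v_hat estimated relative velocity (position units/s).
#' @param z forward-projected position estimate (position units).
#' @param integral_z accumulated integral of the controller input
#'   (position units * s).
#' @return list of class `estimator_state`.
#' @export
estimator_state <- function(x_hat = 0, v_hat = 0, z = x_hat,
                            integral_z = 0) {
  structure(list(x_hat = x_hat, v_hat = v_hat, z = z,
                 integral_z = integral_z),
            class = "estimator_state")
}

#' One step of the steady-state Kalman estimator
#'
#' Applies one update of the constant-gain estimator.  The per-step
#' increments are
#' \deqn{\Delta\hat{x} = -K_{pos}\hat{x} + \Delta t\,\hat{v} + K_{pos}y,
#'       \qquad \Delta\hat{v} = -K_{vel}\hat{x} + K_{vel}y,}
#' and the new state is the old state plus the increments.  The increments
#' are also the model's proxy for the net synaptic input to the two
#' integrating neural populations representing position and velocity, and
#' are the basis of the simulated field potentials.
#'
#' @param state an `estimator_state`.
#' @param y measurement driving the update (position units).
#' @param gains a `kalman_gains` object.
#' @param dt time step (s).
#' @return list with elements `state` (updated), `d_xhat`, `d_vhat`.
#' @export
estimator_step <- function(state, y, gains, dt) {
  if (!is.finite(y)) stop("non-finite measurement", call. = FALSE)
  d_xhat <- -gains$k_pos * state$x_hat + dt * state$v_hat + gains$k_pos * y
  d_vhat <- -gains$k_vel * state$x_hat + gains$k_vel * y
  state$x_hat <- state$x_hat + d_xhat
  state$v_hat <- state$v_hat + d_vhat
  list(state = state, d_xhat = d_xhat, d_vhat = d_vhat)
}

#' Project the position estimate forward over the intrinsic delay
#'
#' The measurement reflects the state one loop delay ago; projecting the
#' estimate forward by the intrinsic delay, `z = x_hat + tau_int * v_hat`,
#' yields the controller's best estimate of the position it is about to
#' act on.
#'
#' @param state an `estimator_state`.
#' @param tau_int intrinsic delay (s).
#' @return projected position estimate (position units).
#' @export
project_estimate <- function(state, tau_int) {
  state$x_hat + tau_int * state$v_hat
}

#' One step of the proportional-integral control law
#'
#' Plain PI law on the stored projected estimate: the integral term
#' accumulates `z * dt` and the command is
#' `u = -k_p * z - k_i * integral_z`.  Inside the full Smith-Predictor loop
#' this law acts on the estimate of current position (the projected
#' noise-state estimate plus the internal copy of the command), which
#' closes the fast internal feedback loop; see [simulate_tracking()].
#'
#' @param state an `estimator_state` whose `z` has been refreshed.
#' @param gains a `pi_gains` object.
#' @param dt time step (s).
#' @return list with `state` (integral updated) and `u` (motor command).
#' @export
pi_step <- function(state, gains, dt) {
  state$integral_z <- state$integral_z + state$z * dt
  u <- -gains$k_p * state$z - gains$k_i * state$integral_z
  list(state = state, u = u)
}
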