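#' Right-hand side of Model 1
#'
#' Time derivative of the smooth part of the Model 1 system at a given
#' state. The medium-replacement impulse of the pulse design is *not*
#' part of the smooth dynamics; it is applied as a discrete event by the
#' simulator (see [apply_medium_replacement()]).
#'
#' The equations, with `kG = (kXG + kXGZ) * G0` derived:
#' \deqn{dY/dt = -(k_{ZY} + k_{XY}) Y + (k_{YZ}/\rho_{ZY}) Z}
#' \deqn{dZ/dt = \rho_{ZY} k_{ZY} Y - (k_{XZ} + k_{YZ}) Z}
#' \deqn{dG/dt = k_G - (k_{XG} + k_{XGZ} e^{-\lambda_{GZ} Z}) G}
#'
#' The back-transfer term uses `kYZ / rhoZY`, the only dimensionally
#' consistent combination given that `rhoZY` converts uM (medium) to
#' pmol/mgprot (cells).
#'
#' @param state Named numeric vector with components `Y` (uM), `Z` and
#'   `G` (pmol/mgprot); all non-negative.
#' @param za A [za_params()] block.
#' @param ag A [model1_ag_params()] block.
#' @return Named numeric vector `c(Y, Z, G)` of time derivatives (per h).
#' @examples
#' za <- za_params(0.007, 0.004, 0.001, 25.46)
#' ag <- model1_ag_params(0.101, 13.25, 0.195, 12.71)
#' model1_rhs(c(Y = 25, Z = 0, G = 12.71), za, ag)
#' @export
model1_rhs <- function(state, za, ag) {
  stopifnot(inherits(za, "za_params"), inherits(ag, "model1_ag_params"))
  s <- check_state(state, c("Y", "Z", "G"))
  kG <- derived_rates(ag)$kG
  c(Y = -(za$kZY + za$kXY) * s[["Y"]] + (za$kYZ / za$rhoZY) * s[["Z"]],
    Z = za$rhoZY * za$kZY * s[["Y"]] - (za$kXZ + za$kYZ) * s[["Z"]],
    G = kG - (ag$kXG + ag$kXGZ * exp(-ag$lambdaGZ * s[["Z"]])) * s[["G"]])
}

#' Right-hand side of Model 2
#'
#' Time derivative of the differential states `(Y, Z, G, B)` of Model 2.
#' The ZA kinetics (`Y`, `Z`) are identical to Model 1. The unbound
#' enzyme percentage is the algebraic variable `U = U0 - B`, substituted
#' exactly rather than integrated:
#' \deqn{dB/dt = k_{BUZ} Z U - k_{UBG} e^{-\lambda_{UBG} G} B}
#' \deqn{dG/dt = k_G - (k_{XGU} U + k_{XG}) G}
#' with `kG = (kXGU * U0 + kXG) * G0` derived.
#'
#' @param state Named numeric vector with components `Y`, `Z`, `G`, `B`;
#'   non-negative and `B <= U0`.
#' @param za A [za_params()] block.
#' @param ag A [model2_ag_params()] block.
#' @return Named numeric vector `c(Y, Z, G, B)` of time derivatives.
#' @examples
#' za <- za_params(0.007, 0.004, 0.001, 25.46)
#' ag <- model2_ag_params(0.081, 0.051, 1.806, 0.099, 0.168, 27.32)
#' model2_rhs(c(Y = 25, Z = 0, G = 27.32, B = 0), za, ag)
#' @export
model2_rhs <- function(state, za, ag) {
  stopifnot(inherits(za, "za_params"), inherits(ag, "model2_ag_params"))
  s <- check_state(state, c("Y", "Z", "G", "B"))
  if (s[["B"]] > ag$U0)
    stop("algebraic constraint violated: B = ", s[["B"]], " exceeds U0 = ",
         ag$U0, call. = FALSE)
  U <- ag$U0 - s[["B"]]
  kG <- derived_rates(ag)$kG
  c(Y = -(za$kZY + za$kXY) * s[["Y"]] + (za$kYZ / za$rhoZY) * s[["Z"]],
    Z = za$rhoZY * za$kZY * s[["Y"]] - (za$kXZ + za$kYZ) * s[["Z"]],
    G = kG - (ag$kXGU * U + ag$kXG) * s[["G"]],
    B = ag$kBUZ * s[["Z"]] * U - ag$kUBG * exp(-ag$lambdaUBG * s[["G"]]) * s[["B"]])
}

# Validate a state vector: right length, finite, non-negative; accepts
# positional vectors and attaches canonical names.
check_state <- function(state, comp) {
  if (length(state) != length(comp))
    stop("state must have components (", paste(comp, collapse = ", "), ")",
         call. = FALSE)
  if (is.null(names(state))) names(state) <- comp
  state <- state[comp]
  if (any(!is.finite(state)))
    stop("state contains non-finite values", call. = FALSE)
  neg <- comp[state < 0]
  if (length(neg))
    stop("negative state component: ", paste(neg, collapse = ", "),
         call. = FALSE)
  state
}
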