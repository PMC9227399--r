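#' Zoledronate kinetic parameter block
#'
#' Parameters of the linear two-compartment ZA sub-model shared by Model 1
#' and Model 2: medium concentration `Y` (uM) and intracellular
#' concentration `Z` (pmol/mgprot).
#'
#' @param kZY Transfer rate from medium to cells (/h).
#' @param kXY Medium ZA loss (degradation) rate (/h).
#' @param kYZ Transfer rate from cell ZA back to the medium (/h).
#' @param rhoZY Conversion factor from uM to pmol/mgprot
#'   (pmol/mgprot per uM); must be strictly positive.
#' @param kXZ Within-cell ZA loss rate (/h). Estimated at zero in the
#'   source experiments.
#' @param Ystar_plus Medium ZA concentration immediately after the
#'   medium replacement of a pulse experiment (uM).
#'
#' @return An object of class `za_params`.
#' @seealso [model1_ag_params()], [model2_ag_params()], [experiment_design()]
#' @examples
#' za_params(kZY = 0.007, kXY = 0.004, kYZ = 0.001, rhoZY = 25.46)
#' @export
za_params <- function(kZY, kXY, kYZ, rhoZY, kXZ = 0, Ystar_plus = 0) {
  p <- list(kZY = kZY, kXY = kXY, kYZ = kYZ, rhoZY = rhoZY,
            kXZ = kXZ, Ystar_plus = Ystar_plus)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0) stop("'", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$rhoZY <= 0) stop("'rhoZY' must be strictly positive", call. = FALSE)
  structure(p, class = "za_params")
}

#' Antigen dynamics parameters, Model 1
#'
#' Model 1 suppresses the IPP elimination rate exponentially with
#' intracellular ZA. The production rate `kG` is never a free quantity: it
#' is derived as `kG = (kXG + kXGZ) * G0 = kXGtot * G0`, which places the
#' antigen pool at steady state before any drug is present.
#'
#' @param kXG Minimal, irreducible antigen elimination rate that persists
#'   even at saturating ZA (/h).
#' @param kXGZ Maximum suppressible antigen elimination rate (/h).
#' @param lambdaGZ Exponential decay rate of the elimination rate with
#'   intracellular ZA (per pmol/mgprot).
#' @param G0 Baseline IPP concentration (pmol/mgprot).
#'
#' @return An object of class `c("model1_ag_params", "ag_params")`.
#' @seealso [derived_rates()], [elimination_rate_limit()]
#' @examples
#' ag <- model1_ag_params(kXG = 0.101, kXGZ = 13.25, lambdaGZ = 0.195, G0 = 12.71)
#' derived_rates(ag)
#' @export
model1_ag_params <- function(kXG, kXGZ, lambdaGZ, G0) {
  p <- list(kXG = kXG, kXGZ = kXGZ, lambdaGZ = lambdaGZ, G0 = G0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  structure(p, class = c("model1_ag_params", "ag_params"))
}

#' Antigen dynamics parameters, Model 2
#'
#' Model 2 tracks the percentage of FPPS bound by ZA (`B`) and its
#' algebraic complement `U = U0 - B`; IPP is eliminated in proportion to
#' the unbound percentage. As in Model 1 the production rate is derived:
#' `kG = (kXGU * U0 + kXG) * G0 = kXGtot * G0`.
#'
#' @param kXG Irreducible antigen elimination rate at zero unbound
#'   enzyme (/h).
#' @param kXGU Antigen elimination rate per percent of unbound
#'   enzyme (/h/%).
#' @param lambdaUBG Exponential decay rate of the bound-enzyme
#'   dissociation rate with IPP concentration (per pmol/mgprot).
#' @param kBUZ Second-order bound-enzyme formation rate
#'   (/h per pmol/mgprot of intracellular ZA).
#' @param kUBG Maximum bound-enzyme dissociation rate (/h).
#' @param G0 Baseline IPP concentration (pmol/mgprot).
#' @param U0 Initial unbound enzyme percentage; fixed at 100.
#'
#' @return An object of class `c("model2_ag_params", "ag_params")`.
#' @examples
#' model2_ag_params(kXG = 0.081, kXGU = 0.051, lambdaUBG = 1.806,
#'                  kBUZ = 0.099, kUBG = 0.168, G0 = 27.32)
#' @export
model2_ag_params <- function(kXG, kXGU, lambdaUBG, kBUZ, kUBG, G0, U0 = 100) {
  p <- list(kXG = kXG, kXGU = kXGU, lambdaUBG = lambdaUBG,
            kBUZ = kBUZ, kUBG = kUBG, G0 = G0, U0 = U0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  if (U0 != 100)
    stop("'U0' is fixed at 100 (enzyme percentages)", call. = FALSE)
  structure(p, class = c("model2_ag_params", "ag_params"))
}

#' Experiment design: dosing mode and sampling grid
#'
#' Describes one in vitro exposure experiment. In `continuous` mode cells
#' sit in ZA-containing medium for the whole observation window; in
#' `pulse` mode the medium is replaced at `t_star` (default 1 h), which
#' the simulator realizes as an instantaneous jump of `Y` down to the
#' post-replacement concentration.
#'
#' @param mode `"continuous"` or `"pulse"`.
#' @param sample_times Strictly increasing observation times (h).
#' @param Y0 Initial medium ZA concentration (uM); the source
#'   experiments use 25 uM.
#' @param t_star Medium-replacement time (h), pulse mode only.
#' @param t_end End of the simulated window (h); defaults to the last
#'   sample time.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design("continuous", sample_times = c(1, 3, 6, 12, 18, 24, 48))
#' @export
experiment_design <- function(mode = c("continuous", "pulse"), sample_times,
                              Y0 = 25, t_star = 1,
                              t_end = max(sample_times)) {
  mode <- match.arg(mode)
  if (!is.numeric(sample_times) || length(sample_times) < 1L)
    stop("'sample_times' must be a non-empty numeric vector", call. = FALSE)
  if (any(diff(sample_times) <= 0))
    stop("'sample_times' must be strictly increasing", call. = FALSE)
  if (any(sample_times < 0) || any(sample_times > t_end))
    stop("'sample_times' must lie within [0, t_end]", call. = FALSE)
  if (Y0 < 0) stop("'Y0' must be non-negative", call. = FALSE)
  if (mode == "pulse" && (t_star <= 0 || t_star >= t_end))
    stop("pulse mode requires 0 < t_star < t_end", call. = FALSE)
  structure(list(mode = mode, Y0 = Y0,
                 t_star = if (mode == "pulse") t_star else NA_real_,
                 t_end = t_end, sample_times = as.numeric(sample_times)),
            class = "experiment_design")
}

#' Derived antigen production and total elimination rates
#'
#' Both antigen sub-models tie the production rate to the baseline pool:
#' `kG = kXGtot * G0`, where the total baseline elimination rate is
#' `kXGtot = kXG + kXGZ` (Model 1) or `kXGtot = kXGU * U0 + kXG`
#' (Model 2). These are pure functions of the parameter block; they are
#' computed, never stored.
#'
#' @param ag A `model1_ag_params` or `model2_ag_params` block.
#' @return A list with components `kG` (pmol/mgprot/h) and `kXGtot` (/h).
#' @examples
#' derived_rates(model1_ag_params(0.101, 13.25, 0.195, 12.71))
#' @export
derived_rates <- function(ag) UseMethod("derived_rates")

#' @export
derived_rates.model1_ag_params <- function(ag) {
  kXGtot <- ag$kXG + ag$kXGZ
  list(kG = kXGtot * ag$G0, kXGtot = kXGtot)
}

#' @export
derived_rates.model2_ag_params <- function(ag) {
  kXGtot <- ag$kXGU * ag$U0 + ag$kXG
  list(kG = kXGtot * ag$G0, kXGtot = kXGtot)
}

#' ZA-dependent antigen elimination rate (Model 1)
#'
#' The instantaneous IPP elimination rate under Model 1,
#' `kXG + kXGZ * exp(-lambdaGZ * Z)`: equal to `kXGtot` at `Z = 0`,
#' monotonically non-increasing in `Z`, and approaching the irreducible
#' floor `kXG` at saturating intracellular ZA.
#'
#' @param ag A `model1_ag_params` block.
#' @param Z Intracellular ZA concentration(s) (pmol/mgprot), `>= 0`.
#' @return Elimination rate(s) (/h), vectorized over `Z`.
#' @examples
#' ag <- model1_ag_params(0.101, 13.25, 0.195, 12.71)
#' elimination_rate_limit(ag, c(0, 1e6))
#' @export
elimination_rate_limit <- function(ag, Z) {
  stopifnot(inherits(ag, "model1_ag_params"))
  if (any(Z < 0)) stop("'Z' must be non-negative", call. = FALSE)
  ag$kXG + ag$kXGZ * exp(-ag$lambdaGZ * Z)
}

#' @export
print.za_params <- function(x, ...) {
  cat("ZA kinetic parameters (/h except rhoZY, Ystar_plus):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.ag_params <- function(x, ...) {
  model <- if (inherits(x, "model1_ag_params")) 1L else 2L
  dr <- derived_rates(x)
  cat(sprintf("Antigen dynamics parameters (Model %d):\n", model))
  print(unlist(x))
  cat(sprintf("derived: kXGtot = %.4g /h, kG = %.4g pmol/mgprot/h\n",
              dr$kXGtot, dr$kG))
  invisible(x)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design: %s, Y0 = %g uM, t_end = %g h\n",
              x$mode, x$Y0, x$t_end))
  if (x$mode == "pulse")
    cat(sprintf("  medium replacement at t* = %g h\n", x$t_star))
  cat("  sample times (h):", paste(x$sample_times, collapse = ", "), "\n")
  invisible(x)
}
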