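#' Generate synthetic observation sets
#'
#' Simulates the true trajectory of a scenario and adds independent
#' Gaussian measurement noise to the intracellular ZA (`Z`) and IPP
#' (`G`) readouts at the design's sample times, matching the i.i.d.
#' normal error structure the least-squares fit assumes. Negative draws
#' are truncated to zero (concentrations) and the truncation count is
#' recorded so studies can verify it stays negligible.
#'
#' By default each variable receives its own noise SD, `sigma_frac`
#' times that variable's trajectory maximum; `Z` (order 1e2) and `G`
#' (order 1e3) differ in scale, and a per-variable SD keeps recovery
#' experiments meaningful for both. `homoscedastic = TRUE` instead
#' applies one shared SD (`sigma_frac` times the larger of the two
#' maxima) to both variables, the literal single-sigma assumption.
#' Explicit `sigma_Z` / `sigma_G` override both.
#'
#' @param model_id 1 or 2.
#' @param za,ag True parameter blocks.
#' @param design An [experiment_design()] (its `sample_times` are the
#'   observation times).
#' @param sigma_Z,sigma_G Noise SDs (same units as the variables); if
#'   `NULL`, derived from `sigma_frac`.
#' @param sigma_frac Noise SD as a fraction of each variable's
#'   trajectory maximum (default 0.02).
#' @param homoscedastic Use one shared SD for both variables.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param step RK4 step for the underlying simulation (h).
#' @return An `observation_set`: a data frame with columns `time`,
#'   `Z_obs`, `G_obs`, carrying the design, the SDs used, the truncation
#'   count and a provenance label as attributes.
#' @examples
#' sc <- scenario_truth("model1_continuous")
#' obs <- generate_observations(1, sc$za, sc$ag, sc$design, seed = 42)
#' obs
#' @export
generate_observations <- function(model_id, za, ag, design,
                                  sigma_Z = NULL, sigma_G = NULL,
                                  sigma_frac = 0.02, homoscedastic = FALSE,
                                  seed = 1, step = 0.01) {
  traj <- simulate_experiment(model_id, za, ag, design, step = step)
  truth <- trajectory_at(traj, design$sample_times)
  if (is.null(sigma_Z) || is.null(sigma_G)) {
    maxZ <- max(traj$states[, "Z"])
    maxG <- max(traj$states[, "G"])
    if (homoscedastic) {
      sig <- sigma_frac * max(maxZ, maxG)
      if (is.null(sigma_Z)) sigma_Z <- sig
      if (is.null(sigma_G)) sigma_G <- sig
    } else {
      if (is.null(sigma_Z)) sigma_Z <- sigma_frac * maxZ
      if (is.null(sigma_G)) sigma_G <- sigma_frac * maxG
    }
  }
  if (sigma_Z < 0 || sigma_G < 0)
    stop("noise SDs must be non-negative", call. = FALSE)

  n <- length(design$sample_times)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  Z_obs <- truth$Z + rnorm(n, 0, sigma_Z)
  G_obs <- truth$G + rnorm(n, 0, sigma_G)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  n_trunc <- sum(Z_obs < 0) + sum(G_obs < 0)
  Z_obs <- pmax(Z_obs, 0)
  G_obs <- pmax(G_obs, 0)
  observation_set(design$sample_times, Z_obs, G_obs, design,
                  sigma_Z = sigma_Z, sigma_G = sigma_G,
                  n_truncated = n_trunc,
                  provenance = sprintf("synthetic model%d %s seed=%d",
                                       model_id, design$mode,
                                       as.integer(seed)))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' Construct an observation set
#'
#' @param time Observation times (h), within the design window.
#' @param Z_obs,G_obs Observed intracellular ZA / IPP concentrations
#'   (pmol/mgprot); `NA` marks a missing reading, but each record must
#'   have at least one of the two.
#' @param design The [experiment_design()] the observations belong to.
#' @param sigma_Z,sigma_G Noise SDs, when known (generator output).
#' @param n_truncated Count of negative draws truncated to zero.
#' @param provenance Free-text label.
#' @return A data frame of class `observation_set`.
#' @export
observation_set <- function(time, Z_obs, G_obs, design,
                            sigma_Z = NA_real_, sigma_G = NA_real_,
                            n_truncated = 0L, provenance = "") {
  stopifnot(inherits(design, "experiment_design"))
  if (length(time) != length(Z_obs) || length(time) != length(G_obs))
    stop("'time', 'Z_obs', 'G_obs' must have equal length", call. = FALSE)
  if (any(time < 0 | time > design$t_end))
    stop("observation times must lie within [0, t_end]", call. = FALSE)
  if (any(is.na(Z_obs) & is.na(G_obs)))
    stop("each record needs at least one non-missing value", call. = FALSE)
  if (any(Z_obs < 0, na.rm = TRUE) || any(G_obs < 0, na.rm = TRUE))
    stop("observed concentrations must be non-negative", call. = FALSE)
  df <- data.frame(time = as.numeric(time), Z_obs = as.numeric(Z_obs),
                   G_obs = as.numeric(G_obs))
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, design = design, sigma_Z = sigma_Z, sigma_G = sigma_G,
            n_truncated = as.integer(n_truncated), provenance = provenance,
            class = c("observation_set", "data.frame"))
}

#' Read / write observation sets as CSV
#'
#' The on-disk format has columns `time_h, Z_obs, G_obs` with empty
#' cells for missing readings, comma separator and `.` decimal mark.
#'
#' @param obs An `observation_set`.
#' @param path File path.
#' @param design Design to attach on read (the CSV itself carries only
#'   the measurements).
#' @return `read_observations()` returns an `observation_set`;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  df <- data.frame(time_h = obs$time, Z_obs = obs$Z_obs, G_obs = obs$G_obs)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path, design) {
  df <- read.csv(path)
  need <- c("time_h", "Z_obs", "G_obs")
  if (!all(need %in% names(df)))
    stop("observation CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  observation_set(df$time_h, df$Z_obs, df$G_obs, design,
                  provenance = path)
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set (%d records, %s): %s\n", nrow(x),
              attr(x, "design")$mode, attr(x, "provenance")))
  if (!is.na(attr(x, "sigma_Z")))
    cat(sprintf("  sigma_Z = %.4g, sigma_G = %.4g, truncated = %d\n",
                attr(x, "sigma_Z"), attr(x, "sigma_G"),
                attr(x, "n_truncated")))
  print.data.frame(x)
  invisible(x)
}
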