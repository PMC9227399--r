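#' Sampling grids of the source uptake experiments
#'
#' The observation schedules of the two published in vitro studies the
#' models were built on: an MCF7 continuous-exposure series and two
#' pulse (1 h exposure, then medium replacement) series on MCF7 and T47D
#' cells. All start from 25 uM ZA in the medium.
#'
#' @param name One of `"raikkonen_continuous"` (samples at
#'   1, 3, 6, 12, 18, 24, 48 h), `"raikkonen_pulse"` (0, 1, 3, 6, 12,
#'   18, 24, 48 h) or `"benzaid_pulse"` (0, 4, 8, 12, 24, 42 h). Pulse
#'   grids use a 1 h replacement time.
#' @return An [experiment_design()].
#' @examples
#' sampling_grid("benzaid_pulse")
#' @export
sampling_grid <- function(name = c("raikkonen_continuous", "raikkonen_pulse",
                                   "benzaid_pulse")) {
  name <- match.arg(name)
  switch(name,
    raikkonen_continuous = experiment_design(
      "continuous", sample_times = c(1, 3, 6, 12, 18, 24, 48), Y0 = 25),
    raikkonen_pulse = experiment_design(
      "pulse", sample_times = c(0, 1, 3, 6, 12, 18, 24, 48),
      Y0 = 25, t_star = 1),
    benzaid_pulse = experiment_design(
      "pulse", sample_times = c(0, 4, 8, 12, 24, 42), Y0 = 25, t_star = 1))
}

#' Reference parameter scenarios
#'
#' Loads one of the four shipped parameter scenarios — the published
#' estimates for each model under each dosing mode — as the ground truth
#' for simulation and parameter-recovery studies.
#'
#' @param name One of `"model1_continuous"`, `"model1_pulse"`,
#'   `"model2_continuous"`, `"model2_pulse"`.
#' @return A list with components `model_id`, `za` ([za_params()]),
#'   `ag` (antigen block), `design` ([experiment_design()]) and `label`.
#' @examples
#' sc <- scenario_truth("model1_continuous")
#' derived_rates(sc$ag)
#' @export
scenario_truth <- function(name = c("model1_continuous", "model1_pulse",
                                    "model2_continuous", "model2_pulse")) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios", paste0(name, ".json"),
                      package = "zaipp", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  za <- do.call(za_params, raw$za)
  ag <- if (raw$model_id == 1) do.call(model1_ag_params, raw$ag)
        else do.call(model2_ag_params, raw$ag)
  design <- do.call(experiment_design, raw$design)
  list(model_id = as.integer(raw$model_id), za = za, ag = ag,
       design = design, label = raw$label, name = name)
}
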