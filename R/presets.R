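#' Calibrated per-model configuration presets
#'
#' Returns the package's calibrated configuration for each migration model.
#' Exact parameter values for the published models are calibration choices of
#' this package (see the methods vignette for the rationale); they were tuned
#' so each model reproduces its characteristic density behavior at desk
#' scale: the base model is Brownian; basic persistence gains speed with
#' density through cell merging without gaining persistence time; the Act
#' model loses speed with density; the plain pseudopod model loses speed with
#' density; and the extended pseudopod model (tip adhesion + pulling +
#' poof-dir touch handling) gains both speed and persistence time with
#' density.
#'
#' @param model one of `"base"`, `"persistence"`, `"act"`, `"ariotti"`,
#'   `"pseudopod-ext"`.
#' @param ... further overrides forwarded to [cpm_config()].
#' @return a validated [cpm_config()].
#' @export
model_preset <- function(model = c("base", "persistence", "act", "ariotti",
                                   "pseudopod-ext"), ...) {
  model <- match.arg(model)
  args <- switch(model,
    base = list(),
    persistence = list(
      "j-cell-cell" = 4,           # cohesive: merging drives the speed rise
      "lambda-persistence" = 0.015, # weak coupling: no emergent flocking
      "decay-time" = 2),
    act = list(
      "j-cell-cell" = 30,          # dispersive contacts: crowding obstructs
      "lambda-act" = 80,
      "max-act" = 40,
      "lambda-v" = 2),
    ariotti = list(
      "j-cell-cell" = 6),
    "pseudopod-ext" = list(
      "j-cell-cell" = 6,
      "j-cell-medium" = 12,
      "pull-strength" = 60,
      "tip-bonus" = 60,
      "max-distance-for-tip-bonus" = 3,
      "touch-behavior" = "poof-dir")
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cpm_config, c(list(model = model), args))
}
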