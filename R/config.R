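# Simulation configuration: flat key-value files, defaults, validation.

.config_keys <- function() {
  list(
    # lattice / run control
    "lattice-width"        = 150,
    "lattice-height"       = 150,
    "cell-count"           = 30,
    "total-mcs"            = 5000,
    "equilibration-mcs"    = 1000,
    "sample-interval"      = 1,
    "snapshot-interval"    = 0,
    "temperature"          = 15,
    "connectivity-constraint" = FALSE,
    "model"                = "base",
    # base energies (calibration choices; see the methods vignette)
    "j-cell-cell"          = 6,
    "j-cell-medium"        = 8,
    "lambda-v"             = 1,
    "target-area"          = 250,
    # basic persistence
    "lambda-persistence"   = 0.05,
    "decay-time"           = 10,
    # Act model
    "lambda-act"           = 200,
    "max-act"              = 40,
    # pseudopod finite-state machine
    "n-pseudopods"         = 3,
    "p-ext"                = 0.3,
    "p-retr"               = 0.3,
    "init-dir-strength"    = 2,
    "cont-dir-strength"    = 5,
    "max-growth-time"      = 60,
    "time-between-extensions" = 10,
    "retraction-mode"      = "backward",
    "neighboring-actin-bonus" = 50,
    "movement-decay-time"  = 10,
    # proposed extensions
    "pull-strength"        = 0,
    "tip-bonus"            = 0,
    "max-distance-for-tip-bonus" = 3,
    "touch-behavior"       = "nothing",
    "p-touch-retr"         = 0.1,
    "lateral-threshold"    = 0.85
  )
}

.models <- c("base", "persistence", "act", "ariotti", "pseudopod-ext")
.touch_behaviors <- c("nothing", "retract", "attach", "poof-dir")
.retraction_modes <- c("backward", "forward")

#' Build a simulation configuration
#'
#' Returns the default configuration, optionally overridden by named
#' arguments using the hyphenated key names also used in config files
#' (e.g. `cpm_config("cell-count" = 60, model = "act")`). Unknown keys are
#' an error naming the nearest valid key.
#'
#' @param ... named overrides of default keys.
#' @return a named list of class `cpm_config`.
#' @export
cpm_config <- function(...) {
  cfg <- .config_keys()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all configuration overrides must be named")
  }
  for (k in names(over)) {
    if (!k %in% names(cfg)) {
      d <- adist(k, names(cfg))
      stop(sprintf("unknown configuration key '%s'; did you mean '%s'?",
                   k, names(cfg)[which.min(d)]))
    }
    cfg[[k]] <- over[[k]]
  }
  class(cfg) <- "cpm_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks types, ranges (temperature > 0, probabilities in \[0, 1\],
#' total MCS > equilibration MCS >= 0) and enum values.
#'
#' @param config a `cpm_config` list.
#' @return the validated config, invisibly usable in pipelines.
#' @export
validate_config <- function(config) {
  c_ <- function(k) config[[k]]
  if (c_("temperature") <= 0) stop("temperature must be > 0")
  if (c_("equilibration-mcs") < 0) stop("equilibration-mcs must be >= 0")
  if (c_("total-mcs") <= c_("equilibration-mcs")) {
    stop("total-mcs must exceed equilibration-mcs")
  }
  if (c_("sample-interval") < 1) stop("sample-interval must be >= 1")
  for (k in c("p-ext", "p-retr", "p-touch-retr")) {
    if (c_(k) < 0 || c_(k) > 1) stop(k, " must be in [0, 1]")
  }
  if (!c_("model") %in% .models) {
    stop("model must be one of: ", paste(.models, collapse = ", "))
  }
  if (!c_("touch-behavior") %in% .touch_behaviors) {
    stop("touch-behavior must be one of: ",
         paste(.touch_behaviors, collapse = ", "))
  }
  if (!c_("retraction-mode") %in% .retraction_modes) {
    stop("retraction-mode must be one of: ",
         paste(.retraction_modes, collapse = ", "))
  }
  if (c_("max-distance-for-tip-bonus") <= 0) {
    stop("max-distance-for-tip-bonus must be > 0")
  }
  if (c_("cell-count") > c_("lattice-width") * c_("lattice-height")) {
    stop("cell-count exceeds lattice capacity")
  }
  config
}

#' Read a simulation configuration file
#'
#' Flat `key = value` lines; `#` starts a comment; blank lines ignored.
#' Unknown keys are an error naming the nearest valid key; keys not present
#' keep their documented defaults.
#'
#' @param path file path.
#' @return a validated `cpm_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop(sprintf("parse error in %s at line '%s': expected 'key = value'",
                   path, lines[i]))
    }
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    over[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else {
      val
    }
  }
  do.call(cpm_config, over)
}

#' Write a configuration to a file
#'
#' @param config a `cpm_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.logical(v)) tolower(as.character(v)) else as.character(v)
  }, character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}

#' @export
print.cpm_config <- function(x, ...) {
  cat("CPM configuration (model:", x[["model"]], ")\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, x[[k]]))
  invisible(x)
}
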