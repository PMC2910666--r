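# Configuration handling. The canonical configuration is a nested named
# list mirroring model_spec(); JSON is the on-disk dialect. Keys:
#
#   preset                         optional preset to start from
#   normal.rate/.capacity/.shape   normal-cell growth law
#   tumor.rate/.capacity/.shape    tumor growth law
#   interaction.enabled/.variant/.beta/.k/.t_crit/.rho0/.rho1/.k_scale/.hill_m
#   drug.mode/.u0/.d/.m/.a_N/.a_T/.t_rx/.lumped_kill_N/.lumped_kill_T
#   init.N0/.T0
#   t_end, dt, therapy_trigger
#   output.timeseries/.summary/.plot   optional output paths
#
# Unknown keys are rejected; every unspecified key defaults to the
# fig1_right preset, so an empty config is runnable.

config_schema <- list(
  normal = c("rate", "capacity", "shape"),
  tumor = c("rate", "capacity", "shape"),
  interaction = c("enabled", "variant", "beta", "k", "t_crit", "rho0",
                  "rho1", "k_scale", "hill_m"),
  drug = c("mode", "u0", "d", "m", "a_N", "a_T", "t_rx",
           "lumped_kill_N", "lumped_kill_T"),
  init = c("N0", "T0"),
  t_end = NULL, dt = NULL, therapy_trigger = NULL,
  output = c("timeseries", "summary", "plot")
)

character_keys <- c("interaction.variant", "drug.mode", "therapy_trigger",
                    "preset", "output.timeseries", "output.summary",
                    "output.plot")
logical_keys <- "interaction.enabled"

# Fixed key order, numeric coercion, NULL optional keys dropped. Keeps the
# echoed configuration bit-identical across a JSON round trip.
canonicalize_config <- function(cfg) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  law <- function(l) list(rate = num(l$rate), capacity = num(l$capacity),
                          shape = num(l$shape))
  out <- list(
    normal = law(cfg$normal),
    tumor = law(cfg$tumor),
    interaction = c(
      list(enabled = isTRUE(cfg$interaction$enabled)),
      if (isTRUE(cfg$interaction$enabled)) list(
        variant = as.character(cfg$interaction$variant),
        beta = num(cfg$interaction$beta),
        k = num(cfg$interaction$k),
        t_crit = num(cfg$interaction$t_crit),
        rho0 = num(cfg$interaction$rho0),
        rho1 = num(cfg$interaction$rho1),
        k_scale = num(cfg$interaction$k_scale),
        hill_m = num(cfg$interaction$hill_m))),
    drug = c(
      list(mode = as.character(cfg$drug$mode)),
      if (cfg$drug$mode != "none") list(
        u0 = num(cfg$drug$u0), d = num(cfg$drug$d), m = num(cfg$drug$m),
        a_N = num(cfg$drug$a_N), a_T = num(cfg$drug$a_T),
        t_rx = num(cfg$drug$t_rx)),
      if (!is.null(cfg$drug$lumped_kill_N))
        list(lumped_kill_N = num(cfg$drug$lumped_kill_N)),
      if (!is.null(cfg$drug$lumped_kill_T))
        list(lumped_kill_T = num(cfg$drug$lumped_kill_T))),
    init = list(N0 = num(cfg$init$N0), T0 = num(cfg$init$T0)),
    t_end = num(cfg$t_end),
    dt = num(cfg$dt),
    therapy_trigger = as.character(cfg$therapy_trigger)
  )
  out
}

# Resolved canonical configuration of a model spec.
model_to_config <- function(spec) {
  stopifnot(inherits(spec, "conjoint_model"))
  ia <- spec$interaction
  drug <- spec$drug
  canonicalize_config(list(
    normal = spec$normal[c("rate", "capacity", "shape")],
    tumor = spec$tumor[c("rate", "capacity", "shape")],
    interaction = if (is.null(ia)) list(enabled = FALSE) else
      c(list(enabled = TRUE), ia[c("variant", "beta", "k", "t_crit",
                                   "rho0", "rho1", "k_scale", "hill_m")]),
    drug = drug[!vapply(drug, is.null, logical(1))],
    init = list(N0 = spec$N0, T0 = spec$T0),
    t_end = spec$t_end, dt = spec$dt,
    therapy_trigger = spec$therapy_trigger))
}

# Build (and thereby validate) a model spec from a canonical configuration.
config_to_model <- function(cfg) {
  ia <- NULL
  if (isTRUE(cfg$interaction$enabled))
    ia <- interaction_params(beta = cfg$interaction$beta,
                             k = cfg$interaction$k,
                             t_crit = cfg$interaction$t_crit,
                             rho0 = cfg$interaction$rho0,
                             rho1 = cfg$interaction$rho1,
                             k_scale = cfg$interaction$k_scale,
                             variant = cfg$interaction$variant,
                             hill_m = cfg$interaction$hill_m)
  d <- cfg$drug
  drug <- if (d$mode == "none") drug_program("none") else
    drug_program(mode = d$mode, u0 = d$u0, d = d$d, m = d$m,
                 a_N = d$a_N, a_T = d$a_T, t_rx = d$t_rx,
                 lumped_kill_N = d$lumped_kill_N,
                 lumped_kill_T = d$lumped_kill_T)
  model_spec(normal = growth_law(cfg$normal$rate, cfg$normal$capacity,
                                 cfg$normal$shape),
             tumor = growth_law(cfg$tumor$rate, cfg$tumor$capacity,
                                cfg$tumor$shape),
             interaction = ia, drug = drug,
             N0 = cfg$init$N0, T0 = cfg$init$T0,
             t_end = cfg$t_end, dt = cfg$dt,
             therapy_trigger = cfg$therapy_trigger)
}

reject_unknown_keys <- function(x, prefix = NULL) {
  allowed <- c(names(config_schema), "preset")
  if (!is.null(prefix)) allowed <- config_schema[[prefix]]
  nm <- names(x)
  if (length(x) && (is.null(nm) || any(nm == "")))
    stop("configuration entries must be named", call. = FALSE)
  bad <- setdiff(nm, allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(bad) > 1) "s" else "",
                 paste(if (is.null(prefix)) bad
                       else paste(prefix, bad, sep = "."), collapse = ", ")),
         call. = FALSE)
  for (k in intersect(nm, names(config_schema))) {
    if (!is.null(config_schema[[k]]) && is.list(x[[k]]))
      reject_unknown_keys(x[[k]], prefix = k)
  }
  invisible(TRUE)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else
      base[[nm]] <- user[[nm]]
  }
  base
}

default_output <- function() list(timeseries = NULL, summary = NULL, plot = NULL)

#' Read a run configuration
#'
#' Parses a JSON configuration, fills every unspecified field from its base
#' (the `preset` named in the file, or `fig1_right` when none is named),
#' validates all invariants and returns the fully resolved configuration.
#' Unknown keys are rejected by name. Writing a resolved configuration with
#' [write_config()] and reading it back is the identity.
#'
#' @param path Path to a JSON configuration file.
#' @return An object of class `conjoint_config`: a list with `model` (the
#'   canonical nested parameter list), `output` (paths for `timeseries`,
#'   `summary`, `plot`; `NULL` when unset) and `preset` (base preset name or
#'   `NULL`).
#' @examples
#' path <- tempfile(fileext = ".json")
#' writeLines('{"drug": {"mode": "exp_decay", "u0": 3, "d": 0.5, "a_T": 0.1}}', path)
#' cfg <- read_config(path)
#' cfg$model$drug$u0
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(user)) stop("config must be a JSON object", call. = FALSE)
  reject_unknown_keys(user)
  preset <- user$preset
  user$preset <- NULL
  output <- merge_config(default_output(), if (is.list(user$output)) user$output else list())
  user$output <- NULL
  base <- model_to_config(get_preset(if (is.null(preset)) "fig1_right" else preset))
  cfg <- merge_config(base, user)
  cfg <- canonicalize_config(cfg)
  config_to_model(cfg)   # validate invariants
  structure(list(model = cfg, output = output, preset = preset),
            class = "conjoint_config")
}

#' Write a run configuration
#'
#' Serializes a resolved configuration (or the configuration echoed by
#' [run_scenario()]) to JSON at full precision.
#'
#' @param cfg A `conjoint_config`, or a bare canonical model configuration
#'   list (as in the `config` element of a scenario result).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  body <- if (inherits(cfg, "conjoint_config")) {
    out <- cfg$model
    keep <- !vapply(cfg$output, is.null, logical(1))
    if (any(keep)) out$output <- cfg$output[keep]
    if (!is.null(cfg$preset)) out <- c(list(preset = cfg$preset), out)
    out
  } else cfg
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# Apply dotted-key overrides to a canonical configuration. Bare leaf names
# that are unambiguous (e.g. "beta", "u0", "N0") are accepted as shorthand.
apply_overrides <- function(cfg, overrides) {
  if (!length(overrides)) return(cfg)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be a named list", call. = FALSE)
  shorthand <- c(
    stats::setNames(paste0("interaction.",
                           c("enabled", "variant", "beta", "k", "t_crit",
                             "rho0", "rho1", "k_scale", "hill_m")),
                    c("enabled", "variant", "beta", "k", "t_crit",
                      "rho0", "rho1", "k_scale", "hill_m")),
    stats::setNames(paste0("drug.", c("mode", "u0", "d", "m", "a_N", "a_T",
                                      "t_rx", "lumped_kill_N", "lumped_kill_T")),
                    c("mode", "u0", "d", "m", "a_N", "a_T",
                      "t_rx", "lumped_kill_N", "lumped_kill_T")),
    N0 = "init.N0", T0 = "init.T0")
  for (nm in names(overrides)) {
    key <- if (grepl(".", nm, fixed = TRUE)) nm
           else if (nm %in% c("t_end", "dt", "therapy_trigger")) nm
           else if (nm %in% names(shorthand)) shorthand[[nm]]
           else stop(sprintf("unknown override key: %s", nm), call. = FALSE)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (!(parts[1] %in% names(config_schema)) ||
        (length(parts) == 2 && !(parts[2] %in% config_schema[[parts[1]]])) ||
        length(parts) > 2)
      stop(sprintf("unknown override key: %s", key), call. = FALSE)
    val <- overrides[[nm]]
    if (key %in% character_keys) val <- as.character(val)
    else if (key %in% logical_keys) val <- as.logical(val)
    else val <- as.numeric(val)
    if (length(parts) == 1) cfg[[parts]] <- val else cfg[[parts[1]]][[parts[2]]] <- val
  }
  canonicalize_config(cfg)
}
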