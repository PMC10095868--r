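#' Default scenario parameters
#'
#' The full resolved default configuration as a nested list: elastic wall,
#' Maxwell--Boltzmann S-curve influx, V0 = 3,691 um^3, total influx
#' 912 um^3 over 3,600 s, water bulk modulus 2,200 MPa, 1-s time step.
#' Entries left `NULL` here are resolved at load time from the other values
#' (`influx.scale_s` from the shape, `influx.midpoint_s` for the logistic,
#' `sim.t_total_s` from the wall model: 7,200 s, or 18,000 s for a
#' viscoelastic wall so relaxation with tau = 100 min completes).
#'
#' @return Nested named list of configuration keys.
#' @export
default_config <- function() {
  list(
    influx = list(
      shape = "mb_cdf",
      dv_total_um3 = 912,
      t_influx_s = 3600,
      scale_s = NULL,
      midpoint_s = NULL
    ),
    wall = list(
      model = "elastic",
      E_MPa = 100,
      E_inst_MPa = 10000,
      E_eq_MPa = 77,
      nu = 0.3,
      d_um = 10,
      t_w_um = 0.5,
      tau_s = 6000
    ),
    fluid = list(K_MPa = 2200),
    sim = list(
      v0_um3 = 3691,
      dt_s = 1,
      t_total_s = NULL,
      solver = "closed_form",
      tol = 1e-9,
      max_iter = 100
    ),
    baseline_p0_MPa = 0
  )
}

# Keys a user may set, and which of them are irrelevant per wall model
# (setting an irrelevant key is a warning, not an error).
.config_schema <- function() {
  list(
    influx = c("shape", "dv_total_um3", "t_influx_s", "scale_s", "midpoint_s"),
    wall = c("model", "E_MPa", "E_inst_MPa", "E_eq_MPa", "nu", "d_um",
             "t_w_um", "tau_s"),
    fluid = "K_MPa",
    sim = c("v0_um3", "dt_s", "t_total_s", "solver", "tol", "max_iter"),
    baseline_p0_MPa = character(0)
  )
}

.irrelevant_wall_keys <- function(model) {
  switch(model,
    soft = c("E_MPa", "E_inst_MPa", "E_eq_MPa", "tau_s", "nu"),
    rigid = c("E_MPa", "E_inst_MPa", "E_eq_MPa", "tau_s", "nu"),
    elastic = c("E_inst_MPa", "E_eq_MPa", "tau_s"),
    viscoelastic = "E_MPa"
  )
}

#' Load, validate and resolve a scenario configuration
#'
#' Reads a YAML configuration document (or starts from the defaults if
#' `path` is `NULL`), applies flat dotted-key overrides (e.g.
#' `list("wall.model" = "rigid")`, overrides win over file values), rejects
#' unknown keys by name, fills unset keys with documented defaults, validates
#' every type invariant naming the offending key, and builds the simulation
#' objects. Keys that the chosen wall model ignores trigger a warning when
#' explicitly set, never a failure. The returned `echo` contains every
#' resolved value actually used, so a run is reproducible from the echo alone.
#'
#' @param path Path to a YAML document, or `NULL` for pure defaults.
#' @param overrides Named list or character-named vector of flat
#'   `section.key = value` overrides.
#' @return A list with elements `cfg` ([simulation_config()]),
#'   `schedule` ([influx_schedule()]), `wall` ([wall_parameters()]),
#'   `fluid` ([fluid_parameters()]), `p0` (baseline turgor, MPa) and
#'   `echo` (fully resolved nested configuration).
#' @examples
#' sc <- load_config(overrides = list("wall.model" = "soft"))
#' sc$echo$wall$model
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    user <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) stop(sprintf("failed to parse config %s: %s",
                                       path, conditionMessage(e)),
                               call. = FALSE)
    )
    if (is.null(user)) user <- list()
    if (!is.list(user)) {
      stop(sprintf("config %s must be a key-value mapping", path),
           call. = FALSE)
    }
  }

  schema <- .config_schema()

  # Track which keys the user set explicitly (file or override), for the
  # irrelevant-key leniency warning.
  set_keys <- character(0)
  for (sec in names(user)) {
    if (!sec %in% names(schema)) {
      stop(sprintf("unknown config key: %s", sec), call. = FALSE)
    }
    if (length(schema[[sec]]) == 0L) { # scalar top-level key
      set_keys <- c(set_keys, sec)
      next
    }
    if (!is.list(user[[sec]])) {
      stop(sprintf("config key %s must be a mapping", sec), call. = FALSE)
    }
    for (k in names(user[[sec]])) {
      if (!k %in% schema[[sec]]) {
        stop(sprintf("unknown config key: %s.%s", sec, k), call. = FALSE)
      }
      set_keys <- c(set_keys, paste0(sec, ".", k))
    }
  }

  # Merge: defaults <- file <- overrides.
  conf <- default_config()
  for (sec in names(user)) {
    if (length(schema[[sec]]) == 0L) {
      conf[[sec]] <- user[[sec]]
    } else {
      for (k in names(user[[sec]])) conf[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  if (length(overrides)) {
    ov <- as.list(overrides)
    if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
      stop("`overrides` must be a fully named list of dotted keys",
           call. = FALSE)
    }
    for (key in names(ov)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1L) {
        if (!(parts %in% names(schema)) || length(schema[[parts]]) != 0L) {
          stop(sprintf("unknown config key: %s", key), call. = FALSE)
        }
        conf[[parts]] <- ov[[key]]
      } else if (length(parts) == 2L && parts[1] %in% names(schema) &&
                 parts[2] %in% schema[[parts[1]]]) {
        conf[[parts[1]]][[parts[2]]] <- ov[[key]]
      } else {
        stop(sprintf("unknown config key: %s", key), call. = FALSE)
      }
      set_keys <- c(set_keys, key)
    }
  }

  .build_scenario(conf, set_keys)
}

# Validate a merged configuration list and construct the scenario objects.
.build_scenario <- function(conf, set_keys = character(0)) {
  fail <- function(key, why) {
    stop(sprintf("invalid value for %s: %s", key, why), call. = FALSE)
  }
  num <- function(sec, key, lo = -Inf, hi = Inf, lo_open = TRUE) {
    x <- conf[[sec]][[key]]
    full <- paste0(sec, ".", key)
    if (is.null(x)) return(NULL)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      fail(full, "must be a single finite number")
    }
    if ((lo_open && x <= lo) || x < lo || x > hi) {
      fail(full, sprintf("must lie in %s%g, %g]", if (lo_open) "(" else "[",
                         lo, hi))
    }
    as.numeric(x)
  }

  model <- conf$wall$model
  if (!is.character(model) || length(model) != 1L ||
      !model %in% c("soft", "rigid", "elastic", "viscoelastic")) {
    fail("wall.model",
         "must be one of soft, rigid, elastic, viscoelastic")
  }
  ignored <- intersect(
    paste0("wall.", .irrelevant_wall_keys(model)),
    set_keys
  )
  if (length(ignored)) {
    warning(sprintf("config key(s) %s ignored for wall.model = \"%s\"",
                    paste(ignored, collapse = ", "), model), call. = FALSE)
  }

  shape <- conf$influx$shape
  if (!is.character(shape) || length(shape) != 1L ||
      !shape %in% c("mb_cdf", "sat_exp", "logistic")) {
    fail("influx.shape", "must be one of mb_cdf, sat_exp, logistic")
  }

  dv <- num("influx", "dv_total_um3", lo = 0)
  t_inf <- num("influx", "t_influx_s", lo = 0)
  scale <- num("influx", "scale_s", lo = 0)
  midpoint <- conf$influx$midpoint_s
  if (!is.null(midpoint)) midpoint <- num("influx", "midpoint_s")

  nu <- conf$wall$nu
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu > 0.5) {
    fail("wall.nu", "must lie in [0, 0.5]")
  }
  wall <- wall_parameters(
    model = model,
    E = num("wall", "E_MPa", lo = 0),
    E_inst = num("wall", "E_inst_MPa", lo = 0),
    E_eq = num("wall", "E_eq_MPa", lo = 0),
    nu = nu,
    d = num("wall", "d_um", lo = 0),
    t_w = num("wall", "t_w_um", lo = 0),
    tau = num("wall", "tau_s", lo = 0)
  )

  fluid <- fluid_parameters(K = num("fluid", "K_MPa", lo = 0))

  t_total <- num("sim", "t_total_s", lo = 0)
  if (is.null(t_total)) {
    t_total <- if (model == "viscoelastic") 18000 else 7200
  }
  solver <- conf$sim$solver
  if (!is.character(solver) || length(solver) != 1L ||
      !solver %in% c("closed_form", "fixed_point")) {
    fail("sim.solver", "must be closed_form or fixed_point")
  }
  cfg <- simulation_config(
    v0 = num("sim", "v0_um3", lo = 0),
    dt = num("sim", "dt_s", lo = 0),
    t_total = t_total,
    solver = solver,
    tol = num("sim", "tol", lo = 0),
    max_iter = num("sim", "max_iter", lo = 1, lo_open = FALSE)
  )

  schedule <- influx_schedule(shape, dv_total = dv, t_influx = t_inf,
                              scale = scale, midpoint = midpoint)

  p0 <- conf$baseline_p0_MPa
  if (!is.numeric(p0) || length(p0) != 1L || !is.finite(p0) || p0 < 0) {
    fail("baseline_p0_MPa", "must be a single number >= 0")
  }

  echo <- conf
  echo$influx$scale_s <- schedule$scale
  echo$influx$midpoint_s <- if (shape == "logistic") schedule$midpoint else NULL
  echo$sim$t_total_s <- t_total
  echo$baseline_p0_MPa <- as.numeric(p0)

  list(cfg = cfg, schedule = schedule, wall = wall, fluid = fluid,
       p0 = as.numeric(p0), echo = echo)
}

#' Scenario presets: wall rheology x influx family
#'
#' Eight canonical scenarios combining the two influx families with the four
#' wall rheologies. `fig1*` presets use the S-curve (`mb_cdf`) influx and
#' `fig2*` the saturating-exponential (`sat_exp`) influx; the letter selects
#' the wall: `b` soft, `c` rigid, `d` elastic, `e` viscoelastic.
#'
#' @param name One of `"fig1b"`, `"fig1c"`, `"fig1d"`, `"fig1e"`,
#'   `"fig2b"`, `"fig2c"`, `"fig2d"`, `"fig2e"`.
#' @return The flat override list defining the preset, usable as the
#'   `overrides` argument of [load_config()].
#' @export
preset_overrides <- function(name) {
  presets <- c("fig1b", "fig1c", "fig1d", "fig1e",
               "fig2b", "fig2c", "fig2d", "fig2e")
  if (!is.character(name) || length(name) != 1L || !name %in% presets) {
    stop(sprintf("unknown preset \"%s\"; available: %s",
                 as.character(name)[1], paste(presets, collapse = ", ")),
         call. = FALSE)
  }
  shape <- if (substr(name, 4, 4) == "1") "mb_cdf" else "sat_exp"
  model <- switch(substr(name, 5, 5),
                  b = "soft", c = "rigid", d = "elastic", e = "viscoelastic")
  list("influx.shape" = shape, "wall.model" = model)
}
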