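#' Guard-cell wall constitutive parameters
#'
#' The guard-cell lumen is idealized as a thin-walled cylinder of internal
#' diameter `d` and wall thickness `t_w`. Four wall rheologies are supported:
#'
#' * `"soft"` — zero stiffness: the wall offers no resistance, the cell
#'   expands exactly by the water taken up and turgor stays at the baseline.
#' * `"rigid"` — infinite stiffness: the lumen volume is fixed and all influx
#'   compresses the fluid.
#' * `"elastic"` — homogeneous, isotropic, linear elastic wall with Young's
#'   modulus `E` and Poisson's ratio `nu`. The volumetric strain per unit
#'   internal pressure of a thin cylinder is
#'   `C = d * (5 - 4 nu) / (4 t_w E)` (the thin-cylinder volumetric-strain coefficient).
#' * `"viscoelastic"` — a standard linear solid: an instantaneous elastic
#'   response with modulus `E_inst` plus a Kelvin (spring-dashpot in
#'   parallel) delayed branch that relaxes toward the equilibrium modulus
#'   `E_eq` with retardation time `tau`. The delayed volumetric strain obeys
#'   `eps(t) = C_delay * p * (1 - exp(-t/tau))` under constant pressure, with
#'   `C_delay = C_eq - C_inst`. Setting `E_inst` effectively infinite
#'   recovers a pure Kelvin--Voigt wall (no instantaneous compliance).
#'
#' Moduli are in MPa, geometry in um, `tau` in seconds. Soft and rigid walls
#' ignore all moduli (degenerate limits).
#'
#' @param model One of `"soft"`, `"rigid"`, `"elastic"`, `"viscoelastic"`.
#' @param E Young's modulus (MPa), elastic model.
#' @param E_inst,E_eq Instantaneous and equilibrium moduli (MPa),
#'   viscoelastic model; requires `E_inst >= E_eq > 0`.
#' @param nu Poisson's ratio, in `[0, 0.5]`.
#' @param d Lumen internal diameter (um).
#' @param t_w Wall thickness (um).
#' @param tau Retardation time of the delayed strain (s); default 6000 s
#'   (100 min), the timescale over which stomatal opening completes.
#'
#' @return An object of class `wall_parameters`.
#' @examples
#' wall_parameters("elastic", E = 100)
#' wall_parameters("viscoelastic", E_inst = 10000, E_eq = 77)
#' @export
wall_parameters <- function(model = c("elastic", "soft", "rigid", "viscoelastic"),
                            E = 100, E_inst = 10000, E_eq = 77,
                            nu = 0.3, d = 10, t_w = 0.5, tau = 6000) {
  model <- match.arg(model)
  chk <- function(x, name, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (positive && x <= 0)) {
      stop(sprintf("`%s` must be a single positive finite number", name),
           call. = FALSE)
    }
  }
  chk(d, "d"); chk(t_w, "t_w")
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0 || nu > 0.5) {
    stop("`nu` must lie in [0, 0.5]", call. = FALSE)
  }
  if (model == "elastic") chk(E, "E")
  if (model == "viscoelastic") {
    chk(E_inst, "E_inst"); chk(E_eq, "E_eq"); chk(tau, "tau")
    if (E_inst < E_eq) {
      stop("viscoelastic wall requires E_inst >= E_eq (compliance ordering C_inst <= C_eq)",
           call. = FALSE)
    }
  }
  structure(
    list(model = model, E = E, E_inst = E_inst, E_eq = E_eq,
         nu = nu, d = d, t_w = t_w, tau = tau),
    class = "wall_parameters"
  )
}

#' Intracellular fluid parameters
#'
#' The intracellular liquid is characterized by its bulk modulus `K`: a
#' confined volume `V` of liquid develops pressure `p = -K * dV/V`. The
#' default 2,200 MPa is the bulk modulus of liquid water near 20 degrees C.
#'
#' @param K Bulk modulus (MPa); > 0.
#' @return An object of class `fluid_parameters`.
#' @export
fluid_parameters <- function(K = 2200) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop("`K` must be a single positive bulk modulus (MPa)", call. = FALSE)
  }
  structure(list(K = K), class = "fluid_parameters")
}

#' Thin-cylinder volumetric compliance of the wall
#'
#' Fractional lumen-volume increase per unit internal pressure,
#' `C = d * (5 - 4 nu) / (4 t_w E_branch)` in 1/MPa. For a rigid wall the
#' compliance is 0; for a soft wall it is unbounded and the sentinel `Inf` is
#' returned — callers must branch on `w$model`, never on the numeric value.
#'
#' @param w A [wall_parameters()] object.
#' @param branch Which modulus to use: `"single"` (elastic model only),
#'   `"instantaneous"` or `"equilibrium"` (viscoelastic model only). Ignored
#'   for soft and rigid walls.
#' @return Compliance in 1/MPa (`>= 0`, or `Inf` for the soft wall).
#' @examples
#' volumetric_compliance(wall_parameters("elastic", E = 100))  # 0.19
#' @export
volumetric_compliance <- function(w,
                                  branch = c("single", "instantaneous",
                                             "equilibrium")) {
  stopifnot(inherits(w, "wall_parameters"))
  branch <- match.arg(branch)
  if (w$model == "rigid") return(0)
  if (w$model == "soft") return(Inf)
  if (w$model == "elastic") {
    if (branch != "single") {
      stop("branch \"", branch, "\" is only defined for the viscoelastic model",
           call. = FALSE)
    }
    E <- w$E
  } else { # viscoelastic
    if (branch == "single") {
      stop("branch \"single\" is only defined for the elastic model; ",
           "use \"instantaneous\" or \"equilibrium\"", call. = FALSE)
    }
    E <- if (branch == "instantaneous") w$E_inst else w$E_eq
  }
  w$d * (5 - 4 * w$nu) / (4 * w$t_w * E)
}

# Compliance governing the instantaneous pressure response: 0 for rigid,
# single-branch for elastic, instantaneous branch for viscoelastic.
# Callers must handle the soft model before calling.
.c_now <- function(w) {
  switch(w$model,
    rigid = 0,
    elastic = volumetric_compliance(w, "single"),
    viscoelastic = volumetric_compliance(w, "instantaneous"),
    stop("no instantaneous compliance for the soft wall", call. = FALSE)
  )
}

.c_delay <- function(w) {
  volumetric_compliance(w, "equilibrium") -
    volumetric_compliance(w, "instantaneous")
}

#' Quasi-static turgor from the water mass balance
#'
#' At each instant the unpressurized water volume `V_w_ref = V0 + W(t)`
#' (initial volume plus cumulative influx) is compressed to fit the
#' wall-bounded lumen, which itself dilates elastically and by accumulated
#' creep:
#'
#' `V_w_ref * (1 - p/K) = V0 * (1 + C_now * p + eps_c)`
#'
#' whose closed-form solution is
#' `p = (V_w_ref - V0 * (1 + eps_c)) / (V_w_ref / K + V0 * C_now)`,
#' floored at 0 (monotone influx never produces suction; the floor guards
#' pathological configurations). `C_now` is the elastic compliance, or the
#' instantaneous-branch compliance for a viscoelastic wall. A soft wall
#' returns exactly 0: the cell simply expands by the influx volume.
#'
#' @param V_w_ref Unpressurized water volume `V0 + W(t)` (um^3).
#' @param eps_c Accumulated delayed (creep) volumetric strain; 0 for
#'   non-viscoelastic walls.
#' @param w A [wall_parameters()] object.
#' @param f A [fluid_parameters()] object.
#' @param V0 Initial lumen volume (um^3); > 0.
#' @return Gauge turgor pressure in MPa, `>= 0`.
#' @examples
#' w <- wall_parameters("rigid")
#' solve_pressure(3691 + 912, 0, w, fluid_parameters(), 3691)  # ~435.9 MPa
#' @export
solve_pressure <- function(V_w_ref, eps_c, w, f, V0) {
  stopifnot(inherits(w, "wall_parameters"), inherits(f, "fluid_parameters"))
  if (!is.numeric(V0) || length(V0) != 1L || !is.finite(V0) || V0 <= 0) {
    stop("`V0` must be a single positive volume (um^3)", call. = FALSE)
  }
  if (w$model == "soft") return(0)
  p <- (V_w_ref - V0 * (1 + eps_c)) / (V_w_ref / f$K + V0 * .c_now(w))
  pmax(p, 0)
}

#' Advance the delayed (creep) strain of a viscoelastic wall
#'
#' Under a pressure `p` held constant over a step `dt`, the Kelvin delayed
#' branch relaxes exponentially toward its ultimate strain `C_delay * p`
#' (with `C_delay = C_eq - C_inst`):
#'
#' `eps_c' = eps_c + (C_delay * p - eps_c) * (1 - exp(-dt/tau))`
#'
#' This is the exact solution of the creep law for frozen pressure, so
#' composing two half-steps equals one full step exactly (semigroup
#' property), and a single step of length `tau` covers the fraction
#' `1 - exp(-1)` (about 63.2%) of the remaining gap.
#'
#' @param eps_c Current delayed volumetric strain (dimensionless).
#' @param p Turgor pressure held over the step (MPa); `>= 0`.
#' @param w A [wall_parameters()] with `model = "viscoelastic"`.
#' @param dt Step duration (s); > 0.
#' @return Updated delayed strain, lying between `eps_c` and `C_delay * p`.
#' @export
creep_step <- function(eps_c, p, w, dt) {
  stopifnot(inherits(w, "wall_parameters"))
  if (w$model != "viscoelastic") {
    stop("creep_step() is only defined for the viscoelastic wall model",
         call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive duration (s)", call. = FALSE)
  }
  if (any(p < 0)) stop("`p` must be >= 0", call. = FALSE)
  eps_c + (.c_delay(w) * p - eps_c) * (1 - exp(-dt / w$tau))
}

#' @export
print.wall_parameters <- function(x, ...) {
  geom <- sprintf("d=%.4g um  t_w=%.4g um  nu=%.3g", x$d, x$t_w, x$nu)
  mod <- switch(x$model,
    soft = "soft wall (zero stiffness)",
    rigid = "rigid wall (infinite stiffness)",
    elastic = sprintf("elastic wall  E=%.6g MPa", x$E),
    viscoelastic = sprintf(
      "viscoelastic wall  E_inst=%.6g MPa  E_eq=%.6g MPa  tau=%.6g s",
      x$E_inst, x$E_eq, x$tau
    )
  )
  cat(sprintf("<wall_parameters> %s  [%s]\n", mod, geom))
  invisible(x)
}

#' @export
print.fluid_parameters <- function(x, ...) {
  cat(sprintf("<fluid_parameters> K=%.6g MPa\n", x$K))
  invisible(x)
}
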