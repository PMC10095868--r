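# Shared scenario builders: the default study conditions (closed-state volume
# 3,691 um^3, 912 um^3 influx over 3,600 s, water K = 2,200 MPa).

default_fluid <- function() fluid_parameters(K = 2200)

default_schedule <- function(shape = "mb_cdf") {
  influx_schedule(shape, dv_total = 912, t_influx = 3600)
}

default_cfg <- function(model = "elastic", ...) {
  simulation_config(
    v0 = 3691,
    t_total = if (model == "viscoelastic") 18000 else 7200,
    ...
  )
}

run_default <- function(model, shape = "mb_cdf", ...) {
  run_simulation(default_cfg(model, ...), default_schedule(shape),
                 wall_parameters(model), default_fluid())
}

# Mass-balance residual per record (non-soft models): water placed vs stored.
mass_balance_residual <- function(traj, K, v0 = 3691) {
  abs((v0 + traj$W) * (1 - traj$p / K) - traj$V_cell) / traj$V_cell
}
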