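# Shared fixtures, built once per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (is.null(.cache[[name]])) .cache[[name]] <- make()
  .cache[[name]]
}

ref_geometry <- function() cached("ref_geo", function() generate_spine(curve_params()))

straight_geometry <- function() cached("straight_geo", function()
  generate_spine(curve_params(mt_cobb = 0, pt_cobb = 0, l_cobb = 0, tk = 0, ll = 0,
                              axial_rotation_t2 = 0, axial_rotation_t7 = 0)))

ref_model <- function() cached("ref_model", function() assemble_model(ref_geometry()))

upright_case <- function() cached("upright_lc", function()
  brace_load_case("upright", ref_geometry()))

upright_muscles <- function() cached("upright_mf", function()
  optimize_muscle_forces(ref_geometry(), upright_case()))

upright_state <- function() cached("upright_st", function()
  solve_static(ref_model(), upright_case(), upright_muscles(),
               update_loads = default_calibration()$load_updates))

study_result <- function() cached("study", function() run_study())

fem_row_params <- function() curve_params(mt_cobb = 39.6, pt_cobb = 22.5,
                                          l_cobb = 33, tk = 11, ll = 42.4)

# Random plausible Rigo-A3-like parameter draw (alternating curve pattern)
draw_params <- function() {
  mt <- runif(1, 20, 45)
  curve_params(
    mt_cobb = mt,
    pt_cobb = runif(1, 0.45, 0.60) * mt,
    l_cobb = runif(1, 0.80, 1.00) * mt,
    tk = runif(1, 5, 25), ll = runif(1, 30, 50),
    axial_rotation_t2 = runif(1, -6, 0), axial_rotation_t7 = runif(1, 0, 12),
    body_mass = runif(1, 35, 55), stature = runif(1, 140, 165)
  )
}

# Total applied wrench about the origin from a model load vector.
applied_wrench <- function(model, f) {
  F <- c(0, 0, 0); M <- c(0, 0, 0)
  for (i in seq_len(model$n)) {
    d <- (6 * (i - 1) + 1):(6 * i)
    Fi <- f[d[1:3]]
    F <- F + Fi
    M <- M + f[d[4:6]] + pracma::cross(model$geometry$vertebrae[[i]]$centroid, Fi)
  }
  list(force = F, moment = M)
}

# Total reaction wrench about the origin from an equilibrium state.
reaction_wrench <- function(state) {
  model <- state$model
  F <- c(0, 0, 0); M <- c(0, 0, 0)
  for (k in seq_along(state$fixed_dofs)) {
    dof <- state$fixed_dofs[k]
    i <- (dof - 1) %/% 6 + 1
    comp <- (dof - 1) %% 6 + 1
    r <- state$reaction[k]
    p <- model$geometry$vertebrae[[i]]$centroid
    if (comp <= 3) {
      Fi <- c(0, 0, 0); Fi[comp] <- r
      F <- F + Fi
      M <- M + pracma::cross(p, Fi)
    } else {
      Mi <- c(0, 0, 0); Mi[comp - 3] <- r
      M <- M + Mi
    }
  }
  list(force = F, moment = M)
}
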