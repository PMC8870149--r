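# Shared small fixtures. Meshes are cached per session: geometry construction
# is deterministic, so reuse across test files is safe.

local_mesh_cache <- new.env(parent = emptyenv())

small_mesh <- function() {
  if (is.null(local_mesh_cache$small))
    local_mesh_cache$small <- ball_mesh(ball_shells(n_tumor = 2, n_rim = 2,
                                                    n_far = 4), subdiv = 1)
  local_mesh_cache$small
}

medium_mesh <- function() {
  if (is.null(local_mesh_cache$medium))
    local_mesh_cache$medium <- ball_mesh(ball_shells(), subdiv = 2)
  local_mesh_cache$medium
}

small_grid <- function(n = 8, spacing = 2, origin = -(n - 1) * spacing / 2) {
  list(origin = rep(origin, 3), spacing = rep(spacing, 3), dims = rep(n, 3))
}

# independent extended-precision reference values for the hindrance factors,
# computed once with mpmath (50 digits) from the published resistance series
hindrance_reference <- data.frame(
  lambda = c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9),
  H = c(0.95947569772772119, 0.64122022515415523, 0.38105348690652149,
        0.20669162615536091, 0.10017121096405391, 0.041983007671748368,
        0.014401548299633533, 0.0036416062080136366, 0.00053514636896509043,
        2.1305000631938977e-5),
  w = c(0.99953674180413674, 0.95744023987309399, 0.84705700692366169,
        0.69552149833655788, 0.52833076799650769, 0.36728903068133503,
        0.22856462378367317, 0.12174093546191315, 0.050006979342377883,
        0.011300053853421615))
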