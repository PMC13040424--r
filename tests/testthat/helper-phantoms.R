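# canonical phantoms used across test files, built once per test run
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(name, spec_fun) {
  if (is.null(.phantom_cache[[name]]))
    .phantom_cache[[name]] <- make_phantom(spec_fun())
  .phantom_cache[[name]]
}

straight_phantom <- function() {
  cached_phantom("straight", function()
    phantom_spec(canal_length = 32, canal_radius_internal = 2,
                 canal_radius_external = 2))
}

torus_phantom <- function() {
  cached_phantom("torus", function()
    phantom_spec(canal_length = pi * 20 / 2, curvature_radius = 20))
}

funnel_phantom <- function() {
  cached_phantom("funnel", function()
    phantom_spec(canal_length = 30, canal_radius_internal = 4,
                 canal_radius_external = 1.6))
}

# a minimal valid label volume: a straight 3-voxel-wide canal bar inside
# stroma, for cheap I/O and error-path tests
tiny_volume <- function(canal = TRUE) {
  a <- array(0L, dim = c(12, 12, 30))
  a[5:8, 5:8, 3:27] <- 1L
  a[6:7, 6:7, 3:27] <- 2L
  if (canal) a[6, 6, 4:26] <- 3L
  aff <- diag(c(0.8, 0.8, 0.8, 1))
  label_volume(a, aff)
}

tiny_axis <- function() uterine_axis(c(0, 0, 0), c(0, 0, -20))
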