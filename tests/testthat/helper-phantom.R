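# Shared fixtures: phantoms are generated in code, and the expensive
# default-phantom pipeline run is computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixture_cache$phantom)) {
    .fixture_cache$phantom <- generate_phantom(phantom_spec())
  }
  .fixture_cache$phantom
}

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_pipeline(default_phantom()$image, pipeline_params())
  }
  .fixture_cache$run
}

# A small random 8-bit test image.
random_image <- function(seed, h = 64, w = 64) {
  set.seed(seed)
  calibrated_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}
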