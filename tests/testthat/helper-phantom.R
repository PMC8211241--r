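# Shared fixtures: phantoms are generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small desk-scale phantom used by most unit tests (fast: ~1 s)
small_spec <- function(...) phantom_spec(grid_shape = c(96, 96, 72), ...)

small_phantom <- function() {
  cached("small_phantom", generate_phantom(small_spec(), seed = 5))
}

small_result <- function() {
  cached("small_result",
         run_mlast(small_phantom()$volume, pipeline_config(seed = 1)))
}

# full study-scale phantom (160 x 160 x 120) for the acceptance suite
study_phantom <- function(seed = 7) {
  cached(paste0("study_phantom_", seed),
         generate_phantom(phantom_spec(), seed = seed))
}

study_result <- function(seed = 7) {
  cached(paste0("study_result_", seed),
         run_mlast(study_phantom(seed)$volume, pipeline_config(seed = 1)))
}

# logical mask of the true thoracic cavity (everything inside the ribcage)
true_cavity <- function(labels) {
  leg <- labels$legend
  array(labels$labels %in% c(leg[["lung"]], leg[["intermediate"]],
                             leg[["soft"]], leg[["diaphragm"]]),
        dim(labels$labels))
}

true_class_mask <- function(labels, class) {
  array(labels$labels == labels$legend[[class]], dim(labels$labels))
}

mid_thorax_slices <- function(labels) {
  nz <- dim(labels$labels)[3]
  seq(round(nz / 3), round(2 * nz / 3))
}
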