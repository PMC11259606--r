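# Lazily built objects shared across test files (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small quenched network used by several files
fixture_net <- function() fixture("net900", function() {
  build_network(N = 900, seed = 1)
})

# template library on the L = 3 geometry of fixture_net()
fixture_lib <- function() fixture("lib3", function() {
  build_template_library(torus_geometry(3), n_per_class = 12, seed = 11)
})
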