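# Shared fixtures, computed lazily once per test run. The reference solves
# are the expensive parts; every test that needs one pulls it from here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

krogh_net <- function() cached("krogh_net", study_fixture("krogh"))

krogh_ref <- function() {
  cached("krogh_ref", solve_reference_field(krogh_net()))
}

krogh_fd <- function() {
  cached("krogh_fd", fd_oracle(krogh_net(), margin = 75))
}

# sealed-voxel oracle for the Krogh-limit comparison: the tissue cube is
# the voxel, zero-flux at its faces (the model's own boundary assumption)
krogh_fd_sealed <- function() {
  cached("krogh_fd_sealed", fd_oracle(krogh_net(), h = 5, margin = 0))
}

parallel4_net <- function() {
  cached("parallel4_net", generate_parallel_array(
    n_vessels = 4, spacing = 75, jitter = 10, length = 150,
    radius_range = c(4, 6), flow_range = c(1e5, 3e5),
    inlet_sao2 = 0.9, margin = 75, seed = 2))
}

parallel4_ref <- function() {
  cached("parallel4_ref", solve_reference_field(parallel4_net()))
}

parallel4_fd <- function() {
  cached("parallel4_fd", fd_oracle(parallel4_net()))
}

bed_ref <- function() {
  cached("bed_ref",
         solve_reference_field(study_fixture("parallel"), margin = 150))
}

tumor_ref <- function() {
  cached("tumor_ref", {
    net <- study_fixture("tumor", seed = 1)
    solve_reference_field(net, tol = 0.75)
  })
}

tumor_maps <- function(L) {
  key <- paste0("tumor_maps_", L)
  cached(key, run_fusion(tumor_ref(), L))
}

brain_ref <- function() {
  cached("brain_ref", {
    net <- study_fixture("brain", seed = 1)
    solve_reference_field(net, params = physiology_params("brain"),
                          tol = 0.75)
  })
}
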