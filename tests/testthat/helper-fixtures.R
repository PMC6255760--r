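# Shared fixtures, built once per test run. Everything is generated in
# code; no files are shipped.

.fx <- new.env(parent = emptyenv())

fx_monomer <- function(seed = 1L) {
  key <- paste0("mono", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- make_synthetic_monomer(synthetic_monomer_spec(seed = seed))
  .fx[[key]]
}

fx_filament <- function(n = 12L, seed = 1L) {
  key <- paste0("fil", n, "_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- build_filament(fx_monomer(seed), rip2_params(), n)
  .fx[[key]]
}

fx_render <- function(n = 30L, seed = 1L, ...) {
  key <- paste0("img", n, "_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- render_micrograph(fx_filament(n, seed),
                                    micrograph_spec(noise_sigma = 0, ...))
  .fx[[key]]
}

# one-subunit, one-atom filament for renderer unit tests
fx_point_filament <- function(y = 10, z = 5) {
  atoms <- atom_table(1L, "CA", "C", 1L, "ALA", "A", x = 12, y = y, z = z)
  filament_model(list(list(index = 0L, transform = rigid_transform(),
                           atoms = atoms)))
}

random_params <- function() {
  helical_params(runif(1, 1, 10),
                 runif(1, -179, 180) + (runif(1) < 0.5) * 1e-4)
}

expect_rt_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
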