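# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_geom <- function() {
  if (is.null(.fixtures$geom)) {
    .fixtures$geom <- generate_geometry(tissue_params(), seed = 42)
  }
  .fixtures$geom
}

fixture_truth <- function() {
  if (is.null(.fixtures$truth)) {
    .fixtures$truth <- analytic_ground_truth(fixture_geom())
  }
  .fixtures$truth
}

# a small sparse field: fast to count, still has every compartment
fixture_small_params <- function() {
  tissue_params(field_width = 300, field_height = 300,
                tubule_radius_mean = 50, tubule_radius_sd = 5,
                lumen_fraction = 0.20,
                target_tubule_area_fraction = 0.35,
                epithelium_cell_density = 800, sertoli_density = 150,
                leydig_density = 300,
                cell_radius = c(leydig = 6, sertoli = 8, germ = 3))
}

# hand-built geometry (bypasses the packer) for probe-rule unit tests
manual_geometry <- function(width, height, tubules = NULL, cells = NULL) {
  if (is.null(tubules)) {
    tubules <- data.frame(x = numeric(0), y = numeric(0),
                          outer_r = numeric(0), lumen_r = numeric(0))
  }
  if (is.null(cells)) {
    cells <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                        class = character(0))
  }
  structure(list(width = width, height = height, tubules = tubules,
                 cells = cells,
                 achieved_tubule_fraction = NA_real_,
                 params = NULL, seed = NA_integer_),
            class = "tissue_geometry")
}

make_count_record <- function(P, I = 0L, Q = c(leydig = 0L, sertoli = 0L,
                                               germ = 0L),
                              P_cell = c(leydig = 0L, sertoli = 0L,
                                         germ = 0L),
                              a_frame = 1e4, L = 450, d = 25) {
  structure(list(P = P, SP = sum(P), P_cell = P_cell, I = I,
                 I_luminal = NA_integer_, Q = Q, a_frame = a_frame,
                 L = L, d = d),
            class = "count_record")
}
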