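# Shared fixtures, built in code at test time.

# small unit-square mesh reused across spde tests
tiny_mesh <- function(max_edge = 0.25, extension = 0.4) {
  pts <- cbind(c(0, 0, 1, 1, 0.5), c(0, 1, 0, 1, 0.5))
  build_mesh(pts, max_edge = max_edge, cutoff = 1e-6, extension = extension)
}

# a small single-year survey configuration (fast end-to-end fixture)
small_config <- function(seed = 1, n_clusters = 60, ...) {
  sim_config(bounds = c(0, 200, 0, 200), n_clusters = n_clusters,
             beta = c(-0.5, 0.4),
             spde = spde_params_from_range(50, 0.2),
             temporal = temporal_spec(2010, "exchangeable"), years = 2010,
             sigma2_nonsp = 0.1, grid_res = 10, seed = seed, ...)
}

# fast fit settings for tests that need a real posterior but not precision
fast_fit_args <- function(...) {
  modifyList(list(chains = 1, iter = 300, warmup = 200,
                  mesh_args = list(max_edge = 40, extension = 50)),
             list(...))
}

# square polygon feature helper (closed ring), GeoJSON-like structure
square_feature <- function(id, xmin, xmax, ymin, ymax) {
  ring <- cbind(c(xmin, xmax, xmax, xmin, xmin),
                c(ymin, ymin, ymax, ymax, ymin))
  list(id = id, type = "Polygon", properties = list(id = id), rings = list(ring))
}
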