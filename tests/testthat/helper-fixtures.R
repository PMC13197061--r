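# Shared fixtures, built once per test run. Everything is generated in code;
# sphere orders are kept small (0-3) except where a check is explicitly about
# the full-resolution mesh.

ico_cache <- new.env(parent = emptyenv())

get_ico <- function(order) {
  key <- as.character(order)
  if (is.null(ico_cache[[key]])) ico_cache[[key]] <- ico_sphere(order)
  ico_cache[[key]]
}

# brute-force unordered adjacency from faces, as a set per vertex
face_adjacency <- function(faces, nv) {
  adj <- vector("list", nv)
  for (f in seq_len(nrow(faces))) {
    tri <- faces[f, ]
    for (k in 1:3) {
      v <- tri[k]
      adj[[v]] <- union(adj[[v]], setdiff(tri, v))
    }
  }
  adj
}

# small deterministic cohort for pipeline-level tests
small_cohort <- function(n = 8, seed = 42, order = 2, ...) {
  make_cohort(cohort_spec(n_subjects = n, order = order, seed = seed, ...))
}

# denoiser closure around explicit parameters, for oracle-free forward checks
tiny_config <- function(order = 1, feat = 2, mask = 1) {
  denoiser_config(order, feat, mask, n_levels = 2L, hidden_dims = c(6L, 8L),
                  time_embed_dim = 8L)
}
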