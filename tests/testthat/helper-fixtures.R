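# Shared fixtures: tiny deterministic volumes and configs built in code.

rand_volume <- function(dims = c(8, 8, 8), seed = 1, lo = 0.5, hi = 2,
                        voxel = c(2, 2, 2)) {
  set.seed(seed)
  image_volume(array(runif(prod(dims), lo, hi), dim = dims), voxel)
}

tiny_cfg <- function(seed = 1, n_controls = 20L, n_athletes = 12L, ...) {
  sim_config(grid_dims = c(12L, 12L, 12L), n_controls = n_controls,
             n_athletes = n_athletes, seed = seed, ...)
}

# independent brute-force percent positivity by triple loop
loop_pct_positive <- function(suvr, gm, thr, cmp = ">=") {
  d <- dim(suvr)
  npos <- ngm <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!gm[i, j, k] || is.na(suvr[i, j, k])) next
    ngm <- ngm + 1L
    hit <- if (cmp == ">=") suvr[i, j, k] >= thr else suvr[i, j, k] > thr
    if (hit) npos <- npos + 1L
  }
  100 * npos / ngm
}
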