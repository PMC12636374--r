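# small hand-built ensembles used across the ensemble-module tests

# M copies of a fixed 4-atom (1-residue) backbone
tiny_atoms <- function(n_res = 1L) {
  tibble::tibble(
    chain = "A",
    resno = rep(seq_len(n_res), each = 4L),
    insert = "",
    atom = rep(c("N", "CA", "C", "O"), n_res),
    resid = "ALA"
  )
}

tiny_coords <- function(n_res = 1L) {
  base <- matrix(c(0, 0, 0,  1.5, 0, 0,  2.3, 1.2, 0,  2.3, 2.4, 0.8),
                 ncol = 3, byrow = TRUE)
  do.call(rbind, lapply(seq_len(n_res), function(r) base + 3.8 * (r - 1)))
}

identical_ensemble <- function(n_models = 3L, n_res = 2L) {
  xyz <- tiny_coords(n_res)
  coords <- array(NA_real_, c(n_models, nrow(xyz), 3))
  for (m in seq_len(n_models)) coords[m, , ] <- xyz
  conformer_ensemble(coords, tiny_atoms(n_res))
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

random_coords <- function(n_atoms, scale = 10) {
  matrix(stats::runif(n_atoms * 3, -scale, scale), ncol = 3)
}

# direct evaluation of the rigid-fit objective over an Euler-angle grid;
# independent of the SVD route
grid_search_rmsd <- function(mobile, target, n = 24L) {
  angles <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  best <- Inf
  rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                                0, -sin(a), cos(a)), 3, 3)
  rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                                sin(a), 0, cos(a)), 3, 3)
  for (a in angles) for (b in angles[seq_len(n / 2)]) for (c in angles) {
    R <- rot_z_mat(a) %*% rot_y(b) %*% rot_x(c)
    r <- sqrt(mean(rowSums((P %*% R - Q)^2)))
    if (r < best) best <- r
  }
  best
}

rot_z_mat <- function(a) matrix(c(cos(a), sin(a), 0,
                                  -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
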