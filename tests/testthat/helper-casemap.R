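# shared builders for small in-memory fixtures

rand_image <- function(dim = c(8, 8, 8), spacing = c(2, 2, 2), id = "s",
                       baseline = 0, sd = 1) {
  voxel_image(array(stats::rnorm(prod(dim), baseline, sd), dim),
              spacing = spacing, subject_id = id)
}

# cohort of images N(mu, sd) i.i.d. per voxel (no smoothing)
rand_cohort <- function(n, dim = c(8, 8, 8), spacing = c(2, 2, 2),
                        mu = 0, sd = 1, prefix = "s") {
  lapply(seq_len(n), function(i)
    rand_image(dim, spacing, sprintf("%s%02d", prefix, i), mu, sd))
}

full_mask <- function(dim = c(8, 8, 8), spacing = c(2, 2, 2)) {
  brain_mask(array(TRUE, dim), spacing = spacing)
}

# two well-separated Gaussian point clouds in feature space
separable_fm <- function(n_per = 10, p = 2, gap = 10, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * p, gap), n_per),
             matrix(stats::rnorm(n_per * p, -gap), n_per))
  feature_matrix(X, c(rep("WS", n_per), rep("TD", n_per)))
}

# feature matrix with `p_inf` informative features (group shift `d`) and
# `p_noise` pure-noise features
planted_fm <- function(n_per = 20, p_inf = 20, p_noise = 200, d = 2,
                       seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  X <- matrix(stats::rnorm(n * (p_inf + p_noise)), n)
  X[seq_len(n_per), seq_len(p_inf)] <- X[seq_len(n_per), seq_len(p_inf)] + d
  fm <- feature_matrix(X, c(rep("WS", n_per), rep("TD", n_per)))
  attr(fm, "informative") <- seq_len(p_inf)
  fm
}
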