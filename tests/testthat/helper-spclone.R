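# shared fixtures, built in code

base_params <- function() balanced_fate_params()

clone_tbl <- function(m, n, ...) {
  tibble::tibble(m_basal = as.integer(m), n_suprabasal = as.integer(n), ...)
}

# a small synthetic clone table with full schema, for IO tests
full_clone_tbl <- function(n = 12, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    clone_id = paste0("c", seq_len(n)),
    animal_id = rep_len(1:3, n),
    condition = "ctrl",
    genotype = rep_len(c("WT", "p53mut"), n),
    time_h = 48,
    m_basal = rpois(n, 2),
    n_suprabasal = rpois(n, 1),
    edu_basal = 0L,
    edu_suprabasal = 0L
  )) |>
    dplyr::mutate(observable = m_basal + n_suprabasal >= 1L)
}

# exhaustive grid oracle for the geometric median: global coarse scan of
# the bounding box followed by a fine 1e-3 scan around the coarse best
grid_median_oracle <- function(pts, fine_step = 1e-3) {
  cost <- function(xs, ys) {
    outer_sum <- matrix(0, length(xs), length(ys))
    for (i in seq_len(nrow(pts))) {
      outer_sum <- outer_sum +
        sqrt(outer((xs - pts[i, 1])^2, (ys - pts[i, 2])^2, `+`))
    }
    outer_sum
  }
  lo <- apply(pts, 2, min) - 0.5
  hi <- apply(pts, 2, max) + 0.5
  xs <- seq(lo[1], hi[1], by = 0.05)
  ys <- seq(lo[2], hi[2], by = 0.05)
  cc <- cost(xs, ys)
  k <- which(cc == min(cc), arr.ind = TRUE)[1, ]
  xs2 <- seq(xs[k[1]] - 0.06, xs[k[1]] + 0.06, by = fine_step)
  ys2 <- seq(ys[k[2]] - 0.06, ys[k[2]] + 0.06, by = fine_step)
  cc2 <- cost(xs2, ys2)
  k2 <- which(cc2 == min(cc2), arr.ind = TRUE)[1, ]
  c(xs2[k2[1]], ys2[k2[2]])
}

random_integer_points <- function(n, lam_x = 2, lam_y = 1.5) {
  cbind(rpois(n, lam_x), rpois(n, lam_y))
}

distance_sum <- function(y, pts) {
  sum(sqrt((pts[, 1] - y[1])^2 + (pts[, 2] - y[2])^2))
}

# degenerate (e.g. collinear even-count) sets have a whole segment of
# minimisers; accept either coincident locations or equal objective values
median_matches_oracle <- function(pts) {
  gm <- geometric_median(pts)
  oracle <- grid_median_oracle(pts)
  dist <- sqrt(sum((c(gm$m, gm$n) - oracle)^2))
  dist < 5e-3 ||
    distance_sum(c(gm$m, gm$n), pts) <= distance_sum(oracle, pts) + 1e-6
}
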