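# ---------------------------------------------------------------------------
# Two-sample two-dimensional Kolmogorov-Smirnov (Peacock) test.
#
# The statistic D is the supremum over quadrants of the absolute
# difference in empirical quadrant probability between the two samples.
# Quadrant corners run over the full pooled coordinate lattice (pooled
# unique x times pooled unique y, Peacock's original construction); each
# corner is evaluated in all four orientations and under both boundary
# conventions (closed and strict), which makes the supremum well defined
# on heavily tied integer data such as clone sizes. The default null is
# a permutation of the pooled points (exact conditional on the pooled
# data); Peacock's asymptotic approximation is available as a labelled
# alternative but is unreliable for tied integer data.
# ---------------------------------------------------------------------------

as_points <- function(s, arg = "sample") {
  if (is.data.frame(s)) {
    cols <- if (all(c("m_basal", "n_suprabasal") %in% names(s))) {
      c("m_basal", "n_suprabasal")
    } else names(s)[1:2]
    s <- as.matrix(s[, cols])
  }
  s <- as.matrix(s)
  storage.mode(s) <- "double"
  if (ncol(s) != 2) abort(sprintf("%s must have two coordinate columns", arg),
                          class = "spclone_domain_error")
  if (nrow(s) == 0) abort(sprintf("%s is empty", arg),
                          class = "spclone_empty_error")
  s
}

#' Peacock 2D Kolmogorov-Smirnov statistic
#'
#' @param sample1,sample2 Two-column matrices or data frames of 2D
#'   points; clone tables are read as `(m_basal, n_suprabasal)`.
#' @return The statistic `D` in `[0, 1]`.
#' @seealso [peacock_test()], [brute_force_statistic()]
#' @export
#' @examples
#' peacock_statistic(cbind(c(0, 1, 2), c(0, 1, 0)),
#'                   cbind(c(0, 2, 1), c(1, 2, 0)))
peacock_statistic <- function(sample1, sample2) {
  peacock_D_cpp(as_points(sample1, "sample1"), as_points(sample2, "sample2"))
}

#' Peacock 2D Kolmogorov-Smirnov test
#'
#' Compares two sets of 2D points (e.g. clone-size pairs of two
#' conditions). The permutation null relabels the pooled points
#' `n_perm` times and uses the add-one estimator
#' `p = (1 + #\{D* >= D\}) / (n_perm + 1)`, so the smallest attainable p
#' is `1/(n_perm + 1)`. Deterministic under a fixed seed.
#'
#' @inheritParams peacock_statistic
#' @param n_perm Number of permutations (>= 99; smaller counts give
#'   unstable p-values).
#' @param seed Optional integer seed.
#' @param method `"permutation"` (default) or `"asymptotic"` (Peacock's
#'   large-sample approximation; unreliable for tied integer data).
#' @return An object of class `peacock_test` with `statistic`,
#'   `p.value`, `method`, `n_perm`, `n1`, `n2`, `seed`.
#' @export
#' @examples
#' s1 <- cbind(rpois(50, 2), rpois(50, 1))
#' s2 <- cbind(rpois(50, 2), rpois(50, 1))
#' peacock_test(s1, s2, n_perm = 199, seed = 1)
peacock_test <- function(sample1, sample2, n_perm = 999, seed = NULL,
                         method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  s1 <- as_points(sample1, "sample1")
  s2 <- as_points(sample2, "sample2")
  if (method == "permutation") {
    if (n_perm < 99) {
      abort("n_perm must be at least 99", class = "spclone_config_error")
    }
    run <- function() peacock_perm_cpp(s1, s2, as.integer(n_perm))
    res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    d <- res$D
    p <- (1 + sum(res$D_perm >= d - 1e-12)) / (n_perm + 1)
  } else {
    d <- peacock_D_cpp(s1, s2)
    n_eff <- nrow(s1) * nrow(s2) / (nrow(s1) + nrow(s2))
    r2 <- mean(c(stats::cor(s1[, 1], s1[, 2]),
                 stats::cor(s2[, 1], s2[, 2]))^2, na.rm = TRUE)
    if (!is.finite(r2)) r2 <- 0
    z <- sqrt(n_eff) * d / (1 + sqrt(1 - r2) * (0.25 - 0.75 / sqrt(n_eff)))
    j <- 1:101
    p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * z^2))))
    n_perm <- NA_integer_
  }
  structure(list(statistic = d, p.value = p, method = method,
                 n_perm = n_perm, n1 = nrow(s1), n2 = nrow(s2),
                 seed = seed),
            class = "peacock_test")
}

#' @export
print.peacock_test <- function(x, ...) {
  cat("Peacock two-sample 2D Kolmogorov-Smirnov test\n")
  cat(sprintf("  D = %.4f, p = %.4g (%s%s), n1 = %d, n2 = %d\n",
              x$statistic, x$p.value, x$method,
              if (!is.na(x$n_perm)) sprintf(", %d permutations", x$n_perm)
              else "", x$n1, x$n2))
  invisible(x)
}

#' @rdname peacock_test
#' @param x A `peacock_test`.
#' @param ... Unused.
#' @export
tidy.peacock_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, method = x$method,
         n_perm = x$n_perm)
}

#' @rdname peacock_test
#' @export
glance.peacock_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, method = x$method,
         n_perm = x$n_perm, n1 = x$n1, n2 = x$n2)
}

#' Brute-force Peacock statistic (definitional oracle)
#'
#' Direct enumeration of every lattice corner, orientation and boundary
#' convention with explicit membership counting. Used as the reference
#' implementation for [peacock_statistic()]; guarded to small inputs
#' because of its cost.
#'
#' @inheritParams peacock_statistic
#' @param max_n Size guard on `n1 + n2`.
#' @param override Set `TRUE` to lift the guard.
#' @return The statistic `D`.
#' @export
brute_force_statistic <- function(sample1, sample2, max_n = 20,
                                  override = FALSE) {
  s1 <- as_points(sample1, "sample1")
  s2 <- as_points(sample2, "sample2")
  if (!override && nrow(s1) + nrow(s2) > max_n) {
    abort("input exceeds the brute-force size guard; set override = TRUE",
          class = "spclone_config_error")
  }
  xs <- sort(unique(c(s1[, 1], s2[, 1])))
  ys <- sort(unique(c(s1[, 2], s2[, 2])))
  frac <- function(s, fx, fy) mean(fx(s[, 1]) & fy(s[, 2]))
  d_max <- 0
  for (x in xs) for (y in ys) {
    cmps <- list(
      list(function(v) v <= x, function(v) v <= y),
      list(function(v) v <= x, function(v) v >  y),
      list(function(v) v >  x, function(v) v <= y),
      list(function(v) v >  x, function(v) v >  y),
      list(function(v) v <  x, function(v) v <  y),
      list(function(v) v <  x, function(v) v >= y),
      list(function(v) v >= x, function(v) v <  y),
      list(function(v) v >= x, function(v) v >= y)
    )
    for (cm in cmps) {
      d <- abs(frac(s1, cm[[1]], cm[[2]]) - frac(s2, cm[[1]], cm[[2]]))
      if (d > d_max) d_max <- d
    }
  }
  d_max
}
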