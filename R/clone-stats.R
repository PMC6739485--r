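# ---------------------------------------------------------------------------
# Lineage-tracing readouts computed from clone tables: 2D clone-size
# histograms f_{m,n}, residual maps between conditions, geometric-median
# clone size, floating-clone fraction, scalar summaries, EdU cohort
# statistics and relative basal density.
# ---------------------------------------------------------------------------

require_clones <- function(data, what = "clone table subset") {
  if (!all(c("m_basal", "n_suprabasal") %in% names(data))) {
    abort("data must contain m_basal and n_suprabasal columns",
          class = "spclone_schema_error")
  }
  if (nrow(data) == 0) {
    abort(paste0("empty ", what, ": nothing to summarise"),
          class = "spclone_empty_error")
  }
  invisible(data)
}

new_histogram2d <- function(f, n_clones, type = c("frequency", "residual"),
                            overflow = "clip") {
  type <- match.arg(type)
  structure(list(f = f, n_clones = n_clones, type = type,
                 m_cap = nrow(f) - 1L, n_cap = ncol(f) - 1L,
                 overflow = overflow),
            class = "clone_histogram")
}

#' Two-dimensional clone-size histogram
#'
#' Builds the normalised clone-size distribution `f[m, n]`: the relative
#' frequency of clones containing `m` basal and `n` suprabasal cells.
#' Floating clones (`m = 0`) are included by default. Clones exceeding
#' the grid caps are either clipped to the edge cell (default, so no
#' mass is lost) or dropped before normalisation.
#'
#' @param data Clone table subset (observable clones).
#' @param m_cap,n_cap Grid caps for basal and suprabasal counts.
#' @param overflow `"clip"` (clip-to-edge) or `"drop"`.
#' @param include_floating Keep the `m = 0` column?
#' @return A `clone_histogram` whose `f` entries are non-negative and sum
#'   to 1.
#' @export
#' @examples
#' tbl <- tibble::tibble(m_basal = c(1, 1, 0, 2), n_suprabasal = c(0, 0, 1, 1))
#' clone_size_histogram(tbl)$f[1:3, 1:2]
clone_size_histogram <- function(data, m_cap = 12, n_cap = 12,
                                 overflow = c("clip", "drop"),
                                 include_floating = TRUE) {
  overflow <- match.arg(overflow)
  require_clones(data)
  m <- data$m_basal; n <- data$n_suprabasal
  if (!include_floating) {
    keep <- m > 0
    m <- m[keep]; n <- n[keep]
  }
  if (overflow == "drop") {
    keep <- m <= m_cap & n <= n_cap
    m <- m[keep]; n <- n[keep]
  } else {
    m <- pmin(m, m_cap); n <- pmin(n, n_cap)
  }
  if (length(m) == 0) {
    abort("no clones left after filtering", class = "spclone_empty_error")
  }
  f <- matrix(0, nrow = m_cap + 1, ncol = n_cap + 1,
              dimnames = list(m = 0:m_cap, n = 0:n_cap))
  counts <- table(factor(m, levels = 0:m_cap), factor(n, levels = 0:n_cap))
  f[] <- counts / length(m)
  new_histogram2d(f, n_clones = length(m), overflow = overflow)
}

#' Residual map between two clone-size histograms
#'
#' Entrywise difference `h2 - h1` of two histograms on identical grids;
#' the result sums to zero and shows where clone-size mass moved between
#' conditions.
#'
#' @param h1,h2 `clone_histogram` objects with identical grids.
#' @return A `clone_histogram` of type `"residual"`.
#' @export
residual_map <- function(h1, h2) {
  stopifnot(inherits(h1, "clone_histogram"), inherits(h2, "clone_histogram"))
  if (!identical(dim(h1$f), dim(h2$f))) {
    abort("histograms are on different grids",
          class = "spclone_dimension_error")
  }
  new_histogram2d(h2$f - h1$f, n_clones = NA_integer_, type = "residual",
                  overflow = h1$overflow)
}

#' @export
print.clone_histogram <- function(x, ...) {
  cat(sprintf("<clone_histogram %s> grid %d x %d, %s clones, overflow '%s'\n",
              x$type, x$m_cap + 1, x$n_cap + 1,
              ifelse(is.na(x$n_clones), "-", format(x$n_clones)), x$overflow))
  invisible(x)
}

#' @rdname clone_size_histogram
#' @param x A `clone_histogram`.
#' @param ... Unused.
#' @export
tidy.clone_histogram <- function(x, ...) {
  expand_grid(m = 0:x$m_cap, n = 0:x$n_cap) |>
    dplyr::mutate(f = as.vector(x$f[cbind(m + 1, n + 1)]))
}

#' Total-variation distance between histograms
#'
#' `0.5 * sum(|f1 - f2|)` over the common grid; used to compare the
#' simulator's empirical clone-size distribution with the
#' master-equation marginal.
#'
#' @param h1,h2 `clone_histogram` objects with identical grids.
#' @return A number in `[0, 1]`.
#' @export
tv_distance <- function(h1, h2) {
  if (!identical(dim(h1$f), dim(h2$f))) {
    abort("histograms are on different grids",
          class = "spclone_dimension_error")
  }
  0.5 * sum(abs(h1$f - h2$f))
}

#' Geometric median of clone sizes
#'
#' The point minimising the sum of Euclidean distances to the clone-size
#' pairs `(m, n)`, computed by Weiszfeld iteration with the Vardi-Zhang
#' correction when an iterate lands on a data point. Operates on the raw
#' integer pairs, not the capped histogram grid.
#'
#' @param data Clone table subset, or a two-column matrix of points.
#' @param tol Convergence tolerance on the iterate step.
#' @param max_iter Iteration cap.
#' @return A one-row tibble with `m`, `n`, `iterations`, `converged`.
#' @export
#' @examples
#' geometric_median(tibble::tibble(m_basal = c(0, 1, 2, 10),
#'                                 n_suprabasal = c(0, 0, 0, 0)))
geometric_median <- function(data, tol = 1e-8, max_iter = 1000) {
  pts <- if (is.matrix(data)) data else {
    require_clones(data)
    cbind(data$m_basal, data$n_suprabasal)
  }
  storage.mode(pts) <- "double"
  if (nrow(pts) == 0) abort("need at least one point",
                            class = "spclone_empty_error")
  if (nrow(pts) == 1) {
    return(tibble(m = pts[1, 1], n = pts[1, 2], iterations = 0L,
                  converged = TRUE))
  }
  y <- colMeans(pts)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((pts - matrix(y, nrow(pts), 2, byrow = TRUE))^2))
    on_pt <- d < 1e-12
    eta <- sum(on_pt)
    if (eta == nrow(pts)) { converged <- TRUE; break }  # all points here
    w <- 1 / d[!on_pt]
    t_y <- colSums(pts[!on_pt, , drop = FALSE] * w) / sum(w)
    if (eta == 0) {
      y_new <- t_y
    } else {
      # Vardi-Zhang step at a data point
      r_vec <- colSums((pts[!on_pt, , drop = FALSE] -
                          matrix(y, sum(!on_pt), 2, byrow = TRUE)) * w)
      r_norm <- sqrt(sum(r_vec^2))
      if (r_norm <= eta) { converged <- TRUE; break }  # y is the median
      a <- min(1, eta / r_norm)
      y_new <- (1 - a) * t_y + a * y
    }
    if (sqrt(sum((y_new - y)^2)) < tol) {
      y <- y_new; converged <- TRUE; break
    }
    y <- y_new
  }
  tibble(m = y[1], n = y[2], iterations = it, converged = converged)
}

#' Floating-clone fraction
#'
#' Percentage of observable clones with no basal cells (`m = 0`,
#' `n >= 1`): clones destined to be lost by shedding.
#'
#' @param data Clone table subset (observable clones).
#' @return A one-row tibble with `n_clones`, `n_floating`,
#'   `floating_pct`.
#' @export
floating_fraction <- function(data) {
  require_clones(data)
  nf <- sum(data$m_basal == 0 & data$n_suprabasal >= 1)
  tibble(n_clones = nrow(data), n_floating = nf,
         floating_pct = 100 * nf / nrow(data))
}

#' Scalar clone-table summaries
#'
#' Mean total clone size, mean per-clone basal and suprabasal fractions,
#' and (when genotypes are mixed) the mutant basal-cell percentage:
#' mutant basal cells over all basal cells.
#'
#' @param data Clone table subset (observable clones).
#' @return A one-row tibble of summaries.
#' @export
summary_stats <- function(data) {
  require_clones(data)
  tot <- data$m_basal + data$n_suprabasal
  mut_basal <- if ("genotype" %in% names(data)) {
    sum(data$m_basal[data$genotype == "p53mut"])
  } else 0
  all_basal <- sum(data$m_basal)
  tibble(
    n_clones = nrow(data),
    mean_total_size = mean(tot),
    mean_basal_fraction = mean(ifelse(tot > 0, data$m_basal / tot, NA)),
    mean_suprabasal_fraction = mean(ifelse(tot > 0,
                                           data$n_suprabasal / tot, NA)),
    mutant_basal_pct = if (all_basal > 0) 100 * mut_basal / all_basal
                       else NA_real_
  )
}

#' EdU cohort readouts
#'
#' Pools EdU-labelled cells over the clones of a subset and reports the
#' percentage of EdU+ cells that are suprabasal, the percentage basal,
#' and the total EdU+ count. With no labelled cells the ratios are
#' undefined and returned as `NA` with a warning, never as silent zeros.
#'
#' @param data Clone table subset with `edu_basal` and `edu_suprabasal`.
#' @return A one-row tibble: `edu_total`, `edu_suprabasal_pct`,
#'   `edu_basal_pct`.
#' @export
edu_readouts <- function(data) {
  require_clones(data)
  if (!all(c("edu_basal", "edu_suprabasal") %in% names(data)) ||
      all(is.na(data$edu_basal))) {
    abort("EdU columns are absent from this table",
          class = "spclone_schema_error")
  }
  eb <- sum(data$edu_basal, na.rm = TRUE)
  es <- sum(data$edu_suprabasal, na.rm = TRUE)
  tot <- eb + es
  if (tot == 0) {
    warn("no EdU-labelled cells in subset; ratios are undefined")
    return(tibble(edu_total = 0L, edu_suprabasal_pct = NA_real_,
                  edu_basal_pct = NA_real_))
  }
  tibble(edu_total = tot, edu_suprabasal_pct = 100 * es / tot,
         edu_basal_pct = 100 * eb / tot)
}

#' Relative basal density from field counts
#'
#' Ratio of mean basal cells per field between a condition and its
#' reference, with a standard error from field-level variances (delta
#' method).
#'
#' @param counts Integer vector of per-field counts for the condition.
#' @param ref_counts Per-field counts for the reference condition.
#' @return A one-row tibble with `ratio` and `se`.
#' @export
density_estimate <- function(counts, ref_counts) {
  if (length(counts) < 1 || length(ref_counts) < 1) {
    abort("need at least one field per condition",
          class = "spclone_empty_error")
  }
  m1 <- mean(counts); m0 <- mean(ref_counts)
  if (m0 == 0) abort("reference field mean is zero",
                     class = "spclone_domain_error")
  v1 <- if (length(counts) > 1) stats::var(counts) / length(counts) else 0
  v0 <- if (length(ref_counts) > 1) stats::var(ref_counts) / length(ref_counts) else 0
  ratio <- m1 / m0
  se <- ratio * sqrt(v1 / m1^2 + v0 / m0^2)
  tibble(ratio = ratio, se = se)
}
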