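# ---------------------------------------------------------------------------
# File formats: clone tables as TSV, histograms/residual maps as dense TSV
# matrices with explicit m/n indices, scalar results as JSON, scenarios as
# YAML. TSV is used (not CSV) to match copy-paste from imaging
# spreadsheets; integers are written unquoted; round trips are bit-exact.
# ---------------------------------------------------------------------------

CLONE_TABLE_COLS <- c("clone_id", "animal_id", "condition", "genotype",
                      "time_h", "m_basal", "n_suprabasal")
CLONE_TABLE_EDU <- c("edu_basal", "edu_suprabasal")

#' Read a clone table from TSV
#'
#' Expects a header with `clone_id`, `animal_id`, `condition`,
#' `genotype`, `time_h`, `m_basal`, `n_suprabasal` and optionally
#' `edu_basal`, `edu_suprabasal`. Rows with negative or non-integer
#' counts raise a parse error naming the offending line. Missing EdU
#' columns are allowed and recorded (`attr(x, "has_edu")`), so that EdU
#' readouts can refuse such tables explicitly.
#'
#' @param path Path to a TSV file.
#' @return A validated clone-table tibble.
#' @export
read_clone_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(CLONE_TABLE_COLS, names(tbl))
  if (length(missing)) {
    abort(paste0("clone table is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "spclone_schema_error")
  }
  has_edu <- all(CLONE_TABLE_EDU %in% names(tbl))
  count_cols <- c("m_basal", "n_suprabasal",
                  if (has_edu) CLONE_TABLE_EDU)
  for (col in count_cols) {
    v <- tbl[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf("invalid %s on line %d of %s (negative or non-integer)",
                    col, bad[1] + 1L, path),  # +1 for the header line
            class = "spclone_parse_error")
    }
    tbl[[col]] <- as.integer(v)
  }
  if (!"observable" %in% names(tbl)) {
    tbl$observable <- tbl$m_basal + tbl$n_suprabasal >= 1L
  }
  attr(tbl, "has_edu") <- has_edu
  tbl
}

#' Write a clone table to TSV
#'
#' @param data Clone table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(data, path) {
  keep <- intersect(c(CLONE_TABLE_COLS, CLONE_TABLE_EDU, "observable"),
                    names(data))
  readr::write_tsv(data[, keep], path)
  invisible(path)
}

#' Write a 2D histogram (or residual map) as a TSV matrix
#'
#' Dense matrix with an explicit basal-count index column `m` and
#' suprabasal-count indices in the header; round trips through
#' [read_histogram_tsv()] bit-exactly.
#'
#' @param hist A `clone_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  stopifnot(inherits(hist, "clone_histogram"))
  df <- as.data.frame(hist$f)
  names(df) <- paste0("n", 0:hist$n_cap)
  out <- dplyr::bind_cols(tibble(m = 0:hist$m_cap), df)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a 2D histogram from a TSV matrix
#'
#' @param path Path written by [write_histogram_tsv()].
#' @param type `"frequency"` or `"residual"`.
#' @return A `clone_histogram`.
#' @export
read_histogram_tsv <- function(path, type = c("frequency", "residual")) {
  type <- match.arg(type)
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  f <- as.matrix(tbl[, -1])
  dimnames(f) <- list(m = tbl$m, n = sub("^n", "", colnames(tbl)[-1]))
  h <- new_histogram2d(f, n_clones = NA_integer_, type = type)
  h
}

#' Read or write a scenario as YAML
#'
#' The YAML mirrors the `scenario` fields (exposure times, genotype mix,
#' antioxidant and EdU flags, sample times, observation geometry, seed,
#' and the response-model parameters). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return `read_scenario()`: a `scenario`; `write_scenario()`: `path`,
#'   invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- preset_scenario(raw$name %||% "ctrl")
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) {
    abort(paste0("unknown scenario keys in ", path, ": ",
                 paste(unknown, collapse = ", ")),
          class = "spclone_config_error")
  }
  sc <- unclass(base)
  for (k in setdiff(names(raw), c("name", "params"))) sc[[k]] <- raw[[k]]
  if (!is.null(raw$params)) {
    unknown_p <- setdiff(names(raw$params), names(sc$params))
    if (length(unknown_p)) {
      abort(paste0("unknown scenario params: ",
                   paste(unknown_p, collapse = ", ")),
            class = "spclone_config_error")
    }
    sc$params[names(raw$params)] <- raw$params
  }
  validate_scenario(structure(sc, class = "scenario"))
}

#' @rdname read_scenario
#' @param scenario A `scenario` object.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  x <- unclass(scenario)
  x$edu_pulse_h <- x$edu_pulse_h %||% NULL
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

# metadata block written next to every artifact: version, seed, config
result_metadata <- function(seed, config = NULL) {
  list(package = "spclone",
       version = as.character(utils::packageVersion("spclone")),
       seed = seed,
       config_hash = if (is.null(config)) NULL else
         rlang::hash(config))
}

#' Write a scalar-result JSON file with metadata
#'
#' @param x A named list of results.
#' @param path Output path.
#' @param seed Seed recorded in the metadata block.
#' @param config Configuration recorded (hashed) in the metadata block.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, seed = NULL, config = NULL) {
  payload <- c(x, list(metadata = result_metadata(seed, config)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
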