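# Acquisition-geometry and signal-table I/O.
#
# Gradient tables use the two-file whitespace dialect: one line of b-values
# and three lines of direction components (x, y, z), one column per volume.
# ROI signal tables are long-format delimited text with an explicit header.

#' Read a two-file gradient table
#'
#' Parses the standard two-file diffusion gradient dialect: a `.bval` file
#' with a single whitespace-separated line of b-values (s/mm^2) and a `.bvec`
#' file with three lines of direction components of equal length.
#'
#' @param bval_path Path to the b-value file (one numeric line).
#' @param bvec_path Path to the direction file (three numeric lines).
#'
#' @return A tibble with one row per acquisition volume and columns
#'   `volume` (1-based index in file order), `b` (s/mm^2), and direction
#'   components `gx`, `gy`, `gz`.
#'
#' @details Volumes are kept in file order. Directions of diffusion-weighted
#'   volumes (b > 0) must be unit vectors to within 1e-3; b = 0 volumes may
#'   carry zero vectors.
#'
#' @examples
#' bval <- tempfile(fileext = ".bval")
#' bvec <- tempfile(fileext = ".bvec")
#' writeLines("0 0 700 700", bval)
#' writeLines(c("0 0 1 0", "0 0 0 1", "0 0 0 0"), bvec)
#' read_btable(bval, bvec)
#' @export
read_btable <- function(bval_path, bvec_path) {
  bvals <- parse_numeric_lines(bval_path, n_lines = 1L)[[1]]
  bvecs <- parse_numeric_lines(bvec_path, n_lines = 3L)
  n_vec <- lengths(bvecs)
  if (length(unique(n_vec)) != 1L) {
    abort(sprintf(
      "bvec rows have unequal lengths (%s) in '%s'.",
      paste(n_vec, collapse = ", "), bvec_path
    ))
  }
  if (length(bvals) != n_vec[1]) {
    abort(sprintf(
      "gradient table mismatch: %d b-values in '%s' but %d direction columns in '%s'.",
      length(bvals), bval_path, n_vec[1], bvec_path
    ))
  }
  btable <- tibble::tibble(
    volume = seq_along(bvals),
    b = bvals,
    gx = bvecs[[1]], gy = bvecs[[2]], gz = bvecs[[3]]
  )
  validate_btable(btable)
}

#' Write a two-file gradient table
#'
#' Inverse of [read_btable()]; writes full-precision whitespace-separated
#' values in volume order.
#'
#' @param btable A gradient table as returned by [read_btable()].
#' @param bval_path,bvec_path Output paths.
#' @return `btable`, invisibly.
#' @export
write_btable <- function(btable, bval_path, bvec_path) {
  btable <- validate_btable(btable)
  num <- function(x) paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                           collapse = " ")
  writeLines(num(btable$b), bval_path)
  writeLines(c(num(btable$gx), num(btable$gy), num(btable$gz)), bvec_path)
  invisible(btable)
}

#' Validate a gradient table
#'
#' Checks the invariants of the acquisition geometry: non-negative b-values
#' and unit-norm directions (to 1e-3) for all diffusion-weighted volumes.
#'
#' @param btable A data frame with columns `volume`, `b`, `gx`, `gy`, `gz`.
#' @return The validated table as a tibble, invisibly usable in pipes.
#' @export
validate_btable <- function(btable) {
  required <- c("volume", "b", "gx", "gy", "gz")
  missing_cols <- setdiff(required, names(btable))
  if (length(missing_cols) > 0) {
    abort(paste0("gradient table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  btable <- tibble::as_tibble(btable)
  if (any(!is.finite(btable$b)) || any(btable$b < 0)) {
    abort("b-values must be finite and non-negative.")
  }
  norms <- sqrt(btable$gx^2 + btable$gy^2 + btable$gz^2)
  dw <- btable$b > 0
  bad <- dw & abs(norms - 1) > 1e-3
  if (any(bad)) {
    abort(sprintf(
      "non-unit direction (|g| = %.6f) at diffusion-weighted volume %d.",
      norms[which(bad)[1]], btable$volume[which(bad)[1]]
    ))
  }
  btable
}

# Parse exactly n_lines whitespace-separated numeric lines, reporting the
# line/column of the first non-numeric token.
parse_numeric_lines <- function(path, n_lines) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != n_lines) {
    abort(sprintf("expected %d non-empty line(s) in '%s', found %d.",
                  n_lines, path, length(lines)))
  }
  lapply(seq_along(lines), function(i) {
    tokens <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    values <- suppressWarnings(as.numeric(tokens))
    if (anyNA(values)) {
      j <- which(is.na(values))[1]
      abort(sprintf("non-numeric token '%s' at line %d, column %d of '%s'.",
                    tokens[j], i, j, path))
    }
    values
  })
}

#' Group acquisition volumes into b-shells
#'
#' Partitions the volumes of a gradient table into shells of (nearly) equal
#' b-value. Sorted b-values are clustered single-linkage: a new shell starts
#' whenever the gap to the previous b-value exceeds `tolerance`. Shell centers
#' are the mean b within each group, and shells are ordered by increasing
#' center, so a b = 0 shell (if present) comes first.
#'
#' @param btable A gradient table (see [read_btable()]).
#' @param tolerance Maximum b-value gap (s/mm^2) bridged within one shell.
#'   The default, 25, is well under half the smallest inter-shell gap of the
#'   fifteen-shell protocol this package emulates.
#'
#' @return A tibble with one row per shell: `shell` (1-based), `b_center`
#'   (mean member b-value), `n_volumes`, and `volumes` (list column of member
#'   volume indices). Every volume is assigned to exactly one shell.
#'
#' @details If chaining merges input b-values further apart than `tolerance`,
#'   the merge is kept (the caller chose the tolerance) but a message is
#'   emitted.
#' @export
group_shells <- function(btable, tolerance = 25) {
  btable <- validate_btable(btable)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    abort("`tolerance` must be a single non-negative number.")
  }
  ord <- order(btable$b)
  b_sorted <- btable$b[ord]
  new_shell <- c(TRUE, diff(b_sorted) > tolerance)
  shell_id_sorted <- cumsum(new_shell)
  shell_id <- integer(nrow(btable))
  shell_id[ord] <- shell_id_sorted

  shells <- tibble::tibble(volume = btable$volume, b = btable$b, shell = shell_id) |>
    dplyr::group_by(.data$shell) |>
    dplyr::summarise(
      b_center = mean(.data$b),
      n_volumes = dplyr::n(),
      volumes = list(.data$volume),
      b_spread = max(.data$b) - min(.data$b),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$b_center) |>
    dplyr::mutate(shell = dplyr::row_number())

  merged <- shells$b_spread > 0
  if (any(merged)) {
    message(sprintf(
      "group_shells: %d shell(s) merge distinct b-values (max spread %.1f s/mm^2).",
      sum(merged), max(shells$b_spread)
    ))
  }
  dplyr::select(shells, "shell", "b_center", "n_volumes", "volumes")
}

#' Emulated fifteen-shell corpus-callosum protocol
#'
#' Builds the gradient table of the multi-b-value protocol this package
#' emulates: sixteen b = 0 volumes followed by fifteen shells at
#' b = 250, 500, 600, 700, 800, 900, 1000, 1250, 1500, 1750, 2000, 2500,
#' 3000, 3500, 3800 s/mm^2 with thirty isotropically distributed directions
#' per shell (466 volumes in total). Directions are a deterministic Fibonacci
#' sphere, rotated per shell so consecutive shells do not repeat directions.
#'
#' @param n_b0 Number of b = 0 volumes (default 16).
#' @param n_directions Directions per non-zero shell (default 30).
#' @param b_values Non-zero shell b-values (s/mm^2).
#' @return A gradient-table tibble (see [read_btable()]).
#' @export
mbi_btable <- function(n_b0 = 16,
                       n_directions = 30,
                       b_values = c(250, 500, 600, 700, 800, 900, 1000, 1250,
                                    1500, 1750, 2000, 2500, 3000, 3500, 3800)) {
  stopifnot(n_b0 >= 0, n_directions >= 1, all(b_values > 0))
  dirs <- fibonacci_sphere(n_directions)
  rows <- list(tibble::tibble(b = rep(0, n_b0), gx = 0, gy = 0, gz = 0))
  golden <- pi * (3 - sqrt(5))
  for (i in seq_along(b_values)) {
    th <- (i - 1) * golden / 7          # small per-shell azimuthal rotation
    rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    d <- dirs %*% rot
    rows[[i + 1]] <- tibble::tibble(b = b_values[i],
                                    gx = d[, 1], gy = d[, 2], gz = d[, 3])
  }
  out <- dplyr::bind_rows(rows)
  out$volume <- seq_len(nrow(out))
  validate_btable(dplyr::select(out, "volume", "b", "gx", "gy", "gz"))
}

# Evenly distributed unit vectors (Fibonacci spiral on the sphere).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Read or write a long-format ROI signal table
#'
#' Signal tables are comma-delimited text with header columns `subject`,
#' `roi`, `volume`, `b`, `signal`: one row per (subject, region, acquisition
#' volume), `signal` a non-negative magnitude in arbitrary units.
#'
#' @param path File path.
#' @return `read_roi_signals()` returns the validated tibble;
#'   `write_roi_signals()` returns `signals` invisibly.
#' @export
read_roi_signals <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_roi_signals(tbl)
}

#' @rdname read_roi_signals
#' @param signals A signal table to write.
#' @export
write_roi_signals <- function(signals, path) {
  signals <- validate_roi_signals(signals)
  readr::write_csv(signals, path, progress = FALSE)
  invisible(signals)
}

#' Validate an ROI signal table
#'
#' Checks the signal-table contract: required columns present, signals
#' non-negative, and (subject, roi, volume) unique.
#'
#' @param signals A data frame with columns `subject`, `roi`, `volume`, `b`,
#'   `signal`.
#' @param btable Optional gradient table; if supplied, each row's `b` must
#'   match the table's b-value for that volume.
#' @return The validated tibble.
#' @export
validate_roi_signals <- function(signals, btable = NULL) {
  required <- c("subject", "roi", "volume", "b", "signal")
  missing_cols <- setdiff(required, names(signals))
  if (length(missing_cols) > 0) {
    abort(paste0("signal table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  signals <- tibble::as_tibble(signals)
  if (any(!is.finite(signals$signal)) || any(signals$signal < 0)) {
    abort("signals must be finite and non-negative.")
  }
  dup <- duplicated(signals[, c("subject", "roi", "volume")])
  if (any(dup)) {
    d <- signals[which(dup)[1], ]
    abort(sprintf("duplicate (subject, roi, volume) key: (%s, %s, %d).",
                  d$subject, d$roi, d$volume))
  }
  if (!is.null(btable)) {
    btable <- validate_btable(btable)
    b_of <- setNames(btable$b, btable$volume)
    mismatch <- abs(signals$b - b_of[as.character(signals$volume)]) > 1e-9
    if (any(is.na(mismatch)) || any(mismatch)) {
      abort("signal table b-values are inconsistent with the gradient table.")
    }
  }
  signals
}
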