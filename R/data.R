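#' Grouped data for multinomial circular logistic regression
#'
#' An `mclr_data` object is a tibble with one row per covariate pattern:
#' `k` angle columns (`angle_1`, ..., `angle_k`, radians in `[0, 2*pi)`)
#' followed by `d + 1` count columns (`count_<label>`), one per response
#' category. The last label is the reference category of the model. The
#' total count of row `i` is the pattern size `n_i`.
#'
#' @param angles numeric vector (one angle per pattern, `k = 1`) or a
#'   matrix with `k` columns of angles in radians. Angles are wrapped
#'   into `[0, 2*pi)`.
#' @param counts matrix of non-negative integer category counts with one
#'   row per pattern and `d + 1` columns, the last column being the
#'   reference category.
#' @param labels optional character vector of `d + 1` category labels;
#'   defaults to `"1", ..., "d+1"`.
#'
#' @return A tibble of class `mclr_data` with attributes `k`, `d` and
#'   `labels`.
#'
#' @examples
#' mclr_data(c(0, pi / 2), rbind(c(3, 1, 2), c(0, 4, 1)))
#' @export
mclr_data <- function(angles, counts, labels = NULL) {
  U <- as.matrix(angles)
  storage.mode(U) <- "double"
  if (any(!is.finite(U))) {
    abort("all angles must be finite", class = "robmclr_invalid_input")
  }
  U <- U %% (2 * pi)
  V <- as.matrix(counts)
  if (nrow(V) != nrow(U)) {
    abort("`angles` and `counts` must describe the same patterns",
          class = "robmclr_invalid_input")
  }
  if (any(V < 0) || any(V != round(V))) {
    abort("counts must be non-negative integers",
          class = "robmclr_invalid_input")
  }
  d <- ncol(V) - 1L
  if (d < 1L) {
    abort("need at least two response categories",
          class = "robmclr_invalid_input")
  }
  k <- ncol(U)
  if (is.null(labels)) labels <- as.character(seq_len(d + 1L))
  if (length(labels) != d + 1L) {
    abort("`labels` must have one entry per category",
          class = "robmclr_invalid_input")
  }
  out <- as_tibble(U, .name_repair = "minimal")
  names(out) <- paste0("angle_", seq_len(k))
  cnt <- as_tibble(V, .name_repair = "minimal")
  names(cnt) <- paste0("count_", labels)
  out <- dplyr::bind_cols(out, cnt)
  structure(out,
            k = k, d = d, labels = labels,
            class = c("mclr_data", class(tibble())))
}

#' @export
print.mclr_data <- function(x, ...) {
  md <- unpack_mclr(x)
  cat(sprintf(
    "<mclr_data> %d covariate pattern(s), %d angular covariate(s), %d categories, n = %d\n",
    md$I, md$k, md$d + 1L, md$n))
  cat(sprintf("reference category: %s\n", md$labels[md$d + 1L]))
  NextMethod()
}

# internal matrix view of an mclr_data tibble
unpack_mclr <- function(data) {
  if (!inherits(data, "mclr_data")) {
    abort("expected an `mclr_data` object (see `mclr_data()`, `group_angular()`)",
          class = "robmclr_invalid_input")
  }
  k <- attr(data, "k")
  d <- attr(data, "d")
  labels <- attr(data, "labels")
  U <- as.matrix(data[, paste0("angle_", seq_len(k)), drop = FALSE])
  V <- as.matrix(data[, paste0("count_", labels), drop = FALSE])
  dimnames(U) <- NULL
  dimnames(V) <- NULL
  ni <- as.numeric(rowSums(V))
  list(U = U, V = V, ni = ni, n = sum(ni), I = nrow(U),
       d = d, k = k, p = d * (2L * k + 1L), labels = labels)
}

#' Group long-format angular records into covariate patterns
#'
#' Takes one row per observation (angles plus a category label), wraps
#' angles to `[0, 2*pi)`, and groups rows whose angle tuples agree after
#' rounding to 1e-9 into covariate patterns with category counts.
#' Patterns keep first-appearance order. The *last* level of
#' `levels` is the reference category.
#'
#' @param df data frame of observations.
#' @param angles character vector of angle column names (one per
#'   circular covariate).
#' @param category name of the category column.
#' @param levels ordered character vector of category labels; defaults
#'   to the sorted unique values of the category column. The last entry
#'   is the reference category.
#' @param unit `"degrees"` (default) or `"radians"`.
#'
#' @return An [mclr_data] tibble.
#' @examples
#' df <- data.frame(a = c(0, 90, 0, 360), y = c("A", "B", "B", "A"))
#' group_angular(df, angles = "a", category = "y", levels = c("A", "B"))
#' @export
group_angular <- function(df, angles, category,
                          levels = NULL, unit = c("degrees", "radians")) {
  unit <- match.arg(unit)
  missing_cols <- setdiff(c(angles, category), names(df))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")),
          class = "robmclr_invalid_input")
  }
  U <- as.matrix(df[, angles, drop = FALSE])
  storage.mode(U) <- "double"
  bad <- which(!stats::complete.cases(U) | !apply(is.finite(U), 1, all))
  if (length(bad)) {
    abort(sprintf("missing or non-finite angle in row(s): %s",
                  paste(head(bad, 10L), collapse = ", ")),
          class = "robmclr_invalid_input")
  }
  if (unit == "degrees") U <- U * pi / 180
  U <- U %% (2 * pi)
  y <- as.character(df[[category]])
  if (is.null(levels)) levels <- sort(unique(y))
  unknown <- which(!(y %in% levels))
  if (length(unknown)) {
    abort(sprintf("unknown category label in row(s): %s",
                  paste(head(unknown, 10L), collapse = ", ")),
          class = "robmclr_invalid_input")
  }
  key <- apply(round(U, 9L), 1L, paste, collapse = "|")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  I <- sum(first)
  V <- matrix(0L, I, length(levels))
  ji <- cbind(pat_id, match(y, levels))
  for (r in seq_len(nrow(ji))) V[ji[r, 1L], ji[r, 2L]] <- V[ji[r, 1L], ji[r, 2L]] + 1L
  mclr_data(U[first, , drop = FALSE], V, labels = levels)
}

#' Read long-format angular observations from a CSV file
#'
#' Thin wrapper around [readr::read_csv()] followed by
#' [group_angular()].
#'
#' @inheritParams group_angular
#' @param path CSV file with one row per observation.
#' @return An [mclr_data] tibble.
#' @export
read_angular_csv <- function(path, angles, category, levels = NULL,
                             unit = c("degrees", "radians")) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  group_angular(df, angles = angles, category = category,
                levels = levels, unit = unit)
}

#' Write / read grouped data as CSV
#'
#' The grouped format has columns `angle_1..angle_k` (radians) and
#' `count_<label>` for each category, one row per covariate pattern.
#' `read_mclr_csv()` reconstructs an identical [mclr_data] object, so
#' the pair round-trips.
#'
#' @param data an [mclr_data] object.
#' @param path file path.
#' @return `write_mclr_csv()` returns `data` invisibly;
#'   `read_mclr_csv()` returns an [mclr_data] tibble.
#' @export
write_mclr_csv <- function(data, path) {
  unpack_mclr(data) # validates
  readr::write_csv(as_tibble(as.data.frame(data)), path)
  invisible(data)
}

#' @rdname write_mclr_csv
#' @export
read_mclr_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  acols <- grep("^angle_", names(df), value = TRUE)
  ccols <- grep("^count_", names(df), value = TRUE)
  if (!length(acols) || length(ccols) < 2L) {
    abort("not a grouped mclr CSV (need angle_* and count_* columns)",
          class = "robmclr_invalid_input")
  }
  mclr_data(as.matrix(df[acols]), as.matrix(df[ccols]),
            labels = sub("^count_", "", ccols))
}
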