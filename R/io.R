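#' Read a typed matrix from delimited text
#'
#' Parses plain delimited numeric text (comma or whitespace separated).  A
#' file may contain one matrix or several blank-line-separated blocks
#' (`block` selects which).  Angle matrices may alternatively be given as
#' an "i j value" triple list (strictly lower positions, 1-based).  The
#' returned object has its type invariants checked: symmetry, exact unit
#' diagonal and \[-1, 1\] range for `"correlation"`; \[0, pi\] range for
#' `"angles"`; \[0, 1\] range for `"draws"`.
#'
#' @param path file path.
#' @param kind one of `"correlation"`, `"angles"`, `"draws"`.
#' @param block which blank-line-separated block to read (default 1).
#' @return a [correlation_matrix()], [angle_matrix()], or plain strictly
#'   lower triangular draw matrix, according to `kind`.
#' @export
read_matrix <- function(path, kind = c("correlation", "angles", "draws"),
                        block = 1L) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blocks <- .split_blocks(lines)
  if (block > length(blocks)) {
    stop(sprintf("requested block %d but file has %d", block, length(blocks)),
         call. = FALSE)
  }
  rows <- lapply(blocks[[block]], .parse_numeric_line, path = path)
  ncols <- vapply(rows, length, 0L)
  if (kind == "angles" && all(ncols == 3L) && length(rows) > 0 &&
      all(vapply(rows, function(r) r[1] == round(r[1]) && r[2] == round(r[2]), TRUE))) {
    return(.angles_from_triples(do.call(rbind, rows)))
  }
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("ragged matrix in %s: row lengths %s", path,
                 paste(ncols, collapse = ", ")), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in %s is %d x %d, not square", path, nrow(m), ncol(m)),
         call. = FALSE)
  }
  switch(kind,
    correlation = .as_correlation_checked(m, path),
    angles = angle_matrix(m),
    draws = .check_unit_draws(m))
}

.split_blocks <- function(lines) {
  lines <- sub("#.*$", "", lines)
  is_blank <- !nzchar(trimws(lines))
  if (all(is_blank)) stop("file contains no numeric data", call. = FALSE)
  grp <- cumsum(is_blank & !c(FALSE, is_blank[-length(is_blank)]))
  keep <- split(lines[!is_blank], grp[!is_blank])
  unname(keep)
}

.parse_numeric_line <- function(line, path) {
  parts <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric value in %s: '%s'", path, line), call. = FALSE)
  }
  vals
}

.angles_from_triples <- function(triples) {
  n <- as.integer(max(triples[, 1]))
  th <- matrix(0, n, n)
  for (r in seq_len(nrow(triples))) {
    i <- as.integer(triples[r, 1]); j <- as.integer(triples[r, 2])
    if (i <= j) {
      stop(sprintf("angle triple row %d: need row > column, got (%d, %d)", r, i, j),
           call. = FALSE)
    }
    th[i, j] <- triples[r, 3]
  }
  angle_matrix(th)
}

.as_correlation_checked <- function(m, path) {
  n <- nrow(m)
  bad_diag <- which(abs(diag(m) - 1) > 1e-9)
  if (length(bad_diag)) {
    stop(sprintf("%s: diagonal entry (%d,%d) = %g; all diagonal entries must be equal to one",
                 path, bad_diag[1], bad_diag[1], diag(m)[bad_diag[1]]), call. = FALSE)
  }
  asym <- abs(m - t(m))
  if (max(asym) > 1e-9) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: not symmetric at (%d,%d)", path, w[1], w[2]), call. = FALSE)
  }
  out_of_range <- which(abs(m) > 1 + 1e-9, arr.ind = TRUE)
  if (nrow(out_of_range)) {
    w <- out_of_range[1, ]
    stop(sprintf("%s: entry (%d,%d) = %g outside [-1, 1]", path, w[1], w[2], m[w[1], w[2]]),
         call. = FALSE)
  }
  correlation_matrix(m)
}

#' Write a matrix as canonical delimited text
#'
#' Deterministic formatting: fixed 10-decimal notation, row-major,
#' newline-terminated.  Formats: `"csv"` (comma separated), `"table"`
#' (space separated), `"triples"` ("i j value" lines for the strictly
#' lower triangle — angle-matrix interchange form).
#'
#' @param obj matrix-like object.
#' @param path output file.
#' @param format one of `"table"`, `"csv"`, `"triples"`.
#' @return the MD5 checksum of the written file, invisibly usable for run
#'   manifests.
#' @export
write_matrix <- function(obj, path, format = c("table", "csv", "triples")) {
  format <- match.arg(format)
  m <- unclass(as.matrix(obj))
  lines <- switch(format,
    table = apply(m, 1, function(r) paste(sprintf("%.10f", r), collapse = " ")),
    csv = apply(m, 1, function(r) paste(sprintf("%.10f", r), collapse = ",")),
    triples = {
      n <- nrow(m)
      out <- character(0)
      for (j in seq_len(n - 1L)) {
        for (i in seq.int(j + 1L, n)) {
          out <- c(out, sprintf("%d %d %.10f", i, j, m[i, j]))
        }
      }
      out
    })
  writeLines(lines, path)
  unname(tools::md5sum(path))
}

#' Seeded fixture bundle: draws, bounds and correlation matrix
#'
#' Generates a strictly lower triangular 5 x 5 (by default) matrix of
#' unit-interval draws and runs it through the boundary-sequential
#' pipeline, yielding the lower-bound matrix L, upper-bound matrix U and
#' the correlation matrix C (before reordering) with its minimum
#' eigenvalue.  Regeneration under the same seed reproduces the bundle
#' exactly.  This is a synthetic stand-in exercising the
#' draws-to-bounds-to-matrix pipeline end to end.
#'
#' @param seed integer seed.
#' @param n dimension (default 5).
#' @param threshold_k boundary-gap threshold (default 0.01).
#' @param path optional directory; when given, writes `E.txt` (draws),
#'   `L.txt`, `U.txt`, `C.txt` and returns their checksums in the bundle.
#' @return list with `draws`, `L`, `U`, `C`, `theta`, `min_eigenvalue`,
#'   and (when written) `checksums`.
#' @export
make_fixtures <- function(seed, n = 5L, threshold_k = 0.01, path = NULL) {
  set.seed(as.integer(seed))
  u <- .draw_unit_matrix(as.integer(n), stats::runif)
  bundle <- bounds_matrices(u, threshold_k = threshold_k)
  bundle$draws <- u
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- c(E = file.path(path, "E.txt"), L = file.path(path, "L.txt"),
               U = file.path(path, "U.txt"), C = file.path(path, "C.txt"))
    sums <- c(write_matrix(u, files["E"]), write_matrix(bundle$L, files["L"]),
              write_matrix(bundle$U, files["U"]), write_matrix(bundle$C, files["C"]))
    names(sums) <- files
    bundle$checksums <- sums
  }
  bundle
}
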