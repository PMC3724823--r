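# Gradient schemes and FSL-dialect bvec/bval tables.

#' Construct a diffusion gradient scheme
#'
#' @param directions n x 3 matrix of gradient directions. Rows with b > 0
#'   are unit-normalised; zero rows are only allowed where b = 0.
#' @param bvalues Numeric vector of b-values in s/mm^2, length n.
#' @return An object of class `gradient_scheme` with unit `directions` and
#'   `bvalues`.
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3) stop("directions must have 3 columns")
  if (nrow(directions) != length(bvalues)) {
    stop("directions (", nrow(directions), " rows) and bvalues (",
         length(bvalues), ") length mismatch")
  }
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  if (!any(bvalues == 0)) stop("scheme must contain at least one b = 0 measurement")
  nrm <- sqrt(rowSums(directions^2))
  zero <- nrm == 0
  if (any(zero & bvalues > 0)) {
    stop("zero gradient direction with b > 0 at measurement ",
         which(zero & bvalues > 0)[1])
  }
  # normalise only genuinely non-unit rows, so a table already unit to
  # printed precision round-trips bit-identically through the writer
  fix <- !zero & abs(nrm - 1) > 1e-4
  directions[fix, ] <- directions[fix, , drop = FALSE] / nrm[fix]
  structure(list(directions = directions, bvalues = as.numeric(bvalues)),
            class = "gradient_scheme")
}

#' @export
length.gradient_scheme <- function(x) length(x$bvalues)

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", length(x), "measurements;",
      sum(x$bvalues == 0), "b=0,",
      sum(x$bvalues > 0), "diffusion-weighted (b =",
      paste(unique(x$bvalues[x$bvalues > 0]), collapse = ", "), "s/mm^2)\n")
  invisible(x)
}

#' Sixty-direction b = 1000 scheme
#'
#' Default acquisition emulated by the phantom: 60 diffusion-encoding
#' directions at b = 1000 s/mm^2 plus `n_b0` unweighted measurements. The
#' directions are an electrostatically even antipodal set built from a
#' Fibonacci hemisphere lattice (deterministic).
#'
#' @param n_dirs Number of diffusion-weighted directions (default 60).
#' @param bvalue b-value for the weighted measurements, s/mm^2.
#' @param n_b0 Number of leading b = 0 measurements (default 1).
#' @return A `gradient_scheme`.
#' @export
default_scheme <- function(n_dirs = 60, bvalue = 1000, n_b0 = 1) {
  i <- seq_len(n_dirs) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- i / n_dirs            # hemisphere only: antipodal symmetry of DWI
  r <- sqrt(1 - z^2)
  th <- golden * i
  dirs <- cbind(r * cos(th), r * sin(th), z)
  gradient_scheme(rbind(matrix(0, n_b0, 3), dirs),
                  c(rep(0, n_b0), rep(bvalue, n_dirs)))
}

#' Read an FSL-dialect gradient table
#'
#' `bvec` holds three whitespace-separated rows (x, y, z components, one
#' column per measurement); `bval` holds one row of b-values.
#'
#' @param bvec_path,bval_path Paths to the two text files.
#' @return A `gradient_scheme`.
#' @export
read_gradient_table <- function(bvec_path, bval_path) {
  parse_rows <- function(path, expect_rows) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != expect_rows) {
      stop(path, ": expected ", expect_rows, " row(s), found ", length(lines))
    }
    rows <- lapply(seq_along(lines), function(i) {
      tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      val <- suppressWarnings(as.numeric(tok))
      if (anyNA(val)) {
        bad <- which(is.na(val))[1]
        stop(path, ": non-numeric token '", tok[bad], "' at row ", i,
             ", column ", bad)
      }
      val
    })
    ncols <- vapply(rows, length, integer(1))
    if (length(unique(ncols)) != 1) {
      stop(path, ": rows have differing column counts (",
           paste(ncols, collapse = ", "), ")")
    }
    do.call(rbind, rows)
  }
  bvec <- parse_rows(bvec_path, 3)
  bval <- parse_rows(bval_path, 1)
  if (ncol(bvec) != ncol(bval)) {
    stop("bvec has ", ncol(bvec), " columns but bval has ", ncol(bval))
  }
  gradient_scheme(t(bvec), as.numeric(bval))
}

#' Write an FSL-dialect gradient table
#'
#' Canonical formatting (`%.6f`, single-space separated) so a
#' write-then-read round trip is bit-identical for the writer's own output.
#'
#' @param scheme A `gradient_scheme`.
#' @param bvec_path,bval_path Output paths.
#' @export
write_gradient_table <- function(scheme, bvec_path, bval_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  fmt <- function(x) sprintf("%.6f", x)
  writeLines(apply(t(scheme$directions), 1,
                   function(r) paste(fmt(r), collapse = " ")), bvec_path)
  writeLines(paste(fmt(scheme$bvalues), collapse = " "), bval_path)
  invisible(NULL)
}
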