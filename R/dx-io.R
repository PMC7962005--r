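#' OpenDX scalar-grid input/output (APBS dialect)
#'
#' Reads and writes the regular scalar-grid OpenDX files emitted by
#' continuum-electrostatics solvers: `object 1 class gridpositions`,
#' orthogonal `delta` rows, data `rank 0 ... data follows` with three
#' values per line and the z index varying fastest.
#'
#' @param grid a [potential_grid()].
#' @param path file path.
#' @param comment optional comment line (written with a `#` prefix).
#' @return `read_dx()` returns a `potential_grid`.
#' @export
write_dx <- function(grid, path, comment = "scalar potential grid (kT/e)") {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", comment), con)
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.6e %.6e %.6e",
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("delta %.6e %.6e %.6e", grid$spacing[1], 0, 0), con)
  writeLines(sprintf("delta %.6e %.6e %.6e", 0, grid$spacing[2], 0), con)
  writeLines(sprintf("delta %.6e %.6e %.6e", 0, 0, grid$spacing[3]), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(d)), con)
  # z fastest: aperm so the flattened vector runs z, then y, then x
  v <- as.vector(aperm(grid$values, c(3, 2, 1)))
  n <- length(v)
  full <- seq_len(n - n %% 3)
  if (length(full)) {
    m <- matrix(v[full], nrow = 3)
    writeLines(sprintf("%.6e %.6e %.6e", m[1, ], m[2, ], m[3, ]), con)
  }
  if (n %% 3 > 0) {
    writeLines(paste(sprintf("%.6e", v[(n - n %% 3 + 1):n]), collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "regular positions regular connections" class field', con)
  writeLines('component "positions" value 1', con)
  writeLines('component "connections" value 2', con)
  writeLines('component "data" value 3', con)
  invisible(path)
}

#' @rdname write_dx
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  .assert(!is.na(gp), "not an OpenDX gridpositions file")
  dims <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  org_line <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(org_line), "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)[1:3]
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4]), numeric(3)))
  .assert(all(abs(dmat[lower.tri(dmat)]) < 1e-12) &&
            all(abs(dmat[upper.tri(dmat)]) < 1e-12),
          "only axis-aligned grids are supported")
  spacing <- diag(dmat)
  data_at <- grep("data follows", lines)[1]
  .assert(!is.na(data_at), "no data section found")
  n <- prod(dims)
  vals <- numeric(0)
  i <- data_at + 1
  while (length(vals) < n && i <= length(lines)) {
    ln <- trimws(lines[i])
    if (nzchar(ln) && !grepl("^(attribute|object|component)", ln)) {
      vals <- c(vals, as.numeric(strsplit(ln, "\\s+")[[1]]))
    }
    i <- i + 1
  }
  .assert(length(vals) >= n, "truncated DX data section")
  arr <- aperm(array(vals[seq_len(n)], dim = rev(dims)), c(3, 2, 1))
  potential_grid(arr, origin, spacing)
}
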