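# Volumetric file I/O: OpenDX (Angstrom) and Gaussian CUBE (Bohr).
# Both formats store values with the last (z) index varying fastest.

#' @keywords internal
field_zfastest <- function(field) as.numeric(aperm(field, c(3, 2, 1)))

#' @keywords internal
check_field_finite <- function(field) {
  bad <- which(!is.finite(field), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite field value at grid index (%d, %d, %d)",
                 bad[1, 1], bad[1, 2], bad[1, 3]))
}

#' Write a 3D field as an OpenDX file
#'
#' Regular-grid OpenDX with origin and deltas in Angstrom; values are
#' written z-fastest, three per line, with enough digits that a
#' read/write cycle reproduces the file byte-for-byte.
#'
#' @param field 3D numeric array.
#' @param grid A [grid_spec()].
#' @param path Output path.
#' @param comment Optional header comment.
#' @return The path, invisibly.
#' @export
write_dx <- function(field, grid, path, comment = "rismhydra field") {
  stopifnot(all(dim(field) == grid$shape))
  check_field_finite(field)
  v <- field_zfastest(field)
  n <- length(v)
  pad <- (-n) %% 3
  vv <- c(sprintf("%.9e", v), rep("", pad))
  rows <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- trimws(paste(rows[, 1], rows[, 2], rows[, 3]), "right")
  hdr <- c(
    sprintf("# %s", comment),
    sprintf("object 1 class gridpositions counts %d %d %d",
            grid$shape[1], grid$shape[2], grid$shape[3]),
    sprintf("origin %.9e %.9e %.9e",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.9e 0 0", grid$spacing[1]),
    sprintf("delta 0 %.9e 0", grid$spacing[2]),
    sprintf("delta 0 0 %.9e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            grid$shape[1], grid$shape[2], grid$shape[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  tail_ <- c('attribute "dep" string "positions"',
             'object "regular positions regular connections" class field',
             'component "positions" value 1',
             'component "connections" value 2',
             'component "data" value 3')
  writeLines(c(hdr, lines, tail_), path)
  invisible(path)
}

#' Read an OpenDX file
#'
#' @param path DX file written by [write_dx()] or another standard
#'   regular-grid writer.
#' @return List: `field` (3D array), `grid` ([grid_spec()]).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  shape <- as.integer(utils::tail(strsplit(gp, " +")[[1]], 3))
  og <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(og, " +")[[1]][2:4])
  dl <- grep("^delta", lines, value = TRUE)
  dmat <- do.call(rbind, lapply(dl, function(x)
    as.numeric(strsplit(x, " +")[[1]][2:4])))
  spacing <- c(dmat[1, 1], dmat[2, 2], dmat[3, 3])
  i0 <- grep("data follows", lines)[1]
  items <- as.integer(sub(".*items +(\\d+) +data.*", "\\1", lines[i0]))
  iend <- grep("^attribute|^object \"", lines)
  iend <- min(iend[iend > i0], length(lines) + 1L)
  v <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(iend - 1)]), " +")))
  v <- v[seq_len(items)]
  field <- aperm(array(v, dim = rev(shape)), c(3, 2, 1))
  list(field = field, grid = grid_spec(origin, spacing, shape))
}

#' @keywords internal
atomic_numbers <- function() {
  z <- c(1, 6, 7, 8, 16, 15, 9, 17, 35, 53, 11, 12, 30, 20, 26, 34)
  names(z) <- c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
                "NA", "MG", "ZN", "CA", "FE", "SE")
  z
}

#' Write a 3D field as a Gaussian CUBE file
#'
#' Standard CUBE: header in Bohr, atom records from the solute, values
#' z-fastest six per line.
#'
#' @param field 3D numeric array.
#' @param grid A [grid_spec()].
#' @param solute Optional [solute_system()] for the atom records; when
#'   `NULL` a single dummy atom at the origin is written (the format
#'   requires at least one).
#' @param path Output path.
#' @param comment Header comment.
#' @return The path, invisibly.
#' @export
write_cube <- function(field, grid, path, solute = NULL,
                       comment = "rismhydra field") {
  stopifnot(all(dim(field) == grid$shape))
  check_field_finite(field)
  b <- BOHR_PER_ANG
  natoms <- if (is.null(solute)) 1L else nrow(solute$atoms)
  hdr <- c(comment, "distribution function on a regular grid",
           sprintf("%5d %11.6f %11.6f %11.6f", natoms,
                   grid$origin[1] * b, grid$origin[2] * b, grid$origin[3] * b),
           sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[1],
                   grid$spacing[1] * b, 0, 0),
           sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[2], 0,
                   grid$spacing[2] * b, 0),
           sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[3], 0, 0,
                   grid$spacing[3] * b))
  at <- if (is.null(solute)) {
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, 0, 0, 0)
  } else {
    a <- solute$atoms
    zt <- atomic_numbers()
    z <- zt[toupper(a$element)]
    z[is.na(z)] <- 1L
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, a$charge,
            a$x * b, a$y * b, a$z * b)
  }
  v <- field_zfastest(field)
  n <- length(v)
  pad <- (-n) %% 6
  vv <- c(sprintf("%13.5e", v), rep("", pad))
  rows <- matrix(vv, ncol = 6, byrow = TRUE)
  lines <- trimws(apply(rows, 1, paste, collapse = " "), "right")
  writeLines(c(hdr, at, lines), path)
  invisible(path)
}

#' Read a Gaussian CUBE file
#'
#' @param path CUBE file.
#' @return List: `field`, `grid` (converted back to Angstrom), `atoms`
#'   (data.frame `z`, `charge`, `x`, `y`, `z_coord` in Angstrom).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  b <- BOHR_PER_ANG
  num <- function(s) as.numeric(strsplit(trimws(s), " +")[[1]])
  h3 <- num(lines[3]); natoms <- as.integer(h3[1]); origin <- h3[2:4] / b
  ax <- lapply(4:6, function(i) num(lines[i]))
  shape <- vapply(ax, function(a) as.integer(a[1]), 1L)
  spacing <- c(ax[[1]][2], ax[[2]][3], ax[[3]][4]) / b
  atoms <- do.call(rbind, lapply(seq_len(abs(natoms)), function(i) {
    f <- num(lines[6 + i])
    data.frame(z = as.integer(f[1]), charge = f[2],
               x = f[3] / b, y = f[4] / b, z_coord = f[5] / b)
  }))
  v <- as.numeric(unlist(strsplit(trimws(
    lines[(7 + abs(natoms)):length(lines)]), " +")))
  v <- v[seq_len(prod(shape))]
  field <- aperm(array(v, dim = rev(shape)), c(3, 2, 1))
  list(field = field, grid = grid_spec(origin, spacing, shape),
       atoms = atoms)
}

#' Write a converged field set as volumetric files
#'
#' @param fields A `solvation_fields` object.
#' @param dir Output directory (created if needed).
#' @param format `"dx"`, `"cube"`, or both.
#' @param solute Solute for CUBE atom records.
#' @param what Which arrays to export (`"g"`, `"h"`, `"c_short"`).
#' @return Character vector of written paths, invisibly.
#' @export
write_volumetric <- function(fields, dir, format = "dx", solute = NULL,
                             what = "g") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (w in what) for (ty in fields$site_types) {
    arr <- fields[[w]][[ty]]
    base <- file.path(dir, sprintf("%s_%s", w, ty))
    if ("dx" %in% format) {
      p <- paste0(base, ".dx")
      write_dx(arr, fields$grid, p, comment = sprintf("%s(%s)", w, ty))
      paths <- c(paths, p)
    }
    if ("cube" %in% format) {
      p <- paste0(base, ".cube")
      write_cube(arr, fields$grid, p, solute = solute,
                 comment = sprintf("%s(%s)", w, ty))
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
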