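# 3-D dose and structure rasters on a shared regular geometry, plus a
# minimal NRRD (ascii encoding) reader/writer so grids travel as plain text.

#' Construct a dose grid
#'
#' @param values 3-D numeric array of dose values (Gy), all finite and >= 0.
#' @param origin Length-3 position of the first voxel center, mm.
#' @param spacing Length-3 (or scalar) voxel spacing, mm, > 0.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin = c(0, 0, 0), spacing = 1) {
  if (length(dim(values)) != 3L) stop_sparc("dose values must be a 3-D array")
  if (any(!is.finite(values)) || any(values < 0))
    stop_sparc("dose values must be finite and non-negative")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop_sparc("spacing must be positive")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing), class = "dose_grid")
}

#' Construct a structure mask
#'
#' @param name Structure name (e.g. `"ctv"`, `"body"`).
#' @param mask 3-D logical array on the same geometry as its dose grid.
#' @param origin,spacing Grid geometry, as in [dose_grid()].
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask, origin = c(0, 0, 0), spacing = 1) {
  if (length(dim(mask)) != 3L) stop_sparc("mask must be a 3-D array")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  structure(list(name = name, mask = array(as.logical(mask), dim(mask)),
                 origin = as.numeric(origin), spacing = spacing),
            class = "structure_mask")
}

same_geometry <- function(a, b, tol = 1e-6) {
  va <- a$values %||% a$mask; vb <- b$values %||% b$mask
  identical(dim(va), dim(vb)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Voxel volume of a grid in cubic centimeters
#' @param grid A `dose_grid` or `structure_mask` (spacing in mm).
#' @return Voxel volume, cc.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

# rigid nearest-voxel translation of the dose values; voxels shifted in
# from outside the grid receive zero dose.
translate_dose <- function(dose, shift_mm) {
  off <- round(shift_mm / dose$spacing)
  if (all(off == 0)) return(dose)
  dm <- dim(dose$values)
  out <- array(0, dm)
  src <- lapply(1:3, function(k) {
    i <- seq_len(dm[k]) - off[k]
    i[i < 1L | i > dm[k]] <- NA_integer_
    i
  })
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    dose$values[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  dose$values <- out
  dose
}

#' Write a grid as an ascii-encoded NRRD file
#'
#' Emits an NRRD0004 header (type, sizes, space origin and directions,
#' `encoding: ascii`) followed by the values in x-fastest order; the whole
#' file is plain text.
#'
#' @param grid A `dose_grid` or `structure_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(grid, path) {
  vals <- grid$values %||% (grid$mask * 1L)
  is_mask <- inherits(grid, "structure_mask")
  dm <- dim(vals)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    paste0("type: ", if (is_mask) "uchar" else "double"),
    "dimension: 3",
    paste0("sizes: ", paste(dm, collapse = " ")),
    "space: left-posterior-superior",
    paste0("space directions: (", grid$spacing[1], ",0,0) (0,",
           grid$spacing[2], ",0) (0,0,", grid$spacing[3], ")"),
    paste0("space origin: (", paste(grid$origin, collapse = ","), ")"),
    "encoding: ascii",
    ""), con)
  vec <- as.vector(vals)
  writeLines(paste(format(vec, trim = TRUE, digits = 12, scientific = FALSE),
                   collapse = " "), con)
  invisible(path)
}

#' Read an ascii-encoded NRRD file
#'
#' Supports the subset written by [write_nrrd()]: 3-D arrays, ascii
#' encoding, axis-aligned space directions.
#'
#' @param path NRRD file path.
#' @param as_mask Return a `structure_mask` (values coerced to logical).
#' @param name Structure name when `as_mask = TRUE`.
#' @return A `dose_grid` or `structure_mask`.
#' @export
read_nrrd <- function(path, as_mask = FALSE, name = "structure") {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop_sparc("%s is not an NRRD file", path)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop_sparc("NRRD header not terminated by a blank line")
  hdr <- lines[2:(blank - 1)]
  getf <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  if (!identical(getf("encoding"), "ascii"))
    stop_sparc("only ascii NRRD encoding is supported")
  sizes <- as.integer(strsplit(getf("sizes"), " ")[[1]])
  nums <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  dirs <- regmatches(getf("space directions") %||% "",
                     gregexpr("\\([^)]*\\)", getf("space directions") %||% ""))[[1]]
  spacing <- if (length(dirs) == 3L)
    vapply(1:3, function(k) nums(dirs[k])[k], numeric(1)) else c(1, 1, 1)
  origin <- if (!is.null(getf("space origin"))) nums(getf("space origin"))
            else c(0, 0, 0)
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != prod(sizes))
    stop_sparc("NRRD data length %d does not match sizes", length(vals))
  arr <- array(vals, sizes)
  if (as_mask) structure_mask(name, arr != 0, origin, spacing)
  else dose_grid(arr, origin, spacing)
}
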