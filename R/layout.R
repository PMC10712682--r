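#' Construct a validated sensing-matrix layout
#'
#' A layout describes the geometry of a row/column pressure-sensing matrix:
#' which crossings of the row and column conductive tapes carry an active
#' sensing unit, and which plantar sub-area (heel, arch, forefoot, toe) each
#' active unit belongs to. Crossings cut away to fit the insole outline are
#' inactive and treated as open circuits everywhere in the package.
#'
#' @param n_rows,n_cols Number of row and column lines.
#' @param mask Logical matrix (`n_rows` x `n_cols`); `TRUE` marks an active
#'   sensing unit at that crossing.
#' @param subarea_map Character matrix of the same dimensions; every active
#'   cell must hold one of `"heel"`, `"arch"`, `"forefoot"`, `"toe"`.
#'   Inactive cells may be `NA`.
#' @param pitch_mm Center-to-center spacing of the sensing units in mm
#'   (5 mm tape plus 5 mm gap by default).
#' @return An object of class `sensor_layout` with elements `n_rows`,
#'   `n_cols`, `mask`, `subarea`, `pitch_mm`, plus `units`, a data.frame of
#'   active crossings (0-based `row`, `col`, `id` of the form `"r{row}c{col}"`,
#'   and `subarea`).
#' @examples
#' lay <- build_layout(2, 2, matrix(TRUE, 2, 2),
#'                     matrix(c("heel", "heel", "toe", "toe"), 2, 2))
#' n_units(lay)
#' @export
build_layout <- function(n_rows, n_cols, mask, subarea_map,
                         pitch_mm = 10) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (!is.matrix(mask) || !identical(dim(mask), c(as.integer(n_rows), as.integer(n_cols))))
    stop("`mask` must be a ", n_rows, "x", n_cols, " logical matrix")
  if (!identical(dim(subarea_map), dim(mask)))
    stop("`subarea_map` dimensions must match `mask`")
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("zero active units: mask selects no crossings")
  valid <- c("heel", "arch", "forefoot", "toe")
  lab <- subarea_map[mask]
  if (anyNA(lab) || !all(lab %in% valid))
    stop("every active crossing needs a sub-area label in ",
         paste(valid, collapse = "/"))

  idx <- which(mask, arr.ind = TRUE)
  # 0-based indices, row-major ordering for stable unit identity
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  units <- data.frame(
    row = idx[, 1] - 1L,
    col = idx[, 2] - 1L,
    subarea = subarea_map[idx],
    stringsAsFactors = FALSE
  )
  units$id <- sprintf("r%dc%d", units$row, units$col)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         mask = mask, subarea = subarea_map, pitch_mm = pitch_mm,
         units = units[, c("id", "row", "col", "subarea")]),
    class = "sensor_layout"
  )
}

#' Number of active sensing units in a layout
#' @param layout A `sensor_layout`.
#' @return Integer count of active crossings.
#' @export
n_units <- function(layout) nrow(layout$units)

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> ", x$n_rows, "x", x$n_cols, " matrix, ",
      n_units(x), " active units\n", sep = "")
  print(table(x$units$subarea))
  invisible(x)
}

#' Default insole layout: 26 x 8 matrix with 174 active units
#'
#' Reconstructs the reference insole sensing matrix: 26 row tapes by 8 column
#' tapes (208 crossings), trimmed to the insole outline so that 174 sensing
#' units remain. Rows run from the toe (row 0) to the heel (row 25); per-row
#' active widths narrow at the toe tip, the lateral arch, and the rounded
#' heel. Sub-areas are assigned by longitudinal bands: toe (rows 0-3),
#' forefoot (rows 4-10), arch (rows 11-17) and heel (rows 18-25).
#'
#' @return A `sensor_layout` with exactly 174 active units.
#' @examples
#' n_units(default_insole_layout())
#' @export
default_insole_layout <- function() {
  widths <- c(4, 6, 7, 8,            # toe tip narrows
              8, 8, 8, 8, 8, 8, 8,   # forefoot: full width
              7, 6, 6, 6, 6, 6, 7,   # arch: lateral trim
              7, 7, 7, 7, 7, 6, 5, 3)# heel: rounded rear
  stopifnot(length(widths) == 26, sum(widths) == 174)
  bands <- rep(c("toe", "forefoot", "arch", "heel"), c(4, 7, 7, 8))
  mask <- matrix(FALSE, 26, 8)
  sub <- matrix(NA_character_, 26, 8)
  for (r in seq_len(26)) {
    w <- widths[r]
    start <- (8 - w) %/% 2 + 1  # centered in the column span
    cols <- seq(start, start + w - 1)
    mask[r, cols] <- TRUE
    sub[r, cols] <- bands[r]
  }
  build_layout(26, 8, mask, sub, pitch_mm = 10)
}

#' Write a layout to a JSON file
#'
#' @param layout A `sensor_layout`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  obj <- list(
    n_rows = layout$n_rows, n_cols = layout$n_cols,
    pitch_mm = layout$pitch_mm,
    active = unname(apply(layout$mask, 1, as.integer, simplify = FALSE)),
    subarea = unname(apply(layout$subarea, 1, function(r) {
      r[is.na(r)] <- ""
      as.list(r)
    }, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a layout from a JSON file
#'
#' @param path File written by [write_layout()].
#' @return A `sensor_layout`.
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path)
  nr <- obj$n_rows; nc <- obj$n_cols
  mask <- matrix(FALSE, nr, nc)
  sub <- matrix(NA_character_, nr, nc)
  for (r in seq_len(nr)) {
    mask[r, ] <- as.logical(unlist(obj$active[[r]]))
    s <- unlist(obj$subarea[[r]])
    s[s == ""] <- NA_character_
    sub[r, ] <- s
  }
  build_layout(nr, nc, mask, sub, pitch_mm = obj$pitch_mm)
}
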