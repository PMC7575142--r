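#' Build a cell metadata table
#'
#' One row per recorded cell.  Soma position is the 2-D position in the
#' slice plane (um); `depth_um` is distance from the slice surface.
#'
#' @param cell_id character vector of unique ids.
#' @param label genetic label, one of `"ORX"`, `"MCH"`, `"VGLUT2"`,
#'   `"GAD65-GFP"`, `"GAD65-cre"`, `"VGAT"`, `"PV/FS"`, `"NPY"`,
#'   `"pyramidal"`, `"n.m."`.
#' @param region `"LH"` or `"mPFC"`.
#' @param x_um,y_um soma coordinates in the slice plane, um (may be `NA`).
#' @param depth_um depth from slice surface, um, `>= 0`.
#' @param opsin_positive logical: does the cell express the opsin?
#' @return a data.frame suitable for the `cells` slot of a [Session-class].
#' @examples
#' cellTable(c("c1", "c2"), label = "n.m.", x_um = c(0, 30), y_um = c(0, 40))
#' @export
cellTable <- function(cell_id, label = "n.m.", region = "LH",
                      x_um = NA_real_, y_um = NA_real_, depth_um = 40,
                      opsin_positive = FALSE) {
  df <- data.frame(cell_id = as.character(cell_id), label = label,
                   region = region, x_um = as.numeric(x_um),
                   y_um = as.numeric(y_um), depth_um = as.numeric(depth_um),
                   opsin_positive = opsin_positive,
                   stringsAsFactors = FALSE)
  if (any(is.infinite(df$x_um)) || any(is.infinite(df$y_um)))
    stop("soma coordinates must be finite (or NA if unavailable)")
  df
}

#' Intersomatic distance in the slice plane
#'
#' Euclidean distance between two somata measured in the 2-D slice plane
#' (depth is excluded, matching micrograph-based measurement).  Returns
#' `NA_real_` -- never 0 -- when either soma position is unavailable.
#'
#' @param cells cell table (see [cellTable()]) or a [Session-class].
#' @param a,b cell ids.
#' @return distance in um (`>= 0`), or `NA_real_` if coordinates missing.
#' @examples
#' cl <- cellTable(c("a", "b"), x_um = c(0, 3), y_um = c(0, 4))
#' intersomaticDistance(cl, "a", "b")  # 5
#' @export
intersomaticDistance <- function(cells, a, b) {
  if (is(cells, "Session")) cells <- cells@cells
  ra <- cells[cells$cell_id == a, , drop = FALSE]
  rb <- cells[cells$cell_id == b, , drop = FALSE]
  if (nrow(ra) != 1L || nrow(rb) != 1L)
    stop("cell id not found: ", if (nrow(ra) != 1L) a else b)
  if (anyNA(c(ra$x_um, ra$y_um, rb$x_um, rb$y_um)))
    return(NA_real_)
  sqrt((ra$x_um - rb$x_um)^2 + (ra$y_um - rb$y_um)^2)
}
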