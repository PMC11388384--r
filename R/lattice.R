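#' Square-cell lattice geometry
#'
#' Defines the tissue geometry used by the diffusion simulator: a plane (or two
#' overgrown planes) of square cells whose borders act as reflective diffusion
#' barriers for membrane-confined molecules. Cells are indexed by integer
#' column/row (`i`, `j`) and a layer in `{0, 1}`; cell `(i, j)` of layer 0
#' occupies the half-open square `[i*L, (i+1)*L) x [j*L, (j+1)*L)` with
#' `L = cell_edge_um`. In the `offset_bilayer` arrangement the second layer is
#' shifted by half a cell edge on both axes, so each interior cell overlaps
#' four cells of the other layer; in `stacked_bilayer` the layers coincide.
#'
#' @param cell_edge_um Cell edge length in micrometres (default 5).
#' @param arrangement One of `"monolayer"`, `"stacked_bilayer"`,
#'   `"offset_bilayer"`.
#' @param extent_cells Integer half-width of the lattice in cells per axis; the
#'   lattice spans `[-extent, +extent]` cells around the sender. Simulations
#'   raise an error if an agent ever reaches the extent, since the model
#'   assumes an effectively unbounded field.
#' @return A `lattice_spec` object.
#' @examples
#' spec <- lattice_spec()
#' cell_of_position(2.5, 2.5, 0, spec)
#' @export
lattice_spec <- function(cell_edge_um = 5,
                         arrangement = c("monolayer", "stacked_bilayer",
                                         "offset_bilayer"),
                         extent_cells = 200L) {
  arrangement <- match.arg(arrangement)
  stopifnot(is.numeric(cell_edge_um), length(cell_edge_um) == 1L,
            is.finite(cell_edge_um), cell_edge_um > 0)
  extent_cells <- as.integer(extent_cells)
  stopifnot(extent_cells >= 1L)
  structure(
    list(cell_edge_um = as.numeric(cell_edge_um),
         arrangement = arrangement,
         extent_cells = extent_cells),
    class = "lattice_spec"
  )
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %s, cell edge %g um, extent +/-%d cells\n",
              x$arrangement, x$cell_edge_um, x$extent_cells))
  invisible(x)
}

n_layers <- function(spec) if (spec$arrangement == "monolayer") 1L else 2L

#' Layer-dependent tiling offset
#'
#' Origin shift of the cell tiling for a given layer: zero except for layer 1
#' of an `offset_bilayer`, where the tiling is shifted by half a cell edge on
#' both axes.
#'
#' @param layer Layer index (0 or 1).
#' @param spec A [lattice_spec()].
#' @return Scalar offset in micrometres applied to both axes.
#' @export
layer_offset <- function(layer, spec) {
  if (spec$arrangement == "offset_bilayer" && layer == 1L)
    spec$cell_edge_um / 2 else 0
}

#' Cell id for a position
#'
#' Maps a point to the cell containing it, under the half-open convention
#' `[iL, (i+1)L)` per axis (a point on a shared border belongs to the cell on
#' its upper-right side).
#'
#' @param x_um,y_um Position in micrometres.
#' @param layer Layer index (0 for monolayer).
#' @param spec A [lattice_spec()].
#' @return A `cell_id` list with integer fields `i`, `j`, `layer`.
#' @export
cell_of_position <- function(x_um, y_um, layer = 0L, spec = lattice_spec()) {
  stopifnot(is.finite(x_um), is.finite(y_um))
  layer <- as.integer(layer)
  if (layer < 0L || layer >= n_layers(spec))
    stop("invalid layer ", layer, " for arrangement ", spec$arrangement)
  L <- spec$cell_edge_um
  off <- layer_offset(layer, spec)
  i <- as.integer(floor((x_um - off) / L))
  j <- as.integer(floor((y_um - off) / L))
  if (max(abs(c(i, j))) > spec$extent_cells)
    stop("position (", x_um, ", ", y_um, ") lies beyond the lattice extent")
  cell_id(i, j, layer)
}

#' @rdname cell_of_position
#' @param i,j Integer cell indices.
#' @export
cell_id <- function(i, j, layer = 0L) {
  structure(list(i = as.integer(i), j = as.integer(j),
                 layer = as.integer(layer)),
            class = "cell_id")
}

#' @export
print.cell_id <- function(x, ...) {
  cat(sprintf("<cell (%d, %d) layer %d>\n", x$i, x$j, x$layer))
  invisible(x)
}

#' @export
format.cell_id <- function(x, ...) sprintf("(%d,%d,%d)", x$i, x$j, x$layer)

#' Lower-left corner of a cell
#'
#' @param cell A [cell_id()].
#' @param spec A [lattice_spec()].
#' @return Numeric `c(x, y)` of the cell's lower-left corner in micrometres.
#' @export
cell_origin <- function(cell, spec) {
  off <- layer_offset(cell$layer, spec)
  c(cell$i * spec$cell_edge_um + off, cell$j * spec$cell_edge_um + off)
}

#' Topological neighbors of a cell
#'
#' A neighbor is a cell reachable by a membrane-confined molecule in a single
#' free episode of vanishing length: the four edge-sharing in-plane cells,
#' plus any cell of the other layer whose square overlaps this cell with
#' nonzero area. Interior degrees are 4 (monolayer), 5 (stacked bilayer:
#' the coincident cell) and 8 (offset bilayer: four quarter-overlapping
#' cells). Cells at the lattice edge simply have fewer neighbors;
#' corner-touching offset cells (zero overlap area) do not count.
#'
#' @param cell A [cell_id()].
#' @param spec A [lattice_spec()].
#' @return List of `cell_id` objects.
#' @export
neighbor_cells <- function(cell, spec) {
  ext <- spec$extent_cells
  stopifnot(max(abs(c(cell$i, cell$j))) <= ext)
  cand <- list(
    c(cell$i - 1L, cell$j, cell$layer),
    c(cell$i + 1L, cell$j, cell$layer),
    c(cell$i, cell$j - 1L, cell$layer),
    c(cell$i, cell$j + 1L, cell$layer)
  )
  if (spec$arrangement == "stacked_bilayer") {
    cand <- c(cand, list(c(cell$i, cell$j, 1L - cell$layer)))
  } else if (spec$arrangement == "offset_bilayer") {
    other <- 1L - cell$layer
    # layer-1 cell (i,j) spans [iL+L/2,(i+1)L+L/2): overlaps layer-0 cells
    # (i,j),(i+1,j),(i,j+1),(i+1,j+1); going 1 -> 0 the offsets are reversed.
    d <- if (cell$layer == 0L) c(-1L, 0L) else c(0L, 1L)
    for (di in d) for (dj in d)
      cand <- c(cand, list(c(cell$i + di, cell$j + dj, other)))
  }
  keep <- Filter(function(c3) max(abs(c3[1:2])) <= ext, cand)
  lapply(keep, function(c3) cell_id(c3[1], c3[2], c3[3]))
}

# Triangle-wave fold of a coordinate into [0, L]: exact specular reflection
# at 0 and L for displacements of any size, applied per axis.
fold_axis <- function(u, L) {
  m <- u %% (2 * L)
  L - abs(m - L)
}

#' Reflect a proposed move into its cell
#'
#' Applies the reflective-boundary rule for membrane-confined molecules: the
#' proposed endpoint is folded back into the cell by specular reflection,
#' independently per axis. The triangle-wave fold handles displacements larger
#' than one cell edge exactly (multiple bounces), and leaves points already
#' inside the cell unchanged.
#'
#' @param x_old,y_old Current position (must lie inside `cell`).
#' @param x_prop,y_prop Proposed position.
#' @param cell The confining [cell_id()].
#' @param spec A [lattice_spec()].
#' @return Numeric `c(x, y)` inside the closed cell square.
#' @export
reflect_into_cell <- function(x_old, y_old, x_prop, y_prop, cell, spec) {
  L <- spec$cell_edge_um
  o <- cell_origin(cell, spec)
  if (x_old < o[1] || x_old >= o[1] + L || y_old < o[2] || y_old >= o[2] + L)
    stop("current position is not inside the confining cell")
  c(o[1] + fold_axis(x_prop - o[1], L),
    o[2] + fold_axis(y_prop - o[2], L))
}
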