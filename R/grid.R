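#' Electrode grid layout
#'
#' Describes the physical arrangement of HD-sEMG channels: `n_grids`
#' electrode patches, each a `rows x cols` matrix of electrodes. Channels
#' are numbered row-major within a grid, grids concatenated, so channel 1
#' is grid 1 row 1 column 1. Two stock layouts cover the use cases here:
#' `grid_layout(4, 4, 4)` (four 16-electrode patches, 64 channels, the
#' child-sized montage) and `grid_layout(8, 16, 1)` (one 128-electrode
#' patch, the adult-sized montage).
#'
#' @param rows,cols electrodes per patch.
#' @param n_grids number of patches.
#' @return an object of class `grid_layout`.
#' @export
grid_layout <- function(rows = 4L, cols = 4L, n_grids = 4L) {
  stopifnot(rows >= 1, cols >= 1, n_grids >= 1)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         n_grids = as.integer(n_grids)),
    class = "grid_layout"
  )
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout> %d grid(s) of %d x %d (%d channels)\n",
              x$n_grids, x$rows, x$cols, n_channels(x)))
  invisible(x)
}

#' Total channel count of a grid layout
#' @param grid a [grid_layout()].
#' @return integer channel count.
#' @export
n_channels <- function(grid) grid$rows * grid$cols * grid$n_grids

#' Channel coordinates of a grid layout
#'
#' @param grid a [grid_layout()].
#' @return data.frame with columns `channel`, `grid`, `row`, `col`
#'   in channel order (row-major within grid).
#' @export
channel_coords <- function(grid) {
  per <- grid$rows * grid$cols
  ch <- seq_len(n_channels(grid))
  within_idx <- (ch - 1L) %% per
  data.frame(
    channel = ch,
    grid = (ch - 1L) %/% per + 1L,
    row = within_idx %/% grid$cols + 1L,
    col = within_idx %% grid$cols + 1L
  )
}

# 4-neighbourhood (up/down/left/right, same grid) of a channel index.
grid_neighbours <- function(grid, channel) {
  co <- channel_coords(grid)
  me <- co[co$channel == channel, ]
  same <- co[co$grid == me$grid, ]
  hit <- (abs(same$row - me$row) + abs(same$col - me$col)) == 1L
  same$channel[hit]
}
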