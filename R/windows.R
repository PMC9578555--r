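#' Build a sliding/tiling window grid
#'
#' Windows are 0-based half-open intervals tiling each scaffold from 0 with
#' the given size and step; a final partial window is retained and flagged.
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths (bp).
#' @param window_size window width in bp.
#' @param step distance between window starts (`step <= window_size`).
#' @return a data frame of class `window_grid` with columns `scaffold_id`,
#'   `start`, `end`, `partial`.
#' @export
make_windows <- function(scaffold_lengths, window_size, step = window_size) {
  if (step < 1 || window_size < step)
    stop("need window_size >= step >= 1")
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("scaffold_%d",
                                       seq_along(scaffold_lengths))
  res <- lapply(names(scaffold_lengths), function(sc) {
    len <- scaffold_lengths[[sc]]
    if (len <= 0)
      return(data.frame(scaffold_id = character(0), start = numeric(0),
                        end = numeric(0), partial = logical(0)))
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window_size, len)
    data.frame(scaffold_id = sc, start = starts, end = ends,
               partial = ends - starts < window_size)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("window_grid", "data.frame")
  out
}

# window index (row of grid) for each site of a scaffold; a position may
# fall in several overlapping windows -> returns a list site -> indices.
# Positions are 1-based bp; windows 0-based half-open, so position p lies in
# [start, end) iff start < p <= end.
sites_in_windows <- function(grid, scaffold_id, positions) {
  g <- grid[grid$scaffold_id == scaffold_id, , drop = FALSE]
  gi <- which(grid$scaffold_id == scaffold_id)
  lapply(seq_along(gi), function(k)
    which(positions > g$start[k] & positions <= g$end[k]))
}
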