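#' Lattice offsets inside a circle
#'
#' All integer-lattice offsets `(i * spacing, j * spacing)` whose Euclidean
#' norm is at most `radius_km` (closed disc), including the centre `(0, 0)`.
#' On a 1-km grid the circles of radius 1.6, 3.2 and 6.4 km hold 9, 37 and
#' 129 intersections respectively — the plot counts entering each landscape
#' buffer average.
#'
#' @param radius_km circle radius in km (> 0).
#' @param spacing_km lattice spacing in km (> 0), default 1.
#' @return data frame with columns `dx`, `dy` (km), in row-major order
#'   (`dy` slow, `dx` fast).
#' @export
lattice_offsets <- function(radius_km, spacing_km = 1) {
  if (!is.numeric(radius_km) || radius_km <= 0)
    stop("radius_km must be positive")
  if (!is.numeric(spacing_km) || spacing_km <= 0)
    stop("spacing_km must be positive")
  k <- floor(radius_km / spacing_km)
  g <- expand.grid(dx = (-k:k) * spacing_km, dy = (-k:k) * spacing_km)
  g <- g[g$dx^2 + g$dy^2 <= radius_km^2, , drop = FALSE]
  g <- g[order(g$dy, g$dx), ]
  rownames(g) <- NULL
  g
}

#' Landscape-scale canopy cover by buffer averaging
#'
#' For each plot, the unweighted mean of `cover_pct` over all plots found at
#' the lattice offsets within `radius_km` of its node (the focal plot
#' included). Lattice intersections carrying no plot (non-forested nodes,
#' domain edges) are skipped, so the average runs over the plots the circle
#' actually holds; `n_available` records how many.
#'
#' @param plots plot table (1-km lattice coordinates `x_km`, `y_km`).
#' @param radius_km buffer radius in km.
#' @return data frame `plot_id`, `cover`, `n_available` aligned with `plots`.
#' @export
landscape_cover <- function(plots, radius_km) {
  assert_plot_table(plots)
  if (nrow(plots) == 0) stop("empty plot table")
  off <- lattice_offsets(radius_km, 1)
  # integer lattice nodes encoded as a single numeric key for fast match()
  key <- function(x, y) x * 2^20 + y
  node_key <- key(plots$x_km, plots$y_km)
  acc <- numeric(nrow(plots))
  nav <- integer(nrow(plots))
  for (i in seq_len(nrow(off))) {
    idx <- match(key(plots$x_km + off$dx[i], plots$y_km + off$dy[i]), node_key)
    hit <- !is.na(idx)
    acc[hit] <- acc[hit] + plots$cover_pct[idx[hit]]
    nav <- nav + hit
  }
  data.frame(plot_id = plots$plot_id, cover = acc / nav, n_available = nav,
             stringsAsFactors = FALSE)
}

#' Cover at the local and all landscape scales
#'
#' @param plots plot table.
#' @param radii landscape buffer radii in km (default 1.6, 3.2, 6.4).
#' @return data frame `plot_id`, `cover_local`, then one `cover_<r>` and
#'   `n_<r>` pair per radius (e.g. `cover_1p6`, `n_1p6`).
#' @export
multiscale_cover <- function(plots, radii = c(1.6, 3.2, 6.4)) {
  assert_plot_table(plots)
  out <- data.frame(plot_id = plots$plot_id, cover_local = plots$cover_pct,
                    stringsAsFactors = FALSE)
  for (r in radii) {
    lc <- landscape_cover(plots, r)
    tag <- scale_tag(r)
    out[[paste0("cover_", tag)]] <- lc$cover
    out[[paste0("n_", tag)]] <- lc$n_available
  }
  out
}

scale_tag <- function(r) gsub("\\.", "p", format(r, trim = TRUE))

#' Exclude plots near the domain border
#'
#' Drops plots closer than `margin_km` to any edge of the axis-aligned
#' bounding rectangle of the plot coordinates (or of explicit `bounds`).
#' Used to avoid landscape buffers spilling over administrative borders
#' where forest continues but no plots were surveyed.
#'
#' @param plots plot table.
#' @param margin_km minimum distance to every domain edge (default 6.4 km).
#' @param bounds optional list with `x` and `y` length-2 ranges overriding the
#'   inferred bounding box.
#' @return the retained plot table.
#' @export
exclude_border <- function(plots, margin_km = 6.4, bounds = NULL) {
  assert_plot_table(plots)
  stopifnot(margin_km >= 0)
  if (is.null(bounds))
    bounds <- list(x = range(plots$x_km), y = range(plots$y_km))
  keep <- plots$x_km - bounds$x[1] >= margin_km &
          bounds$x[2] - plots$x_km >= margin_km &
          plots$y_km - bounds$y[1] >= margin_km &
          bounds$y[2] - plots$y_km >= margin_km
  if (!any(keep))
    stop("border exclusion removed all ", nrow(plots),
         " plots (margin ", margin_km, " km); domain too small")
  out <- plots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
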