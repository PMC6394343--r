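#' Covariate stacks
#'
#' A `covariate_stack` is the package's central container: an ordered set of
#' co-registered single-band raster layers, each flagged `"continuous"` or
#' `"categorical"`, together with the grid geometry and the combined nodata
#' mask. All statistics downstream (strata, histograms, covariance) are
#' computed over the `r` cells that are valid in *every* layer.
#'
#' Grid convention: row 1 is the top of the map; cells are sampled at their
#' centers; cells are half-open so a point exactly on an edge belongs to the
#' cell to the right/below. Coordinates must be in a projected CRS with meter
#' units -- buffer radii and cell sizes are metric throughout.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#'   `NA` marks nodata. Categorical layers hold integer class codes.
#' @param kinds character vector, one of `"continuous"`/`"categorical"` per
#'   layer (recycled if length 1).
#' @param xmin,ymax coordinates of the grid's top-left corner (meters).
#' @param cellsize cell edge length in meters (> 0).
#' @param crs free-text CRS description. Geographic CRSs (anything matching
#'   `longlat`, `EPSG:4326` or `WGS84` lat/long) are rejected: degrees are
#'   not meters.
#' @return an object of class `covariate_stack` with elements `layers`,
#'   `kinds`, `xmin`, `ymax`, `cellsize`, `crs`, `mask` (logical matrix,
#'   `TRUE` = valid in all layers) and `r` (number of valid cells).
#' @export
covariate_stack <- function(layers, kinds, xmin = 0, ymax = NULL,
                            cellsize = 1, crs = NA_character_) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty list of matrices", call. = FALSE)
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    names(layers) <- paste0("layer", seq_along(layers))
  kinds <- rep_len(match.arg(kinds, c("continuous", "categorical"),
                             several.ok = TRUE), length(layers))
  names(kinds) <- names(layers)
  dims <- dim(layers[[1L]])
  for (nm in names(layers)) {
    if (!is.matrix(layers[[nm]]) || !is.numeric(layers[[nm]]))
      stop("layer '", nm, "' is not a numeric matrix", call. = FALSE)
    if (!identical(dim(layers[[nm]]), dims))
      stop("alignment error: layer '", nm, "' has dimensions ",
           paste(dim(layers[[nm]]), collapse = "x"), ", expected ",
           paste(dims, collapse = "x"), call. = FALSE)
  }
  if (!is.na(crs) && grepl("longlat|4326|latitude", crs, ignore.case = TRUE))
    stop("geographic CRS detected ('", crs,
         "'): a projected CRS with meter units is required", call. = FALSE)
  if (cellsize <= 0) stop("`cellsize` must be > 0", call. = FALSE)
  if (is.null(ymax)) ymax <- dims[1L] * cellsize
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  r <- sum(mask)
  if (r == 0L)
    stop("empty stack: no cell is valid in every layer", call. = FALSE)
  structure(list(layers = layers, kinds = kinds,
                 xmin = xmin, ymax = ymax, cellsize = cellsize, crs = crs,
                 mask = mask, r = r),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat("<covariate_stack> ", d[1L], "x", d[2L], " cells (", x$r, " valid), ",
      length(x$layers), " layer(s), cellsize ", x$cellsize, " m\n", sep = "")
  for (nm in names(x$layers))
    cat("  ", format(nm, width = 18), x$kinds[[nm]], "\n", sep = " ")
  invisible(x)
}

#' @export
dim.covariate_stack <- function(x) dim(x$mask)

n_layers <- function(stack) length(stack$layers)

continuous_names <- function(stack) names(stack$kinds)[stack$kinds == "continuous"]
categorical_names <- function(stack) names(stack$kinds)[stack$kinds == "categorical"]

#' Linear indices of valid cells
#'
#' @param stack a [covariate_stack()].
#' @return integer vector of column-major cell indices where all layers are
#'   valid. Invariant under layer reordering.
#' @export
valid_cells <- function(stack) which(stack$mask)

#' Covariate values at a set of cells
#'
#' @param stack a [covariate_stack()].
#' @param cells integer vector of linear (column-major) cell indices;
#'   defaults to all valid cells, i.e. the population table.
#' @return data.frame, one row per cell, one column per layer.
#' @export
cell_values <- function(stack, cells = valid_cells(stack)) {
  out <- lapply(stack$layers, function(m) m[cells])
  as.data.frame(out, optional = TRUE)
}

#' Cell-center coordinates
#'
#' @inheritParams cell_values
#' @return data.frame with columns `x`, `y` (cell centers, meters).
#' @export
cell_xy <- function(stack, cells) {
  nr <- nrow(stack$mask)
  rw <- ((cells - 1L) %% nr) + 1L
  cl <- ((cells - 1L) %/% nr) + 1L
  data.frame(x = stack$xmin + (cl - 0.5) * stack$cellsize,
             y = stack$ymax - (rw - 0.5) * stack$cellsize)
}

#' Cells containing points
#'
#' Half-open cells: a point exactly on a cell edge maps to the cell to the
#' right/below.
#'
#' @param stack a [covariate_stack()].
#' @param x,y point coordinates (meters, same CRS as the stack).
#' @return integer vector of linear cell indices; an error identifies any
#'   point outside the grid extent by position.
#' @export
xy_cell <- function(stack, x, y) {
  d <- dim(stack$mask)
  cl <- floor((x - stack$xmin) / stack$cellsize) + 1L
  rw <- floor((stack$ymax - y) / stack$cellsize) + 1L
  # bottom/right outer edges still belong to the last cell
  cl[x == stack$xmin + d[2L] * stack$cellsize] <- d[2L]
  rw[y == stack$ymax - d[1L] * stack$cellsize] <- d[1L]
  bad <- which(cl < 1L | cl > d[2L] | rw < 1L | rw > d[1L])
  if (length(bad))
    stop("out-of-bounds point(s) at position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  as.integer((cl - 1L) * d[1L] + rw)
}

#' Sample designs
#'
#' A `sample_design` is a data.frame of sampled cells with columns `cell`
#' (linear index), `row`, `col`, `x`, `y`, `provenance` (e.g. `"clhs"`,
#' `"grid"`, `"legacy"`, `"relocated"`, `"ahels"`), followed by one column
#' per covariate holding the stack value at that cell.
#'
#' @param stack a [covariate_stack()].
#' @param cells integer vector of linear cell indices (must lie on the valid
#'   mask).
#' @param provenance character tag, recycled.
#' @return a data.frame with class `sample_design`.
#' @export
sample_design <- function(stack, cells, provenance = "clhs") {
  cells <- as.integer(cells)
  bad <- which(is.na(cells) | cells < 1L | cells > length(stack$mask))
  if (length(bad))
    stop("cells off the valid mask at position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  off <- which(!stack$mask[cells])
  if (length(off))
    stop("cells off the valid mask at position(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  nr <- nrow(stack$mask)
  xy <- cell_xy(stack, cells)
  out <- data.frame(cell = cells,
                    row = ((cells - 1L) %% nr) + 1L,
                    col = ((cells - 1L) %/% nr) + 1L,
                    x = xy$x, y = xy$y,
                    provenance = rep_len(provenance, length(cells)))
  out <- cbind(out, cell_values(stack, cells))
  class(out) <- c("sample_design", "data.frame")
  out
}

design_columns <- c("cell", "row", "col", "x", "y", "provenance")

#' Covariate table of a design
#' @param design a [sample_design()].
#' @return data.frame of covariate columns only.
#' @export
design_values <- function(design) {
  out <- design[, setdiff(names(design), design_columns), drop = FALSE]
  class(out) <- "data.frame"
  out
}

#' Extract stack values at point locations
#'
#' Values are taken from the cell containing each point. Points that fall on
#' nodata cells are dropped with a warning; their positions are recorded in
#' the `dropped` attribute.
#'
#' @param stack a [covariate_stack()].
#' @param points data.frame (or matrix) with columns/cols `x` and `y`, or an
#'   integer vector of linear cell indices.
#' @param provenance tag stored in the design.
#' @return a [sample_design()].
#' @export
extract_table <- function(stack, points, provenance = "legacy") {
  if (is.numeric(points) && is.null(dim(points)) && !is.data.frame(points)) {
    cells <- as.integer(points)
  } else {
    points <- as.data.frame(points)
    if (!all(c("x", "y") %in% names(points)))
      stop("`points` needs columns x and y", call. = FALSE)
    cells <- xy_cell(stack, points$x, points$y)
  }
  drop <- which(!stack$mask[cells])
  if (length(drop)) {
    warning(length(drop), " point(s) on nodata cells dropped (positions: ",
            paste(drop, collapse = ", "), ")", call. = FALSE)
    cells <- cells[-drop]
  }
  if (length(cells) == 0L)
    stop("no point falls on a valid cell", call. = FALSE)
  out <- sample_design(stack, cells, provenance)
  attr(out, "dropped") <- drop
  out
}

#' Write a design to CSV or GeoJSON
#'
#' CSV carries `x`, `y`, `provenance` and all covariate columns; GeoJSON
#' writes one Point feature per site with the same properties. Re-reading
#' with [read_points()] reproduces coordinates and covariate values
#' (<= 1e-9 relative for floats).
#'
#' @param design a non-empty [sample_design()].
#' @param path output file.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_points <- function(design, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (nrow(design) == 0L)
    stop("refusing to write an empty design", call. = FALSE)
  tab <- cbind(design[, c("x", "y", "provenance")], design_values(design))
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(tab)), function(i) {
      props <- as.list(tab[i, setdiff(names(tab), c("x", "y")), drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(tab$x[i], tab$y[i])),
           properties = props)
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a point table written by [write_points()]
#'
#' @param path a CSV or GeoJSON file (sniffed by extension).
#' @return data.frame with columns `x`, `y` and any property columns.
#' @export
read_points <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    rows <- lapply(gj$features, function(f) {
      c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
        f$properties)
    })
    out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, optional = TRUE)))
    rownames(out) <- NULL
    out
  } else {
    utils::read.csv(path)
  }
}
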