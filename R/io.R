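#' Read an ESRI ASCII grid
#'
#' Plain-text single-band raster: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by
#' row-major values, row 1 = top.
#'
#' @param path file to read.
#' @return list with `values` (numeric matrix, `NA` = nodata), `xmin`,
#'   `ymax`, `cellsize`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(path, " is not an ASCII grid (missing header fields)", call. = FALSE)
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(path, ": expected ", nr * nc, " values, found ", length(vals),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  list(values = m, xmin = xll, ymax = yll + nr * hdr$cellsize,
       cellsize = hdr$cellsize)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values numeric matrix (row 1 = top; `NA` written as the nodata
#'   value).
#' @param path output file.
#' @param xmin,ymax,cellsize grid geometry (meters).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, path, xmin = 0, ymax = nrow(values) * cellsize,
                      cellsize = 1, nodata = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           paste("xllcorner", format(xmin, scientific = FALSE)),
           paste("yllcorner", format(ymax - nr * cellsize, scientific = FALSE)),
           paste("cellsize", format(cellsize, scientific = FALSE)),
           paste("nodata_value", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(rowv)
    paste(format(rowv, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a stack of co-registered raster layers
#'
#' All layers must share shape, cell size and origin (within 1e-6 m);
#' the first offending layer is named in the error. The combined nodata
#' mask is the intersection of per-layer validity.
#'
#' @param paths character vector of ASCII-grid files.
#' @param kinds `"continuous"`/`"categorical"` per layer (recycled).
#' @param names layer names; default = file names without extension.
#' @param crs optional CRS text (projected, meter units).
#' @return a [covariate_stack()].
#' @export
read_stack <- function(paths, kinds = "continuous", names = NULL,
                       crs = NA_character_) {
  if (length(paths) == 0L) stop("no raster paths given", call. = FALSE)
  if (is.null(names))
    names <- sub("\\.[^.]*$", "", basename(paths))
  rasters <- lapply(paths, read_asc)
  ref <- rasters[[1L]]
  for (i in seq_along(rasters)) {
    ri <- rasters[[i]]
    if (!identical(dim(ri$values), dim(ref$values)))
      stop("alignment error: layer '", names[i], "' has shape ",
           paste(dim(ri$values), collapse = "x"), ", expected ",
           paste(dim(ref$values), collapse = "x"), call. = FALSE)
    if (abs(ri$cellsize - ref$cellsize) > 1e-6 ||
        abs(ri$xmin - ref$xmin) > 1e-6 || abs(ri$ymax - ref$ymax) > 1e-6)
      stop("alignment error: layer '", names[i],
           "' has a different transform (origin/cellsize)", call. = FALSE)
  }
  layers <- stats::setNames(lapply(rasters, `[[`, "values"), names)
  covariate_stack(layers, kinds, xmin = ref$xmin, ymax = ref$ymax,
                  cellsize = ref$cellsize, crs = crs)
}

#' Read a stack described by a YAML manifest
#'
#' The manifest lists layers as
#' ```yaml
#' crs: "EPSG:28356"
#' layers:
#'   - {path: elev.asc, name: elevation, kind: continuous}
#'   - {path: geol.asc, name: geology,   kind: categorical}
#' ```
#' Relative paths resolve against the manifest's directory.
#'
#' @param path manifest file.
#' @return a [covariate_stack()].
#' @export
read_manifest <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || length(cfg$layers) == 0L)
    stop("manifest has no `layers` entries", call. = FALSE)
  base <- dirname(normalizePath(path))
  paths <- vapply(cfg$layers, `[[`, "", "path")
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
  nms <- vapply(cfg$layers, function(l) l$name %||% sub("\\.[^.]*$", "", basename(l$path)), "")
  kinds <- vapply(cfg$layers, function(l) l$kind %||% "continuous", "")
  read_stack(abs, kinds = kinds, names = nms,
             crs = cfg$crs %||% NA_character_)
}

#' Write every layer of a stack as ASCII grids plus a manifest
#'
#' @param stack a [covariate_stack()].
#' @param dir output directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (nm in names(stack$layers)) {
    v <- stack$layers[[nm]]
    v[!stack$mask] <- NA_real_
    p <- file.path(dir, paste0(nm, ".asc"))
    write_asc(v, p, xmin = stack$xmin, ymax = stack$ymax,
              cellsize = stack$cellsize)
    entries[[length(entries) + 1L]] <-
      list(path = paste0(nm, ".asc"), name = nm,
           kind = unname(stack$kinds[[nm]]))
  }
  man <- file.path(dir, "manifest.yml")
  yaml::write_yaml(list(crs = if (is.na(stack$crs)) NULL else stack$crs,
                        layers = entries), man)
  invisible(man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
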