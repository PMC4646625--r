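# Raster plumbing: ESRI ASCII grid I/O, pixel/coordinate mapping, and
# rasterized prediction of an averaged occurrence model.

#' Read or write an ESRI ASCII grid
#'
#' Minimal headered ASCII raster I/O (\code{ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value} header followed by rows north to south).
#'
#' @param path file path.
#' @return \code{readAsciiGrid}: list with \code{z} (numeric matrix, NA for
#'   nodata) and \code{geotransform} (\code{c(xll, yll, cellsize)}).
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) == 2L && tolower(parts[1L]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header lacks ", k)
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body size does not match header")
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA
  list(z = z, geotransform = c(xll = hdr$xllcorner, yll = hdr$yllcorner,
                               cellsize = hdr$cellsize))
}

#' @describeIn readAsciiGrid write a matrix as an ASCII grid.
#' @param z numeric matrix (row 1 = northernmost).
#' @param geotransform \code{c(xll, yll, cellsize)}.
#' @param nodata value written for \code{NA} cells.
#' @export
writeAsciiGrid <- function(z, path, geotransform = c(xll = 0, yll = 0, cellsize = 0.001),
                           nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(z)),
               paste("nrows", nrow(z)),
               paste("xllcorner", format(geotransform[[1L]], scientific = FALSE)),
               paste("yllcorner", format(geotransform[[2L]], scientific = FALSE)),
               paste("cellsize", format(geotransform[[3L]], scientific = FALSE)),
               paste("NODATA_value", nodata)), con)
  z[is.na(z)] <- nodata
  utils::write.table(z, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map pixels to geographic coordinates
#'
#' Pixel centers under the surface geotransform; row 1 is the northernmost
#' row.  The inverse mapping returns the pixel containing a coordinate.
#'
#' @param surface a \linkS4class{ProbabilitySurface}.
#' @param row,col pixel indices.
#' @return \code{pixelToLatLon}: data.frame \code{lat, lon} of pixel centers.
#' @export
pixelToLatLon <- function(surface, row, col) {
  gt <- surface@geotransform
  nr <- nrow(surface@prob)
  data.frame(lat = gt[["yll"]] + (nr - row + 0.5) * gt[["cellsize"]],
             lon = gt[["xll"]] + (col - 0.5) * gt[["cellsize"]])
}

#' @describeIn pixelToLatLon inverse mapping (coordinates to pixel indices).
#' @param lat,lon decimal-degree coordinates.
#' @export
latLonToPixel <- function(surface, lat, lon) {
  gt <- surface@geotransform
  nr <- nrow(surface@prob)
  data.frame(row = nr - floor((lat - gt[["yll"]]) / gt[["cellsize"]]),
             col = floor((lon - gt[["xll"]]) / gt[["cellsize"]]) + 1L)
}

#' Rasterize an averaged occurrence model
#'
#' Applies the model's inverse-logit prediction to a stack of co-registered
#' covariate rasters and combines it with an exclusion mask (urban areas,
#' water bodies, public lands and the like) marking pixels where no farm may
#' be placed.
#'
#' @param m an \linkS4class{AveragedModel}.
#' @param stack named list of covariate matrices, one per model term, all of
#'   identical dimension.
#' @param mask logical matrix; \code{TRUE} pixels are excluded.
#' @param geotransform \code{c(xll, yll, cellsize)}.
#' @param county integer matrix of county indices (0 = none); default one
#'   county covering the grid.
#' @param countyIds character ids for the county indices.
#' @return A \linkS4class{ProbabilitySurface}; masked pixels keep their
#'   predicted value but are flagged unavailable.
#' @export
predictSurface <- function(m, stack, mask = NULL,
                           geotransform = c(xll = -100, yll = 35, cellsize = 0.001),
                           county = NULL, countyIds = "00001") {
  terms <- setdiff(names(coef(m)), "(Intercept)")
  miss <- setdiff(terms, names(stack))
  if (length(miss)) stop("stack lacks covariate layers: ", paste(miss, collapse = ", "))
  d <- dim(stack[[terms[1L]]])
  for (v in terms)
    if (!identical(dim(stack[[v]]), d)) stop("raster shape mismatch for layer ", v)
  if (is.null(mask)) mask <- matrix(FALSE, d[1L], d[2L])
  if (!identical(dim(mask), d)) stop("mask shape mismatch")
  newdata <- lapply(stack[terms], as.numeric)
  prob <- matrix(predict(m, newdata, type = "response"), d[1L], d[2L])
  probabilitySurface(prob, available = !mask, geotransform = geotransform,
                     county = county, countyIds = countyIds)
}
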