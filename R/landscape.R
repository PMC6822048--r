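#' Generate a synthetic landscape raster stack
#'
#' Builds co-registered feature rasters on a common grid: a three-class land
#' cover (A = forest background, B = open/agricultural patches, C =
#' developed/water patches), binary linear features (interstates, secondary
#' roads, light roads, medium rivers, large rivers, railroads) rasterized as
#' 8-connected polylines spanning the grid, and a smooth continuous
#' elevation field with its derived terrain ruggedness index. Linear
#' features take precedence over land cover where they overlap (the cell
#' still carries both layers; combined resistance resolves precedence via
#' the max rule in [build_surface()]).
#'
#' @param width,height grid size in cells (both >= 8).
#' @param feature_spec list with elements `landcover_b`, `landcover_c`
#'   (patch densities in `[0, 1]`), counts `interstates`,
#'   `secondary_roads`, `light_roads`, `medium_rivers`, `large_rivers`,
#'   `railroads`, and `elevation_relief` (vertical range of the elevation
#'   field, same units as elevation). Missing elements default to 0.
#' @param cellsize cell size (default 90, a 90-m grain).
#' @param seed RNG seed; identical spec + seed gives bit-identical rasters.
#' @return object of class `landscape_stack`: named list of matrices
#'   (`landcover` with values "A"/"B"/"C", one binary matrix per linear
#'   feature, `elevation`, `tri`) plus `cellsize`, `width`, `height`.
#' @export
generate_landscape <- function(width, height, feature_spec = list(), seed = 1,
                               cellsize = 90) {
  if (width < 8 || height < 8) stop("degenerate grid: need >= 8 cells a side")
  spec <- utils::modifyList(list(
    landcover_b = 0, landcover_c = 0, interstates = 0, secondary_roads = 0,
    light_roads = 0, medium_rivers = 0, large_rivers = 0, railroads = 0,
    elevation_relief = 0), feature_spec)
  dens <- unlist(spec[c("landcover_b", "landcover_c")])
  if (any(dens < 0 | dens > 1)) stop("feature densities must lie in [0, 1]")
  lin_names <- c("interstates", "secondary_roads", "light_roads",
                 "medium_rivers", "large_rivers", "railroads")
  with_seed(seed, {
    lc <- matrix("A", height, width)
    for (cl in c("B", "C")) {
      d <- spec[[if (cl == "B") "landcover_b" else "landcover_c"]]
      if (d <= 0) next
      n_cells <- round(d * height * width)
      n_seeds <- max(1, round(n_cells / 25))
      blob <- grow_patches(height, width, n_seeds, n_cells)
      lc[blob] <- cl
    }
    layers <- list(landcover = lc)
    for (f in lin_names) {
      m <- matrix(0L, height, width)
      cnt <- spec[[f]]
      if (cnt > 0) {
        vertical <- f %in% c("interstates", "secondary_roads", "railroads")
        for (i in seq_len(cnt)) m <- m | rasterize_polyline(height, width, vertical)
      }
      layers[[f]] <- m * 1L
    }
    elev <- matrix(0, height, width)
    if (spec$elevation_relief > 0) {
      elev <- smooth_field(height, width, n_bumps = 8)
      elev <- (elev - min(elev)) / diff(range(elev)) * spec$elevation_relief
    }
    layers$elevation <- elev
    layers$tri <- compute_tri(elev)
    structure(c(layers, list(cellsize = cellsize, width = width,
                             height = height)),
              class = "landscape_stack")
  })
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat("landscape_stack:", x$height, "x", x$width, "cells, cellsize",
      x$cellsize, "\n")
  feats <- setdiff(names(x), c("cellsize", "width", "height"))
  cat("  layers:", paste(feats, collapse = ", "), "\n")
  invisible(x)
}

# random-walk polyline spanning the grid. Rasterized 4-connected (diagonal
# moves fill an orthogonal stepping cell), the raster analogue of buffering
# linear features for continuity: an 8-neighbourhood path cannot slip
# through a diagonal crack in the line.
rasterize_polyline <- function(height, width, vertical = TRUE) {
  m <- matrix(0L, height, width)
  if (vertical) {
    col <- sample.int(width, 1)
    m[1, col] <- 1L
    for (row in 2:height) {
      new_col <- min(max(col + sample(c(-1L, 0L, 0L, 1L), 1), 1L), width)
      if (new_col != col) m[row, col] <- 1L  # fill the corner cell
      col <- new_col
      m[row, col] <- 1L
    }
  } else {
    row <- sample.int(height, 1)
    m[row, 1] <- 1L
    for (col in 2:width) {
      new_row <- min(max(row + sample(c(-1L, 0L, 0L, 1L), 1), 1L), height)
      if (new_row != row) m[row, col] <- 1L
      row <- new_row
      m[row, col] <- 1L
    }
  }
  m
}

# grow patches from seed cells to a target cell count (simple dilation)
grow_patches <- function(height, width, n_seeds, n_cells) {
  sel <- matrix(FALSE, height, width)
  seeds <- cbind(sample.int(height, n_seeds, replace = TRUE),
                 sample.int(width, n_seeds, replace = TRUE))
  sel[seeds] <- TRUE
  while (sum(sel) < n_cells) {
    edge <- which(sel, arr.ind = TRUE)
    i <- edge[sample.int(nrow(edge), 1), ]
    dr <- sample(c(-1L, 0L, 1L), 1); dc <- sample(c(-1L, 0L, 1L), 1)
    r <- min(max(i[1] + dr, 1L), height); c <- min(max(i[2] + dc, 1L), width)
    sel[r, c] <- TRUE
  }
  sel
}

# smooth random field as a sum of Gaussian bumps
smooth_field <- function(height, width, n_bumps = 8) {
  rr <- row(matrix(0, height, width)); cc <- col(matrix(0, height, width))
  f <- matrix(0, height, width)
  for (b in seq_len(n_bumps)) {
    cy <- stats::runif(1, 1, height); cx <- stats::runif(1, 1, width)
    s <- stats::runif(1, min(height, width) / 8, min(height, width) / 3)
    a <- stats::rnorm(1)
    f <- f + a * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * s^2))
  }
  f
}

#' Reclassify NLCD land-cover codes into three resistance categories
#'
#' Maps the National Land Cover Database codes to class A (forests and
#' wetlands: 41, 42, 43, 90, 95), class B (open and agricultural: 21, 52,
#' 71, 81, 82), and class C (developed areas and open water: 11, 22, 23,
#' 24, 31). Unknown codes are an error naming the offending codes.
#'
#' @param nlcd_raster integer matrix of NLCD codes (NA passed through).
#' @return character matrix of "A"/"B"/"C".
#' @export
reclassify_landcover <- function(nlcd_raster) {
  map <- c(`41` = "A", `42` = "A", `43` = "A", `90` = "A", `95` = "A",
           `21` = "B", `52` = "B", `71` = "B", `81` = "B", `82` = "B",
           `11` = "C", `22` = "C", `23` = "C", `24` = "C", `31` = "C")
  vals <- as.vector(nlcd_raster)
  known <- is.na(vals) | as.character(vals) %in% names(map)
  if (!all(known))
    stop("unknown NLCD codes: ",
         paste(sort(unique(vals[!known])), collapse = ", "))
  out <- map[as.character(vals)]
  matrix(out, nrow(nlcd_raster), ncol(nlcd_raster))
}

#' Terrain ruggedness index
#'
#' Per cell, the square root of the summed squared elevation differences to
#' the (up to) 8 neighbours; edge cells use the neighbours available.
#'
#' @param elevation numeric matrix.
#' @return numeric matrix of the same shape, TRI >= 0.
#' @export
compute_tri <- function(elevation) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(NA_real_, nr, nc)
    r_src <- max(1, 1 + dr):min(nr, nr + dr)
    c_src <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[r_src - dr, c_src - dc] <- elevation[r_src, c_src]
    d2 <- (elevation - shifted)^2
    d2[is.na(d2)] <- 0
    acc <- acc + d2
  }
  sqrt(acc)
}

#' Build a resistance surface from a landscape stack
#'
#' Three modes. Single-feature: cells of `feature` get `cost`, all other
#' cells 1 (set `cost_assignment` to a single named value). TRI mode
#' (`tri_offset` given, no feature costs): resistance = TRI + offset
#' everywhere. Combined mode (several named costs, optional TRI offset):
#' each cell's resistance is the maximum of the costs assigned to features
#' present there (land cover classes use names `landcover_A/B/C`), with the
#' TRI + offset term also entering the max when given; floor 1 everywhere.
#' The max rule gives linear features precedence over land cover.
#'
#' @param stack a `landscape_stack`.
#' @param cost_assignment named numeric vector, names among
#'   `landcover_A`, `landcover_B`, `landcover_C` and the linear feature
#'   layer names; NULL for TRI-only mode.
#' @param tri_offset additive constant for the TRI term, or NULL to omit.
#' @return object of class `resistance_surface`: `resistance` matrix (>= 1
#'   everywhere), `provenance` (the cost map used), `cellsize`.
#' @export
build_surface <- function(stack, cost_assignment = NULL, tri_offset = NULL) {
  h <- stack$height; w <- stack$width
  r <- matrix(1, h, w)
  if (!is.null(cost_assignment)) {
    if (is.null(names(cost_assignment)) || any(!nzchar(names(cost_assignment))))
      stop("cost_assignment must be a named vector")
    if (any(cost_assignment <= 0)) stop("resistance costs must be positive")
    for (nm in names(cost_assignment)) {
      cost <- cost_assignment[[nm]]
      if (grepl("^landcover_", nm)) {
        cl <- sub("^landcover_", "", nm)
        mask <- stack$landcover == cl
      } else {
        if (is.null(stack[[nm]])) stop("unknown feature layer: ", nm)
        mask <- stack[[nm]] == 1
      }
      r[mask] <- pmax(r[mask], cost)
    }
  }
  if (!is.null(tri_offset)) r <- pmax(r, stack$tri + tri_offset)
  structure(list(resistance = r,
                 provenance = list(costs = cost_assignment,
                                   tri_offset = tri_offset),
                 cellsize = stack$cellsize),
            class = "resistance_surface")
}
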