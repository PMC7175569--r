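#' Habitat class and patch label codes
#'
#' Integer codes used throughout the package and in ESRI ASCII rasters:
#' habitat classes `MATRIX = 0` (traversable but avoided), `DISPERSAL = 1`
#' (traversable and preferred), `BREEDING = 2` (supports territories),
#' `BARRIER = 3` (impassable); patch labels `SOURCE = 1`, `CONNECTIVITY = 2`,
#' `ARRIVAL = 3`.
#'
#' @format Named integer vectors.
#' @export
HABITAT <- c(MATRIX = 0L, DISPERSAL = 1L, BREEDING = 2L, BARRIER = 3L)

#' @rdname HABITAT
#' @export
PATCH <- c(SOURCE = 1L, CONNECTIVITY = 2L, ARRIVAL = 3L)

#' Construct a habitat grid
#'
#' A habitat grid is an integer matrix of habitat classes (see [HABITAT])
#' plus a parallel matrix of patch labels (see [PATCH]) at a fixed cell area
#' of 1 km2. When `patch` is omitted, labels are derived from the breeding
#' habitat: the connected component (4-connectivity) with the smallest column
#' index becomes the source patch, the one with the largest becomes the
#' arrival patch, and everything else is connectivity.
#'
#' @param classes integer matrix of habitat class codes.
#' @param patch optional integer matrix of patch labels, same dimensions.
#' @return An object of class `habitat_grid`.
#' @export
habitat_grid <- function(classes, patch = NULL) {
  storage.mode(classes) <- "integer"
  bad <- which(!(classes %in% HABITAT))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(classes))
    stop(sprintf("unknown habitat class code %d at cell (row %d, col %d)",
                 classes[bad[1]], rc[1], rc[2]))
  }
  if (is.null(patch)) {
    comp <- cpp_label_components(classes == HABITAT[["BREEDING"]])
    patch <- matrix(PATCH[["CONNECTIVITY"]], nrow(classes), ncol(classes))
    ncomp <- max(comp)
    if (ncomp >= 1) {
      mincol <- vapply(seq_len(ncomp), function(k) {
        min(col(comp)[comp == k])
      }, numeric(1))
      patch[comp == which.min(mincol)] <- PATCH[["SOURCE"]]
      if (ncomp >= 2) patch[comp == which.max(mincol)] <- PATCH[["ARRIVAL"]]
    }
  }
  storage.mode(patch) <- "integer"
  stopifnot(identical(dim(patch), dim(classes)))
  structure(list(classes = classes, patch = patch, cell_area = 1),
            class = "habitat_grid")
}

#' @export
print.habitat_grid <- function(x, ...) {
  tab <- table(factor(x$classes, levels = HABITAT, labels = names(HABITAT)))
  cat(sprintf("<habitat_grid> %d x %d cells (1 km2 each)\n",
              nrow(x$classes), ncol(x$classes)))
  print(tab)
  invisible(x)
}

#' @export
dim.habitat_grid <- function(x) dim(x$classes)

#' Landscape specification for the three-patch system
#'
#' Describes one neutral three-patch landscape: the fraction of the
#' connectivity patch covered by dispersal habitat, the degree of
#' fragmentation (1 = randomly distributed, 4 = large contiguous blocks), and
#' a seed for the stochastic spatial arrangement. Alternatively one of the
#' control scenarios: `"CS1"` (connectivity 100% matrix), `"CS2"` (100%
#' dispersal habitat), or `"CS3"` (100% barrier, closing the source patch).
#' When a control scenario is given, fraction and fragmentation are ignored.
#'
#' @param dispersal_fraction proportion of the connectivity patch assigned to
#'   dispersal habitat, in `[0, 1]`.
#' @param fragmentation ordinal degree of fragmentation, 1-4.
#' @param seed integer seed for the landscape surface.
#' @param control optional control scenario, `"CS1"`, `"CS2"` or `"CS3"`.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(dispersal_fraction = 0.3, fragmentation = 1,
                           seed = 1L, control = NULL) {
  if (!is.null(control)) {
    if (!control %in% c("CS1", "CS2", "CS3"))
      stop("unknown control scenario: ", control)
  } else {
    stopifnot(is.numeric(dispersal_fraction),
              dispersal_fraction >= 0, dispersal_fraction <= 1,
              fragmentation %in% 1:4)
  }
  structure(list(dispersal_fraction = dispersal_fraction,
                 fragmentation = as.integer(fragmentation),
                 seed = as.integer(seed), control = control),
            class = "landscape_spec")
}

#' Generate a fractal surface by midpoint displacement
#'
#' Runs the diamond-square (midpoint displacement) algorithm on the smallest
#' enclosing `(2^k + 1)` square lattice and crops to the requested
#' dimensions. The per-level displacement scale is halved by `2^-roughness`,
#' so roughness near 0 yields spatially uncorrelated surfaces and roughness
#' near 1 yields smooth, strongly autocorrelated surfaces.
#'
#' @param n_rows,n_cols requested dimensions in cells (both >= 2).
#' @param roughness smoothness control in `[0, 1]`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return A numeric `n_rows` x `n_cols` matrix with no non-finite values.
#' @export
generate_fractal_surface <- function(n_rows, n_cols, roughness, seed = NULL) {
  if (!is.finite(roughness) || roughness < 0 || roughness > 1)
    stop("roughness must be finite and in [0, 1]")
  if (n_rows < 2 || n_cols < 2) stop("dimensions must be >= 2")
  with_seed(seed, {
    k <- ceiling(log2(max(n_rows, n_cols) - 1))
    n <- as.integer(2^k + 1)
    z <- matrix(0, n, n)
    z[c(1, n), c(1, n)] <- rnorm(4)
    scale <- 2^(-roughness)
    step <- n - 1L
    while (step > 1L) {
      half <- step %/% 2L
      # diamond step: centres of squares
      ctr <- seq.int(half + 1L, n - half, by = step)
      for (r in ctr) for (c in ctr) {
        z[r, c] <- (z[r - half, c - half] + z[r - half, c + half] +
                    z[r + half, c - half] + z[r + half, c + half]) / 4 +
                   rnorm(1) * scale
      }
      # square step: midpoints of edges, averaging available diamond
      # neighbours (3 at grid borders)
      for (r in seq.int(1L, n, by = half)) {
        offset <- if (((r - 1L) %/% half) %% 2L == 0L) half + 1L else 1L
        for (c in seq.int(offset, n, by = step)) {
          s <- 0; m <- 0L
          if (r - half >= 1L) { s <- s + z[r - half, c]; m <- m + 1L }
          if (r + half <= n)  { s <- s + z[r + half, c]; m <- m + 1L }
          if (c - half >= 1L) { s <- s + z[r, c - half]; m <- m + 1L }
          if (c + half <= n)  { s <- s + z[r, c + half]; m <- m + 1L }
          z[r, c] <- s / m + rnorm(1) * scale
        }
      }
      scale <- scale * 2^(-roughness)
      step <- half
    }
    z[seq_len(n_rows), seq_len(n_cols)]
  })
}

#' Threshold a surface to a habitat mask
#'
#' Marks exactly `round(fraction * n_cells)` cells TRUE, chosen as the cells
#' with the highest surface values; ties are broken by raster scan order
#' (column-major), making the mask fully determined by the surface.
#'
#' @param surface numeric matrix.
#' @param fraction proportion of cells to mark, in `[0, 1]`.
#' @return A logical matrix of the same dimensions.
#' @export
threshold_surface <- function(surface, fraction) {
  stopifnot(is.numeric(fraction), fraction >= 0, fraction <= 1)
  k <- round(fraction * length(surface))
  mask <- matrix(FALSE, nrow(surface), ncol(surface))
  if (k > 0) {
    ord <- order(surface, decreasing = TRUE, method = "radix")
    mask[ord[seq_len(k)]] <- TRUE
  }
  mask
}

# fragmentation degree (1 random .. 4 clumped) -> midpoint-displacement
# roughness
fragmentation_roughness <- c(0.1, 0.4, 0.7, 1.0)

#' Assemble a three-patch landscape
#'
#' Builds the standard 65 x 169 cell landscape: a 20 x 65 source breeding
#' patch on the left, a 20 x 65 arrival breeding patch on the right (1300 km2
#' each) and a 129 x 65 connectivity patch between them. For a neutral
#' landscape the connectivity patch is a midpoint-displacement surface
#' thresholded so that the requested fraction of its cells is dispersal
#' habitat (remainder matrix habitat), with the fragmentation degree mapped
#' monotonically to surface roughness (degrees 1-4 map to 0.1, 0.4, 0.7,
#' 1.0). For the control scenarios the
#' connectivity patch is uniform: CS1 all matrix, CS2 all dispersal habitat,
#' CS3 all barrier.
#'
#' @param spec a [landscape_spec()].
#' @return A [habitat_grid()].
#' @export
assemble_three_patch <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nrows <- 65L; bcols <- 20L; ccols <- 129L
  ncols <- 2L * bcols + ccols
  classes <- matrix(HABITAT[["BREEDING"]], nrows, ncols)
  conn <- (bcols + 1L):(bcols + ccols)
  if (!is.null(spec$control)) {
    fill <- switch(spec$control,
                   CS1 = HABITAT[["MATRIX"]],
                   CS2 = HABITAT[["DISPERSAL"]],
                   CS3 = HABITAT[["BARRIER"]])
    classes[, conn] <- fill
  } else {
    rough <- fragmentation_roughness[spec$fragmentation]
    surf <- generate_fractal_surface(nrows, ccols, rough, seed = spec$seed)
    disp <- threshold_surface(surf, spec$dispersal_fraction)
    block <- matrix(HABITAT[["MATRIX"]], nrows, ccols)
    block[disp] <- HABITAT[["DISPERSAL"]]
    classes[, conn] <- block
  }
  patch <- matrix(PATCH[["CONNECTIVITY"]], nrows, ncols)
  patch[, seq_len(bcols)] <- PATCH[["SOURCE"]]
  patch[, (bcols + ccols + 1L):ncols] <- PATCH[["ARRIVAL"]]
  habitat_grid(classes, patch)
}

#' Label connected habitat patches
#'
#' Connected-component labelling (4-connectivity) of a logical mask,
#' e.g. the dispersal-habitat cells of a connectivity patch.
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 outside the mask).
#' @export
label_patches <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  cpp_label_components(mask)
}

#' Read and write habitat rasters as ESRI ASCII grids
#'
#' The raster dialect stores the habitat class codes of [HABITAT] in a plain
#' ESRI ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`
#' header, then one line per row). `write_grid()` followed by `read_grid()`
#' is the identity on class codes and dimensions; patch labels are re-derived
#' from the breeding habitat (see [habitat_grid()]).
#'
#' @param path file path.
#' @param grid a [habitat_grid()].
#' @return `read_grid()` returns a [habitat_grid()]; `write_grid()` returns
#'   `path` invisibly.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed header: fewer than 6 lines")
  hdr <- list()
  for (i in 1:5) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  body_start <- 6L
  if (grepl("^\\s*nodata_value", tolower(lines[6]))) body_start <- 7L
  ncols <- hdr$ncols; nrows <- hdr$nrows
  if (is.null(ncols) || is.null(nrows) || is.na(ncols) || is.na(nrows))
    stop("malformed header: missing ncols/nrows")
  tokens <- unlist(strsplit(trimws(lines[body_start:length(lines)]), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.integer(tokens))
  if (anyNA(vals)) stop("malformed body: non-integer cell value")
  if (length(vals) != nrows * ncols)
    stop(sprintf("header/body mismatch: header declares %d x %d = %d cells, body has %d",
                 nrows, ncols, nrows * ncols, length(vals)))
  classes <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  habitat_grid(classes)
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "habitat_grid"))
  cl <- grid$classes
  hdr <- c(sprintf("ncols %d", ncol(cl)),
           sprintf("nrows %d", nrow(cl)),
           "xllcorner 0",
           "yllcorner 0",
           "cellsize 1000",
           "NODATA_value -9999")
  rows <- apply(cl, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Moran's I spatial autocorrelation over the 4-neighbour graph
#'
#' Used to characterise generated surfaces: higher roughness settings of
#' [generate_fractal_surface()] produce higher Moran's I.
#'
#' @param surface numeric matrix.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(surface) {
  z <- surface - mean(surface)
  num <- 0; wsum <- 0
  # horizontal and vertical neighbour pairs, each counted twice (symmetric)
  h <- z[, -ncol(z)] * z[, -1]
  v <- z[-nrow(z), ] * z[-1, ]
  num <- 2 * (sum(h) + sum(v))
  wsum <- 2 * (length(h) + length(v))
  (length(z) / wsum) * (num / sum(z^2))
}
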