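#' Categorical raster objects
#'
#' A `cat_raster` is a minimal single-band categorical raster: an integer
#' matrix plus a pixel resolution, a lower-left origin and a nodata code.
#' Rows of the matrix run south-to-north (row 1 is the southernmost row of
#' pixels), columns west-to-east, so `values[r, c]` is the pixel whose centre
#' is at `origin + (c - 0.5, r - 0.5) * resolution`.
#'
#' @param values integer matrix of category codes.
#' @param resolution edge length of one pixel, in abstract map units.
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param nodata integer code marking missing pixels (default 255).
#' @param categories optional integer vector declaring the legal category
#'   set; defaults to the distinct non-nodata values present.
#' @return An object of class `cat_raster`.
#' @export
cat_raster <- function(values, resolution = 1, origin = c(0, 0),
                       nodata = 255L, categories = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (any(dim(values) <= 0)) stop("raster dimensions must be positive")
  if (is.null(categories)) {
    categories <- sort(unique(values[values != nodata & !is.na(values)]))
  }
  bad <- setdiff(unique(as.vector(values)), c(categories, nodata, NA))
  if (length(bad) > 0) {
    stop("values outside declared category set: ", paste(bad, collapse = ", "))
  }
  structure(
    list(values = values, resolution = as.numeric(resolution),
         origin = as.numeric(origin), nodata = as.integer(nodata),
         categories = as.integer(categories)),
    class = "cat_raster"
  )
}

#' @export
print.cat_raster <- function(x, ...) {
  cat("<cat_raster> ", nrow(x$values), " x ", ncol(x$values),
      " pixels @ ", x$resolution, " units, origin (",
      x$origin[1], ", ", x$origin[2], "), nodata ", x$nodata, "\n", sep = "")
  tab <- table(factor(x$values[x$values != x$nodata], levels = x$categories))
  print(tab)
  invisible(x)
}

#' @export
dim.cat_raster <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$resolution, b$resolution)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Read / write ESRI ASCII grid
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of pixel
#' values from north to south.
#'
#' @param path file path.
#' @return `read_asc()` returns a [cat_raster()]; `write_asc()` returns
#'   `path` invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  nodata <- if (!is.null(hdr$nodata_value)) as.integer(hdr$nodata_value) else 255L
  vals <- scan(text = lines[i:length(lines)], what = integer(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid ", path, ": expected ", hdr$ncols * hdr$nrows,
         " values, found ", length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[hdr$nrows:1, , drop = FALSE]  # file is north-to-south
  cat_raster(m, resolution = hdr$cellsize,
             origin = c(hdr$xllcorner, hdr$yllcorner), nodata = nodata)
}

#' @rdname read_asc
#' @param raster a [cat_raster()].
#' @export
write_asc <- function(raster, path) {
  v <- raster$values
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", raster$origin[1]), paste("yllcorner", raster$origin[2]),
    paste("cellsize", raster$resolution), paste("NODATA_value", raster$nodata)
  )
  body <- apply(v[nrow(v):1, , drop = FALSE], 1, paste, collapse = " ")
  ok <- tryCatch({
    writeLines(c(hdr, body), path); TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("failed to write ASCII grid to ", path)
  invisible(path)
}

#' Harmonize native category codes to a common scheme
#'
#' Replaces every native class code by its harmonized category, e.g. pooling
#' several survey-specific grassland codes into one semi-natural grassland
#' class. Codes mapped to `NA` are set to nodata (used e.g. for littoral
#' classes that are dropped from the analysis).
#'
#' @param raster a [cat_raster()].
#' @param map named integer vector or two-column data frame
#'   (`native`, `harmonized`) giving the total mapping; `NA` harmonized
#'   values mean "drop to nodata".
#' @return A harmonized [cat_raster()].
#' @export
harmonize <- function(raster, map) {
  if (is.data.frame(map)) {
    m <- stats::setNames(map$harmonized, map$native)
  } else {
    m <- map
  }
  native <- as.integer(names(m))
  v <- raster$values
  present <- unique(v[v != raster$nodata])
  unmapped <- setdiff(present, native)
  if (length(unmapped) > 0) {
    stop("unmapped category code(s): ", paste(sort(unmapped), collapse = ", "))
  }
  out <- v
  for (k in seq_along(m)) {
    tgt <- if (is.na(m[k])) raster$nodata else as.integer(m[k])
    out[v == native[k]] <- tgt
  }
  cat_raster(out, raster$resolution, raster$origin, raster$nodata)
}

#' Nearest-neighbour resampling
#'
#' Re-grids a categorical raster to a new pixel size over the same extent,
#' assigning each target pixel the category of the source pixel containing
#' its centre. Categories are never interpolated.
#'
#' @param raster a [cat_raster()].
#' @param target_resolution new pixel edge length, same units.
#' @return A [cat_raster()] at the target resolution.
#' @export
resample_nearest <- function(raster, target_resolution) {
  if (target_resolution <= 0) stop("target resolution must be positive")
  if (isTRUE(all.equal(target_resolution, raster$resolution))) return(raster)
  ext_x <- ncol(raster$values) * raster$resolution
  ext_y <- nrow(raster$values) * raster$resolution
  ncol_t <- round(ext_x / target_resolution)
  nrow_t <- round(ext_y / target_resolution)
  if (ncol_t < 1 || nrow_t < 1) stop("target resolution exceeds raster extent")
  # centres of target pixels, mapped to source pixel indices
  cx <- (seq_len(ncol_t) - 0.5) * target_resolution
  cy <- (seq_len(nrow_t) - 0.5) * target_resolution
  sc <- pmin(pmax(ceiling(cx / raster$resolution), 1L), ncol(raster$values))
  sr <- pmin(pmax(ceiling(cy / raster$resolution), 1L), nrow(raster$values))
  out <- raster$values[sr, sc, drop = FALSE]
  cat_raster(out, target_resolution, raster$origin, raster$nodata)
}

#' Mask both rasters around a geometry and align their nodata footprints
#'
#' Sets to nodata, in both rasters, every pixel whose centre lies within
#' `buffer_width` of the mask geometry (a set of line segments and/or
#' points), then copies each raster's nodata footprint onto the other so the
#' pair share an identical valid extent. Used to cut a buffer around linear
#' features (roads drawn too wide on historical sheets) before computing
#' change.
#'
#' @param a,b co-registered [cat_raster()] objects.
#' @param mask a data frame of segments (`x0`, `y0`, `x1`, `y1`) and/or
#'   points (`x`, `y`); `NULL` or zero rows means no geometric mask.
#' @param buffer_width buffer distance in map units (default 75, the drawing
#'   width of roads on the historical survey sheets).
#' @return A list with elements `a` and `b`, the masked rasters.
#' @export
apply_common_mask <- function(a, b, mask = NULL, buffer_width = 75) {
  if (!same_grid(a, b)) stop("rasters are not co-registered")
  if (buffer_width < 0) stop("buffer_width must be >= 0")
  va <- a$values; vb <- b$values
  if (!is.null(mask) && nrow(mask) > 0) {
    # rows are stored south-to-north, so the row index maps directly to y
    px <- a$origin[1] + (col(va) - 0.5) * a$resolution
    py <- a$origin[2] + (row(va) - 0.5) * a$resolution
    d2min <- matrix(Inf, nrow(va), ncol(va))
    if (all(c("x0", "y0", "x1", "y1") %in% names(mask))) {
      segs <- mask[stats::complete.cases(mask[, c("x0", "y0", "x1", "y1")]), ]
      for (s in seq_len(nrow(segs))) {
        d2 <- dist2_point_segment(px, py, segs$x0[s], segs$y0[s],
                                  segs$x1[s], segs$y1[s])
        d2min <- pmin(d2min, d2)
      }
    }
    if (all(c("x", "y") %in% names(mask))) {
      pts <- mask[stats::complete.cases(mask[, c("x", "y")]), , drop = FALSE]
      for (s in seq_len(nrow(pts))) {
        d2 <- (px - pts$x[s])^2 + (py - pts$y[s])^2
        d2min <- pmin(d2min, d2)
      }
    }
    hit <- d2min <= buffer_width^2
    va[hit] <- a$nodata
    vb[hit] <- b$nodata
  }
  nd <- va == a$nodata | vb == b$nodata
  va[nd] <- a$nodata
  vb[nd] <- b$nodata
  list(a = cat_raster(va, a$resolution, a$origin, a$nodata),
       b = cat_raster(vb, b$resolution, b$origin, b$nodata))
}

# squared distance from points (px, py) to segment (x0,y0)-(x1,y1)
dist2_point_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x0)^2 + (py - y0)^2)
  t <- ((px - x0) * dx + (py - y0) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
}

# --- coarse-square bookkeeping ---------------------------------------------

# Assign each pixel a coarse square index; returns integer matrix of square
# ids (row-major id = (sq_y - 1) * nsq_x + sq_x, squares counted from the
# lower-left) or stops if square_size is not a pixel multiple.
square_index <- function(raster, square_size) {
  k <- square_size / raster$resolution
  if (abs(k - round(k)) > 1e-9) {
    stop("square_size must be a multiple of the pixel size")
  }
  k <- round(k)
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  sq_x <- ceiling(col(raster$values) / k)
  sq_y <- ceiling(row(raster$values) / k)
  nsq_x <- ceiling(nc / k)
  (sq_y - 1L) * nsq_x + sq_x
}

square_centroids <- function(raster, square_size) {
  k <- round(square_size / raster$resolution)
  nsq_x <- ceiling(ncol(raster$values) / k)
  nsq_y <- ceiling(nrow(raster$values) / k)
  tibble::tibble(
    square_id = seq_len(nsq_x * nsq_y),
    sq_x = rep(seq_len(nsq_x), times = nsq_y),
    sq_y = rep(seq_len(nsq_y), each = nsq_x),
    x = raster$origin[1] + (rep(seq_len(nsq_x), times = nsq_y) - 0.5) * square_size,
    y = raster$origin[2] + (rep(seq_len(nsq_y), each = nsq_x) - 0.5) * square_size
  )
}

#' Per-square land-cover category fractions
#'
#' Fraction of valid (non-nodata) pixels of each category within every
#' coarse square. Squares whose valid-pixel share falls below
#' `min_valid_fraction` are dropped (flagged via the `n_valid` column of the
#' attribute `"dropped"`).
#'
#' @param raster a harmonized [cat_raster()].
#' @param square_size coarse square edge length in map units (a multiple of
#'   the pixel size).
#' @param min_valid_fraction minimum share of valid pixels for a square to
#'   be reported (default 0.5).
#' @return A tibble with `square_id`, `category`, `fraction`; rows sum to 1
#'   within each reported square.
#' @export
category_fractions <- function(raster, square_size, min_valid_fraction = 0.5) {
  idx <- square_index(raster, square_size)
  v <- raster$values
  valid <- v != raster$nodata
  n_pix <- tabulate(idx, nbins = max(idx))
  n_valid <- tabulate(idx[valid], nbins = max(idx))
  keep <- n_valid / pmax(n_pix, 1) >= min_valid_fraction & n_valid > 0
  counts <- table(square_id = idx[valid], category = v[valid])
  long <- tibble::as_tibble(as.data.frame(counts, stringsAsFactors = FALSE))
  long$square_id <- as.integer(as.character(long$square_id))
  long$category <- as.integer(as.character(long$category))
  long <- dplyr::filter(long, .data$square_id %in% which(keep))
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$square_id),
    fraction = .data$Freq / sum(.data$Freq)
  )
  long <- dplyr::select(dplyr::ungroup(long), "square_id", "category", "fraction")
  full <- tidyr::expand_grid(square_id = sort(unique(long$square_id)),
                             category = raster$categories)
  out <- dplyr::left_join(full, long, by = c("square_id", "category"))
  out <- dplyr::mutate(out, fraction = dplyr::coalesce(.data$fraction, 0))
  out <- dplyr::arrange(out, .data$square_id, .data$category)
  attr(out, "dropped") <- which(!keep & n_pix > 0)
  out
}

#' Per-category fractional change between epochs
#'
#' Modern minus historical category fraction within each square; values lie
#' in \[-1, 1\] and sum to zero across categories within a square. Squares
#' present in only one epoch are excluded and listed in the `"excluded"`
#' attribute.
#'
#' @param frac_hist,frac_mod outputs of [category_fractions()] for the two
#'   epochs.
#' @return Tibble with `square_id`, `category`, `hist`, `mod`, `change`.
#' @export
fractional_change <- function(frac_hist, frac_mod) {
  h <- dplyr::rename(frac_hist, hist = "fraction")
  m <- dplyr::rename(frac_mod, mod = "fraction")
  both <- intersect(unique(h$square_id), unique(m$square_id))
  excluded <- setdiff(union(unique(h$square_id), unique(m$square_id)), both)
  out <- dplyr::inner_join(h, m, by = c("square_id", "category"))
  out <- dplyr::mutate(out, change = .data$mod - .data$hist)
  attr(out, "excluded") <- excluded
  out
}

#' Land conversion per coarse square
#'
#' The fraction of valid pixels within each square whose harmonized category
#' differs between the two epochs — the generic "land conversion" covariate
#' L of the persistence models.
#'
#' @param hist,mod co-registered, harmonized, co-masked [cat_raster()]s.
#' @inheritParams category_fractions
#' @return Tibble with `square_id`, `n_valid`, `L`.
#' @export
land_conversion <- function(hist, mod, square_size, min_valid_fraction = 0.5) {
  if (!same_grid(hist, mod)) stop("rasters are not co-registered")
  idx <- square_index(hist, square_size)
  valid <- hist$values != hist$nodata & mod$values != mod$nodata
  changed <- valid & hist$values != mod$values
  n_pix <- tabulate(idx, nbins = max(idx))
  n_valid <- tabulate(idx[valid], nbins = max(idx))
  n_changed <- tabulate(idx[changed], nbins = max(idx))
  keep <- n_valid / pmax(n_pix, 1) >= min_valid_fraction & n_valid > 0
  tibble::tibble(
    square_id = which(keep),
    n_valid = n_valid[keep],
    L = n_changed[keep] / n_valid[keep]
  )
}

#' Pixel-fate transition matrix
#'
#' For pixels of `from_category` (or all categories) in the historical
#' raster, the proportion ending up in each modern category — e.g. the fate
#' of historical lowland meadow and permanent grassland.
#'
#' @param hist,mod co-registered harmonized [cat_raster()]s.
#' @param from_category optional single historical category to restrict to.
#' @return Tibble `from`, `to`, `n`, `proportion`; proportions sum to 1
#'   within each `from` (self-retention included).
#' @export
transition_matrix <- function(hist, mod, from_category = NULL) {
  if (!same_grid(hist, mod)) stop("rasters are not co-registered")
  valid <- hist$values != hist$nodata & mod$values != mod$nodata
  h <- hist$values[valid]; m <- mod$values[valid]
  if (!is.null(from_category)) {
    sel <- h == from_category
    if (!any(sel)) {
      warning("from_category ", from_category, " absent from historical raster")
      return(tibble::tibble(from = integer(), to = integer(),
                            n = integer(), proportion = numeric()))
    }
    h <- h[sel]; m <- m[sel]
  }
  tab <- table(from = h, to = m)
  out <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  out$from <- as.integer(as.character(out$from))
  out$to <- as.integer(as.character(out$to))
  out <- dplyr::rename(out, n = "Freq")
  out <- dplyr::mutate(dplyr::group_by(out, .data$from),
                       proportion = .data$n / sum(.data$n))
  dplyr::arrange(dplyr::ungroup(out), .data$from, .data$to)
}

#' Habitat-specific change covariate for specialists
#'
#' Extracts one category's fractional change per square, for substituting
#' the generic land-conversion variable when modelling habitat specialists
#' (positive values mean retention/gain of the specialist's habitat).
#'
#' @param change output of [fractional_change()].
#' @param habitat_category harmonized category code of the habitat.
#' @return Tibble `square_id`, `habitat_change`.
#' @export
specialist_change <- function(change, habitat_category) {
  if (!habitat_category %in% unique(change$category)) {
    stop("unknown habitat category: ", habitat_category)
  }
  out <- dplyr::filter(change, .data$category == habitat_category)
  dplyr::select(dplyr::mutate(out, habitat_change = .data$change),
                "square_id", "habitat_change")
}

#' Digitisation agreement utilities
#'
#' `pixel_agreement()` is the share of mutually valid pixels assigned the
#' same category by two rasters; `square_rmsd()` is the root-mean-square
#' deviation of per-square category fractions between two rasters.
#'
#' @param a,b co-registered [cat_raster()]s.
#' @return A single number.
#' @export
pixel_agreement <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters are not co-registered")
  valid <- a$values != a$nodata & b$values != b$nodata
  if (!any(valid)) stop("no mutually valid pixels")
  mean(a$values[valid] == b$values[valid])
}

#' @rdname pixel_agreement
#' @inheritParams category_fractions
#' @export
square_rmsd <- function(a, b, square_size) {
  fa <- dplyr::rename(category_fractions(a, square_size), fa = "fraction")
  fb <- dplyr::rename(category_fractions(b, square_size), fb = "fraction")
  j <- dplyr::inner_join(fa, fb, by = c("square_id", "category"))
  sqrt(mean((j$fa - j$fb)^2))
}

#' Per-square temperature trend
#'
#' Ordinary least-squares slope of temperature on year, times ten, giving a
#' warming rate in degrees C per decade. Monthly series are first averaged
#' to annual means; squares with fewer than three annual values inside the
#' window are dropped and listed in the `"dropped"` attribute.
#'
#' @param series data frame with `square_id`, `year`, `temp` and optionally
#'   `month`.
#' @param window integer length-2 `(start, end)` year range (inclusive);
#'   `NULL` uses all years.
#' @return Tibble `square_id`, `n_years`, `temp_trend`.
#' @export
temperature_trend <- function(series, window = NULL) {
  df <- tibble::as_tibble(series)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$year >= window[1], .data$year <= window[2])
  }
  df <- dplyr::summarise(dplyr::group_by(df, .data$square_id, .data$year),
                         temp = mean(.data$temp), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$square_id),
    n_years = dplyr::n(),
    temp_trend = if (dplyr::n() >= 3) {
      10 * stats::cov(.data$year, .data$temp) / stats::var(.data$year)
    } else NA_real_,
    .groups = "drop"
  )
  dropped <- out$square_id[is.na(out$temp_trend)]
  out <- dplyr::filter(out, !is.na(.data$temp_trend))
  attr(out, "dropped") <- dropped
  out
}
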