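#' 2D dose grid on the isocenter plane
#'
#' A scalar field (Gy) on a uniform voxel-center grid in the U (horizontal)
#' / T (vertical) plane at isocenter.  The first array index runs along U
#' (increasing rightward in beam's-eye view), the second along T; `origin`
#' is the (U, T) position of the center of voxel `[1, 1]`.
#'
#' @param values Numeric matrix of doses (Gy), dimension `nU x nT`.
#' @param origin `c(u, t)` of the first voxel center, mm.
#' @param spacing Uniform voxel spacing, mm (> 0), both axes.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing) {
  stopifnot(is.matrix(values), length(origin) == 2)
  if (spacing <= 0) stop("grid spacing must be positive")
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "dose_grid")
}

#' Construct an empty (zero-dose) grid covering a rectangle
#'
#' @param u_range,t_range `c(min, max)` extents in mm (voxel centers).
#' @param spacing Voxel spacing, mm.
#' @return A `dose_grid` of zeros.
#' @export
empty_grid <- function(u_range, t_range, spacing) {
  nu <- floor(round((u_range[2] - u_range[1]) / spacing, 9)) + 1L
  nt <- floor(round((t_range[2] - t_range[1]) / spacing, 9)) + 1L
  dose_grid(matrix(0, nu, nt), origin = c(u_range[1], t_range[1]), spacing = spacing)
}

# voxel-center coordinates along each axis
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(u = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing,
       t = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$spacing - b$spacing) < tol
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  ax <- grid_axes(x)
  cat(sprintf("<dose_grid> %d x %d voxels, %.3g mm spacing\n", d[1], d[2], x$spacing))
  cat(sprintf("  U [%.1f, %.1f] mm, T [%.1f, %.1f] mm; max %.4g Gy, integral %.4g Gy.mm^2\n",
              ax$u[1], ax$u[d[1]], ax$t[1], ax$t[d[2]],
              max(x$values), sum(x$values) * x$spacing^2))
  invisible(x)
}

# Bilinear interpolation of grid values at arbitrary (u, t) points.
# Points outside the grid return `outside`.
interp_grid <- function(grid, u, t, outside = 0) {
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  fu <- (u - grid$origin[1]) / grid$spacing
  ft <- (t - grid$origin[2]) / grid$spacing
  i0 <- floor(fu); j0 <- floor(ft)
  wu <- fu - i0; wt <- ft - j0
  inside <- i0 >= 0 & j0 >= 0 & i0 <= d[1] - 1 & j0 <= d[2] - 1 &
    fu <= d[1] - 1 + 1e-9 & ft <= d[2] - 1 + 1e-9
  # clamp upper edge so points exactly on the last voxel center interpolate
  i0 <- pmin(pmax(i0, 0), d[1] - 2); j0 <- pmin(pmax(j0, 0), d[2] - 2)
  wu <- pmin(pmax(fu - i0, 0), 1); wt <- pmin(pmax(ft - j0, 0), 1)
  v <- grid$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  out <- (1 - wu) * (1 - wt) * idx(i0, j0) +
    wu * (1 - wt) * idx(i0 + 1L, j0) +
    (1 - wu) * wt * idx(i0, j0 + 1L) +
    wu * wt * idx(i0 + 1L, j0 + 1L)
  out[!inside] <- outside
  out
}

# index of the voxel whose center is nearest to (u, t)
nearest_voxel <- function(grid, u, t) {
  d <- dim(grid$values)
  i <- round((u - grid$origin[1]) / grid$spacing) + 1L
  j <- round((t - grid$origin[2]) / grid$spacing) + 1L
  c(min(max(i, 1L), d[1]), min(max(j, 1L), d[2]))
}

#' Dose at an arbitrary point (bilinear interpolation)
#' @param grid A `dose_grid`.
#' @param u,t Position in mm.
#' @return Dose in Gy (0 outside the grid).
#' @export
dose_at <- function(grid, u, t) interp_grid(grid, u, t)

#' Rigidly translate a dose grid
#'
#' Resamples the field at positions shifted by `(-du, -dt)` so the features
#' move by `(+du, +dt)`; used to apply the five-spot offset correction to a
#' measured map.  Regions translated in from outside the grid are zero.
#'
#' @param grid A `dose_grid`.
#' @param du,dt Translation in mm.
#' @return A translated `dose_grid` on the same geometry.
#' @export
translate_grid <- function(grid, du, dt) {
  ax <- grid_axes(grid)
  pts <- expand.grid(u = ax$u, t = ax$t)
  vals <- interp_grid(grid, pts$u - du, pts$t - dt)
  dose_grid(matrix(pmax(vals, 0), nrow = length(ax$u)), grid$origin, grid$spacing)
}

#' Write a dose grid as CSV plus a JSON geometry sidecar
#'
#' The CSV holds the value matrix (rows = U index, columns = T index); the
#' sidecar `<path minus .csv>.geom.json` records origin, spacing and units.
#'
#' @param grid A `dose_grid` (or `dose_rate_grid`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dose_grid <- function(grid, path) {
  units <- if (inherits(grid, "dose_rate_grid")) "Gy/s" else "Gy"
  vals <- grid$values
  if (!is.null(grid$valid_mask)) vals[!grid$valid_mask] <- NA
  write.table(vals, path, sep = ",", row.names = FALSE, col.names = FALSE, na = "NA")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".geom.json")
  jsonlite::write_json(list(origin_mm = grid$origin, spacing_mm = grid$spacing,
                            dim = dim(grid$values), units = units,
                            axes = c("U", "T")),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dose grid written by [write_dose_grid()]
#' @param path CSV path (the `.geom.json` sidecar must sit next to it).
#' @return A `dose_grid`.
#' @export
read_dose_grid <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".geom.json")
  if (!file.exists(sidecar)) stop("geometry sidecar not found: ", sidecar)
  geom <- jsonlite::fromJSON(sidecar)
  vals <- as.matrix(read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  vals[is.na(vals)] <- 0
  dose_grid(vals, origin = geom$origin_mm, spacing = geom$spacing_mm)
}

#' Per-voxel dose-rate grid
#'
#' Same geometry as [dose_grid()]; carries a validity mask (voxels whose
#' dose exceeds the dose floor and whose 5%-95% time window is non-zero)
#' and a reason string per invalid voxel.
#'
#' @param values Matrix of dose rates, Gy/s (NA where invalid).
#' @param origin,spacing Geometry as in [dose_grid()].
#' @param valid_mask Logical matrix.
#' @param invalid_reason Character matrix (`""` where valid).
#' @return Object of classes `dose_rate_grid`, `dose_grid`.
#' @export
dose_rate_grid <- function(values, origin, spacing, valid_mask,
                           invalid_reason = NULL) {
  stopifnot(is.matrix(values), all(dim(values) == dim(valid_mask)))
  if (spacing <= 0) stop("grid spacing must be positive")
  if (any(values[valid_mask] < 0, na.rm = TRUE)) stop("dose rates must be non-negative")
  values[!valid_mask] <- NA_real_
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), valid_mask = valid_mask,
                 invalid_reason = invalid_reason),
            class = c("dose_rate_grid", "dose_grid"))
}

#' @export
print.dose_rate_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_rate_grid> %d x %d voxels, %.3g mm spacing; %d valid\n",
              d[1], d[2], x$spacing, sum(x$valid_mask)))
  if (any(x$valid_mask)) {
    cat(sprintf("  dose rate [%.4g, %.4g] Gy/s (valid voxels)\n",
                min(x$values[x$valid_mask]), max(x$values[x$valid_mask])))
  }
  invisible(x)
}
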