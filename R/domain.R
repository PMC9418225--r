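#' Material label codes
#'
#' Integer codes used in label rasters. Every voxel carries exactly one code.
#' `EXTERIOR` marks background outside the organ outline, `AIR` marks air
#' inside the bounding box; both carry no flow or thermal unknowns and expose
#' neighbouring tissue to the ambient (Robin) boundary condition.
#'
#' @format Named integer vector with elements `EXTERIOR`, `TISSUE`, `ARTERY`,
#'   `VEIN`, `AIR`.
#' @export
MATERIALS <- c(EXTERIOR = 0L, TISSUE = 1L, ARTERY = 2L, VEIN = 3L, AIR = 4L)

#' Construct a labeled voxel grid
#'
#' A structured 3-D raster of material labels with (possibly anisotropic)
#' voxel spacing. This is the porous-flow and thermal mesh: tissue voxels
#' carry compartment pressures and a temperature, vessel voxels belong to a
#' 1-D vessel element, and exterior/air voxels carry no unknowns.
#'
#' Voxels are addressed by 1-based linear index in R's native array order
#' (x fastest, then y, then z); matrix row ordering throughout the package is
#' derived from this order and is therefore reproducible.
#'
#' @param labels integer 3-D array of \code{\link{MATERIALS}} codes.
#' @param spacing numeric length-3 vector, voxel edge lengths (m).
#' @return An object of class `voxel_grid` with fields `shape`, `spacing`,
#'   `labels`, and `voxel_volume` (m^3, the product of the spacings).
#' @examples
#' g <- voxel_grid(array(MATERIALS["TISSUE"], c(2, 2, 2)), c(64e-6, 64e-6, 333e-6))
#' g$voxel_volume
#' @export
voxel_grid <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive lengths (m)")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% MATERIALS))
    stop("unknown material code in `labels`")
  g <- structure(list(
    shape = dim(labels),
    spacing = as.numeric(spacing),
    labels = labels,
    voxel_volume = prod(as.numeric(spacing))
  ), class = "voxel_grid")
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %s m\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  tab <- table(factor(x$labels, levels = MATERIALS, labels = names(MATERIALS)))
  for (nm in names(tab)) if (tab[[nm]] > 0) cat(sprintf("  %-9s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Voxel center coordinates
#'
#' @param grid a `voxel_grid`.
#' @param idx linear voxel indices (1-based, x fastest); default all voxels.
#' @return numeric matrix with columns x, y, z (m).
#' @export
voxel_centers <- function(grid, idx = seq_len(prod(grid$shape))) {
  a <- arrayInd(idx, grid$shape)
  cbind(x = (a[, 1] - 0.5) * grid$spacing[1],
        y = (a[, 2] - 0.5) * grid$spacing[2],
        z = (a[, 3] - 0.5) * grid$spacing[3])
}

in_domain <- function(labels)
  labels == MATERIALS[["TISSUE"]] | labels == MATERIALS[["ARTERY"]] |
    labels == MATERIALS[["VEIN"]]

#' Convert a single labeled slice into a three-layer 3-D domain
#'
#' Planar vessel maps place arterial and venous trees in the same voxel
#' layer, which walls off sources from sinks. The slice is split into three
#' sub-slices across its depth: layer 1 keeps the arterial labels (venous
#' positions become tissue), layer 2 is all tissue inside the organ outline,
#' and layer 3 keeps the venous labels (arterial positions become tissue).
#' Blood delivered in layer 1 must then perfuse through layer 2 to reach the
#' venous sinks in layer 3. Voxels outside the organ outline stay
#' exterior/air in every layer.
#'
#' @param slice_labels integer matrix of \code{\link{MATERIALS}} codes.
#' @param slice_thickness full slice thickness (m); each layer gets a third.
#' @param spacing_xy in-plane voxel edge lengths (m), length 2.
#' @param require_vessels error when the slice lacks arterial or venous
#'   labels (default TRUE: such a domain admits no flow roots). Set FALSE
#'   for purely geometric conversions.
#' @return a `voxel_grid` of shape `(nrow, ncol, 3)`.
#' @export
build_three_layer_domain <- function(slice_labels, slice_thickness,
                                     spacing_xy = c(64e-6, 64e-6),
                                     require_vessels = TRUE) {
  if (!is.matrix(slice_labels)) stop("`slice_labels` must be a matrix")
  storage.mode(slice_labels) <- "integer"
  TIS <- MATERIALS[["TISSUE"]]; ART <- MATERIALS[["ARTERY"]]; VEN <- MATERIALS[["VEIN"]]
  if (!any(in_domain(slice_labels)))
    stop("slice contains no in-organ voxel")
  if (require_vessels &&
      (!any(slice_labels == ART) || !any(slice_labels == VEN)))
    stop("slice has no arterial and/or venous labels: no flow roots possible")
  inside <- in_domain(slice_labels)
  l1 <- slice_labels; l1[inside & l1 == VEN] <- TIS
  l2 <- slice_labels; l2[inside] <- TIS
  l3 <- slice_labels; l3[inside & l3 == ART] <- TIS
  labs <- array(0L, c(dim(slice_labels), 3L))
  labs[, , 1] <- l1; labs[, , 2] <- l2; labs[, , 3] <- l3
  voxel_grid(labs, c(spacing_xy, slice_thickness / 3))
}

#' Enumerate grid faces with geometric factors
#'
#' One face per 6-neighbour pair of in-domain voxels (tissue/artery/vein),
#' each pair reported once, plus ambient faces where an in-domain voxel
#' abuts air, exterior, or the edge of the raster. Face area is the product
#' of the two spacings orthogonal to the face axis; the center distance is
#' the spacing along the axis (interior and ambient alike; for ambient faces
#' it is the half-cell distance doubled, used in the Robin coefficient).
#'
#' @param grid a `voxel_grid`.
#' @return list with data frames `interior` (columns `i`, `j`, `axis`,
#'   `area`, `dist`) and `ambient` (columns `i`, `axis`, `area`, `dist`).
#' @export
interior_faces <- function(grid) {
  sh <- grid$shape; sp <- grid$spacing
  dom <- in_domain(grid$labels)
  lin <- array(seq_len(prod(sh)), sh)
  int_i <- integer(0); int_j <- integer(0); int_ax <- integer(0)
  amb_i <- integer(0); amb_ax <- integer(0)
  for (ax in 1:3) {
    n <- sh[ax]
    # faces between slabs s and s+1 along ax
    if (n > 1) {
      idx_lo <- slab_index(sh, ax, 1:(n - 1))
      idx_hi <- slab_index(sh, ax, 2:n)
      both <- dom[idx_lo] & dom[idx_hi]
      int_i <- c(int_i, lin[idx_lo][both]); int_j <- c(int_j, lin[idx_hi][both])
      int_ax <- c(int_ax, rep.int(ax, sum(both)))
      # in-domain next to out-of-domain neighbour
      lo_amb <- dom[idx_lo] & !dom[idx_hi]
      hi_amb <- dom[idx_hi] & !dom[idx_lo]
      amb_i <- c(amb_i, lin[idx_lo][lo_amb], lin[idx_hi][hi_amb])
      amb_ax <- c(amb_ax, rep.int(ax, sum(lo_amb) + sum(hi_amb)))
    }
    # raster boundary faces
    first <- slab_index(sh, ax, 1); last <- slab_index(sh, ax, n)
    amb_i <- c(amb_i, lin[first][dom[first]], lin[last][dom[last]])
    amb_ax <- c(amb_ax, rep.int(ax, sum(dom[first]) + sum(dom[last])))
  }
  areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  list(
    interior = data.frame(i = int_i, j = int_j, axis = int_ax,
                          area = areas[int_ax], dist = sp[int_ax]),
    ambient = data.frame(i = amb_i, axis = amb_ax,
                         area = areas[amb_ax], dist = sp[amb_ax])
  )
}

# logical index selecting slabs `pos` along axis `ax` of a grid of shape `sh`
slab_index <- function(sh, ax, pos) {
  ix <- list(seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3]))
  ix[[ax]] <- pos
  m <- array(FALSE, sh)
  m[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
  m
}
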