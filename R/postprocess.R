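# Morphological refinement of the CMF mask.

#' Disc-shaped structuring element
#'
#' Offsets are all integer lattice points with \code{dy^2 + dx^2 <= radius^2}
#' (a radius-5 disc has 81 offsets).
#'
#' @param radius nonnegative integer radius in pixels
#' @return a [StructuringElement-class]
#' @export
makeDiscSE <- function(radius) {
  if (radius < 0 || radius != round(radius))
    stop("radius must be a nonnegative integer", call. = FALSE)
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- g$dy^2 + g$dx^2 <= r^2
  new("StructuringElement",
      offsets = as.matrix(g[keep, , drop = FALSE]), radius = radius)
}

.asMaskSlices <- function(mask) {
  if (is(mask, "BinaryMask")) return(mask@data)
  if (is.matrix(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
    return(array(mask, c(1L, dim(mask))))
  }
  stop("mask must be a BinaryMask or a binary matrix", call. = FALSE)
}

.wrapLike <- function(out, template) {
  if (is(template, "BinaryMask")) BinaryMask(out, template@spacing)
  else out[1, , , drop = TRUE]
}

.morphSlice <- function(slice, se, op) {
  acc <- matrix(if (op == "dilate") 0 else 1, nrow(slice), ncol(slice))
  for (i in seq_len(nrow(se@offsets))) {
    dy <- se@offsets[i, 1]; dx <- se@offsets[i, 2]
    # dilation translates the reflected SE; erosion tests the SE fit, with
    # everything outside the image treated as background
    sh <- if (op == "dilate") .shiftMatrix(slice, dy, dx, 0)
          else .shiftMatrix(slice, -dy, -dx, 0)
    acc <- if (op == "dilate") pmax(acc, sh) else pmin(acc, sh)
  }
  acc
}

#' Morphological dilation and erosion of a binary mask
#'
#' Dilation is the union of the reflected structuring element translated to
#' every foreground pixel; erosion keeps the positions where the element fits
#' entirely inside the mask (pixels beyond the image border count as
#' background). Operates per axial slice.
#'
#' @param mask a [BinaryMask-class] or binary matrix
#' @param se a [StructuringElement-class]
#' @return object of the same kind as \code{mask}
#' @export
dilateMask <- function(mask, se) {
  a <- .asMaskSlices(mask)
  .wrapLike(.mapSlices(a, .morphSlice, se = se, op = "dilate"), mask)
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, se) {
  a <- .asMaskSlices(mask)
  .wrapLike(.mapSlices(a, .morphSlice, se = se, op = "erode"), mask)
}

# label connected components of a binary matrix by iterated minimum
# propagation; returns a matrix of component ids (0 = background), where each
# component's id is the linear (column-major) index of its first pixel
.labelComponents <- function(m, connectivity = 8) {
  offs <- if (connectivity == 8)
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  lab <- matrix(seq_along(m), nrow(m), ncol(m))
  lab[m == 0] <- Inf
  repeat {
    nl <- lab
    for (o in offs)
      nl <- pmin(nl, .shiftMatrix(lab, o[1], o[2], Inf))
    nl[m == 0] <- Inf
    if (identical(nl, lab)) break
    lab <- nl
  }
  lab[!is.finite(lab)] <- 0
  lab
}

.largestComponentSlice <- function(m, connectivity) {
  lab <- .labelComponents(m, connectivity)
  ids <- lab[lab > 0]
  if (!length(ids)) return(m * 0)
  tab <- table(ids)
  biggest <- as.numeric(names(tab)[which.max(tab)])  # ties: smallest id =
  (lab == biggest) * 1                               # first in scan order
}

#' Keep only the largest connected component
#'
#' Everything but the maximum-area component is zeroed (treated as noise).
#' Ties are broken in favor of the component whose first pixel comes first in
#' column-major scan order. Per-slice by default; \code{perSlice = FALSE}
#' labels in 3-D (26- or 6-connectivity) and keeps one component in the
#' volume.
#'
#' @param mask a [BinaryMask-class] or binary matrix
#' @param connectivity 8 (default) or 4 in 2-D; 26 or 6 in 3-D volume mode
#' @param perSlice retain one component per axial slice (default) or one per
#'   volume
#' @return object of the same kind as \code{mask}; an empty mask comes back
#'   empty (with a message)
#' @export
largestComponent <- function(mask, connectivity = 8, perSlice = TRUE) {
  a <- .asMaskSlices(mask)
  if (sum(a) == 0) {
    message("largestComponent: empty mask")
    return(.wrapLike(a, mask))
  }
  if (perSlice || dim(a)[1] == 1L) {
    conn2 <- if (connectivity %in% c(8, 26)) 8 else 4
    return(.wrapLike(.mapSlices(a, .largestComponentSlice,
                                connectivity = conn2), mask))
  }
  .wrapLike(.largestComponent3D(a, connectivity), mask)
}

.largestComponent3D <- function(a, connectivity = 26) {
  d <- dim(a)
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (connectivity == 6 && sum(abs(c(dz, dy, dx))) != 1) next
    offs[[length(offs) + 1]] <- c(dz, dy, dx)
  }
  shift3 <- function(x, o) {
    out <- array(Inf, d)
    zs <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    ys <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    xs <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    out[zs, ys, xs] <- x[zs - o[1], ys - o[2], xs - o[3]]
    out
  }
  lab <- array(seq_along(a), d)
  lab[a == 0] <- Inf
  repeat {
    nl <- lab
    for (o in offs) nl <- pmin(nl, shift3(lab, o))
    nl[a == 0] <- Inf
    if (identical(nl, lab)) break
    lab <- nl
  }
  ids <- lab[is.finite(lab)]
  tab <- table(ids)
  biggest <- as.numeric(names(tab)[which.max(tab)])
  (lab == biggest & is.finite(lab)) * 1
}

#' Morphological refinement of a CMF segmentation mask
#'
#' Three steps: dilate by a disc (reconnecting fragments near the lesion),
#' keep the largest connected component of the dilation, then intersect the
#' retained region with the original mask -- restoring the lesion's own
#' pixels inside the winning region while discarding distant speckle. The
#' output never contains a pixel absent from the input mask.
#'
#' @param mask a [BinaryMask-class] or binary matrix (CMF output)
#' @param seRadius disc radius in pixels (default 5)
#' @param connectivity component connectivity (default 8)
#' @param perSlice refine per axial slice (default) or per volume
#' @return refined mask of the same kind
#' @export
refineMask <- function(mask, seRadius = 5, connectivity = 8, perSlice = TRUE) {
  a <- .asMaskSlices(mask)
  se <- makeDiscSE(seRadius)
  dil <- .mapSlices(a, .morphSlice, se = se, op = "dilate")
  if (sum(dil) == 0) return(.wrapLike(a, mask))
  big <- if (perSlice || dim(a)[1] == 1L)
    .mapSlices(dil, .largestComponentSlice,
               connectivity = if (connectivity %in% c(8, 26)) 8 else 4)
  else .largestComponent3D(dil, connectivity)
  .wrapLike(big * a, mask)
}
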