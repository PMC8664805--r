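# raster operations on plain matrices (row/col grids, one value per pixel)

# TRUE where any 8-neighbor (queen's rule) of a cell satisfies `mask`;
# cells outside the grid border never contribute
neighbor_any <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  out <- matrix(FALSE, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1 && dc == 1) next
    out <- out | pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  out
}

#' Detect forest pixels on anthropogenic edges
#'
#' Flags every forest pixel adjacent (queen's rule, 8 neighbors) to a
#' non-forest pixel of an anthropogenic class (cultivated or developed by
#' default; the reclassification map is configurable). The grid border
#' itself does not create edge: only in-bounds neighbors are considered.
#'
#' @param land_cover Character matrix of land-cover classes.
#' @param forest_class Class treated as forest.
#' @param anthropogenic_classes Classes whose adjacency defines an
#'   anthropogenic edge.
#' @param known_classes Full legend; any other value is an error listing
#'   the offending codes.
#' @return Logical matrix, `TRUE` on edge forest pixels.
#' @export
detect_anthropogenic_edges <- function(land_cover, forest_class = "forest",
                                       anthropogenic_classes = c("developed",
                                                                 "cultivated"),
                                       known_classes = c("forest",
                                                         "developed",
                                                         "cultivated",
                                                         "water", "other")) {
  vals <- unique(as.vector(land_cover))
  bad <- setdiff(vals[!is.na(vals)], known_classes)
  if (length(bad) > 0) {
    stop_ef("unknown land-cover class code(s): ", paste(bad, collapse = ", "))
  }
  forest <- !is.na(land_cover) & land_cover == forest_class
  anthro <- !is.na(land_cover) & land_cover %in% anthropogenic_classes
  forest & neighbor_any(anthro)
}

#' Detect forest pixels on any edge
#'
#' Flags every forest pixel adjacent (queen's rule) to any non-forest
#' pixel, with the same border convention as
#' [detect_anthropogenic_edges()].
#'
#' @param forest Logical forest mask.
#' @return Logical matrix, `TRUE` on edge forest pixels.
#' @export
detect_any_edges <- function(forest) {
  storage.mode(forest) <- "logical"
  forest & neighbor_any(!forest)
}

#' Threshold a canopy-cover raster into a forest mask
#'
#' `forest <=> cover >= tau`; the boundary is inclusive because forest
#' definitions phrased as "more than x% canopy cover" are applied to
#' integer-percent raster products.
#'
#' @param canopy Numeric matrix of percent canopy cover `[0, 100]`.
#' @param tau Threshold percent (10 by default; 30 for the robustness
#'   check).
#' @return Logical forest mask.
#' @export
forest_mask <- function(canopy, tau = 10) {
  if (any(canopy < 0 | canopy > 100, na.rm = TRUE)) {
    stop_ef("canopy cover must lie in [0, 100]")
  }
  !is.na(canopy) & canopy >= tau
}

#' Fill gaps in a covariate raster from the nearest valid cell
#'
#' Every missing cell takes the value of the nearest non-missing cell by
#' Euclidean pixel distance; ties are broken by row-major cell order.
#'
#' @param m Numeric matrix with `NA` gaps.
#' @return The matrix with all gaps filled (unchanged when gap-free).
#' @export
fill_covariate_gaps <- function(m) {
  na_idx <- which(is.na(m))
  if (length(na_idx) == 0) return(m)
  valid_idx <- which(!is.na(m))
  if (length(valid_idx) == 0) stop_ef("raster has no valid cells to fill from")
  nr <- nrow(m)
  # row-major order index for tie-breaking (R matrices are column-major)
  rm_order <- function(idx) {
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    (r - 1) * ncol(m) + c
  }
  vr <- (valid_idx - 1) %% nr + 1
  vc <- (valid_idx - 1) %/% nr + 1
  v_rm <- rm_order(valid_idx)
  ord <- order(v_rm)
  vr <- vr[ord]; vc <- vc[ord]
  vals <- m[valid_idx][ord]
  for (i in na_idx) {
    r <- (i - 1) %% nr + 1
    c <- (i - 1) %/% nr + 1
    d2 <- (vr - r)^2 + (vc - c)^2
    m[i] <- vals[which.min(d2)]   # first minimum = lowest row-major order
  }
  m
}
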