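# Vein-network skeletonization and junction detection.

#' Skeletonize the vein network
#'
#' Applies two-subiteration morphological thinning (Zhang-Suen scheme) to
#' the vein (dark) phase of a binarized wing until stable, reducing the
#' vein network to a 1-px-wide centerline while preserving its
#' connectivity and holes.
#'
#' @param image A `wa_binary` object (veins are the `FALSE` phase).
#' @return A `wa_skeleton` object: list with logical `mask` (`TRUE` =
#'   skeleton pixel) and `dims`.
#' @export
skeletonize <- function(image) {
  stopifnot(inherits(image, "wa_binary"))
  veins <- !image$mask
  if (!any(veins)) {
    warning("no vein pixels; skeleton is empty")
    return(structure(list(mask = veins, dims = dim(veins)),
                     class = "wa_skeleton"))
  }
  structure(list(mask = thin_zs_cpp(veins), dims = dim(veins)),
            class = "wa_skeleton")
}

# Neighbor stack (8 shifted copies of the mask in cyclic order
# N, NE, E, SE, S, SW, W, NW) used for the junction rule.
neighbor_stack <- function(mask) {
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lapply(seq_len(8), function(k)
    shift_mat(mask * 1L, offs[k, 1], offs[k, 2], 0L))
}

# Raw junction-pixel rule on a thin skeleton: a skeleton pixel whose
# 8-neighborhood holds >= 3 skeleton pixels and whose crossing number
# (0 -> 1 transitions around the cyclic neighborhood) is >= 3.
junction_pixel_mask <- function(mask) {
  nb <- neighbor_stack(mask)
  count <- Reduce(`+`, nb)
  cn <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(8)) {
    nxt <- if (k == 8) 1 else k + 1
    cn <- cn + (nb[[k]] == 0L & nb[[nxt]] == 1L)
  }
  mask & count >= 3 & cn >= 3
}

#' Detect vein junctions on a skeleton
#'
#' A skeleton pixel is a raw junction pixel if its 8-neighborhood contains
#' at least 3 skeleton pixels and its crossing number (number of 0 to 1
#' transitions around the cyclic 8-neighborhood) is at least 3 -- the
#' standard characterization of branch points on thin skeletons. Adjacent
#' raw junction pixels (common at X-crossings after thinning) are merged by
#' 8-connected clustering into one junction at the cluster centroid. Open
#' skeleton spurs shorter than `prune` pixels are removed first, since
#' thinning artifacts otherwise create false junctions.
#'
#' @param skeleton A `wa_skeleton` object.
#' @param prune Minimum branch length (px); shorter free-ended spurs are
#'   pruned before detection. Set to 0 to disable.
#' @return Data frame `junction_id, row, col`, sorted by (row, col).
#' @export
detect_junctions <- function(skeleton, prune = 5) {
  stopifnot(inherits(skeleton, "wa_skeleton"))
  mask <- skeleton$mask
  if (prune > 0 && any(mask)) mask <- prune_spurs_cpp(mask, as.integer(prune))
  raw <- junction_pixel_mask(mask)
  if (!any(raw))
    return(data.frame(junction_id = integer(0), row = numeric(0),
                      col = numeric(0)))
  comp <- cc_label_cpp(raw, 8L)
  idx <- which(comp > 0)
  lab <- comp[idx]
  nr <- nrow(mask)
  rr <- ((idx - 1) %% nr) + 1; cc <- ((idx - 1) %/% nr) + 1
  n <- max(lab)
  cnt <- tabulate(lab, nbins = n)
  pos <- data.frame(row = rowsum(rr, lab)[, 1] / cnt,
                    col = rowsum(cc, lab)[, 1] / cnt)
  pos <- pos[order(pos$row, pos$col), ]
  data.frame(junction_id = seq_len(n), row = pos$row, col = pos$col,
             row.names = NULL)
}

#' @export
print.wa_skeleton <- function(x, ...) {
  cat("<wa_skeleton> ", x$dims[1], "x", x$dims[2], ", ",
      sum(x$mask), " skeleton pixels\n", sep = "")
  invisible(x)
}
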