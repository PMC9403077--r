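#' Cortical parcellation atlas (68 regions)
#'
#' An `roi_atlas` holds the metadata of the 68-region Desikan-Killiany
#' cortical parcellation used throughout the pipeline: region labels
#' (34 per hemisphere), lobe membership, region centroids (mm) and a
#' spatial adjacency matrix used by the nodal-level cluster statistics.
#'
#' Lobe categories are `frontal`, `parietal`, `temporal`, `occipital` and
#' `other`; cingulate and insular regions are assigned to `other` and are
#' excluded from lobe-averaged power maps, which summarize the four lobes
#' only. Region ordering is fixed: left hemisphere first, alphabetical
#' within hemisphere; every matrix produced by the package uses this order.
#'
#' @name roi_atlas
NULL

ATLAS_LOBES <- c("frontal", "parietal", "temporal", "occipital", "other")

new_roi_atlas <- function(labels, hemi, lobe, centroid, adjacency,
                          threshold_mm = NA_real_) {
  a <- list(labels = labels, hemi = hemi, lobe = lobe,
            centroid = centroid, adjacency = adjacency,
            threshold_mm = threshold_mm)
  class(a) <- "roi_atlas"
  validate_atlas(a)
  a
}

validate_atlas <- function(a) {
  n <- length(a$labels)
  if (n != 68L)
    stop(sprintf("expected 68 ROIs, found %d", n))
  if (anyDuplicated(a$labels))
    stop(sprintf("duplicate ROI label: %s",
                 a$labels[duplicated(a$labels)][1L]))
  if (!all(a$lobe %in% ATLAS_LOBES))
    stop("unknown lobe category: ",
         paste(setdiff(unique(a$lobe), ATLAS_LOBES), collapse = ", "))
  A <- a$adjacency
  if (!is.matrix(A) || any(dim(A) != n))
    stop("adjacency must be a 68x68 matrix")
  if (!isTRUE(all(A == t(A))))
    stop("adjacency matrix is not symmetric")
  if (any(diag(A) != 0))
    stop("adjacency diagonal must be zero")
  for (h in unique(a$hemi)) {
    idx <- which(a$hemi == h)
    g <- igraph::graph_from_adjacency_matrix(A[idx, idx, drop = FALSE],
                                             mode = "undirected")
    if (igraph::components(g)$no != 1L)
      warning(sprintf("adjacency graph is disconnected within hemisphere %s", h))
  }
  invisible(a)
}

#' Derive spatial adjacency from region centroids
#'
#' Two regions are adjacent when their centroid distance is below a
#' threshold. The threshold (default 40 mm) was chosen once so that the
#' packaged atlas graph is connected within each hemisphere; the derived
#' matrix is shipped explicitly with the default atlas file so downstream
#' statistics are reproducible byte-for-byte.
#'
#' @param centroid numeric n x 3 matrix of coordinates in mm.
#' @param threshold_mm adjacency radius in mm.
#' @return symmetric logical-valued 0/1 matrix with zero diagonal.
#' @export
derive_adjacency <- function(centroid, threshold_mm = 40) {
  d <- as.matrix(stats::dist(centroid))
  A <- (d < threshold_mm) * 1
  diag(A) <- 0
  A
}

#' Load a parcellation atlas from a delimited file
#'
#' The file is tab-delimited with one region per row and columns
#' `label`, `hemi`, `lobe`, `x`, `y`, `z` and optionally `neighbors`
#' (semicolon-separated labels). When `neighbors` is present it defines
#' the adjacency matrix explicitly (and must be symmetric); otherwise
#' adjacency is derived from centroids with [derive_adjacency()].
#'
#' @param path file path; defaults to the packaged 68-region atlas.
#' @param threshold_mm centroid-distance threshold used when no explicit
#'   neighbor column is present.
#' @return an `roi_atlas`.
#' @export
load_atlas <- function(path = system.file("extdata", "dk68_atlas.tsv",
                                          package = "icohnet"),
                       threshold_mm = 40) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "hemi", "lobe", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("atlas file must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) != 68L)
    stop(sprintf("expected 68 ROIs, found %d rows", nrow(tab)))
  if (anyDuplicated(tab$label))
    stop(sprintf("duplicate ROI label: %s",
                 tab$label[duplicated(tab$label)][1L]))
  ord <- order(tab$hemi, tab$label)  # lh before rh, alphabetical within
  tab <- tab[ord, , drop = FALSE]
  centroid <- as.matrix(tab[, c("x", "y", "z")])
  rownames(centroid) <- tab$label
  if ("neighbors" %in% names(tab) && any(nzchar(tab$neighbors))) {
    A <- matrix(0, 68, 68, dimnames = list(tab$label, tab$label))
    for (i in seq_len(68)) {
      nb <- strsplit(tab$neighbors[i], ";", fixed = TRUE)[[1L]]
      nb <- nb[nzchar(nb)]
      bad <- setdiff(nb, tab$label)
      if (length(bad))
        stop(sprintf("row %d (%s): unknown neighbor label %s",
                     i, tab$label[i], bad[1L]))
      A[i, match(nb, tab$label)] <- 1
    }
    if (!isTRUE(all(A == t(A)))) {
      off <- which(A != t(A), arr.ind = TRUE)[1L, ]
      stop(sprintf("asymmetric explicit adjacency between %s and %s",
                   tab$label[off[1L]], tab$label[off[2L]]))
    }
    diag(A) <- 0
  } else {
    A <- derive_adjacency(centroid, threshold_mm)
  }
  new_roi_atlas(tab$label, tab$hemi, stats::setNames(tab$lobe, tab$label),
                centroid, A, threshold_mm)
}

#' Write an atlas back to its delimited representation
#'
#' Inverse of [load_atlas()]: the written file round-trips exactly.
#'
#' @param atlas an `roi_atlas`.
#' @param path output file path.
#' @export
write_atlas <- function(atlas, path) {
  nb <- vapply(seq_along(atlas$labels), function(i) {
    paste(atlas$labels[atlas$adjacency[i, ] != 0], collapse = ";")
  }, character(1))
  tab <- data.frame(label = atlas$labels, hemi = atlas$hemi,
                    lobe = unname(atlas$lobe),
                    x = atlas$centroid[, 1], y = atlas$centroid[, 2],
                    z = atlas$centroid[, 3], neighbors = nb)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition atlas regions into the four lobes
#'
#' Returns the region indices of the frontal, parietal, temporal and
#' occipital lobes. Regions labeled `other` (cingulate, insula) are not
#' part of any lobe list and are excluded from lobe-averaged power maps.
#'
#' @param atlas an `roi_atlas`.
#' @return named list of integer index vectors (possibly empty).
#' @export
lobe_partition <- function(atlas) {
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  out <- lapply(lobes, function(l) which(unname(atlas$lobe) == l))
  names(out) <- lobes
  out
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas> %d regions (%d lh / %d rh), %d adjacency edges\n",
              length(x$labels), sum(x$hemi == "lh"), sum(x$hemi == "rh"),
              sum(x$adjacency) / 2))
  tl <- table(unname(x$lobe))
  cat("  lobes:", paste(sprintf("%s=%d", names(tl), tl), collapse = ", "), "\n")
  invisible(x)
}
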