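check_weight_matrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix")
  if (any(W < 0))
    stop("negative edge weight: split polarities before computing indices")
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  invisible(W)
}

#' Nodal strength (weighted degree)
#'
#' Sum of each node's edge weights.
#'
#' @param W nonnegative symmetric weight matrix with zero diagonal.
#' @return numeric vector of length `nrow(W)`.
#' @export
nodal_strength <- function(W) {
  check_weight_matrix(W)
  rowSums(W)
}

#' Nodal weighted clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity around each node on weights
#' normalized by the network-wide maximum:
#' `C_i = sum_{j,k} (w_ij w_jk w_ki)^(1/3) / (k_i (k_i - 1))` with
#' `k_i` the number of nonzero neighbors; `C_i = 0` when `k_i < 2`.
#' Invariant to global weight rescaling.
#'
#' @param W nonnegative symmetric weight matrix with zero diagonal.
#' @return numeric vector in [0, 1].
#' @export
nodal_clustering <- function(W) {
  check_weight_matrix(W)
  mx <- max(W)
  if (mx == 0) return(rep(0, nrow(W)))
  Wh <- (W / mx)^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  out <- rep(0, nrow(W))
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Characteristic path length of a weighted network
#'
#' Edge lengths are inverse weights (`1/w`); shortest paths are computed
#' with Dijkstra's algorithm and the characteristic path length is the
#' mean of the finite off-diagonal distances. Disconnected pairs are
#' excluded from the mean and their fraction reported.
#'
#' @param W nonnegative symmetric weight matrix with zero diagonal.
#' @return list: `path_length`, `distances` (matrix, `Inf` for
#'   disconnected pairs), `frac_infinite`.
#' @export
char_path_length <- function(W) {
  check_weight_matrix(W)
  if (all(W == 0)) stop("path length undefined: network has no edges")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  off <- D[upper.tri(D)]
  list(path_length = mean(off[is.finite(off)]),
       distances = D,
       frac_infinite = mean(!is.finite(off)))
}

#' Global and nodal weighted network indices
#'
#' The three global indices of the analysis — strength, clustering
#' coefficient, characteristic path length — plus the two nodal vectors
#' (strength, clustering). Global strength and clustering aggregate the
#' nodal values by their mean (a sum aggregation is available via
#' `strength_agg` for strength).
#'
#' @param W nonnegative symmetric weight matrix with zero diagonal.
#' @param band optional band label carried through.
#' @param polarity optional polarity label (`"positive"`/`"negative"`).
#' @param strength_agg `"mean"` (default) or `"sum"`.
#' @return a `network_indices` list: `global_strength`,
#'   `global_clustering`, `char_path_length`, `frac_infinite`,
#'   `nodal_strength`, `nodal_clustering`, `band`, `polarity`.
#' @export
global_indices <- function(W, band = NA_character_,
                           polarity = NA_character_,
                           strength_agg = c("mean", "sum")) {
  strength_agg <- match.arg(strength_agg)
  ns <- nodal_strength(W)
  nc <- nodal_clustering(W)
  pl <- char_path_length(W)
  structure(list(
    global_strength = if (strength_agg == "mean") mean(ns) else sum(ns),
    global_clustering = mean(nc),
    char_path_length = pl$path_length,
    frac_infinite = pl$frac_infinite,
    nodal_strength = ns, nodal_clustering = nc,
    band = band, polarity = polarity), class = "network_indices")
}

#' @export
print.network_indices <- function(x, ...) {
  cat(sprintf(
    "<network_indices>%s%s strength %.3f, clustering %.3f, path length %.3f\n",
    if (is.na(x$band)) "" else paste0(" ", x$band),
    if (is.na(x$polarity)) "" else paste0("/", x$polarity),
    x$global_strength, x$global_clustering, x$char_path_length))
  invisible(x)
}

#' Tidy table of network indices for one subject's connectome
#'
#' @param tc a [task_normalize()] connectome.
#' @param subject subject identifier.
#' @param labels region labels (defaults to the matrix dimnames).
#' @return data.frame: subject, band, polarity, level, roi, metric, value.
#' @export
connectome_index_table <- function(tc, subject = NA_character_,
                                   labels = NULL) {
  stopifnot(inherits(tc, "task_connectome"))
  labels <- labels %||% rownames(tc$positive) %||%
    sprintf("roi%02d", seq_len(nrow(tc$positive)))
  rows <- lapply(c("positive", "negative"), function(pol) {
    gi <- global_indices(tc[[pol]], band = tc$band, polarity = pol)
    rbind(
      data.frame(subject = subject, band = tc$band, polarity = pol,
                 level = "global", roi = "global",
                 metric = c("strength", "clustering", "path_length"),
                 value = c(gi$global_strength, gi$global_clustering,
                           gi$char_path_length)),
      data.frame(subject = subject, band = tc$band, polarity = pol,
                 level = "nodal", roi = labels, metric = "strength",
                 value = gi$nodal_strength),
      data.frame(subject = subject, band = tc$band, polarity = pol,
                 level = "nodal", roi = labels, metric = "clustering",
                 value = gi$nodal_clustering))
  })
  do.call(rbind, rows)
}
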