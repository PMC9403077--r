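#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a master seed and a stage tag
#'
#' Stages of the pipeline draw their randomness from seeds derived
#' deterministically from one master seed, so a stage can be re-run in
#' isolation and still reproduce the full-run output.
#'
#' @param master integer master seed.
#' @param tag character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  # mix the tag characters and the master seed through two rounds of a
  # Lehmer step so that structured tags (S001, S002, ...) do not map to
  # structured seeds; everything stays in double precision below 2^31
  # (R integers are 32-bit)
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(master) * 48271 + h) %% 2147483647
  s <- (s * 48271 + 11) %% 2147483647
  as.integer((s * 48271) %% 2147483647)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
msg_log <- function(log, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE, sep = "")
  invisible(line)
}

#' Column means/variances split by a two-level grouping
#' @keywords internal
group_col_stats <- function(X, grp) {
  g <- unique(grp)
  stopifnot(length(g) == 2L)
  out <- lapply(g, function(gi) {
    Xi <- X[grp == gi, , drop = FALSE]
    n <- nrow(Xi)
    m <- colMeans(Xi)
    v <- (colSums(Xi^2) - n * m^2) / (n - 1)
    list(n = n, m = m, v = pmax(v, 0))
  })
  names(out) <- as.character(g)
  out
}
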