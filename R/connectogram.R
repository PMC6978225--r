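#' Connectogram objects
#'
#' A connectogram holds one subject's along-tract diffusion profile data: a
#' numeric array of dimension 76 (tracts) x 100 (steps) x 7 (indices), with
#' dimnames fixed to the canonical registries and the subject identifier kept
#' as an attribute.  Anisotropy and non-Gaussianity indices are unitless;
#' diffusivities are in um^2/ms.
#'
#' @param values Numeric array \code{76 x 100 x 7} (all values finite), in
#'   canonical tract/index order.
#' @param subject_id Single character subject identifier.
#' @return An object of class \code{"connectogram"}.
#' @examples
#' cg <- connectogram(array(0.4, c(76, 100, 7)), "sub-001")
#' dim(cg)
#' @export
connectogram <- function(values, subject_id) {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id))
    stop("'subject_id' must be a single character string")
  values <- unname(values)
  if (!is.numeric(values) || !identical(dim(values),
      c(.TA$n_tracts, .TA$n_steps, .TA$n_index)))
    stop(sprintf("connectogram values must be a numeric %d x %d x %d array",
                 .TA$n_tracts, .TA$n_steps, .TA$n_index))
  if (!all(is.finite(values)))
    stop("connectogram values must all be finite")
  dimnames(values) <- list(.TA$tracts, NULL, .TA$indices)
  structure(values, subject_id = subject_id, class = "connectogram")
}

#' @export
print.connectogram <- function(x, ...) {
  cat(sprintf("connectogram: subject '%s', %d tracts x %d steps x %d indices\n",
              attr(x, "subject_id"), dim(x)[1], dim(x)[2], dim(x)[3]))
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
as.data.frame.connectogram <- function(x, ...) {
  data.frame(
    subject = attr(x, "subject_id"),
    tract   = rep(.TA$tracts, times = .TA$n_steps * .TA$n_index),
    step    = rep(rep(0:(.TA$n_steps - 1L), each = .TA$n_tracts),
                  times = .TA$n_index),
    index   = rep(.TA$indices, each = .TA$n_tracts * .TA$n_steps),
    value   = as.vector(unclass(x)),
    stringsAsFactors = FALSE
  )
}

#' @export
subject_id <- function(x) UseMethod("subject_id")

#' @export
subject_id.connectogram <- function(x) attr(x, "subject_id")

# ---- internal flat-matrix conversions -------------------------------------
# flat layout: one row per subject, 53200 columns ordered cell-major
# (tract outer, index inner, then 100 steps per cell).

# connectogram array (76 x 100 x 7) -> flat row (length 53200)
.cg_to_row <- function(cg) {
  # want order: for t, for k, for s  => permute to (step, index, tract) then
  # read with step fastest: aperm to (100, 7, 76) gives s fastest, then k,
  # then t; as.vector of aperm(x, c(2, 3, 1)) yields s,k,t nesting
  as.vector(aperm(unclass(cg), c(2L, 3L, 1L)))
}

# flat row -> connectogram array
.row_to_cg <- function(row, subject_id) {
  a <- array(row, dim = c(.TA$n_steps, .TA$n_index, .TA$n_tracts))
  connectogram(aperm(a, c(3L, 1L, 2L)), subject_id)
}

# list of connectograms -> n x 53200 matrix (rownames = subject ids)
.cg_list_to_matrix <- function(conns) {
  stopifnot(length(conns) >= 1L)
  m <- vapply(conns, .cg_to_row, numeric(.TA$n_cells * .TA$n_steps))
  m <- t(m)
  rownames(m) <- vapply(conns, function(c) attr(c, "subject_id"), character(1))
  m
}

.matrix_to_cg_list <- function(m) {
  ids <- rownames(m)
  lapply(seq_len(nrow(m)), function(i) .row_to_cg(m[i, ], ids[i]))
}
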