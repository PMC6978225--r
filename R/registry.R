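#' Canonical tract and diffusion-index registries
#'
#' Along-tract profiling samples scalar diffusion indices at 100 normalized
#' steps along 76 predefined white matter tract bundles, yielding a per-subject
#' 76 x 100 x 7 "connectogram" array.  All objects in this package share one
#' canonical ordering of tracts (alphabetical) and indices, defined here.
#'
#' The 76-name registry is a synthetic reconstruction: it follows the standard
#' tract families (bilateral association and projection bundles plus callosal
#' segments) and the abbreviation style used in tract-based automatic analysis
#' atlases (e.g. \code{UF_R}, \code{FS_OFC_L}, \code{SLF_II_R},
#' \code{CF_genu}).  It is a naming scheme for simulated data, not a claim
#' about any particular atlas release.
#'
#' @return \code{tract_registry()} returns a character vector of 76 tract
#'   names in canonical (alphabetical) order.  \code{diffusion_indices()}
#'   returns the 7 index names in canonical order: GFA, AD, RD, MD, NG, NGO,
#'   NGP.
#' @examples
#' length(tract_registry())   # 76
#' diffusion_indices()
#' @export
tract_registry <- function() .TA$tracts

#' @rdname tract_registry
#' @export
diffusion_indices <- function() .TA$indices

# package-wide constants, built once at load time
.TA <- new.env(parent = emptyenv())

.ta_build_registry <- function() {
  bilateral <- c(
    "AF", "AR", "CG_C", "CG_H", "CPT_frontal", "CPT_parietal", "CST", "EMC",
    "FS_DLPFC", "FS_MPFC", "FS_motor_PCG", "FS_OFC", "FS_PPC", "FS_SMA",
    "FX", "IFOF", "ILF", "MdLF", "PF", "SFOF", "SLF_I", "SLF_II", "SLF_III",
    "ST", "TR_anterior", "TR_dorsal", "TR_optic", "TR_posterior",
    "TR_ventral", "UF"
  )
  callosal <- c(
    "CF_rostrum", "CF_genu", "CF_rostral_body", "CF_body_prefrontal",
    "CF_body_premotor", "CF_body_precentral", "CF_body_postcentral",
    "CF_body_SMA", "CF_body_parietal", "CF_body_temporal",
    "CF_splenium_parietal", "CF_splenium_temporal", "CF_splenium_occipital",
    "CF_splenium_limbic", "CF_tapetum", "CF_dorsal_hippocampal"
  )
  tracts <- c(paste0(rep(bilateral, each = 2L), c("_L", "_R")), callosal)
  # radix sort: locale-independent canonical order
  sort(tracts, method = "radix")
}

.ta_init_constants <- function() {
  .TA$tracts  <- .ta_build_registry()
  .TA$indices <- c("GFA", "AD", "RD", "MD", "NG", "NGO", "NGP")
  .TA$n_tracts <- length(.TA$tracts)   # 76
  .TA$n_steps  <- 100L
  .TA$n_index  <- length(.TA$indices)  # 7
  .TA$n_cells  <- .TA$n_tracts * .TA$n_index  # 532
  # feature names, tract-major (tract slowest? no: tract outer, index inner)
  .TA$cell_tract <- rep(.TA$tracts, each = .TA$n_index)
  .TA$cell_index <- rep(.TA$indices, times = .TA$n_tracts)
  .TA$features <- paste(.TA$cell_tract, .TA$cell_index, sep = ".")
}

.ta_init_constants()

#' Canonical feature names
#'
#' The 532 tract features are the (tract, index) pairs in tract-major order:
#' all 7 diffusion indices of the first tract, then the second tract, and so
#' on.  Names are \code{"<tract>.<index>"}.
#'
#' @return Character vector of length 532.
#' @export
feature_names <- function() .TA$features

# index of a flattened (cell, step) layout used by the matrix engine:
# columns ordered cell-major, i.e. for each (tract, index) cell the 100
# consecutive steps.  This is the single layout all internal matrix code uses.
.ta_flat_cols <- function() {
  list(
    cell = rep(seq_len(.TA$n_cells), each = .TA$n_steps),
    step = rep(seq_len(.TA$n_steps), times = .TA$n_cells)
  )
}
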