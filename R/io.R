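#' Read and write connectograms as long-format TSV
#'
#' The on-disk format is a plain tab-separated table with columns
#' \code{subject}, \code{tract}, \code{step} (0-99), \code{index},
#' \code{value}, one row per (tract, step, index) cell.  Values are written
#' at full double precision (\code{\%.17g}), so
#' \code{read_connectogram(write_connectogram(x))} reproduces \code{x}
#' bit-identically.  Row order on disk is irrelevant: reading always
#' reassembles the canonical tract/index ordering.
#'
#' @param cg A \code{\link{connectogram}}.
#' @param path File path.
#' @return \code{write_connectogram} returns \code{path} invisibly;
#'   \code{read_connectogram} returns a \code{\link{connectogram}}.
#' @export
write_connectogram <- function(cg, path) {
  stopifnot(inherits(cg, "connectogram"))
  df <- as.data.frame(cg)
  df$value <- sprintf("%.17g", df$value)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_connectogram
#' @export
read_connectogram <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("subject", "tract",
                                                          "index"),
                                            integer = "step",
                                            numeric = "value"),
                          showProgress = FALSE)
  need <- c("subject", "tract", "step", "index", "value")
  if (!all(need %in% names(dt)))
    stop("parse error: missing column(s): ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  subj <- unique(dt$subject)
  if (length(subj) != 1L)
    stop("parse error: file must contain exactly one subject")
  bad_idx <- which(!(dt$index %in% .TA$indices))
  if (length(bad_idx))
    stop(sprintf("parse error: unknown index name '%s' at row %d",
                 dt$index[bad_idx[1]], bad_idx[1]))
  bad_tr <- which(!(dt$tract %in% .TA$tracts))
  if (length(bad_tr))
    stop(sprintf("parse error: unknown tract name '%s' at row %d",
                 dt$tract[bad_tr[1]], bad_tr[1]))
  if (any(dt$step < 0L | dt$step > 99L))
    stop("parse error: step out of range 0-99")

  ti <- match(dt$tract, .TA$tracts)
  ki <- match(dt$index, .TA$indices)
  pos <- ti + .TA$n_tracts * (dt$step + 100L * (ki - 1L))  # 1-based array pos
  dup <- which(duplicated(pos))
  if (length(dup))
    stop(sprintf("parse error: duplicate (tract, step, index) key at row %d (%s, %d, %s)",
                 dup[1], dt$tract[dup[1]], dt$step[dup[1]], dt$index[dup[1]]))
  n_expect <- .TA$n_tracts * .TA$n_steps * .TA$n_index
  if (nrow(dt) != n_expect) {
    miss_tracts <- setdiff(.TA$tracts, unique(dt$tract))
    if (length(miss_tracts))
      stop("parse error: incomplete tract set (missing ",
           paste(miss_tracts, collapse = ", "), ")")
    stop(sprintf("parse error: expected %d cells, found %d", n_expect,
                 nrow(dt)))
  }
  vals <- array(NA_real_, dim = c(.TA$n_tracts, .TA$n_steps, .TA$n_index))
  vals[pos] <- dt$value
  connectogram(vals, subj)
}

#' Read and write cohort metadata tables
#'
#' Cohort tables are CSV files with one row per subject and columns
#' \code{subject_id}, \code{age}, \code{sex} (M/F), \code{handedness}
#' (percent, -100..100), \code{group} (train, test, normative, control/
#' controls, lmtle, rmtle), and the clinical fields \code{age_of_onset},
#' \code{duration_of_illness}, \code{seizure_frequency},
#' \code{n_aed_classes}.  Clinical fields must be present (non-missing) for
#' patient groups (\code{lmtle}, \code{rmtle}) and may be missing otherwise.
#'
#' @param path CSV path.
#' @return \code{read_cohort} returns a validated data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @param df A data frame to validate.
#' @export
validate_cohort <- function(df) {
  need <- c("subject_id", "age", "sex", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("validation error: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("validation error: duplicate subject_id: ",
         df$subject_id[duplicated(df$subject_id)][1])
  if (!all(df$sex %in% c("M", "F")))
    stop("validation error: sex must be 'M' or 'F'")
  clin <- c("age_of_onset", "duration_of_illness", "seizure_frequency",
            "n_aed_classes")
  for (col in clin) if (is.null(df[[col]])) df[[col]] <- NA_real_
  patient <- df$group %in% c("lmtle", "rmtle")
  if (any(patient)) {
    bad <- patient & !stats::complete.cases(df[, clin])
    if (any(bad))
      stop("validation error: patient row(s) missing clinical fields: ",
           paste(df$subject_id[bad], collapse = ", "))
  }
  df
}
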