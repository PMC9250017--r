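#' Write binned curves and an optional genotype comparison to file
#'
#' Results are serialized as JSON: one record per bin per curve under
#' `curves` (with each curve's genotype, bin count and volume-correction
#' flag), plus a `comparison` block when a comparison is given. The file is
#' re-parseable with [read_results()].
#'
#' @param curves a `binned_curve` or list of them.
#' @param comparison an `auc_comparison`, or `NULL` for none.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(curves, comparison = NULL, path) {
  if (inherits(curves, "binned_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "binned_curve")))
  payload <- list(
    curves = lapply(curves, function(cv) {
      list(genotype = attr(cv, "genotype"),
           n_bins = attr(cv, "n_bins"),
           volume_corrected = isTRUE(attr(cv, "volume_corrected")),
           bins = as.data.frame(cv))
    }))
  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "auc_comparison"))
    payload$comparison <- unclass(comparison)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a [write_results()] file
#'
#' @param path path written by [write_results()].
#' @return list with `curves` (list of `binned_curve`) and `comparison`
#'   (an `auc_comparison` or `NULL`).
#' @export
read_results <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  curves <- lapply(seq_len(length(raw$curves$genotype)), function(i) {
    structure(raw$curves$bins[[i]],
              class = c("binned_curve", "data.frame"),
              n_bins = raw$curves$n_bins[i],
              genotype = raw$curves$genotype[i],
              volume_corrected = raw$curves$volume_corrected[i])
  })
  comparison <- NULL
  if (!is.null(raw$comparison)) {
    comparison <- structure(raw$comparison, class = "auc_comparison")
  }
  list(curves = curves, comparison = comparison)
}
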