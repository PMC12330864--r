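#' Write a multichannel series as plain matrix + JSON sidecar
#'
#' Tab-separated samples x channels matrix with a header row of channel
#' names, plus `<path>.meta.json` holding the sampling rate and any meta
#' entries (generator parameters, filters applied, seed).
#'
#' @param series an [mc_series()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(series, path) {
  stopifnot_series(series)
  utils::write.table(t(series$values), path, sep = "\t",
                     row.names = FALSE, col.names = series$channel_names,
                     quote = FALSE)
  jsonlite::write_json(list(rate = series$rate,
                            channel_names = series$channel_names,
                            meta = series$meta),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a multichannel series written by [write_series_matrix()]
#'
#' @param path TSV path (sidecar `<path>.meta.json` must exist unless
#'   `rate` is given).
#' @param rate optional sampling rate overriding the sidecar.
#' @return an [mc_series()].
#' @export
read_series_matrix <- function(path, rate = NULL) {
  dat <- utils::read.delim(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- list()
  if (file.exists(meta_path)) {
    side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(rate)) rate <- side$rate
    if (!is.null(side$meta) && length(side$meta)) meta <- as.list(side$meta)
  }
  if (is.null(rate)) stop("`rate` must come from the sidecar or be supplied")
  mc_series(t(as.matrix(dat)), rate, colnames(dat), meta)
}
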