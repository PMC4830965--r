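#' @include AllClasses.R
NULL

#' Write a per-frame series table as TSV
#'
#' Plain tab-separated output with a header line; the common interchange
#' format for all per-frame series in this package (RMSD, chi1, distances,
#' pocket volume, hydration).
#'
#' @param df a `data.frame`
#' @param path output path
#' @return invisibly, the path
#' @export
writeSeriesTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV series table
#' @param path TSV path
#' @return a `data.frame`
#' @export
readSeriesTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Serialize a DihedralSeries as TSV tables
#'
#' Writes the per-frame table (`time`, `chi1_deg`, `state`) to `path` and
#' the flip-event table (`start`, `end`, `from`, `to`) to `<path>.events`.
#'
#' @param series a [DihedralSeries-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeDihedralTSV <- function(series, path) {
  writeSeriesTSV(data.frame(time = series@times, chi1_deg = series@chi1,
                            state = series@states), path)
  writeSeriesTSV(series@events, paste0(path, ".events"))
  invisible(path)
}

#' Write a ThicknessMap as a TSV matrix with a sidecar header
#'
#' The thickness matrix goes to `path` (rows = x cells, columns = y cells,
#' `NA` for undefined cells), the sample-count matrix to `<path>.counts`,
#' and the grid geometry (origin, spacing, units) to the YAML sidecar
#' `<path>.meta`.
#'
#' @param map a [ThicknessMap-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeThicknessMapTSV <- function(map, path) {
  utils::write.table(map@thickness, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(map@counts, paste0(path, ".counts"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(origin = as.numeric(map@origin),
                        spacing = map@spacing, units = "nm"),
                   paste0(path, ".meta"))
  invisible(path)
}

#' Read a ThicknessMap written by [writeThicknessMapTSV()]
#' @param path TSV path (sidecars `<path>.counts`, `<path>.meta` expected)
#' @return a [ThicknessMap-class]
#' @export
readThicknessMapTSV <- function(path) {
  thick <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  cnt <- as.matrix(utils::read.table(paste0(path, ".counts"), sep = "\t",
                                     header = FALSE))
  meta <- yaml::read_yaml(paste0(path, ".meta"))
  dimnames(thick) <- NULL
  dimnames(cnt) <- NULL
  storage.mode(cnt) <- "integer"
  out <- new("ThicknessMap", origin = as.numeric(meta$origin),
             spacing = meta$spacing,
             thickness = ifelse(cnt > 0, 0, NA_real_), counts = cnt)
  ## direct slot fill: difference maps are legitimately signed
  out@thickness <- thick
  out
}
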