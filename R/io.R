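#' Write a trace dataset as TSV files plus a JSON manifest
#'
#' Each trace becomes `trace_<id>.tsv` with columns `frame_index`, `time_s`,
#' `donor`, `acceptor`; dataset-level metadata (site pair, voltage, pHs,
#' construct, seed, generator parameters) goes into `manifest.json`.
#'
#' @param traces list of `intensity_trace` objects.
#' @param dir output directory (created if missing).
#' @param manifest named list of dataset metadata stored alongside the files.
#' @return invisibly, the manifest path.
#' @export
write_traces <- function(traces, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    n <- length(tr$donor)
    df <- data.frame(frame_index = seq_len(n) - 1L,
                     time_s = (seq_len(n) - 1L) * tr$dt,
                     donor = tr$donor, acceptor = tr$acceptor)
    files[i] <- sprintf("trace_%04d.tsv", i)
    utils::write.table(df, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest$n_traces <- length(traces)
  manifest$frame_interval_s <- traces[[1]]$dt
  manifest$files <- files
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a trace dataset written by [write_traces()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list of `intensity_trace` objects with manifest metadata attached.
#' @export
read_traces <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  meta <- manifest[setdiff(names(manifest), c("files", "n_traces",
                                              "frame_interval_s"))]
  lapply(seq_along(manifest$files), function(i) {
    df <- utils::read.table(file.path(dir, manifest$files[i]), header = TRUE,
                            sep = "\t")
    m <- meta
    m$trace_id <- i
    structure(list(donor = df$donor, acceptor = df$acceptor,
                   dt = manifest$frame_interval_s, meta = m,
                   truth = NULL),
              class = "intensity_trace")
  })
}
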