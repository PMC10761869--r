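#' Read a photon stream from a columnar text file
#'
#' The columnar dialect is a plain-text table with three columns
#' `tick, detector, excitation` (header row required) preceded by `#`-prefixed
#' metadata lines carrying at least `clock_period` and `duration`:
#'
#' ```
#' # clock_period 1e-07
#' # duration 10
#' tick detector excitation
#' 120 donor donor
#' ...
#' ```
#'
#' @param path file to read.
#' @param format `"auto"` or `"columnar-text"`.
#' @return A [photon_stream()].
#' @export
read_photons <- function(path, format = c("auto", "columnar-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "\\s+")[[1L]]
    if (length(kv) >= 2) meta[[kv[1L]]] <- suppressWarnings(as.numeric(kv[2L]))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) <= 1L) {
    # header only (or nothing): empty stream
    return(photon_stream(numeric(0), integer(0), integer(0),
                         clock_period = meta$clock_period %||% 1e-7,
                         duration = meta$duration %||% 0,
                         metadata = meta))
  }
  tab <- read.table(text = body, header = TRUE, stringsAsFactors = FALSE)
  need <- c("tick", "detector", "excitation")
  if (!all(need %in% names(tab))) {
    stop("columnar photon file must have columns: ", paste(need, collapse = ", "))
  }
  ts <- as.numeric(tab$tick)
  if (length(ts) > 1L) {
    bad <- which(diff(ts) < 0)
    if (length(bad)) stop("unsorted timestamps: first offending row ", bad[1L] + 1L)
  }
  photon_stream(ts, tab$detector, tab$excitation,
                clock_period = meta$clock_period %||% 1e-7,
                duration = meta$duration %||%
                  (if (length(ts)) max(ts) * (meta$clock_period %||% 1e-7) else 0),
                metadata = meta)
}

#' Write a photon stream to a columnar text file
#'
#' @param stream a [photon_stream()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_photons <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# clock_period %.17g", stream$clock_period),
    sprintf("# duration %.17g", stream$duration)
  ), con)
  lab <- c("donor", "acceptor")
  df <- data.frame(tick = format(stream$timestamps, scientific = FALSE, trim = TRUE),
                   detector = lab[stream$detector + 1L],
                   excitation = lab[stream$excitation + 1L])
  writeLines("tick detector excitation", con)
  if (nrow(df)) {
    writeLines(paste(df$tick, df$detector, df$excitation), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
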