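## Plain-text raster I/O. Scans are stored as ASCII PGM (P2, maxval 65535,
## intensity = round(x * 65535)); masks use maxval 1. PGM keeps the whole
## deliverable text-only while remaining a standard grayscale format.

#' Write an intensity image as ASCII PGM (P2)
#' @param image Numeric matrix in \[0, 1\] (or logical for masks).
#' @param path Output path.
#' @param maxval Maximum gray value (65535 for scans, 1 for masks).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = if (is.logical(image)) 1L else 65535L) {
  stopifnot(is.matrix(image))
  vals <- if (is.logical(image)) image * 1L else {
    as.integer(round(pmin(pmax(image, 0), 1) * maxval))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)), con)
  ## one raster row per line
  m <- matrix(vals, nrow(image), ncol(image))
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) raster
#' @param path PGM path.
#' @param as_mask Return a logical matrix (nonzero = TRUE)?
#' @return Numeric matrix scaled back to \[0, 1\] (or logical if `as_mask`).
#' @export
read_pgm <- function(path, as_mask = FALSE) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file: ", path, call. = FALSE)
  dims <- as.integer(tok[2:3])          # width height
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != prod(dims)) {
    stop("corrupt PGM: expected ", prod(dims), " pixels, found ", length(vals),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  if (as_mask) m > 0 else m / maxval
}

## md5-digest manifest written next to every artifact-producing command
write_manifest <- function(dir, stage, config, seeds, files) {
  manifest <- list(
    package = "petresponse",
    version = as.character(utils::packageVersion("petresponse")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  path <- file.path(dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
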