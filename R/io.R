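#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities are rounded to integers and clamped to `[0, 65535]`;
#' within that range the round trip through [read_stack()] is exact.
#'
#' @param stack numeric array, rows x cols x frames (or a matrix for a
#'   single frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(i)
    pmin(pmax(round(stack[, , i]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file written by [write_stack()] (or any grayscale
#'   multi-page TIFF).
#' @return numeric array rows x cols x frames, in integer intensity units.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such TIFF file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("malformed TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse any extra channel
    round(p * 65535)
  })
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write a simulation's burst stacks following the filename convention
#'
#' One file per burst, named `burst000.tif`, `burst001.tif`, ... so that
#' lexical order equals burst order.
#'
#' @param sim a `gc_simulation`.
#' @param dir output directory (created if missing).
#' @return character vector of file paths.
#' @export
write_sequence <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("burst%03d.tif",
                                  seq_along(sim$stacks) - 1L))
  for (i in seq_along(sim$stacks)) write_stack(sim$stacks[[i]], paths[i])
  paths
}

#' Discover burst stack files in a directory
#'
#' @param dir directory containing `burst*.tif` files.
#' @return character vector of paths ordered by burst index.
#' @export
discover_sequence <- function(dir) {
  f <- list.files(dir, pattern = "^burst[0-9]+\\.tif$", full.names = TRUE)
  if (!length(f)) stop("no burst TIFFs found in ", dir)
  f[order(as.integer(sub("^burst([0-9]+)\\.tif$", "\\1", basename(f))))]
}

#' Run-length encode a binary mask as a plain-text string
#'
#' Column-major run lengths, starting with the count of leading `FALSE`
#' pixels: `"<nrow> <ncol>;l1 l2 l3 ..."`.
#'
#' @param mask logical matrix.
#' @return single character string.
#' @export
encode_mask_rle <- function(mask) {
  r <- rle(as.vector(mask))
  runs <- r$lengths
  if (r$values[1]) runs <- c(0L, runs)
  paste0(nrow(mask), " ", ncol(mask), ";", paste(runs, collapse = " "))
}

#' Decode a run-length-encoded mask string
#'
#' @param s string from [encode_mask_rle()].
#' @return logical matrix.
#' @export
decode_mask_rle <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  dims <- as.integer(strsplit(parts[1], " ")[[1]])
  runs <- as.integer(strsplit(parts[2], " ")[[1]])
  vals <- rep(c(FALSE, TRUE), length.out = length(runs))
  matrix(rep(vals, runs), nrow = dims[1], ncol = dims[2])
}

#' Write observation tables as CSV files
#'
#' @param tables named list of data.frames (e.g. from
#'   [assemble_observations()]).
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read/write a run configuration as YAML
#'
#' @param config nested list of run parameters.
#' @param path YAML file path.
#' @return `read_run_config` returns the list; `write_run_config` the
#'   path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}
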