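# tabular writers share one audit header: package version, seed, checksums.
# no timestamps — identical inputs must give byte-identical files.
write_tsv_with_header <- function(df, path, meta = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(sprintf("# asthmod %s", as.character(packageVersion("asthmod"))),
             "# currency: GBP 2022")
  for (nm in names(meta))
    lines <- c(lines, sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  cols <- lapply(df, function(col) {
    if (is.numeric(col))
      vapply(col, function(x) {
        if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1))
    else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

input_checksums <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return("none")
  sums <- tools::md5sum(paths)
  paste(sprintf("%s=%s", basename(names(sums)), unname(sums)), collapse = " ")
}

#' Export a PSA summary table
#'
#' @param r A `psa_result`.
#' @param path Output path (tab-separated).
#' @param meta Extra header fields (named list).
#' @return `path`, invisibly.
#' @export
write_psa_summary <- function(r, path, meta = list()) {
  meta <- c(list(type = "psa_summary", seed = r$seed, iterations = r$n_iterations), meta)
  write_tsv_with_header(r$summary, path, meta)
}

#' Export all PSA draws in long format
#'
#' @param r A `psa_result`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_psa_draws <- function(r, path) {
  write_tsv_with_header(r$draws, path,
                        list(type = "psa_draws", seed = r$seed,
                             iterations = r$n_iterations))
}
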