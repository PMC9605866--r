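## Grid result files: TSV matrices with "# key=value" header lines carrying
## bin size, origin, leaflet/species and frame window. Missing bins
## (count 0) are written as NA, never 0.

#' Write a thickness or density map as annotated TSV
#'
#' @param map a `thickness_map` or `density_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("# type=%s", class(map)[1]),
    sprintf("# bin=%.10g", map$bin),
    sprintf("# origin=%.10g,%.10g", map$origin[1], map$origin[2]),
    if (!is.null(map$leaflet)) sprintf("# leaflet=%s", map$leaflet),
    if (!is.null(map$species)) sprintf("# species=%s", map$species),
    sprintf("# window=%d,%d", map$window[1], map$window[2])
  )
  writeLines(hdr, con)
  if (!is.null(map$mean)) {
    utils::write.table(map$mean, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, na = "NA")
    writeLines("# counts", con)
  }
  utils::write.table(map$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a grid TSV written by [write_grid_tsv()]
#'
#' @param path input path.
#' @return the reconstructed `thickness_map` or `density_map`.
#' @export
read_grid_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (h in grep("^# [a-z]+=", lines, value = TRUE)) {
    m <- regmatches(h, regexec("^# ([a-z]+)=(.*)$", h))[[1]]
    kv[[m[2]]] <- m[3]
  }
  body <- which(!grepl("^#", lines))
  counts_mark <- which(lines == "# counts")
  parse_mat <- function(ls)
    do.call(rbind, lapply(strsplit(ls, "\t"), function(s) {
      s[s == "NA"] <- NA_character_
      as.numeric(s)
    }))
  origin <- as.numeric(strsplit(kv$origin, ",")[[1]])
  window <- as.integer(strsplit(kv$window, ",")[[1]])
  bin <- as.numeric(kv$bin)
  if (identical(kv$type, "density_map")) {
    counts <- parse_mat(lines[body])
    structure(list(species = kv$species, counts = counts, bin = bin,
                   origin = origin, window = window),
              class = "density_map")
  } else {
    main <- parse_mat(lines[body[body < counts_mark]])
    counts <- parse_mat(lines[body[body > counts_mark]])
    structure(list(leaflet = kv$leaflet, mean = main, counts = counts,
                   bin = bin, origin = origin, window = window),
              class = "thickness_map")
  }
}
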