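#' Write / read annotation files
#'
#' Serialises an annotation set to plain-text files in `dir`: three BED-like
#' tables with 0-based half-open intervals (`regions.bed` with name column
#' `gene|type`, `islands.bed` with the context as name, `transposons.bed`
#' with the class as name) and `pathways.tsv` with one gene set per line
#' (`name TAB gene,gene,...`). `read_annotations()` restores the same
#' structure and validates intervals (end must exceed start).
#'
#' @param annotations A `methpair_annotations` object.
#' @param dir Directory (created if needed).
#' @return `dir` invisibly (write); a `methpair_annotations` list (read).
#' @export
write_annotations <- function(annotations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed <- function(df, name_col, path) {
    readr::write_tsv(
      tibble(chrom = df$chrom, start = df$start, end = df$end,
             name = name_col),
      path, col_names = FALSE)
  }
  r <- annotations$regions
  bed(r, paste(r$gene, r$type, sep = "|"), file.path(dir, "regions.bed"))
  bed(annotations$islands, annotations$islands$context,
      file.path(dir, "islands.bed"))
  bed(annotations$transposons, annotations$transposons$class,
      file.path(dir, "transposons.bed"))
  pw <- split(annotations$pathways$gene, annotations$pathways$pathway)
  writeLines(vapply(names(pw), function(nm)
    paste0(nm, "\t", paste(pw[[nm]], collapse = ",")), character(1)),
    file.path(dir, "pathways.tsv"))
  invisible(dir)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(dir) {
  read_bed <- function(path) {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                          show_col_types = FALSE,
                          col_types = "ciic")
    bad <- which(df$end <= df$start)
    if (length(bad) > 0)
      abort(sprintf("Malformed interval (end <= start) in '%s' at line %d.",
                    path, bad[1]))
    df
  }
  r <- read_bed(file.path(dir, "regions.bed"))
  parts <- strsplit(r$name, "|", fixed = TRUE)
  regions <- tibble(chrom = r$chrom, start = r$start, end = r$end,
                    gene = vapply(parts, `[`, character(1), 1),
                    type = vapply(parts, `[`, character(1), 2))
  isl <- read_bed(file.path(dir, "islands.bed"))
  tx <- read_bed(file.path(dir, "transposons.bed"))
  lines <- readLines(file.path(dir, "pathways.tsv"))
  pieces <- strsplit(lines, "\t", fixed = TRUE)
  pathways <- purrr::map_dfr(pieces, function(p)
    tibble(pathway = p[1], gene = strsplit(p[2], ",", fixed = TRUE)[[1]]))
  structure(
    list(regions = regions,
         islands = tibble(chrom = isl$chrom, start = isl$start,
                          end = isl$end, context = isl$name),
         transposons = tibble(chrom = tx$chrom, start = tx$start,
                              end = tx$end, class = tx$name),
         pathways = pathways),
    class = "methpair_annotations")
}
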