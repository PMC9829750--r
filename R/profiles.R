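#' Read a per-sample methylome table
#'
#' Reads a TSV of CpG log2-ratios (columns `cpg_id`, `chrom`, `pos`,
#' `log2ratio`; positions are 1-based array-manifest coordinates), validates
#' it and returns it sorted genome-wide by chromosome (natural order
#' chr1..chr22, chrX, chrY) then position, with position ties broken by
#' `cpg_id`. Input row order is irrelevant.
#'
#' @param path Path to the TSV file.
#' @param sample_id,patient_id Sample descriptors attached as columns.
#' @param tissue Tissue of the metastasis, one of `"brain"`, `"lung"`,
#'   `"lymph_node"`, `"liver"`, `"skin"`, `"soft_tissue"`.
#' @return A tibble with columns `sample_id`, `patient_id`, `tissue`,
#'   `cpg_id`, `chrom`, `pos`, `log2ratio`.
#' @export
read_methylome <- function(path, sample_id, patient_id,
                           tissue = c("brain", "lung", "lymph_node", "liver",
                                      "skin", "soft_tissue")) {
  tissue <- match.arg(tissue)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("cpg_id", "chrom", "pos", "log2ratio")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    abort(sprintf("Methylome file '%s' lacks required column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  as_methylome(
    tibble(cpg_id = raw$cpg_id, chrom = raw$chrom,
           pos = parse_numeric_col(raw$pos, "pos", path),
           log2ratio = parse_numeric_col(raw$log2ratio, "log2ratio", path)),
    sample_id = sample_id, patient_id = patient_id, tissue = tissue)
}

parse_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad) > 0)
    abort(sprintf("Non-numeric value '%s' in column '%s' of '%s' (data row %d).",
                  x[bad[1]], col, path, bad[1]))
  out
}

# Validate and sort an in-memory methylome table.
as_methylome <- function(records, sample_id, patient_id, tissue) {
  dup <- records$cpg_id[duplicated(records$cpg_id)]
  if (length(dup) > 0)
    abort(sprintf("Duplicated cpg_id '%s' in sample '%s'.", dup[1], sample_id))
  records <- dplyr::arrange(records, chrom_order(.data$chrom), .data$pos,
                            .data$cpg_id)
  dplyr::bind_cols(
    tibble(sample_id = sample_id, patient_id = patient_id, tissue = tissue,
           .rows = nrow(records)),
    records)
}

#' Write a methylome table to TSV
#'
#' Writes the four record columns (`cpg_id`, `chrom`, `pos`, `log2ratio`);
#' sample descriptors travel separately. Round-trips through
#' [read_methylome()].
#'
#' @param methylome A methylome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(methylome, path) {
  readr::write_tsv(methylome[, c("cpg_id", "chrom", "pos", "log2ratio")], path)
  invisible(path)
}

#' Build a patient-matched pair difference profile
#'
#' Subtracts the extracranial sample's log2-ratio from the intracranial
#' sample's at every shared CpG (`delta = intra - extra`), the core
#' per-pair quantity the HMM segments. CpGs missing (non-finite) in either
#' sample are dropped, so the profile's CpG set is the intersection of the
#' two samples' non-missing CpGs, ordered genome-wide by chromosome then
#' position.
#'
#' @param intra,extra Methylome tibbles of the intracranial and extracranial
#'   sample of one patient (see [read_methylome()]).
#' @param pair_id Identifier for the pair; default
#'   `"<patient>_<intra sample>_<extra sample>"`.
#' @param allow_patient_mismatch Set `TRUE` to permit samples from different
#'   patients (otherwise an error).
#' @return A tibble with columns `pair_id`, `patient_id`,
#'   `extracranial_tissue`, `cpg_id`, `chrom`, `pos`, `delta`.
#' @export
build_pair_profile <- function(intra, extra, pair_id = NULL,
                               allow_patient_mismatch = FALSE) {
  pid_i <- unique(intra$patient_id); pid_e <- unique(extra$patient_id)
  if (!identical(pid_i, pid_e) && !allow_patient_mismatch)
    abort(sprintf(
      "Samples come from different patients ('%s' vs '%s'); set `allow_patient_mismatch = TRUE` to override.",
      pid_i[1], pid_e[1]))
  pair_id <- pair_id %||%
    paste(pid_i[1], unique(intra$sample_id)[1], unique(extra$sample_id)[1],
          sep = "_")
  j <- dplyr::inner_join(
    dplyr::select(dplyr::filter(intra, is.finite(.data$log2ratio)),
                  "cpg_id", "chrom", "pos", intra = "log2ratio"),
    dplyr::select(dplyr::filter(extra, is.finite(.data$log2ratio)),
                  "cpg_id", extra = "log2ratio"),
    by = "cpg_id")
  if (nrow(j) == 0) abort("The two samples share no non-missing CpGs.")
  tibble(pair_id = pair_id, patient_id = pid_i[1],
         extracranial_tissue = unique(extra$tissue)[1],
         cpg_id = j$cpg_id, chrom = j$chrom, pos = j$pos,
         delta = j$intra - j$extra) |>
    dplyr::arrange(chrom_order(.data$chrom), .data$pos, .data$cpg_id)
}

#' Write / read a pair profile TSV
#'
#' @param profile A pair-profile tibble.
#' @param path File path.
#' @return The profile (read) or `path` invisibly (write).
#' @export
write_pair_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_pair_profile
#' @export
read_pair_profile <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pair_id = readr::col_character(),
                    patient_id = readr::col_character(),
                    extracranial_tissue = readr::col_character(),
                    cpg_id = readr::col_character(),
                    chrom = readr::col_character(),
                    pos = readr::col_double(),
                    delta = readr::col_double()))
}
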