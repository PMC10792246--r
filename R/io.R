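# Plain-text I/O: all tables are TSV with a header row; alignments are
# aligned FASTA; configuration/provenance is JSON.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read / write a well table
#'
#' TSV with columns `construct`, `condition`, `medium`, `lysate`, `renilla`,
#' `experiment`, `replicate` (and optionally `treatment`).
#'
#' @param path file path.
#' @return a `well_table` data.frame.
#' @export
read_well_table <- function(path) {
  x <- read_tsv(path)
  need <- c("construct", "condition", "medium", "lysate", "experiment")
  if (!all(need %in% names(x))) {
    stop("well table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("well_table", "data.frame")
  x
}

#' @rdname read_well_table
#' @param wells a `well_table`.
#' @export
write_well_table <- function(wells, path) write_tsv(wells, path)

#' Read / write a blot table
#'
#' TSV with columns `construct`, `band1`, `band2`, `actin`, `experiment`
#' (and optionally `condition`).
#'
#' @param path file path.
#' @return a `blot_table` data.frame.
#' @export
read_blot_table <- function(path) {
  x <- read_tsv(path)
  need <- c("construct", "band1", "band2", "actin", "experiment")
  if (!all(need %in% names(x))) {
    stop("blot table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("blot_table", "data.frame")
  x
}

#' @rdname read_blot_table
#' @param blots a `blot_table`.
#' @export
write_blot_table <- function(blots, path) write_tsv(blots, path)

#' Read / write a surface-assay table
#'
#' TSV with columns `construct`, `surface_signal`, `total_level`,
#' `experiment`, `condition`.
#'
#' @param path file path.
#' @return a `surface_table` data.frame.
#' @export
read_surface_table <- function(path) {
  x <- read_tsv(path)
  need <- c("construct", "surface_signal", "total_level", "experiment")
  if (!all(need %in% names(x))) {
    stop("surface table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("surface_table", "data.frame")
  x
}

#' @rdname read_surface_table
#' @param surface a `surface_table`.
#' @export
write_surface_table <- function(surface, path) write_tsv(surface, path)

#' Read / write a variant list
#'
#' TSV with columns `hgvs_p`, `role` (one of `query`, `pathogenic_control`,
#' `negative_control`) and optionally `source` and `true_activity`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  x <- read_tsv(path)
  if (!all(c("hgvs_p", "role") %in% names(x))) {
    stop("variant table must have columns hgvs_p, role", call. = FALSE)
  }
  parse_hgvs_p(x$hgvs_p)   # validates the notation
  x
}

#' @rdname read_variant_table
#' @param variants variant data.frame.
#' @export
write_variant_table <- function(variants, path) write_tsv(variants, path)

#' Read / write an aligned FASTA protein alignment
#'
#' @param path FASTA path.
#' @param human_id identifier of the human reference row.
#' @return an `msa` object (named character vector, attribute `human_id`).
#' @export
read_msa <- function(path, human_id = "Homo_sapiens") {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- names(set)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  if (!human_id %in% names(seqs)) {
    stop("mapping error: human row '", human_id, "' absent from alignment",
         call. = FALSE)
  }
  structure(seqs, class = "msa", human_id = human_id)
}

#' @rdname read_msa
#' @param msa an `msa` object.
#' @export
write_msa <- function(msa, path) {
  set <- Biostrings::AAStringSet(unclass(msa))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
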