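# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a locus metadata table
#'
#' A loci table declares the genotyped panel: one row per locus with its
#' type (`"microsat"` or `"mhc"`) and, for microsatellites, the repeat-motif
#' length in base pairs (needed to express allele differences in repeat
#' units).
#'
#' @param loci A data frame with columns `locus`, `type` and `motif_length`.
#' @return The validated loci tibble (invisibly usable in pipes).
#' @export
validate_loci <- function(loci) {
  loci <- tibble::as_tibble(loci)
  req <- c("locus", "type")
  missing_cols <- setdiff(req, names(loci))
  if (length(missing_cols) > 0) {
    stop("loci table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"motif_length" %in% names(loci)) loci$motif_length <- NA_integer_
  bad <- setdiff(unique(loci$type), c("microsat", "mhc"))
  if (length(bad) > 0) {
    stop("unknown locus type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(loci$locus)) {
    stop("duplicated locus id(s): ",
         paste(unique(loci$locus[duplicated(loci$locus)]), collapse = ", "),
         call. = FALSE)
  }
  ms <- loci$type == "microsat"
  if (any(ms & (is.na(loci$motif_length) | loci$motif_length <= 0))) {
    stop("every microsatellite locus needs a positive motif_length",
         call. = FALSE)
  }
  loci
}

# Column names holding the two allele calls of a locus.
locus_cols <- function(locus) paste0(locus, c("_a", "_b"))

# Two-column matrix of allele calls (character) for one locus.
geno_matrix <- function(individuals, locus) {
  cols <- locus_cols(locus)
  missing_cols <- setdiff(cols, names(individuals))
  if (length(missing_cols) > 0) {
    stop("individuals table lacks genotype column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- cbind(as.character(individuals[[cols[1]]]),
             as.character(individuals[[cols[2]]]))
  rownames(m) <- individuals$id
  m
}

# TRUE where both allele calls of the locus are present.
typed_at <- function(individuals, locus) {
  g <- geno_matrix(individuals, locus)
  !is.na(g[, 1]) & !is.na(g[, 2])
}

assert_ids_exist <- function(ids, individuals, what) {
  unknown <- setdiff(ids, individuals$id)
  if (length(unknown) > 0) {
    stop("unknown ", what, " id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) ", ..." else "", call. = FALSE)
  }
  invisible(TRUE)
}

# Named list (by locus) of named frequency vectors, from a tidy freqs table.
freq_list <- function(freqs) {
  split(freqs, freqs$locus) |>
    lapply(function(d) stats::setNames(d$freq, d$allele))
}
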