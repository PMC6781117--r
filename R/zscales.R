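#' Amino-acid z-descriptor table
#'
#' The five z-descriptors (z1..z5) are principal-component scores that
#' summarise physiochemical properties of the 20 proteinogenic amino acids
#' (z1 tracks hydrophobicity, z2 steric bulk, z3 polarity/charge, z4 and z5
#' electronic properties). The values shipped here are the extended z-scale
#' set of Sandberg and colleagues (1998), as reproduced across the QSAR and
#' MHC-compatibility literature; see `inst/extdata/zscales.tsv` for the
#' versioned copy.
#'
#' @return A tibble with columns `residue` (one-letter code) and `z1`..`z5`.
#' @examples
#' zscale_table()
#' @export
zscale_table <- function() {
  path <- system.file("extdata", "zscales.tsv", package = "mhcmate",
                      mustWork = TRUE)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  tbl <- tibble::as_tibble(tbl)
  stopifnot(nrow(tbl) == 20L, all(c("residue", paste0("z", 1:5)) %in% names(tbl)))
  tbl
}

# 20 x 5 numeric matrix keyed by residue, for fast lookups.
zscale_matrix <- function(ztable = zscale_table()) {
  ztable <- tibble::as_tibble(ztable)
  m <- as.matrix(ztable[, paste0("z", 1:5)])
  rownames(m) <- ztable$residue
  m
}
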