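#' Read an adult genotype table
#'
#' Reads a delimited text table of adults with one row per individual:
#' columns `id`, `sex` (`female`/`male`), `pond`, and two allele columns per
#' locus named `<locus>_a` / `<locus>_b`. A single combined column per locus
#' (`<locus>` holding `"a/b"`) is accepted as a dialect and split on read.
#' Microsatellite alleles are fragment sizes in base pairs and must parse as
#' integers; MHC alleles are allele names. A genotype equal to the missing
#' sentinel (default `"NA"`) in either allele column marks the locus untyped
#' for that individual; untyped loci are excluded from per-locus statistics
#' rather than dropping the individual.
#'
#' @param path Path to a delimited text file with a header row.
#' @param loci Locus metadata table (see [validate_loci()]).
#' @param delim Field delimiter, default tab; comma accepted.
#' @param missing Missing-genotype sentinel string, default `"NA"`.
#' @return A tibble of individuals, loci in the order given by `loci`.
#' @export
read_individuals <- function(path, loci, delim = "\t", missing = "NA") {
  loci <- validate_loci(loci)
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  req <- c("id", "sex", "pond")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("individuals file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(id = raw$id, sex = raw$sex, pond = raw$pond)
  for (i in seq_len(nrow(loci))) {
    loc <- loci$locus[i]
    cols <- locus_cols(loc)
    if (all(cols %in% names(raw))) {
      a <- raw[[cols[1]]]
      b <- raw[[cols[2]]]
    } else if (loc %in% names(raw)) {
      parts <- stringr::str_split_fixed(raw[[loc]], "/", 2)
      a <- parts[, 1]
      b <- parts[, 2]
    } else {
      stop("no genotype column(s) found for locus ", loc, call. = FALSE)
    }
    a[a == missing | a == ""] <- NA_character_
    b[b == missing | b == ""] <- NA_character_
    # a half-called genotype is treated as untyped, never as homozygous
    untyped <- is.na(a) | is.na(b)
    a[untyped] <- NA_character_
    b[untyped] <- NA_character_
    if (loci$type[i] == "microsat") {
      for (v in list(c1 = a, c2 = b)) {
        num <- suppressWarnings(as.integer(v))
        bad <- which(!is.na(v) & is.na(num))
        if (length(bad) > 0) {
          stop(sprintf("malformed allele size '%s' at row %d, locus %s",
                       v[bad[1]], bad[1], loc), call. = FALSE)
        }
      }
      out[[cols[1]]] <- as.integer(a)
      out[[cols[2]]] <- as.integer(b)
    } else {
      out[[cols[1]]] <- a
      out[[cols[2]]] <- b
    }
  }
  validate_individuals(out, loci)
}

#' Validate an individuals table
#'
#' Checks the schema produced by [read_individuals()] (and by the synthetic
#' generator): unique ids, non-empty ponds, known sexes, positive allele
#' sizes, and both allele columns present for every declared locus.
#'
#' @inheritParams read_individuals
#' @param individuals An individuals tibble.
#' @return The validated tibble.
#' @export
validate_individuals <- function(individuals, loci) {
  loci <- validate_loci(loci)
  individuals <- tibble::as_tibble(individuals)
  dup <- unique(individuals$id[duplicated(individuals$id)])
  if (length(dup) > 0) {
    stop("duplicated individual id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(individuals$pond) | individuals$pond == "")) {
    stop("every individual needs a non-empty pond", call. = FALSE)
  }
  bad_sex <- setdiff(unique(individuals$sex), c("female", "male"))
  if (length(bad_sex) > 0) {
    stop("sex must be 'female' or 'male'; found: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(loci))) {
    g <- geno_matrix(individuals, loci$locus[i])
    if (loci$type[i] == "microsat") {
      sizes <- suppressWarnings(as.numeric(g))
      if (any(!is.na(sizes) & sizes <= 0)) {
        stop("non-positive allele size at locus ", loci$locus[i],
             call. = FALSE)
      }
    }
  }
  individuals
}

#' Write an individuals table to delimited text
#'
#' Inverse of [read_individuals()]: writes the two-column-per-locus layout
#' with the chosen missing sentinel, so that a read/write round trip
#' reproduces the genotype content field for field.
#'
#' @inheritParams read_individuals
#' @param individuals An individuals tibble.
#' @return `path`, invisibly.
#' @export
write_individuals <- function(individuals, path, delim = "\t", missing = "NA") {
  out <- as.data.frame(individuals)
  for (j in seq_along(out)) {
    v <- as.character(out[[j]])
    v[is.na(v)] <- missing
    out[[j]] <- v
  }
  utils::write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mating-pair table
#'
#' Reads realised female-by-male matings (columns `female_id`, `male_id`,
#' `pond`, `n_offspring`) and validates them against the adult table: both
#' ids must exist, sexes must match the columns, the clutch size must be a
#' non-negative integer, and both members must live in the stated pond --
#' ponds are physically separated enclosures, so a cross-pond pair is a data
#' error, not a rare event.
#'
#' @inheritParams read_individuals
#' @param individuals The adult table the pairs refer to.
#' @return A tibble of validated mating pairs.
#' @export
read_pairs <- function(path, individuals, delim = "\t") {
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE)
  pairs <- tibble::as_tibble(raw)
  validate_pairs(pairs, individuals)
}

#' Validate a mating-pair table against the adult table
#'
#' @inheritParams read_pairs
#' @param pairs A pair tibble with columns `female_id`, `male_id`, `pond`,
#'   `n_offspring`.
#' @return The validated pair tibble.
#' @export
validate_pairs <- function(pairs, individuals) {
  pairs <- tibble::as_tibble(pairs)
  req <- c("female_id", "male_id", "pond", "n_offspring")
  missing_cols <- setdiff(req, names(pairs))
  if (length(missing_cols) > 0) {
    stop("pairs table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(pairs) == 0) return(pairs)
  assert_ids_exist(pairs$female_id, individuals, "female")
  assert_ids_exist(pairs$male_id, individuals, "male")
  lookup <- stats::setNames(individuals$pond, individuals$id)
  sex <- stats::setNames(individuals$sex, individuals$id)
  if (any(sex[pairs$female_id] != "female") ||
      any(sex[pairs$male_id] != "male")) {
    stop("pair member listed under the wrong sex column", call. = FALSE)
  }
  fpond <- unname(lookup[pairs$female_id])
  mpond <- unname(lookup[pairs$male_id])
  bad <- which(fpond != pairs$pond | mpond != pairs$pond)
  if (length(bad) > 0) {
    stop(sprintf("cross-pond pair: %s x %s (row %d)",
                 pairs$female_id[bad[1]], pairs$male_id[bad[1]], bad[1]),
         call. = FALSE)
  }
  if (any(is.na(pairs$n_offspring) | pairs$n_offspring < 0)) {
    stop("n_offspring must be a non-negative count", call. = FALSE)
  }
  pairs
}

#' Read an offspring trio table
#'
#' One row per offspring with `offspring_id`, `mother_id`, `father_id` and
#' the offspring's own genotype columns (`<locus>_a` / `<locus>_b`).
#' Parental genotypes are looked up in the adult table at audit time.
#'
#' @inheritParams read_individuals
#' @return A tibble of trios.
#' @export
read_trios <- function(path, loci, delim = "\t", missing = "NA") {
  loci <- validate_loci(loci)
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  req <- c("offspring_id", "mother_id", "father_id")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("trios file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  for (loc in loci$locus) {
    for (col in locus_cols(loc)) {
      if (!col %in% names(out)) {
        stop("trios file lacks genotype column ", col, call. = FALSE)
      }
      v <- out[[col]]
      v[v == missing | v == ""] <- NA_character_
      out[[col]] <- v
    }
  }
  out
}

#' Read an MHC allele sequence catalogue from FASTA
#'
#' FASTA headers follow the `locus|allele` convention. Each coding sequence
#' is translated (standard code) in the declared reading frame; sequences
#' whose length is not a multiple of three in that frame, that contain
#' non-ACGT characters, or whose translation contains an internal stop are
#' rejected, as are duplicate allele names within a locus.
#'
#' @param path Path to a FASTA file.
#' @param frame Reading frame (1, 2 or 3) applied to every record, or a
#'   named vector giving a frame per locus.
#' @return A tibble with columns `locus`, `allele`, `dna`, `protein`.
#' @export
read_allele_fasta <- function(path, frame = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path, call. = FALSE)
  headers <- names(seqs)
  parts <- stringr::str_split_fixed(headers, stringr::fixed("|"), 2)
  if (any(parts[, 2] == "")) {
    stop("FASTA header not in 'locus|allele' form: ",
         headers[which(parts[, 2] == "")[1]], call. = FALSE)
  }
  locus <- parts[, 1]
  allele <- stringr::str_trim(parts[, 2])
  dup <- duplicated(paste(locus, allele, sep = "|"))
  if (any(dup)) {
    stop("duplicate allele record: ", headers[which(dup)[1]], call. = FALSE)
  }
  dna <- unname(as.character(seqs))
  if (any(grepl("[^ACGTacgt]", dna))) {
    stop("non-ACGT character in sequence ",
         headers[which(grepl("[^ACGTacgt]", dna))[1]], call. = FALSE)
  }
  dna <- toupper(dna)
  frames <- if (length(frame) == 1 && is.null(names(frame))) {
    rep(as.integer(frame), length(dna))
  } else {
    fr <- as.integer(frame[locus])
    if (any(is.na(fr))) {
      stop("no reading frame declared for locus ",
           locus[which(is.na(fr))[1]], call. = FALSE)
    }
    fr
  }
  protein <- character(length(dna))
  for (i in seq_along(dna)) {
    coding <- substring(dna[i], frames[i])
    if (nchar(coding) %% 3 != 0) {
      stop(sprintf("sequence %s has length %d in frame %d (not a codon multiple)",
                   headers[i], nchar(coding), frames[i]), call. = FALSE)
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(coding)))
    if (grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)) {
      stop("internal stop codon in translation of ", headers[i], call. = FALSE)
    }
    # a trailing stop is tolerated and trimmed
    if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
    protein[i] <- aa
  }
  tibble::tibble(locus = locus, allele = allele, dna = dna, protein = protein)
}

#' Write an allele catalogue to FASTA
#'
#' @param alleles Tibble as returned by [read_allele_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(alleles, path) {
  lines <- character(0)
  for (i in seq_len(nrow(alleles))) {
    lines <- c(lines,
               paste0(">", alleles$locus[i], "|", alleles$allele[i]),
               alleles$dna[i])
  }
  writeLines(lines, path)
  invisible(path)
}
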