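#' uniparental: population structure from uniparental markers
#'
#' Analysis of maternally (mtDNA) and paternally (MSY) inherited markers:
#' alignment masking, haplotype collapsing, diversity estimation, haplotype
#' sharing, AMOVA-based pairwise PhiST, ordination (NMDS, correspondence
#' analysis), and a forward-time simulator of sex-biased migration.
#'
#' All coordinates in this package are 1-based and range-inclusive.
#'
#' @keywords internal
"_PACKAGE"

VALID_BASES <- c("A", "C", "G", "T", "N", "-")

new_alignment_set <- function(seqs, reference_id = NULL, column_to_refpos = NULL) {
  stopifnot(is.matrix(seqs), !is.null(rownames(seqs)))
  if (is.null(column_to_refpos)) column_to_refpos <- seq_len(ncol(seqs))
  structure(
    list(
      sample_ids = rownames(seqs),
      seqs = seqs,
      reference_id = reference_id,
      column_to_refpos = column_to_refpos
    ),
    class = "alignment_set"
  )
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf(
    "<alignment_set> %d sequences x %d columns%s\n",
    nrow(x$seqs), ncol(x$seqs),
    if (!is.null(x$reference_id)) paste0(" (reference: ", x$reference_id, ")") else ""
  ))
  invisible(x)
}

#' Read a multiple sequence alignment from FASTA
#'
#' Reads an aligned FASTA file (all records must have equal length) into an
#' `alignment_set`. Bases are upper-cased on read; only `A`, `C`, `G`, `T`,
#' `N` and the gap character `-` are accepted — IUPAC ambiguity codes are
#' rejected because downstream masking and haplotype identity are defined
#' only over this alphabet.
#'
#' If `reference_id` names one of the records, alignment columns are mapped
#' to 1-based reference positions by numbering the non-gap characters of that
#' row `1..L`; columns where the reference carries a gap map to `NA`. Without
#' a reference, columns map to themselves (identity coordinates).
#'
#' @param path Path to a FASTA file.
#' @param reference_id Optional name of the coordinate-bearing record.
#' @return An `alignment_set`: sample ids, a samples-by-columns character
#'   matrix, the reference id, and the column-to-reference-position map.
#' @export
read_fasta_alignment <- function(path, reference_id = NULL) {
  dna <- suppressWarnings(ape::read.FASTA(path))  # validation below is stricter
  if (length(dna) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    bad <- names(dna)[lens != lens[1L]][1L]
    stop(
      "FASTA records are not aligned: record '", bad, "' has length ",
      lens[names(dna) == bad][1L], " but '", names(dna)[1L], "' has length ",
      lens[1L], call. = FALSE
    )
  }
  if (anyDuplicated(names(dna))) {
    stop("duplicate sequence id(s): ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(as.matrix(dna)))
  bad <- setdiff(unique(as.vector(seqs)), VALID_BASES)
  if (length(bad) > 0L) {
    stop("alignment contains characters outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  map <- NULL
  if (!is.null(reference_id)) {
    if (!reference_id %in% rownames(seqs)) {
      stop("reference record '", reference_id, "' not found in alignment",
           call. = FALSE)
    }
    ref <- seqs[reference_id, ]
    map <- rep(NA_integer_, length(ref))
    map[ref != "-"] <- seq_len(sum(ref != "-"))
  }
  new_alignment_set(seqs, reference_id = reference_id, column_to_refpos = map %||% seq_len(ncol(seqs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an alignment to FASTA
#'
#' Sequences are wrapped at 70 columns. Round-trips losslessly with
#' [read_fasta_alignment()].
#'
#' @param aln An `alignment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment_set"))
  dna <- ape::as.DNAbin(aln$seqs)
  ape::write.FASTA(dna, path)
  invisible(path)
}

new_genotype_table <- function(sample_ids, site_positions, calls, missing_token = "N") {
  stopifnot(is.matrix(calls))
  rownames(calls) <- sample_ids
  colnames(calls) <- as.character(site_positions)
  structure(
    list(
      sample_ids = sample_ids,
      site_positions = as.integer(site_positions),
      calls = calls,
      missing_token = missing_token
    ),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "<genotype_table> %d samples x %d sites (missing token '%s')\n",
    length(x$sample_ids), length(x$site_positions), x$missing_token
  ))
  invisible(x)
}

validate_biallelic <- function(calls, site_positions, missing_token) {
  for (j in seq_len(ncol(calls))) {
    alleles <- setdiff(unique(calls[, j]), missing_token)
    if (length(alleles) > 2L) {
      stop("site ", site_positions[j], " has more than two alleles: ",
           paste(sort(alleles), collapse = ","), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a biallelic SNP genotype table
#'
#' Expects tab-delimited text: a `sample_id` column followed by one column
#' per site, with 1-based site positions (e.g. hg19 coordinates) as the
#' header and one row per sample. Positions must be strictly increasing;
#' each site may carry at most two observed alleles beside the missing
#' token.
#'
#' @param path Path to the TSV file.
#' @param missing_token Token encoding a missing call (default `"N"`).
#' @return A `genotype_table`.
#' @export
read_genotype_table <- function(path, missing_token = "N") {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("genotype table needs a sample_id column plus >=1 site", call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (anyNA(pos)) stop("site header contains non-numeric positions", call. = FALSE)
  if (length(pos) > 1L && any(diff(pos) <= 0)) {
    stop("site positions are not strictly increasing", call. = FALSE)
  }
  calls <- as.matrix(df[, -1L, drop = FALSE])
  validate_biallelic(calls, pos, missing_token)
  new_genotype_table(ids, pos, calls, missing_token)
}

#' Write a genotype table to TSV
#'
#' @param g A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path) {
  stopifnot(inherits(g, "genotype_table"))
  df <- data.frame(sample_id = g$sample_ids, g$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

METADATA_COLUMNS <- c("sample_id", "population", "language_family", "country", "dataset_tag")

#' Read a sample metadata table
#'
#' Tab-delimited text with required columns `sample_id` and `population`;
#' optional `language_family`, `country` and `dataset_tag` default to the
#' empty token.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per sample and the five metadata
#'   columns, class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  as_sample_metadata(df)
}

#' Coerce a data frame to sample metadata
#'
#' @param df Data frame with at least `sample_id` and `population` columns.
#' @return The validated metadata data frame.
#' @export
as_sample_metadata <- function(df) {
  need <- c("sample_id", "population")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s) in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$population))) {
    stop("metadata contains empty population labels", call. = FALSE)
  }
  for (col in setdiff(METADATA_COLUMNS, names(df))) df[[col]] <- ""
  df <- df[, METADATA_COLUMNS]
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read per-sample haplogroup assignments
#'
#' Tab-delimited with columns `sample_id` and `haplogroup`. A trailing
#' asterisk (e.g. `R*`) marks a paragroup: haplotypes assigned to the clade
#' but to none of its defined subclades. The star may appear only as the
#' final character.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `sample_id` and `haplogroup`.
#' @export
read_haplogroups <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "haplogroup")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("haplogroup table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s) in haplogroup table", call. = FALSE)
  }
  if (any(!nzchar(df$haplogroup))) stop("empty haplogroup label(s)", call. = FALSE)
  internal_star <- grepl("\\*.", df$haplogroup)
  if (any(internal_star)) {
    stop("'*' may appear only as the final character of a haplogroup label: ",
         paste(unique(df$haplogroup[internal_star]), collapse = ", "), call. = FALSE)
  }
  df[, need]
}

#' Write a labelled numeric matrix to TSV
#'
#' Values are written with 6 significant digits by default so the file
#' round-trips losslessly at the stated precision via [read_matrix()].
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param digits Significant digits to keep.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, digits = 6) {
  if (!is.matrix(m) || !is.numeric(m)) stop("'m' must be a numeric matrix", call. = FALSE)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("cannot write an empty matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must have row and column labels", call. = FALSE)
  }
  out <- data.frame(id = rownames(m), signif(m, digits), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1L] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled numeric matrix written by [write_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A labelled numeric matrix.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read a mask specification from TSV
#'
#' Three columns: `start`, `end`, `label`, 1-based inclusive reference
#' coordinates.
#'
#' @param path Path to the TSV file.
#' @return A `mask_spec`.
#' @export
read_mask <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mask_spec(df$start, df$end, df$label)
}
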