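# Per-gene orthologous protein alignments.
#
# An `ortholog_alignment` holds one multiple alignment of orthologous
# proteins over the species set, one aligned row per species, with the
# human row as the coordinate reference.  Rows use the multiz-derived
# dialect: amino-acid letters, '-' for alignment gaps, 'X' for unknown
# residues, '*' for stop codons.  'X' and '*' (and '-') carry no residue
# information: they are treated as MISSING everywhere downstream, so a
# low-quality draft-genome row can never support or veto a lysine call.

new_ortholog_alignment <- function(gene_id, rows, reference, audit = list()) {
  structure(list(gene_id = gene_id, rows = rows, reference = reference,
                 audit = audit),
            class = "ortholog_alignment")
}

#' Read a per-gene ortholog alignment from FASTA
#'
#' @param path Path to an aligned FASTA file, one record per species.  The
#'   species code is extracted from the record header via `species_pattern`
#'   (first capture group; default: the first whitespace-delimited token).
#' @param gene_id Gene identifier to attach to the alignment (defaults to
#'   the file name without extension).
#' @param reference Species code of the coordinate-reference (human) row.
#' @param species_pattern Regular expression with one capture group
#'   extracting the species code from a FASTA header.
#' @param require_reference Fail if the reference row is absent.
#' @return An `ortholog_alignment`: list with `gene_id`, `rows` (named
#'   character vector of equal-length aligned sequences, uppercase),
#'   `reference`, and an `audit` log of row replacements.
#' @export
parse_alignment_fasta <- function(path, gene_id = NULL, reference = "hg19",
                                  species_pattern = "^(\\S+)",
                                  require_reference = TRUE) {
  if (is.null(gene_id))
    gene_id <- tools::file_path_sans_ext(basename(path))
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L)
    stop("alignment file ", path, " contains no sequences")
  species <- vapply(names(x), function(h) {
    g <- regmatches(h, regexec(species_pattern, h, perl = TRUE))[[1L]]
    if (length(g) == 0L)
      stop("alignment file ", path, ": header '", h,
           "' does not match species pattern")
    if (length(g) >= 2L) g[2L] else g[1L]
  }, character(1), USE.NAMES = FALSE)
  dup <- unique(species[duplicated(species)])
  if (length(dup) > 0L)
    stop("alignment file ", path, ": duplicate species record(s): ",
         paste(dup, collapse = ", "))
  widths <- Biostrings::width(x)
  if (length(unique(widths)) != 1L)
    stop("alignment file ", path, ": ragged rows (lengths ",
         paste(sort(unique(widths)), collapse = ", "), ")")
  rows <- stats::setNames(toupper(as.character(x)), species)
  if (require_reference && !reference %in% species)
    stop("alignment file ", path, ": reference species '", reference,
         "' not present")
  new_ortholog_alignment(gene_id, rows, reference)
}

#' Alignment length (number of columns)
#' @param aln An `ortholog_alignment`.
#' @return Integer number of alignment columns.
#' @export
alignment_length <- function(aln) nchar(aln$rows[[1L]])

# Ungapped (degapped) sequence of one row.
degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Ungapped reference sequence and length
#' @param aln An `ortholog_alignment`.
#' @return The reference (human) row with gap characters removed.
#' @export
reference_sequence <- function(aln) degap(aln$rows[[aln$reference]])

#' Map a 1-based reference protein position to a 0-based alignment column
#'
#' @param aln An `ortholog_alignment`.
#' @param position 1-based residue index in the ungapped reference protein.
#' @return 0-based alignment column index holding that residue.
#' @export
column_of_position <- function(aln, position) {
  chars <- strsplit(aln$rows[[aln$reference]], "", fixed = TRUE)[[1L]]
  nongap <- which(chars != "-")
  if (position < 1L || position > length(nongap))
    stop("position ", position, " out of range for reference of length ",
         length(nongap), " (gene ", aln$gene_id, ")")
  nongap[position] - 1L
}

#' Map a 0-based alignment column back to a 1-based reference position
#'
#' Inverse of [column_of_position()]; errors if the reference row has a gap
#' at the column.
#'
#' @param aln An `ortholog_alignment`.
#' @param column 0-based alignment column index.
#' @return 1-based residue index in the ungapped reference protein.
#' @export
position_of_column <- function(aln, column) {
  chars <- strsplit(aln$rows[[aln$reference]], "", fixed = TRUE)[[1L]]
  if (column < 0L || column >= length(chars))
    stop("column ", column, " out of range")
  if (chars[column + 1L] == "-")
    stop("reference row has a gap at column ", column)
  sum(chars[seq_len(column + 1L)] != "-")
}

#' Residue profile of one alignment column
#'
#' Extracts the residue of every species at one column.  Gap (`-`),
#' unknown (`X`) and stop (`*`) characters, and species absent from the
#' alignment (when a species tree supplies the full species set), are
#' reported as `NA` (MISSING).
#'
#' @param aln An `ortholog_alignment`.
#' @param column 0-based alignment column index.
#' @param tree Optional `species_tree`; when given, the profile covers all
#'   tree species (absent ones as `NA`), in tree tip order.
#' @return Named character vector, one entry per species; `NA` = MISSING.
#'   The column index is attached as attribute `"column"`.
#' @export
residue_profile <- function(aln, column, tree = NULL) {
  if (column < 0L || column >= alignment_length(aln))
    stop("column ", column, " out of range")
  species <- names(aln$rows)
  if (!is.null(tree))
    species <- union(tree$phy$tip.label, species)
  res <- vapply(species, function(sp) {
    if (!sp %in% names(aln$rows)) return(NA_character_)
    ch <- toupper(substr(aln$rows[[sp]], column + 1L, column + 1L))
    if (ch %in% AA20) ch else NA_character_
  }, character(1))
  attr(res, "column") <- column
  res
}

#' Replace (or add) one species row of an alignment
#'
#' Used to patch low-quality rows with curated sequences, or to add a
#' species absent from the original alignment set (for example a gibbon
#' row predicted from a newer assembly).  The previous row, if any, is
#' retained in the alignment's audit log.
#'
#' @param aln An `ortholog_alignment`.
#' @param species Species code of the row to replace or add.
#' @param new_row Aligned sequence; must match the alignment length.
#' @return The updated `ortholog_alignment`.
#' @export
replace_sequence <- function(aln, species, new_row) {
  new_row <- toupper(new_row)
  if (nchar(new_row) != alignment_length(aln))
    stop("replacement row for ", species, " has length ", nchar(new_row),
         "; alignment length is ", alignment_length(aln))
  old <- if (species %in% names(aln$rows)) aln$rows[[species]]
         else NA_character_
  aln$audit[[length(aln$audit) + 1L]] <-
    list(species = species, old_row = old)
  aln$rows[species] <- new_row
  aln
}

#' Write an ortholog alignment to FASTA
#' @param aln An `ortholog_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  x <- Biostrings::AAStringSet(aln$rows)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat("ortholog alignment '", x$gene_id, "': ", length(x$rows),
      " species x ", alignment_length(x), " columns (reference ",
      x$reference, ")\n", sep = "")
  invisible(x)
}
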