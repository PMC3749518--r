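# Standard residue alphabets. Ambiguity codes are retained on read so that
# files round-trip exactly, but every statistic in the package treats a
# character outside the standard 4/20-letter alphabet as a gap.
NUC_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NUC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
AA_AMBIGUITY <- c("X", "B", "Z", "J", "U", "O", "*")
GAP_CHARS <- c("-", ".")

#' Residue alphabet for an alignment type
#'
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return Character vector of standard residues (4 or 20 letters).
#' @export
alignment_alphabet <- function(alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") NUC_ALPHABET else AA_ALPHABET
}

ambiguity_set <- function(alphabet) {
  if (alphabet == "nucleotide") NUC_AMBIGUITY else AA_AMBIGUITY
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` stores equal-length gapped sequences keyed by unique taxon ids,
#' with a declared alphabet. Sequences are upper-cased and, for nucleotide
#' alignments, `U` is normalised to `T`. Characters must belong to the
#' standard alphabet, the gap set (`-` and `.`) or the ambiguity set;
#' ambiguity codes are treated as gaps by all downstream statistics.
#'
#' @param seqs Named character vector of gapped sequences (one per taxon).
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return An object of class `msa`: a list with elements `mat` (character
#'   matrix, rows = taxa), `taxa`, `alphabet`, `gap_chars`.
#' @export
msa <- function(seqs, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) < 1L) stop("alignment needs at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a taxon id")
  if (anyDuplicated(ids)) {
    stop("duplicate taxon ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  if (alphabet == "nucleotide") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    tab <- table(lens)
    expected <- as.integer(names(tab)[which.max(tab)])
    bad <- ids[lens != expected][1L]
    stop("unequal sequence lengths: record '", bad, "' has length ",
         nchar(seqs[[bad]]), ", expected ", expected)
  }
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  allowed <- c(alignment_alphabet(alphabet), ambiguity_set(alphabet), GAP_CHARS)
  bad <- setdiff(unique(as.vector(mat)), allowed)
  if (length(bad) > 0L) {
    stop("characters outside the ", alphabet, " alphabet: ",
         paste(bad, collapse = ", "))
  }
  structure(list(mat = mat, taxa = ids, alphabet = alphabet,
                 gap_chars = GAP_CHARS),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment (", x$alphabet, "): ",
      length(x$taxa), " taxa x ", ncol(x$mat), " columns\n", sep = "")
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$mat)

#' Number of alignment columns / taxa
#' @param x An `msa`.
#' @return Integer count.
#' @export
n_columns <- function(x) ncol(x$mat)

#' @rdname n_columns
#' @export
n_taxa <- function(x) nrow(x$mat)

#' Logical gap mask of an alignment
#'
#' Gap characters and ambiguity codes both count as gaps (statistics operate
#' on the standard residue alphabet only).
#'
#' @param x An `msa`.
#' @return Logical matrix, same shape as the alignment, `TRUE` where the
#'   character is not a standard residue.
#' @export
gap_mask <- function(x) {
  !matrix(x$mat %in% alignment_alphabet(x$alphabet), nrow = nrow(x$mat),
          dimnames = dimnames(x$mat))
}

#' Subset an alignment
#'
#' @param x An `msa`.
#' @param taxa Taxon ids to keep (default all).
#' @param columns Column indices to keep (default all).
#' @return A new `msa`.
#' @export
msa_subset <- function(x, taxa = NULL, columns = NULL) {
  if (is.null(taxa)) taxa <- x$taxa
  missing_taxa <- setdiff(taxa, x$taxa)
  if (length(missing_taxa) > 0L) {
    stop("taxa absent from alignment: ", paste(missing_taxa, collapse = ", "))
  }
  if (is.null(columns)) columns <- seq_len(ncol(x$mat))
  mat <- x$mat[taxa, columns, drop = FALSE]
  out <- x
  out$mat <- mat
  out$taxa <- taxa
  out
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return An [msa] object. Taxon ids are the first whitespace-delimited
#'   token of each header.
#' @export
read_alignment <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  msa(seqs, alphabet = alphabet)
}

#' Write an alignment to FASTA
#'
#' @param x An [msa].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  seqs <- apply(x$mat, 1L, paste, collapse = "")
  lines <- as.vector(rbind(paste0(">", x$taxa), seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxon-to-group mapping
#'
#' Expects a tab-separated file with a header row and columns `taxon`,
#' `group` and optionally `species` (used for one-strain-per-species
#' subsampling).
#'
#' @param path TSV path.
#' @return A data frame with columns `taxon`, `group` and (if present)
#'   `species`, class `taxon_grouping`.
#' @export
read_grouping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("taxon", "group")
  if (!all(need %in% names(df))) {
    stop("grouping TSV needs columns 'taxon' and 'group'")
  }
  taxon_grouping(df$taxon, df$group,
                 species = if ("species" %in% names(df)) df$species else NULL)
}

#' Construct a taxon grouping
#'
#' @param taxon Character vector of taxon ids.
#' @param group Group label per taxon (non-empty).
#' @param species Optional species id per taxon.
#' @return Data frame of class `taxon_grouping`.
#' @export
taxon_grouping <- function(taxon, group, species = NULL) {
  if (length(taxon) != length(group)) stop("taxon and group lengths differ")
  if (any(!nzchar(group))) stop("group labels must be non-empty")
  dup <- duplicated(taxon)
  if (any(dup)) {
    # a taxon may be repeated only if its group is consistent
    for (t in unique(taxon[dup])) {
      if (length(unique(group[taxon == t])) > 1L) {
        stop("taxon '", t, "' listed with conflicting groups")
      }
    }
    keep <- !dup
    taxon <- taxon[keep]; group <- group[keep]
    if (!is.null(species)) species <- species[keep]
  }
  df <- data.frame(taxon = taxon, group = group, stringsAsFactors = FALSE)
  if (!is.null(species)) df$species <- species
  class(df) <- c("taxon_grouping", "data.frame")
  df
}

#' Taxa belonging to one group
#'
#' @param grouping A [taxon_grouping].
#' @param group Group label.
#' @param one_per_species If `TRUE` and a `species` column is present, keep
#'   a single representative per species (the lexicographically smallest
#'   taxon id).
#' @return Character vector of taxon ids.
#' @export
group_taxa <- function(grouping, group, one_per_species = FALSE) {
  sel <- grouping[grouping$group == group, , drop = FALSE]
  if (one_per_species && "species" %in% names(sel)) {
    sel <- sel[order(sel$taxon), , drop = FALSE]
    sel <- sel[!duplicated(sel$species), , drop = FALSE]
  }
  sel$taxon
}

#' Read a presence/absence matrix
#'
#' Tab-separated, header row; first column `taxon`, remaining columns one
#' trait each with cells `0`/`1` or `true`/`false` (case-insensitive).
#'
#' @param path TSV path.
#' @return Logical matrix, rows = taxa, columns = traits.
#' @export
read_presence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"taxon" %in% names(df)) stop("presence TSV needs a 'taxon' column")
  taxa <- df$taxon
  if (anyDuplicated(taxa)) stop("duplicate taxa in presence matrix")
  traits <- setdiff(names(df), "taxon")
  if (length(traits) == 0L) stop("presence TSV has no trait columns")
  parse_cell <- function(v) {
    lv <- tolower(v)
    out <- rep(NA, length(v))
    out[lv %in% c("1", "true")] <- TRUE
    out[lv %in% c("0", "false")] <- FALSE
    if (anyNA(out)) {
      stop("presence cells must be 0/1 or true/false; offending value: '",
           v[which(is.na(out))[1L]], "'")
    }
    out
  }
  m <- vapply(df[traits], parse_cell, logical(length(taxa)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(taxa))
  dimnames(m) <- list(taxa, traits)
  m
}

#' Write a presence/absence matrix
#' @param m Logical matrix (rows = taxa, columns = traits).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_presence <- function(m, path) {
  df <- data.frame(taxon = rownames(m),
                   ifelse(m, 1L, 0L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a taxon grouping
#' @param grouping A [taxon_grouping].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_grouping <- function(grouping, path) {
  utils::write.table(as.data.frame(grouping), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
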