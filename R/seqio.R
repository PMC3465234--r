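#' Binding-site collections
#'
#' A `site_set` holds the known binding sites of one transcription factor:
#' variable-length DNA strings over A/C/G/T plus identifiers. A
#' `species_dataset` groups the site sets of one species, keyed by TF id.
#'
#' @param tf_id Transcription factor identifier.
#' @param species Species label.
#' @param site_id Character vector of site identifiers (unique within the TF).
#' @param sequence Character vector of DNA sequences; silently uppercased,
#'   any character outside A/C/G/T is an error.
#' @return An object of class `site_set`.
#' @export
site_set <- function(tf_id, species, site_id, sequence) {
  stopifnot(length(site_id) == length(sequence), length(sequence) >= 1)
  sequence <- toupper(as.character(sequence))
  bad <- grepl("[^ACGT]", sequence) | nchar(sequence) == 0
  if (any(bad)) {
    stop(sprintf("site '%s' (tf '%s') contains characters outside A/C/G/T or is empty",
                 site_id[which(bad)[1]], tf_id))
  }
  if (anyDuplicated(site_id)) {
    stop(sprintf("duplicate site_id '%s' in tf '%s'",
                 site_id[anyDuplicated(site_id)], tf_id))
  }
  structure(list(tf_id = as.character(tf_id), species = as.character(species),
                 site_id = as.character(site_id), sequence = sequence),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set> tf '%s' (%s): %d sites, lengths %d-%d\n",
              x$tf_id, x$species, length(x$sequence),
              min(nchar(x$sequence)), max(nchar(x$sequence))))
  invisible(x)
}

#' @export
length.site_set <- function(x) length(x$sequence)

#' @rdname site_set
#' @param site_sets A list of `site_set` objects (names taken from their TF ids).
#' @export
species_dataset <- function(species, site_sets) {
  stopifnot(all(vapply(site_sets, inherits, logical(1), "site_set")))
  names(site_sets) <- vapply(site_sets, function(s) s$tf_id, character(1))
  if (anyDuplicated(names(site_sets))) stop("duplicate tf_id in dataset")
  structure(list(species = as.character(species), site_sets = site_sets),
            class = "species_dataset")
}

#' @export
print.species_dataset <- function(x, ...) {
  n_sites <- sum(vapply(x$site_sets, length, integer(1)))
  cat(sprintf("<species_dataset> %s: %d TFs, %d sites\n",
              x$species, length(x$site_sets), n_sites))
  invisible(x)
}

#' Read a tab-separated site table
#'
#' The canonical on-disk dataset layout: a TSV file with header columns
#' `species`, `tf_id`, `site_id`, `sequence`, one binding site per row.
#' Rows are grouped by TF (row order preserved within each TF).
#'
#' @param path Path to the TSV file. Must describe a single species.
#' @return A [species_dataset()].
#' @export
read_site_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("site table has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  need <- c("species", "tf_id", "site_id", "sequence")
  if (!all(need %in% header)) {
    stop("site table header must contain columns: ", paste(need, collapse = ", "))
  }
  idx <- match(need, header)
  rows <- lapply(seq_along(fields)[-1], function(i) {
    f <- fields[[i]]
    if (length(f) < length(header)) {
      stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                   i, length(header), length(f)))
    }
    f[idx]
  })
  tab <- do.call(rbind, rows)
  species <- unique(tab[, 1])
  if (length(species) != 1) {
    stop("site table describes more than one species: ",
         paste(species, collapse = ", "))
  }
  seqs <- toupper(tab[, 4])
  bad <- grepl("[^ACGT]", seqs) | nchar(seqs) == 0
  if (any(bad)) {
    stop(sprintf("site '%s' contains characters outside A/C/G/T",
                 tab[which(bad)[1], 3]))
  }
  sets <- lapply(split(seq_len(nrow(tab)), factor(tab[, 2], levels = unique(tab[, 2]))),
                 function(i) site_set(tab[i[1], 2], species, tab[i, 3], seqs[i]))
  species_dataset(species, unname(sets))
}

#' @rdname read_site_table
#' @param dataset A [species_dataset()].
#' @export
write_site_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "species_dataset"))
  rows <- do.call(rbind, lapply(dataset$site_sets, function(s) {
    cbind(s$species, s$tf_id, s$site_id, s$sequence)
  }))
  colnames(rows) <- c("species", "tf_id", "site_id", "sequence")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binding sites from a FASTA file
#'
#' One site per record; record ids become site ids. Sequences are uppercased
#' and must contain only A/C/G/T.
#'
#' @inheritParams site_set
#' @param path Path to a FASTA file.
#' @return A [site_set()].
#' @export
read_fasta_sites <- function(path, tf_id, species) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("no records in FASTA file '", path, "'")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) stop("duplicate FASTA id '", ids[anyDuplicated(ids)], "'")
  site_set(tf_id, species, ids, as.character(x))
}

#' Multiple alignments of binding sites
#'
#' A `tfbs_alignment` is a set of equal-length gapped rows over
#' \{A,C,G,T,-\}; each row degaps to its source site sequence. Row names are
#' the site ids (provenance).
#'
#' @param rows Named character vector of gapped rows (names = site ids).
#' @return An object of class `tfbs_alignment` with fields `rows` and `width`.
#' @export
tfbs_alignment <- function(rows) {
  nm <- names(rows)
  rows <- stats::setNames(toupper(as.character(rows)), nm)
  widths <- unname(nchar(rows))
  if (length(unique(widths)) != 1) {
    stop("alignment rows have unequal lengths: ", paste(widths, collapse = ", "))
  }
  if (any(grepl("[^ACGT-]", rows))) stop("alignment rows contain characters outside A/C/G/T/-")
  if (is.null(names(rows))) names(rows) <- paste0("row", seq_along(rows))
  structure(list(rows = rows, width = widths[1]), class = "tfbs_alignment")
}

#' @export
print.tfbs_alignment <- function(x, ...) {
  cat(sprintf("<tfbs_alignment> %d rows x %d columns\n", length(x$rows), x$width))
  for (i in seq_along(x$rows)) cat(sprintf("  %s  %s\n", x$rows[i], names(x$rows)[i]))
  invisible(x)
}

#' Remove gaps from alignment rows
#' @param alignment A [tfbs_alignment()].
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(alignment) {
  gsub("-", "", alignment$rows, fixed = TRUE)
}

# Character matrix view of an alignment (rows x columns).
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$rows, ""))
  rownames(m) <- names(alignment$rows)
  m
}

#' Read / write alignments
#'
#' Reads an aligned FASTA file (all records equal length, gap `-`) or a
#' Clustal-dialect file. Writing always emits aligned FASTA; write-then-read
#' reproduces rows and their order.
#'
#' @param path File path.
#' @param format `"auto"` (sniff the first line), `"fasta"` or `"clustal"`.
#' @return A [tfbs_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^\\s*CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  if (format == "clustal") {
    rows <- parse_clustal(path)
  } else {
    # read as plain FASTA text so ragged rows reach our own width check
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0) stop("no records in alignment file '", path, "'")
    rows <- toupper(as.character(x))
    names(rows) <- sub("\\s.*$", "", names(x))
  }
  tfbs_alignment(rows)
}

# Minimal Clustal-dialect reader: a header line, then blocks of
# "<name> <chunk>" rows (optionally ending in a cumulative residue count),
# with conservation lines (leading whitespace) ignored. Chunks accumulate
# per name across blocks, in first-seen order.
parse_clustal <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^\\s*CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("not a Clustal file: '", path, "'")
  }
  chunks <- list()
  for (line in lines[-1]) {
    if (!nzchar(trimws(line)) || grepl("^\\s", line)) next
    m <- regmatches(line, regexec("^(\\S+)\\s+(\\S+?)(\\s+\\d+)?\\s*$", line))[[1]]
    if (length(m) < 3) stop("malformed Clustal line: '", line, "'")
    nm <- m[2]
    chunks[[nm]] <- paste0(if (is.null(chunks[[nm]])) "" else chunks[[nm]], m[3])
  }
  if (length(chunks) == 0) stop("no sequences in Clustal file '", path, "'")
  unlist(chunks)
}

#' @rdname read_alignment
#' @param alignment A [tfbs_alignment()].
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "tfbs_alignment"))
  x <- Biostrings::BStringSet(alignment$rows)
  Biostrings::writeXStringSet(x, path, width = max(80L, alignment$width))
  invisible(path)
}
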