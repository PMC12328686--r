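#' Construct an Alignment object
#'
#' An `Alignment` is a query sequence plus homolog rows, all expressed in
#' query-column space: after removing lowercase insertion characters, every
#' row spans exactly `nchar(query_seq)` match columns (uppercase residues or
#' `-`). It is the unit that the windowed merge operates on.
#'
#' @param query_id Label of the query record.
#' @param query_seq Ungapped amino-acid string (20 standard letters plus X).
#' @param ids Character vector of homolog row labels (may be empty).
#' @param aligned Character vector of aligned row strings over
#'   `{uppercase, '-', lowercase}`; same length as `ids`.
#' @param provenance Per-row provenance, one of `"native"`, `"scaffold"`,
#'   `"peptide"`, `"query"`. Recycled if length 1.
#' @param source_tag Free-text tag recording where the alignment came from
#'   (e.g. `"scaffold"` or `"peptide"`).
#' @param metadata Character vector of `#`-header lines preserved from an
#'   A3M file (ColabFold cardinality header), or `character(0)`.
#' @return An object of class `"chim_alignment"`.
#' @export
alignment <- function(query_id, query_seq, ids = character(), aligned = character(),
                      provenance = "native", source_tag = "", metadata = character()) {
  stopifnot(is.character(query_id), length(query_id) == 1L)
  if (!.valid_query_seq(query_seq)) {
    stop("query sequence must be a non-empty string over the 20 amino-acid letters plus X",
         call. = FALSE)
  }
  if (length(ids) != length(aligned)) {
    stop("'ids' and 'aligned' must have equal length", call. = FALSE)
  }
  provenance <- rep_len(as.character(provenance), length(ids))
  qlen <- nchar(query_seq)
  bad <- which(match_length(aligned) != qlen)
  if (length(bad)) {
    stop(sprintf("row '%s': match-state length %d != query length %d",
                 ids[bad[1L]], match_length(aligned[bad[1L]]), qlen), call. = FALSE)
  }
  structure(
    list(query_id = query_id, query_seq = query_seq,
         ids = as.character(ids), aligned = as.character(aligned),
         provenance = provenance, source_tag = source_tag,
         metadata = as.character(metadata)),
    class = "chim_alignment"
  )
}

#' @export
print.chim_alignment <- function(x, ...) {
  cat(sprintf("Alignment '%s': query length %d, %d homolog row(s)%s\n",
              x$query_id, nchar(x$query_seq), length(x$ids),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

#' Number of homolog rows in an alignment
#'
#' Counts the non-query rows. The redundancy pipeline drops any peptide whose
#' alignment has fewer than 2 hits, because such shallow alignments carry no
#' usable coevolution signal.
#'
#' @param aln An [alignment()] object.
#' @return Non-negative integer count of homolog rows.
#' @export
hit_count <- function(aln) {
  stopifnot(inherits(aln, "chim_alignment"))
  length(aln$ids)
}

#' Filter alignments by minimum MSA depth
#'
#' Keeps only alignments with at least `min_hits` homolog rows.
#'
#' @param alns A list of [alignment()] objects.
#' @param min_hits Minimum number of non-query rows required (default 2).
#' @return The retained sublist, order preserved.
#' @export
filter_by_depth <- function(alns, min_hits = 2L) {
  stopifnot(is.list(alns))
  alns[vapply(alns, hit_count, integer(1)) >= min_hits]
}

#' Per-row fractional identity to the query
#'
#' For each homolog row, the fraction of match-state columns whose residue
#' equals the query residue at that column, divided by the query length.
#' Gap columns count as non-matches, so an all-gap row scores 0. Insertion
#' (lowercase) characters are ignored: identity is defined in query-column
#' space only.
#'
#' @param aln An [alignment()] object.
#' @return Named numeric vector in `[0, 1]`, one entry per homolog row.
#' @export
identity_to_query <- function(aln) {
  stopifnot(inherits(aln, "chim_alignment"))
  qchars <- strsplit(aln$query_seq, "")[[1]]
  out <- vapply(aln$aligned, function(a) {
    rchars <- strsplit(strip_insertions(a), "")[[1]]
    sum(rchars == qchars & rchars != "-") / length(qchars)
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(out, aln$ids)
}

#' Per-column coverage profile
#'
#' Number of sequences (query included) holding a residue, rather than a gap,
#' at each match column. This is the depth curve drawn under MSA coverage
#' plots; for a merged windowed alignment its restriction to the peptide
#' window reproduces the peptide alignment's own profile.
#'
#' @param aln An [alignment()] object.
#' @return Integer vector of length `nchar(query_seq)`; every entry lies in
#'   `[1, depth]` because the query covers all columns.
#' @export
coverage_profile <- function(aln) {
  stopifnot(inherits(aln, "chim_alignment"))
  qlen <- nchar(aln$query_seq)
  counts <- rep(1L, qlen)  # query row covers every column
  for (a in aln$aligned) {
    rchars <- strsplit(strip_insertions(a), "")[[1]]
    counts <- counts + as.integer(rchars != "-")
  }
  counts
}

.parse_fasta_records <- function(lines, path) {
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) {
    stop(sprintf("'%s': no FASTA records found", path), call. = FALSE)
  }
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  ids <- sub("^>\\s*", "", lines[hdr_idx])
  # keep only the first whitespace-delimited token as the id
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    block <- lines[seq.int(hdr_idx[i] + 1L, ends[i])]
    if (hdr_idx[i] + 1L > ends[i]) "" else paste(block, collapse = "")
  }, character(1))
  list(ids = ids, seqs = gsub("[[:space:]]", "", seqs))
}

.dedup_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  make.unique(ids, sep = "_dup")
}

#' Read an A3M or aligned-FASTA alignment
#'
#' Parses the MMseqs2/ColabFold A3M dialect: `>`-headers, optional leading
#' `#` cardinality lines (preserved as metadata), uppercase/`-` match columns
#' and lowercase insertion columns. The first record must be the query and
#' must contain no gaps once insertions are stripped. Duplicate row ids are
#' tolerated and suffixed, as MMseqs2 output may repeat ids.
#'
#' @param path Path to an A3M or aligned-FASTA file.
#' @param strip Logical; when `TRUE` (default) lowercase insertion columns
#'   are deleted from every row so the result is in pure query-column space.
#'   Stripping is idempotent.
#' @param source_tag Optional free-text tag stored on the result.
#' @return An [alignment()] object.
#' @export
read_a3m <- function(path, strip = TRUE, source_tag = "") {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  meta <- lines[grepl("^#", lines)]
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop(sprintf("'%s': empty alignment file", path), call. = FALSE)
  rec <- .parse_fasta_records(lines, path)
  qseq <- strip_insertions(rec$seqs[1L])
  if (grepl("-", qseq, fixed = TRUE)) {
    stop(sprintf("'%s': first record '%s' contains gaps; the query must be record 0",
                 path, rec$ids[1L]), call. = FALSE)
  }
  if (!.valid_query_seq(qseq)) {
    stop(sprintf("'%s': query '%s' contains characters outside the amino-acid alphabet",
                 path, rec$ids[1L]), call. = FALSE)
  }
  rows_aligned <- rec$seqs[-1L]
  rows_ids <- .dedup_ids(rec$ids[-1L])
  qlen <- nchar(qseq)
  bad <- which(match_length(rows_aligned) != qlen)
  if (length(bad)) {
    stop(sprintf("'%s': record '%s' has match-state length %d, expected %d",
                 path, rows_ids[bad[1L]], match_length(rows_aligned[bad[1L]]), qlen),
         call. = FALSE)
  }
  if (strip) rows_aligned <- strip_insertions(rows_aligned)
  alignment(query_id = rec$ids[1L], query_seq = qseq,
            ids = rows_ids, aligned = rows_aligned,
            provenance = "native", source_tag = source_tag, metadata = meta)
}

#' Write an alignment as A3M / aligned FASTA
#'
#' Writes the query first, then the homolog rows in order, preserving any
#' `#` metadata lines at the top. Reading the file back with [read_a3m()]
#' reproduces the alignment record-for-record with byte-identical aligned
#' strings.
#'
#' @param aln An [alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_a3m <- function(aln, path) {
  stopifnot(inherits(aln, "chim_alignment"))
  out <- character(0)
  if (length(aln$metadata)) out <- aln$metadata
  out <- c(out, paste0(">", aln$query_id), aln$query_seq)
  if (length(aln$ids)) {
    out <- c(out, as.vector(rbind(paste0(">", aln$ids), aln$aligned)))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write alignment to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read ungapped sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase ungapped sequences.
#' @export
read_fasta_seqs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^[#;]", lines)]
  if (!length(lines)) stop(sprintf("'%s': empty FASTA file", path), call. = FALSE)
  rec <- .parse_fasta_records(lines, path)
  stats::setNames(toupper(gsub("-", "", rec$seqs)), .dedup_ids(rec$ids))
}

#' Write ungapped sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}
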