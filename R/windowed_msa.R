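#' Attach a linker to a scaffold alignment
#'
#' The windowed strategy treats the flexible Gly-Ser linker as part of the
#' scaffold sub-alignment: the scaffold query gains the linker residues on
#' the side facing the peptide, and every homolog row receives gaps at the
#' new linker columns (offline, no homolog covers residues that do not
#' exist in nature).
#'
#' @param scaffold_aln Insertion-stripped [alignment()] of the scaffold.
#' @param linker Linker sequence; empty returns the alignment unchanged.
#' @param side `"append"` (C-terminal fusions) or `"prepend"` (N-terminal).
#' @return An [alignment()] whose query is scaffold+linker (or linker+scaffold).
#' @export
incorporate_linker <- function(scaffold_aln, linker, side = c("append", "prepend")) {
  stopifnot(inherits(scaffold_aln, "chim_alignment"))
  side <- match.arg(side)
  if (any(grepl("[a-z]", scaffold_aln$aligned))) {
    stop("alignment must be insertion-stripped before linker incorporation",
         call. = FALSE)
  }
  if (nchar(linker) == 0L) return(scaffold_aln)
  if (!.valid_aa_seq(linker)) stop("illegal character in linker", call. = FALSE)
  pad <- .gaps(nchar(linker))
  has_rows <- length(scaffold_aln$aligned) > 0L
  if (side == "append") {
    q <- paste0(scaffold_aln$query_seq, linker)
    rows <- if (has_rows) paste0(scaffold_aln$aligned, pad) else character(0)
  } else {
    q <- paste0(linker, scaffold_aln$query_seq)
    rows <- if (has_rows) paste0(pad, scaffold_aln$aligned) else character(0)
  }
  alignment(scaffold_aln$query_id, q, scaffold_aln$ids, rows,
            provenance = scaffold_aln$provenance,
            source_tag = scaffold_aln$source_tag,
            metadata = scaffold_aln$metadata)
}

#' Merge scaffold and peptide alignments into a windowed MSA
#'
#' The core operation: two independently generated sub-alignments are merged
#' into one block-diagonal alignment over the chimeric query. Each scaffold
#' homolog keeps its aligned residues across the scaffold (and linker)
#' columns and carries gaps across the peptide window; each peptide homolog
#' carries gaps across the scaffold and linker windows. No columns are added
#' or removed, so the merged length equals the sum of the part lengths and no
#' spurious residue pairing across the fusion point can arise. The two
#' sub-queries are consumed into the single chimeric query row.
#'
#' @param scaffold_aln Insertion-stripped [alignment()] whose query equals
#'   the construct's scaffold part, optionally already carrying the linker
#'   on the peptide-facing side.
#' @param peptide_aln Insertion-stripped [alignment()] whose query equals
#'   the construct's peptide part.
#' @param construct A [make_fusion()] construct.
#' @return A `"windowed_alignment"` object: `construct`, `merged` (an
#'   [alignment()] whose query is the full chimeric sequence; row order is
#'   scaffold rows then peptide rows), `row_provenance`.
#' @export
build_windowed_msa <- function(scaffold_aln, peptide_aln, construct) {
  stopifnot(inherits(scaffold_aln, "chim_alignment"),
            inherits(peptide_aln, "chim_alignment"),
            inherits(construct, "fusion_construct"))
  if (any(grepl("[a-z]", c(scaffold_aln$aligned, peptide_aln$aligned)))) {
    stop("input alignments must be insertion-stripped before merging", call. = FALSE)
  }
  scaf_part <- fusion_part(construct, "scaffold")
  link_part <- fusion_part(construct, "linker")
  pep_part <- fusion_part(construct, "peptide")
  side <- if (construct$terminus == "C") "append" else "prepend"
  scaf_with_linker <- if (side == "append") paste0(scaf_part, link_part) else
    paste0(link_part, scaf_part)

  if (scaffold_aln$query_seq == scaf_part) {
    scaffold_aln <- incorporate_linker(scaffold_aln, link_part, side)
  } else if (scaffold_aln$query_seq != scaf_with_linker) {
    stop(sprintf("scaffold alignment query does not match the construct's scaffold window ('%s')",
                 construct$name), call. = FALSE)
  }
  if (peptide_aln$query_seq != pep_part) {
    stop(sprintf("peptide alignment query does not match the construct's peptide window ('%s')",
                 construct$name), call. = FALSE)
  }

  ns <- nchar(scaffold_aln$query_seq)  # scaffold + linker block
  np <- nchar(pep_part)
  pad <- function(rows, left, right) {
    if (!length(rows)) character(0) else paste0(.gaps(left), rows, .gaps(right))
  }
  if (construct$terminus == "C") {
    scaf_rows <- pad(scaffold_aln$aligned, 0L, np)
    pep_rows <- pad(peptide_aln$aligned, ns, 0L)
  } else {
    scaf_rows <- pad(scaffold_aln$aligned, np, 0L)
    pep_rows <- pad(peptide_aln$aligned, 0L, ns)
  }
  ids <- c(scaffold_aln$ids, peptide_aln$ids)
  merged <- alignment(
    query_id = construct$name, query_seq = construct$full_seq,
    ids = .dedup_ids(ids), aligned = c(scaf_rows, pep_rows),
    provenance = c(rep("scaffold", length(scaffold_aln$ids)),
                   rep("peptide", length(peptide_aln$ids))),
    source_tag = "windowed")
  structure(
    list(construct = construct, merged = merged,
         row_provenance = merged$provenance),
    class = "windowed_alignment"
  )
}

#' @export
print.windowed_alignment <- function(x, ...) {
  cat(sprintf("WindowedAlignment '%s': %d columns, depth %d (1 query + %d scaffold + %d peptide)\n",
              x$construct$name, nchar(x$merged$query_seq),
              length(x$merged$ids) + 1L,
              sum(x$row_provenance == "scaffold"),
              sum(x$row_provenance == "peptide")))
  invisible(x)
}

.window_cols <- function(w) if (w[1] >= w[2]) integer(0) else seq.int(w[1] + 1L, w[2])

#' Validate the block-diagonal structure of a windowed alignment
#'
#' Checks every invariant of the merged alignment: query equals the chimeric
#' full sequence, column count equals the sum of part lengths, depth equals
#' 1 + scaffold hits + peptide hits, and no row carries a residue in a
#' foreign window (scaffold rows must be all-gap across the peptide window;
#' peptide rows all-gap across scaffold and linker windows). A clean report
#' is required before export.
#'
#' @param waln A [build_windowed_msa()] result.
#' @return A `"windowed_report"` object with logical `clean` and a
#'   data.frame `violations` (row id, column, description).
#' @export
validate_windowed <- function(waln) {
  stopifnot(inherits(waln, "windowed_alignment"))
  fc <- waln$construct
  m <- waln$merged
  viol <- list()
  note <- function(id, column, what) {
    viol[[length(viol) + 1L]] <<- data.frame(
      row = id, column = column, problem = what, stringsAsFactors = FALSE)
  }
  if (m$query_seq != fc$full_seq) {
    note(m$query_id, NA_integer_, "merged query differs from chimeric full sequence")
  }
  expect_len <- nchar(fc$full_seq)
  if (any(nchar(m$aligned) != expect_len)) {
    note(m$ids[which(nchar(m$aligned) != expect_len)[1L]], NA_integer_,
         "row length differs from construct length")
  }
  pep_cols <- .window_cols(fc$peptide_window)
  scaf_cols <- c(.window_cols(fc$scaffold_window), .window_cols(fc$linker_window))
  for (i in seq_along(m$ids)) {
    chars <- strsplit(m$aligned[i], "")[[1]]
    foreign <- if (waln$row_provenance[i] == "scaffold") pep_cols else scaf_cols
    bad <- foreign[chars[foreign] != "-"]
    for (col in bad) note(m$ids[i], col, "residue in foreign window")
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(row = character(0), column = integer(0), problem = character(0),
               stringsAsFactors = FALSE)
  structure(list(clean = nrow(violations) == 0L, violations = violations,
                 depth = length(m$ids) + 1L),
            class = "windowed_report")
}

#' @export
print.windowed_report <- function(x, ...) {
  if (x$clean) cat(sprintf("Windowed alignment clean (depth %d)\n", x$depth))
  else {
    cat(sprintf("Windowed alignment INVALID: %d violation(s)\n", nrow(x$violations)))
    print(utils::head(x$violations, 10))
  }
  invisible(x)
}

#' Export a windowed alignment for a structure predictor
#'
#' Writes the merged alignment in the requested dialect. The ColabFold A3M
#' dialect prepends a `#<query length>\t1` cardinality header describing a
#' single-chain query; aligned FASTA writes plain records. Export refuses to
#' write an alignment whose validation report is not clean.
#'
#' @param waln A [build_windowed_msa()] result.
#' @param path Output file path.
#' @param dialect `"a3m_colabfold"` or `"aligned_fasta"`.
#' @return `path`, invisibly.
#' @export
export_for_predictor <- function(waln, path, dialect = c("a3m_colabfold", "aligned_fasta")) {
  stopifnot(inherits(waln, "windowed_alignment"))
  dialect <- match.arg(dialect)
  rep <- validate_windowed(waln)
  if (!rep$clean) {
    stop(paste0("refusing to export an invalid windowed alignment:\n",
                paste(utils::capture.output(print(rep)), collapse = "\n")),
         call. = FALSE)
  }
  m <- waln$merged
  if (dialect == "a3m_colabfold") {
    m$metadata <- sprintf("#%d\t1", nchar(m$query_seq))
  } else {
    m$metadata <- character(0)
  }
  write_a3m(m, path)
}
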