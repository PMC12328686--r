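#' Assemble a chimeric fusion construct
#'
#' Joins a scaffold protein and a peptide tag through a flexible Gly-Ser
#' linker, attaching the peptide at the chosen terminus of the scaffold.
#' A C-terminal fusion reads scaffold-linker-peptide; an N-terminal fusion
#' reads peptide-linker-scaffold. The residue windows of the three parts are
#' recorded as 0-based half-open intervals into the full sequence, so each
#' part can be recovered exactly and downstream evaluation can address the
#' peptide region alone.
#'
#' @param scaffold Scaffold amino-acid sequence (non-empty).
#' @param peptide Peptide amino-acid sequence (non-empty).
#' @param terminus `"C"` (peptide appended after the scaffold) or `"N"`
#'   (peptide prepended before the scaffold).
#' @param linker Linker sequence, default `"GS"`; may be empty.
#' @param scaffold_id,peptide_id Optional part labels used to build the
#'   construct name `scaffold_peptide_terminus`.
#' @return A `"fusion_construct"` object with fields `name`, `scaffold_id`,
#'   `peptide_id`, `terminus`, `linker_seq`, `full_seq`, and the three
#'   windows `scaffold_window`, `linker_window`, `peptide_window` (each an
#'   integer `c(start, end)`, 0-based half-open).
#' @export
make_fusion <- function(scaffold, peptide, terminus = c("C", "N"), linker = "GS",
                        scaffold_id = "scaffold", peptide_id = "peptide") {
  terminus <- match.arg(terminus)
  if (!is.character(scaffold) || nchar(scaffold) == 0L) {
    stop("scaffold sequence must be non-empty", call. = FALSE)
  }
  if (!is.character(peptide) || nchar(peptide) == 0L) {
    stop("peptide sequence must be non-empty", call. = FALSE)
  }
  for (s in list(scaffold = scaffold, peptide = peptide, linker = linker)) {
    if (!.valid_aa_seq(s)) stop("illegal character in sequence", call. = FALSE)
  }
  ns <- nchar(scaffold); nl <- nchar(linker); np <- nchar(peptide)
  if (terminus == "C") {
    full <- paste0(scaffold, linker, peptide)
    sw <- c(0L, ns); lw <- c(ns, ns + nl); pw <- c(ns + nl, ns + nl + np)
  } else {
    full <- paste0(peptide, linker, scaffold)
    pw <- c(0L, np); lw <- c(np, np + nl); sw <- c(np + nl, np + nl + ns)
  }
  structure(
    list(name = paste(scaffold_id, peptide_id, terminus, sep = "_"),
         scaffold_id = scaffold_id, peptide_id = peptide_id,
         terminus = terminus, linker_seq = linker, full_seq = full,
         scaffold_window = as.integer(sw), linker_window = as.integer(lw),
         peptide_window = as.integer(pw)),
    class = "fusion_construct"
  )
}

#' @export
print.fusion_construct <- function(x, ...) {
  cat(sprintf("FusionConstruct '%s' (%s-terminal): %d aa = scaffold[%d,%d) + linker[%d,%d) + peptide[%d,%d)\n",
              x$name, x$terminus, nchar(x$full_seq),
              x$scaffold_window[1], x$scaffold_window[2],
              x$linker_window[1], x$linker_window[2],
              x$peptide_window[1], x$peptide_window[2]))
  invisible(x)
}

#' Extract one part of a fusion construct
#'
#' @param fc A [make_fusion()] construct.
#' @param part `"scaffold"`, `"linker"` or `"peptide"`.
#' @return The part's amino-acid sequence (possibly empty for the linker).
#' @export
fusion_part <- function(fc, part = c("scaffold", "linker", "peptide")) {
  stopifnot(inherits(fc, "fusion_construct"))
  part <- match.arg(part)
  w <- fc[[paste0(part, "_window")]]
  if (w[1] == w[2]) return("")
  substr(fc$full_seq, w[1] + 1L, w[2])
}

#' Enumerate all scaffold x peptide x terminus fusion constructs
#'
#' Builds the full combinatorial dataset: every scaffold fused to every
#' peptide at each requested terminus (4 scaffolds x 51 peptides x both
#' termini gives the canonical 408-construct set). Order is stable:
#' scaffold-major, then peptide, then terminus; names follow
#' `scaffold_peptide_terminus` and are collision-checked.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param peptides Named character vector of peptide sequences.
#' @param termini Character vector drawn from `c("N", "C")`.
#' @param linker Linker sequence shared by all constructs.
#' @return List of `"fusion_construct"` objects of length
#'   `length(scaffolds) * length(peptides) * length(termini)`.
#' @export
enumerate_constructs <- function(scaffolds, peptides, termini = c("N", "C"),
                                 linker = "GS") {
  stopifnot(is.character(scaffolds), is.character(peptides))
  if (length(scaffolds) && is.null(names(scaffolds)) ||
      length(peptides) && is.null(names(peptides))) {
    stop("scaffolds and peptides must be named", call. = FALSE)
  }
  if (anyDuplicated(names(scaffolds)) || anyDuplicated(names(peptides))) {
    stop("duplicate names within scaffold or peptide set", call. = FALSE)
  }
  termini <- unique(match.arg(termini, c("N", "C"), several.ok = TRUE))
  out <- vector("list", length(scaffolds) * length(peptides) * length(termini))
  k <- 0L
  for (si in seq_along(scaffolds)) {
    for (pi in seq_along(peptides)) {
      for (tm in termini) {
        k <- k + 1L
        out[[k]] <- make_fusion(scaffolds[[si]], peptides[[pi]], terminus = tm,
                                linker = linker,
                                scaffold_id = names(scaffolds)[si],
                                peptide_id = names(peptides)[pi])
      }
    }
  }
  nms <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("construct name collision: '%s'", nms[duplicated(nms)][1L]),
         call. = FALSE)
  }
  out
}

.aa_identity_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      letters21 <- c(Biostrings::AA_STANDARD, "X")
      mm <- diag(1, length(letters21))
      dimnames(mm) <- list(letters21, letters21)
      m <<- mm
    }
    m
  }
})

#' Global pairwise identity and bidirectional coverage
#'
#' Aligns two sequences globally (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()]; match +1, mismatch 0, affine gap
#' penalties open 2 / extend 0.5) and summarizes the alignment as
#' `identity` = identical aligned residue pairs / aligned-pair count and
#' `coverage` = aligned-pair count / `min(nchar(a), nchar(b))`. Measuring
#' coverage against the shorter sequence makes an 80 % requirement bind in
#' both directions.
#'
#' @param a,b Non-empty amino-acid sequences.
#' @return Named numeric vector `c(identity=, coverage=)`, both in `[0, 1]`.
#' @export
pairwise_identity_coverage <- function(a, b) {
  if (!is.character(a) || nchar(a) == 0L || !is.character(b) || nchar(b) == 0L) {
    stop("both sequences must be non-empty", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .aa_identity_matrix(),
    gapOpening = 2, gapExtension = 0.5
  )
  sa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  paired <- sa != "-" & sb != "-"
  npair <- sum(paired)
  ident <- if (npair == 0L) 0 else sum(sa[paired] == sb[paired]) / npair
  cov <- npair / min(nchar(a), nchar(b))
  c(identity = ident, coverage = min(cov, 1))
}

#' Greedy centroid redundancy clustering
#'
#' Removes redundancy from a sequence set the way MMseqs2-style pipelines
#' do: sequences are processed in descending length order (ties broken
#' lexicographically by id); each sequence joins the first existing
#' representative with which it reaches both the identity and the
#' bidirectional-coverage threshold, otherwise it founds a new cluster.
#' The canonical setting is 50 % identity with 80 % coverage.
#'
#' @param seqs Named character vector of non-empty sequences.
#' @param identity_threshold Fraction in `(0, 1]`, default 0.5.
#' @param coverage_threshold Fraction in `(0, 1]`, default 0.8.
#' @return A `"cluster_result"` object: `representatives` (ids in creation
#'   order), `membership` (named character, id -> representative id),
#'   `details` (data.frame of member, representative, identity, coverage),
#'   and the thresholds used.
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.5, coverage_threshold = 0.8) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty", call. = FALSE)
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      coverage_threshold <= 0 || coverage_threshold > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character(0)
  membership <- character(0)
  det <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    assigned <- FALSE
    for (r in reps) {
      ic <- pairwise_identity_coverage(seqs[[i]], seqs[[r]])
      if (ic[["identity"]] >= identity_threshold &&
          ic[["coverage"]] >= coverage_threshold) {
        membership[id] <- r
        det[[length(det) + 1L]] <- data.frame(
          member = id, representative = r,
          identity = ic[["identity"]], coverage = ic[["coverage"]],
          stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      membership[id] <- id
      det[[length(det) + 1L]] <- data.frame(
        member = id, representative = id, identity = 1, coverage = 1,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(representatives = reps, membership = membership,
         details = do.call(rbind, det),
         identity_threshold = identity_threshold,
         coverage_threshold = coverage_threshold),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("ClusterResult: %d sequence(s) -> %d cluster(s) at identity >= %.2f, coverage >= %.2f\n",
              length(x$membership), length(x$representatives),
              x$identity_threshold, x$coverage_threshold))
  invisible(x)
}

#' Write a clustering result as TSV
#'
#' Columns: member, representative, identity, coverage.
#'
#' @param cl A [greedy_cluster()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(cl, path) {
  stopifnot(inherits(cl, "cluster_result"))
  utils::write.table(cl$details, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
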