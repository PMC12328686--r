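# Run code under a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards. All generators route through this so they
# are bit-reproducible from (config, seed) with no hidden global state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic alignment
#'
#' Draws a random query uniformly over the 20 standard amino acids, then
#' derives each homolog row by independent per-column substitution (uniform
#' over the other 19 letters) and gap conversion. Columns mutate i.i.d. with
#' no phylogeny: adequate for testing merge, coverage and identity
#' mechanics, not an evolutionary simulation.
#'
#' @param query_length Positive integer.
#' @param depth Total number of sequences including the query (`>= 1`).
#' @param substitution_rate,gap_rate Per-column rates in `[0, 1)`.
#' @param seed Integer seed; the generator is bit-reproducible from it.
#' @param query_id Label for the query record.
#' @param source_tag Stored on the resulting alignment.
#' @return An [alignment()] with `depth - 1` homolog rows.
#' @export
synth_msa <- function(query_length, depth, substitution_rate = 0.2, gap_rate = 0.1,
                      seed = 1L, query_id = "query", source_tag = "synthetic") {
  stopifnot(query_length >= 1L, depth >= 1L,
            substitution_rate >= 0, substitution_rate < 1,
            gap_rate >= 0, gap_rate < 1)
  with_seed(seed, {
    qchars <- sample(.AA20, query_length, replace = TRUE)
    rows <- character(0)
    if (depth > 1L) {
      rows <- vapply(seq_len(depth - 1L), function(i) {
        chars <- qchars
        sub_mask <- stats::runif(query_length) < substitution_rate
        if (any(sub_mask)) {
          chars[sub_mask] <- vapply(qchars[sub_mask], function(q) {
            sample(setdiff(.AA20, q), 1L)
          }, character(1))
        }
        gap_mask <- stats::runif(query_length) < gap_rate
        chars[gap_mask] <- "-"
        paste(chars, collapse = "")
      }, character(1))
    }
    ids <- if (depth > 1L) sprintf("%s_hom%03d", query_id, seq_len(depth - 1L)) else character(0)
    alignment(query_id, paste(qchars, collapse = ""), ids, rows,
              provenance = "native", source_tag = source_tag)
  })
}

#' Generate synthetic CA coordinates
#'
#' Builds a CA trace of an ideal alpha-helix (1.5 Angstrom rise, 100 degree
#' turn, 2.3 Angstrom radius) or an extended chain (3.8 Angstrom CA-CA
#' spacing), optionally perturbed by isotropic Gaussian noise.
#'
#' @param n_residues Number of residues (`>= 3`).
#' @param geometry `"ideal_helix"` or `"extended"`.
#' @param noise_sigma Standard deviation of isotropic coordinate noise
#'   in Angstrom (`>= 0`).
#' @param seed Integer seed.
#' @param sequence Optional amino-acid string of length `n_residues`; random
#'   when `NULL`.
#' @param plddt Optional per-residue confidence (scalar recycled or vector);
#'   default `NA`.
#' @return A `"structure_model"` object (single model, chain A).
#' @export
synth_coords <- function(n_residues, geometry = c("ideal_helix", "extended"),
                         noise_sigma = 0, seed = 1L, sequence = NULL, plddt = NA_real_) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 3L, noise_sigma >= 0)
  with_seed(seed, {
    i <- seq_len(n_residues) - 1L
    if (geometry == "ideal_helix") {
      theta <- i * 100 * pi / 180
      xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    } else {
      xyz <- cbind(3.8 * i, 0, 0)
    }
    if (noise_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(3L * n_residues, sd = noise_sigma), ncol = 3L)
    }
    aa <- if (is.null(sequence)) sample(.AA20, n_residues, replace = TRUE) else {
      stopifnot(nchar(sequence) == n_residues)
      strsplit(sequence, "")[[1]]
    }
    plddt <- rep_len(plddt, n_residues)
    residues <- data.frame(resno = seq_len(n_residues), aa = aa,
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           plddt = plddt, stringsAsFactors = FALSE)
    atoms <- data.frame(resno = residues$resno, elety = "CA",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    structure(list(model_index = 0L, chain_id = "A", n_models = 1L,
                   residues = residues, atoms = atoms),
              class = "structure_model")
  })
}

#' Extract a model's CA coordinate matrix
#'
#' @param model A `"structure_model"`.
#' @return Numeric `n x 3` matrix of CA coordinates.
#' @export
ca_coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$residues[, c("x", "y", "z")])
}

#' Generate sequence families with a known partition
#'
#' Plants `n_families` unrelated progenitor sequences (independent uniform
#' draws, so cross-family identity sits near 1/20) and derives each member
#' by point mutations at rate `1 - within_identity`. The known partition
#' serves as ground truth for clustering-recovery tests.
#'
#' @param n_families,members_per_family Positive integers.
#' @param within_identity Expected member-progenitor identity, larger than
#'   the ~0.05 cross-family background.
#' @param length Sequence length (default 60).
#' @param seed Integer seed.
#' @return Named character vector; names `fam<i>_m<j>` encode the true
#'   family partition.
#' @export
planted_families <- function(n_families, members_per_family, within_identity = 0.9,
                             length = 60L, seed = 1L) {
  stopifnot(n_families >= 1L, members_per_family >= 1L,
            within_identity > 0.2, within_identity <= 1)
  with_seed(seed, {
    out <- character(0)
    for (f in seq_len(n_families)) {
      prog <- sample(.AA20, length, replace = TRUE)
      for (m in seq_len(members_per_family)) {
        chars <- prog
        if (m > 1L) {
          mut <- stats::runif(length) < (1 - within_identity)
          if (any(mut)) {
            chars[mut] <- vapply(prog[mut], function(q) sample(setdiff(.AA20, q), 1L),
                                 character(1))
          }
        }
        out[sprintf("fam%d_m%d", f, m)] <- paste(chars, collapse = "")
      }
    }
    out
  })
}

#' Write a structure model as a PDB file
#'
#' Emits fixed-width CA `ATOM` records (confidence in the B-factor column),
#' wrapping each model of an ensemble in `MODEL`/`ENDMDL` records when more
#' than one model is supplied. Files round-trip through [read_structure()].
#'
#' @param models A `"structure_model"` or list of them (an ensemble; all
#'   must share residue numbering).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "structure_model")))
  multi <- length(models) > 1L
  lines <- character(0)
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", mi))
    r <- m$residues
    b <- ifelse(is.na(r$plddt), 0, r$plddt)
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(r)), vapply(r$aa, bio3d::aa123, character(1)),
      m$chain_id, r$resno, r$x, r$y, r$z, 1.0, b))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
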