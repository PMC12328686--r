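#' Read a structure model from PDB or mmCIF
#'
#' Parses a coordinate file with bio3d and returns one model as a
#' residue-indexed CA trace plus backbone atoms. For multi-MODEL NMR
#' depositions, `model_index` selects the ensemble member (0 = first model,
#' the conventional evaluation reference). Per-residue confidence (pLDDT for
#' predictor output) is read from the B-factor column on the 0-100 scale.
#' Residues lacking a CA atom are excluded with a warning.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param model_index 0-based model index into the ensemble; default 0.
#' @param chain Chain identifier; default the file's first chain.
#' @return A `"structure_model"` object: `model_index`, `chain_id`,
#'   `residues` (data.frame: `resno`, `aa`, `x`, `y`, `z`, `plddt`) and
#'   `atoms` (backbone N/CA/C/O coordinates for the same model).
#' @export
read_structure <- function(path, model_index = 0L, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  }
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  if (model_index < 0L || model_index >= n_models) {
    stop(sprintf("model index %d not available; file has models 0..%d",
                 model_index, n_models - 1L), call. = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' not found in '%s'", chain, path), call. = FALSE)
  coords <- xyz[model_index + 1L, ]

  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]  # drop altloc duplicates
  all_res <- unique(at$resno)
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca)) {
    warning(sprintf("residue(s) without CA atom excluded: %s",
                    paste(missing_ca, collapse = ", ")), call. = FALSE)
  }
  ca_xyz <- matrix(coords[bio3d::atom2xyz(match(ca$eleno, pdb$atom$eleno))],
                   ncol = 3L, byrow = TRUE)
  residues <- data.frame(
    resno = ca$resno,
    aa = bio3d::aa321(ca$resid),
    x = ca_xyz[, 1], y = ca_xyz[, 2], z = ca_xyz[, 3],
    plddt = ca$b,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    stop(sprintf("non-finite coordinates in '%s'", path), call. = FALSE)
  }
  bb <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  bb_xyz <- matrix(coords[bio3d::atom2xyz(match(bb$eleno, pdb$atom$eleno))],
                   ncol = 3L, byrow = TRUE)
  atoms <- data.frame(resno = bb$resno, elety = bb$elety,
                      x = bb_xyz[, 1], y = bb_xyz[, 2], z = bb_xyz[, 3],
                      stringsAsFactors = FALSE)
  structure(list(model_index = as.integer(model_index), chain_id = chain,
                 n_models = n_models, residues = residues, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("StructureModel: chain %s, model %d/%d, %d residue(s)\n",
              x$chain_id, x$model_index, x$n_models, nrow(x$residues)))
  invisible(x)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R P + t` onto `Q` over paired coordinates, via the SVD of the covariance
#' of the centred sets. A reflection in the raw SVD solution is corrected by
#' flipping the sign of the smallest singular direction, so the returned
#' rotation always has determinant +1 even for mirror-image inputs.
#'
#' @param P,Q Numeric `n x 3` matrices of paired coordinates, `n >= 3`.
#' @return A `"superposition"` object: `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom), `n_atoms`, and
#'   `ill_conditioned` (TRUE when the paired set is degenerate, e.g.
#'   collinear, so the rotation about the degenerate axis is arbitrary;
#'   the RMSD itself is still the minimum).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (ncol(P) != 3L || ncol(Q) != 3L) stop("coordinates must be n x 3", call. = FALSE)
  if (nrow(P) != nrow(Q)) stop("P and Q must pair the same number of points", call. = FALSE)
  if (nrow(P) < 3L) stop("at least 3 paired points are required", call. = FALSE)
  if (any(!is.finite(P)) || any(!is.finite(Q))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  # degenerate (rank-deficient) point sets leave a rotation axis unconstrained
  ill <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  rotP <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((rotP - Qc)^2)))
  translation <- as.numeric(cq - R %*% cp)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_atoms = nrow(P), ill_conditioned = ill),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: RMSD %.4f A%s\n", x$n_atoms, x$rmsd,
              if (x$ill_conditioned) " (ill-conditioned)" else ""))
  invisible(x)
}

.model_window <- function(model, window) {
  sel <- model$residues$resno >= window[1] & model$residues$resno <= window[2]
  model$residues[sel, , drop = FALSE]
}

#' Residue-number window of a fusion part
#'
#' Converts a construct's 0-based half-open part window into the inclusive
#' 1-based residue-number interval used by coordinate files whose residues
#' are numbered 1..L along the chimeric sequence.
#'
#' @param fc A [make_fusion()] construct.
#' @param part `"scaffold"`, `"linker"` or `"peptide"`.
#' @return Integer `c(first_resno, last_resno)`.
#' @export
fusion_window_resno <- function(fc, part = c("scaffold", "linker", "peptide")) {
  stopifnot(inherits(fc, "fusion_construct"))
  part <- match.arg(part)
  w <- fc[[paste0(part, "_window")]]
  if (w[1] >= w[2]) stop(sprintf("'%s' window is empty", part), call. = FALSE)
  c(w[1] + 1L, w[2])
}

#' Region RMSD between a predicted window and a reference structure
#'
#' Extracts the stated residue window from the predicted model, pairs its
#' residues one-to-one (in order) with the reference residues, and returns
#' the Kabsch-minimized RMSD over that pairing alone. The superposition is
#' local to the window: the peptide region is fitted onto the reference
#' peptide independently of the scaffold, so scaffold coordinates cannot
#' influence the value. Correspondence is positional, not by residue
#' number, because fusion constructs renumber residues; a sequence mismatch
#' between paired residues triggers a warning naming the positions.
#'
#' @param predicted,reference `"structure_model"` objects.
#' @param window Inclusive residue-number interval `c(lo, hi)` in the
#'   predicted model (see [fusion_window_resno()]).
#' @param reference_window Optional interval in the reference; default all
#'   reference residues.
#' @param atoms `"CA"` (default) or `"backbone"` (N, CA, C, O).
#' @return RMSD in Angstrom (scalar).
#' @export
region_rmsd <- function(predicted, reference, window, reference_window = NULL,
                        atoms = c("CA", "backbone")) {
  stopifnot(inherits(predicted, "structure_model"),
            inherits(reference, "structure_model"))
  atoms <- match.arg(atoms)
  pw <- .model_window(predicted, window)
  if (!nrow(pw)) stop("window contains no residues of the predicted model", call. = FALSE)
  n_expect <- window[2] - window[1] + 1L
  if (nrow(pw) != n_expect) {
    missing <- setdiff(seq.int(window[1], window[2]), pw$resno)
    stop(sprintf("unmapped residue(s) in predicted window: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rw <- if (is.null(reference_window)) reference$residues else
    .model_window(reference, reference_window)
  if (nrow(rw) != nrow(pw)) {
    stop(sprintf("window pairs %d predicted residue(s) with %d reference residue(s)",
                 nrow(pw), nrow(rw)), call. = FALSE)
  }
  mism <- which(pw$aa != rw$aa)
  if (length(mism)) {
    warning(sprintf("sequence mismatch at paired position(s): %s",
                    paste(mism, collapse = ", ")), call. = FALSE)
  }
  if (atoms == "CA") {
    P <- as.matrix(pw[, c("x", "y", "z")])
    Q <- as.matrix(rw[, c("x", "y", "z")])
  } else {
    P <- .backbone_coords(predicted, pw$resno)
    Q <- .backbone_coords(reference, rw$resno)
    if (nrow(P) != nrow(Q)) {
      stop("backbone atom sets differ between predicted and reference windows",
           call. = FALSE)
    }
  }
  kabsch_superpose(P, Q)$rmsd
}

.backbone_coords <- function(model, resnos) {
  sel <- model$atoms[model$atoms$resno %in% resnos, , drop = FALSE]
  ord <- order(match(sel$resno, resnos), match(sel$elety, c("N", "CA", "C", "O")))
  as.matrix(sel[ord, c("x", "y", "z")])
}

#' Mean per-residue confidence (pLDDT) over a window
#'
#' @param predicted A `"structure_model"` with confidence values (B-factor
#'   column of predictor output, 0-100 scale).
#' @param window Inclusive residue-number interval `c(lo, hi)`.
#' @return Arithmetic mean confidence over the window, in `[0, 100]`.
#' @export
region_plddt <- function(predicted, window) {
  stopifnot(inherits(predicted, "structure_model"))
  pw <- .model_window(predicted, window)
  if (!nrow(pw)) stop("window contains no residues", call. = FALSE)
  if (any(is.na(pw$plddt))) stop("missing confidence values in window", call. = FALSE)
  mean(pw$plddt)
}

#' Summarize in-context vs isolated RMSD across constructs
#'
#' Builds the per-construct ratio of the RMSD of a target predicted in
#' scaffold context to its RMSD predicted in isolation, plus grouped mean
#' ratios over any of the columns `scaffold`, `terminus`, `msa_mode` that
#' are present. When exactly two MSA modes are supplied, the report also
#' gives the fraction of constructs where the first mode's in-context RMSD
#' is strictly lower than the second's.
#'
#' @param pairs data.frame with columns `construct`, `rmsd_in_context`,
#'   `rmsd_isolated`, and optionally `scaffold`, `terminus`, `msa_mode`.
#' @param compare Character vector of two mode labels (default
#'   `c("windowed", "standard")`) used for the strictly-lower fraction when
#'   `msa_mode` is present.
#' @return A list: `per_construct` (input plus `ratio`; the ratio is `NA`
#'   where `rmsd_isolated == 0`, and such rows are excluded from
#'   summaries), `summaries` (named list of grouped mean ratios), and
#'   `strictly_lower_fraction` (or `NA` when modes are absent).
#' @export
rmsd_ratio_report <- function(pairs, compare = c("windowed", "standard")) {
  stopifnot(is.data.frame(pairs),
            all(c("construct", "rmsd_in_context", "rmsd_isolated") %in% names(pairs)))
  pairs$ratio <- ifelse(pairs$rmsd_isolated > 0,
                        pairs$rmsd_in_context / pairs$rmsd_isolated, NA_real_)
  ok <- !is.na(pairs$ratio)
  summaries <- list()
  for (g in intersect(c("scaffold", "terminus", "msa_mode"), names(pairs))) {
    summaries[[g]] <- if (any(ok)) {
      agg <- stats::aggregate(pairs$ratio[ok],
                              by = list(group = pairs[[g]][ok]), FUN = mean)
      stats::setNames(agg, c(g, "mean_ratio"))
    } else {
      stats::setNames(data.frame(character(0), numeric(0)), c(g, "mean_ratio"))
    }
  }
  frac <- NA_real_
  if ("msa_mode" %in% names(pairs) && all(compare %in% pairs$msa_mode)) {
    a <- pairs[pairs$msa_mode == compare[1L], c("construct", "rmsd_in_context")]
    b <- pairs[pairs$msa_mode == compare[2L], c("construct", "rmsd_in_context")]
    m <- merge(a, b, by = "construct", suffixes = c("_a", "_b"))
    if (nrow(m)) frac <- mean(m$rmsd_in_context_a < m$rmsd_in_context_b)
  }
  list(per_construct = pairs, summaries = summaries,
       strictly_lower_fraction = frac)
}
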