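random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("Kabsch superposition handles congruent and transformed inputs exactly", {
  set.seed(2)
  P <- matrix(stats::rnorm(36), ncol = 3)
  sp <- kabsch_superpose(P, P)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp$translation, rep(0, 3), tolerance = 1e-9)

  R <- random_rotation(); tr <- c(4, -2, 7)
  Q <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  sp2 <- kabsch_superpose(P, Q)
  expect_lt(sp2$rmsd, 1e-9)
  expect_equal(sp2$rotation, R, tolerance = 1e-6)
  expect_equal(sp2$translation, tr, tolerance = 1e-6)
})

test_that("Kabsch input validation", {
  P <- matrix(stats::rnorm(30), ncol = 3)
  expect_error(kabsch_superpose(P, P[1:9, ]), "pair")
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  Pbad <- P; Pbad[1, 1] <- NA
  expect_error(kabsch_superpose(Pbad, P), "finite")
  # collinear sets are computed but flagged
  line <- cbind(1:5 * 3.8, 0, 0)
  expect_true(kabsch_superpose(line, line)$ill_conditioned)
})

test_that("rotations are always proper, including on mirror-image inputs", {
  set.seed(3)
  for (i in 1:30) {
    P <- matrix(stats::rnorm(3 * sample(4:15, 1)), ncol = 3)
    Q <- P %*% diag(c(-1, 1, 1))  # reflected copy
    sp <- kabsch_superpose(P, Q)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9)
    # and for generic pairs
    sp2 <- kabsch_superpose(P, matrix(stats::rnorm(length(P)), ncol = 3))
    expect_equal(det(sp2$rotation), 1, tolerance = 1e-9)
  }
})

test_that("analytic RMSD matches the quaternion-grid brute-force oracle", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    P <- matrix(stats::rnorm(3 * n, sd = 3), ncol = 3)
    Q <- P %*% t(random_rotation()) +
      matrix(stats::rnorm(3 * n, sd = 0.5), ncol = 3)
    k <- kabsch_superpose(P, Q)$rmsd
    b <- brute_force_rmsd(P, Q, seed = 1000 + i)
    expect_lt(abs(k - b), 1e-4)
    expect_lte(k, b + 1e-9)  # the analytic answer is never beaten
  }
})

test_that("RMSD is invariant under rigid motion of both sets and never exceeds the raw pairing", {
  set.seed(6)
  for (i in 1:15) {
    n <- sample(5:15, 1)
    P <- matrix(stats::rnorm(3 * n, sd = 2), ncol = 3)
    Q <- matrix(stats::rnorm(3 * n, sd = 2), ncol = 3)
    base <- kabsch_superpose(P, Q)$rmsd
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 10)
    move <- function(M) M %*% t(R) + matrix(tr, n, 3, byrow = TRUE)
    expect_equal(kabsch_superpose(move(P), move(Q))$rmsd, base, tolerance = 1e-9)
    raw <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(base, raw + 1e-12)
  }
})

test_that("PDB reading selects ensemble models and transcribes confidence", {
  m1 <- synth_coords(10, "ideal_helix", seed = 1, plddt = 87.5)
  m2 <- synth_coords(10, "ideal_helix", noise_sigma = 1.0, seed = 2, plddt = 55)
  m3 <- synth_coords(10, "ideal_helix", noise_sigma = 2.0, seed = 3, plddt = 30)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(list(m1, m2, m3), f)

  s0 <- read_structure(f, model_index = 0)
  expect_equal(s0$n_models, 3L)
  expect_equal(nrow(s0$residues), 10L)
  expect_equal(s0$residues$plddt[1], 87.5)
  expect_equal(as.matrix(s0$residues[, c("x", "y", "z")]), ca_coords(m1),
               ignore_attr = TRUE, tolerance = 1e-3)
  # the first MODEL block is the evaluation reference
  s1 <- read_structure(f, model_index = 1)
  expect_gt(kabsch_superpose(ca_coords(s1), ca_coords(s0))$rmsd, 0.1)
  expect_error(read_structure(f, model_index = 3), "models 0..2")

  fsingle <- tempfile(fileext = ".pdb")
  write_structure_pdb(m1, fsingle)
  expect_equal(read_structure(fsingle)$n_models, 1L)
  expect_error(read_structure(fsingle, model_index = 1), "models 0..0")
})

test_that("region RMSD is local to the window and blind to the scaffold", {
  # fused model: 20-residue "scaffold" + 8-residue helical "peptide"
  pep_ref <- synth_coords(8, "ideal_helix", seed = 10, sequence = "ACDEFGHI")
  scaffold_part <- synth_coords(20, "extended", seed = 11)
  fused <- scaffold_part
  shift <- function(m, dx, resoff) {
    m$residues$resno <- m$residues$resno + resoff
    m$atoms$resno <- m$atoms$resno + resoff
    m$residues[, c("x", "y", "z")] <- m$residues[, c("x", "y", "z")] + dx
    m$atoms[, c("x", "y", "z")] <- m$atoms[, c("x", "y", "z")] + dx
    m
  }
  pep_in_context <- shift(pep_ref, 30, 20L)
  fused$residues <- rbind(fused$residues, pep_in_context$residues)
  fused$atoms <- rbind(fused$atoms, pep_in_context$atoms)

  # geometrically identical peptide region: RMSD 0
  expect_lt(region_rmsd(fused, pep_ref, c(21, 28)), 1e-9)

  # perturbing the scaffold leaves the peptide-window RMSD unchanged
  fused2 <- fused
  sel <- fused2$residues$resno <= 20
  fused2$residues[sel, c("x", "y", "z")] <-
    fused2$residues[sel, c("x", "y", "z")] + matrix(stats::rnorm(60, sd = 5), ncol = 3)
  expect_equal(region_rmsd(fused2, pep_ref, c(21, 28)),
               region_rmsd(fused, pep_ref, c(21, 28)))
})

test_that("region RMSD on a displaced-terminus helix agrees with the oracle", {
  ref <- synth_coords(8, "ideal_helix", seed = 20, sequence = "ACDEFGHI")
  pred <- ref
  pred$residues[8, "z"] <- pred$residues[8, "z"] + 3  # 3 A axial displacement
  got <- region_rmsd(pred, ref, c(1, 8))
  want <- brute_force_rmsd(ca_coords(pred), ca_coords(ref), seed = 77)
  expect_equal(got, want, tolerance = 1e-4)
  expect_gt(got, 0.5)
})

test_that("region RMSD validates windows and flags sequence mismatches", {
  ref <- synth_coords(8, "ideal_helix", seed = 30, sequence = "ACDEFGHI")
  pred <- synth_coords(8, "ideal_helix", seed = 30, sequence = "ACDEFGHI")
  expect_error(region_rmsd(pred, ref, c(10, 17)), "no residues")
  expect_error(region_rmsd(pred, ref, c(5, 12)), "unmapped")
  pred_mut <- synth_coords(8, "ideal_helix", seed = 30, sequence = "ACDEFGHW")
  expect_warning(region_rmsd(pred_mut, ref, c(1, 8)), "mismatch")
  # mapping is positional, not by residue numbering
  pred_renum <- pred
  pred_renum$residues$resno <- pred_renum$residues$resno + 100L
  pred_renum$atoms$resno <- pred_renum$atoms$resno + 100L
  expect_lt(region_rmsd(pred_renum, ref, c(101, 108)), 1e-9)
})

test_that("window mean pLDDT", {
  m <- synth_coords(10, "ideal_helix", seed = 40, plddt = 90)
  expect_equal(region_plddt(m, c(1, 10)), 90)
  m$residues$plddt <- c(rep(80, 5), rep(100, 5))
  expect_equal(region_plddt(m, c(1, 10)), 90)
  expect_equal(region_plddt(m, c(1, 5)), 80)
  expect_error(region_plddt(m, c(11, 12)), "no residues")
  m$residues$plddt[3] <- NA
  expect_error(region_plddt(m, c(1, 10)), "missing")
})

test_that("RMSD ratio report: ratios, grouping and the strictly-lower fraction", {
  df <- data.frame(construct = c("a", "b"), rmsd_in_context = c(2.0, 1.0),
                   rmsd_isolated = c(0.5, 1.0))
  rep1 <- rmsd_ratio_report(df)
  expect_equal(rep1$per_construct$ratio, c(4.0, 1.0))

  # zero isolated RMSD is undefined, excluded from summaries
  df0 <- data.frame(construct = "z", rmsd_in_context = 1, rmsd_isolated = 0,
                    scaffold = "s1")
  rep0 <- rmsd_ratio_report(df0)
  expect_true(is.na(rep0$per_construct$ratio))
  expect_equal(nrow(rep0$summaries$scaffold), 0L)

  # 10 constructs, 7 with windowed strictly lower than standard
  cons <- sprintf("c%02d", 1:10)
  wn <- c(rep(0.5, 7), rep(2.0, 3))
  st <- rep(1.0, 10)
  df2 <- data.frame(construct = rep(cons, 2),
                    msa_mode = rep(c("windowed", "standard"), each = 10),
                    rmsd_in_context = c(wn, st),
                    rmsd_isolated = 0.5)
  rep2 <- rmsd_ratio_report(df2)
  expect_equal(rep2$strictly_lower_fraction, 0.7)

  # all equal: ratios 1, strictly-lower fraction 0
  df3 <- data.frame(construct = rep(cons, 2),
                    msa_mode = rep(c("windowed", "standard"), each = 10),
                    rmsd_in_context = 1, rmsd_isolated = 1)
  rep3 <- rmsd_ratio_report(df3)
  expect_true(all(rep3$per_construct$ratio == 1))
  expect_equal(rep3$strictly_lower_fraction, 0)
})
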