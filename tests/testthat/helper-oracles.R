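# Independent oracles used to cross-check package computations.
# Both are deliberately brute-force and share no code with the implementation.

# Exhaustively enumerate every global alignment of two short sequences under
# match +1 / mismatch 0 and affine gap cost (open + extend * gap_length per
# gap run, matching the package's documented scoring). Returns the optimal
# score and the identity/coverage of every optimal alignment.
enumerate_global_alignments <- function(a, b, open = 2, extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, layouts = list())
  recurse <- function(i, j, sa, sb, score, last) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score + 1e-9) {
        best$score <<- score
        best$layouts <<- list(list(sa = sa, sb = sb))
      } else if (abs(score - best$score) <= 1e-9) {
        best$layouts[[length(best$layouts) + 1L]] <<- list(sa = sa, sb = sb)
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1L, j + 1L, c(sa, av[i]), c(sb, bv[j]),
              score + as.numeric(av[i] == bv[j]), "m")
    }
    if (i <= length(av)) {
      cost <- if (last == "ga") extend else open + extend
      recurse(i + 1L, j, c(sa, av[i]), c(sb, "-"), score - cost, "ga")
    }
    if (j <= length(bv)) {
      cost <- if (last == "gb") extend else open + extend
      recurse(i, j + 1L, c(sa, "-"), c(sb, bv[j]), score - cost, "gb")
    }
  }
  recurse(1L, 1L, character(0), character(0), 0, "start")
  stats <- lapply(best$layouts, function(l) {
    paired <- l$sa != "-" & l$sb != "-"
    npair <- sum(paired)
    c(identity = if (npair) sum(l$sa[paired] == l$sb[paired]) / npair else 0,
      coverage = npair / min(length(av), length(bv)))
  })
  list(score = best$score, stats = stats)
}

# Brute-force minimum RMSD over rotations: dense random start set in
# axis-angle space (direction uniform on the sphere, angle uniform on
# [0, pi]), the best starts polished by Nelder-Mead. Translation is handled
# by centroid removal, which is optimal for any fixed rotation. No SVD.
brute_force_rmsd <- function(P, Q, n_starts = 150, n_refine = 6, seed = 1234) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot_of <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) {
    R <- rot_of(v)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  starts <- rbind(
    matrix(0, 1, 3),
    t(replicate(n_starts, {
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      d * stats::runif(1, 0, pi)
    }))
  )
  vals <- apply(starts, 1, obj)
  keep <- order(vals)[seq_len(n_refine)]
  best <- Inf
  for (k in keep) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

# Small convenience used across test files: a reproducible random alignment.
random_alignment <- function(seed, max_len = 40, max_depth = 8) {
  len <- 3L + (seed * 7L) %% max_len
  depth <- 1L + (seed * 13L) %% max_depth
  synth_msa(query_length = len, depth = depth,
            substitution_rate = 0.25, gap_rate = 0.15, seed = seed,
            query_id = sprintf("q%03d", seed))
}
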