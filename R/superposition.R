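#' Optimal global pairwise alignment of two sequences
#'
#' Affine-gap Needleman-Wunsch global alignment (via
#' `Biostrings::pairwiseAlignment`), returning the residue-position
#' correspondence rather than the aligned strings. A gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param seq_a,seq_b one-letter amino-acid strings.
#' @param sub_matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties (positive costs), defaults
#'   11 and 1.
#' @param type `"global"` (default; end gaps penalised) or `"overlap"`
#'   (end gaps free - the right convention when one model is a trimmed
#'   fragment of the other, where penalised end gaps can buy a spurious
#'   terminal pair).
#' @return an `alignment_trace`: list with `pairs` (two-column integer
#'   matrix of aligned positions, strictly increasing in both columns),
#'   `identity_fraction` (identities / aligned columns), `score`, and
#'   `aligned` (the two gapped strings).
#' @export
pairwise_align <- function(seq_a, seq_b, sub_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           type = c("global", "overlap")) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  type <- match.arg(type)
  mat <- get_submatrix(sub_matrix)
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = type,
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  # overlap alignments clip unaligned ends: offset positions accordingly
  trace_from_aligned(al_a, al_b, score = Biostrings::score(pa),
                     offset_a = BiocGenerics::start(Biostrings::pattern(pa)) - 1L,
                     offset_b = BiocGenerics::start(Biostrings::subject(pa)) - 1L)
}

#' @noRd
get_submatrix <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @noRd
trace_from_aligned <- function(al_a, al_b, score, offset_a = 0L, offset_b = 0L) {
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  pos_a <- cumsum(ca != "-") + offset_a
  pos_b <- cumsum(cb != "-") + offset_b
  both <- ca != "-" & cb != "-"
  pairs <- cbind(a = pos_a[both], b = pos_b[both])
  idf <- if (sum(both) == 0L) 0 else mean(ca[both] == cb[both])
  structure(list(pairs = pairs, identity_fraction = idf, score = score,
                 aligned = c(al_a, al_b)),
            class = "alignment_trace")
}

#' @export
print.alignment_trace <- function(x, ...) {
  cat(sprintf("<alignment_trace: %d pairs, identity %.1f%%, score %.1f>\n",
              nrow(x$pairs), 100 * x$identity_fraction, x$score))
  invisible(x)
}

#' Three-state secondary structure from a Calpha trace
#'
#' Geometric assignment from the i to i+3 Calpha distance: about 5.1
#' Angstrom in an alpha helix, above 9 in an extended strand. Used by
#' the sequence-independent superposition mode; deliberately coarse.
#'
#' @param ca_xyz n x 3 matrix of Calpha coordinates in chain order.
#' @return character vector of length n over `{"H", "E", "C"}`.
#' @export
assign_ss3 <- function(ca_xyz) {
  ca_xyz <- as.matrix(ca_xyz)
  n <- nrow(ca_xyz)
  ss <- rep("C", n)
  if (n >= 4L) {
    d13 <- sqrt(rowSums((ca_xyz[1:(n - 3L), , drop = FALSE] -
                         ca_xyz[4:n, , drop = FALSE])^2))
    ss[1:(n - 3L)][d13 >= 4.2 & d13 <= 6.2] <- "H"
    ss[1:(n - 3L)][d13 >= 9.0] <- "E"
    ss[(n - 2L):n] <- ss[n - 3L]
  }
  ss
}

#' Global alignment with secondary-structure-augmented scoring
#'
#' Affine-gap global alignment where each match position scores its
#' substitution-matrix value plus `ss_bonus` when the two residues share
#' the same three-state secondary-structure assignment. With
#' `ss_bonus = 0` and the default gap costs it reduces to ordinary
#' Needleman-Wunsch. Gap penalties default to a relaxed setting, which
#' suits structure-guided correspondence at low sequence identity.
#'
#' @param seq_a,seq_b one-letter sequences.
#' @param ss_a,ss_b secondary-structure strings/vectors over
#'   `{"H","E","C"}`, same lengths as the sequences.
#' @param ss_bonus score bonus per matched-state column (default 2).
#' @param gap_open,gap_extend gap penalties (default 5 and 0.5).
#' @param sub_matrix substitution matrix name or matrix.
#' @param type `"global"` (default) or `"overlap"` (end gaps free).
#' @return an `alignment_trace`.
#' @export
align_with_ss <- function(seq_a, seq_b, ss_a, ss_b, ss_bonus = 2,
                          gap_open = 5, gap_extend = 0.5,
                          sub_matrix = "BLOSUM62",
                          type = c("global", "overlap")) {
  type <- match.arg(type)
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(ss_a) == 1L) ss_a <- strsplit(ss_a, "")[[1]]
  if (length(ss_b) == 1L) ss_b <- strsplit(ss_b, "")[[1]]
  stopifnot(length(ss_a) == length(a), length(ss_b) == length(b))
  mat <- get_submatrix(sub_matrix)
  n <- length(a); m <- length(b)
  S <- mat[a, b, drop = FALSE] + ss_bonus * outer(ss_a, ss_b, "==")
  go <- gap_open; ge <- gap_extend
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L); Ix <- M; Iy <- M
  M[1L, 1L] <- 0
  if (type == "overlap") {
    Ix[2L:(n + 1L), 1L] <- 0
    Iy[1L, 2L:(m + 1L)] <- 0
  } else {
    Ix[2L:(n + 1L), 1L] <- -(go + ge * seq_len(n))
    Iy[1L, 2L:(m + 1L)] <- -(go + ge * seq_len(m))
  }
  # traceback pointers: 1 = from M, 2 = from Ix, 3 = from Iy
  tM <- matrix(0L, n + 1L, m + 1L); tIx <- tM; tIy <- tM
  for (i in 2L:(n + 1L)) {
    Mi1 <- M[i - 1L, ]; Ixi1 <- Ix[i - 1L, ]; Iyi1 <- Iy[i - 1L, ]
    # Ix: gap in b (vertical) - no dependency along j, vectorise
    cand1 <- Mi1 - (go + ge); cand2 <- Ixi1 - ge; cand3 <- Iyi1 - (go + ge)
    Ix[i, ] <- pmax(cand1, cand2, cand3)
    tIx[i, ] <- ifelse(Ix[i, ] == cand2, 2L, ifelse(Ix[i, ] == cand1, 1L, 3L))
    Mi <- M[i, ]; Iyi <- Iy[i, ]; Ixi <- Ix[i, ]
    tMi <- tM[i, ]; tIyi <- tIy[i, ]
    for (j in 2L:(m + 1L)) {
      s <- S[i - 1L, j - 1L]
      best <- Mi1[j - 1L]; ptr <- 1L
      if (Ixi1[j - 1L] > best) { best <- Ixi1[j - 1L]; ptr <- 2L }
      if (Iyi1[j - 1L] > best) { best <- Iyi1[j - 1L]; ptr <- 3L }
      Mi[j] <- best + s; tMi[j] <- ptr
      c1 <- Mi[j - 1L] - (go + ge); c2 <- Iyi[j - 1L] - ge
      c3 <- Ixi[j - 1L] - (go + ge)
      if (c2 >= c1 && c2 >= c3) { Iyi[j] <- c2; tIyi[j] <- 3L }
      else if (c1 >= c3) { Iyi[j] <- c1; tIyi[j] <- 1L }
      else { Iyi[j] <- c3; tIyi[j] <- 2L }
    }
    M[i, ] <- Mi; Iy[i, ] <- Iyi
    tM[i, ] <- tMi; tIy[i, ] <- tIyi
  }
  cell_best <- function(i, j) {
    v <- c(M[i, j], Ix[i, j], Iy[i, j])
    k <- which.max(v)
    c(v[k], k)
  }
  if (type == "overlap") {
    # free trailing gaps: end anywhere on the last row or column
    cand <- rbind(cbind(n + 1L, seq_len(m + 1L)),
                  cbind(seq_len(n), m + 1L))
    vals <- apply(cand, 1L, function(ij) cell_best(ij[1L], ij[2L]))
    k <- which.max(vals[1L, ])
    ie <- cand[k, 1L]; je <- cand[k, 2L]
    score <- vals[1L, k]; state <- vals[2L, k]
    ra <- if (ie <= n) a[ie:n] else character(0)
    rb <- if (je <= m) b[je:m] else character(0)
    if (ie <= n) rb <- c(rep("-", n - ie + 1L), rb)
    if (je <= m) ra <- c(ra, rep("-", m - je + 1L))
  } else {
    v <- cell_best(n + 1L, m + 1L)
    score <- v[1L]; state <- v[2L]
    ie <- n + 1L; je <- m + 1L
    ra <- character(0); rb <- character(0)
  }
  # traceback; along the borders only one state is reachable
  i <- ie; j <- je
  while (i > 1L || j > 1L) {
    if (i == 1L) state <- 3L else if (j == 1L) state <- 2L
    if (state == 1L) {
      ptr <- tM[i, j]
      ra <- c(a[i - 1L], ra); rb <- c(b[j - 1L], rb)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ptr <- tIx[i, j]
      ra <- c(a[i - 1L], ra); rb <- c("-", rb)
      i <- i - 1L
    } else {
      ptr <- tIy[i, j]
      ra <- c("-", ra); rb <- c(b[j - 1L], rb)
      j <- j - 1L
    }
    state <- ptr
  }
  trace_from_aligned(paste(ra, collapse = ""), paste(rb, collapse = ""),
                     score = score)
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets, by centroid subtraction, SVD of the
#' covariance matrix and determinant sign correction. The returned
#' transform maps `target` coordinates onto the `query` frame:
#' `y' = y R^T + t` (see [apply_transform()]).
#'
#' @param query,target n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return list with `transform` (a `rigid_transform`: `rotation` 3x3
#'   with `det = +1`, `translation` length-3) and `rmsd` after applying
#'   the transform.
#' @export
kabsch <- function(query, target) {
  X <- as.matrix(query); Y <- as.matrix(target)
  stopifnot(ncol(X) == 3L, ncol(Y) == 3L)
  if (nrow(X) != nrow(Y)) stopf("coordinate sets differ in length (%d vs %d)",
                                nrow(X), nrow(Y))
  if (nrow(X) < 3L) stopf("kabsch needs at least 3 point pairs (got %d)", nrow(X))
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  C <- crossprod(Yc, Xc)                      # 3x3 covariance
  sv <- svd(C)
  if (sv$d[2L] <= 1e-8 * max(sv$d[1L], 1e-8))
    stopf("degenerate geometry: point pairs are (near-)collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.vector(cx - R %*% cy)
  tr <- new_rigid_transform(R, t)
  fitted <- apply_transform(tr, Y)
  list(transform = tr, rmsd = sqrt(mean(rowSums((fitted - X)^2))))
}

#' @noRd
new_rigid_transform <- function(rotation, translation) {
  structure(list(rotation = rotation, translation = as.vector(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform` (from [kabsch()] or
#'   [superpose()]).
#' @param xyz n x 3 coordinate matrix (or length-3 vector).
#' @return transformed coordinates, same shape.
#' @export
apply_transform <- function(transform, xyz) {
  v <- is.null(dim(xyz))
  xyz <- matrix(as.numeric(xyz), ncol = 3L, byrow = v)
  out <- xyz %*% t(transform$rotation) +
    matrix(transform$translation, nrow(xyz), 3L, byrow = TRUE)
  if (v) as.vector(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f)>\n",
              ang, x$translation[1L], x$translation[2L], x$translation[3L]))
  invisible(x)
}

#' Superpose a homolog structure onto a query model
#'
#' Builds a Calpha residue correspondence by global sequence alignment,
#' then fits it by iterative Kabsch superposition with outlier
#' rejection: pairs whose residual exceeds `reject_cutoff` are dropped
#' and the fit recomputed, up to `max_cycles` cycles or until no pair is
#' dropped.
#'
#' The correspondence mode is gated on sequence identity, following the
#' usual convention for structure-superposition tools: above the gate
#' (default 30% identity) a plain sequence alignment suffices
#' (`sequence_dependent`); at or below it the alignment is augmented
#' with secondary-structure-state matching and relaxed gap penalties
#' (`sequence_independent`), which keeps the correspondence meaningful
#' between distant homologs.
#'
#' @param query,target `structure3d` objects (the transform maps
#'   `target` onto `query`).
#' @param mode `"auto"` (default), `"sequence_dependent"` or
#'   `"sequence_independent"`.
#' @param chain_query,chain_target chain selections; default first
#'   polymer chain.
#' @param identity_gate identity fraction above which auto mode picks
#'   the sequence-dependent alignment (default 0.30).
#' @param reject_cutoff outlier-rejection residual cutoff in Angstrom
#'   (default 2.0). Use `Inf` to disable rejection.
#' @param max_cycles maximum fit cycles (default 5).
#' @param ss_bonus secondary-structure bonus for the
#'   sequence-independent mode.
#' @return a `superposition_result`: list with `transform`, `rmsd`
#'   (over retained pairs), `rmsd_all` (all aligned pairs under the
#'   final transform), `n_pairs_initial`, `n_pairs_retained`,
#'   `n_cycles`, `mode`, `identity_fraction`, and `pairs` (retained
#'   residue numbers, columns `resno_query`, `resno_target`).
#' @export
superpose <- function(query, target, mode = c("auto", "sequence_dependent",
                                              "sequence_independent"),
                      chain_query = NULL, chain_target = NULL,
                      identity_gate = 0.30, reject_cutoff = 2.0,
                      max_cycles = 5L, ss_bonus = 2) {
  mode <- match.arg(mode)
  ca_q <- ca_table(query, chain_query)
  ca_t <- ca_table(target, chain_target)
  if (nrow(ca_q) < 3L || nrow(ca_t) < 3L)
    stopf("superposition needs at least 3 Calpha atoms per structure")
  seq_q <- paste(ca_q$aa, collapse = "")
  seq_t <- paste(ca_t$aa, collapse = "")
  # identity for the mode gate comes from the global alignment (gap
  # columns are not counted, so a trimmed fragment is not penalised);
  # the coordinate correspondence uses the end-gap-free alignment, which
  # cannot buy spurious terminal pairs
  identity_fraction <- pairwise_align(seq_q, seq_t)$identity_fraction
  plain <- pairwise_align(seq_q, seq_t, type = "overlap")
  if (mode == "auto")
    mode <- if (identity_fraction > identity_gate)
      "sequence_dependent" else "sequence_independent"
  trace <- if (mode == "sequence_dependent") plain else
    align_with_ss(seq_q, seq_t,
                  assign_ss3(ca_q[, c("x", "y", "z")]),
                  assign_ss3(ca_t[, c("x", "y", "z")]),
                  ss_bonus = ss_bonus, type = "overlap")
  pairs <- trace$pairs
  X <- as.matrix(ca_q[pairs[, 1L], c("x", "y", "z")])
  Y <- as.matrix(ca_t[pairs[, 2L], c("x", "y", "z")])
  keep <- rep(TRUE, nrow(pairs))
  n_cycles <- 0L
  fit <- NULL
  repeat {
    if (sum(keep) < 3L) stopf("superposition failed: %d pair(s) survive rejection",
                              sum(keep))
    fit <- kabsch(X[keep, , drop = FALSE], Y[keep, , drop = FALSE])
    n_cycles <- n_cycles + 1L
    res <- sqrt(rowSums((apply_transform(fit$transform, Y) - X)^2))
    worse <- keep & res > reject_cutoff
    # never reject below a fittable pair set: a grossly divergent pair
    # of structures keeps its (large) RMSD instead of failing
    if (!any(worse) || n_cycles >= max_cycles ||
        sum(keep & !worse) < 3L) break
    keep <- keep & !worse
  }
  res_all <- sqrt(rowSums((apply_transform(fit$transform, Y) - X)^2))
  out <- list(
    transform = fit$transform,
    rmsd = fit$rmsd,
    rmsd_all = sqrt(mean(res_all^2)),
    n_pairs_initial = nrow(pairs),
    n_pairs_retained = sum(keep),
    n_cycles = n_cycles,
    mode = mode,
    identity_fraction = identity_fraction,
    pairs = data.frame(resno_query = ca_q$resno[pairs[keep, 1L]],
                       resno_target = ca_t$resno[pairs[keep, 2L]]),
    residuals = data.frame(resno_query = ca_q$resno[pairs[, 1L]],
                           resno_target = ca_t$resno[pairs[, 2L]],
                           residual = res_all, retained = keep)
  )
  class(out) <- "superposition_result"
  out
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(paste0("<superposition_result: mode %s, rmsd %.3f A over %d/%d pairs",
                     " (%d cycle(s)), identity %.1f%%>\n"),
              x$mode, x$rmsd, x$n_pairs_retained, x$n_pairs_initial,
              x$n_cycles, 100 * x$identity_fraction))
  invisible(x)
}
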