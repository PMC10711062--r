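# Column matching by Tucker congruence.
#
# Rotated solutions are permutation- and sign-indeterminate, so before any
# comparison with a reference the estimated factors must be matched to the
# reference factors. match_columns() finds the column permutation (and sign
# flips) maximizing the summed absolute congruence: exact enumeration of all
# q! permutations for q <= 7, greedy assignment refined by pairwise swaps
# beyond that.

congruence_matrix <- function(a, b) {
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  na[na == 0] <- 1e-300; nb[nb == 0] <- 1e-300
  crossprod(a, b) / outer(na, nb)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

# Maximize sum_j |C[perm[j], j]| over permutations: perm[j] gives the column
# of `a` assigned to reference column j of `b`.
solve_assignment <- function(absC) {
  q <- ncol(absC)
  if (q <= 7) {
    perms <- all_permutations(q)
    scores <- apply(perms, 1, function(p) sum(absC[cbind(p, seq_len(q))]))
    return(perms[which.max(scores), ])
  }
  # greedy: repeatedly take the globally best remaining (row, col) pair
  perm <- integer(q)
  m <- absC
  for (i in seq_len(q)) {
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    perm[idx[2]] <- idx[1]
    m[idx[1], ] <- -Inf
    m[, idx[2]] <- -Inf
  }
  # 2-opt refinement
  repeat {
    improved <- FALSE
    for (i in seq_len(q - 1)) for (j in (i + 1):q) {
      cur <- absC[perm[i], i] + absC[perm[j], j]
      alt <- absC[perm[j], i] + absC[perm[i], j]
      if (alt > cur + 1e-12) {
        tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  perm
}

match_columns <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  cc <- congruence_matrix(a, b)
  perm <- solve_assignment(abs(cc))
  signs <- ifelse(cc[cbind(perm, seq_len(ncol(b)))] < 0, -1, 1)
  list(perm = perm, signs = signs,
       congruence = cc[cbind(perm, seq_len(ncol(b)))] * signs)
}

#' Align a rotated solution to a reference loading pattern
#'
#' Chooses the column permutation and sign reflections of `pattern` that
#' maximize the summed absolute Tucker congruence with `reference`, and
#' applies them consistently to the pattern columns and to the rows and
#' columns of the factor inter-correlation matrix. Required before any
#' bias or RMS comparison with population values (or with a total-sample
#' solution in the stability analysis).
#'
#' @param pattern Estimated loading pattern (matrix or data frame).
#' @param phi Estimated q x q factor inter-correlation matrix.
#' @param reference Reference loading pattern of the same shape.
#' @return A list with the aligned `pattern` and `phi`, plus the applied
#'   `perm` and `signs` (as acting on the original columns).
#' @export
align_to_population <- function(pattern, phi, reference) {
  pattern <- as_loading_matrix(pattern)
  reference <- as_loading_matrix(reference)
  phi <- as.matrix(phi)
  stopifnot(all(dim(pattern) == dim(reference)),
            nrow(phi) == ncol(pattern), ncol(phi) == ncol(pattern))
  mt <- match_columns(pattern, reference)
  d <- diag(mt$signs, length(mt$signs))
  out_pattern <- pattern[, mt$perm, drop = FALSE] %*% d
  out_phi <- d %*% phi[mt$perm, mt$perm, drop = FALSE] %*% d
  dimnames(out_pattern) <- dimnames(reference)
  dimnames(out_phi) <- list(colnames(reference), colnames(reference))
  list(pattern = out_pattern, phi = out_phi, perm = mt$perm, signs = mt$signs)
}
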