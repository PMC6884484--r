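#' Sparse-representation fusion configuration
#'
#' @param epsilon residual tolerance for the sparse solve; `NULL` (default)
#'   uses the relative rule `0.01 * ||PT||_2` per target patch.
#' @param max_support sparsity cap: maximum number of dictionary atoms.
#' @param nonnegative restrict the pursuit to positively correlated atoms and
#'   clip fitted coefficients at zero (with refit).
#' @param branch number of candidate first atoms explored by the pursuit
#'   (best completion wins); 1 recovers a single greedy pass. Default 8,
#'   which makes the solver exhaustive over atom pairs for dictionaries of
#'   up to 8 columns.
#' @return An object of class `srlf_config`.
#' @export
srlf_config <- function(epsilon = NULL, max_support = 5L, nonnegative = FALSE,
                        branch = 8L) {
  if (!is.null(epsilon) && epsilon < 0) stop("epsilon must be >= 0")
  if (max_support < 1) stop("max_support must be >= 1")
  if (branch < 1) stop("branch must be >= 1")
  structure(list(epsilon = epsilon, max_support = as.integer(max_support),
                 nonnegative = isTRUE(nonnegative), branch = as.integer(branch)),
            class = "srlf_config")
}

# One pursuit run. Atom selection maximizes the residual-norm reduction of a
# least-squares refit (computed in closed form by projecting the candidate
# columns off the current support), which keeps each step optimal given the
# atoms already chosen. `first` forces the initial atom (used for branching).
.oomp_run <- function(pt, D, eps, cap, nonneg, first = NULL) {
  m <- ncol(D)
  alpha <- numeric(m)
  support <- integer(0)
  banned <- logical(m)
  resid <- pt
  rn <- sqrt(sum(resid^2))
  Q <- NULL
  while (rn > eps && length(support) < cap) {
    B <- if (is.null(Q)) D else D - Q %*% crossprod(Q, D)
    den <- colSums(B^2)
    proj <- as.numeric(crossprod(B, resid))
    gain <- ifelse(den > 1e-12, proj^2 / den, 0)
    gain[support] <- 0
    gain[banned] <- 0
    if (nonneg) gain[proj <= 0] <- 0
    if (!is.null(first)) {
      j <- first
      first <- NULL
      if (gain[j] <= 0) break
    } else {
      if (max(gain) <= 1e-14) break
      j <- which.max(gain)
    }
    prev_alpha <- alpha
    prev_support <- support
    prev_rn <- rn
    support <- c(support, j)
    qrS <- qr(D[, support, drop = FALSE])
    coefs <- qr.coef(qrS, pt)
    coefs[is.na(coefs)] <- 0
    if (nonneg) {
      while (length(support) && any(coefs < 0)) {
        banned[support[coefs < 0]] <- TRUE
        support <- support[coefs >= 0]
        coefs <- if (length(support)) {
          cf <- qr.coef(qr(D[, support, drop = FALSE]), pt)
          cf[is.na(cf)] <- 0
          cf
        } else numeric(0)
      }
      qrS <- if (length(support)) qr(D[, support, drop = FALSE]) else NULL
    }
    alpha[] <- 0
    if (length(support)) alpha[support] <- coefs
    resid <- as.numeric(pt - D %*% alpha)
    rn_new <- sqrt(sum(resid^2))
    if (rn_new > prev_rn + 1e-12) {   # nonnegative clipping made things worse
      alpha <- prev_alpha
      support <- prev_support
      break
    }
    improved <- prev_rn - rn_new > 1e-12
    rn <- rn_new
    Q <- if (length(support)) qr.Q(qrS) else NULL
    if (!improved) break
  }
  list(alpha = alpha, residual_norm = rn, support = support)
}

#' Greedy sparse coding of a target patch over an atlas-patch dictionary
#'
#' Approximates the L0 problem
#' `min ||alpha||_0 s.t. ||PT - D alpha||_2 <= epsilon` by an optimized
#' matching pursuit: at every step the atom whose least-squares refit reduces
#' the residual the most is added (computed in closed form by projecting
#' candidates off the current support), until the residual norm reaches
#' `epsilon` or the support reaches `max_support`. Because the very first pick
#' dominates the quality of any greedy pursuit, the `branch` most promising
#' first atoms are each completed and the best solution wins (ties prefer the
#' higher-ranked first atom). With `branch >= m` and `max_support <= 2` the
#' search is exhaustive over atom pairs.
#'
#' In nonnegative mode only positively correlated atoms are eligible and any
#' atom whose fitted coefficient turns negative is removed (and banned) with a
#' refit, so the returned coefficients are nonnegative.
#'
#' @param target numeric vector or `gplf_patch` (the target patch PT).
#' @param dictionary a `patch_library` or a numeric matrix whose columns are
#'   atlas patch vectors.
#' @param cfg an [srlf_config()].
#' @return An object of class `sparse_solution`: `alpha` (length-m coefficient
#'   vector), `residual_norm` and `support` (indices of nonzero alpha).
#' @export
sparse_code <- function(target, dictionary, cfg = srlf_config()) {
  pt <- if (inherits(target, "gplf_patch")) target$vector else as.numeric(target)
  D <- if (inherits(dictionary, "patch_library")) dictionary$columns else as.matrix(dictionary)
  if (!ncol(D)) stop("empty dictionary")
  if (nrow(D) != length(pt)) stop("target length differs from dictionary column length")
  m <- ncol(D)
  ptn <- sqrt(sum(pt^2))
  eps <- if (is.null(cfg$epsilon)) 0.01 * ptn else cfg$epsilon
  cap <- min(cfg$max_support, m)
  zero <- structure(list(alpha = numeric(m), residual_norm = ptn,
                         support = integer(0)), class = "sparse_solution")
  if (ptn <= eps) return(zero)

  den <- colSums(D^2)
  proj <- as.numeric(crossprod(D, pt))
  gain <- ifelse(den > 1e-12, proj^2 / den, 0)
  if (cfg$nonnegative) gain[proj <= 0] <- 0
  firsts <- order(-gain)
  firsts <- firsts[gain[firsts] > 0]
  firsts <- firsts[seq_len(min(cfg$branch, length(firsts)))]
  if (!length(firsts)) return(zero)

  good_enough <- max(eps, 1e-12 * ptn)
  best <- NULL
  for (f in firsts) {
    sol <- .oomp_run(pt, D, eps, cap, cfg$nonnegative, first = f)
    if (is.null(best) || sol$residual_norm < best$residual_norm - 1e-10 * max(1, ptn))
      best <- sol
    if (best$residual_norm <= good_enough) break
  }
  structure(list(alpha = best$alpha, residual_norm = best$residual_norm,
                 support = which(best$alpha != 0)),
            class = "sparse_solution")
}

#' Sparse-representation label fusion at one voxel
#'
#' The sparse coefficients act as vote weights (negatives carry no vote mass)
#' over the centre labels of the dictionary patches.
#'
#' @param target target patch (`gplf_patch` or numeric vector).
#' @param library a `patch_library`.
#' @param cfg an [srlf_config()].
#' @return A `vote_result` (see [weighted_vote()]).
#' @export
srlf_fuse_voxel <- function(target, library, cfg = srlf_config()) {
  stopifnot(inherits(library, "patch_library"))
  sol <- sparse_code(target, library, cfg)
  weighted_vote(pmax(sol$alpha, 0), library$center_labels)
}
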