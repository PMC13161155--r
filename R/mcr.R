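# Multivariate curve resolution by alternating least squares (MCR-ALS):
# factorizes the spectra matrix X (cells x channels) into non-negative
# concentrations C (cells x k) and pure-component spectra S (k x channels)
# under the bilinear model X ~ C %*% S. Rank is suggested from the singular
# value spectrum, initial pure spectra come from SIMPLISMA pure-variable
# selection, and each ALS subproblem is solved exactly under the
# non-negativity constraint (which guarantees a monotone residual).

# Solve min ||A %*% F - B||_F subject to F >= 0, column by column.
# The unconstrained normal-equation solution is used where it is already
# feasible; violating columns fall back to exact Lawson-Hanson NNLS.
nnls_multi <- function(A, B) {
  AtA <- crossprod(A)
  AtB <- crossprod(A, B)
  F <- tryCatch(solve(AtA, AtB),
                error = function(e) pracma::pinv(AtA) %*% AtB)
  bad <- which(apply(F, 2L, function(v) any(v < -1e-10)))
  for (j in bad) F[, j] <- pracma::lsqnonneg(A, B[, j])$x
  F[F < 0] <- 0
  F
}

#' Rank diagnostics from the singular value spectrum
#'
#' Suggests the chemical rank at the largest elbow of the log singular
#' value spectrum (the maximum of its second difference, i.e. the sharpest
#' signal-to-noise bend); the full singular spectrum is returned for manual
#' inspection and override.
#'
#' @param x Non-empty numeric matrix.
#' @return A `rank_diagnostics` list: `singular_values` (descending),
#'   `suggested_rank`, `method`.
#' @export
select_rank_svd <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("empty matrix", call. = FALSE)
  s <- svd(x, nu = 0L, nv = 0L)$d
  if (length(s) < 3L) {
    rank <- 1L
  } else {
    s_clamped <- pmax(s, max(s) * 1e-15)
    rank <- which.max(diff(log(s_clamped), differences = 2L))
  }
  structure(list(singular_values = s, suggested_rank = as.integer(rank),
                 method = "elbow"), class = "rank_diagnostics")
}

#' SIMPLISMA pure-variable initial estimates
#'
#' Classical determinant-based SIMPLISMA: purity of a variable is its
#' standard deviation over its mean offset by the noise term
#' `alpha = (noise_percent/100) * max(mean)`; after each selection the
#' purity is deflated by the determinant-based independence weight against
#' the already-chosen variables (computed on the length-scaled
#' correlation-around-origin matrix), so successive pure variables are
#' mutually independent. In `"channel"` mode pure wavenumber channels are
#' selected and their intensity columns act as initial concentration
#' profiles, converted to spectral estimates by non-negative least squares;
#' in `"sample"` mode pure rows (spectra) are selected and used directly.
#'
#' @param x Cells x channels matrix.
#' @param n_components Number of components to select.
#' @param noise_percent Noise level as a percentage (default 10).
#' @param mode `"channel"` (default) or `"sample"`.
#' @return A `simplisma_init` list: `S` (k x channels, rows max-normalized),
#'   `pure_variables` (selected indices), `mode`.
#' @export
simplisma <- function(x, n_components, noise_percent = 10,
                      mode = c("channel", "sample")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  work <- if (mode == "channel") x else t(x)
  p <- ncol(work)
  if (n_components > p) {
    stop("parameter error: n_components exceeds the number of variables",
         call. = FALSE)
  }
  n <- nrow(work)
  mu <- colMeans(work)
  sig <- sqrt(colMeans(sweep(work, 2L, mu)^2))
  alpha <- (noise_percent / 100) * max(mu)
  p1 <- sig / (mu + alpha)
  lambda <- sqrt(mu^2 + (sig + alpha)^2)
  z <- sweep(work, 2L, lambda * sqrt(n), `/`)
  coo <- crossprod(z)
  chosen <- integer(0L)
  for (step in seq_len(n_components)) {
    w <- vapply(seq_len(p), function(j) {
      ix <- c(j, chosen)
      det(coo[ix, ix, drop = FALSE])
    }, numeric(1L))
    purity <- p1 * pmax(w, 0)
    purity[chosen] <- -Inf
    chosen <- c(chosen, which.max(purity))
  }
  if (mode == "channel") {
    c_init <- work[, chosen, drop = FALSE]
    S <- nnls_multi(c_init, work)
  } else {
    # pure variables are samples; their spectra are used directly
    S <- x[chosen, , drop = FALSE]
  }
  mx <- apply(S, 1L, max)
  mx[mx <= 0] <- 1
  S <- S / mx
  structure(list(S = unname(as.matrix(S)), pure_variables = chosen,
                 mode = mode), class = "simplisma_init")
}

#' Fit MCR-ALS with non-negativity constraints
#'
#' Alternates exact non-negative least squares for C (given S) and S (given
#' C); after each full iteration the residual standard deviation
#' `||X - C S||_F / sqrt(n p)` is computed, and the loop stops when its
#' relative change drops below `tol` (default 0.1%) or `max_iter` is
#' reached. Scale ambiguity is fixed by max-normalizing each pure spectrum
#' and absorbing the scale into C; components are reported in descending
#' total-concentration order.
#'
#' @param x Cells x channels data matrix.
#' @param s_init Initial pure spectra, k x channels matrix or a
#'   [simplisma()] result.
#' @param max_iter Maximum ALS iterations (default 50).
#' @param tol Relative residual-standard-deviation change for convergence
#'   (default 0.001, i.e. 0.1%).
#' @return An `mcr_model`: `C` (cells x k, >= 0), `S` (k x channels, >= 0,
#'   unit row maxima), `explained_variance`, `lack_of_fit`, `rsd_history`,
#'   `n_iter`, `converged`.
#' @export
mcr_als_fit <- function(x, s_init, max_iter = 50L, tol = 0.001) {
  x <- as.matrix(x)
  if (inherits(s_init, "simplisma_init")) s_init <- s_init$S
  S <- as.matrix(s_init)
  if (ncol(S) != ncol(x)) {
    stop("shape error: s_init channels do not match the data", call. = FALSE)
  }
  if (any(apply(S, 1L, function(r) all(r == 0)))) {
    stop("initialization error: all-zero row in s_init", call. = FALSE)
  }
  np <- length(x)
  rsd_prev <- Inf
  rsd_history <- numeric(0L)
  converged <- FALSE
  n_iter <- 0L
  C <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    C <- t(nnls_multi(t(S), t(x)))
    S <- nnls_multi(C, x)
    stopifnot(all(C >= 0), all(S >= 0))
    rsd <- sqrt(sum((x - C %*% S)^2) / np)
    rsd_history <- c(rsd_history, rsd)
    if (is.finite(rsd_prev) && rsd_prev > 0 &&
        abs(rsd_prev - rsd) / rsd_prev < tol) {
      converged <- TRUE
      break
    }
    if (rsd == 0) { converged <- TRUE; break }
    rsd_prev <- rsd
  }
  # fix scale: unit row maxima in S, scale absorbed into C
  mx <- apply(S, 1L, max)
  live <- mx > 0
  S[live, ] <- S[live, , drop = FALSE] / mx[live]
  C[, live] <- sweep(C[, live, drop = FALSE], 2L, mx[live], `*`)
  ord <- order(colSums(C), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  C <- C[, ord, drop = FALSE]
  ss_tot <- sum(x^2)
  ss_res <- sum((x - C %*% S)^2)
  structure(list(C = C, S = S,
                 explained_variance = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 lack_of_fit = if (ss_tot > 0) sqrt(ss_res / ss_tot) else NA_real_,
                 rsd_history = rsd_history, n_iter = n_iter,
                 converged = converged), class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf(
    "<mcr_model> %d components, explained variance %.2f%%, %d iterations (%s)\n",
    nrow(x$S), 100 * x$explained_variance, x$n_iter,
    if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' Explained variance of a bilinear factorization
#'
#' `1 - ||X - C S||_F^2 / ||X||_F^2`; `NA` for an all-zero matrix.
#'
#' @param x Data matrix.
#' @param model An `mcr_model` (or any list with `C` and `S`).
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
explained_variance <- function(x, model) {
  x <- as.matrix(x)
  if (nrow(model$C) != nrow(x) || ncol(model$S) != ncol(x)) {
    stop("shape error: model dimensions do not match the matrix",
         call. = FALSE)
  }
  ss_tot <- sum(x^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((x - model$C %*% model$S)^2) / ss_tot
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match estimated components to reference components
#'
#' Resolves the permutation ambiguity of MCR: finds the assignment of
#' estimated to reference components maximizing total cosine similarity
#' (exhaustive over all permutations for k <= 6, greedy beyond).
#'
#' @param s_est,s_ref k x channels matrices with equal component counts.
#' @return List: `permutation` (index p such that `s_est[p[i], ]` matches
#'   `s_ref[i, ]`) and `similarities` (cosine, per reference component).
#' @export
match_components <- function(s_est, s_ref) {
  s_est <- as.matrix(s_est); s_ref <- as.matrix(s_ref)
  k <- nrow(s_ref)
  if (nrow(s_est) != k) {
    stop("shape error: component counts differ", call. = FALSE)
  }
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sim[i, j] <- cosine_sim(s_est[i, ], s_ref[j, ])
  }
  if (k <= 6L) {
    perms <- pracma::perms(seq_len(k))
    totals <- apply(perms, 1L, function(p) sum(sim[cbind(p, seq_len(k))]))
    best <- perms[which.max(totals), ]
  } else {
    best <- integer(k)
    taken <- logical(k)
    for (j in seq_len(k)) {
      cand <- sim[, j]
      cand[taken] <- -Inf
      best[j] <- which.max(cand)
      taken[best[j]] <- TRUE
    }
  }
  list(permutation = as.integer(best),
       similarities = sim[cbind(best, seq_len(k))])
}

#' Group comparison of resolved component abundances
#'
#' For each MCR component, compares the concentration column between the
#' two response groups: group means and SDs plus a two-sided test chosen by
#' the normality / variance-homogeneity rule (see [group_compare()]) with
#' significance stars.
#'
#' @param model An `mcr_model`.
#' @param meta Metadata data frame with a `group` column (CR/NR), one row
#'   per cell, aligned with `model$C`.
#' @param component_names Optional component labels.
#' @return Data frame: one row per component with means, SDs, `p_value`,
#'   `test_used` and `stars`.
#' @export
compare_component_scores <- function(model, meta,
                                     component_names = NULL) {
  groups <- unique(meta$group[meta$group %in% c("CR", "NR")])
  if (length(groups) != 2L) {
    stop("label error: both CR and NR must be present", call. = FALSE)
  }
  k <- ncol(model$C)
  if (is.null(component_names)) component_names <- paste0("component_", seq_len(k))
  rows <- lapply(seq_len(k), function(j) {
    a <- model$C[meta$group == "CR", j]
    b <- model$C[meta$group == "NR", j]
    cmp <- group_compare(a, b)
    data.frame(component = component_names[j],
               mean_CR = mean(a), sd_CR = stats::sd(a),
               mean_NR = mean(b), sd_NR = stats::sd(b),
               p_value = cmp$p_value, test_used = cmp$test_used,
               stars = significance_stars(cmp$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
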