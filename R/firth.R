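# Bias-reduced (Jeffreys-prior / Firth) binomial GLM for allele-dose
# genetic-interaction incidence data.  The model is
#   logit p = b0 + b_tbx5 * tbx5_dose + b_gene * gene_dose + b_int * (dose product)
# with tbx5_dose in {0, 1} and gene_dose in {0, 1, 2}.  The Jeffreys penalty
# 1/2 log det I(beta) keeps estimates finite under complete separation
# (e.g. a zero-event control group), which ordinary ML cannot.

#' Genotype incidence counts table
#'
#' @param df data.frame with columns `genotype_label`, `tbx5_dose` (0/1),
#'   `gene_dose` (0/1/2), `affected`, `total`.
#' @return validated object of class `genotype_counts` (a data.frame).
#' @export
genotype_counts <- function(df) {
  need <- c("genotype_label", "tbx5_dose", "gene_dose", "affected", "total")
  assert_that(all(need %in% names(df)), "validation_error",
              "counts need columns: %s", paste(need, collapse = ", "))
  assert_that(all(df$tbx5_dose %in% 0:1), "validation_error",
              "tbx5_dose must be 0 or 1")
  assert_that(all(df$gene_dose %in% 0:2), "validation_error",
              "gene_dose must be 0, 1 or 2")
  assert_that(all(df$affected >= 0 & df$affected <= df$total),
              "validation_error", "need 0 <= affected <= total")
  structure(as.data.frame(df)[need], class = c("genotype_counts", "data.frame"))
}

#' Read / write genotype counts as CSV
#'
#' CSV dialect: UTF-8, comma separated, `.` decimal, mandatory header with
#' columns `genotype_label, tbx5_dose, gene_dose, affected, total`.
#'
#' @param path CSV file path.
#' @export
read_genotype_counts <- function(path) {
  genotype_counts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_genotype_counts
#' @param counts a [genotype_counts()] table.
#' @export
write_genotype_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' Allele-dose design matrix
#'
#' Columns `(intercept, tbx5_dose, gene_dose, tbx5_dose * gene_dose)`, one
#' row per genotype group; `interaction = FALSE` drops the product column.
#'
#' @param counts a [genotype_counts()] table.
#' @param interaction include the interaction column (default TRUE).
#' @return numeric matrix.
#' @export
design_matrix <- function(counts, interaction = TRUE) {
  counts <- genotype_counts(counts)
  assert_that(nrow(counts) >= 1L, "validation_error", "empty counts table")
  X <- cbind(intercept = 1,
             tbx5_dose = counts$tbx5_dose,
             gene_dose = counts$gene_dose)
  if (interaction) {
    X <- cbind(X, interaction = counts$tbx5_dose * counts$gene_dose)
  }
  X
}

# Penalized (Jeffreys-prior) binomial log-likelihood.
penalized_loglik <- function(beta, X, y, n) {
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
              (n - y) * stats::plogis(-eta, log.p = TRUE))
  W <- n * mu * (1 - mu)
  I <- crossprod(X, X * W)
  ld <- determinant(I, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  ll + 0.5 * as.numeric(ld$modulus)
}

#' Fit a bias-reduced binomial logistic regression (Firth / Jeffreys prior)
#'
#' Maximizes `l(beta) + 0.5 * log det I(beta)` by Newton iteration on the
#' Firth-modified score
#' `U*(beta) = X' (y - n mu + h (1/2 - mu))`, where `h` are the hat-diagonal
#' leverages, with step-halving on the penalized log-likelihood.  Wald
#' z-statistics and p-values use the penalized-information covariance
#' `I(beta)^-1`.
#'
#' @param X design matrix (full column rank on the observed groups).
#' @param affected,totals event and trial counts per row of `X`.
#' @param tol convergence tolerance on the score and the relative penalized
#'   log-likelihood change (default 1e-8; max score 1e-6).
#' @param max_iter Newton iteration cap.
#' @return object of class `firth_fit`: `coefficients`, `vcov`, `se`, `z`,
#'   `p`, `loglik_penalized`, `iterations`, `converged`.
#' @export
fit_firth <- function(X, affected, totals, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(affected)
  n <- as.numeric(totals)
  assert_that(nrow(X) == length(y) && length(y) == length(n),
              "validation_error", "X, affected, totals sizes disagree")
  assert_that(qr(X)$rank == ncol(X), "singular_design",
              "design matrix is rank deficient on the observed groups")
  p <- ncol(X)
  beta <- rep(0, p)
  ll_old <- penalized_loglik(beta, X, y, n)
  converged <- FALSE
  it <- 0L
  max_score <- Inf
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- n * mu * (1 - mu)
    I <- crossprod(X, X * W)
    Iinv <- solve(I)
    h <- W * rowSums((X %*% Iinv) * X)
    U <- drop(crossprod(X, y - n * mu + h * (0.5 - mu)))
    max_score <- max(abs(U))
    delta <- drop(Iinv %*% U)
    step <- 1
    repeat {
      ll_new <- penalized_loglik(beta + step * delta, X, y, n)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { ll_new <- ll_old; break }
    }
    beta <- beta + step * delta
    rel <- abs(ll_new - ll_old) / (abs(ll_old) + 1e-8)
    ll_old <- ll_new
    if (max_score < 1e-6 && rel < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  I <- crossprod(X, X * (n * mu * (1 - mu)))
  V <- solve(I)
  se <- sqrt(diag(V))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("b", seq_len(p) - 1L)
  names(beta) <- names(se) <- names(z) <- names(pv) <- nm
  dimnames(V) <- list(nm, nm)
  if (!converged) sq_warn("fit_firth did not converge in %d iterations", it)
  structure(list(coefficients = beta, vcov = V, se = se, z = z, p = pv,
                 loglik_penalized = ll_old, iterations = it,
                 converged = converged),
            class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Bias-reduced binomial GLM (Jeffreys-prior penalized likelihood)\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("converged: %s in %d iterations; penalized logLik %.4f\n",
              x$converged, x$iterations, x$loglik_penalized))
  invisible(x)
}

#' Fit the allele-dose interaction model to a counts table
#'
#' Convenience wrapper: builds the design matrix with [design_matrix()] and
#' fits with [fit_firth()].
#'
#' @param counts a [genotype_counts()] table.
#' @param interaction include the interaction term.
#' @inheritParams fit_firth
#' @return a `firth_fit`.
#' @export
fit_allele_dose <- function(counts, interaction = TRUE, tol = 1e-8,
                            max_iter = 100L) {
  counts <- genotype_counts(counts)
  X <- design_matrix(counts, interaction = interaction)
  fit_firth(X, counts$affected, counts$total, tol = tol, max_iter = max_iter)
}

#' Effects on the scale reported in incidence figures
#'
#' Per-allele (heterozygous) coefficient, its doubling for homozygotes,
#' the interaction coefficient, the exponentiated odds ratios and Wald
#' p-values.
#'
#' @param fit a converged `firth_fit` of the allele-dose interaction model.
#' @return list with `het_logOR`, `hom_logOR` (= `2 * het`), `int_logOR`,
#'   `tbx5_logOR`, corresponding `OR`s and `p` values.
#' @export
reported_effects <- function(fit) {
  assert_that(inherits(fit, "firth_fit"), "invalid_spec", "fit must be a firth_fit")
  assert_that(isTRUE(fit$converged), "unconverged_fit",
              "fit did not converge (%d iterations); refusing to report",
              fit$iterations)
  b <- fit$coefficients
  need <- c("gene_dose")
  assert_that(all(need %in% names(b)), "invalid_spec",
              "fit lacks a gene_dose coefficient")
  het <- unname(b[["gene_dose"]])
  int <- if ("interaction" %in% names(b)) unname(b[["interaction"]]) else NA_real_
  list(het_logOR = het,
       hom_logOR = 2 * het,
       int_logOR = int,
       tbx5_logOR = unname(b[["tbx5_dose"]]),
       het_OR = exp(het), hom_OR = exp(2 * het),
       int_OR = if (is.na(int)) NA_real_ else exp(int),
       p_gene = unname(fit$p[["gene_dose"]]),
       p_int = if ("interaction" %in% names(fit$p))
         unname(fit$p[["interaction"]]) else NA_real_)
}

#' Grid-search oracle for the penalized likelihood
#'
#' Exhaustively evaluates the Jeffreys-penalized binomial log-likelihood on
#' a bounded grid and returns the maximizing coefficient vector; intended as
#' an independent check of [fit_firth()] (optionally with iterative local
#' refinement around the incumbent).
#'
#' @param X design matrix (at most 4 columns).
#' @param affected,totals counts per row.
#' @param lower,upper per-coefficient grid bounds (finite).
#' @param n_grid grid points per axis.
#' @param refine number of local refinement passes (each shrinks the grid
#'   around the incumbent by 10x).
#' @return list with `beta` (argmax) and `loglik` at the argmax.
#' @export
brute_force_penalized_loglik <- function(X, affected, totals,
                                         lower = rep(-10, ncol(X)),
                                         upper = rep(10, ncol(X)),
                                         n_grid = 15L, refine = 6L) {
  X <- as.matrix(X)
  p <- ncol(X)
  assert_that(p <= 4L, "invalid_spec", "grid oracle supports at most 4 parameters")
  assert_that(all(is.finite(lower)) && all(is.finite(upper)),
              "invalid_spec", "grid bounds must be finite")
  lo <- rep_len(lower, p); hi <- rep_len(upper, p)
  best <- NULL; best_ll <- -Inf
  for (pass in seq_len(refine + 1L)) {
    axes <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], length.out = n_grid))
    grid <- as.matrix(do.call(expand.grid, axes))
    ll <- apply(grid, 1L, function(b) penalized_loglik(b, X, affected, totals))
    k <- which.max(ll)
    if (ll[k] > best_ll) { best_ll <- ll[k]; best <- grid[k, ] }
    span <- (hi - lo) / 10
    lo <- best - span; hi <- best + span
  }
  list(beta = unname(best), loglik = best_ll)
}

#' Sensitivity of reported effects to the plausible group sets
#'
#' The incidence experiments leave the exact group set ambiguous (whether
#' homozygous groups enter the interaction fit; the control denominator).
#' This runs the allele-dose fit across the plausible specifications and
#' tabulates the reported effects for each.
#'
#' @param counts the full [genotype_counts()] table (control row included).
#' @param control_totals control denominators to try (default `c(14, 7)`).
#' @return data.frame with one row per specification: group-set label,
#'   control n, het/hom/interaction log(OR)s and the interaction p-value.
#' @export
firth_sensitivity <- function(counts, control_totals = c(14L, 7L)) {
  counts <- genotype_counts(counts)
  subsets <- list(
    all_groups = rep(TRUE, nrow(counts)),
    no_homozygotes = counts$gene_dose < 2L
  )
  rows <- list()
  for (sub_nm in names(subsets)) {
    for (ctrl_n in control_totals) {
      cc <- counts[subsets[[sub_nm]], , drop = FALSE]
      is_ctrl <- cc$tbx5_dose == 0L & cc$gene_dose == 0L
      cc$total[is_ctrl] <- ctrl_n
      cc$affected[is_ctrl] <- pmin(cc$affected[is_ctrl], ctrl_n)
      X <- design_matrix(cc)
      if (qr(X)$rank < ncol(X)) next
      fit <- fit_firth(X, cc$affected, cc$total)
      eff <- reported_effects(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        group_set = sub_nm, control_n = ctrl_n,
        het_logOR = eff$het_logOR, hom_logOR = eff$hom_logOR,
        int_logOR = eff$int_logOR, p_int = eff$p_int)
    }
  }
  do.call(rbind, rows)
}
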