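# Matched-stratum conditional logistic regression: partial likelihood,
# Newton-Raphson with step halving, Wald inference, AIC, and within-stratum
# concordance. Written against the matched case-control (1 used : k
# available) design produced by the step-sampling stage.

#' Build a conditional-logistic design from raw pieces
#'
#' @param X Numeric covariate matrix (one row per candidate step) with
#'   column names.
#' @param stratum Stratum identifier per row.
#' @param case 0/1 (or logical) used-step indicator per row.
#' @return A `clogit_design` with rows grouped by stratum.
#' @export
clogit_design <- function(X, stratum, case) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(is.finite(X))) err_design("design matrix has non-finite values")
  case <- as.integer(case)
  ord <- order(match(stratum, unique(stratum)), -case)
  X <- X[ord, , drop = FALSE]
  stratum <- stratum[ord]
  case <- case[ord]
  s <- match(stratum, unique(stratum))
  ncase <- tapply(case, s, sum)
  sizes <- tabulate(s)
  if (any(ncase != 1)) {
    err_format(sprintf(
      "stratum integrity violated: stratum %s has %d case rows",
      unique(stratum)[which(ncase != 1)[1]], ncase[ncase != 1][1]))
  }
  if (any(sizes < 2)) err_design("every stratum needs at least one control row")
  structure(list(X = X, stratum = s, case = case == 1L,
                 n_strata = max(s)), class = "clogit_design")
}

# design from a case-control table and a term vector ("a" or "a:b")
build_design <- function(table, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(table))
    if (length(miss)) {
      err_design(paste("term references missing column(s):",
                       paste(miss, collapse = ", ")))
    }
    Reduce(`*`, lapply(parts, function(p) table[[p]]))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  clogit_design(X, table$stratum_id, table$case)
}

# per-stratum log-sum-exp pieces; returns list(ll, p) where p are the
# within-stratum softmax probabilities
pl_pieces <- function(beta, design) {
  eta <- as.vector(design$X %*% beta)
  s <- design$stratum
  m <- vapply(split(eta, s), max, numeric(1))
  w <- exp(eta - m[s])
  denom <- as.vector(rowsum(w, s))
  ll <- sum(eta[design$case]) - sum(m + log(denom))
  list(ll = ll, p = w / denom[s])
}

#' Conditional logistic partial log-likelihood
#'
#' `l(beta) = sum_s [ beta' x_case - log sum_{j in s} exp(beta' x_j) ]`,
#' evaluated with a log-sum-exp guard; always <= 0.
#'
#' @param beta Coefficient vector (length = number of design columns).
#' @param design A `clogit_design`.
#' @return The partial log-likelihood (a single finite number).
#' @export
partial_loglik <- function(beta, design) {
  if (length(beta) != ncol(design$X)) {
    err_design("beta length does not match the number of design columns")
  }
  pl_pieces(beta, design)$ll
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximizes the partial likelihood with Newton-Raphson and step halving.
#' Columns that are constant within every stratum contribute nothing to the
#' partial likelihood and are dropped with a warning, as are columns that
#' are collinear (within-stratum) with earlier ones. Standard errors come
#' from the inverse observed information; p-values are two-sided Wald.
#' Complete separation (a standardized coefficient exceeding 15 or an
#' information matrix with condition number above 1e12) is an error naming
#' the offending term.
#'
#' @param design A `clogit_design` (or the result of passing a
#'   case-control table plus terms to the model-competition layer).
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol_loglik,tol_score Convergence tolerances on the log-likelihood
#'   change and the score norm.
#' @return A `clogit_fit`: `terms`, `beta`, `se`, `z`, `p`, `loglik`,
#'   `aic`, `concordance`, `dropped_terms`, `converged`, `iterations`,
#'   `n_strata`.
#' @export
fit_clogit <- function(design, max_iter = 100, tol_loglik = 1e-8,
                       tol_score = 1e-6) {
  X <- design$X
  s <- design$stratum
  terms <- colnames(X)

  # within-stratum deviations identify structurally inestimable columns
  means <- rowsum(X, s) / as.vector(table(s))
  dev <- X - means[s, , drop = FALSE]
  const <- apply(abs(dev), 2, max) < 1e-10 * pmax(1, apply(abs(X), 2, max))
  dropped <- terms[const]
  if (any(const)) {
    warning(paste("dropping within-stratum-constant term(s):",
                  paste(dropped, collapse = ", ")))
  }
  keep <- which(!const)
  # greedy rank screen in column order, so earlier terms win
  if (length(keep) > 1) {
    sel <- integer(0)
    for (j in keep) {
      cand <- c(sel, j)
      if (qr(dev[, cand, drop = FALSE])$rank == length(cand)) {
        sel <- cand
      } else {
        dropped <- c(dropped, terms[j])
        warning(paste("dropping collinear term:", terms[j]))
      }
    }
    keep <- sel
  }
  if (length(keep) == 0) {
    err_design("no estimable terms: all covariates are constant within strata")
  }

  Xk <- X[, keep, drop = FALSE]
  dk <- structure(list(X = Xk, stratum = s, case = design$case,
                       n_strata = design$n_strata), class = "clogit_design")
  p <- ncol(Xk)
  beta <- rep(0, p)
  pieces <- pl_pieces(beta, dk)
  ll <- pieces$ll
  converged <- FALSE
  iter <- 0L
  H <- NULL

  while (iter < max_iter) {
    iter <- iter + 1L
    w <- pieces$p
    score <- as.vector(crossprod(Xk, dk$case - w))
    Mu <- rowsum(Xk * w, s)
    H <- crossprod(Xk, Xk * w) - crossprod(Mu)
    step <- tryCatch(solve(H, score), error = function(e) {
      err_design("information matrix is singular (separation or redundancy)")
    })
    # step halving keeps the ascent monotone
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      pieces_new <- pl_pieces(beta_new, dk)
      if (pieces_new$ll >= ll - 1e-12 || lam < 1e-10) break
      lam <- lam / 2
    }
    dll <- pieces_new$ll - ll
    beta <- beta_new
    pieces <- pieces_new
    ll <- pieces$ll
    if (abs(dll) < tol_loglik && max(abs(score)) < tol_score) {
      converged <- TRUE
      break
    }
  }

  sds <- apply(Xk - (rowsum(Xk, s) / as.vector(table(s)))[s, , drop = FALSE],
               2, sd)
  bstd <- abs(beta) * sds
  if (any(bstd > 15)) {
    err_design(paste("complete separation detected for term(s):",
                     paste(colnames(Xk)[bstd > 15], collapse = ", ")))
  }
  # condition of the correlation-form information: scale-invariant, so unit
  # disparity between raw and standardized columns is not mistaken for
  # separation
  d <- sqrt(diag(H))
  Hn <- H / tcrossprod(d)
  if (!all(is.finite(Hn)) || kappa(Hn, exact = TRUE) > 1e12) {
    err_design("information matrix condition number exceeds 1e12 (separation)")
  }

  se <- sqrt(diag(solve(H)))
  z <- beta / se
  pval <- 2 * pnorm(-abs(z))
  fit <- structure(list(
    terms = colnames(Xk),
    beta = stats::setNames(beta, colnames(Xk)),
    se = stats::setNames(se, colnames(Xk)),
    z = stats::setNames(z, colnames(Xk)),
    p = stats::setNames(pval, colnames(Xk)),
    loglik = ll,
    aic = 2 * length(beta) - 2 * ll,
    concordance = NA_real_,
    dropped_terms = dropped,
    converged = converged,
    iterations = iter,
    n_strata = dk$n_strata
  ), class = "clogit_fit")
  fit$concordance <- stratum_concordance(fit, dk)
  fit
}

#' Within-stratum concordance of a fitted model
#'
#' Fraction of (case, control) pairs within a stratum in which the linear
#' predictor ranks the used step above the available one; ties count 0.5.
#' The matched-design analog of the survival c-index.
#'
#' @param fit A `clogit_fit` (only `beta` is used).
#' @param design A `clogit_design` whose columns match `fit$terms`.
#' @return Concordance in `[0, 1]`.
#' @export
stratum_concordance <- function(fit, design) {
  X <- design$X[, fit$terms, drop = FALSE]
  eta <- as.vector(X %*% fit$beta)
  s <- design$stratum
  eta_case <- eta[design$case][s]
  ctrl <- !design$case
  diff <- eta_case[ctrl] - eta[ctrl]
  (sum(diff > 0) + 0.5 * sum(diff == 0)) / sum(ctrl)
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("<clogit_fit> %d strata, loglik %.4f, AIC %.2f, concordance %.3f%s\n",
              x$n_strata, x$loglik, x$aic, x$concordance,
              if (x$converged) "" else " (NOT converged)"))
  print(data.frame(beta = x$beta, se = x$se, z = x$z, p = x$p,
                   row.names = x$terms))
  if (length(x$dropped_terms)) {
    cat("dropped:", paste(x$dropped_terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' @param fit A `clogit_fit`.
#' @param path Output file.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
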