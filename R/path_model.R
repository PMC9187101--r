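#' Specify a recursive observed-variable path model
#'
#' A path model is a DAG over observed variables; each directed edge carries a
#' standardized path coefficient to be estimated. Edges are written as
#' `"source -> target"` strings (whitespace flexible).
#'
#' @param edges Character vector of `"a -> b"` edge specifications.
#' @return List of class `"path_model"`: `vars`, `edges` (data.frame with
#'   `from`, `to`), `exogenous`, `endogenous`, `order` (a topological order).
#' @examples
#' m <- path_model(c("pH -> richness", "pH -> MF", "richness -> MF"))
#' @export
path_model <- function(edges) {
  stopifnot(is.character(edges), length(edges) >= 1)
  parts <- regmatches(edges, regexec("^\\s*(\\S+)\\s*->\\s*(\\S+)\\s*$", edges))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stop("malformed edge specification: ", paste(edges[bad], collapse = "; "))
  ed <- data.frame(from = vapply(parts, `[`, "", 2),
                   to = vapply(parts, `[`, "", 3),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ed)) stop("duplicate edges in model")
  if (any(ed$from == ed$to)) stop("self-loop in model")
  vars <- unique(c(ed$from, ed$to))
  order <- topo_sort(vars, ed)          # errors on cycles
  endo <- unique(ed$to)
  structure(list(vars = vars, edges = ed,
                 exogenous = setdiff(vars, endo), endogenous = endo,
                 order = order),
            class = "path_model")
}

topo_sort <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    out <- c(out, v)
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(out) != length(vars)) stop("edge set contains a cycle")
  out
}

#' Fit a recursive path model by equation-wise least squares
#'
#' Variables are standardized to mean 0 / SD 1; each endogenous variable is
#' regressed on its parents (for recursive models with independent errors this
#' is the maximum-likelihood estimate, so no iterative SEM optimizer is
#' needed). The implied correlation matrix is assembled from the path
#' coefficients and the (fixed) sample correlations among exogenous
#' variables; model fit is summarized by
#' \eqn{\chi^2 = (n-1) F_{ML}}, its degrees of freedom, the normed chi-square
#' NC = \eqn{\chi^2/df}, and the comparative fit index CFI against the
#' independence baseline.
#'
#' Free parameters counted for df: one per edge, one residual variance per
#' endogenous variable, one variance per exogenous variable; exogenous
#' correlations are fixed at their sample values. A saturated model therefore
#' has df = 0 and, by convention, \eqn{\chi^2 = 0} and CFI = 1.
#'
#' @param model A [path_model()].
#' @param data `data.frame` containing every model variable.
#' @return List of class `"path_fit"`: `coefficients` (data.frame `from`,
#'   `to`, `estimate`, `se`, `p`), `residual_variance`, `implied` and
#'   `sample` correlation matrices, `chisq`, `df`, `nc`, `cfi`, `n`, and
#'   `heywood` (logical).
#' @export
fit_path_model <- function(model, data) {
  stopifnot(inherits(model, "path_model"))
  missing <- setdiff(model$vars, names(data))
  if (length(missing)) stop("data lacks model variables: ",
                            paste(missing, collapse = ", "))
  d <- data[, model$vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p <- length(model$vars)
  if (n <= p + 2) stop("too few complete observations for the model")
  z <- as.data.frame(lapply(d, function(x) zscore(x, "model variable")))
  S <- stats::cor(as.matrix(z))
  if (abs(det(S)) < 1e-12) stop("singular sample correlation matrix")

  # equation-wise OLS on standardized data
  B <- matrix(0, p, p, dimnames = list(model$vars, model$vars))  # B[to, from]
  psi <- stats::setNames(rep(NA_real_, p), model$vars)
  coefs <- list()
  for (v in model$endogenous) {
    parents <- model$edges$from[model$edges$to == v]
    fml <- stats::reformulate(sprintf("`%s`", parents), response = sprintf("`%s`", v))
    fit <- stats::lm(fml, data = z)
    est <- stats::coef(fit)[-1]                 # drop intercept (~0)
    sm <- summary(fit)$coefficients
    B[v, parents] <- unname(est)
    # residual variance chosen so the implied variance reproduces the
    # sample variance (1 on the correlation scale)
    psi[v] <- 1 - drop(t(B[v, parents]) %*% S[parents, parents] %*% B[v, parents])
    coefs[[v]] <- data.frame(from = parents, to = v,
                             estimate = unname(est),
                             se = unname(sm[-1, "Std. Error"]),
                             p = unname(sm[-1, "Pr(>|t|)"]),
                             stringsAsFactors = FALSE)
  }
  psi[model$exogenous] <- 1
  coefficients <- do.call(rbind, coefs)
  rownames(coefficients) <- NULL
  heywood <- any(abs(coefficients$estimate) > 1) || any(psi < 0)
  if (heywood) warning("standardized coefficient |b| > 1 or negative residual variance (Heywood case)")

  # implied covariance: x = Bx + e, Sigma = (I-B)^-1 Psi (I-B)^-T with the
  # exogenous block of Psi fixed at the sample correlations
  Psi <- diag(psi, p); dimnames(Psi) <- dimnames(B)
  ex <- model$exogenous
  Psi[ex, ex] <- S[ex, ex, drop = FALSE]
  A <- solve(diag(p) - B)
  Sigma <- A %*% Psi %*% t(A)
  dimnames(Sigma) <- dimnames(S)

  # ML discrepancy and fit indices
  fml_val <- ml_discrepancy(S, Sigma)
  chisq <- max(0, (n - 1) * fml_val)
  t_free <- nrow(model$edges) + length(model$endogenous) + length(model$exogenous)
  df <- p * (p + 1) / 2 - t_free
  if (df < 0) stop("negative degrees of freedom: over-parameterized model")
  if (df == 0) chisq <- 0                      # saturated: perfect fit by convention
  base_chisq <- (n - 1) * ml_discrepancy(S, diag(p))
  base_df <- p * (p - 1) / 2
  num <- max(chisq - df, 0)
  den <- max(base_chisq - base_df, num)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(1, max(0, cfi))
  nc <- if (df > 0) chisq / df else 0

  structure(list(model = model, coefficients = coefficients,
                 residual_variance = psi, implied = Sigma, sample = S,
                 chisq = chisq, df = df, nc = nc, cfi = cfi, n = n,
                 heywood = heywood),
            class = "path_fit")
}

ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  val <- log(det(Sigma)) - log(det(S)) + sum(diag(S %*% solve(Sigma))) - p
  max(val, 0)
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model: %d variables, %d edges, n = %d\n",
              length(x$model$vars), nrow(x$model$edges), x$n))
  cat(sprintf("chi-square = %.3f on %d df, NC = %.3f, CFI = %.3f\n",
              x$chisq, x$df, x$nc, x$cfi))
  co <- x$coefficients
  co$estimate <- round(co$estimate, 3)
  co$se <- round(co$se, 3)
  co$p <- signif(co$p, 3)
  print(co)
  invisible(x)
}

#' Indirect and total effects along directed paths
#'
#' The indirect effect of `from` on `to` is the sum over all directed paths
#' of length >= 2 of the product of standardized edge coefficients; the total
#' effect adds the direct edge (if any). Returns 0 when no path exists.
#'
#' @param fit A [fit_path_model()] result.
#' @param from,to Variable names.
#' @return Numeric scalar.
#' @export
indirect_effect <- function(fit, from, to) {
  sum_path_products(fit, from, to, min_len = 2L)
}

#' @rdname indirect_effect
#' @export
total_effect <- function(fit, from, to) {
  sum_path_products(fit, from, to, min_len = 1L)
}

sum_path_products <- function(fit, from, to, min_len) {
  stopifnot(inherits(fit, "path_fit"))
  vars <- fit$model$vars
  if (!from %in% vars || !to %in% vars) stop("variable not in model")
  ed <- fit$coefficients
  acc <- 0
  walk <- function(node, prod, len) {
    nxt <- which(ed$from == node)
    for (i in nxt) {
      tgt <- ed$to[i]
      pr <- prod * ed$estimate[i]
      if (tgt == to && len + 1L >= min_len) acc <<- acc + pr
      if (tgt != to) walk(tgt, pr, len + 1L)   # DAG: no revisit possible
    }
  }
  walk(from, 1, 0L)
  acc
}
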