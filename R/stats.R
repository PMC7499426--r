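# Genotype comparison: mixed model, Wald chi-square, transforms, Meff.

#' MeffResult: effective number of independent tests
#'
#' Result of the eigenvalue-based multiplicity computation: for k
#' non-independent tests, Meff = 1 + (k - 1) (1 - Vcorr / k) where Vcorr is
#' the sample variance (denominator k - 1) of the eigenvalues of the
#' Spearman rank-correlation matrix of the k parameters. Independence gives
#' Meff = k; perfect correlation gives Meff = 1.
#'
#' @slot k number of tests.
#' @slot eigenvalues eigenvalues of the Spearman correlation matrix.
#' @slot vcorr sample variance of the eigenvalues.
#' @slot meff the effective number of tests.
#' @export
setClass("MeffResult",
  representation(k = "numeric", eigenvalues = "numeric",
                 vcorr = "numeric", meff = "numeric"))

setValidity("MeffResult", function(object) {
  msg <- character()
  if (object@k >= 2 && abs(sum(object@eigenvalues) - object@k) > 1e-6)
    msg <- c(msg, "eigenvalues of a correlation matrix must sum to k")
  if (object@meff < 1 - 1e-9 || object@meff > object@k + 1e-9)
    msg <- c(msg, "meff must lie in [1, k]")
  if (length(msg)) msg else TRUE
})

#' @describeIn MeffResult compact display
#' @param object a MeffResult
#' @export
setMethod("show", "MeffResult", function(object) {
  cat(sprintf("Meff = %.3f (k = %d, Vcorr = %.3f)\n",
              object@meff, as.integer(object@k), object@vcorr))
  invisible(NULL)
})

setMethod("$", "MeffResult", function(x, name) slot(x, name))

#' Effective number of independent tests
#'
#' @param mat numeric matrix, fish in rows, kinematic parameters in columns
#'   (k >= 1 columns; at least k + 1 rows for a meaningful correlation).
#' @return a [MeffResult-class].
#' @examples
#' computeMeff(matrix(rnorm(200), 50, 4))  # near 4 for independent columns
#' @export
computeMeff <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k == 1)
    return(new("MeffResult", k = 1, eigenvalues = 1, vcorr = 0, meff = 1))
  rv <- apply(mat, 2, function(col) stats::var(rank(col)))
  if (any(rv == 0))
    stop("constant column(s): ",
         paste(colnames(mat)[rv == 0], collapse = ", "),
         " have zero rank variance; Spearman correlation undefined",
         call. = FALSE)
  S <- stats::cor(mat, method = "spearman", use = "pairwise.complete.obs")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  vcorr <- stats::var(ev)
  meff <- 1 + (k - 1) * (1 - vcorr / k)
  new("MeffResult", k = k, eigenvalues = ev, vcorr = vcorr, meff = meff)
}

#' Adjust p-values by the effective number of tests
#'
#' @param p_raw numeric vector of raw p-values.
#' @param meff effective number of tests (>= 1), a number or [MeffResult-class].
#' @return elementwise \code{min(1, p_raw * meff)}.
#' @export
adjustPvalues <- function(p_raw, meff) {
  if (is(meff, "MeffResult")) meff <- meff@meff
  stopifnot(meff >= 1)
  pmin(1, p_raw * meff)
}

#' Choose a variance-stabilizing transform
#'
#' Selects among no transform, log and square root the one minimizing the
#' absolute skewness of the residuals after removing genotype means. The log
#' is only considered for strictly positive data, the square root for
#' non-negative data.
#'
#' @param values numeric response per fish.
#' @param genotype grouping factor.
#' @return "none", "log" or "sqrt".
#' @export
chooseTransform <- function(values, genotype) {
  ok <- is.finite(values)
  values <- values[ok]; genotype <- genotype[ok]
  cand <- list(none = identity)
  if (all(values > 0)) cand$log <- log
  if (all(values >= 0)) cand$sqrt <- sqrt
  sk <- vapply(cand, function(f) {
    y <- f(values)
    r <- y - stats::ave(y, genotype)
    abs(e1071::skewness(r, type = 2))
  }, numeric(1))
  names(cand)[which.min(sk)]
}

applyTransform <- function(values, transform) {
  switch(transform, none = values, log = log(values), sqrt = sqrt(values))
}

#' Genotype comparison with a clutch random effect
#'
#' Fits the linear mixed model \code{response ~ genotype + (1 | clutch)}
#' (random clutch intercept) and returns the 1-df Type II Wald chi-square
#' for the genotype effect with its p-value. For a single two-level fixed
#' factor this equals the squared Wald z of the genotype coefficient. When
#' the mixed fit fails (e.g. a degenerate random-effect variance) the
#' marginal fixed-effects model is used instead, so a finite statistic is
#' always returned.
#'
#' @param data data.frame with the response, genotype and clutch columns.
#' @param response name of the response column (already transformed).
#' @param genotype,clutch column names.
#' @return list with \code{wald_chi2}, \code{p_raw}, \code{model} ("lmm" or
#'   "lm").
#' @export
fitGenotypeModel <- function(data, response, genotype = "genotype",
                             clutch = "clutch") {
  data <- data[is.finite(data[[response]]), , drop = FALSE]
  if (length(unique(data[[genotype]])) < 2)
    stop("both genotypes must be present", call. = FALSE)
  data[[genotype]] <- factor(data[[genotype]])
  fml <- stats::as.formula(
    paste(response, "~", genotype, "+ (1 |", clutch, ")"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = data,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    b <- lme4::fixef(fit)[2]
    se <- sqrt(diag(as.matrix(stats::vcov(fit)))[2])
    model <- "lmm"
  } else {
    lmfit <- stats::lm(stats::as.formula(paste(response, "~", genotype)),
                       data = data)
    b <- stats::coef(lmfit)[2]
    se <- sqrt(diag(stats::vcov(lmfit))[2])
    model <- "lm"
  }
  chi2 <- unname((b / se)^2)
  list(wald_chi2 = chi2, p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       model = model)
}

# parameter sets of the three published analyses plus the standalone rate
analysisColumns <- function(analysis) {
  switch(analysis,
    forward = paste0("fwd_", .slowParams),
    turn = paste0("trn_", .slowParams),
    escape = paste0("esc_", .escapeParams),
    boutrate = "bout_rate_hz",
    stop("unknown analysis: ", analysis, call. = FALSE))
}

#' Compare genotypes over a family of kinematic parameters
#'
#' Runs the full per-family comparison on a fish-summary table: QC
#' filtering, automatic transform choice, the mixed-model Wald chi-square
#' per parameter, a family-wide Meff from the Spearman correlation of the
#' parameters, and Meff-multiplied p-values capped at 1. The bout-rate
#' analysis is a single unadjusted test (Meff = 1 by the k = 1 convention).
#'
#' @param summaries fish-summary table ([summarizeFish()] rows).
#' @param analysis one of "escape", "forward", "turn", "boutrate".
#' @param alpha significance level recorded in the result.
#' @return data.frame, one row per parameter: group means and SEM per
#'   genotype (original scale), transform, Wald chi-square, raw and adjusted
#'   p, the shared Meff, and a significance flag at \code{alpha}.
#' @export
compareGroups <- function(summaries, analysis = c("forward", "turn",
                                                  "escape", "boutrate"),
                          alpha = 0.05) {
  analysis <- match.arg(analysis)
  cols <- analysisColumns(analysis)
  s <- summaries[summaries$qc_pass, , drop = FALSE]
  if (analysis == "escape") s <- s[s$n_selected > 0, , drop = FALSE]
  if (length(unique(s$genotype)) < 2)
    stop("both genotypes must be present after QC", call. = FALSE)
  meff <- if (length(cols) > 1) computeMeff(as.matrix(s[, cols]))@meff else 1
  gl <- sort(unique(s$genotype))
  rows <- lapply(cols, function(p) {
    tr <- chooseTransform(s[[p]], s$genotype)
    d <- s
    d$.y <- applyTransform(d[[p]], tr)
    ft <- fitGenotypeModel(d, ".y")
    gm <- vapply(gl, function(g) mean(s[[p]][s$genotype == g], na.rm = TRUE),
                 numeric(1))
    gs <- vapply(gl, function(g) {
      v <- s[[p]][s$genotype == g]
      stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
    }, numeric(1))
    data.frame(parameter = p, transform = tr,
               mean_1 = gm[1], sem_1 = gs[1], mean_2 = gm[2], sem_2 = gs[2],
               wald_chi2 = ft$wald_chi2, p_raw = ft$p_raw, model = ft$model,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "mean_1"] <- paste0("mean_", gl[1])
  names(out)[names(out) == "sem_1"] <- paste0("sem_", gl[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", gl[2])
  names(out)[names(out) == "sem_2"] <- paste0("sem_", gl[2])
  out$meff <- meff
  out$p_adj <- adjustPvalues(out$p_raw, meff)
  out$significant <- out$p_adj < alpha
  attr(out, "analysis") <- analysis
  attr(out, "n_fish") <- table(s$genotype)
  out
}
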