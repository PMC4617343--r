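# Negative-binomial GLM differential expression: one group coefficient per
# (conditioning type, time point) against the unconditioned reference, with
# additive replicate blocking, trended dispersion and per-contrast
# likelihood-ratio tests.

#' Build the blocked one-way design for one species
#'
#' The model is `~ replicate + group` with the unconditioned group as the
#' intercept reference: one indicator column per replicate beyond the
#' first (blocking) and one per (conditioning type, time point) group.
#' Each non-reference group defines one contrast against the reference.
#'
#' @param meta sample metadata data.frame (sample_id, species,
#'   conditioning_type, time_point, replicate) for a single species.
#' @return an object of class `design_spec`: list with `samples`, `group`,
#'   `block`, `X` (design matrix), `contrasts` (labels "type|tp") and
#'   `group_cols` (design column per contrast).
#' @export
build_design <- function(meta) {
  if (length(unique(meta$species)) != 1L)
    stop("build_design expects one species at a time")
  grp <- ifelse(meta$conditioning_type == "unconditioned", "unconditioned",
                paste(meta$conditioning_type, meta$time_point, sep = "|"))
  if (!any(grp == "unconditioned")) stop("no unconditioned samples")
  lv <- c("unconditioned", unique(grp[grp != "unconditioned"]))
  if (length(lv) < 2L) stop("design has no contrast: only one group present")
  group <- factor(grp, levels = lv)
  block <- factor(meta$replicate)
  X <- if (nlevels(block) > 1L) model.matrix(~ block + group) else
    model.matrix(~ group)
  colnames(X) <- sub("^group", "", colnames(X))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  structure(list(samples = meta$sample_id, group = group, block = block,
                 X = X, contrasts = lv[-1],
                 group_cols = match(lv[-1], colnames(X))),
            class = "design_spec")
}

#' Residual degrees of freedom of the dispersion design
#'
#' The arithmetic used by dispersion estimation: number of samples minus
#' number of condition classes (e.g. 12 samples across four condition
#' classes leave 8 degrees of freedom).
#'
#' @param n_samples number of samples.
#' @param n_condition_classes number of condition classes.
#' @return integer degrees of freedom.
#' @export
residual_df <- function(n_samples, n_condition_classes) {
  stopifnot(n_condition_classes >= 1)
  df <- as.integer(n_samples) - as.integer(n_condition_classes)
  if (df <= 0) stop("nonpositive residual degrees of freedom")
  df
}

# pooled Pearson moment estimate: the phi solving
# sum((y - mu)^2 / (mu + phi mu^2)) = n_rows * df over a set of rows
pooled_pearson_phi <- function(y, mu, rows, df) {
  f <- function(phi)
    sum((y[rows, , drop = FALSE] - mu[rows, , drop = FALSE])^2 /
          (mu[rows, , drop = FALSE] + phi * mu[rows, , drop = FALSE]^2)) -
      length(rows) * df
  if (f(1e-8) <= 0) return(1e-8)   # at or below the Poisson limit
  if (f(100) >= 0) return(100)
  stats::uniroot(f, c(1e-8, 100), tol = 1e-10)$root
}

#' Estimate common and trended NB dispersions
#'
#' The common dispersion maximises the Cox-Reid adjusted profile
#' likelihood summed over transcripts. The trend pools transcripts into
#' abundance bins (by average log-CPM), solves one moment (Pearson)
#' equation per bin with the residual degrees of freedom of the design,
#' smooths the bin estimates with lowess, and is refined once by
#' refitting means at the trended values; the per-transcript dispersion
#' is the trend evaluated at the transcript's abundance (no tagwise
#' shrinkage). Pooling within bins avoids the strong downward bias of
#' smoothing individual per-transcript moment estimates, whose sampling
#' distribution is highly right-skewed at small residual df.
#'
#' @param counts filtered integer count matrix.
#' @param design a [build_design()] result.
#' @param span lowess span for the trend fit.
#' @param lib_sizes optional library sizes for the offset; defaults to
#'   the column sums.
#' @return object of class `nb_dispersion`: list with `common`, `trend`
#'   (data.frame x/y on the average log-CPM scale), `per_transcript`
#'   (named vector) and `ave_log_cpm`.
#' @export
estimate_dispersions <- function(counts, design, span = 0.5,
                                 lib_sizes = NULL) {
  X <- design$X
  if (nrow(counts) == 0L) stop("empty count matrix")
  if (ncol(counts) < ncol(X)) stop("fewer samples than design columns")
  y <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  libsize <- lib_sizes %||% colSums(y)
  off <- matrix(log(libsize), nrow(y), ncol(y), byrow = TRUE)
  ave <- log2(rowMeans(t(t(y) / libsize) * 1e6) + 0.25)
  df <- ncol(y) - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom for dispersion")
  nonzero <- rowSums(y) > 0

  nbins <- max(1L, min(50L, sum(nonzero) %/% 20L))
  bins <- integer(nrow(y))
  bins[nonzero] <- as.integer(cut(rank(ave[nonzero], ties.method = "first"),
                                  nbins))
  phi_work <- rep(0.1, nrow(y))
  trend_xy <- NULL
  for (pass in 1:2) {
    fit <- .nbglm_fit_cpp(y, X, off, phi_work)
    mu <- pmax(fit$fitted, 1e-8)
    bx <- by <- numeric(nbins)
    for (b in seq_len(nbins)) {
      rows <- which(bins == b)
      bx[b] <- mean(ave[rows])
      by[b] <- pooled_pearson_phi(y, mu, rows, df)
    }
    lw <- stats::lowess(bx, by, f = span)
    trend_xy <- data.frame(x = lw$x, y = pmax(lw$y, 1e-6))
    phi_work <- pmax(stats::approx(trend_xy$x, trend_xy$y, xout = ave,
                                   rule = 2, ties = "ordered")$y, 1e-6)
  }

  sub <- seq_len(nrow(y))
  if (length(sub) > 2000L) {
    o <- order(ave)
    sub <- o[round(seq(1, length(o), length.out = 2000L))]
  }
  common <- 10^stats::optimize(function(lp)
    .nb_apl_cpp(y[sub, , drop = FALSE], X, off[sub, , drop = FALSE], 10^lp),
    interval = c(-6, 1), maximum = TRUE, tol = 1e-4)$maximum

  structure(list(common = common, trend = trend_xy,
                 per_transcript = setNames(phi_work, rownames(counts)),
                 ave_log_cpm = setNames(ave, rownames(counts))),
            class = "nb_dispersion")
}

#' Evaluate a fitted dispersion trend at given abundances
#' @param object an `nb_dispersion`.
#' @param ave_log_cpm abundances (average log2-CPM) to evaluate at.
#' @return dispersion values.
#' @export
trend_dispersion <- function(object, ave_log_cpm) {
  pmax(stats::approx(object$trend$x, object$trend$y, xout = ave_log_cpm,
                     rule = 2, ties = "ordered")$y, 1e-6)
}

#' Fit NB GLMs and test every contrast against the unconditioned reference
#'
#' For each transcript an NB GLM with log link and log-library-size offset
#' is fitted by IRLS under the full design (deviance tolerance 1e-8,
#' at most 100 iterations); each contrast is tested by a likelihood-ratio
#' test of the full fit against the design without that group's
#' coefficient, with p-values from the chi-square distribution on 1 df.
#' All-zero transcripts report logFC 0 and p 1. Transcripts whose full or
#' reduced fit fails to converge are excluded from the calls and listed in
#' the `nonconverged` attribute.
#'
#' @param counts filtered integer count matrix.
#' @param design a [build_design()] result.
#' @param dispersions an `nb_dispersion` object or a per-transcript
#'   numeric vector (recycled if length 1).
#' @param alpha significance threshold on the (possibly adjusted) p-value.
#' @param bh apply Benjamini-Hochberg adjustment before thresholding?
#'   Off by default: calls use the raw p-value cutoff.
#' @param lib_sizes optional library sizes for the offset; defaults to
#'   the column sums.
#' @return object of class `de_calls` (a data.frame): transcript_id,
#'   conditioning_type, time_point, logFC (log2), p_value, direction,
#'   significant.
#' @export
fit_and_test <- function(counts, design, dispersions, alpha = 0.05,
                         bh = FALSE, lib_sizes = NULL) {
  X <- design$X
  y <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
              dimnames = dimnames(counts))
  phi <- if (inherits(dispersions, "nb_dispersion")) {
    unname(dispersions$per_transcript[rownames(y)])
  } else rep_len(as.numeric(dispersions), nrow(y))
  if (anyNA(phi)) stop("dispersions do not cover all transcripts")
  off <- matrix(log(lib_sizes %||% colSums(y)), nrow(y), ncol(y),
                byrow = TRUE)

  full <- .nbglm_fit_cpp(y, X, off, phi)
  ok <- full$converged
  res <- vector("list", length(design$contrasts))
  for (i in seq_along(design$contrasts)) {
    red <- .nbglm_fit_cpp(y, X[, -design$group_cols[i], drop = FALSE],
                          off, phi)
    ok <- ok & red$converged
    stat <- pmax(red$deviance - full$deviance, 0)
    lfc <- full$coefficients[, design$group_cols[i]] / log(2)
    allzero <- rowSums(y) == 0
    lfc[allzero] <- 0
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    p[allzero] <- 1
    lab <- strsplit(design$contrasts[i], "|", fixed = TRUE)[[1]]
    res[[i]] <- data.frame(transcript_id = rownames(y),
                           conditioning_type = lab[1], time_point = lab[2],
                           logFC = lfc, p_value = p,
                           stringsAsFactors = FALSE)
  }
  bad <- rownames(y)[!ok]
  if (length(bad)) {
    md_log("de", length(bad), " transcript(s) failed to converge; excluded")
    res <- lapply(res, function(d) d[!d$transcript_id %in% bad, ])
  }
  calls <- do.call(rbind, res)
  rownames(calls) <- NULL
  pcrit <- if (bh) stats::p.adjust(calls$p_value, "BH") else calls$p_value
  calls$direction <- ifelse(calls$logFC < 0, "down", "up")
  calls$significant <- pcrit < alpha
  structure(calls, class = c("de_calls", "data.frame"), alpha = alpha,
            bh = bh, nonconverged = bad)
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("NB-GLM differential expression calls: %d tests, %d transcripts, %d contrasts\n",
              nrow(x), length(unique(x$transcript_id)),
              nrow(unique(x[, c("conditioning_type", "time_point")]))))
  cat(sprintf("significant at alpha = %g%s: %d (%d up, %d down)\n",
              attr(x, "alpha"), if (isTRUE(attr(x, "bh"))) " (BH)" else "",
              sum(x$significant), sum(x$significant & x$direction == "up"),
              sum(x$significant & x$direction == "down")))
  invisible(x)
}

#' @export
summary.de_calls <- function(object, ...) {
  sig <- object[object$significant, ]
  tab <- table(paste(sig$conditioning_type, sig$time_point, sep = "|"),
               sig$direction)
  print(tab)
  invisible(tab)
}
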