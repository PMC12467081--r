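## Single-marker association with PCA covariates and the iterative
## remove-and-rescan procedure for resolving multiple linked signals
## within a region. The single-marker test is a documented ordinary
## least-squares stand-in behind a pluggable contract: the iteration logic
## is agnostic to the test's internals.

#' Principal-component covariates from the dosage matrix
#'
#' Computes principal components of the accession-by-marker dosage matrix
#' after per-marker mean imputation of missing dosages and centering.
#' Columns are ordered by decreasing explained variance; the attribute
#' \code{explained} carries the per-component variance fractions.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param nComponents number of components (default 4, the count that in
#'   practice removes most structure-driven false positives while keeping
#'   genuine signals).
#' @return accession x component numeric matrix with attribute
#'   \code{explained}.
#' @export
pcaCovariates <- function(ms, nComponents = 4) {
    stopifnot(is(ms, "MarkerSet"))
    d <- dosages(ms)
    if (ncol(d) < nComponents + 1L || nrow(d) < nComponents)
        stop("need > nComponents accessions and >= nComponents markers")
    X <- t(d)  # accessions x markers
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) {
        na <- is.na(X[, j])
        if (any(na)) X[na, j] <- mu[j]
    }
    X <- sweep(X, 2L, colMeans(X))
    if (all(abs(X) < 1e-12))
        stop("rank error: dosage matrix is constant")
    pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
    k <- min(nComponents, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    rownames(scores) <- accessionIds(ms)
    attr(scores, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    scores
}

#' Single-marker association test
#'
#' Ordinary least squares of the trait on marker dosage plus covariates
#' plus an intercept, over pairwise-complete observations. The p-value is
#' the two-sided t-test of the dosage coefficient; the effect is the
#' dosage coefficient (trait units per non-reference allele copy, positive
#' when alternate-allele carriers score higher); PVE is 100 times the
#' R-squared of the dosage-only fit to the covariate-residualised trait.
#'
#' @param d numeric dosage vector.
#' @param trait numeric trait vector, same length.
#' @param covariates optional numeric matrix of covariates (rows =
#'   accessions).
#' @param id marker id recorded in the result.
#' @return one-row data.frame: marker_id, p_value, maf, effect, pve, note.
#'   A marker monomorphic after deletion is returned with NA statistics
#'   and note \code{"monomorphic"} rather than an error, so scans can skip
#'   it.
#' @export
singleMarkerTest <- function(d, trait, covariates = NULL, id = "marker") {
    stopifnot(length(d) == length(trait))
    if (!is.null(covariates)) {
        covariates <- as.matrix(covariates)
        stopifnot(nrow(covariates) == length(d))
    }
    ok <- !is.na(d) & !is.na(trait)
    if (!is.null(covariates)) ok <- ok & !apply(is.na(covariates), 1L, any)
    res <- data.frame(marker_id = id, p_value = NA_real_, maf = NA_real_,
                      effect = NA_real_, pve = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    x <- d[ok]; y <- trait[ok]
    cv <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
    if (length(unique(x)) < 2L) {
        res$note <- "monomorphic"
        return(res)
    }
    npar <- 2L + if (is.null(cv)) 0L else ncol(cv)
    if (length(x) <= npar)
        stop("rank error: n <= number of model parameters")
    dat <- data.frame(y = y, x = x)
    fit <- if (is.null(cv)) stats::lm(y ~ x, data = dat) else
        stats::lm(y ~ x + cv)
    sm <- summary(fit)$coefficients
    res$effect <- unname(sm["x", "Estimate"])
    res$p_value <- unname(sm["x", "Pr(>|t|)"])
    res$maf <- minorAlleleFrequency(x)
    yr <- if (is.null(cv)) y - mean(y) else
        stats::resid(stats::lm(y ~ cv))
    res$pve <- 100 * summary(stats::lm(yr ~ x))$r.squared
    res
}

#' Iterative remove-and-rescan of a region
#'
#' Repeats: test every remaining marker; if the most significant marker
#' lying inside \code{region} passes the Bonferroni threshold
#' (\code{alpha} over the number of markers tested), record it, remove it
#' from the marker set, and rescan — until no in-region marker is
#' significant or \code{maxIter} is reached. This mirrors conditional
#' GWAS practice where a multi-locus model reports one marker per linked
#' group and is re-run after removing it to expose further signals.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param trait numeric trait vector aligned with \code{accessionIds(ms)}
#'   (or named by accession id).
#' @param region a \code{GRanges} of length 1 (chrom, start, end; 1-based
#'   inclusive) bounding the stopping rule. All markers are tested; only
#'   in-region markers are reported and removed.
#' @param covariates optional covariate matrix (e.g.
#'   \code{\link{pcaCovariates}}).
#' @param alpha significance level before Bonferroni correction
#'   (default 0.05).
#' @param maxIter iteration cap (default 10).
#' @param condition when TRUE, previously discovered markers are added as
#'   covariates in later iterations (a true conditional scan); when FALSE
#'   (default) discovered markers are only removed from the set.
#' @return data.frame of association results in discovery order, with
#'   logical attribute \code{truncated} set when \code{maxIter} stopped
#'   the scan.
#' @export
iterativeRegionScan <- function(ms, trait, region, covariates = NULL,
                                alpha = 0.05, maxIter = 10L,
                                condition = FALSE) {
    stopifnot(is(ms, "MarkerSet"), is(region, "GRanges"),
              length(region) == 1L)
    if (!is.null(names(trait))) trait <- trait[accessionIds(ms)]
    stopifnot(length(trait) == ncol(ms))
    found <- list()
    truncated <- FALSE
    extra <- NULL
    repeat {
        inreg <- IRanges::overlapsAny(
            SummarizedExperiment::rowRanges(ms), region)
        if (!any(inreg)) break
        d <- dosages(ms)
        cv <- covariates
        if (condition && !is.null(extra))
            cv <- cbind(cv, extra)
        tests <- lapply(seq_len(nrow(ms)), function(i)
            singleMarkerTest(d[i, ], trait, cv, id = markerIds(ms)[i]))
        tab <- do.call(rbind, tests)
        tested <- !is.na(tab$p_value)
        m <- sum(tested)
        if (m == 0L) break
        thr <- alpha / m
        cand <- which(inreg & tested)
        if (!length(cand)) break
        best <- cand[which.min(tab$p_value[cand])]
        if (tab$p_value[best] > thr) break
        found[[length(found) + 1L]] <- tab[best, ]
        if (condition)
            extra <- cbind(extra, d[best, ])
        ms <- ms[-best, ]
        if (length(found) >= maxIter && nrow(ms) > 0L) {
            truncated <- TRUE
            break
        }
        if (nrow(ms) == 0L) break
    }
    out <- if (length(found)) do.call(rbind, found) else
        data.frame(marker_id = character(), p_value = numeric(),
                   maf = numeric(), effect = numeric(), pve = numeric(),
                   note = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "truncated") <- truncated
    out
}
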