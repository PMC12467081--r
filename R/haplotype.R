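## Haplotype-group assignment from a defined marker set, additive total
## effects, and one-way ANOVA comparison of trait distributions.

#' Assign accessions to haplotype groups
#'
#' An accession "carries" a marker when its dosage is at least
#' \code{carrierMinDosage} (default 1: heterozygous carriage suffices;
#' missing dosage counts as not carried). Accessions carrying at least
#' \code{minCount} of the listed markers form haplotype 2, the rest
#' haplotype 1.
#'
#' @param ms a \linkS4class{MarkerSet}.
#' @param markerIds character vector of marker ids defining the haplotype.
#' @param minCount minimum carried-marker count for haplotype 2
#'   (default 7).
#' @param carrierMinDosage minimum dosage that counts as carrying
#'   (default 1).
#' @return data.frame: accession_id, carried_marker_count, group (factor
#'   \code{haplotype1}/\code{haplotype2}).
#' @export
assignHaplotypes <- function(ms, markerIds, minCount = 7L,
                             carrierMinDosage = 1L) {
    stopifnot(is(ms, "MarkerSet"))
    missing_ids <- setdiff(markerIds, rownames(ms))
    if (length(missing_ids))
        stop("unknown marker id(s): ",
             paste(missing_ids, collapse = ", "))
    d <- dosages(ms)[markerIds, , drop = FALSE]
    carried <- colSums(!is.na(d) & d >= carrierMinDosage)
    grp <- factor(ifelse(carried >= minCount, "haplotype2", "haplotype1"),
                  levels = c("haplotype1", "haplotype2"))
    data.frame(accession_id = accessionIds(ms),
               carried_marker_count = as.integer(carried),
               group = grp, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Total additive effect of a marker set
#'
#' Sum over markers of (per-allele effect) x (dosage): the expected trait
#' shift from carrying the listed non-reference alleles, assuming
#' additivity across loci and allele copies. Missing dosages contribute 0;
#' the logical attribute \code{complete} is FALSE when any dosage was
#' missing.
#'
#' @param dosages named numeric vector of dosages (0/1/2/NA) per marker.
#' @param effects named numeric vector of per-allele effects sharing the
#'   same names.
#' @return total effect in trait units, with attribute \code{complete}.
#' @examples
#' totalAdditiveEffect(c(m1 = 1, m2 = 1, m3 = 1),
#'                     c(m1 = 0.876, m2 = -1.165, m3 = -1.035))
#' @export
totalAdditiveEffect <- function(dosages, effects) {
    stopifnot(!is.null(names(dosages)), !is.null(names(effects)),
              setequal(names(dosages), names(effects)))
    eff <- effects[names(dosages)]
    d <- dosages
    complete <- !anyNA(d)
    d[is.na(d)] <- 0
    out <- sum(eff * d)
    attr(out, "complete") <- complete
    out
}

#' One-way ANOVA comparison of trait values between groups
#'
#' Classic fixed-effects one-way ANOVA across two or more groups. When all
#' values are identical across groups (zero variance everywhere, equal
#' means) the degenerate F = 0, p = 1 path is returned instead of NaN.
#'
#' @param valuesByGroup named list of numeric vectors, one per group,
#'   each with at least 2 values.
#' @return list with elements \code{F} and \code{p_value}.
#' @export
compareGroupsAnova <- function(valuesByGroup) {
    stopifnot(is.list(valuesByGroup), length(valuesByGroup) >= 2L,
              all(lengths(valuesByGroup) >= 2L))
    y <- unlist(valuesByGroup, use.names = FALSE)
    g <- factor(rep(names(valuesByGroup) %||%
                        seq_along(valuesByGroup),
                    lengths(valuesByGroup)))
    if (stats::var(y) == 0)
        return(list(F = 0, p_value = 1))
    fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
    list(F = unname(fit$statistic), p_value = unname(fit$p.value))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
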