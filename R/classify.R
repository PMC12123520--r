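# Profile-level interpretation: inconclusive / single-source / mixture
# categories and the 3:1 peak-height major-contributor rule. All rules
# operate on autosomal loci, mirroring the counting conventions.

#' Classification thresholds
#'
#' @param min_typed_loci Profiles with fewer typed autosomal loci than this
#'   are inconclusive (default 10; "fewer than" is strict, so exactly 10
#'   typed loci is not inconclusive).
#' @param mixture_min_loci Number of loci that must show extra allelic
#'   signals to call a mixture (default 2).
#' @param mixture_min_alleles Allele count per locus that counts as an extra
#'   signal, i.e. "more than two" (default 3).
#' @param major_ratio Minimum peak-height ratio of the putative major
#'   contributor's alleles over the remaining alleles of the same locus
#'   (default 3).
#' @return A list of class \code{classification_thresholds}.
#' @export
classification_thresholds <- function(min_typed_loci = 10L,
                                      mixture_min_loci = 2L,
                                      mixture_min_alleles = 3L,
                                      major_ratio = 3.0) {
  stopifnot(min_typed_loci >= 1, mixture_min_loci >= 1,
            mixture_min_alleles >= 1, major_ratio >= 1)
  structure(list(min_typed_loci = as.integer(min_typed_loci),
                 mixture_min_loci = as.integer(mixture_min_loci),
                 mixture_min_alleles = as.integer(mixture_min_alleles),
                 major_ratio = major_ratio),
            class = "classification_thresholds")
}

#' Number of typed autosomal loci
#'
#' A locus is typed when at least one allele is called there.
#'
#' @param profile An \code{str_profile}.
#' @param panel Locus panel.
#' @return Integer in [0, 23].
#' @export
typed_locus_count <- function(profile, panel = fusion6c_panel()) {
  stopifnot(inherits(profile, "str_profile"))
  aut <- panel_loci(panel, "autosomal")
  length(unique(profile$calls$locus[profile$calls$locus %in% aut]))
}

#' Classify an evidence profile
#'
#' A profile with fewer than \code{min_typed_loci} typed autosomal loci is
#' \code{inconclusive}. Otherwise it is a \code{mixture} when at least
#' \code{mixture_min_loci} loci carry \code{mixture_min_alleles} or more
#' distinct alleles, and \code{single_source} otherwise. For mixtures whose
#' calls all carry peak heights, the 3:1 major-contributor rule
#' (\code{\link{extract_major_contributor}}) is applied and the extracted
#' profile, when the rule succeeds at every typed locus, is returned as the
#' strong contributor.
#'
#' @param evidence An \code{str_profile}.
#' @param thresholds A \code{\link{classification_thresholds}} object.
#' @param panel Locus panel.
#' @return List of class \code{profile_classification}: \code{category}
#'   (\code{"inconclusive"}, \code{"single_source"} or \code{"mixture"}),
#'   \code{typed_loci}, \code{mixture_loci} (count of loci with extra
#'   signals) and \code{strong_contributor} (an \code{str_profile} or
#'   \code{NULL}; only ever non-NULL for mixtures).
#' @export
classify_profile <- function(evidence,
                             thresholds = classification_thresholds(),
                             panel = fusion6c_panel()) {
  stopifnot(inherits(evidence, "str_profile"),
            inherits(thresholds, "classification_thresholds"))
  typed <- typed_locus_count(evidence, panel)
  aut <- panel_loci(panel, "autosomal")
  per_locus <- table(unique(evidence$calls[evidence$calls$locus %in% aut,
                                           c("locus", "allele")])$locus)
  n_mix <- sum(per_locus >= thresholds$mixture_min_alleles)
  category <- if (typed < thresholds$min_typed_loci) "inconclusive"
  else if (n_mix >= thresholds$mixture_min_loci) "mixture"
  else "single_source"
  strong <- NULL
  if (category == "mixture" && nrow(evidence$calls) &&
      !anyNA(evidence$calls$height)) {
    strong <- extract_major_contributor(evidence, thresholds, panel)
  }
  structure(list(category = category, typed_loci = typed,
                 mixture_loci = as.integer(n_mix),
                 strong_contributor = strong),
            class = "profile_classification")
}

#' @export
print.profile_classification <- function(x, ...) {
  cat(sprintf("classification: %s (%d typed loci, %d loci with >2 signals)%s\n",
              x$category, x$typed_loci, x$mixture_loci,
              if (!is.null(x$strong_contributor)) "; strong contributor found"
              else ""))
  invisible(x)
}

#' Extract the major contributor of a mixture by the 3:1 rule
#'
#' At each typed autosomal locus the one or two tallest alleles are taken
#' as the putative major contribution. The locus passes when the shortest
#' selected peak is at least \code{major_ratio} times the tallest
#' unselected peak. Selection is adaptive: a pair of peaks is preferred
#' (a diploid contributor carries up to two alleles), falling back to the
#' single tallest peak when only that dominates — so a homozygous major
#' over a distinct minor allele is recovered as one allele. Loci with a
#' single called allele pass trivially; two-allele loci where neither peak
#' dominates pass with both alleles selected. The major profile is returned
#' only when every typed locus passes.
#'
#' Height ties are broken by allele designation (lexicographic) so the
#' extraction is deterministic; the result is invariant to rescaling all
#' heights by a positive constant.
#'
#' @param evidence An \code{str_profile}; every call must carry a height.
#' @param thresholds A \code{\link{classification_thresholds}} object.
#' @param panel Locus panel.
#' @return An \code{str_profile} restricted to the selected major alleles
#'   (autosomal loci only), or \code{NULL} when some typed locus fails the
#'   ratio rule.
#' @export
extract_major_contributor <- function(evidence,
                                      thresholds = classification_thresholds(),
                                      panel = fusion6c_panel()) {
  stopifnot(inherits(evidence, "str_profile"))
  aut <- panel_loci(panel, "autosomal")
  calls <- evidence$calls[evidence$calls$locus %in% aut, , drop = FALSE]
  if (!nrow(calls)) return(NULL)
  if (anyNA(calls$height))
    stop("major-contributor extraction needs a height on every call")
  R <- thresholds$major_ratio
  sel <- lapply(split(calls, calls$locus), function(lc) {
    lc <- lc[order(-lc$height, lc$allele), , drop = FALSE]
    n <- nrow(lc)
    h <- lc$height
    if (n == 1L) return(lc)
    if (n == 2L) {
      # lone dominant peak reads as a homozygous major over a minor allele
      if (h[1] >= R * h[2]) return(lc[1, , drop = FALSE])
      return(lc)
    }
    if (h[2] >= R * h[3]) return(lc[1:2, , drop = FALSE])
    if (h[1] >= R * h[2]) return(lc[1, , drop = FALSE])
    NULL  # locus fails the rule
  })
  if (any(vapply(sel, is.null, logical(1)))) return(NULL)
  str_profile(paste0(evidence$sample_id, "_major"),
              do.call(rbind, sel), sex = evidence$sex, panel = panel)
}
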